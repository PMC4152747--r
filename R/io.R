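#' Read a chromosome-measurement table
#'
#' Reads a UTF-8 CSV with header columns `plate_id`, `accession_id`,
#' `chromosome_label`, `arm1`, `arm2` (arm lengths in micrometres; dot
#' decimal). Arm order in input files is not trusted: rows are
#' canonicalised so `short_arm <= long_arm` at read time.
#'
#' @param path path to the CSV file.
#' @return a list of metaphase plates (one per `plate_id`, in order of
#'   first appearance): data frames with columns `plate_id`,
#'   `accession_id`, `chromosome_label`, `short_arm`, `long_arm`.
#' @export
read_measurements <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("plate_id", "accession_id", "chromosome_label", "arm1", "arm2")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("measurement table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(d) == 0L) return(list())
  bad <- which(!is.finite(d$arm1) | !is.finite(d$arm2) | d$arm1 <= 0 | d$arm2 <= 0)
  if (length(bad))
    stop("non-positive or non-numeric arm length at data row(s): ",
         paste(bad, collapse = ", "))
  d$short_arm <- pmin(d$arm1, d$arm2)
  d$long_arm  <- pmax(d$arm1, d$arm2)
  d$arm1 <- d$arm2 <- NULL
  ids <- unique(d$plate_id)
  plates <- lapply(ids, function(id) {
    p <- d[d$plate_id == id, , drop = FALSE]
    rownames(p) <- NULL
    p
  })
  names(plates) <- ids
  plates
}

#' Write a chromosome-measurement table
#'
#' Inverse of [read_measurements()]; writes canonical arms as
#' `arm1 = short_arm`, `arm2 = long_arm` so a round trip is the identity.
#'
#' @param plates list of plate data frames.
#' @param path output CSV path.
#' @export
write_measurements <- function(plates, path) {
  d <- do.call(rbind, lapply(plates, function(p)
    data.frame(plate_id = p$plate_id, accession_id = p$accession_id,
               chromosome_label = p$chromosome_label,
               arm1 = p$short_arm, arm2 = p$long_arm,
               stringsAsFactors = FALSE)))
  utils::write.csv(d, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read Feulgen densitometry readings
#'
#' CSV columns: `accession_id`, `role` (`"sample"` or `"standard"`),
#' `reading_au` (arbitrary absorbance units, positive).
#'
#' @param path path to the CSV file.
#' @return list of `densitometry_batch` objects, one per
#'   `(accession_id, role)` pair, each with fields `accession_id`, `role`,
#'   `readings`, `n_nuclei`.
#' @export
read_densitometry <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("accession_id", "role", "reading_au")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("densitometry table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(d) == 0L) return(list())
  bad_role <- which(!d$role %in% c("sample", "standard"))
  if (length(bad_role))
    stop("role must be 'sample' or 'standard' at data row(s): ",
         paste(bad_role, collapse = ", "))
  bad <- which(!is.finite(d$reading_au) | d$reading_au <= 0)
  if (length(bad))
    stop("non-positive reading_au at data row(s): ", paste(bad, collapse = ", "))
  key <- paste(d$accession_id, d$role, sep = "\r")
  keys <- unique(key)
  out <- lapply(keys, function(k) {
    rows <- d[key == k, , drop = FALSE]
    densitometry_batch(rows$accession_id[1], rows$role[1], rows$reading_au)
  })
  names(out) <- vapply(out, function(b) paste(b$accession_id, b$role, sep = ":"),
                       character(1))
  out
}

#' Construct a densitometry batch
#'
#' @param accession_id accession identifier.
#' @param role `"sample"` or `"standard"`.
#' @param readings positive arbitrary-unit absorbance values, one per
#'   nucleus.
#' @return object of class `densitometry_batch`.
#' @export
densitometry_batch <- function(accession_id, role = c("sample", "standard"),
                               readings) {
  role <- match.arg(role)
  if (length(readings) < 1L || any(!is.finite(readings)) || any(readings <= 0))
    stop("readings must be a non-empty vector of positive values")
  structure(list(accession_id = accession_id, role = role,
                 readings = as.numeric(readings),
                 n_nuclei = length(readings)),
            class = "densitometry_batch")
}

#' Write densitometry batches to CSV
#'
#' @param batches list of `densitometry_batch` objects.
#' @param path output CSV path.
#' @export
write_densitometry <- function(batches, path) {
  d <- do.call(rbind, lapply(batches, function(b)
    data.frame(accession_id = b$accession_id, role = b$role,
               reading_au = b$readings, stringsAsFactors = FALSE)))
  utils::write.csv(d, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a species summary table
#'
#' Tab-separated output mirroring the conventional column order of
#' published karyotype/genome-size summaries: species, 2n, 2C, 1Cx, CI_S,
#' CI_L, A1, A2, M_CA, CV_CL, CV_S, formula.
#'
#' @param records data frame in the layout of [hippeastrum_species()].
#' @param path output TSV path.
#' @export
write_species_summary <- function(records, path) {
  cols <- c("species", "n2", "c2_pg", "c1x_pg", "ci_s", "ci_l",
            "a1", "a2", "m_ca", "cv_cl", "cv_s", "formula")
  out <- records[, intersect(cols, names(records)), drop = FALSE]
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
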