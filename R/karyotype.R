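#' Construct a haploid-complement karyotype
#'
#' Builds a `karyotype` object from per-chromosome arm lengths of one
#' haploid complement, ordered by decreasing total length, with relative
#' lengths normalised to sum to 100, centromeric indices, Levan morphology
#' classes and a short/long bimodal partition.
#'
#' @param short_arm,long_arm numeric vectors of arm lengths (any common
#'   unit; only ratios matter). Pairs are canonicalised so that
#'   `short_arm <= long_arm`.
#' @param ploidy integer ploidy level (multiples of the basic number).
#' @param accession_id optional accession identifier.
#' @param method bimodal partition method, `"fixed_count"` or
#'   `"largest_gap"`. Default: `"fixed_count"` with `n_short = 4` when the
#'   basic number is 11 (the Hippeastrum case), otherwise `"largest_gap"`.
#' @param n_short number of short chromosomes for `"fixed_count"`.
#' @param boundary_tolerance relative half-width of the compound-class band
#'   around each Levan boundary (see [classify_levan()]).
#' @return a data frame of class `karyotype` with columns `short_arm`,
#'   `long_arm` (rescaled so total length sums to 100), `relative_length`,
#'   `ci`, `arm_ratio`, `class`, `subset`, plus attributes `ploidy`, `x`,
#'   `accession_id`, `n_short`, `bimodal_method`, `boundary_tolerance`.
#' @examples
#' k <- karyotype(short_arm = c(2, 2, 1, 1), long_arm = c(5, 4, 1.2, 1))
#' karyotype_metrics(k)
#' @export
karyotype <- function(short_arm, long_arm, ploidy = 2L, accession_id = NA_character_,
                      method = NULL, n_short = NULL, boundary_tolerance = 0.05) {
  if (length(short_arm) != length(long_arm) || length(short_arm) < 1L)
    stop("short_arm and long_arm must be non-empty vectors of equal length")
  if (any(!is.finite(short_arm)) || any(!is.finite(long_arm)))
    stop("arm lengths must be finite")
  s <- pmin(short_arm, long_arm)
  l <- pmax(short_arm, long_arm)
  if (any(s <= 0)) stop("all arm lengths must be positive")
  x <- length(s)
  total <- s + l
  o <- order(total, decreasing = TRUE)
  s <- s[o]; l <- l[o]; total <- total[o]
  # scale-free: express arms so that total complement length is 100
  f <- 100 / sum(total)
  s <- s * f; l <- l * f; total <- total * f

  subset <- rep("long", x)
  if (x > 1L) {
    if (is.null(method)) {
      if (x == 11L) { method <- "fixed_count"; if (is.null(n_short)) n_short <- 4L }
      else method <- "largest_gap"
    }
    part <- bimodal_partition(total, method = method, n_short = n_short)
    subset[part$short] <- "short"
  } else {
    method <- NA_character_        # partition disabled for a single chromosome
  }

  r <- l / s
  k <- data.frame(
    chromosome      = seq_len(x),
    short_arm       = s,
    long_arm        = l,
    relative_length = total,
    ci              = centromeric_index(s, l),
    arm_ratio       = r,
    class           = classify_levan(r, boundary_tolerance = boundary_tolerance),
    subset          = subset,
    stringsAsFactors = FALSE
  )
  structure(k,
            class = c("karyotype", "data.frame"),
            ploidy = as.integer(ploidy), x = x,
            accession_id = accession_id,
            n_short = sum(subset == "short"),
            bimodal_method = method,
            boundary_tolerance = boundary_tolerance)
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf("Haploid-complement karyotype: x = %d, ploidy = %d%s\n",
              attr(x, "x"), attr(x, "ploidy"),
              if (!is.na(attr(x, "accession_id")))
                paste0(" (", attr(x, "accession_id"), ")") else ""))
  cat(sprintf("Formula: %s\n", karyotype_formula(x)))
  print.data.frame(cbind(x[, c("chromosome", "subset", "class")],
                         round(x[, c("relative_length", "ci", "arm_ratio")], 2)),
                   row.names = FALSE)
  invisible(x)
}

#' Average metaphase plates into a haploid-complement karyotype
#'
#' Within each plate, chromosomes are sorted by decreasing total length and
#' each plate is rescaled to unit total length (removing condensation-stage
#' differences between metaphases). Arms are then position-averaged across
#' plates into `ploidy * x` mean chromosomes, and homologous copies (runs of
#' `ploidy` consecutive ranks) are averaged into the `x` chromosomes of one
#' haploid complement. Homolog pairing is by length rank, as in standard
#' measurement software; arms are averaged first and the centromeric index
#' derived from the averaged arms.
#'
#' @param plates a list of metaphase plates as returned by
#'   [read_measurements()] or [simulate_metaphases()]: data frames with
#'   columns `short_arm` and `long_arm` (one row per chromosome).
#' @param ploidy integer ploidy level.
#' @param x basic chromosome number; each plate must hold `ploidy * x`
#'   chromosomes.
#' @param ... passed to [karyotype()] (partition method, tolerance, ...).
#' @return a [karyotype()] object.
#' @export
average_karyotype <- function(plates, ploidy, x, ...) {
  if (length(plates) < 1L) stop("at least one metaphase plate is required")
  n2 <- ploidy * x
  counts <- vapply(plates, nrow, integer(1))
  if (length(unique(counts)) != 1L)
    stop("plates have differing chromosome counts: ", paste(unique(counts), collapse = ", "))
  if (counts[1] != n2)
    stop(sprintf("each plate must hold ploidy * x = %d chromosomes, found %d", n2, counts[1]))

  arms <- lapply(plates, function(p) {
    s <- pmin(p$short_arm, p$long_arm)
    l <- pmax(p$short_arm, p$long_arm)
    if (any(s <= 0)) stop("non-positive arm length in plate")
    tot <- s + l
    o <- order(tot, decreasing = TRUE)
    cbind(s[o], l[o]) / sum(tot)           # per-plate scale normalisation
  })
  s_bar <- rowMeans(vapply(arms, function(a) a[, 1], numeric(n2)))
  l_bar <- rowMeans(vapply(arms, function(a) a[, 2], numeric(n2)))

  # collapse runs of `ploidy` consecutive ranks (homologous copies)
  grp <- rep(seq_len(x), each = ploidy)
  s_hap <- tapply(s_bar, grp, mean)
  l_hap <- tapply(l_bar, grp, mean)
  acc <- if (!is.null(plates[[1]]$accession_id)) as.character(plates[[1]]$accession_id[1]) else NA_character_
  karyotype(as.numeric(s_hap), as.numeric(l_hap), ploidy = ploidy,
            accession_id = acc, ...)
}
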