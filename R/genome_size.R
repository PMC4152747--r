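#' Calibrate Feulgen arbitrary units to a 2C value in picograms
#'
#' Converts mean absorbance of a sample batch to DNA mass through an
#' internal standard of known 2C value measured under the same conditions:
#' `C2 = standard_2c_pg * mean(sample AU) / mean(standard AU)`. The
#' default standard is *Allium cepa* 'Ailsa Craig' with 2C = 33.55 pg.
#' The standard error is propagated from the sample readings only (delta
#' method on the sample mean; the standard mean is treated as a fixed
#' calibration constant, as is conventional when per-accession SEs are
#' reported).
#'
#' @param sample,standard [densitometry_batch()] objects with roles
#'   `"sample"` and `"standard"` respectively.
#' @param standard_2c_pg 2C DNA amount of the standard in pg.
#' @return object of class `genome_size_estimate`: list with
#'   `accession_id`, `c2_pg`, `c2_se`, `n_nuclei`.
#' @examples
#' s <- densitometry_batch("acc1", "sample", c(98, 101, 103))
#' st <- densitometry_batch("std", "standard", c(100, 100.5, 99.5))
#' calibrate_2c(s, st)
#' @export
calibrate_2c <- function(sample, standard, standard_2c_pg = 33.55) {
  stopifnot(inherits(sample, "densitometry_batch"),
            inherits(standard, "densitometry_batch"))
  if (sample$role != "sample" || standard$role != "standard")
    stop("batch roles must be 'sample' and 'standard'")
  m_std <- mean(standard$readings)
  if (!is.finite(m_std) || m_std <= 0) stop("standard mean must be positive")
  k <- standard_2c_pg / m_std
  n <- sample$n_nuclei
  c2 <- k * mean(sample$readings)
  se <- if (n > 1) k * stats::sd(sample$readings) / sqrt(n) else NA_real_
  structure(list(accession_id = sample$accession_id,
                 c2_pg = c2, c2_se = se, n_nuclei = n),
            class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf("2C = %.2f pg (SE %.3f, n = %d nuclei)%s\n",
              x$c2_pg, x$c2_se, x$n_nuclei,
              if (!is.na(x$accession_id)) paste0(" [", x$accession_id, "]") else ""))
  invisible(x)
}

# round half away from zero (report convention; `round()` rounds half to even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' DNA amount per basic genome (1Cx)
#'
#' 1Cx = 2C / ploidy, reported at 2 decimals with half-away-from-zero
#' rounding (the convention of published C-value tables).
#'
#' @param c2_pg 2C DNA amount in pg.
#' @param ploidy integer ploidy level, >= 1.
#' @param digits decimals for the reported value; `NA` returns the
#'   unrounded quotient.
#' @return 1Cx in pg.
#' @examples
#' one_cx(64.67, 6) # 10.78
#' @export
one_cx <- function(c2_pg, ploidy, digits = 2) {
  if (any(ploidy < 1)) stop("ploidy must be >= 1")
  v <- c2_pg / ploidy
  if (is.na(digits)) v else round_half_up(v, digits)
}

#' Genome downsizing across ploidy levels
#'
#' Per-ploidy unweighted species means of 1Cx, then the percent decrease
#' between consecutive ploidy levels in ascending order:
#' `100 * (mean_from - mean_to) / mean_from`. A positive value is genome
#' downsizing (less DNA per basic genome at the higher ploidy).
#'
#' @param records data frame with columns `ploidy` and `c1x_pg` (layout of
#'   [hippeastrum_species()]); rows with `NA` 1Cx are dropped.
#' @return data frame with one row per consecutive ploidy step: columns
#'   `from_ploidy`, `to_ploidy`, `mean_1cx_from`, `mean_1cx_to`,
#'   `percent_decrease`.
#' @examples
#' downsizing_table(hippeastrum_species())
#' @export
downsizing_table <- function(records) {
  d <- records[!is.na(records$c1x_pg) & !is.na(records$ploidy), , drop = FALSE]
  levels <- sort(unique(d$ploidy))
  if (length(levels) < 2L) stop("need at least 2 distinct ploidy levels")
  m <- vapply(levels, function(p) mean(d$c1x_pg[d$ploidy == p]), numeric(1))
  k <- length(levels) - 1L
  data.frame(
    from_ploidy = levels[seq_len(k)],
    to_ploidy = levels[seq_len(k) + 1L],
    mean_1cx_from = m[seq_len(k)],
    mean_1cx_to = m[seq_len(k) + 1L],
    percent_decrease = 100 * (m[seq_len(k)] - m[seq_len(k) + 1L]) / m[seq_len(k)]
  )
}
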