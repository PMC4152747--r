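#' Bimodal 11-chromosome karyotype template
#'
#' A haploid-complement template with the canonical Hippeastrum structure:
#' x = 11, four short near-metacentric chromosomes (CI ~45, together ~24 %
#' of complement length) and seven long chromosomes. `asymmetry_level`
#' moves the mean long-set centromeric index across the observed diploid
#' span: ~26 (`"low"` asymmetry), ~23 (`"mid"`), ~20 (`"high"`).
#'
#' @param asymmetry_level `"low"`, `"mid"` or `"high"`.
#' @return object of class `karyotype_template`: data frame with columns
#'   `relative_length` (%, summing to 100) and `ci` (%), attributes `x`
#'   and `n_short`.
#' @examples
#' karyotype_metrics(template_karyotype(hippeastrum_template("mid")))
#' @export
hippeastrum_template <- function(asymmetry_level = c("mid", "low", "high")) {
  asymmetry_level <- match.arg(asymmetry_level)
  rl <- c(12.4, 11.6, 11.2, 10.8, 10.4, 10.0, 9.6,   # 7 long
          6.6, 6.2, 5.8, 5.4)                        # 4 short, sum 24
  ci_long <- switch(asymmetry_level,
                    low  = c(21, 23, 25, 26, 27, 29, 31),
                    mid  = c(18, 20, 22, 23, 24, 26, 28),
                    high = c(15, 17, 19, 20, 21, 23, 25))
  ci <- c(ci_long, rep(45, 4))
  structure(data.frame(relative_length = rl, ci = ci),
            x = 11L, n_short = 4L, asymmetry_level = asymmetry_level,
            class = c("karyotype_template", "data.frame"))
}

#' Karyotype object from a template (noise-free)
#'
#' @param template a `karyotype_template` (columns `relative_length`,
#'   `ci`; attribute `n_short`).
#' @param ploidy ploidy recorded on the result.
#' @param ... passed to [karyotype()].
#' @return a [karyotype()] object with the template's exact geometry.
#' @export
template_karyotype <- function(template, ploidy = 2L, ...) {
  s <- template$relative_length * template$ci / 100
  l <- template$relative_length - s
  karyotype(s, l, ploidy = ploidy,
            n_short = attr(template, "n_short"),
            method = if (!is.null(attr(template, "n_short"))) "fixed_count" else NULL,
            ...)
}

#' Simulate metaphase plates from a karyotype template
#'
#' Each plate receives a lognormal condensation factor (metaphases differ
#' in overall contraction) and every arm of every chromosome copy a
#' multiplicative measurement error: `arm = template_arm * plate_factor *
#' (1 + e)`, `e ~ N(0, arm_cv)`. Error is length-proportional, as
#' microscopy measurement error is. Plates hold `ploidy * x` chromosomes
#' (homolog copies are unlabelled, as in real measurement tables).
#'
#' @param template a `karyotype_template`.
#' @param ploidy integer ploidy.
#' @param k_plates number of plates (a study would use at least 5).
#' @param plate_scale_sd lognormal sigma of the per-plate scale factor.
#' @param arm_cv fractional SD of per-arm multiplicative noise.
#' @param seed integer seed; the output is a pure function of arguments
#'   and seed.
#' @param accession_id identifier stamped on the plates.
#' @return list of plate data frames compatible with
#'   [average_karyotype()] and [write_measurements()].
#' @export
simulate_metaphases <- function(template, ploidy = 2L, k_plates = 5L,
                                plate_scale_sd = 0.1, arm_cv = 0.03,
                                seed = 1L, accession_id = "sim") {
  if (k_plates < 1L) stop("k_plates must be >= 1")
  if (arm_cv < 0 || plate_scale_sd < 0) stop("noise parameters must be >= 0")
  set.seed(seed)
  x <- nrow(template)
  s0 <- rep(template$relative_length * template$ci / 100, each = ploidy)
  l0 <- rep(template$relative_length, each = ploidy) - s0
  n2 <- ploidy * x
  lapply(seq_len(k_plates), function(p) {
    f <- exp(stats::rnorm(1, 0, plate_scale_sd))
    s <- s0 * f * (1 + stats::rnorm(n2, 0, arm_cv))
    l <- l0 * f * (1 + stats::rnorm(n2, 0, arm_cv))
    data.frame(plate_id = sprintf("%s_p%02d", accession_id, p),
               accession_id = accession_id,
               chromosome_label = sprintf("c%02d", seq_len(n2)),
               short_arm = pmin(s, l), long_arm = pmax(s, l),
               stringsAsFactors = FALSE)
  })
}

#' Simulate Feulgen densitometry batches
#'
#' Sample and standard nuclei share an arbitrary-units-per-picogram
#' factor; readings are normal with mean proportional to the true 2C and
#' fractional SD `cv` (means over many nuclei are near-normal, matching
#' the SE formula used in calibration).
#'
#' @param true_2c_pg true 2C of the sample, pg.
#' @param n_nuclei sample nuclei count (published designs use 25-50).
#' @param cv fractional SD of individual readings (>= 0).
#' @param standard_2c_pg true 2C of the calibration standard, pg.
#' @param standard_n standard nuclei count.
#' @param au_per_pg arbitrary-unit scale factor (cancels in calibration).
#' @param seed integer seed.
#' @param accession_id sample identifier.
#' @return list with `sample` and `standard` [densitometry_batch()]s.
#' @examples
#' b <- simulate_densitometry(30, n_nuclei = 40, cv = 0.05, seed = 1)
#' calibrate_2c(b$sample, b$standard)
#' @export
simulate_densitometry <- function(true_2c_pg, n_nuclei = 40L, cv = 0.05,
                                  standard_2c_pg = 33.55, standard_n = 30L,
                                  au_per_pg = 10, seed = 1L,
                                  accession_id = "sim") {
  if (cv < 0) stop("cv must be >= 0")
  set.seed(seed)
  draw <- function(mu, n) {
    r <- stats::rnorm(n, mu, cv * mu)
    pmax(r, mu * 1e-6)                  # AU readings are positive
  }
  list(sample = densitometry_batch(accession_id, "sample",
                                   draw(true_2c_pg * au_per_pg, n_nuclei)),
       standard = densitometry_batch("standard", "standard",
                                     draw(standard_2c_pg * au_per_pg, standard_n)))
}

#' Simulate a replicate 1Cx study from a species summary
#'
#' Draws per-species normal replicates around the recorded 1Cx means with
#' SD = `cv * mean`, the input shape expected by [lsd_letters()].
#'
#' @param records data frame with `species`, `ploidy`, `c1x_pg` columns
#'   (rows with `NA` 1Cx are dropped).
#' @param n_per_species replicates per species (>= 2).
#' @param cv fractional SD of replicates.
#' @param seed integer seed.
#' @return data frame with columns `species`, `ploidy`, `c1x`.
#' @export
simulate_study <- function(records, n_per_species = 30L, cv = 0.03, seed = 1L) {
  if (n_per_species < 2L) stop("n_per_species must be >= 2")
  d <- records[!is.na(records$c1x_pg), , drop = FALSE]
  set.seed(seed)
  out <- lapply(seq_len(nrow(d)), function(i) {
    data.frame(species = d$species[i], ploidy = d$ploidy[i],
               c1x = stats::rnorm(n_per_species, d$c1x_pg[i], cv * d$c1x_pg[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
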