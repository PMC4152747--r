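#' Published Hippeastrum species summary (18 accessions, 2x-6x)
#'
#' Chromosome numbers, Feulgen genome sizes and karyotype parameters for
#' the 18 *Hippeastrum* accessions with both a 2C value and a ploidy
#' determination: 9 diploids, 1 triploid, 4 tetraploids, 3 pentaploids and
#' 1 hexaploid, all with basic number x = 11. Values are as printed in the
#' source summary (2C and 1Cx in pg with standard errors; centromeric
#' indices and asymmetry indices; karyotype formula strings; letters from
#' the published Fisher-LSD compact letter display on 1Cx).
#'
#' Known internal inconsistency, preserved as printed: for *H. cybister*
#' (5x) the printed 2C/ploidy = 56.35/5 = 11.27 pg disagrees with the
#' printed 1Cx of 11.20 pg. The row is flagged via the `c1x_consistent`
#' column rather than silently corrected.
#'
#' @return data frame with one row per accession and columns `species`,
#'   `ploidy`, `n2` (2n), `c2_pg`, `c2_se`, `c1x_pg`, `c1x_se`, `letter`,
#'   `ci_s`, `ci_l`, `a1`, `a2`, `m_ca`, `cv_cl`, `cv_s`, `formula`
#'   (karyotype parameters are `NA` for the four accessions published
#'   without them), and `c1x_consistent`.
#' @examples
#' sp <- hippeastrum_species()
#' range(sp$c2_pg[sp$ploidy == 2])
#' @export
hippeastrum_species <- function() {
  d <- data.frame(
    species = c("H. machupijchense", "H. solandriflorum", "H. psittacinum",
                "H. evansiae", "H. tucumanum", "H. parodii", "H. correiense",
                "H. rutilum 2x", "H. morelianum", "H. puniceum 3x",
                "H. reginae", "H. rutilum 4x", "H. starkii", "H. blossfeldiae",
                "H. scopulorum", "H. rutilum 5x", "H. cybister",
                "H. puniceum 6x"),
    ploidy = c(rep(2L, 9), 3L, rep(4L, 4), rep(5L, 3), 6L),
    c2_pg = c(34.17, 33.77, 31.34, 30.92, 30.64, 30.21, 29.05, 27.98, 26.80,
              38.69, 52.79, 48.93, 47.19, 46.04, 58.71, 58.20, 56.35, 64.67),
    c2_se = c(0.20, 0.50, 0.23, 0.28, 0.17, 0.23, 0.25, 0.28, 0.19,
              0.48, 0.30, 0.37, 0.30, 0.29, 0.26, 0.42, 0.38, 0.41),
    c1x_pg = c(17.08, 16.88, 15.67, 15.46, 15.32, 15.11, 14.53, 13.99, 13.40,
               12.90, 13.20, 12.23, 11.80, 11.51, 11.74, 11.64, 11.20, 10.78),
    c1x_se = c(0.10, 0.25, 0.12, 0.14, 0.09, 0.11, 0.13, 0.14, 0.09,
               0.16, 0.08, 0.09, 0.08, 0.07, 0.05, 0.10, 0.11, 0.07),
    letter = c("A", "AB", "E", "EF", "FG", "G", "H", "I", "J",
               "K", "J", "L", "M", "N", "M", "MN", "O", "P"),
    ci_s = c(42.42, 42.48, 45.85, 46.87, 43.20, 42.46, 45.58, 45.10, 43.75,
             44.76, NA, 42.63, NA, 42.85, NA, 45.26, 45.23, 44.88),
    ci_l = c(26.17, 24.39, 25.37, 23.83, 24.89, 23.27, 22.78, 22.38, 19.99,
             23.97, NA, 23.23, NA, 23.18, NA, 24.37, 23.15, 34.10),
    a1 = c(0.50, 0.51, 0.48, 0.47, 0.50, 0.52, 0.51, 0.51, 0.55,
           0.49, NA, 0.54, NA, 0.53, NA, 0.49, 0.50, 0.42),
    a2 = c(0.30, 0.31, 0.32, 0.32, 0.31, 0.29, 0.29, 0.31, 0.32,
           0.30, NA, 0.32, NA, 0.32, NA, 0.29, 0.30, 0.33),
    m_ca = c(NA, 36.00, NA, 36.08, 39.24, 37.04, 35.46, 33.57, 37.39,
             31.88, NA, 39.75, NA, 39.30, NA, 35.62, 37.55, 28.61),
    cv_cl = c(30.56, 31.03, 32.03, 32.20, 31.01, 29.20, 29.04, 31.03, 32.08,
              30.33, NA, 32.02, NA, 32.01, NA, 29.02, 30.04, 33.01),
    cv_s = c(23.65, 23.59, 24.85, 23.24, 24.90, 23.91, 24.44, 23.97, 23.21,
             24.14, NA, 23.14, NA, 23.05, NA, 24.69, 25.01, 25.12),
    formula = c("[4m] + 4sm + 3st",
                "[4m] + 4sm + 1sm–st + 2st",
                "[4m] + 3sm + 1sm–st + 3st",
                "[4m] + 3sm + 1sm–st + 2st + 1st–t",
                "[4m] + 3sm + 1sm–st + 3st",
                "[4m] + 3sm + 1sm–st + 3st",
                "[4m] + 2sm + 2sm–st + 1st + 2t",
                "[4m] + 2sm + 1sm–st + 3st + 1t",
                "[4m] + 2sm + 1sm–st + 2st + 2t",
                "[4m] + 1sm + 3sm–st + 2st + 1t",
                NA,
                "[3m + 1m–sm] + 1sm + 2sm–st + 3st + 1t",
                NA,
                "[3m + 1m–sm] + 2sm + 1sm–st + 3st + 1t",
                NA,
                "[4m] + 3sm–st + 4st",
                "[4m] + 1sm + 3sm–st + 3st",
                "4m + 3sm + 3sm–st + 1st"),
    stringsAsFactors = FALSE
  )
  d$n2 <- 11L * d$ploidy
  d$c1x_consistent <- abs(d$c2_pg / d$ploidy - d$c1x_pg) <= 0.01
  d
}
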