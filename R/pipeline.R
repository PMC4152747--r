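#' Run the full karyotype / genome-size analysis pipeline
#'
#' Wires the stages together for a directory of outputs: species summary
#' (TSV, published column order), downsizing table (TSV), 2C-on-ploidy fit
#' with its 1Cx hyperbola (JSON), optional LSD letter table from a
#' replicate study, optional figures, and a provenance block recording the
#' configuration, seed and package version. Deterministic under a fixed
#' configuration and seed.
#'
#' @param output_dir directory to write into (created if absent).
#' @param records species summary data frame; default
#'   [hippeastrum_species()].
#' @param measurements_csv optional measurement CSV; when given, karyotype
#'   parameters are recomputed from the measurements per accession and a
#'   `measured_metrics.tsv` is written (requires `ploidy_map`, a named
#'   vector of ploidy per accession).
#' @param ploidy_map named integer vector, accession -> ploidy, for
#'   `measurements_csv`.
#' @param replicates optional replicate table (columns `species`, `c1x`)
#'   for the ANOVA/LSD stage.
#' @param x basic chromosome number.
#' @param alpha LSD significance level.
#' @param boundary_tolerance compound-class band width for classification.
#' @param weights `"equal"` or a numeric vector for the regression.
#' @param seed integer recorded in provenance (stages here are
#'   deterministic; the seed matters when generators feed the pipeline).
#' @param plots write PDF figures.
#' @return invisibly, a list with `summary`, `downsizing`, `fit`,
#'   `letters` (or NULL), `files`.
#' @export
run_full_pipeline <- function(output_dir,
                              records = hippeastrum_species(),
                              measurements_csv = NULL, ploidy_map = NULL,
                              replicates = NULL,
                              x = 11L, alpha = 0.05,
                              boundary_tolerance = 0.05,
                              weights = "equal", seed = 1L, plots = FALSE) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  summary_path <- file.path(output_dir, "species_summary.tsv")
  write_species_summary(records, summary_path)
  files <- c(files, summary_path)

  ds <- downsizing_table(records)
  ds_path <- file.path(output_dir, "downsizing.tsv")
  utils::write.table(cbind(ds[1:4], percent_decrease = round_half_up(ds$percent_decrease, 2)),
                     ds_path, sep = "\t", row.names = FALSE, quote = FALSE)
  files <- c(files, ds_path)

  w <- if (identical(weights, "equal")) NULL else weights
  fit <- fit_2c_on_ploidy(records$ploidy, records$c2_pg, weights = w)
  dip_mean <- mean(records$c2_pg[records$ploidy == 2])
  fit_path <- file.path(output_dir, "ploidy_fit.json")
  jsonlite::write_json(list(
    intercept_pg = fit$coefficients[["intercept"]],
    slope_pg_per_x = fit$coefficients[["slope"]],
    r_squared = fit$r_squared,
    weights = fit$weights_used,
    n_accessions = nrow(fit$data),
    hyperbola = "1Cx(x) = intercept/x + slope",
    extrapolated_diploid_slope = dip_mean / 2
  ), fit_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, fit_path)

  metrics_tab <- NULL
  if (!is.null(measurements_csv)) {
    plates <- read_measurements(measurements_csv)
    accs <- unique(vapply(plates, function(p) as.character(p$accession_id[1]), character(1)))
    rows <- lapply(accs, function(a) {
      pl <- plates[vapply(plates, function(p) p$accession_id[1] == a, logical(1))]
      p_here <- if (!is.null(ploidy_map)) ploidy_map[[a]] else 2L
      k <- average_karyotype(pl, ploidy = p_here, x = x,
                             boundary_tolerance = boundary_tolerance)
      m <- karyotype_metrics(k)
      data.frame(accession = a, ploidy = p_here,
                 ci_s = m$CI_S, ci_l = m$CI_L, a1 = m$A1, a2 = m$A2,
                 m_ca = m$M_CA, cv_cl = m$CV_CL, cv_s = m$CV_S,
                 formula = m$formula, stringsAsFactors = FALSE)
    })
    metrics_tab <- do.call(rbind, rows)
    mt_path <- file.path(output_dir, "measured_metrics.tsv")
    utils::write.table(metrics_tab, mt_path, sep = "\t", row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
    files <- c(files, mt_path)
  }

  let <- NULL
  if (!is.null(replicates)) {
    let <- lsd_letters(replicates$c1x, replicates$species, alpha = alpha)
    let_path <- file.path(output_dir, "letters.tsv")
    utils::write.table(let$table, let_path, sep = "\t", row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
    files <- c(files, let_path)
  }

  if (plots) {
    f1 <- file.path(output_dir, "fit_2c_1cx.pdf")
    grDevices::pdf(f1, width = 9, height = 4.5)
    plot(fit, extrapolated = extrapolated_diploid_line(dip_mean))
    grDevices::dev.off()
    f2 <- file.path(output_dir, "asymmetry_vs_dna.pdf")
    plot_asymmetry_vs_dna(records, f2)
    files <- c(files, f1, f2)
  }

  prov_path <- file.path(output_dir, "provenance.json")
  jsonlite::write_json(list(
    package = "karyoploid",
    version = as.character(utils::packageVersion("karyoploid")),
    seed = seed, alpha = alpha, boundary_tolerance = boundary_tolerance,
    weights = if (is.null(w)) "equal" else "custom", x = x,
    n_records = nrow(records)
  ), prov_path, auto_unbox = TRUE)
  files <- c(files, prov_path)

  invisible(list(summary = records, downsizing = ds, fit = fit,
                 metrics = metrics_tab, letters = let, files = files))
}

#' Asymmetry indices against DNA content, per accession
#'
#' Bar-style figure: one bar per accession showing total 2C DNA with the
#' 1Cx portion filled black, with the M_CA and CV_CL asymmetry indices
#' overlaid as points on a secondary scale.
#'
#' @param records species summary rows with `c2_pg`, `c1x_pg`, `m_ca`,
#'   `cv_cl` (rows lacking asymmetry values are dropped).
#' @param file output PDF path.
#' @return invisibly, the data frame actually plotted (one row per bar) —
#'   useful for verifying the figure against its source table.
#' @export
plot_asymmetry_vs_dna <- function(records, file) {
  d <- records[!is.na(records$cv_cl) & !is.na(records$c2_pg), , drop = FALSE]
  if (nrow(d) == 0L) stop("no records with asymmetry values to plot")
  grDevices::pdf(file, width = max(6, nrow(d) * 0.6), height = 5)
  op <- graphics::par(mar = c(9, 4, 2, 4))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  bp <- graphics::barplot(d$c2_pg, names.arg = d$species, las = 2,
                          ylab = "DNA amount (pg)", col = "grey85",
                          cex.names = 0.7)
  graphics::barplot(d$c1x_pg, add = TRUE, col = "black", axes = FALSE)
  sc <- max(d$c2_pg) / 50                 # index scale: 0-50 onto bar axis
  graphics::points(bp, d$m_ca * sc, pch = 19, col = "red3")
  graphics::points(bp, d$cv_cl * sc, pch = 17, col = "blue3")
  graphics::axis(4, at = seq(0, 50, 10) * sc, labels = seq(0, 50, 10))
  graphics::mtext("asymmetry index", side = 4, line = 2.5)
  graphics::legend("topleft", pch = c(19, 17), col = c("red3", "blue3"),
                   legend = c("M_CA", "CV_CL"), bty = "n")
  invisible(d[, c("species", "c2_pg", "c1x_pg", "m_ca", "cv_cl")])
}
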