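#' Fit the 2C-vs-ploidy weighted least-squares line
#'
#' Regresses total DNA content (2C, pg) on ploidy level by weighted least
#' squares. Weighting by the number of nuclei measured per accession
#' compensates for unequal measurement effort; with equal weights the fit
#' reduces to ordinary least squares. Each accession contributes one point
#' (its mean 2C). The weighted coefficient of determination is
#' `R2 = 1 - SSE_w / SST_w` with `SST_w` taken about the weighted mean.
#'
#' @param ploidy numeric vector of ploidy levels (>= 2 distinct values,
#'   >= 3 points).
#' @param c2_pg 2C values in pg, parallel to `ploidy`.
#' @param weights optional positive weights (e.g. nuclei counts); `NULL`
#'   means equal weights.
#' @param data optional data frame supplying the columns named by `ploidy`
#'   and `c2_pg` when those are given as strings; usually omitted.
#' @return object of class `ploidy_fit`: list with `coefficients`
#'   (`intercept`, `slope`), `r_squared`, `weights_used` (`"equal"`,
#'   `"n_nuclei"` or `"custom"`), `fitted`, `residuals`, `data` and the
#'   underlying `lm` object (`fit`).
#' @examples
#' sp <- hippeastrum_species()
#' fit <- fit_2c_on_ploidy(sp$ploidy, sp$c2_pg)
#' coef(fit)
#' predict(fit, ploidy = 2:6)
#' @export
fit_2c_on_ploidy <- function(ploidy, c2_pg, weights = NULL, data = NULL) {
  if (!is.null(data)) {
    ploidy <- data[[ploidy]]
    c2_pg <- data[[c2_pg]]
  }
  if (length(ploidy) != length(c2_pg)) stop("ploidy and c2_pg lengths differ")
  ok <- is.finite(ploidy) & is.finite(c2_pg)
  ploidy <- ploidy[ok]; c2_pg <- c2_pg[ok]
  if (length(ploidy) < 3L) stop("need at least 3 points")
  if (length(unique(ploidy)) < 2L)
    stop("singular design: all ploidy values identical")
  label <- "equal"
  if (is.null(weights)) {
    w <- rep(1, length(ploidy))
  } else {
    w <- weights[ok]
    if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive")
    label <- "custom"
  }
  d <- data.frame(ploidy = ploidy, c2_pg = c2_pg, w = w)
  fit <- stats::lm(c2_pg ~ ploidy, data = d, weights = w)
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  ybar_w <- sum(w * c2_pg) / sum(w)
  r2 <- 1 - sum(w * res^2) / sum(w * (c2_pg - ybar_w)^2)
  structure(list(
    coefficients = c(intercept = unname(cf[1]), slope = unname(cf[2])),
    r_squared = r2,
    weights_used = label,
    fitted = stats::fitted(fit),
    residuals = stats::residuals(fit),
    data = d,
    fit = fit
  ), class = "ploidy_fit")
}

#' @export
print.ploidy_fit <- function(x, digits = 3, ...) {
  cf <- x$coefficients
  cat("2C-on-ploidy weighted least-squares fit\n")
  cat(sprintf("  2C = %.*f * ploidy + %.*f   (weights: %s)\n",
              digits, cf["slope"], digits, cf["intercept"], x$weights_used))
  cat(sprintf("  weighted R-squared: %.*f,  n = %d accessions\n",
              digits, x$r_squared, nrow(x$data)))
  invisible(x)
}

#' @export
summary.ploidy_fit <- function(object, ...) {
  s <- summary(object$fit)
  out <- list(coefficients = s$coefficients, r_squared = object$r_squared,
              weights_used = object$weights_used, n = nrow(object$data),
              hyperbola = sprintf("1Cx(x) = %.3f/x + %.3f",
                                  object$coefficients["intercept"],
                                  object$coefficients["slope"]))
  class(out) <- "summary.ploidy_fit"
  out
}

#' @export
print.summary.ploidy_fit <- function(x, ...) {
  cat("2C-on-ploidy fit (", x$weights_used, " weights, n = ", x$n, ")\n\n", sep = "")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("\nWeighted R-squared: %.4f\n", x$r_squared))
  cat("Derived 1Cx hyperbola:", x$hyperbola, "\n")
  invisible(x)
}

#' @export
coef.ploidy_fit <- function(object, ...) object$coefficients

#' @export
residuals.ploidy_fit <- function(object, ...) object$residuals

#' @export
fitted.ploidy_fit <- function(object, ...) object$fitted

#' @export
predict.ploidy_fit <- function(object, ploidy = NULL, ...) {
  if (is.null(ploidy)) return(object$fitted)
  cf <- object$coefficients
  unname(cf["intercept"] + cf["slope"] * ploidy)
}

#' @export
simulate.ploidy_fit <- function(object, nsim = 1, seed = NULL, ...)
  stats::simulate(object$fit, nsim = nsim, seed = seed, ...)

#' 1Cx-vs-ploidy hyperbola from a fitted line
#'
#' Rearranges the fitted line `2C(x) = a + b*x` into DNA per basic genome:
#' `1Cx(x) = 2C(x)/x = a/x + b`. For a positive intercept the curve
#' decreases monotonically towards the asymptote `b` — the signature of
#' genome downsizing levelling off at high ploidy.
#'
#' @param fit a `ploidy_fit` object.
#' @return a function of ploidy `x > 0` returning 1Cx in pg.
#' @examples
#' sp <- hippeastrum_species()
#' h <- hyperbola_from_fit(fit_2c_on_ploidy(sp$ploidy, sp$c2_pg))
#' h(2:6)
#' @export
hyperbola_from_fit <- function(fit) {
  stopifnot(inherits(fit, "ploidy_fit"))
  a <- fit$coefficients[["intercept"]]
  b <- fit$coefficients[["slope"]]
  function(x) {
    if (any(x <= 0)) stop("ploidy must be positive")
    a / x + b
  }
}

#' No-downsizing reference line extrapolated from diploids
#'
#' The line through the origin with slope equal to the diploid mean 1Cx:
#' `2C(x) = x * diploid_mean_2c / 2`. It models strict genome additivity —
#' each added genome copy contributing the full diploid 1Cx — and serves
#' as the reference against which the fitted line's gentler slope
#' demonstrates downsizing.
#'
#' @param diploid_mean_2c mean 2C of the diploids, pg.
#' @return a function of ploidy returning the extrapolated 2C.
#' @export
extrapolated_diploid_line <- function(diploid_mean_2c) {
  if (diploid_mean_2c <= 0) stop("diploid mean 2C must be positive")
  slope <- diploid_mean_2c / 2
  f <- function(x) x * slope
  attr(f, "slope") <- slope
  f
}

#' Plot a fitted 2C-on-ploidy model
#'
#' Two panels in the style of C-value/ploidy studies: observed 2C against
#' ploidy with the fitted line and (optionally) the diploid-extrapolated
#' reference, and the derived 1Cx hyperbola with per-ploidy observed 1Cx.
#'
#' @param x a `ploidy_fit` object.
#' @param extrapolated optional function from [extrapolated_diploid_line()].
#' @param which `1` (2C panel), `2` (1Cx panel) or `1:2`.
#' @param ... passed to `plot`.
#' @export
plot.ploidy_fit <- function(x, extrapolated = NULL, which = 1:2, ...) {
  d <- x$data
  if (length(which) > 1L) {
    op <- graphics::par(mfrow = c(1, length(which)))
    on.exit(graphics::par(op))
  }
  xs <- seq(min(d$ploidy), max(d$ploidy), length.out = 200)
  if (1 %in% which) {
    graphics::plot(d$ploidy, d$c2_pg, xlab = "ploidy level (x)",
                   ylab = "2C DNA (pg)", pch = 19, ...)
    graphics::abline(x$coefficients["intercept"], x$coefficients["slope"])
    if (!is.null(extrapolated))
      graphics::lines(xs, extrapolated(xs), lty = 2)
  }
  if (2 %in% which) {
    h <- hyperbola_from_fit(x)
    graphics::plot(d$ploidy, d$c2_pg / d$ploidy, xlab = "ploidy level (x)",
                   ylab = "1Cx DNA (pg)", pch = 19, ...)
    graphics::lines(xs, h(xs))
    if (!is.null(extrapolated))
      graphics::lines(xs, extrapolated(xs) / xs, lty = 2)
  }
  invisible(x)
}
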