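#' One-way fixed-effects ANOVA
#'
#' Classical one-way decomposition for comparing replicate genome-size
#' (or other) measurements across accessions, computed through `stats::lm`.
#'
#' @param values numeric replicate measurements.
#' @param groups group labels parallel to `values`; every group needs at
#'   least 2 replicates.
#' @return object of class `anova_oneway`: list with `F`, `df_between`,
#'   `df_within`, `MSE`, `p_value`, and per-group `means` and `ns`
#'   (in decreasing-mean order).
#' @examples
#' set.seed(1)
#' a <- anova_oneway(c(rnorm(5, 10), rnorm(5, 12)), rep(c("a", "b"), each = 5))
#' a$F
#' @export
anova_oneway <- function(values, groups) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) stop("values and groups lengths differ")
  ns <- table(groups)
  if (length(ns) < 2L) stop("need at least 2 groups")
  if (any(ns < 2L))
    stop("every group needs >= 2 replicates; offending group(s): ",
         paste(names(ns)[ns < 2], collapse = ", "))
  means <- tapply(values, groups, mean)
  o <- order(means, names(means), decreasing = c(TRUE, FALSE), method = "radix")
  k <- length(ns); N <- length(values)
  if (sum((values - mean(values))^2) == 0) {
    # no variance anywhere: define F = 0 rather than 0/0
    return(structure(list(F = 0, df_between = k - 1L, df_within = N - k,
                          MSE = 0, p_value = 1,
                          means = means[o],
                          ns = as.integer(ns[names(means)[o]])),
                     class = "anova_oneway"))
  }
  fit <- stats::lm(values ~ factor(groups))
  tab <- suppressWarnings(stats::anova(fit))
  F <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  if (!is.finite(F)) { F <- Inf; p <- 0 }   # zero within-group variance
  structure(list(F = F,
                 df_between = tab$Df[1],
                 df_within = tab$Df[2],
                 MSE = tab$`Mean Sq`[2],
                 p_value = p,
                 means = means[o],
                 ns = as.integer(ns[names(means)[o]])),
            class = "anova_oneway")
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.2f, MSE = %.4g, p = %.3g\n",
              x$df_between, x$df_within, x$F, x$MSE, x$p_value))
  invisible(x)
}

#' Fisher LSD pairwise significance matrix
#'
#' Unprotected least-significant-difference contrasts after a one-way
#' ANOVA: pair (i, j) is significant when
#' `|mean_i - mean_j| > t(1 - alpha/2, df_within) * sqrt(MSE * (1/n_i + 1/n_j))`.
#'
#' @param means named vector of group means.
#' @param ns group replicate counts, parallel to `means`.
#' @param MSE within-group mean square from the ANOVA.
#' @param df_within residual degrees of freedom (> 0).
#' @param alpha two-sided significance level, default 0.05.
#' @return symmetric logical matrix (`TRUE` = significantly different),
#'   diagonal `FALSE`, dimnames from `names(means)`.
#' @export
fisher_lsd <- function(means, ns, MSE, df_within, alpha = 0.05) {
  if (df_within <= 0) stop("df_within must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  k <- length(means)
  if (length(ns) != k) stop("means and ns lengths differ")
  tcrit <- stats::qt(1 - alpha / 2, df_within)
  diff <- abs(outer(means, means, "-"))
  lsd <- tcrit * sqrt(MSE * outer(1 / ns, 1 / ns, "+"))
  sig <- diff > lsd
  diag(sig) <- FALSE
  dimnames(sig) <- list(names(means), names(means))
  sig
}

#' Compact letter display from a pairwise significance matrix
#'
#' Insert-and-absorb letter assignment: groups sorted by descending mean
#' start in a single letter column; each significant pair splits every
#' column containing both members; columns that become subsets of another
#' are absorbed. The output satisfies the letter contract exactly: two
#' groups share at least one letter if and only if they are not
#' significantly different. Ties in means are broken by group label so the
#' display is deterministic.
#'
#' @param signif symmetric logical significance matrix (as from
#'   [fisher_lsd()]), with group dimnames.
#' @param means named vector of group means (defines letter order).
#' @param alpha significance level recorded in the result.
#' @return object of class `letter_display`: named character vector of
#'   letter strings (in decreasing-mean order) with attribute `alpha`.
#' @examples
#' m <- c(a = 10, b = 9.5, c = 1)
#' sig <- matrix(c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE,
#'                 TRUE, TRUE, FALSE), 3, dimnames = list(names(m), names(m)))
#' compact_letter_display(sig, m)
#' @export
compact_letter_display <- function(signif, means, alpha = 0.05) {
  g <- names(means)
  if (is.null(g)) g <- rownames(signif)
  if (is.null(g)) stop("group names required")
  stopifnot(nrow(signif) == length(g), isTRUE(all(signif == t(signif))))
  o <- order(-means, g, method = "radix")
  g <- g[o]
  sig <- signif[o, o, drop = FALSE]
  k <- length(g)

  cols <- list(seq_len(k))               # columns are index sets into g
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (!sig[i, j]) next
    newcols <- list()
    for (cset in cols) {
      if (i %in% cset && j %in% cset) {
        newcols <- c(newcols, list(setdiff(cset, i)), list(setdiff(cset, j)))
      } else newcols <- c(newcols, list(cset))
    }
    # absorb: drop duplicates and any column that is a proper subset of another
    newcols <- unique(lapply(newcols, sort))
    keep <- rep(TRUE, length(newcols))
    for (a in seq_along(newcols)) for (b in seq_along(newcols)) {
      if (a != b && keep[b] && length(newcols[[a]]) < length(newcols[[b]]) &&
          all(newcols[[a]] %in% newcols[[b]])) keep[a] <- FALSE
    }
    cols <- newcols[keep]
  }
  # order columns by their top-most (highest-mean) member, assign letters
  first <- vapply(cols, min, numeric(1))
  cols <- cols[order(first)]
  letters_used <- make_letter_labels(length(cols))
  out <- vapply(seq_len(k), function(i) {
    paste(letters_used[vapply(cols, function(cset) i %in% cset, logical(1))],
          collapse = "")
  }, character(1))
  names(out) <- g
  structure(out, alpha = alpha, class = "letter_display")
}

# a, b, ..., z, aa, ab, ... for > 26 columns
make_letter_labels <- function(n) {
  if (n <= 26L) return(letters[seq_len(n)])
  c(letters, as.vector(outer(letters, letters, function(a, b) paste0(a, b))))[seq_len(n)]
}

#' @export
print.letter_display <- function(x, ...) {
  cat(sprintf("Compact letter display (alpha = %g):\n", attr(x, "alpha")))
  print(unclass(x))
  invisible(x)
}

#' Means, standard errors and LSD letters for a replicate table
#'
#' One-stop wrapper reproducing the superscript-letter style of published
#' genome-size tables: one-way ANOVA, Fisher LSD contrasts, compact letter
#' display.
#'
#' @param values replicate measurements.
#' @param groups group labels.
#' @param alpha significance level for the LSD contrasts.
#' @return list with `anova` (an `anova_oneway`), `letters` (a
#'   `letter_display`) and `table` (data frame: group, n, mean, se,
#'   letters, in decreasing-mean order).
#' @export
lsd_letters <- function(values, groups, alpha = 0.05) {
  a <- anova_oneway(values, groups)
  sig <- fisher_lsd(a$means, a$ns, a$MSE, a$df_within, alpha = alpha)
  cld <- compact_letter_display(sig, a$means, alpha = alpha)
  se <- tapply(values, as.character(groups),
               function(v) stats::sd(v) / sqrt(length(v)))[names(a$means)]
  list(anova = a, letters = cld,
       table = data.frame(group = names(a$means), n = a$ns,
                          mean = as.numeric(a$means), se = as.numeric(se),
                          letters = as.character(cld),
                          stringsAsFactors = FALSE, row.names = NULL))
}
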