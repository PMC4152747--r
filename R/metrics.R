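#' Centromeric index
#'
#' CI = 100 * S / (S + L), the short-arm fraction of chromosome length in
#' percent. 50 is perfectly metacentric; values approach 0 for telocentrics.
#'
#' @param short_arm,long_arm positive arm lengths with
#'   `short_arm <= long_arm` (canonical order is enforced, not silently
#'   fixed, so that a CI > 50 can never be produced unnoticed).
#' @return CI in percent, in (0, 50].
#' @examples
#' centromeric_index(1, 1)    # 50, metacentric
#' centromeric_index(1.5, 8.5) # 15
#' @export
centromeric_index <- function(short_arm, long_arm) {
  if (any(short_arm <= 0)) stop("short_arm must be positive")
  if (any(long_arm < short_arm)) stop("long_arm must be >= short_arm (canonicalize arms first)")
  100 * short_arm / (short_arm + long_arm)
}

# Levan base boundaries on the arm ratio r = L/S
.levan_boundaries <- c(m_sm = 1.7, sm_st = 3.0, st_t = 7.0)
.levan_order <- c("m", "m–sm", "sm", "sm–st", "st", "st–t", "t")

#' Levan morphology class from the arm ratio
#'
#' Classifies chromosomes as metacentric (m, r in 1.0-1.7), submetacentric
#' (sm, 1.7-3.0), subtelocentric (st, 3.0-7.0) or telocentric (t, r > 7.0).
#' A relative tolerance band around each boundary yields the compound
#' classes (m-sm, sm-st, st-t) seen in published karyotype formulae: r
#' falls in a compound class when `|r - boundary| <= boundary_tolerance *
#' boundary`.
#'
#' @param r arm ratio(s), long arm / short arm, `r >= 1`.
#' @param boundary_tolerance relative half-width of the compound band,
#'   in `[0, 0.2)`. Default 0.05 (i.e. the sm-st band is 3.0 +/- 0.15).
#' @param ascii if `TRUE` use ASCII hyphens ("m-sm") instead of en-dashes.
#' @return character vector of class labels.
#' @examples
#' classify_levan(c(1, 2, 3.05, 5, 10))
#' @export
classify_levan <- function(r, boundary_tolerance = 0.05, ascii = FALSE) {
  if (any(r < 1)) stop("arm ratio must be >= 1 (use long/short)")
  if (boundary_tolerance < 0 || boundary_tolerance >= 0.2)
    stop("boundary_tolerance must be in [0, 0.2)")
  b <- unname(.levan_boundaries)
  lab <- ifelse(r < b[1], "m", ifelse(r < b[2], "sm", ifelse(r < b[3], "st", "t")))
  lab <- unname(lab)
  compound <- c("m–sm", "sm–st", "st–t")
  if (boundary_tolerance > 0) {
    for (i in seq_along(b)) {
      band <- abs(r - b[i]) <= boundary_tolerance * b[i]
      lab[band] <- compound[i]
    }
  }
  if (ascii) lab <- gsub("–", "-", lab)
  lab
}

#' Partition a complement into short and long chromosome sets
#'
#' Bimodal karyotypes have two sharply distinct size classes. Two methods
#' are provided: `"fixed_count"` takes the `n_short` smallest chromosomes
#' (the natural choice when the complement structure is known, e.g. 4 short
#' + 7 long for Hippeastrum with x = 11); `"largest_gap"` splits the sorted
#' lengths at the maximal adjacent gap.
#'
#' @param lengths chromosome (relative) lengths, at least 2.
#' @param method `"fixed_count"` or `"largest_gap"`.
#' @param n_short required for `"fixed_count"`.
#' @return list with integer index vectors `short` and `long` (indices into
#'   `lengths`), both non-empty.
#' @export
bimodal_partition <- function(lengths, method = c("fixed_count", "largest_gap"),
                              n_short = NULL) {
  method <- match.arg(method)
  n <- length(lengths)
  if (n < 2L) stop("need at least 2 chromosomes to partition")
  o <- order(lengths)                      # ascending
  if (method == "fixed_count") {
    if (is.null(n_short) || n_short < 1L || n_short >= n)
      stop("fixed_count requires 1 <= n_short < number of chromosomes")
    short <- o[seq_len(n_short)]
  } else {
    s <- lengths[o]
    gaps <- diff(s)
    if (all(gaps == 0)) stop("degenerate bimodality: all lengths equal")
    cut <- which.max(gaps)
    short <- o[seq_len(cut)]
  }
  list(short = sort(short), long = sort(setdiff(seq_len(n), short)))
}

#' Karyotype asymmetry indices
#'
#' Computes the four asymmetry statistics used for bimodal-karyotype
#' comparisons: A1 (intrachromosomal, `1 - mean(S/L)`), A2
#' (interchromosomal, `sd(length)/mean(length)` with the n-1 denominator),
#' CV_CL (`100 * A2`, the coefficient of variation of chromosome length)
#' and M_CA (mean centromeric asymmetry, `100 * mean((L-S)/(L+S))`).
#'
#' @param k a [karyotype()] object (at least 2 chromosomes; A2/CV_CL are
#'   undefined for a single chromosome).
#' @return list with `A1`, `A2`, `CV_CL`, `M_CA`.
#' @export
asymmetry <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  s <- k$short_arm; l <- k$long_arm
  if (length(s) < 2L) stop("A2/CV_CL undefined for a single-chromosome karyotype")
  tot <- s + l
  a2 <- stats::sd(tot) / mean(tot)
  list(A1    = 1 - mean(s / l),
       A2    = a2,
       CV_CL = 100 * a2,
       M_CA  = 100 * mean((l - s) / (l + s)))
}

#' Mean centromeric index of the short and long subsets
#'
#' @param k a [karyotype()] object with a bimodal partition assigned.
#' @return list with `CI_S` and `CI_L`, the unweighted mean CI over each
#'   subset, in percent.
#' @export
subset_ci <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  sh <- k$subset == "short"
  if (!any(sh) || all(sh)) stop("both subsets must be non-empty")
  list(CI_S = mean(k$ci[sh]), CI_L = mean(k$ci[!sh]))
}

#' Short-chromosome fraction of total complement size
#'
#' CV_S: the summed length of the short set as a percentage of the summed
#' length of the whole complement. Length is used as the size proxy (the
#' measurement source provides lengths, not physical volumes).
#'
#' @param k a [karyotype()] object.
#' @return percent in (0, 100).
#' @export
cv_s <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  sh <- k$subset == "short"
  if (!any(sh) || all(sh)) stop("both subsets must be non-empty")
  100 * sum(k$relative_length[sh]) / sum(k$relative_length)
}

#' Karyotype formula string
#'
#' Renders the count-by-class summary in the conventional dialect: the
#' short set first, in square brackets, then the long set, classes ordered
#' m, m-sm, sm, sm-st, st, st-t, t, each as "<count><label>", joined by
#' " + " (e.g. `"[4m] + 4sm + 3st"`).
#'
#' @param k a [karyotype()] object, or a character vector of class labels
#'   (then `subsets` must be given).
#' @param subsets optional character vector `"short"`/`"long"` parallel to
#'   the labels; if all chromosomes are `"long"` (or `subsets` is NULL for
#'   a label vector) no brackets are emitted.
#' @param ascii use ASCII hyphens in compound labels.
#' @return a single string.
#' @export
karyotype_formula <- function(k, subsets = NULL, ascii = FALSE) {
  if (inherits(k, "karyotype")) {
    labels <- k$class
    subsets <- k$subset
  } else {
    labels <- as.character(k)
    if (is.null(subsets)) subsets <- rep("long", length(labels))
  }
  order_ref <- .levan_order
  fmt <- function(lab) {
    lab <- factor(lab, levels = order_ref)
    tab <- table(lab)
    tab <- tab[tab > 0]
    paste0(as.integer(tab), names(tab))
  }
  parts <- character(0)
  if (any(subsets == "short"))
    parts <- paste0("[", paste(fmt(labels[subsets == "short"]), collapse = " + "), "]")
  if (any(subsets == "long"))
    parts <- c(parts, fmt(labels[subsets == "long"]))
  out <- paste(parts, collapse = " + ")
  if (ascii) out <- gsub("–", "-", out)
  out
}

#' All karyotype parameters of a complement
#'
#' Convenience wrapper returning the full parameter block reported in
#' comparative karyotype studies: subset centromeric indices, asymmetry
#' indices, short-set size fraction and the formula string.
#'
#' @param k a [karyotype()] object.
#' @param ascii use ASCII hyphens in the formula.
#' @return object of class `karyotype_metrics`: a list with `CI_S`, `CI_L`,
#'   `A1`, `A2`, `M_CA`, `CV_CL`, `CV_S`, `formula`.
#' @export
karyotype_metrics <- function(k, ascii = FALSE) {
  a <- asymmetry(k)
  ci <- subset_ci(k)
  structure(list(CI_S = ci$CI_S, CI_L = ci$CI_L,
                 A1 = a$A1, A2 = a$A2, M_CA = a$M_CA, CV_CL = a$CV_CL,
                 CV_S = cv_s(k),
                 formula = karyotype_formula(k, ascii = ascii)),
            class = "karyotype_metrics")
}

#' @export
print.karyotype_metrics <- function(x, digits = 2, ...) {
  num <- unlist(x[c("CI_S", "CI_L", "A1", "A2", "M_CA", "CV_CL", "CV_S")])
  print(round(num, digits))
  cat("formula:", x$formula, "\n")
  invisible(x)
}
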