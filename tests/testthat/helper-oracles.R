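# Independent closed-form WLS oracle: direct normal equations.
wls_oracle <- function(x, y, w = rep(1, length(x))) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  yhat <- drop(X %*% beta)
  ybar <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * (y - yhat)^2) / sum(w * (y - ybar)^2)
  list(intercept = beta[1], slope = beta[2], r_squared = r2)
}

# Build a karyotype directly from relative lengths and centromeric indices.
karyotype_from_ci <- function(rel, ci, ...) {
  s <- rel * ci / 100
  karyotype(short_arm = s, long_arm = rel - s, ...)
}

# Exhaustive check of the compact-letter contract:
# two groups share a letter  <=>  they are NOT significantly different.
cld_contract_holds <- function(letters, signif) {
  g <- names(letters)
  for (i in seq_along(g)) for (j in seq_along(g)) {
    if (i >= j) next
    shared <- length(intersect(strsplit(letters[[g[i]]], "")[[1]],
                               strsplit(letters[[g[j]]], "")[[1]])) > 0
    if (shared == signif[g[i], g[j]]) return(FALSE)
  }
  TRUE
}

# A fixed small measurement CSV written to a temp file.
write_measurement_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(c("plate_id,accession_id,chromosome_label,arm1,arm2", lines), f)
  f
}
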