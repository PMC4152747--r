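test_that("ANOVA handles degenerate and two-group cases", {
  # all observations identical: no variance anywhere, F defined as 0
  a0 <- anova_oneway(rep(5, 6), rep(c("a", "b", "c"), each = 2))
  expect_equal(a0$F, 0)
  expect_equal(a0$p_value, 1)

  # two groups: F equals the square of the pooled t statistic
  set.seed(31)
  v <- c(rnorm(8, 10, 1), rnorm(12, 11.5, 1))
  g <- rep(c("a", "b"), c(8, 12))
  a <- anova_oneway(v, g)
  t2 <- t.test(v ~ g, var.equal = TRUE)$statistic^2
  expect_equal(a$F, unname(t2), tolerance = 1e-9)
  expect_equal(a$df_between, 1)
  expect_equal(a$df_within, 18)

  expect_error(anova_oneway(c(1, 2, 3), c("a", "a", "b")), "replicates")
})

test_that("strong between-group separation yields tiny p-values", {
  set.seed(32)
  mu <- rnorm(18, 0, 10)
  v <- unlist(lapply(mu, function(m) rnorm(30, m, 1)))
  g <- rep(sprintf("g%02d", 1:18), each = 30)
  a <- anova_oneway(v, g)
  expect_lt(a$p_value, 1e-6)
  expect_equal(a$df_between, 17)
  expect_equal(a$df_within, 18 * 30 - 18)
})

test_that("F is invariant to shifting and scaling the observations", {
  set.seed(33)
  v <- rnorm(30, 10, 2)
  g <- rep(c("a", "b", "c"), each = 10)
  a <- anova_oneway(v, g)
  expect_equal(anova_oneway(v + 100, g)$F, a$F, tolerance = 1e-9)
  expect_equal(anova_oneway(v * 0.01, g)$F, a$F, tolerance = 1e-9)
})

test_that("Fisher LSD thresholds follow the t-quantile formula", {
  sig0 <- fisher_lsd(c(a = 5, b = 5), c(4, 4), MSE = 1, df_within = 6)
  expect_false(sig0["a", "b"])

  sig <- fisher_lsd(c(a = 0, b = 10), c(5, 5), MSE = 1, df_within = 8)
  expect_true(sig["a", "b"])
  lsd <- qt(0.975, 8) * sqrt(1 * (1 / 5 + 1 / 5))
  expect_lt(lsd, 1.5)     # ~1.46, far below the 10-unit difference
  expect_true(isSymmetric(sig))
  expect_false(any(diag(sig)))

  expect_error(fisher_lsd(c(a = 1, b = 2), c(3, 3), 1, 0), "df_within")
})

test_that("shrinking MSE never turns a significant pair non-significant", {
  set.seed(34)
  m <- c(a = 0, b = 0.8, c = 2, d = 5)
  ns <- c(5, 7, 5, 6)
  for (mse in c(4, 2, 1, 0.5, 0.1)) {
    sig_hi <- fisher_lsd(m, ns, mse, 19)
    sig_lo <- fisher_lsd(m, ns, mse / 2, 19)
    expect_true(all(sig_lo[sig_hi]))
  }
})

test_that("compact letter display handles the canonical cases", {
  m3 <- c(g1 = 3, g2 = 2, g3 = 1)
  none <- matrix(FALSE, 3, 3, dimnames = list(names(m3), names(m3)))
  expect_equal(unclass(compact_letter_display(none, m3)),
               c(g1 = "a", g2 = "a", g3 = "a"), ignore_attr = TRUE)

  m4 <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
  all_sig <- matrix(TRUE, 4, 4, dimnames = list(names(m4), names(m4)))
  diag(all_sig) <- FALSE
  expect_equal(unclass(compact_letter_display(all_sig, m4)),
               c(g1 = "a", g2 = "b", g3 = "c", g4 = "d"), ignore_attr = TRUE)

  # chain: 1~2 and 2~3 not significant, 1 vs 3 significant
  chain <- matrix(FALSE, 3, 3, dimnames = list(names(m3), names(m3)))
  chain["g1", "g3"] <- chain["g3", "g1"] <- TRUE
  cld <- compact_letter_display(chain, m3)
  expect_equal(unclass(cld), c(g1 = "a", g2 = "ab", g3 = "b"),
               ignore_attr = TRUE)
  expect_true(cld_contract_holds(cld, chain))
})

test_that("the letter contract holds for arbitrary significance patterns", {
  set.seed(35)
  for (i in 1:40) {
    k <- sample(3:9, 1)
    g <- sprintf("g%d", seq_len(k))
    m <- stats::setNames(rnorm(k), g)
    sig <- matrix(FALSE, k, k, dimnames = list(g, g))
    up <- upper.tri(sig)
    sig[up] <- runif(sum(up)) < 0.4
    sig <- sig | t(sig)
    cld <- compact_letter_display(sig, m)
    expect_true(cld_contract_holds(cld, sig))
  }
})

test_that("alpha extremes collapse or fully separate the letters", {
  set.seed(36)
  st <- simulate_study(hippeastrum_species()[c(1, 9, 18), ],
                       n_per_species = 10, cv = 0.02, seed = 36)
  tiny <- lsd_letters(st$c1x, st$species, alpha = 1e-300)
  expect_true(all(unclass(tiny$letters) == "a"))
  wide <- lsd_letters(st$c1x, st$species, alpha = 0.9999)
  expect_equal(anyDuplicated(unclass(wide$letters)), 0)
})

test_that("letters separate the extreme accessions across repeated studies", {
  sp <- hippeastrum_species()
  top_dip <- "H. machupijchense"; low_dip <- "H. morelianum"
  hexa <- "H. puniceum 6x"
  sep_dip <- 0; sep_hex <- 0
  for (s in 1:100) {
    st <- simulate_study(sp, n_per_species = 30, cv = 0.032, seed = s)
    cld <- lsd_letters(st$c1x, st$species)$letters
    shares <- function(a, b)
      length(intersect(strsplit(cld[[a]], "")[[1]],
                       strsplit(cld[[b]], "")[[1]])) > 0
    if (!shares(top_dip, low_dip)) sep_dip <- sep_dip + 1
    if (!shares(top_dip, hexa)) sep_hex <- sep_hex + 1
  }
  expect_gte(sep_dip, 95)
  expect_gte(sep_hex, 99)
})
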