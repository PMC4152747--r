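test_that("centromeric index follows 100*S/(S+L) and rejects bad arms", {
  expect_equal(centromeric_index(1, 1), 50)
  expect_equal(centromeric_index(1, 3), 25)
  expect_equal(centromeric_index(1.5, 8.5), 15)
  expect_error(centromeric_index(3, 1), "canonicalize")
  expect_error(centromeric_index(0, 1), "positive")
})

test_that("Levan classification returns base and compound labels", {
  expect_equal(classify_levan(1.0), "m")
  expect_equal(classify_levan(5.0, boundary_tolerance = 0.05), "st")
  expect_equal(classify_levan(3.05, boundary_tolerance = 0.05), "sm–st")
  expect_equal(classify_levan(3.05, boundary_tolerance = 0.05, ascii = TRUE), "sm-st")
  expect_equal(classify_levan(c(1.2, 1.7, 2.2, 7.3, 10)),
               c("m", "m–sm", "sm", "st–t", "t"))
  expect_error(classify_levan(0.9), ">= 1")
  expect_error(classify_levan(2, boundary_tolerance = 0.3), "boundary_tolerance")
})

test_that("classification is monotone in the arm ratio", {
  ord <- c("m", "m–sm", "sm", "sm–st", "st", "st–t", "t")
  for (tol in c(0, 0.02, 0.05, 0.1)) {
    r <- seq(1, 12, by = 0.01)
    idx <- match(classify_levan(r, boundary_tolerance = tol), ord)
    expect_true(all(diff(idx) >= 0))
  }
})

test_that("bimodal partition splits by count or by the largest gap", {
  tpl <- hippeastrum_template("mid")
  p <- bimodal_partition(tpl$relative_length, "fixed_count", n_short = 4)
  expect_length(p$short, 4)
  expect_equal(sort(tpl$relative_length[p$short]), c(5.4, 5.8, 6.2, 6.6))

  p2 <- bimodal_partition(c(1, 1, 1, 5, 5), "largest_gap")
  expect_equal(p2$short, 1:3)
  expect_equal(p2$long, 4:5)

  expect_error(bimodal_partition(rep(2, 5), "largest_gap"), "degenerate")
})

test_that("largest-gap partition recovers well-separated clusters", {
  # iid clusters of 4 and 7; 10-SD mean separation gives complete recovery
  set.seed(1)
  hits <- 0
  for (i in 1:200) {
    v <- c(rnorm(4, 10, 1), rnorm(7, 20, 1))
    p <- bimodal_partition(v, "largest_gap")
    if (identical(p$short, 1:4)) hits <- hits + 1
  }
  expect_equal(hits, 200)

  # structured 11-chromosome template at 3 % multiplicative noise
  tpl <- hippeastrum_template("mid")
  set.seed(2)
  hits <- 0
  for (i in 1:200) {
    v <- tpl$relative_length * (1 + rnorm(11, 0, 0.03))
    p <- bimodal_partition(v, "largest_gap")
    if (identical(p$short, 8:11)) hits <- hits + 1
  }
  expect_equal(hits, 200)
})

test_that("asymmetry indices satisfy the textbook identities", {
  # all metacentric, equal length: perfectly symmetric karyotype
  k <- karyotype(rep(1, 4), rep(1, 4), n_short = 2, method = "fixed_count")
  a <- asymmetry(k)
  expect_equal(a$A1, 0)
  expect_equal(a$A2, 0)
  expect_equal(a$M_CA, 0)
  expect_equal(a$CV_CL, 0)

  # two chromosomes (S, L) = (1, 3): hand arithmetic
  k2 <- karyotype(c(1, 1), c(3, 3), n_short = 1, method = "fixed_count")
  a2 <- asymmetry(k2)
  expect_equal(a2$M_CA, 50)
  expect_equal(a2$A1, 2 / 3)
  expect_equal(a2$A2, 0)
})

test_that("metric identities hold on random karyotypes", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:14, 1)
    s <- runif(n, 0.5, 3)
    l <- s * runif(n, 1, 8)
    k <- karyotype(s, l, method = "largest_gap")
    a <- asymmetry(k)
    # CV_CL = 100*A2 by construction
    expect_identical(a$CV_CL, 100 * a$A2)
    # per-chromosome cross-formula agreement via the arm ratio
    r <- k$arm_ratio
    expect_equal((k$long_arm - k$short_arm) / (k$long_arm + k$short_arm),
                 (r - 1) / (r + 1), tolerance = 1e-12)
    expect_equal(1 - k$short_arm / k$long_arm, (r - 1) / r, tolerance = 1e-12)
    # scale invariance: karyotype() normalises, so a rescaled input matches
    k_sc <- karyotype(s * 3.7, l * 3.7, method = "largest_gap")
    expect_equal(asymmetry(k_sc), a, tolerance = 1e-12)
    # permutation invariance
    perm <- sample(n)
    k_pm <- karyotype(s[perm], l[perm], method = "largest_gap")
    expect_equal(asymmetry(k_pm), a, tolerance = 1e-12)
  }
})

test_that("published A2 and CV_CL pairs agree within rounding", {
  sp <- hippeastrum_species()
  ok <- !is.na(sp$a2) & !is.na(sp$cv_cl)
  dev <- abs(sp$cv_cl[ok] - 100 * sp$a2[ok])
  # 13 of 14 pairs agree within the 2-dp rounding slack; the remaining pair
  # (H. machupijchense, A2 0.30 vs CV_CL 30.56) misses it by 0.01
  expect_true(all(dev <= 0.56))
  expect_equal(sum(dev > 0.505), 1)
  expect_equal(sp$species[ok][dev > 0.505], "H. machupijchense")
})

test_that("subset centromeric indices average each size class", {
  k <- karyotype_from_ci(rep(c(10, 5), c(7, 4)),
                         rep(c(23, 44), c(7, 4)),
                         n_short = 4, method = "fixed_count")
  ci <- subset_ci(k)
  expect_equal(ci$CI_S, 44)
  expect_equal(ci$CI_L, 23)

  # recovery from noisy plates built on the same geometry
  tpl <- structure(data.frame(relative_length = rep(c(10, 5), c(7, 4)),
                              ci = rep(c(23, 44), c(7, 4))),
                   x = 11L, n_short = 4L,
                   class = c("karyotype_template", "data.frame"))
  pl <- simulate_metaphases(tpl, ploidy = 2, k_plates = 10, arm_cv = 0.03,
                            seed = 13)
  km <- karyotype_metrics(average_karyotype(pl, ploidy = 2, x = 11))
  expect_lt(abs(km$CI_S - 44), 1.5)
})

test_that("short-set size fraction is a length share in percent", {
  k <- karyotype(rep(0.5, 11), rep(0.5, 11), n_short = 4, method = "fixed_count")
  expect_equal(cv_s(k), 400 / 11)

  k2 <- karyotype_from_ci(c(rep(76 / 7, 7), rep(6, 4)),
                          rep(30, 11), n_short = 4, method = "fixed_count")
  expect_equal(cv_s(k2), 24)
})

test_that("karyotype formula renders counts, classes and bracketed short set", {
  lab <- c(rep("m", 4), rep("sm", 4), rep("st", 3))
  sub <- rep(c("short", "long"), c(4, 7))
  expect_equal(karyotype_formula(lab, sub), "[4m] + 4sm + 3st")

  lab2 <- c("m", "m", "m", "m–sm", "sm", "sm–st", "sm–st", "st", "st", "st", "t")
  sub2 <- rep(c("short", "long"), c(4, 7))
  expect_equal(karyotype_formula(lab2, sub2),
               "[3m + 1m–sm] + 1sm + 2sm–st + 3st + 1t")
  expect_equal(karyotype_formula(lab2, sub2, ascii = TRUE),
               "[3m + 1m-sm] + 1sm + 2sm-st + 3st + 1t")

  # single metacentric chromosome, no partition: unbracketed
  k1 <- karyotype(1, 1)
  expect_equal(karyotype_formula(k1), "1m")
})
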