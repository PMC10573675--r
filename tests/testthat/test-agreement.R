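test_that("Lin CCC: perfect agreement, hand-computed shift case, edge cases", {
  x <- c(3, 1, 4, 1, 5, 9, 2.6)
  expect_equal(lin_ccc(x, x)$ccc, 1)

  # x = 1:3, y = 2:4 by direct formula: means 2 and 3, population
  # variances 2/3, covariance 2/3 -> ccc = (4/3) / (2/3 + 2/3 + 1) = 4/7
  res <- lin_ccc(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$ccc, 4 / 7)
  expect_equal(res$pearson_r, 1)       # shift penalizes CCC, not Pearson
  expect_lt(res$ccc, res$pearson_r)

  expect_equal(lin_ccc(rep(5, 4), rep(5, 4))$ccc, 1)
  expect_warning(res0 <- lin_ccc(rep(5, 4), rep(7, 4)), "constant")
  expect_equal(res0$ccc, 0)
  expect_error(lin_ccc(1:2, 3:4), "at least 3")
})

test_that("Lin CCC invariances: symmetry, joint rescale, |ccc| <= |r|", {
  set.seed(13)
  for (rep in 1:10) {
    x <- rnorm(20, 10, 3); y <- x + rnorm(20, 1, 2)
    a <- lin_ccc(x, y); b <- lin_ccc(y, x)
    expect_equal(a$ccc, b$ccc)
    # identical positive rescaling of both series leaves ccc unchanged
    s <- runif(1, 0.1, 10)
    expect_equal(lin_ccc(s * x, s * y)$ccc, a$ccc, tolerance = 1e-12)
    # rescaling only one series lowers agreement
    expect_lt(lin_ccc(3 * x, y)$ccc, a$ccc)
    # ccc = r * C_b with C_b in (0, 1]
    expect_lte(abs(a$ccc), abs(a$pearson_r) + 1e-12)
    expect_gt(a$c_b, 0); expect_lte(a$c_b, 1)
    # CI brackets the point estimate
    expect_lte(a$ci_low, a$ccc); expect_gte(a$ci_high, a$ccc)
  }
})

test_that("Kendall W: perfect concordance, Spearman identity, tie handling", {
  expect_equal(kendall_w(cbind(1:6, 1:6, 1:6))$w, 1)
  # reversing one rater's ranking of two raters gives W = 0 at m = 2
  expect_lt(kendall_w(cbind(1:6, 6:1))$w, 1e-12)

  # no-ties identity: W = ((m-1) * mean pairwise Spearman + 1) / m
  set.seed(17)
  for (rep in 1:8) {
    m <- sample(3:5, 1); n <- sample(4:9, 1)
    r <- matrix(rnorm(n * m), n, m)
    w <- kendall_w(r)$w
    rho <- cor(apply(r, 2, rank), method = "pearson")
    rho_bar <- mean(rho[lower.tri(rho)])
    expect_equal(w, ((m - 1) * rho_bar + 1) / m, tolerance = 1e-10)
  }

  # permutation of case order leaves W unchanged
  r <- matrix(rnorm(24), 8, 3)
  expect_equal(kendall_w(r[sample(8), ])$w, kendall_w(r)$w)

  # degenerate: all raters constant
  expect_warning(wdeg <- kendall_w(matrix(1, 4, 3)), "degenerate")
  expect_equal(wdeg$w, 1)
  expect_error(kendall_w(matrix(1:3, 3, 1)), "at least 2")
})

test_that("Kendall W agrees with vegan's implementation, with and without ties", {
  skip_if_not_installed("vegan")
  set.seed(19)
  r1 <- matrix(rnorm(30), 10, 3)
  r2 <- matrix(sample(1:4, 36, replace = TRUE), 12, 3)  # heavy ties
  for (r in list(r1, r2)) {
    ours <- kendall_w(r)
    ref <- vegan::kendall.global(r)
    expect_equal(ours$w, unname(ref$Concordance_analysis["W", 1]),
                 tolerance = 1e-10)
    expect_equal(ours$chi2, unname(ref$Concordance_analysis["Chi2", 1]),
                 tolerance = 1e-10)
  }
})

test_that("coefficient of variation: hand case, zero spread, scale invariance", {
  tab <- data.frame(case_id = 1, observer_id = "A", replicate = 1:3,
                    volume_mm3 = c(90, 100, 110))
  cv <- coefficient_of_variation(tab)
  expect_equal(cv$per_case$cv_percent, 10)  # sample SD 10, mean 100

  flat <- data.frame(case_id = 1, observer_id = "A", replicate = 1:5,
                     volume_mm3 = rep(5, 5))
  expect_equal(coefficient_of_variation(flat)$per_case$cv_percent, 0)

  tab3 <- tab; tab3$volume_mm3 <- 3 * tab3$volume_mm3
  expect_equal(coefficient_of_variation(tab3)$per_case$cv_percent, 10)

  zero <- data.frame(case_id = 1, observer_id = "A", replicate = 1:3,
                     volume_mm3 = rep(0, 3))
  expect_true(is.na(coefficient_of_variation(zero)$per_case$cv_percent))
})

test_that("Bland-Altman: identity pair, RC/SD ratio, LoA coverage", {
  x <- c(10, 20, 30, 40)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0); expect_equal(ba0$sd_diff, 0); expect_equal(ba0$rc, 0)

  set.seed(23)
  for (rep in 1:6) {
    x <- rnorm(30, 100, 20); y <- x + rnorm(30, 5, 10)
    ba <- bland_altman(x, y)
    expect_equal(ba$rc / ba$sd_diff, 1.96)            # by construction
    expect_equal(ba$loa_high - ba$loa_low, 2 * ba$rc)
    expect_equal(ba$bias, mean(x - y))
  }
  # a difference SD of 422 gives the repeatability coefficient 827.12
  expect_equal(1.96 * 422, 827.12)

  # ~95% of Normal differences fall inside the limits of agreement
  set.seed(29)
  d <- rnorm(10000, 0, 250)
  ba <- bland_altman(d, rep(0, 10000))
  inside <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_equal(inside, 0.95, tolerance = 0.012)

  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("paired t-test matches the textbook formula and is antisymmetric", {
  x <- c(12, 15, 11, 19, 14); y <- c(10, 16, 9, 15, 12)
  res <- paired_t_test(x, y)
  d <- x - y
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t, t_manual)
  expect_equal(res$p, 2 * pt(-abs(t_manual), length(d) - 1))

  swap <- paired_t_test(y, x)
  expect_equal(swap$t, -res$t)
  expect_equal(swap$p, res$p)

  expect_error(paired_t_test(x, x + 3), "zero variance")
})

test_that("Mann-Whitney: exact path equals the enumeration-free reference", {
  # identical singletons: midrank U = 0.5 * 1 * 1
  expect_equal(mann_whitney_u(5, 5)$u, 0.5)

  set.seed(31)
  for (rep in 1:10) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    a <- rnorm(na); b <- rnorm(nb, 0.5)
    ours <- mann_whitney_u(a, b)
    expect_equal(ours$method, "exact")
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$u, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }

  # extreme separation reaches the minimal two-sided p for n = m = 4
  p_min <- mann_whitney_u(1:4, 101:104)$p
  expect_equal(p_min, 2 / choose(8, 4))

  # ties or large n fall back to the normal approximation
  big <- mann_whitney_u(rnorm(20), rnorm(25, 1))
  expect_equal(big$method, "normal")
  tied <- mann_whitney_u(c(1, 2, 2, 3), c(2, 3, 4, 4))
  expect_equal(tied$method, "normal")
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("agreement study on a perfectly repeating trio", {
  tab <- perfect_trio_table()
  expect_warning(fit <- agreement_study(tab, aggregation = "median"),
                 "no metadata")
  expect_s3_class(fit, "stone_agreement")
  expect_true(all(fit$pairwise$lin_ccc == 1))
  expect_equal(fit$overall$w, 1)
  expect_true(all(fit$per_observer$mean_cv_percent == 0))
  expect_true(all(fit$per_observer$intra_w == 1))
})

test_that("agreement study: raw aggregation, metadata subgroups, warnings", {
  set.seed(37)
  n_cases <- 10
  tab <- expand.grid(case_id = seq_len(n_cases),
                     observer_id = c("A", "B", "C"), replicate = 1:4,
                     KEEP.OUT.ATTRS = FALSE)
  base <- 200 * tab$case_id
  # complex cases get 5x the replicate noise by construction
  complex_case <- tab$case_id <= 4
  tab$volume_mm3 <- base + rnorm(nrow(tab), 0, ifelse(complex_case, 50, 10))
  tab$is_complex <- complex_case

  fit_raw <- agreement_study(tab, aggregation = "raw")
  fit_med <- agreement_study(tab, aggregation = "median")
  expect_equal(nrow(fit_raw$pairwise), 3)
  expect_true(all(fit_med$pairwise$lin_ccc > 0.99))

  sg <- fit_med$subgroups$complexity
  expect_gt(sg$median_cv_true, sg$median_cv_false)  # injected extra variance
  expect_lt(sg$p, 0.05)

  # no metadata -> subgroups skipped with a warning, rest still runs
  tab2 <- tab[setdiff(names(tab), "is_complex")]
  expect_warning(fit2 <- agreement_study(tab2), "subgroup")
  expect_equal(nrow(fit2$pairwise), 3)
  expect_null(fit2$subgroups)

  expect_error(agreement_study(tab[tab$observer_id == "A", ]), "2 observers")
})

test_that("agreement study reproduces the published per-case-median table", {
  tab <- read_table2b()
  fit <- agreement_study(tab, aggregation = "median")
  expect_equal(fit$n_cases, 50)
  expect_equal(fit$n_observers, 3)
  expect_gte(fit$overall$w, 0.99)
  expect_true(all(fit$pairwise$lin_ccc >= 0.98))
  # the published extreme Bland-Altman spreads: RC 593.47 (junior-expert)
  # and 827.11 (senior-expert), up to rounding of the printed SDs
  rc <- setNames(fit$pairwise$rc, fit$pairwise$pair)
  expect_equal(unname(rc["junior vs expert"]), 593.47, tolerance = 2e-4)
  expect_equal(unname(rc["senior vs expert"]), 827.11, tolerance = 2e-4)
})
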