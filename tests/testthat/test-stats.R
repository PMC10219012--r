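test_that("chi-square and Cramer's V match a hand-computed oracle", {
  # hand oracle: sum (O - E)^2 / E with E from the margins
  tab <- rbind(c(20, 30, 10), c(10, 15, 35))
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expected)^2 / expected)
  res <- chi_square_cramers_v(tab)
  expect_equal(res$statistic, chi2, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$cramers_v, sqrt(chi2 / n), tolerance = 1e-12)
  # V is invariant to transposing the table
  expect_equal(chi_square_cramers_v(t(tab))$cramers_v, res$cramers_v)

  # the study's sex-by-cluster table
  study <- rbind(female = c(36, 171, 116), male = c(92, 33, 66))
  res2 <- chi_square_cramers_v(study)
  expect_equal(res2$cramers_v, 0.451, tolerance = 0.001)
  expect_lt(res2$p_value, 0.001)

  # perfectly proportional: no association
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  expect_equal(chi_square_cramers_v(prop)$statistic, 0, tolerance = 1e-12)
  expect_equal(chi_square_cramers_v(prop)$cramers_v, 0, tolerance = 1e-12)
  # perfect association in a 2x2
  expect_equal(
    chi_square_cramers_v(rbind(c(10, 0), c(0, 10)))$cramers_v, 1
  )
  expect_error(chi_square_cramers_v(rbind(c(0, 0), c(1, 2))), "zero margin")
  expect_error(chi_square_cramers_v(rbind(c(-1, 2), c(1, 2))), "non-negative")
})

test_that("ANOVA/Tukey matches closed forms and dominates unadjusted t-tests", {
  # identical groups: no between-group signal at all
  df0 <- tibble::tibble(v = rep(c(1, 2, 3), 3), g = rep(1:3, each = 3))
  res0 <- anova_tukey(df0, "v", "g")
  expect_equal(res0$f_statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_true(all(res0$pairs$p_adj == 1))
  expect_equal(nrow(res0$pairs), 3)

  # two groups: Tukey HSD reduces to the pooled two-sided t-test
  set.seed(50)
  df2 <- tibble::tibble(v = c(rnorm(8), rnorm(12, 1)), g = rep(1:2, c(8, 12)))
  res2 <- anova_tukey(df2, "v", "g")
  tt <- t.test(v ~ g, data = df2, var.equal = TRUE)
  expect_equal(res2$pairs$p_adj, tt$p.value, tolerance = 1e-9)

  # widely separated groups: every pair significant
  df3 <- tibble::tibble(
    v = c(rnorm(30, 0), rnorm(30, 10), rnorm(30, 20)),
    g = rep(1:3, each = 30)
  )
  res3 <- anova_tukey(df3, "v", "g")
  expect_true(res3$all_pairs_significant)

  # Tukey-adjusted p >= unadjusted pairwise pooled-t p on the same data
  set.seed(51)
  dfr <- tibble::tibble(
    v = rnorm(45) + rep(c(0, 0.5, 1), each = 15),
    g = rep(1:3, each = 15)
  )
  resr <- anova_tukey(dfr, "v", "g")
  for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
    sub <- dfr[dfr$g %in% pr, ]
    p_unadj <- t.test(v ~ g, data = sub, var.equal = TRUE)$p.value
    p_adj <- resr$pairs$p_adj[resr$pairs$pair == paste(pr[2], pr[1], sep = "-")]
    expect_gte(p_adj, p_unadj - 1e-12)
  }

  expect_error(
    anova_tukey(tibble::tibble(v = rep(1, 6), g = rep(1:3, 2)), "v", "g"),
    "Zero within-group variance"
  )
})

test_that("the all-pairs selection rule keeps only fully separating variables", {
  set.seed(52)
  n <- 20
  g <- rep(1:3, each = n)
  df <- tibble::tibble(
    cluster = g,
    all_three = rnorm(3 * n, mean = c(0, 10, 20)[g], sd = 0.5),
    two_only = rnorm(3 * n, mean = c(0, 0, 10)[g], sd = 0.5),
    none = rnorm(3 * n, mean = 5, sd = 0.5)
  )
  sel <- select_discriminative_variables(df, c("all_three", "two_only", "none"))
  expect_equal(sel$variable[sel$keep], "all_three")
  expect_false(sel$keep[sel$variable == "two_only"])
  # the two-separating variable is still strongly significant in its pairs
  expect_lt(sel$min_pair_p[sel$variable == "two_only"], 0.001)
  expect_false(sel$keep[sel$variable == "none"])
})

test_that("Mann-Whitney U matches symmetry, separation and exact permutation", {
  # complete separation
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$u, 0)
  # identical groups: U at its null mean, p ~ 1
  a <- c(1.2, 3.4, 2.2, 5.1)
  resAA <- mann_whitney(a, a)
  expect_equal(resAA$u, length(a)^2 / 2)
  expect_gt(resAA$p_value, 0.9)
  # all values identical across both groups: p = 1 by convention
  expect_equal(mann_whitney(rep(2, 5), rep(2, 4))$p_value, 1)

  # approximation vs exhaustive permutation oracle (n = 5 vs 5, with a tie)
  g1 <- c(1.1, 2.0, 2.0, 4.7, 6.2)
  g2 <- c(1.8, 3.3, 5.0, 5.9, 8.4)
  res <- mann_whitney(g1, g2)
  expect_lt(abs(res$p_value - exact_mw_p(g1, g2)), 0.02)
  # and against R's tie-corrected continuity-corrected normal approximation
  wt <- suppressWarnings(wilcox.test(g1, g2, exact = FALSE, correct = TRUE))
  expect_equal(res$u, unname(wt$statistic))
  expect_equal(res$p_value, wt$p.value, tolerance = 1e-9)

  set.seed(53)
  for (i in 1:5) {
    x <- round(rnorm(6), 1)
    y <- round(rnorm(7, 0.5), 1)
    expect_lt(abs(mann_whitney(x, y)$p_value - exact_mw_p(x, y)), 0.05)
  }
  expect_error(mann_whitney(numeric(), 1:3), "non-empty")
})

test_that("per-cluster summaries reduce to the textbook formulas", {
  df <- tibble::tibble(v = c(1, 3), cluster = c(1, 1))
  s <- summarize_clusters(df, "v")
  expect_equal(s$mean, 2)
  expect_equal(s$sd, sqrt(2))

  set.seed(54)
  whole <- tibble::tibble(v = rnorm(40), w = runif(40), cluster = 1L)
  s2 <- summarize_clusters(whole, c("v", "w"))
  expect_equal(s2$mean, c(mean(whole$v), mean(whole$w)))
  expect_equal(s2$sd, c(sd(whole$v), sd(whole$w)))
  expect_equal(s2$n, c(40L, 40L))
})

test_that("Bonwill/Balkwill report flags clusters against the classical norms", {
  cohort <- tibble::tibble(
    axv_mm = c(36.2, 36.2, 26.5, 26.5, 35.9, 35.9),
    axh_mm = c(98.9, 98.9, 88.1, 88.1, 85.6, 85.6),
    cluster = c(1, 1, 2, 2, 3, 3)
  )
  rep <- bonwill_balkwill_report(cohort)
  expect_equal(rep$balkwill_mean, c(20.1, 16.7, 22.8), tolerance = 0.1)
  # the vertical-II cluster sits below the 18-25 degree Balkwill range
  expect_equal(rep$balkwill_within_norm, c(TRUE, FALSE, TRUE))
  # only the balanced cluster is close to the 101.6 mm Bonwill arm (here
  # SD = 0 within cluster, so "close" means numerically distant for all)
  expect_equal(rep$ie_ax_mean, c(105.3, 92.0, 92.8), tolerance = 0.05)

  expect_equal(nrow(bonwill_balkwill_report(cohort[0, ])), 0)
})
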