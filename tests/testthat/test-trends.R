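test_that("fit_linear_trend recovers exact and degenerate fits", {
  ft <- fit_linear_trend(c(10, 20, 30, 40))
  expect_equal(ft$slope, 1 / 3, tolerance = 1e-12)
  expect_equal(ft$r_squared, 1, tolerance = 1e-12)
  expect_true(ft$low_n)

  const <- fit_linear_trend(c(5, 5, 5, 5))
  expect_equal(const$slope, 0)
  expect_equal(const$r_squared, 0)
  expect_true(is.na(const$p_value))
})

test_that("fit_linear_trend matches the normal-equations oracle", {
  x <- c(1915, 1945, 1975, 2005)
  y <- c(100, 111, 105, 75)
  ft <- fit_linear_trend(y, x)
  or <- oracle_ols(x, y)
  expect_equal(ft$slope, or$slope, tolerance = 1e-10)
  expect_equal(ft$se, or$se, tolerance = 1e-10)
  expect_equal(ft$p_value, or$p, tolerance = 1e-10)
  expect_equal(ft$r_squared, or$r2, tolerance = 1e-10)
  expect_equal(ft$intercept, or$intercept, tolerance = 1e-8)
  # residual orthogonality on standardized data
  res <- y - ft$intercept - ft$slope * x
  xs <- (x - mean(x)) / stats::sd(x)
  expect_lt(abs(sum(res * xs)), 1e-8)
})

test_that("quadratic_vs_linear detects curvature and only curvature", {
  lin <- quadratic_vs_linear(c(10, 20, 30, 40))
  expect_equal(lin$f_statistic, 0, tolerance = 1e-6)
  expect_equal(lin$preferred, "linear")

  x <- c(1915, 1945, 1975, 2005)
  parab <- 0.5 + 0.0002 * (x - 1960)^2
  qf <- quadratic_vs_linear(parab, x)
  expect_lt(qf$rss_quadratic, 1e-16)
  expect_gt(qf$f_statistic, 1e6)
  expect_equal(qf$preferred, "quadratic")

  # U-shaped inequality-like series: F matches brute-force polynomial RSS
  y <- c(0.85, 0.80, 0.77, 0.86)
  qv <- quadratic_vs_linear(y, x)
  rss1 <- oracle_poly_rss(x, y, 1)
  rss2 <- oracle_poly_rss(x, y, 2)
  expect_equal(qv$rss_linear, rss1, tolerance = 1e-10)
  expect_equal(qv$rss_quadratic, rss2, tolerance = 1e-10)
  expect_equal(qv$f_statistic, (rss1 - rss2) / rss2, tolerance = 1e-8)
})

test_that("quadratic RSS never exceeds linear RSS", {
  set.seed(6)
  x <- c(1915, 1945, 1975, 2005)
  for (i in 1:200) {
    y <- stats::rnorm(4)
    qv <- quadratic_vs_linear(y, x)
    expect_lte(qv$rss_quadratic, qv$rss_linear + 1e-12)
  }
})

test_that("welch_t matches hand computation and textbook cases", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  a <- c(1, 2, 3); b <- c(11, 12, 13)
  wt <- welch_t(a, b)
  or <- oracle_welch(a, b)
  expect_equal(wt$t, or$t, tolerance = 1e-10)
  expect_equal(wt$df, or$df, tolerance = 1e-10)
  expect_equal(wt$p_value, or$p, tolerance = 1e-10)
  # antisymmetry
  expect_equal(welch_t(b, a)$t, -wt$t)
  # equal-variance equal-n case equals Student's t
  set.seed(2)
  g1 <- stats::rnorm(6); g2 <- stats::rnorm(6)
  st <- stats::t.test(g1, g2, var.equal = TRUE)
  wt2 <- welch_t(g1, g2)
  if (abs(stats::var(g1) - stats::var(g2)) < 1e-12)
    expect_equal(wt2$t, unname(st$statistic), tolerance = 1e-10)
  # p always in (0, 1]
  expect_true(wt$p_value > 0 && wt$p_value <= 1)
})

test_that("pearson_cor matches direct covariance formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  y <- c(2.3, 1.1, 4.5, 3.2, 5.9)
  pc <- pearson_cor(x, y)
  or <- oracle_pearson(x, y)
  expect_equal(pc$r, or$r, tolerance = 1e-12)
  expect_equal(pc$p_value, or$p, tolerance = 1e-12)
  expect_error(pearson_cor(c(1, 1, 1), y[1:3]), "variance")
})

test_that("two-way ANOVA decomposes sums of squares exactly", {
  grid <- expand.grid(family = c("Canidae", "Felidae", "Mustelidae"),
                      period = c("P1", "P2", "P3", "P4"),
                      stringsAsFactors = FALSE)
  # all equal -> both F are 0 (lm reports NaN F on zero variance; accept 0/NaN)
  g0 <- grid; g0$gini <- 0.5
  av0 <- gini_two_way_anova(g0)
  expect_true(all(av0$sum_sq < 1e-20))

  # pure family (row) effect -> period F = 0
  g1 <- grid
  g1$gini <- c(Canidae = 0.8, Felidae = 0.7, Mustelidae = 0.6)[g1$family]
  av1 <- gini_two_way_anova(g1)
  expect_lt(av1$sum_sq[av1$effect == "period"], 1e-20)
  expect_gt(av1$f_statistic[av1$effect == "family"], 1e10)

  # random table matches the direct SS decomposition
  set.seed(9)
  g2 <- grid; g2$gini <- stats::runif(12, 0.5, 0.95)
  av2 <- gini_two_way_anova(g2)
  or <- oracle_two_way_ss(g2)
  expect_equal(av2$sum_sq[av2$effect == "family"], or$family, tolerance = 1e-10)
  expect_equal(av2$sum_sq[av2$effect == "period"], or$period, tolerance = 1e-10)
  expect_equal(av2$sum_sq[av2$effect == "residuals"], or$residual,
               tolerance = 1e-10)
  expect_equal(sum(av2$sum_sq), or$total, tolerance = 1e-8)

  # incomplete designs are rejected
  expect_error(gini_two_way_anova(g2[-1, ]), "incomplete")
  g3 <- g2; g3$gini[3] <- NA
  expect_error(gini_two_way_anova(g3), "incomplete")
})

test_that("trend_table covers metrics, families and pooled fits", {
  tbl <- generate_occurrences(small_synth(seed = 16, n = 4000))
  fl <- filter_records(parse_occurrences(tbl), attr(tbl, "registry"))
  mt <- metrics_by_slice(fl$records, seed = 1)
  gt <- gini_by_slice(fl$records)
  tt <- trend_table(mt, gt)
  expect_true(all(c("linear_trend", "quadratic_vs_linear",
                    "welch_early_vs_recent", "pearson_nodes_edges",
                    "edges_on_nodes") %in% tt$analysis))
  lt <- tt[tt$analysis == "linear_trend" & tt$metric == "nodes", ]
  expect_setequal(lt$family, c("Canidae", "Felidae", "Mustelidae", "pooled"))
})

test_that("sensitivity suite reproduces baseline at threshold 1", {
  tbl <- generate_occurrences(small_synth(seed = 17, n = 3000))
  fl <- filter_records(parse_occurrences(tbl), attr(tbl, "registry"))
  sens <- sensitivity_suite(fl$records, thresholds = c(1, 5),
                            binnings = list(default = default_periods()))
  base <- metrics_by_slice(fl$records, seed = 1)
  mids <- stats::setNames(default_periods()$midpoint, default_periods()$label)
  ft <- fit_linear_trend(base$nodes, mids[base$period])
  got <- sens[sens$threshold == 1 & sens$metric == "nodes", ]
  expect_equal(got$slope, ft$slope, tolerance = 1e-12)
  expect_true(all(c("gini") %in% sens$metric))
})

test_that("thresholds do not matter when all weights exceed them", {
  rec <- data.frame(family = "Canidae",
                    origin_country = rep(c("KEN", "TZA", "BRA"), each = 4),
                    holding_country = rep(c("USA", "NOR", "DNK"), each = 4),
                    year = rep(c(1910, 1940, 1970, 2000), 3),
                    count = 25, source_row = 1:12)
  s <- sensitivity_suite(rec, thresholds = c(1, 5, 10),
                         gini_variants = "participants_only",
                         binnings = list(default = default_periods()))
  for (m in unique(s$metric)) {
    sl <- s$slope[s$metric == m]
    expect_true(all(abs(sl - sl[1]) < 1e-12), label = paste("metric", m))
  }
})
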