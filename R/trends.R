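# Temporal trend statistics. All metrics are regressed on period midpoints
# treated as a continuous predictor (1915, 1945, 1975, 2005 by default).
# With four points per family these fits have very few residual degrees of
# freedom, so every result carries a low-n flag and should be read as
# descriptive rather than confirmatory.

#' Ordinary least-squares linear trend
#'
#' @param values Metric values, one per period (NAs dropped).
#' @param midpoints Period midpoints, same length as `values`.
#' @return One-row data frame: `slope`, `se`, `p_value`, `r_squared`,
#'   `intercept`, `n_points`, `low_n`. With exactly 2 points the fit is
#'   reported with missing `se`/`p`. Constant responses yield slope 0 and
#'   `r_squared` 0 with missing `p`.
#' @export
#' @examples
#' fit_linear_trend(c(10, 20, 30, 40))  # slope 1/3 per year, R^2 = 1
fit_linear_trend <- function(values, midpoints = c(1915, 1945, 1975, 2005)) {
  stopifnot(length(values) == length(midpoints))
  ok <- is.finite(values) & is.finite(midpoints)
  y <- values[ok]; x <- midpoints[ok]
  n <- length(y)
  if (n < 2) stop("need at least 2 finite points")
  if (stats::var(y) == 0) {
    return(data.frame(slope = 0, se = 0, p_value = NA_real_, r_squared = 0,
                      intercept = y[1], n_points = n, low_n = n <= 4))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  se <- if (n >= 3) co["x", "Std. Error"] else NA_real_
  p <- if (n >= 3) co["x", "Pr(>|t|)"] else NA_real_
  data.frame(slope = unname(co["x", "Estimate"]), se = unname(se),
             p_value = unname(p), r_squared = sm$r.squared,
             intercept = unname(co["(Intercept)", "Estimate"]),
             n_points = n, low_n = n <= 4)
}

#' Quadratic vs. linear model comparison
#'
#' Fits linear and quadratic polynomials in the midpoints and compares them
#' with a nested-model F test (detects non-monotonic, U-shaped patterns).
#' With four points the quadratic leaves a single residual degree of freedom,
#' so `F = (RSS_lin - RSS_quad) / (RSS_quad / 1)` on (1, 1) df.
#'
#' @param values Metric values (at least 4 finite).
#' @param midpoints Period midpoints.
#' @param alpha Significance level for preferring the quadratic.
#' @return One-row data frame: `f_statistic`, `p_value`, `df1`, `df2`,
#'   `rss_linear`, `rss_quadratic`, `preferred`.
#' @export
quadratic_vs_linear <- function(values, midpoints = c(1915, 1945, 1975, 2005),
                                alpha = 0.05) {
  ok <- is.finite(values) & is.finite(midpoints)
  y <- values[ok]; x <- midpoints[ok]
  if (length(y) < 4) stop("need at least 4 finite points")
  xc <- x - mean(x)   # centring keeps the quadratic design well-conditioned
  lin <- stats::lm(y ~ xc)
  quad <- stats::lm(y ~ xc + I(xc^2))
  rss1 <- sum(stats::residuals(lin)^2)
  rss2 <- sum(stats::residuals(quad)^2)
  df2 <- stats::df.residual(quad)
  eps <- max(1e-12, 1e-10 * max(1, sum(y^2)))
  if (rss2 < eps && (rss1 - rss2) < eps) {
    f <- 0; p <- 1   # both fits exact: no evidence of curvature
  } else {
    f <- (rss1 - rss2) / (rss2 / df2)
    p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  }
  data.frame(f_statistic = f, p_value = p, df1 = 1, df2 = df2,
             rss_linear = rss1, rss_quadratic = rss2,
             preferred = if (is.finite(p) && p < alpha) "quadratic" else "linear",
             stringsAsFactors = FALSE)
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom;
#' two-sided p.
#'
#' @param early,recent Numeric vectors (each >= 2 values).
#' @return List with `t`, `df`, `p_value`, `mean_early`, `mean_recent`.
#' @export
welch_t <- function(early, recent) {
  early <- early[is.finite(early)]; recent <- recent[is.finite(recent)]
  if (length(early) < 2 || length(recent) < 2)
    stop("both groups need at least 2 finite values")
  if (stats::var(early) == 0 && stats::var(recent) == 0) {
    same <- isTRUE(all.equal(mean(early), mean(recent)))
    return(list(t = if (same) 0 else sign(mean(early) - mean(recent)) * Inf,
                df = length(early) + length(recent) - 2,
                p_value = if (same) 1 else 0,
                mean_early = mean(early), mean_recent = mean(recent)))
  }
  ht <- stats::t.test(early, recent, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value,
       mean_early = mean(early), mean_recent = mean(recent))
}

#' Pearson correlation with t-based p value
#'
#' @param x,y Numeric vectors (>= 3 pairs, nonzero variance).
#' @return List with `r` and `p_value`.
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in one of the inputs")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p_value = ht$p.value)
}

#' Two-way fixed-effects ANOVA on slice Gini values
#'
#' Additive model `gini ~ family + period` on a complete design with one
#' observation per cell; with no replication the interaction is untestable
#' and serves as the residual. Reports F and p for each main effect.
#'
#' @param gini_table Data frame with columns `family`, `period`, `gini`
#'   (e.g. from [gini_by_slice()], one variant).
#' @return Data frame: `effect`, `df`, `sum_sq`, `mean_sq`, `f_statistic`,
#'   `p_value` (rows: family, period, residuals).
#' @export
gini_two_way_anova <- function(gini_table) {
  d <- gini_table[, c("family", "period", "gini")]
  if (any(is.na(d$gini))) stop("incomplete design: NA gini values")
  tab <- table(d$family, d$period)
  if (nrow(tab) < 2 || ncol(tab) < 2 || any(tab != 1))
    stop("incomplete design: need a complete family x period grid with one observation per cell")
  d$family <- factor(d$family); d$period <- factor(d$period)
  av <- stats::anova(stats::lm(gini ~ family + period, data = d))
  out <- data.frame(effect = c("family", "period", "residuals"),
                    df = av$Df, sum_sq = av$`Sum Sq`,
                    mean_sq = av$`Mean Sq`,
                    f_statistic = av$`F value`, p_value = av$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Early vs. recent period grouping
#'
#' Default split: first two periods (1900-1929, 1930-1959) vs. last two
#' (1960-1989, 1990-2020).
#' @param periods A [period_spec()].
#' @param early_labels Optional explicit early-period labels.
#' @return List with `early` and `recent` label vectors.
#' @export
early_recent_split <- function(periods = default_periods(),
                               early_labels = NULL) {
  if (is.null(early_labels))
    early_labels <- periods$label[seq_len(ceiling(nrow(periods) / 2))]
  list(early = early_labels,
       recent = setdiff(periods$label, early_labels))
}

#' Full trend analysis of slice metrics and Gini
#'
#' For each topology metric and the Gini, fits per-family and pooled linear
#' trends on period midpoints; adds the quadratic-vs-linear comparison for
#' Gini, Welch early-vs-recent tests for nodes and edges, the nodes-edges
#' Pearson correlation and the edges ~ nodes regression.
#'
#' @param metrics Table from [metrics_by_slice()].
#' @param ginis Table from [gini_by_slice()] (single variant).
#' @param periods A [period_spec()].
#' @return Tidy data frame with columns `analysis`, `family`, `metric`,
#'   `estimate`, `se`, `statistic`, `p_value`, `r_squared`, `n`.
#' @export
trend_table <- function(metrics, ginis, periods = default_periods()) {
  mids <- stats::setNames(periods$midpoint, periods$label)
  rows <- list()
  add <- function(analysis, family, metric, estimate = NA, se = NA,
                  statistic = NA, p_value = NA, r_squared = NA, n = NA) {
    rows[[length(rows) + 1]] <<- data.frame(
      analysis = analysis, family = family, metric = metric,
      estimate = estimate, se = se, statistic = statistic,
      p_value = p_value, r_squared = r_squared, n = n,
      stringsAsFactors = FALSE)
  }
  metric_names <- c("nodes", "edges", "density", "reciprocity",
                    "giant_fraction", "modularity")
  fams <- sort(unique(metrics$family))
  long <- metrics
  long$midpoint <- mids[long$period]
  gin <- ginis
  gin$midpoint <- mids[gin$period]

  for (m in metric_names) {
    for (f in fams) {
      sub <- long[long$family == f, ]
      ft <- try(fit_linear_trend(sub[[m]], sub$midpoint), silent = TRUE)
      if (!inherits(ft, "try-error"))
        add("linear_trend", f, m, ft$slope, ft$se, NA, ft$p_value,
            ft$r_squared, ft$n_points)
    }
    ft <- try(fit_linear_trend(long[[m]], long$midpoint), silent = TRUE)
    if (!inherits(ft, "try-error"))
      add("linear_trend", "pooled", m, ft$slope, ft$se, NA, ft$p_value,
          ft$r_squared, ft$n_points)
  }
  for (f in sort(unique(gin$family))) {
    sub <- gin[gin$family == f, ]
    ft <- try(fit_linear_trend(sub$gini, sub$midpoint), silent = TRUE)
    if (!inherits(ft, "try-error"))
      add("linear_trend", f, "gini", ft$slope, ft$se, NA, ft$p_value,
          ft$r_squared, ft$n_points)
    qv <- try(quadratic_vs_linear(sub$gini, sub$midpoint), silent = TRUE)
    if (!inherits(qv, "try-error"))
      add("quadratic_vs_linear", f, "gini", statistic = qv$f_statistic,
          p_value = qv$p_value, n = length(sub$gini))
  }
  ft <- try(fit_linear_trend(gin$gini, gin$midpoint), silent = TRUE)
  if (!inherits(ft, "try-error"))
    add("linear_trend", "pooled", "gini", ft$slope, ft$se, NA, ft$p_value,
        ft$r_squared, ft$n_points)

  split <- early_recent_split(periods)
  for (m in c("nodes", "edges")) {
    e <- long[[m]][long$period %in% split$early]
    r <- long[[m]][long$period %in% split$recent]
    wt <- try(welch_t(e, r), silent = TRUE)
    if (!inherits(wt, "try-error"))
      add("welch_early_vs_recent", "pooled", m,
          estimate = wt$mean_early - wt$mean_recent,
          statistic = wt$t, p_value = wt$p_value, n = length(e) + length(r))
  }
  pc <- try(pearson_cor(long$nodes, long$edges), silent = TRUE)
  if (!inherits(pc, "try-error"))
    add("pearson_nodes_edges", "pooled", "nodes~edges",
        estimate = pc$r, p_value = pc$p_value, n = nrow(long))
  en <- try(fit_linear_trend(long$edges, long$nodes), silent = TRUE)
  if (!inherits(en, "try-error"))
    add("edges_on_nodes", "pooled", "edges~nodes", en$slope, en$se, NA,
        en$p_value, en$r_squared, en$n_points)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sensitivity-analysis suite
#'
#' Recomputes slice metrics and Gini under every combination of minimum
#' edge-weight threshold, Gini variant and temporal binning, and summarises
#' the qualitative direction (sign of the pooled linear trend slope) of each
#' metric per configuration.
#'
#' @param records Filtered records.
#' @param thresholds Minimum edge weights (default `c(1, 5, 10)`).
#' @param gini_variants Gini variants to evaluate.
#' @param binnings Named list of [period_spec()] objects.
#' @param seed Louvain seed.
#' @return Tidy data frame: `binning`, `threshold`, `variant`, `metric`,
#'   `slope`, `p_value`, `direction`.
#' @export
sensitivity_suite <- function(records, thresholds = c(1, 5, 10),
                              gini_variants = c("participants_only",
                                                "include_zeros"),
                              binnings = list(default = default_periods(),
                                              decadal = alternative_periods("decadal"),
                                              forty = alternative_periods("forty")),
                              seed = 1L) {
  rows <- list()
  for (bn in names(binnings)) {
    periods <- binnings[[bn]]
    mids <- stats::setNames(periods$midpoint, periods$label)
    for (th in thresholds) {
      mt <- metrics_by_slice(records, periods, seed = seed, min_weight = th)
      mt$midpoint <- mids[mt$period]
      for (m in c("nodes", "edges", "density", "reciprocity",
                  "giant_fraction")) {
        ft <- try(fit_linear_trend(mt[[m]], mt$midpoint), silent = TRUE)
        if (inherits(ft, "try-error")) next
        rows[[length(rows) + 1]] <- data.frame(
          binning = bn, threshold = th, variant = NA_character_, metric = m,
          slope = ft$slope, p_value = ft$p_value,
          direction = sign(ft$slope), stringsAsFactors = FALSE)
      }
      gt <- gini_by_slice(records, periods, variants = gini_variants,
                          min_weight = th)
      gt$midpoint <- mids[gt$period]
      for (v in gini_variants) {
        sub <- gt[gt$variant == v, ]
        ft <- try(fit_linear_trend(sub$gini, sub$midpoint), silent = TRUE)
        if (inherits(ft, "try-error")) next
        rows[[length(rows) + 1]] <- data.frame(
          binning = bn, threshold = th, variant = v, metric = "gini",
          slope = ft$slope, p_value = ft$p_value,
          direction = sign(ft$slope), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
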