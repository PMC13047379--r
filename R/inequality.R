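# Holdings inequality. Holdings of a country in a slice are its total
# specimens held: international in-strength plus the domestic ledger. The
# Gini coefficient is computed by default over participants only (countries
# with nonzero holdings), so non-participation is not counted as inequality;
# the zero-inclusive variant is retained for sensitivity analysis.

#' Holdings distribution for one slice
#'
#' @param net A `flow_network`.
#' @return Object of class `holdings_distribution`: list with `family`,
#'   `period`, and `holdings` -- a named numeric vector (ISO3 -> specimens,
#'   international in-strength + domestic) restricted to countries with
#'   positive holdings.
#' @export
#' @examples
#' rec <- data.frame(family = "Canidae",
#'                   origin_country = c("KEN", "USA"),
#'                   holding_country = c("USA", "USA"),
#'                   year = c(1910, 1911), count = c(4, 5))
#' holdings_distribution(build_flow_network(rec))$holdings  # USA: 9
holdings_distribution <- function(net) {
  ns <- node_strengths(net)
  h <- stats::setNames(ns$in_strength + ns$domestic, ns$country)
  structure(list(family = net$family, period = net$period,
                 holdings = h[h > 0]),
            class = "holdings_distribution")
}

#' Gini coefficient
#'
#' Population estimator `G = sum_ij |x_i - x_j| / (2 n^2 mu)`; the
#' `sample_corrected` estimator multiplies by `n / (n - 1)`. The default
#' (`population`, `participants_only`) matches the convention of computing
#' inequality amongst countries actively holding specimens.
#'
#' @param values Non-negative numeric vector.
#' @param variant `"participants_only"` drops zero values before computing;
#'   `"include_zeros"` keeps them.
#' @param estimator `"population"` (default) or `"sample_corrected"`.
#' @return Numeric Gini in `[0, 1)` (population estimator).
#' @export
#' @examples
#' gini(c(100, 100, 100, 100))                      # 0
#' gini(c(1, 3))                                    # 0.25
#' gini(c(0, 0, 5, 5), variant = "include_zeros")   # 0.5
gini <- function(values, variant = c("participants_only", "include_zeros"),
                 estimator = c("population", "sample_corrected")) {
  variant <- match.arg(variant)
  estimator <- match.arg(estimator)
  x <- as.numeric(values)
  if (any(is.na(x))) stop("values must not contain NA")
  if (any(x < 0)) stop("values must be non-negative")
  if (variant == "participants_only") x <- x[x > 0]
  if (!length(x) || sum(x) == 0)
    stop("Gini undefined: no positive values after variant filtering")
  n <- length(x)
  x <- sort(x)
  g <- 2 * sum(seq_len(n) * x) / (n * sum(x)) - (n + 1) / n
  if (estimator == "sample_corrected") {
    if (n < 2) stop("sample-corrected Gini requires at least 2 values")
    g <- g * n / (n - 1)
  }
  g
}

#' Gini coefficients for every family x period slice
#'
#' For the `include_zeros` variant, zero-holding countries are the slice's
#' participating countries (node set plus domestic holders) with zero
#' holdings, i.e. pure exporters. Slices with no participants emit an `NA`
#' row.
#'
#' @param records Filtered records.
#' @param periods A [period_spec()].
#' @param variants Character vector of Gini variants.
#' @param estimator Gini estimator, see [gini()].
#' @param min_weight Optional edge-weight threshold applied to each slice
#'   network before computing holdings.
#' @return Tidy data frame: `family`, `period`, `variant`, `estimator`,
#'   `gini`, `n_participants`.
#' @export
gini_by_slice <- function(records, periods = default_periods(),
                          variants = "participants_only",
                          estimator = "population", min_weight = 1) {
  fams <- sort(unique(records$family))
  out <- list()
  for (f in fams) for (p in periods$label) {
    net <- build_flow_network(records, f, p, periods)
    if (min_weight > 1) net <- apply_weight_threshold(net, min_weight)
    ns <- node_strengths(net)
    all_holdings <- stats::setNames(ns$in_strength + ns$domestic, ns$country)
    for (v in variants) {
      vals <- if (v == "include_zeros") all_holdings else
        all_holdings[all_holdings > 0]
      g <- if (length(vals) && sum(vals) > 0)
        gini(vals, variant = "include_zeros", estimator = estimator)
      else NA_real_
      out[[paste(f, p, v)]] <- data.frame(
        family = f, period = p, variant = v, estimator = estimator,
        gini = g, n_participants = sum(all_holdings > 0),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
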