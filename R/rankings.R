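# Net importer/exporter rankings. Ranking key is the raw net count
# (in - out); the scale-free net balance is reported alongside but does not
# drive the ordering.

#' Net-flow table for one slice
#'
#' One row per country in the network's node set (countries with
#' international flow); domestic-only countries are excluded here because
#' their net international flow is identically zero.
#'
#' @param net A `flow_network`.
#' @return Data frame: `family`, `period`, `country`, `in_strength`,
#'   `out_strength`, `net`, `net_balance`.
#' @export
net_flow_table <- function(net) {
  ns <- node_strengths(net)
  ns <- ns[ns$country %in% net$nodes, , drop = FALSE]
  out <- data.frame(family = rep(net$family, nrow(ns)),
                    period = rep(net$period, nrow(ns)),
                    ns[, c("country", "in_strength", "out_strength",
                           "net", "net_balance")],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Top net importers or exporters
#'
#' Importers sort by net descending, exporters by net ascending; ties are
#' broken by ISO3 code ascending. Fewer than `k` rows returns all.
#'
#' @param table A net-flow table from [net_flow_table()].
#' @param direction `"importers"` or `"exporters"`.
#' @param k Number of countries (default 5).
#' @return Ranked subset of `table` with a `rank` column.
#' @export
top_net <- function(table, direction = c("importers", "exporters"), k = 5L) {
  direction <- match.arg(direction)
  stopifnot(k >= 1)
  ord <- if (direction == "importers")
    order(-table$net, table$country) else order(table$net, table$country)
  out <- utils::head(table[ord, , drop = FALSE], k)
  out$rank <- seq_len(nrow(out))
  out$direction <- direction
  rownames(out) <- NULL
  out
}

#' Rankings for every slice
#'
#' Per-family slices plus (optionally) an all-families pooled slice per
#' period, as displayed in combined net-flow summaries.
#'
#' @param records Filtered records.
#' @param periods A [period_spec()].
#' @param k Top-k per direction.
#' @param pooled Also compute family-pooled rankings (family `"all"`).
#' @return Long data frame of ranked importer and exporter rows.
#' @export
rankings_by_slice <- function(records, periods = default_periods(), k = 5L,
                              pooled = TRUE) {
  fams <- sort(unique(records$family))
  out <- list()
  for (p in periods$label) {
    slices <- as.list(fams)
    if (pooled) slices <- c(slices, list(NULL))
    for (f in slices) {
      net <- build_flow_network(records, f, p, periods)
      if (!nrow(net$edges)) next
      tbl <- net_flow_table(net)
      out[[length(out) + 1]] <- rbind(top_net(tbl, "importers", k),
                                      top_net(tbl, "exporters", k))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
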