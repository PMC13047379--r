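# Directed, weighted country-to-country flow networks, one per
# family x period slice. Nodes are countries incident to at least one
# international edge; edge weight is the summed specimen count of all records
# on that origin -> holding pair. Domestic flows (origin == holding) live in a
# separate ledger: excluded from every topology metric, retained for holdings.

#' Build a flow network for one slice
#'
#' Aggregates filtered records into a directed weighted country graph.
#' Records with `origin == holding` are routed to the domestic ledger and do
#' not create nodes; the node set is derived from international edges only.
#' An empty slice yields a valid empty network.
#'
#' @param records Filtered records (see [filter_records()]).
#' @param family Optional family to slice on; `NULL` pools all families.
#' @param period Optional period label to slice on; `NULL` pools all years.
#' @param periods A [period_spec()] used to resolve `period`.
#' @return Object of class `flow_network`: list with `family`, `period`,
#'   `edges` (data frame `origin`, `holding`, `weight`), `domestic` (named
#'   integer vector), `nodes` (sorted character vector).
#' @export
#' @examples
#' rec <- data.frame(family = "Canidae",
#'                   origin_country = c("KEN", "KEN", "USA"),
#'                   holding_country = c("USA", "USA", "USA"),
#'                   year = c(1910, 1912, 1915), count = c(1, 2, 5))
#' net <- build_flow_network(rec)
#' net$edges      # KEN -> USA, weight 3
#' net$domestic   # USA: 5
build_flow_network <- function(records, family = NULL, period = NULL,
                               periods = default_periods()) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(family)) keep <- keep & records$family == family
  if (!is.null(period))
    keep <- keep & assign_period(records$year, periods) == period
  rec <- records[keep, , drop = FALSE]

  dom_mask <- rec$origin_country == rec$holding_country
  dom <- rec[dom_mask, , drop = FALSE]
  int <- rec[!dom_mask, , drop = FALSE]

  if (nrow(int)) {
    agg <- stats::aggregate(count ~ origin_country + holding_country,
                            data = int, FUN = sum)
    edges <- data.frame(origin = agg$origin_country,
                        holding = agg$holding_country,
                        weight = as.integer(agg$count),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$origin, edges$holding), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(origin = character(0), holding = character(0),
                        weight = integer(0), stringsAsFactors = FALSE)
  }
  domestic <- if (nrow(dom)) {
    v <- tapply(dom$count, dom$origin_country, sum)
    stats::setNames(as.integer(v), names(v))
  } else stats::setNames(integer(0), character(0))

  structure(list(family = if (is.null(family)) "all" else family,
                 period = if (is.null(period)) "all" else period,
                 edges = edges,
                 domestic = domestic,
                 nodes = sort(unique(c(edges$origin, edges$holding)))),
            class = "flow_network")
}

#' @export
print.flow_network <- function(x, ...) {
  cat(sprintf("<flow_network %s / %s: %d countries, %d flows, %d domestic ledger entries>\n",
              x$family, x$period, length(x$nodes), nrow(x$edges),
              length(x$domestic)))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = net$nodes)
}

#' Network size: participating countries
#'
#' Number of countries with at least one international in- or out-edge
#' (isolates and domestic-only countries are not counted).
#' @param net A `flow_network`.
#' @return Integer.
#' @export
network_size <- function(net) length(net$nodes)

#' Network complexity: unique directed flows
#' @param net A `flow_network`.
#' @return Integer number of unique origin -> holding pairs.
#' @export
network_complexity <- function(net) nrow(net$edges)

#' Directed density
#'
#' Realised fraction of possible directed edges,
#' `edges / (nodes * (nodes - 1))`. Returns 0 for networks with fewer than
#' two nodes (convention; such slices carry no meaningful density).
#' @param net A `flow_network`.
#' @return Numeric in `[0, 1]`.
#' @export
flow_density <- function(net) {
  n <- network_size(net)
  if (n < 2) return(0)
  network_complexity(net) / (n * (n - 1))
}

#' Edge reciprocity
#'
#' Weight-blind fraction of existing directed edges whose reverse edge also
#' exists (the igraph default-mode definition). Undefined (NA) on edgeless
#' networks.
#' @param net A `flow_network`.
#' @return Numeric in `[0, 1]`, or `NA` if there are no edges.
#' @export
flow_reciprocity <- function(net) {
  if (network_complexity(net) == 0) return(NA_real_)
  igraph::reciprocity(as_igraph(net), ignore.loops = TRUE, mode = "default")
}

#' Giant weakly-connected component fraction
#'
#' Share of participating countries in the largest weakly connected component
#' (edge direction ignored).
#' @param net A `flow_network`.
#' @return Numeric in `(0, 1]`, or `NA` for an empty network.
#' @export
giant_component_fraction <- function(net) {
  if (network_size(net) == 0) return(NA_real_)
  comp <- igraph::components(as_igraph(net), mode = "weak")
  max(comp$csize) / network_size(net)
}

#' Louvain modularity on the undirected weight-summed projection
#'
#' Collapses the directed network to an undirected graph, summing the weights
#' of antiparallel edges, then runs the Louvain algorithm. Louvain is
#' stochastic, so a seed is required and the best modularity over `restarts`
#' seeded runs is reported.
#'
#' @param net A `flow_network` with at least one edge.
#' @param seed Integer seed.
#' @param restarts Number of seeded restarts (default 5).
#' @return List with `modularity` (numeric) and `partition` (named integer
#'   membership vector).
#' @export
modularity_louvain <- function(net, seed = 1L, restarts = 5L) {
  if (network_complexity(net) == 0)
    return(list(modularity = NA_real_, partition = integer(0)))
  g <- igraph::as_undirected(as_igraph(net), mode = "collapse",
                             edge.attr.comb = list(weight = "sum"))
  best <- NULL
  for (i in seq_len(restarts)) {
    set.seed(seed + i - 1L)
    cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
    q <- igraph::modularity(cl)
    if (is.null(best) || q > best$modularity)
      best <- list(modularity = q,
                   partition = stats::setNames(as.integer(igraph::membership(cl)),
                                               names(igraph::membership(cl))))
  }
  best
}

#' Per-country flow statistics
#'
#' Weighted in- and out-strengths over international edges, the domestic
#' ledger, raw net flow (`in - out`) and the normalised net balance
#' `(in - out) / (in + out)` (NA when a country has no international flow).
#' Covers every country with any activity, international or domestic.
#'
#' @param net A `flow_network`.
#' @return Data frame: `country`, `in_strength`, `out_strength`, `domestic`,
#'   `net`, `net_balance`.
#' @export
node_strengths <- function(net) {
  countries <- sort(unique(c(net$nodes, names(net$domestic))))
  s_in <- s_out <- stats::setNames(numeric(length(countries)), countries)
  if (nrow(net$edges)) {
    ti <- tapply(net$edges$weight, net$edges$holding, sum)
    to <- tapply(net$edges$weight, net$edges$origin, sum)
    s_in[names(ti)] <- ti
    s_out[names(to)] <- to
  }
  dom <- stats::setNames(numeric(length(countries)), countries)
  dom[names(net$domestic)] <- net$domestic
  tot <- s_in + s_out
  data.frame(country = countries,
             in_strength = as.numeric(s_in),
             out_strength = as.numeric(s_out),
             domestic = as.numeric(dom),
             net = as.numeric(s_in - s_out),
             net_balance = ifelse(tot > 0, (s_in - s_out) / tot, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Top-k edges by weight
#'
#' Ties broken by weight descending, then origin and holding codes ascending,
#' so the selection is deterministic. All edges are returned when fewer than
#' `k` exist (mirrors "top 200 flows, or all flows if fewer").
#'
#' @param net A `flow_network`.
#' @param k Number of edges (>= 1).
#' @return Edge data frame subset.
#' @export
top_k_edges <- function(net, k = 200L) {
  stopifnot(k >= 1)
  e <- net$edges
  e <- e[order(-e$weight, e$origin, e$holding), , drop = FALSE]
  rownames(e) <- NULL
  utils::head(e, k)
}

#' Apply a minimum edge-weight threshold
#'
#' Removes international edges lighter than `min_weight` and recomputes the
#' node set (countries left without edges drop out). The domestic ledger is
#' untouched.
#'
#' @param net A `flow_network`.
#' @param min_weight Minimum retained weight (>= 1).
#' @return A thresholded `flow_network`.
#' @export
apply_weight_threshold <- function(net, min_weight = 1) {
  stopifnot(min_weight >= 1)
  edges <- net$edges[net$edges$weight >= min_weight, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(family = net$family, period = net$period, edges = edges,
                 domestic = net$domestic,
                 nodes = sort(unique(c(edges$origin, edges$holding)))),
            class = "flow_network")
}

#' All slice-level topology metrics
#'
#' @param net A `flow_network`.
#' @param seed,restarts Passed to [modularity_louvain()].
#' @return One-row data frame: `nodes`, `edges`, `density`, `reciprocity`,
#'   `giant_fraction`, `modularity`, `edges_to_nodes`.
#' @export
network_metrics <- function(net, seed = 1L, restarts = 5L) {
  n <- network_size(net)
  e <- network_complexity(net)
  data.frame(
    nodes = n, edges = e,
    density = flow_density(net),
    reciprocity = flow_reciprocity(net),
    giant_fraction = giant_component_fraction(net),
    modularity = modularity_louvain(net, seed, restarts)$modularity,
    edges_to_nodes = if (n > 0) e / n else NA_real_
  )
}

#' Topology metrics for every family x period slice
#'
#' @param records Filtered records.
#' @param periods A [period_spec()].
#' @param seed,restarts Louvain control.
#' @param min_weight Optional edge-weight threshold applied before metrics.
#' @return Tidy data frame, one row per family x period.
#' @export
metrics_by_slice <- function(records, periods = default_periods(),
                             seed = 1L, restarts = 5L, min_weight = 1) {
  fams <- sort(unique(records$family))
  out <- list()
  for (f in fams) for (p in periods$label) {
    net <- build_flow_network(records, f, p, periods)
    if (min_weight > 1) net <- apply_weight_threshold(net, min_weight)
    out[[paste(f, p)]] <- cbind(
      data.frame(family = f, period = p, stringsAsFactors = FALSE),
      network_metrics(net, seed = seed, restarts = restarts))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
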