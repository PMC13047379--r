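# Independent oracles. These deliberately avoid the code paths (and, for the
# graph metrics, the library) used by the package: brute-force pairwise sums,
# set enumeration, union-find, and hand-rolled normal equations.

# Gini by literal pairwise mean absolute difference.
oracle_gini <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

# Directed-graph metrics from a bare edge data frame (origin, holding).
oracle_density <- function(edges) {
  nodes <- unique(c(edges$origin, edges$holding))
  n <- length(nodes)
  if (n < 2) return(0)
  nrow(unique(edges[, c("origin", "holding")])) / (n * (n - 1))
}

oracle_reciprocity <- function(edges) {
  if (!nrow(edges)) return(NA_real_)
  keys <- paste(edges$origin, edges$holding)
  rev_keys <- paste(edges$holding, edges$origin)
  mean(rev_keys %in% keys)
}

# Giant weak-component fraction via union-find.
oracle_giant_fraction <- function(edges) {
  nodes <- sort(unique(c(edges$origin, edges$holding)))
  if (!length(nodes)) return(NA_real_)
  parent <- seq_along(nodes)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(edges))) {
    a <- find(match(edges$origin[k], nodes))
    b <- find(match(edges$holding[k], nodes))
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  max(table(roots)) / length(nodes)
}

# Newman modularity of an undirected weighted graph under a membership
# vector, computed straight from the definition via the adjacency matrix.
oracle_modularity <- function(edges, membership) {
  nodes <- names(membership)
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    i <- edges$a[k]; j <- edges$b[k]; w <- edges$w[k]
    A[i, j] <- A[i, j] + w
    if (i != j) A[j, i] <- A[j, i] + w
  }
  deg <- rowSums(A)
  m2 <- sum(deg)            # 2m
  q <- 0
  for (i in nodes) for (j in nodes)
    if (membership[i] == membership[j])
      q <- q + A[i, j] - deg[i] * deg[j] / m2
  q / m2
}

# All set partitions of n elements as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxv) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1]] <<- prefix; return() }
    for (v in seq_len(maxv + 1)) recurse(c(prefix, v), max(maxv, v))
  }
  recurse(integer(0), 0L)
  out
}

# Exhaustive-search optimal modularity over every partition (feasible n <= 8).
oracle_best_modularity <- function(edges, nodes) {
  best <- -Inf
  for (p in all_partitions(length(nodes))) {
    memb <- stats::setNames(p, nodes)
    q <- oracle_modularity(edges, memb)
    if (q > best) best <- q
  }
  best
}

# OLS via explicit normal equations, with SE, t-based p and R^2.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- slope / se
  list(slope = slope, intercept = intercept, se = se,
       p = 2 * stats::pt(-abs(tval), n - 2), r2 = 1 - rss / tss, rss = rss)
}

# Degree-k polynomial fit RSS by normal equations on the Vandermonde matrix.
oracle_poly_rss <- function(x, y, degree) {
  X <- outer(x - mean(x), 0:degree, `^`)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  sum((y - X %*% beta)^2)
}

# Welch statistic straight from the textbook formulas.
oracle_welch <- function(a, b) {
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

oracle_pearson <- function(x, y) {
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  n <- length(x)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# Two-way additive ANOVA sums of squares by direct decomposition.
oracle_two_way_ss <- function(d) {
  gm <- mean(d$gini)
  fam_means <- tapply(d$gini, d$family, mean)
  per_means <- tapply(d$gini, d$period, mean)
  a <- length(fam_means); b <- length(per_means)
  ss_fam <- b * sum((fam_means - gm)^2)
  ss_per <- a * sum((per_means - gm)^2)
  ss_tot <- sum((d$gini - gm)^2)
  list(family = ss_fam, period = ss_per,
       residual = ss_tot - ss_fam - ss_per, total = ss_tot)
}

# Random directed graph as an edge data frame (no self-loops, no duplicates).
random_edges <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- LETTERS[seq_len(n_nodes)]
  pairs <- expand.grid(origin = nodes, holding = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$origin != pairs$holding, ]
  pick <- pairs[sample(nrow(pairs), min(n_edges, nrow(pairs))), ]
  pick$weight <- sample(1:20, nrow(pick), replace = TRUE)
  rownames(pick) <- NULL
  pick
}

# Wrap an edge data frame as a flow_network without going through records.
edges_to_net <- function(edges) {
  structure(list(family = "test", period = "test",
                 edges = edges[, c("origin", "holding", "weight")],
                 domestic = stats::setNames(integer(0), character(0)),
                 nodes = sort(unique(c(edges$origin, edges$holding)))),
            class = "flow_network")
}
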