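#' Threshold a connectivity matrix by connection density
#'
#' Retains the K strongest off-diagonal weights, where
#' `K = round(d * n * (n - 1) / 2)` (half-up), as a weighted -- not
#' binarized -- undirected network. Ties at the K-th weight are broken by
#' lexicographic channel-pair order so the result is deterministic.
#'
#' @param m Symmetric connectivity matrix (e.g. an [sl_matrix()]).
#' @param d Connection density in `(0, 1]`.
#' @return An object of class `thresholded_network` with fields `weights`
#'   (matrix, zeros where edges were removed), `density` and
#'   `retained_edges`.
#' @export
threshold_by_density <- function(m, d) {
  if (!(d > 0 && d <= 1)) stop("density must lie in (0, 1]")
  m <- unclass(m)
  n <- nrow(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[upper.tri(m)]
  K <- as.integer(round_half_up(d * nrow(ut)))
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(K)]
  out <- matrix(0, n, n, dimnames = dimnames(m))
  out[cbind(ut[keep, 1], ut[keep, 2])] <- w[keep]
  out <- out + t(out)
  structure(list(weights = out, density = d, retained_edges = K),
            class = "thresholded_network")
}

net_weights <- function(net) {
  if (inherits(net, "thresholded_network")) return(net$weights)
  w <- unclass(net)
  diag(w) <- 0
  w
}

# mean weighted nodal clustering, geometric-mean triangle form on
# max-normalized weights (nodes with degree < 2 contribute 0)
weighted_clustering <- function(w) {
  mx <- max(w)
  if (mx <= 0) return(0)
  wh <- (w / mx)^(1 / 3)
  tri <- diag(wh %*% wh %*% wh)
  k <- colSums(w > 0)
  ci <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  mean(ci)
}

shortest_path_lengths <- function(w) {
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

# mean inverse shortest-path length over distinct pairs; Inf -> 0
efficiency_from_dist <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

#' Global weighted network measures
#'
#' Computes the weighted clustering coefficient `C` (geometric-mean
#' triangle form on max-normalized weights), the characteristic path
#' length `L` (mean shortest-path length with edge length = 1/weight,
#' averaged over pairs of the largest connected component so that sparse,
#' fragmented networks keep a finite value), and global efficiency `Eg`
#' (mean inverse shortest-path length over all pairs; disconnected pairs
#' contribute 0).
#'
#' @param net A [threshold_by_density()] result or a weighted adjacency
#'   matrix.
#' @return Named list with `C`, `L`, `Eg`.
#' @export
global_metrics <- function(net) {
  w <- net_weights(net)
  if (all(w == 0)) stop("empty network: no retained edges")
  d <- shortest_path_lengths(w)
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    w > 0, mode = "undirected", diag = FALSE))
  big <- which(comp$membership == which.max(comp$csize))
  dl <- d[big, big, drop = FALSE]
  L <- if (length(big) >= 2) mean(dl[upper.tri(dl)]) else NA_real_
  list(C = weighted_clustering(w), L = L, Eg = efficiency_from_dist(d))
}

#' Nodal weighted network measures
#'
#' Strength `s` (sum of incident weights), betweenness centrality `b`
#' (number of shortest paths through the node on the 1/weight distance
#' graph), and local efficiency `El` (global efficiency of each node's
#' neighbourhood subgraph, on weights normalized by the network maximum so
#' `El` lies in `[0, 1]`).
#'
#' @inheritParams global_metrics
#' @return Data frame with columns `node`, `strength`, `betweenness`,
#'   `local_eff`.
#' @export
nodal_metrics <- function(net) {
  w <- net_weights(net)
  if (all(w == 0)) stop("empty network: no retained edges")
  labels <- rownames(w) %||% paste0("ch", seq_len(nrow(w)))
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  btw <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight)
  wn <- w / max(w)
  el <- vapply(seq_len(nrow(w)), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- wn[nb, nb, drop = FALSE]
    if (all(sub == 0)) return(0)
    efficiency_from_dist(shortest_path_lengths(sub))
  }, numeric(1))
  data.frame(node = labels, strength = rowSums(w), betweenness = as.numeric(btw),
             local_eff = el, row.names = NULL, stringsAsFactors = FALSE)
}

#' Surrogate-normalized clustering, path length and small-worldness
#'
#' Normalizes `C` and `L` against an ensemble of surrogate networks that
#' preserve the degree sequence of the thresholded topology
#' (degree-preserving rewiring) with the retained weights randomly
#' reassigned to the rewired edges: `gamma = C / <C_surr>`,
#' `lambda = L / <L_surr>`, `sigma = gamma / lambda`.
#'
#' @inheritParams global_metrics
#' @param n_surrogates Ensemble size (default 50).
#' @param seed Integer seed; the ensemble is reproducible.
#' @return Named list with `gamma`, `lambda`, `sigma`.
#' @export
normalized_metrics <- function(net, n_surrogates = 50L, seed = 1L) {
  if (n_surrogates < 1) stop("n_surrogates must be >= 1")
  w <- net_weights(net)
  obs <- global_metrics(w)
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected",
                                           diag = FALSE)
  weights <- w[upper.tri(w)][w[upper.tri(w)] > 0]
  set.seed(seed)
  cs <- ls_ <- numeric(n_surrogates)
  for (r in seq_len(n_surrogates)) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(
      niter = max(100L, 10L * igraph::ecount(g))))
    el <- igraph::as_edgelist(gr, names = FALSE)
    ws <- matrix(0, nrow(w), ncol(w))
    ws[el] <- sample(weights)
    ws <- ws + t(ws)
    mr <- global_metrics(ws)
    cs[r] <- mr$C
    ls_[r] <- mr$L
  }
  if (!is.finite(mean(cs)) || mean(cs) <= 0 || !is.finite(mean(ls_)))
    stop("degenerate surrogate ensemble")
  gamma <- obs$C / mean(cs)
  lambda <- obs$L / mean(ls_)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' Erdos-Renyi full-connection density bound
#'
#' The density `2 ln(N) / N` above which an Erdos-Renyi random graph on
#' `N` nodes is almost surely connected (about 23.2% for 29 nodes).
#'
#' @param N Number of nodes (>= 2).
#' @return Density as a fraction.
#' @export
er_full_connection_density <- function(N) {
  if (N < 2) stop("N must be >= 2")
  2 * log(N) / N
}
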