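# drop covariates that carry no information (single-level factors,
# zero-variance numerics), which would break the design matrix
clean_covariates <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  df <- as.data.frame(covariates)
  keep <- vapply(df, function(v) {
    if (is.numeric(v)) stats::sd(v) > .Machine$double.eps
    else length(unique(v)) > 1
  }, logical(1))
  if (!any(keep)) return(NULL)
  df[, keep, drop = FALSE]
}

#' Covariate-adjusted permutation test for a group difference
#'
#' Two-group permutation inference on a per-subject scalar (mean SL or a
#' network metric). The observed statistic is the t-value of the group
#' coefficient in `lm(value ~ group + covariates)`. Covariates are handled
#' by the Freedman-Lane scheme: the reduced (covariates-only) model is
#' fitted once, its residuals are permuted and added back to its fitted
#' values, and the group t is recomputed on each reconstructed response
#' under the fixed design. Without covariates this reduces to the ordinary
#' relabeling test with the pooled-variance t.
#'
#' @param values Numeric per-subject vector.
#' @param groups Factor (or coercible) with exactly two levels; group sizes
#'   are preserved under permutation.
#' @param covariates Optional data frame of nuisance covariates (e.g. age,
#'   sex, IQ).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param alternative `"two.sided"` (default), or the one-sided
#'   `"greater"`/`"less"` on the first-minus-second level contrast.
#' @return An object of class `permutation_result` with `observed_t`,
#'   `p_value`, `n_perm`, `seed`, `alternative`.
#' @export
permutation_test <- function(values, groups, covariates = NULL,
                             n_perm = 10000L, seed = 1L,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) < 2)) stop("each group needs at least 2 subjects")
  if (!all(is.finite(values))) stop("values must be finite")
  n <- length(values)
  covariates <- clean_covariates(covariates)
  gdum <- as.numeric(groups == levels(groups)[1])
  Z <- if (is.null(covariates)) matrix(1, n, 1) else
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  X <- cbind(Z, group = gdum)
  j <- ncol(X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design matrix is rank deficient")
  xtxinv_jj <- chol2inv(qr.R(qx))[j, j]
  tstat_batch <- function(Y) {
    cf <- qr.coef(qx, Y)
    res <- Y - X %*% cf
    s2 <- colSums(res^2) / (n - ncol(X))
    tv <- cf[j, ] / sqrt(s2 * xtxinv_jj)
    # a response the design fits exactly has only rounding noise left in
    # both numerator and denominator; call that t = 0, not their ratio
    tv[!is.finite(tv) | s2 <= 1e-24 * (colMeans(Y^2) + 1)] <- 0
    unname(tv)
  }
  t_obs <- tstat_batch(matrix(values, ncol = 1))[1]
  qz <- qr(Z)
  fit_red <- qr.fitted(qz, values)
  res_red <- values - fit_red
  set.seed(seed)
  t_null <- numeric(n_perm)
  chunk <- 2000L
  done <- 0L
  while (done < n_perm) {
    b <- min(chunk, n_perm - done)
    P <- vapply(seq_len(b), function(k) res_red[sample.int(n)], numeric(n))
    t_null[done + seq_len(b)] <- tstat_batch(fit_red + P)
    done <- done + b
  }
  exceed <- switch(alternative,
                   two.sided = sum(abs(t_null) >= abs(t_obs)),
                   greater = sum(t_null >= t_obs),
                   less = sum(t_null <= t_obs))
  structure(list(observed_t = t_obs,
                 p_value = (1 + exceed) / (n_perm + 1),
                 n_perm = n_perm, seed = seed, alternative = alternative,
                 null_t = t_null),
            class = "permutation_result")
}

#' Upper-tail critical value of the t distribution
#'
#' @param tail_p One-tailed probability in `(0, 0.5)`.
#' @param df Degrees of freedom (>= 1).
#' @return The upper `tail_p` quantile of the central t distribution
#'   (e.g. 2.61 for `tail_p = 0.005`, `df = 142`).
#' @export
critical_t <- function(tail_p, df) {
  if (!(tail_p > 0 && tail_p < 0.5)) stop("tail_p must lie in (0, 0.5)")
  if (df < 1) stop("df must be >= 1")
  stats::qt(1 - tail_p, df)
}

# pooled-variance two-sample t for every column of X, (group1 - group2)
edgewise_t <- function(X, g1_idx, g2_idx) {
  n1 <- length(g1_idx); n2 <- length(g2_idx)
  m1 <- colMeans(X[g1_idx, , drop = FALSE])
  m2 <- colMeans(X[g2_idx, , drop = FALSE])
  ss1 <- colSums(X[g1_idx, , drop = FALSE]^2) - n1 * m1^2
  ss2 <- colSums(X[g2_idx, , drop = FALSE]^2) - n2 * m2^2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  tv <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tv[!is.finite(tv) | sp2 <= 1e-24 * (m1^2 + m2^2 + 1)] <- 0
  tv
}

# connected components of an edge list over n nodes; returns per-component
# edge membership (components with >= 1 edge only)
edge_components <- function(edges, n_nodes) {
  if (nrow(edges) == 0) return(list())
  parent <- seq_len(n_nodes)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(edges[, 1], find, integer(1))
  split(seq_len(nrow(edges)), roots)
}

#' Network-based statistic (NBS) on edge-wise connectivity differences
#'
#' Mass-univariate pooled-variance t-tests at every edge of a per-subject
#' connectivity stack; edges exceeding an uncorrected t-threshold form the
#' suprathreshold graph, whose connected components are scored by their
#' number of links. Family-wise-corrected p-values come from the
#' permutation null of the maximal component size under group relabeling
#' (sizes preserved).
#'
#' @param matrices List of symmetric subject matrices, or a 3-d array
#'   (subjects x nodes x nodes).
#' @param groups Two-level factor over subjects.
#' @param t_threshold Uncorrected edge threshold (default 2.61, the upper
#'   0.005 t quantile at 142 df).
#' @param n_perm Number of relabelings (default 10000).
#' @param seed Integer seed.
#' @param alternative `"greater"` (default) keeps edges with
#'   t(first level - second level) above the threshold; `"less"` the
#'   mirrored contrast; `"two.sided"` uses |t|.
#' @return An object of class `nbs_result`: suprathreshold `edges` (data
#'   frame with node indices, labels, t), `components` (list of edge-index
#'   vectors, decreasing size), `component_sizes` (links), `corrected_p`,
#'   and the permutation `null_max_size` distribution. With no
#'   suprathreshold edges the result has zero components and is a
#'   no-finding, not an error.
#' @export
nbs <- function(matrices, groups, t_threshold = 2.61, n_perm = 10000L,
                seed = 1L, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.list(matrices)) {
    matrices <- simplify2array(matrices)          # nodes x nodes x subjects
    matrices <- aperm(matrices, c(3, 1, 2))
  }
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) < 2)) stop("each group needs at least 2 subjects")
  n_sub <- dim(matrices)[1]
  n_nodes <- dim(matrices)[2]
  labels <- dimnames(matrices)[[2]] %||% paste0("ch", seq_len(n_nodes))
  ut <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  X <- matrix(matrices, nrow = n_sub)[, (ut[, 2] - 1) * n_nodes + ut[, 1],
                                      drop = FALSE]
  keep_fun <- switch(alternative,
                     greater = function(t) t > t_threshold,
                     less = function(t) t < -t_threshold,
                     two.sided = function(t) abs(t) > t_threshold)
  g1 <- which(groups == levels(groups)[1])
  g2 <- which(groups == levels(groups)[2])
  t_obs <- edgewise_t(X, g1, g2)
  supra <- which(keep_fun(t_obs))
  comps <- unname(edge_components(ut[supra, , drop = FALSE], n_nodes))
  sizes <- vapply(comps, length, integer(1))
  ord <- order(-sizes)
  comps <- lapply(comps[ord], function(ix) supra[ix])
  sizes <- sizes[ord]
  set.seed(seed)
  null_max <- integer(n_perm)
  for (p in seq_len(n_perm)) {
    idx <- sample.int(n_sub)
    tp <- edgewise_t(X, idx[seq_along(g1)], idx[-seq_along(g1)])
    sp <- which(keep_fun(tp))
    if (length(sp)) {
      cs <- edge_components(ut[sp, , drop = FALSE], n_nodes)
      null_max[p] <- max(vapply(cs, length, integer(1)))
    }
  }
  corrected_p <- if (length(sizes))
    vapply(sizes, function(s) (1 + sum(null_max >= s)) / (n_perm + 1),
           numeric(1)) else numeric(0)
  edges <- data.frame(i = ut[supra, 1], j = ut[supra, 2],
                      from = labels[ut[supra, 1]], to = labels[ut[supra, 2]],
                      t = t_obs[supra], stringsAsFactors = FALSE)
  structure(list(t_threshold = t_threshold, edges = edges,
                 components = lapply(comps, function(ix)
                   edges[match(ix, supra), , drop = FALSE]),
                 component_sizes = sizes, corrected_p = corrected_p,
                 max_component_links = if (length(sizes)) sizes[1] else 0L,
                 null_max_size = null_max, n_perm = n_perm, seed = seed,
                 alternative = alternative),
            class = "nbs_result")
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of both variables after linear
#' regression on the covariates, with the t-transform p-value at
#' `df = n - n_covariates - 2`.
#'
#' @param metric,score Numeric per-subject vectors.
#' @param covariates Data frame of controlling variables (may be NULL for
#'   a plain correlation).
#' @return An object of class `correlation_result` with `r`, `p_value`,
#'   `n`, `df`, `covariates`.
#' @export
partial_correlation <- function(metric, score, covariates = NULL) {
  covariates <- clean_covariates(covariates)
  ok <- stats::complete.cases(metric, score,
                              if (is.null(covariates)) rep(TRUE, length(metric))
                              else covariates)
  metric <- metric[ok]; score <- score[ok]
  n <- length(metric)
  k <- if (is.null(covariates)) 0L else ncol(as.data.frame(covariates))
  if (n < k + 3) stop("need at least ", k + 3, " complete cases")
  if (stats::sd(metric) < .Machine$double.eps ||
      stats::sd(score) < .Machine$double.eps)
    stop("constant metric or score")
  if (k > 0) {
    Z <- stats::model.matrix(~ ., data = as.data.frame(covariates)[ok, ,
                                                                   drop = FALSE])
    metric <- stats::lm.fit(Z, metric)$residuals
    score <- stats::lm.fit(Z, score)$residuals
  }
  r <- stats::cor(metric, score)
  df <- n - k - 2
  tval <- r * sqrt(df / (1 - r^2))
  structure(list(r = r, p_value = 2 * stats::pt(-abs(tval), df), n = n,
                 df = df,
                 covariates = if (k > 0) colnames(as.data.frame(covariates))
                 else character(0)),
            class = "correlation_result")
}

#' Demographic comparison table for a two-group cohort
#'
#' Chi-square test (1 df, no continuity correction) on the 2x2 sex table
#' and pooled-variance two-sample t-tests on age, education and IQ,
#' mirroring the conventional cohort-description table.
#'
#' @param meta Metadata data frame with columns `group`, `sex`, `age`,
#'   `education`, `iq`.
#' @return Data frame with columns `variable`, `statistic`, `df`,
#'   `p_value`.
#' @export
demographic_tests <- function(meta) {
  groups <- droplevels(as.factor(meta$group))
  if (nlevels(groups) != 2) stop("both groups must be present")
  tab <- table(groups, meta$sex)
  if (any(dim(tab) != 2) || any(tab == 0))
    stop("sex table has empty cells")
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  rows <- list(data.frame(variable = "sex",
                          statistic = unname(chi$statistic),
                          df = unname(chi$parameter),
                          p_value = chi$p.value))
  for (v in c("age", "education", "iq")) {
    tt <- stats::t.test(meta[[v]] ~ groups, var.equal = TRUE)
    rows[[v]] <- data.frame(variable = v, statistic = unname(tt$statistic),
                            df = unname(tt$parameter), p_value = tt$p.value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
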