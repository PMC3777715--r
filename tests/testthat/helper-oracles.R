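# Independent brute-force oracles, deliberately naive: every quantity is
# computed by direct enumeration in plain R, sharing no code with the
# package implementations they check.

# synchronization likelihood by the literal definition: delay-embed within
# epochs, open Theiler/outer window on the concatenated sample index,
# critical distance = k-th smallest candidate distance (ties included),
# instantaneous SL = |joint hits| / max(|hits_x|, |hits_y|)
sl_oracle <- function(x, y, params, metric = "euclidean") {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (is.vector(y)) y <- matrix(y, nrow = 1)
  lag <- params$lag; m <- params$m
  E <- nrow(x); S <- ncol(x); Ne <- S - (m - 1) * lag
  embed_all <- function(z) {
    v <- vector("list", E * Ne); g <- integer(E * Ne)
    idx <- 0L
    for (e in seq_len(E)) for (i in seq_len(Ne)) {
      idx <- idx + 1L
      v[[idx]] <- z[e, i + (0:(m - 1)) * lag]
      g[idx] <- (e - 1L) * S + i
    }
    list(v = v, g = g)
  }
  ex <- embed_all(x); ey <- embed_all(y)
  dfun <- if (metric == "euclidean") function(a, b) sum((a - b)^2)
          else function(a, b) max(abs(a - b))
  vals <- numeric(0)
  for (a in seq_along(ex$g)) {
    sep <- abs(ex$g - ex$g[a])
    cand <- which(sep > params$w1 & sep < params$w2)
    if (!length(cand)) next
    k <- max(1, floor(params$p_ref * length(cand) + 0.5))
    dx <- vapply(cand, function(b) dfun(ex$v[[a]], ex$v[[b]]), numeric(1))
    dy <- vapply(cand, function(b) dfun(ey$v[[a]], ey$v[[b]]), numeric(1))
    hx <- cand[dx <= sort(dx)[k]]
    hy <- cand[dy <= sort(dy)[k]]
    vals <- c(vals, length(intersect(hx, hy)) / max(length(hx), length(hy)))
  }
  mean(vals)
}

# all-pairs shortest paths by Floyd-Warshall on edge lengths 1/weight
fw_distances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[w > 0] <- 1 / w[w > 0]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_path_length <- function(w) {
  d <- fw_distances(w)
  comp_of <- function() {
    # connected components by repeated expansion over finite distances
    lab <- seq_len(nrow(w))
    for (i in seq_len(nrow(w))) for (j in seq_len(nrow(w)))
      if (is.finite(d[i, j])) lab[j] <- min(lab[j], lab[i])
    for (i in seq_len(nrow(w))) for (j in seq_len(nrow(w)))
      if (is.finite(d[i, j])) { m <- min(lab[i], lab[j]); lab[i] <- m; lab[j] <- m }
    lab
  }
  lab <- comp_of()
  big <- which(lab == names(sort(table(lab), decreasing = TRUE))[1])
  dl <- d[big, big]
  mean(dl[upper.tri(dl)])
}

oracle_global_eff <- function(w) {
  d <- fw_distances(w)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

# weighted clustering, geometric-mean triangle form, by triple loop
oracle_clustering <- function(w) {
  n <- nrow(w)
  wh <- (w / max(w))^(1 / 3)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n))
      if (j != i && h != i && j != h) s <- s + wh[i, j] * wh[i, h] * wh[j, h]
    ci[i] <- s / (k * (k - 1))
  }
  mean(ci)
}

# betweenness by enumerating all simple paths between every pair and
# crediting interior nodes of the shortest ones (fractional on ties)
oracle_betweenness <- function(w) {
  n <- nrow(w)
  len <- matrix(Inf, n, n); len[w > 0] <- 1 / w[w > 0]
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path, total) {
      last <- path[length(path)]
      if (last == t) { out[[length(out) + 1]] <<- list(p = path, d = total); return() }
      for (nx in seq_len(n))
        if (is.finite(len[last, nx]) && !(nx %in% path))
          walk(c(path, nx), total + len[last, nx])
    }
    walk(s, 0)
    out
  }
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in seq((s + 1), n)) {
    ps <- all_paths(s, t)
    if (!length(ps)) next
    ds <- vapply(ps, `[[`, numeric(1), "d")
    mn <- min(ds)
    sh <- ps[abs(ds - mn) < 1e-12]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(sh, function(pp) v %in% pp$p, logical(1)))
      b[v] <- b[v] + through / length(sh)
    }
  }
  b
}

# two-channel band-coupled mixture: x = c*s + (1-c)*n, band-filtered noise
coupled_pair <- function(n, coupling, band = c(8, 12), fs = 250) {
  bp <- function(v) {
    f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
    f <- pmin(f, fs - f)
    keep <- f >= band[1] & f <= band[2]
    y <- Re(stats::fft(stats::fft(v) * keep, inverse = TRUE)) / n
    y / sqrt(mean(y^2))
  }
  s <- bp(stats::rnorm(n))
  list(x = coupling * s + (1 - coupling) * bp(stats::rnorm(n)),
       y = coupling * s + (1 - coupling) * bp(stats::rnorm(n)))
}

# small cohort spec used across tests: short recordings, fs already at the
# analysis rate, patient alpha-coupling deficit on the standard five nodes
tiny_cohort_spec <- function(n_patients = 4, n_controls = 4, duration = 12,
                             fs = 250, seed = 1, artifact_rate = 0, ...) {
  cohort_spec(n_patients = n_patients, n_controls = n_controls,
              fs = fs, duration = duration, artifact_rate = artifact_rate,
              seed = seed, ...)
}

fast_params <- function(band = c(8, 12), fs = 250)
  embed_parameters(band[1], band[2], fs, p_ref = 0.02, n_ref = 5)
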