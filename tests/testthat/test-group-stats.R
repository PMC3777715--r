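test_that("permutation test handles degenerate and planted-shift cases", {
  g <- factor(rep(c("a", "b"), each = 20))
  # identical values: t = 0, p = 1
  r0 <- permutation_test(rep(3.7, 40), g, n_perm = 200, seed = 1)
  expect_equal(r0$observed_t, 0)
  expect_equal(r0$p_value, 1)
  # p floor respects the permutation count
  set.seed(2)
  big <- c(stats::rnorm(20, 10), stats::rnorm(20, 0))
  rb <- permutation_test(big, g, n_perm = 200, seed = 1)
  expect_equal(rb$p_value, 1 / 201)
  expect_error(permutation_test(stats::rnorm(5), factor(c("a", "a", "a", "a", "b"))),
               "at least 2")
  expect_error(permutation_test(c(1, NA, 2, 3), factor(c("a", "a", "b", "b"))),
               "finite")
})

test_that("permutation test has power against a one-SD shift", {
  g <- factor(rep(c("a", "b"), each = 30))
  hits <- vapply(seq_len(100), function(r) {
    set.seed(1000 + r)
    v <- c(stats::rnorm(30, 1), stats::rnorm(30, 0))
    permutation_test(v, g, n_perm = 300, seed = r)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.80)
})

test_that("permutation p is reproducible under a fixed seed and covariates are absorbed", {
  set.seed(5)
  n <- 60
  g <- factor(rep(c("a", "b"), each = n / 2))
  cov <- data.frame(age = stats::rnorm(n, 40, 10),
                    sex = sample(c("m", "f"), n, TRUE),
                    iq = stats::rnorm(n, 100, 15))
  v <- 0.05 * cov$age + stats::rnorm(n)
  r1 <- permutation_test(v, g, cov, n_perm = 500, seed = 9)
  r2 <- permutation_test(v, g, cov, n_perm = 500, seed = 9)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$null_t, r2$null_t)
  # a pure covariate effect is not mistaken for a group effect
  expect_gt(r1$p_value, 0.01)
  # the observed t matches lm() on the same model
  fit <- summary(stats::lm(v ~ age + sex + iq + I(g == "a"), data = cov))
  expect_equal(unname(r1$observed_t), unname(fit$coefficients[5, "t value"]),
               tolerance = 1e-10)
})

test_that("one-sided alternatives order p-values coherently", {
  set.seed(6)
  g <- factor(rep(c("a", "b"), each = 15))
  v <- c(stats::rnorm(15, 0.8), stats::rnorm(15))
  pg <- permutation_test(v, g, n_perm = 400, seed = 3,
                         alternative = "greater")$p_value
  pl <- permutation_test(v, g, n_perm = 400, seed = 3,
                         alternative = "less")$p_value
  expect_lt(pg, pl)
})

test_that("critical t values match the t table", {
  expect_equal(round(critical_t(0.005, 142), 2), 2.61)
  expect_equal(critical_t(0.005, 1e7), stats::qnorm(0.995), tolerance = 1e-3)
  expect_equal(round(critical_t(0.025, 10), 3), 2.228)
  expect_error(critical_t(0.7, 10), "tail_p")
  expect_error(critical_t(0.005, 0), "df")
})

null_stack <- function(n1, n2, n_nodes = 10, seed = 1, shift = NULL) {
  set.seed(seed)
  n <- n1 + n2
  out <- array(0, c(n, n_nodes, n_nodes))
  for (s in seq_len(n)) {
    m <- matrix(0, n_nodes, n_nodes)
    m[upper.tri(m)] <- stats::rnorm(n_nodes * (n_nodes - 1) / 2, 0.3, 0.05)
    if (!is.null(shift) && s <= n1)
      m[shift] <- m[shift] - 0.15
    m <- m + t(m); diag(m) <- 1
    out[s, , ] <- m
  }
  out
}

test_that("NBS reports no finding when the groups do not differ", {
  g <- factor(rep(c("a", "b"), c(12, 12)))
  r <- nbs(null_stack(12, 12, seed = 21), g, t_threshold = 30,
           n_perm = 100, seed = 1)
  expect_equal(nrow(r$edges), 0L)
  expect_length(r$components, 0)
  expect_length(r$corrected_p, 0)
  expect_equal(r$max_component_links, 0L)
})

test_that("NBS recovers a planted connected deficit with corrected significance", {
  # edges among nodes 1-4 (a connected 5-edge set) are lowered in group a
  idx <- cbind(c(1, 1, 1, 2, 3), c(2, 3, 4, 3, 4))
  hits <- vapply(1:10, function(r) {
    stack <- null_stack(15, 15, seed = 100 + r, shift = idx)
    g <- factor(rep(c("a", "b"), each = 15))
    res <- nbs(stack, g, t_threshold = 2.61, n_perm = 300, seed = r,
               alternative = "less")
    length(res$components) > 0 &&
      res$corrected_p[1] < 0.05 &&
      sum(res$components[[1]]$i <= 4 & res$components[[1]]$j <= 4) >= 4
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})

test_that("NBS component bookkeeping matches a constructed suprathreshold graph", {
  # two separated strong components: edges among 1-3 and among 6-7
  idx <- cbind(c(1, 1, 2, 6), c(2, 3, 3, 7))
  stack <- null_stack(20, 20, seed = 77, shift = idx)
  g <- factor(rep(c("a", "b"), each = 20))
  res <- nbs(stack, g, t_threshold = 3, n_perm = 50, seed = 2,
             alternative = "less")
  sizes <- sort(res$component_sizes, decreasing = TRUE)
  expect_gte(length(res$components), 2)
  expect_equal(sizes[1], 3L)
  expect_true(all(res$components[[1]]$i %in% 1:3 &
                    res$components[[1]]$j %in% 1:3))
  # determinism under seed
  res2 <- nbs(stack, g, t_threshold = 3, n_perm = 50, seed = 2,
              alternative = "less")
  expect_identical(res$corrected_p, res2$corrected_p)
})

test_that("partial correlation matches the analytic trivariate construction", {
  set.seed(31)
  n <- 500
  z <- stats::rnorm(n)
  cov <- data.frame(z = z)
  # both variables load on z; partial correlation beyond z is rho
  rho <- 0.5
  e1 <- stats::rnorm(n); e2 <- rho * e1 + sqrt(1 - rho^2) * stats::rnorm(n)
  x <- 2 * z + e1
  y <- -1 * z + e2
  r <- partial_correlation(x, y, cov)
  expect_lt(abs(r$r - rho), 0.1)
  expect_equal(r$df, n - 3)
  # perfect dependence after orthogonal covariates
  w <- stats::rnorm(n)
  r1 <- partial_correlation(w, w, data.frame(c1 = stats::rnorm(n)))
  expect_equal(r1$r, 1, tolerance = 1e-10)
  expect_error(partial_correlation(rep(1, n), w, cov), "constant")
  expect_error(partial_correlation(1:4, c(2, 3, 4, 5),
                                   data.frame(a = 1:4, b = c(1, 2, 1, 2), c = 4:1)),
               "complete cases")
})

test_that("demographic tests reproduce the closed-form chi-square", {
  meta <- data.frame(
    group = rep(c("patient", "control"), c(57, 87)),
    sex = c(rep(c("male", "female"), c(25, 32)),
            rep(c("male", "female"), c(35, 52))),
    age = stats::rnorm(144, 40, 10),
    education = stats::rnorm(144, 13, 3),
    iq = stats::rnorm(144, 104, 15))
  tt <- demographic_tests(meta)
  chi <- tt$statistic[tt$variable == "sex"]
  # closed form sum((O-E)^2/E) on the 2x2 table
  O <- matrix(c(32, 52, 25, 35), 2)  # table(group, sex): female col first
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(chi, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_equal(round(chi, 3), 0.187)
  expect_equal(tt$df[tt$variable == "sex"], 1)
  # pooled-variance t: df = n - 2
  expect_equal(unique(tt$df[tt$variable != "sex"]), 142)
  # identical group compositions give chi-square zero
  bal <- data.frame(group = rep(c("patient", "control"), each = 20),
                    sex = rep(rep(c("male", "female"), each = 10), 2),
                    age = stats::rnorm(40), education = stats::rnorm(40),
                    iq = stats::rnorm(40))
  expect_equal(demographic_tests(bal)$statistic[1], 0, tolerance = 1e-12)
  solo <- meta[meta$group == "patient", ]
  expect_error(demographic_tests(solo), "both groups")
})
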