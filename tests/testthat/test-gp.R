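test_that("the ARD kernel reproduces hand-computed entries", {
  hy <- ard_hyper(1, 1, 0.5)
  X <- matrix(c(0, 1), 2, 1)
  K <- ard_kernel(X, X, hy, add_noise = TRUE)
  expect_equal(K[1, 1], 1^2 + 0.5^2, tolerance = 1e-12)   # alpha^2 + sigma^2
  expect_equal(K[1, 2], exp(-0.5), tolerance = 1e-12)     # unit separation
  # multivariate entry: alpha^2 exp(-1/2 sum((dx/rho)^2))
  hy2 <- ard_hyper(1.3, c(0.7, 2.1), 0.2)
  X1 <- matrix(c(0.3, -1), 1); X2 <- matrix(c(-0.4, 0.5), 1)
  expect_equal(ard_kernel(X1, X2, hy2)[1, 1],
               1.3^2 * exp(-0.5 * ((0.7 / 0.7)^2 + (1.5 / 2.1)^2)),
               tolerance = 1e-12)
  # long length-scale limit: entries approach alpha^2
  hy3 <- ard_hyper(2, 1e8, 0.1)
  expect_equal(max(abs(ard_kernel(X, X, hy3) - 4)), 0, tolerance = 1e-10)
})

test_that("kernel matrices are symmetric PSD and inputs are validated", {
  set.seed(1)
  X <- matrix(rnorm(60), 20, 3)
  hy <- ard_hyper(1.5, c(0.5, 1, 2), 0.3)
  K <- ard_kernel(X, X, hy, add_noise = TRUE)
  expect_equal(K, t(K), tolerance = 1e-12)
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_error(ard_kernel(X, matrix(0, 2, 2), hy), "dimension")
  expect_error(ard_hyper(-1, 1, 1), "positive")
  expect_error(ard_hyper(1, c(1, -2), 1), "positive")
  expect_error(ard_hyper(1, 1, 0), "positive")
})

test_that("the hyperparameter log posterior matches a 1-point closed form", {
  # n = 1, y = 0: marginal is a zero-mean Gaussian with variance alpha^2+sigma^2
  hy <- ard_hyper(1, 1, 1)
  lp <- gp_log_posterior(hy, matrix(0, 1, 1), 0)
  marginal <- dnorm(0, 0, sqrt(2), log = TRUE)
  half_normal <- function(x) log(2) + dnorm(x, log = TRUE)
  inv_gamma <- function(x, a = 5, b = 5) a * log(b) - lgamma(a) -
    (a + 1) * log(x) - b / x
  expect_equal(lp, marginal + 2 * half_normal(1) + inv_gamma(1),
               tolerance = 1e-7)
})

test_that("the inverse-gamma(5, 5) prior peaks at rho = 5/6", {
  grid <- seq(0.1, 3, by = 0.001)
  dens <- -(5 + 1) * log(grid) - 5 / grid
  expect_equal(grid[which.max(dens)], 5 / 6, tolerance = 1e-3)
  # and the full prior term in the posterior respects it: at fixed data the
  # posterior with rho = 5/6 beats rho far in the tails for pure-noise y
  X <- matrix(c(-1, 0, 1), 3, 1)
  y <- c(0.1, -0.2, 0.1)
  lp_mode <- gp_log_posterior(ard_hyper(1, 5 / 6, 1), X, y)
  lp_tail <- gp_log_posterior(ard_hyper(1, 100, 1), X, y)
  expect_gt(lp_mode, lp_tail)
})

test_that("MAP fitting is deterministic and recovers length-scales", {
  sim <- gp_sim(n = 80, rho = 0.5, seed = 3)
  m1 <- fit_node_gp("y", "X", sim$table, map_config())
  m2 <- fit_node_gp("y", "X", sim$table, map_config())
  expect_identical(m1$map, m2$map)
  # factor-2 recovery of rho = 0.5 in at least 8 of 10 seeds
  ok <- vapply(1:10, function(s) {
    sm <- gp_sim(n = 80, rho = 0.5, seed = s)
    m <- fit_node_gp("y", "X", sm$table, map_config())
    m$map$rho >= 0.25 && m$map$rho <= 1.0
  }, logical(1L))
  expect_gte(sum(ok), 8L)
})

test_that("ARD suppresses an irrelevant input", {
  wins <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 60
    x1 <- runif(n, -2, 2); x2 <- runif(n, -2, 2)
    y <- sin(x1) + rnorm(n, 0, 0.1)  # x2 carries no signal
    tab <- trait_table(data.frame(y = y, x1 = x1, x2 = x2),
                       variety = rep("v", n))
    m <- fit_node_gp("y", c("x1", "x2"), tab, map_config())
    m$map$rho[2L] > m$map$rho[1L]
  }, logical(1L))
  expect_gte(sum(wins), 8L)
})

test_that("the gradient-based sampler mixes on a small problem", {
  sim <- gp_sim(n = 40, rho = 0.8, seed = 4)
  cfg <- gp_sampler_config("mcmc", chains = 4L, warmup = 120L, iter = 120L,
                           seed = 5)
  m <- fit_node_gp("y", "X", sim$table, cfg)
  expect_identical(m$diagnostics$mode, "mcmc")
  expect_true(all(is.finite(m$diagnostics$rhat)))
  expect_lte(max(m$diagnostics$rhat), 1.1)
  expect_gte(length(m$hyper_draws), 50L)
})

test_that("posterior predictive moments match the textbook GP formulae", {
  sim <- gp_sim(n = 25, rho = 0.7, seed = 6)
  m <- fit_node_gp("y", "X", sim$table, map_config())
  hy <- ard_hyper(1.2, 0.7, 0.3)
  Xn <- matrix(seq(-2, 2, length.out = 5), 5, 1)
  got <- gp_posterior(m, Xn, hyper = hy)
  # independent textbook implementation, mirroring the recorded jitter
  st <- m$standardisation
  Xs <- (Xn - st$x_center) / st$x_scale
  Xt <- m$X_train
  kf <- function(a, b) hy$alpha^2 * exp(-0.5 * outer(a[, 1], b[, 1], `-`)^2 / hy$rho^2)
  Ktt <- kf(Xt, Xt) + diag(hy$sigma^2, nrow(Xt))
  Ktt <- Ktt + diag(1e-8 * mean(diag(Ktt)), nrow(Xt))
  Kst <- kf(Xs, Xt)
  mu <- drop(Kst %*% solve(Ktt, m$y_train))
  cov <- kf(Xs, Xs) - Kst %*% solve(Ktt, t(Kst))
  expect_equal(got$mean, st$y_center + st$y_scale * mu, tolerance = 1e-8)
  expect_equal(got$cov, st$y_scale^2 * cov, tolerance = 1e-8)
  expect_true(all(diag(got$cov) >= 0))
})

test_that("a near-noiseless GP interpolates its training targets", {
  set.seed(7)
  n <- 30
  x <- seq(-2, 2, length.out = n)
  y <- sin(x)
  tab <- trait_table(data.frame(y = y, x = x), variety = rep("v", n))
  m <- fit_node_gp("y", "x", tab, map_config())
  m$hyper_draws <- list(ard_hyper(m$map$alpha, m$map$rho, 1e-6))
  po <- gp_posterior(m, matrix(x[10], 1, 1), hyper = m$hyper_draws[[1L]])
  expect_equal(po$mean, y[10], tolerance = 1e-3)
})

test_that("sampled draws agree with the analytic predictive in the mean", {
  sim <- gp_sim(n = 40, rho = 0.8, seed = 8)
  m <- fit_node_gp("y", "X", sim$table, map_config())
  Xn <- matrix(c(-1, 0.5), 2, 1)
  dr <- predict_node(m, Xn, n_draws = 10000L, seed = 9)
  po <- gp_posterior(m, Xn, include_noise = TRUE)
  se <- sqrt(diag(po$cov) / 10000)
  expect_lt(abs(mean(dr[, 1L]) - po$mean[1L]), 3 * se[1L])
  expect_lt(abs(mean(dr[, 2L]) - po$mean[2L]), 3 * se[2L])
})

test_that("predictive uncertainty grows away from the training data", {
  sim <- gp_sim(n = 50, rho = 0.5, seed = 10)
  m <- fit_node_gp("y", "X", sim$table, map_config())
  centre <- matrix(mean(sim$X), 1, 1)
  far <- matrix(max(sim$X) + 5 * m$map$rho, 1, 1)
  sd_centre <- sqrt(diag(gp_posterior(m, centre)$cov))
  sd_far <- sqrt(diag(gp_posterior(m, far)$cov))
  expect_gt(sd_far, sd_centre)
})

test_that("standardisation round-trips exactly", {
  sim <- gp_sim(n = 30, rho = 1, seed = 11)
  m <- fit_node_gp("y", "X", sim$table, map_config())
  st <- m$standardisation
  back <- sweep(sweep(m$X_train, 2L, st$x_scale, `*`), 2L, st$x_center, `+`)
  expect_equal(back, sim$X[, , drop = FALSE], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(st$y_center + st$y_scale * m$y_train, sim$y, tolerance = 1e-10)
})

test_that("network fitting stores GP models for non-roots and samples for roots", {
  tab <- chain_table(n = 60)
  nw <- fit_trait_network(chain_dag(), tab, map_config())
  expect_true(is.numeric(nw$node_models$x))
  expect_s3_class(nw$node_models$y, "gp_node_model")
  expect_identical(nw$node_models$z$parents, "y")
})
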