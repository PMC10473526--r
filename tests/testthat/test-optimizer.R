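test_that("closed-form EI matches Monte-Carlo estimates and limit cases", {
  set.seed(1)
  triples <- cbind(mean = runif(20, -2, 2), sd = runif(20, 0.1, 2),
                   best = runif(20, -1, 1))
  for (i in seq_len(nrow(triples))) {
    m <- triples[i, "mean"]; s <- triples[i, "sd"]; b <- triples[i, "best"]
    draws <- rnorm(1e5, m, s)
    imp <- pmax(draws - b, 0)
    mc <- mean(imp)
    se <- sd(imp) / sqrt(length(draws))
    expect_lt(abs(expected_improvement(m, s, b) - mc), 3 * se)
  }
  expect_equal(expected_improvement(-1, 0, 0), 0)      # dominated, no noise
  expect_equal(expected_improvement(2, 0, 0), 2)       # sd = 0 degenerate
  expect_equal(expected_improvement(0, 1, 0), dnorm(0), tolerance = 1e-12)
  expect_error(expected_improvement(0, -1, 0), "non-negative")
})

test_that("EI is non-negative and vanishes for dominated noiseless points", {
  grid <- expand.grid(mean = seq(-3, 3, by = 0.5), sd = c(0, 0.01, 1))
  ei <- expected_improvement(grid$mean, grid$sd, best_observed = 1)
  expect_true(all(ei >= 0))
  expect_true(all(ei[grid$sd == 0 & grid$mean <= 1] == 0))
})

gap_surrogate <- function(seed = 7) {
  set.seed(seed)
  x <- c(runif(30, 0, 0.3), runif(30, 0.7, 1))
  y <- -(x - 0.5)^2 + rnorm(60, 0, 0.01)
  tab <- trait_table(data.frame(y = y, x = x), variety = rep("v", 60))
  list(model = fit_node_gp("y", "x", tab, map_config()), x = x, y = y)
}

test_that("acquisition maximisation finds the unexplored gap", {
  fx <- gap_surrogate()
  prop <- maximise_acquisition(fx$model, max(fx$y), rbind(c(0, 1)),
                               restarts = 30L, seed = 1)
  expect_gt(prop$point, 0.35)
  expect_lt(prop$point, 0.65)
  # dense-grid oracle: the found EI matches the grid maximum within 1%
  grid <- matrix(seq(0, 1, length.out = 2000), ncol = 1)
  mo <- ideonet:::surrogate_moments(fx$model, grid)
  grid_max <- max(expected_improvement(mo$mean, mo$sd, max(fx$y)))
  expect_gte(prop$ei, grid_max * 0.99)
})

test_that("proposals always stay inside the bounds", {
  for (s in 1:10) {
    set.seed(s)
    n <- 30
    X <- cbind(runif(n, -1, 2), runif(n, 0, 5))
    y <- X[, 1] - 0.3 * X[, 2] + rnorm(n, 0, 0.2)
    tab <- trait_table(data.frame(y = y, a = X[, 1], b = X[, 2]),
                       variety = rep("v", n))
    m <- fit_node_gp("y", c("a", "b"), tab, map_config())
    b <- t(apply(X, 2, range))
    prop <- maximise_acquisition(m, max(y), b, restarts = 10L, seed = s)
    expect_true(all(prop$point >= b[, 1] - 1e-9))
    expect_true(all(prop$point <= b[, 2] + 1e-9))
  }
  # degenerate bounds return the single feasible point
  fx <- gap_surrogate()
  prop <- maximise_acquisition(fx$model, max(fx$y), rbind(c(0.4, 0.4)))
  expect_equal(unname(prop$point), 0.4)
})

test_that("a batch of one equals plain acquisition maximisation", {
  fx <- gap_surrogate()
  single <- maximise_acquisition(fx$model, max(fx$y), rbind(c(0, 1)),
                                 restarts = 20L, seed = 3)
  batch <- propose_batch_constant_liar(fx$model, max(fx$y), rbind(c(0, 1)),
                                       q = 1L, restarts = 20L, seed = 3)
  expect_equal(batch$x[1L], unname(single$point), tolerance = 1e-9)
})

test_that("the Constant Liar spreads a 2-D batch and is seed-deterministic", {
  # multimodal response: several competing acquisition basins, so the lie
  # must push successive proposals to genuinely different regions
  set.seed(4)
  n <- 30
  X <- cbind(runif(n), runif(n))
  y <- sin(2 * pi * X[, 1]) * sin(2 * pi * X[, 2]) + rnorm(n, 0, 0.05)
  tab <- trait_table(data.frame(y = y, a = X[, 1], b = X[, 2]),
                     variety = rep("v", n))
  m <- fit_node_gp("y", c("a", "b"), tab, map_config())
  bounds <- rbind(c(0, 1), c(0, 1))
  dmin <- vapply(1:10, function(s) {
    batch <- propose_batch_constant_liar(m, max(y), bounds, q = 5L,
                                         restarts = 15L, seed = s)
    pts <- as.matrix(batch[, c("a", "b")])
    min(dist(scale(pts, center = FALSE,
                   scale = m$standardisation$x_scale)))
  }, numeric(1L))
  expect_true(all(dmin > 0.05))  # liar repulsion in standardised units
  batch <- propose_batch_constant_liar(m, max(y), bounds, q = 5L,
                                       restarts = 15L, seed = 5)
  expect_identical(sort(batch$rank), 1:5)
  again <- propose_batch_constant_liar(m, max(y), bounds, q = 5L,
                                       restarts = 15L, seed = 5)
  expect_identical(batch, again)
})

test_that("inserting the lie removes improvement mass at the first proposal", {
  fx <- gap_surrogate()
  m <- fx$model
  best <- max(fx$y)
  prop <- maximise_acquisition(m, best, rbind(c(0, 1)), restarts = 20L, seed = 6)
  hy <- ideonet:::frozen_hyper(m)
  lied <- m
  lied$X_train <- rbind(m$X_train,
                        ideonet:::standardise_inputs(m, matrix(prop$point, 1)))
  lied$y_train <- c(m$y_train, (best - m$standardisation$y_center) /
                      m$standardisation$y_scale)
  lied$hyper_draws <- list(hy)
  mo <- ideonet:::surrogate_moments(lied, matrix(prop$point, 1))
  ei_after <- expected_improvement(mo$mean, mo$sd, best)
  expect_lt(ei_after, prop$ei)
})

test_that("exceedance probabilities are calibrated against Monte Carlo", {
  set.seed(8)
  mean <- 0.4; sd <- 0.7; best <- 0.9
  p <- pnorm((mean - best) / sd)
  mc <- mean(rnorm(2e5, mean, sd) > best)
  expect_lt(abs(p - mc), 3 * sqrt(p * (1 - p) / 2e5))
})

test_that("the PC basis captures correlation structure and round-trips", {
  set.seed(9)
  n <- 200
  a <- rnorm(n)
  perf <- cbind(a = a, b = 2 * a)  # perfectly correlated pair
  expect_equal(build_pc_basis(perf, 0.95)$n_components, 1L)
  X <- cbind(a = a, b = rnorm(n), c = a + rnorm(n, 0, 0.5))
  basis <- build_pc_basis(X, threshold = 1)
  S <- pc_scores(basis, X, all_components = TRUE)
  expect_lt(max(abs(pc_reconstruct(basis, S) - X)), 1e-10)
  expect_lt(max(abs(cor(S)[upper.tri(diag(3))])), 1e-10)
  expect_error(build_pc_basis(cbind(a = a, flat = rep(1, n))), "flat")
})

tradeoff_fixture <- function(seed = 1, n = 120) {
  # hard negative trade-off between the two yield parents: u + v ~ 0
  set.seed(seed)
  u <- runif(n, -1.5, 1.5)
  v <- -u + rnorm(n, 0, 0.15)
  yield <- u + 0.6 * v + rnorm(n, 0, 0.05)  # truth rewards breaking the trade-off
  tab <- trait_table(data.frame(yield = yield, u = u, v = v),
                     variety = rep(sprintf("v%d", 1:24), length.out = n))
  dag <- trait_dag(c("u", "v", "yield"),
                   data.frame(parent = c("u", "v"), child = "yield"))
  list(table = tab, network = fit_trait_network(dag, tab, map_config()),
       u = u, v = v, yield = yield)
}

test_that("PC constraints keep proposals on an engineered trade-off that
           unconstrained search breaks", {
  fx <- tradeoff_fixture()
  un <- propose_ideotypes(fx$network, q = 5L, constrained = FALSE,
                          restarts = 20L, seed = 2)
  con <- propose_ideotypes(fx$network, q = 5L, constrained = TRUE,
                           threshold = 0.95, restarts = 20L, seed = 2)
  # residual of v on u measures distance from the trade-off line v = -u
  fitline <- lm(fx$v ~ fx$u)
  resid_sd <- sd(residuals(fitline))
  off_line <- function(df) {
    abs(df$v - (coef(fitline)[1L] + coef(fitline)[2L] * df$u))
  }
  # unconstrained top proposal exploits u and v jointly, far off the line
  expect_gt(max(off_line(un)), 2 * resid_sd)
  # constrained proposals respect the observed correlation structure
  expect_lt(max(off_line(con)), 2 * resid_sd)
  # and all reported values stay inside the observed trait box
  expect_true(all(con$u >= min(fx$u) & con$u <= max(fx$u)))
  expect_true(all(con$v >= min(fx$v) & con$v <= max(fx$v)))
})

test_that("PC-constrained proposals stay inside the trait box and the score box", {
  set.seed(10)
  n <- 150
  u <- runif(n, -1, 1); v <- 0.55 * runif(n, -1, 1)
  yield <- u + v + rnorm(n, 0, 0.05)
  tab <- trait_table(data.frame(yield = yield, u = u, v = v),
                     variety = rep("v", n))
  dag <- trait_dag(c("u", "v", "yield"),
                   data.frame(parent = c("u", "v"), child = "yield"))
  nw <- fit_trait_network(dag, tab, map_config())
  con <- propose_ideotypes(nw, q = 1L, constrained = TRUE, threshold = 1,
                           restarts = 25L, seed = 3)
  expect_true(con$u >= min(u) && con$u <= max(u))
  expect_true(con$v >= min(v) && con$v <= max(v))
  basis <- build_pc_basis(cbind(u = u, v = v), threshold = 1)
  sc_obs <- pc_scores(basis, cbind(u = u, v = v))
  sc_prop <- attr(con, "pc_points")
  for (k in 1:2) {
    expect_gte(sc_prop[1, k], min(sc_obs[, k]) - 1e-8)
    expect_lte(sc_prop[1, k], max(sc_obs[, k]) + 1e-8)
  }
})

test_that("proposal tables export as CSV with ranks intact", {
  fx <- tradeoff_fixture()
  con <- propose_ideotypes(fx$network, q = 3L, restarts = 10L, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ideotypes_csv(con, path)
  back <- utils::read.csv(path)
  expect_identical(back$rank, 1:3)
  expect_true(all(c("predicted_yield_mean", "exceedance_probability")
                  %in% names(back)))
})
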