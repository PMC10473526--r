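#' ARD hyperparameter set for a Gaussian-process node model
#'
#' @param alpha signal amplitude (> 0).
#' @param rho per-input length-scales (vector of positives, one per parent
#'   trait; short length-scales mean relevant inputs, long ones suppress
#'   irrelevant inputs — the automatic relevance determination property).
#' @param sigma observation noise scale (> 0).
#' @return An object of class `ard_hyper`.
#' @export
ard_hyper <- function(alpha, rho, sigma) {
  alpha <- as.numeric(alpha); rho <- as.numeric(rho); sigma <- as.numeric(sigma)
  if (length(alpha) != 1L || length(sigma) != 1L) stop("alpha and sigma are scalars")
  if (!all(is.finite(c(alpha, rho, sigma))) ||
      alpha <= 0 || sigma <= 0 || any(rho <= 0)) {
    stop("all hyperparameters must be strictly positive and finite")
  }
  structure(list(alpha = alpha, rho = rho, sigma = sigma), class = "ard_hyper")
}

#' @export
print.ard_hyper <- function(x, ...) {
  cat("ard_hyper: alpha =", format(x$alpha, digits = 3),
      " rho = [", paste(format(x$rho, digits = 3), collapse = ", "),
      "] sigma =", format(x$sigma, digits = 3), "\n")
  invisible(x)
}

#' Automatic relevance determination covariance matrix
#'
#' Entry (i, j) is `alpha^2 * exp(-1/2 * sum_k ((x1_ik - x2_jk) / rho_k)^2)`,
#' with `sigma^2` added on the diagonal when `add_noise` is TRUE (meaningful
#' only when `X1` and `X2` index the same points).
#'
#' @param X1,X2 input matrices with one column per parent trait.
#' @param hyper an [ard_hyper()] whose `rho` length equals the input
#'   dimension.
#' @param add_noise add the observation-noise term on the diagonal.
#' @return The `nrow(X1)` x `nrow(X2)` covariance matrix.
#' @export
ard_kernel <- function(X1, X2, hyper, add_noise = FALSE) {
  stopifnot(inherits(hyper, "ard_hyper"))
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  q <- length(hyper$rho)
  if (ncol(X1) != q || ncol(X2) != q) {
    stop("input dimension must match length(rho) = ", q)
  }
  A1 <- sweep(X1, 2L, hyper$rho, `/`)
  A2 <- sweep(X2, 2L, hyper$rho, `/`)
  d2 <- outer(rowSums(A1^2), rowSums(A2^2), `+`) - 2 * tcrossprod(A1, A2)
  d2[d2 < 0] <- 0
  K <- hyper$alpha^2 * exp(-0.5 * d2)
  if (add_noise) {
    if (nrow(X1) != nrow(X2)) stop("add_noise requires square kernel (same points)")
    K <- K + diag(hyper$sigma^2, nrow(X1))
  }
  K
}

# Cholesky with escalating jitter 1e-8 -> 1e-4.
chol_jitter <- function(K) {
  jit <- 1e-8 * mean(diag(K))
  for (tries in 1:5) {
    L <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jit))
    jit <- jit * 10
  }
  stop("Cholesky factorisation failed after jitter escalation")
}

# log prior: half-normal(0,1) on alpha and sigma, inverse-gamma(5, 5) on rho
log_hyper_prior <- function(hyper) {
  hn <- function(x) log(2) - 0.5 * log(2 * pi) - 0.5 * x^2
  ig <- function(x, a = 5, b = 5) a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
  hn(hyper$alpha) + hn(hyper$sigma) + sum(ig(hyper$rho))
}

#' Log unnormalised posterior of GP hyperparameters
#'
#' The Gaussian-process marginal log-likelihood of `y` under
#' `N(0, K(X, X) + sigma^2 I)` plus the log prior densities: half-normal(0, 1)
#' on the positive scales `alpha` and `sigma`, and inverse-gamma(shape 5,
#' scale 5) on each length-scale.
#'
#' @param hyper an [ard_hyper()].
#' @param X input matrix (n x q).
#' @param y response vector (length n).
#' @return The scalar log density (finite for all positive hyperparameters).
#' @export
gp_log_posterior <- function(hyper, X, y) {
  stopifnot(inherits(hyper, "ard_hyper"))
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows must match length(y)")
  if (!all(is.finite(y))) stop("y must be finite")
  K <- ard_kernel(X, X, hyper, add_noise = TRUE)
  cj <- chol_jitter(K)
  alpha_v <- backsolve(cj$L, forwardsolve(t(cj$L), y))
  ll <- -0.5 * sum(y * alpha_v) - sum(log(diag(cj$L))) -
    length(y) / 2 * log(2 * pi)
  ll + log_hyper_prior(hyper)
}

# log posterior and gradient in eta = log(c(alpha, rho, sigma)) space,
# including the log-Jacobian (sum(eta)) when `jacobian` is TRUE (the HMC
# target); MAP optimisation uses jacobian = FALSE (mode of the density in
# the positive parameterisation).
gp_eta_posterior <- function(eta, X, y, D2list, jacobian = TRUE, grad = FALSE) {
  q <- ncol(X)
  theta <- exp(eta)
  alpha <- theta[1L]; rho <- theta[1L + seq_len(q)]; sigma <- theta[q + 2L]
  n <- nrow(X)
  E <- matrix(0, n, n)
  for (k in seq_len(q)) E <- E + D2list[[k]] / rho[k]^2
  R <- exp(-0.5 * E)
  K <- alpha^2 * R + diag(sigma^2, n)
  cj <- chol_jitter(K)
  w <- backsolve(cj$L, forwardsolve(t(cj$L), y))
  ll <- -0.5 * sum(y * w) - sum(log(diag(cj$L))) - n / 2 * log(2 * pi)
  lp <- ll - 0.5 * alpha^2 - 0.5 * sigma^2 +
    sum(-6 * log(rho) - 5 / rho) +
    2 * log(2) - log(2 * pi) + 5 * q * log(5) - q * lgamma(5)
  if (jacobian) lp <- lp + sum(eta)
  if (!grad) return(list(lp = lp))
  Kinv <- chol2inv(cj$L)
  G <- tcrossprod(w) - Kinv
  g <- numeric(q + 2L)
  # d/d alpha, chain-ruled to eta; prior d/d alpha = -alpha
  g[1L] <- alpha * (0.5 * sum(G * (2 * alpha * R)) - alpha)
  aR <- alpha^2 * R
  for (k in seq_len(q)) {
    dK <- aR * D2list[[k]] / rho[k]^3
    g[1L + k] <- rho[k] * (0.5 * sum(G * dK) - 6 / rho[k] + 5 / rho[k]^2)
  }
  g[q + 2L] <- sigma * (0.5 * sum(diag(G)) * 2 * sigma - sigma)
  if (jacobian) g <- g + 1
  list(lp = lp, grad = g)
}

#' Sampler configuration for GP node fits
#'
#' @param mode `"mcmc"` (gradient-based MCMC over the hyperparameter
#'   posterior, the default) or `"map"` (a fast deterministic maximum a
#'   posteriori point, useful for tests and pipelines at desk scale).
#' @param chains,warmup,iter MCMC chain count and per-chain warm-up /
#'   sampling iterations (defaults 4, 1000, 1000).
#' @param leapfrog_steps leapfrog steps per HMC proposal.
#' @param max_store maximum number of posterior draws retained for
#'   prediction (thinned from the pooled sample).
#' @param seed integer RNG seed.
#' @return An object of class `gp_sampler_config`.
#' @export
gp_sampler_config <- function(mode = c("mcmc", "map"), chains = 4L,
                              warmup = 1000L, iter = 1000L,
                              leapfrog_steps = 10L, max_store = 100L,
                              seed = 1L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, chains = as.integer(chains),
                 warmup = as.integer(warmup), iter = as.integer(iter),
                 leapfrog_steps = as.integer(leapfrog_steps),
                 max_store = as.integer(max_store), seed = as.integer(seed)),
            class = "gp_sampler_config")
}

# deterministic multi-start MAP in eta space (L-BFGS-B with analytic gradient)
gp_map_fit <- function(X, y, D2list) {
  q <- ncol(X)
  starts <- list(c(1, rep(1, q), 0.5),
                 c(1, rep(2, q), 0.2),
                 c(0.5, rep(0.5, q), 1))
  best <- NULL
  for (s in starts) {
    eta0 <- log(s)
    fit <- tryCatch(stats::optim(
      eta0,
      fn = function(e) -gp_eta_posterior(e, X, y, D2list, jacobian = FALSE)$lp,
      gr = function(e) -gp_eta_posterior(e, X, y, D2list, jacobian = FALSE,
                                         grad = TRUE)$grad,
      method = "L-BFGS-B", lower = log(1e-4), upper = log(1e4),
      control = list(maxit = 200L)), error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("MAP optimisation failed for all starts")
  theta <- exp(best$par)
  ard_hyper(theta[1L], theta[1L + seq_len(q)], theta[q + 2L])
}

# static-metric HMC with dual-averaging step-size adaptation during warmup
gp_hmc_fit <- function(X, y, D2list, config, init_eta) {
  q <- ncol(X)
  d <- q + 2L
  n_keep <- config$iter
  draws <- array(NA_real_, c(n_keep, d, config$chains))
  target_accept <- 0.8
  for (ch in seq_len(config$chains)) {
    set.seed(config$seed + 1000L * ch)
    eta <- init_eta + stats::rnorm(d, 0, 0.1)
    cur <- gp_eta_posterior(eta, X, y, D2list, grad = TRUE)
    # dual averaging state
    log_eps <- log(0.1); log_eps_bar <- 0; Hbar <- 0
    mu <- log(10 * exp(log_eps)); gamma <- 0.05; t0 <- 10; kappa <- 0.75
    total <- config$warmup + n_keep
    for (it in seq_len(total)) {
      eps <- exp(if (it <= config$warmup) log_eps else log_eps_bar)
      p0 <- stats::rnorm(d)
      e <- eta; p <- p0; g <- cur$grad
      p <- p + 0.5 * eps * g
      for (l in seq_len(config$leapfrog_steps)) {
        e <- e + eps * p
        st <- tryCatch(gp_eta_posterior(e, X, y, D2list, grad = TRUE),
                       error = function(err) NULL)
        if (is.null(st) || !is.finite(st$lp)) { st <- NULL; break }
        g <- st$grad
        if (l < config$leapfrog_steps) p <- p + eps * g
      }
      if (is.null(st)) {
        acc_prob <- 0
      } else {
        p <- p + 0.5 * eps * g
        log_ratio <- (st$lp - 0.5 * sum(p^2)) - (cur$lp - 0.5 * sum(p0^2))
        acc_prob <- min(1, exp(log_ratio))
        if (stats::runif(1L) < acc_prob) { eta <- e; cur <- st }
      }
      if (it <= config$warmup) {
        frac <- 1 / (it + t0)
        Hbar <- (1 - frac) * Hbar + frac * (target_accept - acc_prob)
        log_eps <- mu - sqrt(it) / gamma * Hbar
        w <- it^(-kappa)
        log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      } else {
        draws[it - config$warmup, , ch] <- eta
      }
    }
  }
  draws
}

# split-Rhat of Gelman et al. on an iterations x chains matrix
split_rhat <- function(x) {
  n <- nrow(x) %/% 2L
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2L, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit a Gaussian-process model for one DAG node
#'
#' Standardises the parent inputs and the node response to zero mean and unit
#' variance, then estimates the ARD-kernel hyperparameters under the priors of
#' [gp_log_posterior()]. In `"mcmc"` mode a MAP-initialised gradient-based
#' Hamiltonian sampler draws the hyperparameter posterior (4 chains, 1000
#' warm-up and 1000 sampling iterations by default) and the fit is marked
#' converged when every hyperparameter's split-R-hat is at most 1.05; a
#' non-converged fit is returned with a warning, and the caller decides
#' policy. In `"map"` mode a deterministic multi-start optimisation returns a
#' single MAP point.
#'
#' @param node response trait name.
#' @param parents character vector of parent trait names (non-empty; root
#'   nodes are represented by their empirical marginal in
#'   [fit_trait_network()]).
#' @param table a complete [trait_table()].
#' @param sampler_config a [gp_sampler_config()].
#' @return An object of class `gp_node_model`: training matrices (in
#'   standardised units), `hyper_draws` (list of [ard_hyper()]; a single MAP
#'   point in `"map"` mode), the standardisation constants, and convergence
#'   diagnostics (`rhat`, `converged`).
#' @export
fit_node_gp <- function(node, parents, table, sampler_config = gp_sampler_config()) {
  stopifnot(inherits(table, "trait_table"), inherits(sampler_config, "gp_sampler_config"))
  if (!length(parents)) stop("parents must be non-empty; roots carry no GP model")
  M <- trait_values(table, c(node, parents))
  if (anyNA(M)) stop("table must be complete (impute first)")
  y_raw <- M[, 1L]
  X_raw <- M[, -1L, drop = FALSE]
  x_center <- colMeans(X_raw); x_scale <- apply(X_raw, 2L, stats::sd)
  if (any(x_scale == 0)) stop("constant parent column for node '", node, "'")
  y_center <- mean(y_raw); y_scale <- stats::sd(y_raw)
  if (y_scale == 0) stop("constant response for node '", node, "'")
  X <- sweep(sweep(X_raw, 2L, x_center), 2L, x_scale, `/`)
  y <- (y_raw - y_center) / y_scale
  q <- ncol(X)
  D2list <- lapply(seq_len(q), function(k) {
    d <- outer(X[, k], X[, k], `-`); d * d
  })
  map <- gp_map_fit(X, y, D2list)
  diagnostics <- list(rhat = NULL, converged = TRUE, mode = sampler_config$mode)
  if (sampler_config$mode == "map") {
    hyper_draws <- list(map)
  } else {
    init_eta <- log(c(map$alpha, map$rho, map$sigma))
    draws <- gp_hmc_fit(X, y, D2list, sampler_config, init_eta)
    rhat <- vapply(seq_len(dim(draws)[2L]), function(j) split_rhat(draws[, j, ]),
                   numeric(1L))
    names(rhat) <- c("alpha", paste0("rho_", parents), "sigma")
    converged <- all(is.finite(rhat)) && all(rhat <= 1.05)
    if (!converged) {
      warning("GP fit for node '", node, "' not converged (max split-Rhat = ",
              format(max(rhat), digits = 3), ")")
    }
    pooled <- do.call(rbind, lapply(seq_len(dim(draws)[3L]),
                                    function(ch) draws[, , ch, drop = FALSE][, , 1L]))
    keep <- unique(round(seq(1L, nrow(pooled),
                             length.out = min(sampler_config$max_store, nrow(pooled)))))
    hyper_draws <- lapply(keep, function(i) {
      th <- exp(pooled[i, ])
      ard_hyper(th[1L], th[1L + seq_len(q)], th[q + 2L])
    })
    diagnostics <- list(rhat = rhat, converged = converged, mode = "mcmc")
  }
  structure(list(node = node, parents = parents, X_train = X, y_train = y,
                 hyper_draws = hyper_draws, map = map,
                 standardisation = list(x_center = x_center, x_scale = x_scale,
                                        y_center = y_center, y_scale = y_scale),
                 diagnostics = diagnostics),
            class = "gp_node_model")
}

#' @export
print.gp_node_model <- function(x, ...) {
  cat("gp_node_model:", x$node, "~", paste(x$parents, collapse = " + "),
      "(", length(x$hyper_draws), "hyper draw(s),", x$diagnostics$mode, "mode )\n")
  invisible(x)
}

# standardise new inputs with the model's recorded constants
standardise_inputs <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$parents)) {
    stop("X_new must have ", length(model$parents), " columns")
  }
  sweep(sweep(X_new, 2L, model$standardisation$x_center), 2L,
        model$standardisation$x_scale, `/`)
}

#' Gaussian-process posterior predictive moments
#'
#' Standard GP regression algebra at fixed hyperparameters: with
#' `K = k(X, X) + sigma^2 I`, the posterior mean at new points is
#' `k(X*, X) K^-1 y` and the covariance `k(X*, X*) - k(X*, X) K^-1 k(X, X*)`
#' (plus `sigma^2 I` when `include_noise`). Values are returned in the
#' original (de-standardised) units of the response.
#'
#' @param model a [gp_node_model()].
#' @param X_new matrix of parent values in original units.
#' @param hyper an [ard_hyper()]; defaults to the model's MAP point.
#' @param include_noise add observation noise to the predictive covariance.
#' @return List with `mean` (length m) and `cov` (m x m matrix).
#' @export
gp_posterior <- function(model, X_new, hyper = NULL, include_noise = FALSE) {
  stopifnot(inherits(model, "gp_node_model"))
  if (is.null(hyper)) hyper <- model$map
  Xs <- standardise_inputs(model, X_new)
  K <- ard_kernel(model$X_train, model$X_train, hyper, add_noise = TRUE)
  cj <- chol_jitter(K)
  Ks <- ard_kernel(Xs, model$X_train, hyper)
  w <- backsolve(cj$L, forwardsolve(t(cj$L), model$y_train))
  mu <- drop(Ks %*% w)
  V <- forwardsolve(t(cj$L), t(Ks))
  Kss <- ard_kernel(Xs, Xs, hyper)
  cov <- Kss - crossprod(V)
  if (include_noise) cov <- cov + diag(hyper$sigma^2, nrow(Xs))
  ysd <- model$standardisation$y_scale
  list(mean = model$standardisation$y_center + ysd * mu, cov = ysd^2 * cov)
}

# fast diagonal-variance predictive (mean + per-point sd), standardised units
gp_predictive_marginal <- function(model, Xs, hyper, include_noise = TRUE) {
  K <- ard_kernel(model$X_train, model$X_train, hyper, add_noise = TRUE)
  cj <- chol_jitter(K)
  Ks <- ard_kernel(Xs, model$X_train, hyper)
  w <- backsolve(cj$L, forwardsolve(t(cj$L), model$y_train))
  mu <- drop(Ks %*% w)
  V <- forwardsolve(t(cj$L), t(Ks))
  var_f <- hyper$alpha^2 + cj$jitter - colSums(V^2)
  var_f[var_f < 0] <- 0
  if (include_noise) var_f <- var_f + hyper$sigma^2
  list(mean = mu, sd = sqrt(var_f))
}

#' Draw posterior predictive samples from a node model
#'
#' For each retained hyperparameter draw the standard GP posterior predictive
#' is computed and function-plus-noise values are sampled per point (points
#' are treated as independent plants, so marginal predictive variances are
#' used). Draws are pooled over hyperparameter draws and de-standardised.
#'
#' @param model a [gp_node_model()].
#' @param X_new matrix of parent values in original units.
#' @param n_draws total number of draws.
#' @param seed integer RNG seed.
#' @return `n_draws` x `nrow(X_new)` matrix of sampled response values.
#' @export
predict_node <- function(model, X_new, n_draws = 1000L, seed = 1L) {
  stopifnot(inherits(model, "gp_node_model"))
  Xs <- standardise_inputs(model, X_new)
  set.seed(as.integer(seed))
  H <- model$hyper_draws
  nh <- length(H)
  per <- diff(round(seq(0, n_draws, length.out = nh + 1L)))
  out <- matrix(NA_real_, n_draws, nrow(Xs))
  row0 <- 0L
  for (h in seq_len(nh)) {
    if (per[h] == 0L) next
    pr <- gp_predictive_marginal(model, Xs, H[[h]], include_noise = TRUE)
    z <- matrix(stats::rnorm(per[h] * nrow(Xs)), per[h], nrow(Xs))
    out[row0 + seq_len(per[h]), ] <- rep(pr$mean, each = per[h]) +
      z * rep(pr$sd, each = per[h])
    row0 <- row0 + per[h]
  }
  ysd <- model$standardisation$y_scale
  model$standardisation$y_center + ysd * out
}

#' Fit GP node models for every non-root node of a trait DAG
#'
#' Root nodes carry no regression model; their empirical marginal sample is
#' stored instead (interventions hold them at observed values).
#'
#' @param dag a [trait_dag()].
#' @param table a complete [trait_table()] containing every DAG node.
#' @param sampler_config a [gp_sampler_config()].
#' @return An object of class `fitted_trait_network` with elements `dag`,
#'   `node_models` (named list; `gp_node_model` for non-roots, a numeric
#'   marginal sample for roots) and `table` (the training data).
#' @export
fit_trait_network <- function(dag, table, sampler_config = gp_sampler_config()) {
  stopifnot(inherits(dag, "trait_dag"), inherits(table, "trait_table"))
  models <- list()
  for (nd in dag$nodes) {
    pa <- dag_parents(dag, nd)
    models[[nd]] <- if (length(pa)) {
      fit_node_gp(nd, pa, table, sampler_config)
    } else {
      trait_values(table, nd)[, 1L]
    }
  }
  structure(list(dag = dag, node_models = models, table = table),
            class = "fitted_trait_network")
}

#' @export
print.fitted_trait_network <- function(x, ...) {
  nroot <- sum(vapply(x$node_models, is.numeric, logical(1L)))
  cat("fitted_trait_network:", length(x$dag$nodes), "nodes (", nroot,
      "roots ),", nrow(x$table$values), "training plants\n")
  invisible(x)
}
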