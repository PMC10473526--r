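#' Expected Improvement acquisition function
#'
#' `E[max(f - best_observed, 0)]` for `f ~ Normal(mean, sd^2)`: the expected
#' amount by which a candidate beats the incumbent best observation. Closed
#' form `(mean - best) * pnorm(z) + sd * dnorm(z)` with
#' `z = (mean - best)/sd`; at `sd = 0` it degenerates to
#' `max(mean - best, 0)`. Always non-negative. Vectorised over `mean`/`sd`.
#'
#' @param mean,sd predictive mean and standard deviation (sd >= 0).
#' @param best_observed incumbent best response value.
#' @return Expected improvement (same length as `mean`).
#' @export
expected_improvement <- function(mean, sd, best_observed) {
  if (any(sd < 0)) stop("sd must be non-negative")
  out <- pmax(mean - best_observed, 0)
  pos <- sd > 0
  if (any(pos)) {
    z <- (mean[pos] - best_observed) / sd[pos]
    out[pos] <- (mean[pos] - best_observed) * stats::pnorm(z) +
      sd[pos] * stats::dnorm(z)
  }
  pmax(out, 0)
}

# component-wise posterior-median hyperparameters (frozen for liar refits)
frozen_hyper <- function(model) {
  H <- model$hyper_draws
  if (length(H) == 1L) return(H[[1L]])
  mat <- t(vapply(H, function(h) c(h$alpha, h$rho, h$sigma),
                  numeric(length(H[[1L]]$rho) + 2L)))
  med <- apply(mat, 2L, stats::median)
  q <- length(H[[1L]]$rho)
  ard_hyper(med[1L], med[1L + seq_len(q)], med[q + 2L])
}

# latent-function predictive (no observation noise) at fixed hyper,
# for an arbitrary (possibly lie-augmented) standardised training set;
# noise_var allows per-row observation noise (lie rows are treated as exact)
gp_lite_predict <- function(X_train, y_train, hyper, X_new, noise_var = NULL) {
  if (is.null(noise_var)) noise_var <- rep(hyper$sigma^2, nrow(X_train))
  K <- ard_kernel(X_train, X_train, hyper) + diag(noise_var, nrow(X_train))
  cj <- chol_jitter(K)
  Ks <- ard_kernel(X_new, X_train, hyper)
  w <- backsolve(cj$L, forwardsolve(t(cj$L), y_train))
  V <- forwardsolve(t(cj$L), t(Ks))
  var_f <- hyper$alpha^2 + cj$jitter - colSums(V^2)
  var_f[var_f < 0] <- 0
  list(mean = drop(Ks %*% w), sd = sqrt(var_f))
}

# moment-matched latent predictive pooled over all hyper draws, original units
surrogate_moments <- function(model, X_new_orig) {
  Xs <- standardise_inputs(model, X_new_orig)
  H <- model$hyper_draws
  mus <- vars <- matrix(NA_real_, length(H), nrow(Xs))
  for (h in seq_along(H)) {
    pr <- gp_lite_predict(model$X_train, model$y_train, H[[h]], Xs,
                          noise_var = model$noise_var)
    mus[h, ] <- pr$mean; vars[h, ] <- pr$sd^2
  }
  mu <- colMeans(mus)
  v <- colMeans(vars + mus^2) - mu^2
  v[v < 0] <- 0
  ysd <- model$standardisation$y_scale
  list(mean = model$standardisation$y_center + ysd * mu, sd = ysd * sqrt(v))
}

as_bounds_matrix <- function(bounds) {
  b <- as.matrix(bounds)
  if (nrow(b) == 2L && ncol(b) != 2L) b <- t(b)
  if (ncol(b) != 2L) stop("bounds must give [min, max] per trait")
  if (any(!is.finite(b))) stop("bounds must be finite")
  if (any(b[, 2L] < b[, 1L])) stop("bounds must have min <= max")
  b
}

#' Maximise Expected Improvement over a bounded trait box
#'
#' Multi-start bounded optimisation of EI under a GP surrogate: Latin-
#' hypercube starts (plus the surrogate's own training points) are scored,
#' the most promising are polished by bounded quasi-Newton local search, and
#' the best point found is returned. Proposals always stay inside the
#' observed per-trait `[min, max]` box.
#'
#' @param surrogate a [gp_node_model()] for the response (e.g. seed yield
#'   given its parent traits).
#' @param best_observed incumbent best observed response.
#' @param bounds per-input `[min, max]` (rows = inputs), original units.
#' @param restarts number of Latin-hypercube starts (default 50).
#' @param seed integer RNG seed.
#' @return List with `point` (named vector), `ei`, `mean`, `sd`.
#' @export
maximise_acquisition <- function(surrogate, best_observed, bounds,
                                 restarts = 50L, seed = 1L) {
  b <- as_bounds_matrix(bounds)
  d <- nrow(b)
  if (length(surrogate$parents) != d) stop("bounds length must match surrogate inputs")
  span <- b[, 2L] - b[, 1L]
  if (all(span == 0)) {
    pt <- b[, 1L]
    mo <- surrogate_moments(surrogate, matrix(pt, 1L))
    return(list(point = stats::setNames(pt, surrogate$parents),
                ei = expected_improvement(mo$mean, mo$sd, best_observed),
                mean = mo$mean, sd = mo$sd))
  }
  set.seed(as.integer(seed))
  starts <- lhs::randomLHS(as.integer(restarts), d)
  starts <- sweep(sweep(starts, 2L, span, `*`), 2L, b[, 1L], `+`)
  train <- sweep(sweep(surrogate$X_train, 2L, surrogate$standardisation$x_scale, `*`),
                 2L, surrogate$standardisation$x_center, `+`)
  train <- pmin(pmax(train, matrix(b[, 1L], nrow(train), d, byrow = TRUE)),
                matrix(b[, 2L], nrow(train), d, byrow = TRUE))
  cand <- rbind(starts, train)
  ei_at <- function(M) {
    mo <- surrogate_moments(surrogate, M)
    expected_improvement(mo$mean, mo$sd, best_observed)
  }
  cand_ei <- ei_at(cand)
  best_pt <- cand[which.max(cand_ei), ]
  best_ei <- max(cand_ei)
  n_polish <- min(10L, nrow(starts))
  top <- order(-cand_ei)[seq_len(n_polish)]
  for (k in top) {
    fit <- tryCatch(stats::optim(
      cand[k, ],
      fn = function(x) -ei_at(matrix(x, 1L)),
      method = "L-BFGS-B", lower = b[, 1L], upper = b[, 2L],
      control = list(maxit = 100L, factr = 1e10)), error = function(e) NULL)
    if (!is.null(fit) && -fit$value > best_ei) {
      best_ei <- -fit$value
      best_pt <- pmin(pmax(fit$par, b[, 1L]), b[, 2L])
    }
  }
  if (best_ei <= 1e-12) {
    # improvement mass numerically exhausted (e.g. every basin already carries
    # a lie): fall back to pure exploration, the most uncertain candidate
    mo_all <- surrogate_moments(surrogate, cand)
    best_pt <- cand[which.max(mo_all$sd), ]
    best_ei <- expected_improvement(mo_all$mean[which.max(mo_all$sd)],
                                    max(mo_all$sd), best_observed)
  }
  mo <- surrogate_moments(surrogate, matrix(best_pt, 1L))
  list(point = stats::setNames(best_pt, surrogate$parents), ei = best_ei,
       mean = mo$mean, sd = mo$sd)
}

#' Propose a batch of ideotypes with the Constant Liar heuristic
#'
#' Proposals are generated sequentially: after each EI maximisation the new
#' point is appended to the surrogate's training set with the response set to
#' the "lie" `L` (here the maximum experimentally observed response), the
#' predictive equations are refit with hyperparameters frozen at their
#' posterior medians, and the next point is proposed. The lie removes the
#' improvement mass around pending proposals, so the batch spreads out.
#' Afterwards the batch is ranked by exceedance probability
#' `P(f(x) > best_observed)` under the original, lie-free surrogate (rank 1 =
#' best chance of beating the best observed plant); EI is kept as metadata.
#'
#' @inheritParams maximise_acquisition
#' @param q batch size (default 10 ranked ideotypes).
#' @param lie response value assumed for pending proposals; defaults to
#'   `best_observed`.
#' @return An `ideotype_proposals` data.frame: `rank`, one column per input
#'   trait, `predicted_yield_mean`, `predicted_yield_sd`, `ei`,
#'   `exceedance_probability` (rows ordered by rank).
#' @export
propose_batch_constant_liar <- function(surrogate, best_observed, bounds,
                                        q = 10L, lie = NULL, restarts = 50L,
                                        seed = 1L) {
  q <- as.integer(q)
  if (q < 1L) stop("q must be >= 1")
  if (is.null(lie)) lie <- best_observed
  b <- as_bounds_matrix(bounds)
  hyper <- frozen_hyper(surrogate)
  st <- surrogate$standardisation
  lie_std <- (lie - st$y_center) / st$y_scale
  Xaug <- surrogate$X_train
  yaug <- surrogate$y_train
  nvar <- rep(hyper$sigma^2, nrow(Xaug))
  lie_noise <- (hyper$sigma / 100)^2  # pending lies act as exact observations
  pts <- matrix(NA_real_, q, nrow(b))
  eis <- numeric(q)
  work <- surrogate
  for (i in seq_len(q)) {
    work$X_train <- Xaug
    work$y_train <- yaug
    work$noise_var <- nvar
    work$hyper_draws <- list(hyper)
    prop <- maximise_acquisition(work, best_observed, b,
                                 restarts = restarts, seed = seed + i - 1L)
    pts[i, ] <- prop$point
    eis[i] <- prop$ei
    Xaug <- rbind(Xaug, standardise_inputs(surrogate, matrix(prop$point, 1L)))
    yaug <- c(yaug, lie_std)
    nvar <- c(nvar, lie_noise)
  }
  finalize_proposals(surrogate, pts, eis, best_observed)
}

# rank points by exceedance probability under the lie-free surrogate
finalize_proposals <- function(surrogate, pts, eis, best_observed,
                               report_pts = NULL) {
  mo <- surrogate_moments(surrogate, pts)
  exceed <- ifelse(mo$sd > 0, stats::pnorm((mo$mean - best_observed) / mo$sd),
                   as.numeric(mo$mean > best_observed))
  rk <- rank(-exceed, ties.method = "first")
  if (is.null(report_pts)) report_pts <- pts
  if (is.null(colnames(report_pts))) colnames(report_pts) <- surrogate$parents
  out <- data.frame(rank = rk, report_pts,
                    predicted_yield_mean = mo$mean, predicted_yield_sd = mo$sd,
                    ei = eis, exceedance_probability = exceed,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ideotype_proposals", "data.frame")
  out
}

#' @export
print.ideotype_proposals <- function(x, ...) {
  cat("ideotype_proposals:", nrow(x), "ranked proposals\n")
  NextMethod()
}

#' Principal-component basis of the yield-parent trait space
#'
#' Standardises the parent-trait columns and eigendecomposes their
#' correlation matrix, keeping the smallest number of components whose
#' cumulative explained variance exceeds `threshold`. Optimising in this
#' independent basis (over the observed score ranges) constrains proposals to
#' respect the empirically observed correlation structure among traits —
#' e.g. a seed-number versus seed-weight trade-off.
#'
#' @param x matrix or data.frame of parent-trait values (plants x traits), or
#'   a [trait_table()] together with `traits`.
#' @param threshold cumulative explained-variance target in (0, 1]
#'   (default 0.95).
#' @param traits trait subset when `x` is a `trait_table`.
#' @return An object of class `pc_basis`: `loadings` (traits x components,
#'   orthonormal columns), `centre`, `scale`, `n_components`,
#'   `variance_explained` (cumulative fractions).
#' @export
build_pc_basis <- function(x, threshold = 0.95, traits = NULL) {
  if (inherits(x, "trait_table")) x <- trait_values(x, traits)
  X <- as.matrix(x)
  if (nrow(X) < 2L) stop("need at least 2 rows")
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant column: ", colnames(X)[which(sds == 0)[1L]])
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  n_comp <- which(cum >= threshold)[1L]
  structure(list(loadings = pc$rotation, centre = pc$center, scale = pc$scale,
                 n_components = n_comp, variance_explained = cum),
            class = "pc_basis")
}

#' @export
print.pc_basis <- function(x, ...) {
  cat("pc_basis:", ncol(x$loadings), "components over", nrow(x$loadings),
      "traits;", x$n_components, "retained (",
      round(100 * x$variance_explained[x$n_components], 1), "% variance )\n")
  invisible(x)
}

#' Project traits onto a PC basis / reconstruct traits from scores
#'
#' `pc_scores` returns scores on the retained components (or all components
#' with `all_components = TRUE`); `pc_reconstruct` maps retained-component
#' scores back to trait space (exact when all components are used).
#'
#' @param basis a [pc_basis()].
#' @param X trait matrix (plants x traits) in original units.
#' @param scores score matrix (plants x retained components).
#' @param all_components use every component rather than the retained ones.
#' @return Matrix of scores, or of reconstructed trait values.
#' @export
pc_scores <- function(basis, X, all_components = FALSE) {
  Xs <- sweep(sweep(as.matrix(X), 2L, basis$centre), 2L, basis$scale, `/`)
  k <- if (all_components) ncol(basis$loadings) else basis$n_components
  Xs %*% basis$loadings[, seq_len(k), drop = FALSE]
}

#' @rdname pc_scores
#' @export
pc_reconstruct <- function(basis, scores) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  Xs <- scores %*% t(basis$loadings[, seq_len(k), drop = FALSE])
  out <- sweep(sweep(Xs, 2L, basis$scale, `*`), 2L, basis$centre, `+`)
  colnames(out) <- rownames(basis$loadings)
  out
}

#' Batch Bayesian optimisation in a correlation-constrained PC basis
#'
#' Runs the Constant-Liar batch proposal in the independent PC basis, with
#' per-component bounds equal to the observed score ranges; proposals are
#' back-transformed to trait space, clipped to the observed per-trait
#' `[min, max]` box, and reported in original units.
#'
#' @param surrogate_on_pcs a [gp_node_model()] fitted with the retained PC
#'   scores as inputs.
#' @param basis the [pc_basis()] used to build those scores.
#' @param bounds_original per-trait `[min, max]` in original units (rows =
#'   traits, in the basis' trait order).
#' @inheritParams propose_batch_constant_liar
#' @return An `ideotype_proposals` data.frame reported in trait units, with
#'   the PC-space coordinates attached as attribute `"pc_points"`.
#' @export
optimise_in_pc_space <- function(surrogate_on_pcs, basis, bounds_original,
                                 best_observed, q = 10L, lie = NULL,
                                 restarts = 50L, seed = 1L) {
  b_orig <- as_bounds_matrix(bounds_original)
  st <- surrogate_on_pcs$standardisation
  scores_obs <- sweep(sweep(surrogate_on_pcs$X_train, 2L, st$x_scale, `*`),
                      2L, st$x_center, `+`)
  b_pc <- t(apply(scores_obs, 2L, range))
  if (is.null(lie)) lie <- best_observed
  q <- as.integer(q)
  hyper <- frozen_hyper(surrogate_on_pcs)
  lie_std <- (lie - st$y_center) / st$y_scale
  Xaug <- surrogate_on_pcs$X_train
  yaug <- surrogate_on_pcs$y_train
  nvar <- rep(hyper$sigma^2, nrow(Xaug))
  lie_noise <- (hyper$sigma / 100)^2
  pts_pc <- matrix(NA_real_, q, nrow(b_pc))
  eis <- numeric(q)
  work <- surrogate_on_pcs
  for (i in seq_len(q)) {
    work$X_train <- Xaug
    work$y_train <- yaug
    work$noise_var <- nvar
    work$hyper_draws <- list(hyper)
    prop <- maximise_acquisition(work, best_observed, b_pc,
                                 restarts = restarts, seed = seed + i - 1L)
    pts_pc[i, ] <- prop$point
    eis[i] <- prop$ei
    Xaug <- rbind(Xaug, standardise_inputs(surrogate_on_pcs, matrix(prop$point, 1L)))
    yaug <- c(yaug, lie_std)
    nvar <- c(nvar, lie_noise)
  }
  traits_pts <- pc_reconstruct(basis, pts_pc)
  traits_pts <- pmin(pmax(traits_pts,
                          matrix(b_orig[, 1L], q, nrow(b_orig), byrow = TRUE)),
                     matrix(b_orig[, 2L], q, nrow(b_orig), byrow = TRUE))
  out <- finalize_proposals(surrogate_on_pcs, pts_pc, eis, best_observed,
                            report_pts = traits_pts)
  attr(out, "pc_points") <- pts_pc
  out
}

#' Propose high-yield ideotypes from a fitted trait network
#'
#' Convenience wrapper: takes the yield node's GP (seed yield given its
#' direct DAG parents only), sets the incumbent to the maximum observed
#' yield and the Constant-Liar value to the same, and proposes a ranked
#' batch. With `constrained = TRUE` the optimisation runs in the PC basis of
#' the yield parents (components explaining > `threshold` of variance, over
#' observed score ranges), respecting observed trait correlations; otherwise
#' it searches the full observed trait box.
#'
#' @param network a `fitted_trait_network` whose DAG contains a yield sink.
#' @param yield yield node name; defaults to the unique sink with parents.
#' @param q batch size.
#' @param constrained impose the PC correlation constraint.
#' @param threshold PC cumulative-variance threshold.
#' @param restarts Latin-hypercube starts per proposal.
#' @param seed integer RNG seed.
#' @param sampler_config sampler for the PC-space surrogate refit (default
#'   MAP, which is deterministic and fast).
#' @return An `ideotype_proposals` data.frame.
#' @export
propose_ideotypes <- function(network, yield = NULL, q = 10L,
                              constrained = TRUE, threshold = 0.95,
                              restarts = 50L, seed = 1L,
                              sampler_config = gp_sampler_config("map")) {
  stopifnot(inherits(network, "fitted_trait_network"))
  dag <- network$dag
  if (is.null(yield)) {
    sinks <- setdiff(dag$nodes, dag$edges$parent)
    sinks <- sinks[vapply(sinks, function(s) length(dag_parents(dag, s)) > 0, logical(1L))]
    if (length(sinks) != 1L) stop("yield node ambiguous; pass `yield`")
    yield <- sinks
  }
  parents <- dag_parents(dag, yield)
  if (!length(parents)) stop("yield node has no parent traits")
  tab <- network$table
  y_obs <- trait_values(tab, yield)[, 1L]
  best_observed <- max(y_obs)
  P <- trait_values(tab, parents)
  bounds <- t(apply(P, 2L, range))
  if (!constrained) {
    return(propose_batch_constant_liar(network$node_models[[yield]],
                                       best_observed, bounds, q = q,
                                       restarts = restarts, seed = seed))
  }
  basis <- build_pc_basis(P, threshold = threshold)
  S <- pc_scores(basis, P)
  colnames(S) <- paste0("PC", seq_len(ncol(S)))
  sc_tab <- trait_table(data.frame(yield = y_obs, S, check.names = FALSE),
                        variety = tab$variety, group = tab$group)
  names(sc_tab$values)[1L] <- yield
  sc_tab$trait_names[1L] <- yield
  surrogate <- fit_node_gp(yield, colnames(S), sc_tab, sampler_config)
  optimise_in_pc_space(surrogate, basis, bounds, best_observed, q = q,
                       restarts = restarts, seed = seed)
}

#' Write ranked ideotype proposals as CSV
#'
#' @param proposals an `ideotype_proposals` data.frame.
#' @param path output path.
#' @export
write_ideotypes_csv <- function(proposals, path) {
  utils::write.csv(as.data.frame(proposals), path, row.names = FALSE)
  invisible(path)
}
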