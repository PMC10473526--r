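#' Impute missing trait values by predictive mean matching
#'
#' Chained-equations predictive mean matching (PMM). Incomplete traits are
#' visited in turn (most-complete first); each is regressed on all other
#' trait columns using the complete cases of that trait, with a small ridge
#' term for numerical stability. Regression coefficients are perturbed by a
#' draw from their approximate posterior (a Bayesian linear-regression draw:
#' scaled inverse-chi-squared residual variance, then Gaussian coefficients),
#' so imputation uncertainty is propagated between sweeps. For every missing
#' cell the `donors` observed cases whose predicted means are closest to the
#' missing case's (perturbed) predicted mean are found, and the observed
#' value of one donor, chosen uniformly at random, is copied in. Imputed
#' values are therefore always observed values of the same trait, and
#' observed cells are never altered.
#'
#' @param table a [trait_table()] with missing cells.
#' @param donors number of candidate donors per missing cell (default 5, the
#'   method's conventional setting).
#' @param n_iterations number of chained-equation sweeps (default 5).
#' @param seed integer RNG seed.
#' @return A completed [trait_table()] (single imputation).
#' @export
impute_pmm <- function(table, donors = 5L, n_iterations = 5L, seed = 1L) {
  stopifnot(inherits(table, "trait_table"))
  donors <- as.integer(donors); n_iterations <- as.integer(n_iterations)
  if (donors < 1L) stop("donors must be >= 1")
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  X <- trait_values(table)
  miss <- is.na(X)
  if (!any(miss)) return(table)
  n_obs <- colSums(!miss)
  if (any(n_obs == 0L)) {
    stop("trait '", colnames(X)[which(n_obs == 0L)[1L]], "' has no observed values")
  }
  if (any(n_obs < donors)) {
    stop("trait '", colnames(X)[which(n_obs < donors)[1L]],
         "' has fewer complete cases than donors")
  }
  set.seed(as.integer(seed))
  # initial fill: column means of observed values
  for (j in seq_len(ncol(X))) {
    if (any(miss[, j])) X[miss[, j], j] <- mean(X[!miss[, j], j])
  }
  incomplete <- order(colSums(miss))
  incomplete <- incomplete[colSums(miss)[incomplete] > 0L]
  for (it in seq_len(n_iterations)) {
    for (j in incomplete) {
      obs <- !miss[, j]
      y <- X[obs, j]
      D <- cbind(1, X[, -j, drop = FALSE])
      Dobs <- D[obs, , drop = FALSE]
      p <- ncol(Dobs)
      XtX <- crossprod(Dobs)
      ridge <- 1e-5 * mean(diag(XtX))
      A <- XtX + diag(ridge, p)
      Ainv <- solve(A)
      beta_hat <- Ainv %*% crossprod(Dobs, y)
      resid <- y - Dobs %*% beta_hat
      df <- max(length(y) - p, 1L)
      sigma2_star <- sum(resid^2) / stats::rchisq(1L, df)
      Rchol <- chol((Ainv + t(Ainv)) / 2)
      beta_star <- beta_hat + sqrt(sigma2_star) * t(Rchol) %*% stats::rnorm(p)
      yhat_obs <- drop(Dobs %*% beta_hat)
      yhat_mis <- drop(D[!obs, , drop = FALSE] %*% beta_star)
      mis_idx <- which(!obs)
      for (k in seq_along(mis_idx)) {
        d <- abs(yhat_obs - yhat_mis[k])
        pool <- order(d)[seq_len(donors)]
        pick <- pool[sample.int(donors, 1L)]
        X[mis_idx[k], j] <- y[pick]
      }
    }
  }
  out <- trait_table_replace(table, X)
  attr(out$values, "imputed_mask") <- miss
  out
}
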