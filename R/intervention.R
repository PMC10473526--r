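#' Predict the consequences of fixing one trait to a grid of values
#'
#' Emulates a do-style intervention on a single trait: the trait is fixed to
#' each value of a grid spanning its experimentally observed range, every
#' plant of the base table is used as an intervention background, and sampled
#' predictions are propagated through the DAG in topological order — each
#' descendant is drawn from its GP given its parent values, where descendant
#' parents take previously sampled values and non-descendant parents keep
#' their observed in-planta values. Draws are pooled over plants, posterior
#' hyperparameter draws and the supplied candidate networks, and per-
#' descendant quantile curves (10% to 90% by 10%) are reported.
#'
#' @param networks a `fitted_trait_network` or list of them (e.g. per-fold
#'   models, averaged over candidate DAG structures).
#' @param trait the trait to intervene on (present in every network's DAG).
#' @param base_table complete [trait_table()] of intervention backgrounds;
#'   defaults to the first network's training table.
#' @param n_grid number of evenly spaced grid values (default 20).
#' @param grid optional explicit grid vector overriding `n_grid`.
#' @param n_draws pooled draws per grid point and network (default 1000).
#' @param seed integer RNG seed.
#' @return An object of class `intervention_result`: `trait`, `grid`,
#'   `quantiles` (named list: descendant -> grid x 9 quantile matrix),
#'   `n_draws`, `networks_averaged`.
#' @export
do_intervene <- function(networks, trait, base_table = NULL, n_grid = 20L,
                         grid = NULL, n_draws = 1000L, seed = 1L) {
  if (inherits(networks, "fitted_trait_network")) networks <- list(networks)
  stopifnot(length(networks) >= 1L)
  for (nw in networks) {
    if (!trait %in% nw$dag$nodes) stop("trait '", trait, "' missing from a network DAG")
  }
  if (is.null(base_table)) base_table <- networks[[1L]]$table
  stopifnot(inherits(base_table, "trait_table"))
  V0 <- trait_values(base_table)
  if (anyNA(V0)) stop("base_table must be complete")
  if (is.null(grid)) {
    rng <- range(V0[, trait])
    grid <- seq(rng[1L], rng[2L], length.out = as.integer(n_grid))
  }
  qs <- seq(0.1, 0.9, by = 0.1)
  all_desc <- unique(unlist(lapply(networks, function(nw) dag_descendants(nw$dag, trait))))
  if (!length(all_desc)) {
    warning("trait '", trait, "' has no descendants; nothing to predict")
    return(structure(list(trait = trait, grid = grid,
                          quantiles = setNames(list(), character(0)),
                          n_draws = n_draws, networks_averaged = length(networks)),
                     class = "intervention_result"))
  }
  set.seed(as.integer(seed))
  n_rows <- nrow(V0)
  draws_store <- lapply(all_desc, function(d) vector("list", length(grid)))
  names(draws_store) <- all_desc
  for (w in seq_along(networks)) {
    nw <- networks[[w]]
    desc <- dag_descendants(nw$dag, trait)
    if (!length(desc)) next
    ord <- intersect(topological_order(nw$dag), desc)
    reps <- max(1L, ceiling(n_draws / n_rows))
    base <- V0[rep(seq_len(n_rows), reps), , drop = FALSE]
    for (gidx in seq_along(grid)) {
      V <- base
      V[, trait] <- grid[gidx]
      for (nd in ord) {
        model <- nw$node_models[[nd]]
        X <- V[, model$parents, drop = FALSE]
        V[, nd] <- draw_one_per_row(model, X)
        draws_store[[nd]][[gidx]] <- c(draws_store[[nd]][[gidx]], V[, nd])
      }
    }
  }
  quantiles <- lapply(draws_store, function(dl) {
    qmat <- t(vapply(dl, function(v) {
      if (is.null(v)) rep(NA_real_, length(qs)) else stats::quantile(v, qs, names = FALSE)
    }, numeric(length(qs))))
    colnames(qmat) <- paste0("q", round(100 * qs))
    qmat
  })
  structure(list(trait = trait, grid = grid, quantiles = quantiles,
                 n_draws = n_draws, networks_averaged = length(networks)),
            class = "intervention_result")
}

# one function-plus-noise draw per row, cycling over retained hyper draws
draw_one_per_row <- function(model, X) {
  Xs <- standardise_inputs(model, X)
  n <- nrow(Xs)
  H <- model$hyper_draws
  nh <- length(H)
  out <- numeric(n)
  block <- rep_len(seq_len(nh), n)
  for (h in seq_len(nh)) {
    idx <- which(block == h)
    if (!length(idx)) next
    pr <- gp_predictive_marginal(model, Xs[idx, , drop = FALSE], H[[h]],
                                 include_noise = TRUE)
    out[idx] <- pr$mean + pr$sd * stats::rnorm(length(idx))
  }
  model$standardisation$y_center + model$standardisation$y_scale * out
}

#' @export
print.intervention_result <- function(x, ...) {
  cat("intervention_result: do(", x$trait, ") over", length(x$grid),
      "grid values;", length(x$quantiles), "descendant trait(s);",
      x$networks_averaged, "network(s) averaged\n")
  invisible(x)
}

#' Tidy data.frame view of an intervention result
#'
#' @param x an `intervention_result`.
#' @param ... unused.
#' @return data.frame with columns `trait`, `grid_value`, `descendant`,
#'   `quantile`, `value`.
#' @export
as.data.frame.intervention_result <- function(x, ...) {
  out <- list()
  for (d in names(x$quantiles)) {
    qmat <- x$quantiles[[d]]
    for (qn in colnames(qmat)) {
      out[[length(out) + 1L]] <- data.frame(
        trait = x$trait, grid_value = x$grid, descendant = d,
        quantile = as.numeric(sub("^q", "", qn)) / 100, value = qmat[, qn],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(trait = character(), grid_value = numeric(),
                      descendant = character(), quantile = numeric(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Write an intervention result as tidy CSV
#'
#' @param result an `intervention_result`.
#' @param path output path.
#' @export
write_intervention_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}

#' Quantile-fan plot of an intervention result
#'
#' Draws the median response curve of each descendant with lighter
#' inter-decile quantile curves, one panel per descendant.
#'
#' @param x an `intervention_result`.
#' @param traits descendants to plot (default: all).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.intervention_result <- function(x, traits = NULL, ...) {
  if (is.null(traits)) traits <- names(x$quantiles)
  if (!length(traits)) return(invisible(x))
  old <- graphics::par(mfrow = c(1, length(traits)))
  on.exit(graphics::par(old))
  for (d in traits) {
    qmat <- x$quantiles[[d]]
    graphics::matplot(x$grid, qmat, type = "l", lty = 1,
                      col = grDevices::grey(0.75), xlab = x$trait, ylab = d, ...)
    graphics::lines(x$grid, qmat[, "q50"], lwd = 2)
  }
  invisible(x)
}
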