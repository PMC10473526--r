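#' Broad-sense heritability from ANOVA mean squares
#'
#' One-way ANOVA of the trait by variety. The genetic variance component is
#' `sigma_g^2 = max(0, (MS_genotype - MS_error) / r)` with `r` the harmonic
#' mean number of replicates per variety (the standard unbalanced-design
#' correction), `sigma_e^2 = MS_error`, and
#' `H2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`. With `use_residuals = TRUE`
#' the response is the trait minus its GP posterior-mean prediction from its
#' parent traits ("direct" heritability, conditioning away variation caused
#' by heritable parents); traits without parents fall back to the raw mode.
#'
#' @param table a complete [trait_table()].
#' @param trait trait name.
#' @param use_residuals condition on parent traits via network residuals.
#' @param network a `fitted_trait_network`; required when `use_residuals`.
#' @return An `h2_estimate` list: `trait`, `H2`, `sigma2_g`, `sigma2_e`,
#'   `mode` (`"raw"` or `"residual"`), `anova_p`, `clipped` (TRUE when the
#'   genetic component was truncated at zero).
#' @export
estimate_h2 <- function(table, trait, use_residuals = FALSE, network = NULL) {
  stopifnot(inherits(table, "trait_table"))
  variety <- factor(table$variety)
  if (nlevels(variety) < 2L) stop("need at least two varieties")
  reps <- table(variety)
  if (sum(reps >= 2L) < 2L) stop("need at least two varieties with two replicates")
  mode <- "raw"
  y <- trait_values(table, trait)[, 1L]
  if (use_residuals) {
    if (is.null(network)) stop("use_residuals requires a fitted network")
    model <- network$node_models[[trait]]
    if (inherits(model, "gp_node_model")) {
      X <- trait_values(table, model$parents)
      y <- y - surrogate_moments(model, X)$mean
      mode <- "residual"
    }  # parentless traits: residuals equal raw values
  }
  if (anyNA(y)) stop("trait has missing values; impute first")
  fit <- stats::aov(y ~ variety)
  tab <- summary(fit)[[1L]]
  ms_g <- tab["variety", "Mean Sq"]
  ms_e <- tab["Residuals", "Mean Sq"]
  p <- tab["variety", "Pr(>F)"]
  r_bar <- length(reps) / sum(1 / as.numeric(reps))  # harmonic mean replicates
  sg2_raw <- (ms_g - ms_e) / r_bar
  clipped <- sg2_raw < 0
  sg2 <- max(0, sg2_raw)
  h2 <- sg2 / (sg2 + ms_e)
  structure(list(trait = trait, H2 = h2, sigma2_g = sg2, sigma2_e = ms_e,
                 mode = mode, anova_p = p, clipped = clipped),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat("h2_estimate:", x$trait, "(", x$mode, ") H2 =", format(x$H2, digits = 3),
      " p =", format(x$anova_p, digits = 3), "\n")
  invisible(x)
}

#' Raw versus residual heritability for every trait
#'
#' Mirrors a per-trait heritability summary table: total ("raw") broad-sense
#' heritability next to "direct" heritability on network residuals, with
#' Benjamini-Hochberg adjusted ANOVA p-values. Parentless traits show
#' `NA` in the residual column (their residuals equal their raw values).
#'
#' @param table a complete [trait_table()].
#' @param network a `fitted_trait_network`.
#' @param traits trait subset (default: all network nodes).
#' @return data.frame: `trait`, `H2_raw`, `H2_residual`, `p_raw_adj`,
#'   `p_residual_adj`.
#' @export
heritability_table <- function(table, network, traits = NULL) {
  if (is.null(traits)) traits <- network$dag$nodes
  raw <- lapply(traits, function(tr) estimate_h2(table, tr))
  res <- lapply(traits, function(tr)
    estimate_h2(table, tr, use_residuals = TRUE, network = network))
  has_parents <- vapply(res, function(e) e$mode == "residual", logical(1L))
  data.frame(
    trait = traits,
    H2_raw = vapply(raw, `[[`, numeric(1L), "H2"),
    H2_residual = ifelse(has_parents, vapply(res, `[[`, numeric(1L), "H2"), NA_real_),
    p_raw_adj = stats::p.adjust(vapply(raw, `[[`, numeric(1L), "anova_p"), "BH"),
    p_residual_adj = stats::p.adjust(vapply(res, `[[`, numeric(1L), "anova_p"), "BH"),
    stringsAsFactors = FALSE)
}

#' Residuals of a trait table under a fitted trait network
#'
#' For every non-root trait, residual = observed value minus the GP
#' posterior-mean prediction from its parents; root traits pass through
#' unchanged, as do traits absent from the network (with a warning).
#'
#' @param network a `fitted_trait_network`.
#' @param table a complete [trait_table()].
#' @return A [trait_table()] of residuals (roots unchanged).
#' @export
compute_residuals <- function(network, table) {
  stopifnot(inherits(network, "fitted_trait_network"), inherits(table, "trait_table"))
  vals <- table$values
  for (nm in table$trait_names) {
    model <- network$node_models[[nm]]
    if (is.null(model)) {
      warning("trait '", nm, "' absent from network; passed through")
      next
    }
    if (!inherits(model, "gp_node_model")) next  # root trait
    X <- trait_values(table, model$parents)
    if (anyNA(X) || anyNA(vals[[nm]])) stop("table must be complete (impute first)")
    vals[[nm]] <- vals[[nm]] - surrogate_moments(model, X)$mean
  }
  trait_table_replace(table, vals)
}

#' Simulate genotypes with mediated pleiotropy between two traits
#'
#' Biallelic SNPs are drawn independently as Bernoulli(0.5) 0/1 codes. The
#' parent trait is the weighted sum of its causal ("parent") SNPs plus
#' Gaussian noise; the child trait is the weighted sum of its own ("child")
#' SNPs plus `gamma` times the parent trait plus noise. Parent SNPs
#' therefore affect the child only through the parent trait (mediated
#' pleiotropy); the remaining SNPs are non-causal.
#'
#' @param n_plants number of individuals.
#' @param n_parent_snps,n_child_snps,n_null_snps SNP class sizes.
#' @param gamma parent-to-child causal effect.
#' @param sigma noise sd added to both traits (> 0).
#' @param weights_sd sd of the Normal(0, weights_sd^2) SNP effect weights.
#' @param seed integer RNG seed.
#' @return A `mediated_pleiotropy_sim` list: `genotypes` (plants x SNPs 0/1),
#'   `parent_trait`, `child_trait`, index sets `parent_snps`, `child_snps`,
#'   `null_snps`, `weights` (list `parent`, `child`), `gamma`, `sigma`.
#' @export
simulate_mediated_pleiotropy <- function(n_plants, n_parent_snps = 20L,
                                         n_child_snps = 20L, n_null_snps = 460L,
                                         gamma = 1, sigma = 0.5,
                                         weights_sd = 0.5, seed = 1L) {
  if (n_plants < 2L) stop("n_plants must be >= 2")
  if (any(c(n_parent_snps, n_child_snps, n_null_snps) < 0)) stop("SNP counts must be >= 0")
  if (!is.finite(gamma) || !is.finite(sigma) || sigma <= 0) {
    stop("gamma must be finite and sigma positive")
  }
  set.seed(as.integer(seed))
  m <- n_parent_snps + n_child_snps + n_null_snps
  G <- matrix(stats::rbinom(n_plants * m, 1L, 0.5), n_plants, m)
  colnames(G) <- sprintf("snp_%04d", seq_len(m))
  parent_snps <- seq_len(n_parent_snps)
  child_snps <- n_parent_snps + seq_len(n_child_snps)
  null_snps <- n_parent_snps + n_child_snps + seq_len(n_null_snps)
  wp <- stats::rnorm(n_parent_snps, 0, weights_sd)
  wc <- stats::rnorm(n_child_snps, 0, weights_sd)
  p <- drop(G[, parent_snps, drop = FALSE] %*% wp) + stats::rnorm(n_plants, 0, sigma)
  cc <- drop(G[, child_snps, drop = FALSE] %*% wc) + gamma * p +
    stats::rnorm(n_plants, 0, sigma)
  structure(list(genotypes = G, parent_trait = p, child_trait = cc,
                 parent_snps = parent_snps, child_snps = child_snps,
                 null_snps = null_snps, weights = list(parent = wp, child = wc),
                 gamma = gamma, sigma = sigma),
            class = "mediated_pleiotropy_sim")
}

#' @export
print.mediated_pleiotropy_sim <- function(x, ...) {
  cat("mediated_pleiotropy_sim:", nrow(x$genotypes), "plants,",
      ncol(x$genotypes), "SNPs ( gamma =", x$gamma, ", sigma =", x$sigma, ")\n")
  invisible(x)
}

#' Single-SNP association scan with Bonferroni family-wise control
#'
#' SNPs with minor-allele frequency at or below `maf_min` (including
#' monomorphic SNPs) are dropped; each remaining SNP is tested by simple
#' linear regression of the trait on the 0/1 genotype (two-sided t-test),
#' and declared a hit when `p < alpha_fwer / m` with `m` the number of SNPs
#' actually tested (Bonferroni at the requested family-wise error rate).
#'
#' @param trait_values numeric response vector (one value per plant).
#' @param genotypes plants x SNPs 0/1 matrix.
#' @param alpha_fwer family-wise error rate (default 0.1).
#' @param maf_min minor-allele-frequency exclusion threshold (default 0.05).
#' @return List: `hits` (column indices of significant SNPs), `p_values`
#'   (per-SNP, `NA` for untested SNPs), `n_tested`, `threshold`.
#' @export
association_scan <- function(trait_values, genotypes, alpha_fwer = 0.1,
                             maf_min = 0.05) {
  y <- as.numeric(trait_values)
  G <- as.matrix(genotypes)
  if (length(y) != nrow(G)) stop("trait and genotype rows must align")
  if (alpha_fwer <= 0 || alpha_fwer >= 1) stop("alpha_fwer must lie in (0, 1)")
  f <- colMeans(G)
  maf <- pmin(f, 1 - f)
  tested <- which(maf > maf_min)
  p_values <- rep(NA_real_, ncol(G))
  if (length(tested)) {
    n <- length(y)
    r <- suppressWarnings(stats::cor(y, G[, tested, drop = FALSE]))[1L, ]
    r2 <- pmin(r^2, 1 - 1e-12)
    tstat <- r * sqrt((n - 2) / (1 - r2))
    p_values[tested] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  m <- length(tested)
  thr <- if (m) alpha_fwer / m else NA_real_
  hits <- if (m) tested[which(p_values[tested] < thr)] else integer(0)
  list(hits = hits, p_values = p_values, n_tested = m, threshold = thr)
}

#' Detection power of raw versus residual association scans
#'
#' For each `(gamma, sigma)` grid cell, `n_reps` mediated-pleiotropy panels
#' are simulated and the child trait scanned either directly ("raw") or
#' after removing the fitted linear effect of the parent trait ("residual",
#' the regression residual of child on parent). Power is the fraction of
#' SNPs of each class (parent / child / null) declared significant.
#'
#' @param grid data.frame with columns `gamma` and `sigma`.
#' @param n_reps simulations per cell.
#' @param n_plants,n_parent_snps,n_child_snps,n_null_snps,weights_sd passed
#'   to [simulate_mediated_pleiotropy()].
#' @param alpha_fwer,maf_min passed to [association_scan()].
#' @param seed integer RNG seed.
#' @return Tidy data.frame: `gamma`, `sigma`, `mode`, `class`, `power`.
#' @export
power_experiment <- function(grid, n_reps = 50L, n_plants = 200L,
                             n_parent_snps = 20L, n_child_snps = 20L,
                             n_null_snps = 460L, weights_sd = 0.5,
                             alpha_fwer = 0.1, maf_min = 0.05, seed = 1L) {
  grid <- as.data.frame(grid)
  if (!nrow(grid)) stop("grid must be non-empty")
  if (!all(c("gamma", "sigma") %in% names(grid))) {
    stop("grid needs columns gamma, sigma")
  }
  out <- list()
  for (g in seq_len(nrow(grid))) {
    hit_counts <- matrix(0, 2L, 3L,
                         dimnames = list(c("raw", "residual"),
                                         c("parent", "child", "null")))
    for (r in seq_len(n_reps)) {
      sim <- simulate_mediated_pleiotropy(
        n_plants, n_parent_snps, n_child_snps, n_null_snps,
        gamma = grid$gamma[g], sigma = grid$sigma[g], weights_sd = weights_sd,
        seed = as.integer(seed) + 7919L * (g - 1L) + r)
      classes <- list(parent = sim$parent_snps, child = sim$child_snps,
                      null = sim$null_snps)
      y_raw <- sim$child_trait
      y_res <- stats::residuals(stats::lm(sim$child_trait ~ sim$parent_trait))
      for (mode in c("raw", "residual")) {
        y <- if (mode == "raw") y_raw else y_res
        scan <- association_scan(y, sim$genotypes, alpha_fwer, maf_min)
        for (cl in names(classes)) {
          if (length(classes[[cl]])) {
            hit_counts[mode, cl] <- hit_counts[mode, cl] +
              length(intersect(scan$hits, classes[[cl]])) / length(classes[[cl]])
          }
        }
      }
    }
    for (mode in c("raw", "residual")) for (cl in c("parent", "child", "null")) {
      out[[length(out) + 1L]] <- data.frame(
        gamma = grid$gamma[g], sigma = grid$sigma[g], mode = mode, class = cl,
        power = hit_counts[mode, cl] / n_reps, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write a 0/1 genotype matrix as CSV or a minimal VCF-like TSV
#'
#' The TSV layout has columns `CHROM`, `POS`, `ID` then one 0/1 column per
#' sample (one row per SNP), for interoperability with variant tooling.
#'
#' @param genotypes plants x SNPs 0/1 matrix.
#' @param path output path.
#' @export
write_genotypes_csv <- function(genotypes, path) {
  utils::write.csv(as.data.frame(genotypes), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_csv
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  G <- as.matrix(genotypes)
  ids <- colnames(G)
  if (is.null(ids)) ids <- sprintf("snp_%04d", seq_len(ncol(G)))
  df <- data.frame(CHROM = "sim1", POS = seq_len(ncol(G)), ID = ids,
                   t(G), check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-(1:3)] <- sprintf("sample_%04d", seq_len(nrow(G)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
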