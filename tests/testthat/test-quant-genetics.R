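root_trait_sim <- function(vsd, esd, n_var = 50L, reps = 5L, seed = 1) {
  sp <- scm_spec("t", c(t = 0L), NULL, "t", noise_sd = esd,
                 variety_effect_sd = vsd, n_varieties = n_var,
                 reps_per_variety = reps)
  generate_scm_table(sp, seed = seed)$table
}

test_that("heritability is near zero without variety effects", {
  h <- vapply(1:10, function(s) {
    estimate_h2(root_trait_sim(vsd = 1e-9, esd = 1, seed = s), "t")$H2
  }, numeric(1L))
  expect_lte(mean(h), 0.1)
})

test_that("heritability recovers the simulated variance ratio", {
  h <- vapply(1:20, function(s) {
    estimate_h2(root_trait_sim(vsd = 1, esd = 1, seed = s), "t")$H2
  }, numeric(1L))
  expect_equal(mean(h), 0.5, tolerance = 0.1 / 0.5)
  # H2 is always a proper proportion
  expect_true(all(h >= 0 & h <= 1))
})

test_that("unbalanced designs are handled through harmonic-mean replicates", {
  tab <- root_trait_sim(vsd = 1, esd = 1, n_var = 40L, reps = 5L, seed = 3)
  drop <- c(1, 2, 6, 11, 16)  # unbalance a few varieties
  tab <- trait_table_subset(tab, setdiff(seq_len(200), drop))
  est <- estimate_h2(tab, "t")
  expect_gt(est$H2, 0.2)
  expect_lt(est$H2, 0.8)
  expect_error(estimate_h2(trait_table_subset(tab, 3:5), "t"), "varieties")
})

mediated_fixture <- function(seed = 1) {
  # child's variety-level variation flows almost entirely through the parent
  set.seed(seed)
  nv <- 50L; reps <- 5L
  variety <- rep(sprintf("v%02d", seq_len(nv)), each = reps)
  g <- rep(rnorm(nv, 0, 1), each = reps)
  parent <- g + rnorm(nv * reps, 0, 0.3)
  child <- 2 * parent + rnorm(nv * reps, 0, 0.3)
  tab <- trait_table(data.frame(parent = parent, child = child),
                     variety = variety)
  dag <- trait_dag(c("parent", "child"),
                   data.frame(parent = "parent", child = "child"))
  list(table = tab, network = fit_trait_network(dag, tab, map_config()))
}

test_that("conditioning on a heritable parent collapses the child's heritability", {
  fx <- mediated_fixture()
  raw <- estimate_h2(fx$table, "child")
  res <- estimate_h2(fx$table, "child", use_residuals = TRUE,
                     network = fx$network)
  expect_identical(res$mode, "residual")
  expect_gte(raw$H2 / max(res$H2, 1e-6), 2)
  # parentless traits fall back to raw mode
  res_root <- estimate_h2(fx$table, "parent", use_residuals = TRUE,
                          network = fx$network)
  expect_identical(res_root$mode, "raw")
  expect_equal(res_root$H2, estimate_h2(fx$table, "parent")$H2)
})

test_that("the heritability table mirrors raw and residual modes per trait", {
  fx <- mediated_fixture()
  h2 <- heritability_table(fx$table, fx$network)
  expect_identical(h2$trait, c("parent", "child"))
  expect_true(is.na(h2$H2_residual[1L]))  # parentless: dash semantics
  expect_false(is.na(h2$H2_residual[2L]))
  expect_true(all(h2$p_raw_adj >= 0 & h2$p_raw_adj <= 1))
})

test_that("network residuals are centred, decorrelated from parents, and keep roots", {
  tab <- chain_table(n = 120, noise = 1e-3, seed = 5)
  nw <- fit_trait_network(chain_dag(), tab, map_config())
  res <- compute_residuals(nw, tab)
  V <- trait_values(tab); R <- trait_values(res)
  expect_identical(R[, "x"], V[, "x"])                # root passthrough
  expect_lt(max(abs(R[, "y"])), 1e-2)                 # near-noiseless child
  expect_lt(abs(mean(R[, "z"])) / sd(V[, "z"]), 0.05) # centred
  expect_lt(abs(cor(R[, "z"], V[, "y"])), 0.1)        # orthogonal to parent
})

test_that("the mediated-pleiotropy generator matches its stated moments", {
  sim <- simulate_mediated_pleiotropy(2000L, 20L, 20L, 60L, gamma = 0,
                                      sigma = 0.5, weights_sd = 0.5, seed = 6)
  expect_true(all(sim$genotypes %in% c(0L, 1L)))
  expect_lt(abs(cor(sim$parent_trait, sim$child_trait)), 0.1)  # gamma = 0
  expect_lt(abs(mean(sim$genotypes) - 0.5), 0.03)     # overall allele frequency
  expect_lt(max(abs(colMeans(sim$genotypes) - 0.5)), 0.05)
  # index sets partition the SNPs
  expect_identical(sort(c(sim$parent_snps, sim$child_snps, sim$null_snps)),
                   seq_len(100L))
  # variance algebra: var(c) = sum(w_c^2)/4 + gamma^2 var(p) + sigma^2
  sim2 <- simulate_mediated_pleiotropy(5000L, 20L, 20L, 10L, gamma = 1.5,
                                       sigma = 0.5, weights_sd = 0.5, seed = 7)
  expected <- sum(sim2$weights$child^2) * 0.25 +
    1.5^2 * var(sim2$parent_trait) + 0.5^2
  expect_equal(var(sim2$child_trait), expected, tolerance = 0.1)
  # bitwise reproducibility
  again <- simulate_mediated_pleiotropy(2000L, 20L, 20L, 60L, gamma = 0,
                                        sigma = 0.5, weights_sd = 0.5, seed = 6)
  expect_identical(sim$genotypes, again$genotypes)
  expect_identical(sim$child_trait, again$child_trait)
})

test_that("the association scan controls the family-wise error on null traits", {
  set.seed(8)
  n <- 200L; m <- 500L
  any_hit <- vapply(1:500, function(r) {
    G <- matrix(rbinom(n * m, 1L, 0.5), n, m)
    y <- rnorm(n)
    length(association_scan(y, G, alpha_fwer = 0.1)$hits) > 0L
  }, logical(1L))
  expect_lte(mean(any_hit), 0.1 + 0.03)
})

test_that("perfect associations are found and filtered SNPs never tested", {
  set.seed(9)
  n <- 100L
  G <- matrix(rbinom(n * 50L, 1L, 0.5), n, 50L)
  G[, 7L] <- rep(c(0L, 1L), n / 2)
  G[, 13L] <- 0L  # monomorphic
  y <- as.numeric(G[, 7L])
  scan <- association_scan(y, G, alpha_fwer = 0.1)
  expect_true(7L %in% scan$hits)
  expect_lt(scan$p_values[7L], 1e-10)
  expect_true(is.na(scan$p_values[13L]))
  expect_equal(scan$n_tested, 49L)
  expect_error(association_scan(y[-1], G), "align")
})

test_that("residual scans recover child SNPs once mediation is controlled", {
  grid <- data.frame(gamma = c(0, 3), sigma = c(0.5, 0.1))
  pw <- power_experiment(grid, n_reps = 25L, seed = 10)
  cell <- function(g, s, mode, cl) {
    pw$power[pw$gamma == g & pw$sigma == s & pw$mode == mode & pw$class == cl]
  }
  # gamma = 0: raw and residual child power agree
  expect_lt(abs(cell(0, 0.5, "raw", "child") - cell(0, 0.5, "residual", "child")),
            0.05)
  # gamma = 3, sigma = 0.1: raw flags parents over children; residual reverses
  expect_gt(cell(3, 0.1, "raw", "parent"), cell(3, 0.1, "raw", "child"))
  expect_gt(cell(3, 0.1, "residual", "child"), cell(3, 0.1, "residual", "parent"))
  # residual child power never falls materially below raw
  expect_gte(cell(3, 0.1, "residual", "child"), cell(3, 0.1, "raw", "child") - 0.05)
  # null-SNP rates stay tiny in both modes
  expect_lt(max(pw$power[pw$class == "null"]), 0.01)
})

test_that("genotypes export as CSV and as the VCF-like TSV layout", {
  sim <- simulate_mediated_pleiotropy(10L, 2L, 2L, 2L, gamma = 1, sigma = 0.5,
                                      seed = 11)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes_csv(sim$genotypes, p1)
  write_genotypes_tsv(sim$genotypes, p2)
  expect_equal(dim(utils::read.csv(p1)), c(10L, 6L))
  tsv <- utils::read.delim(p2)
  expect_identical(names(tsv)[1:3], c("CHROM", "POS", "ID"))
  expect_equal(nrow(tsv), 6L)
})
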