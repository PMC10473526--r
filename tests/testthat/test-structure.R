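# independently coded Gaussian log-likelihood of one node given parents (OLS)
oracle_local_loglik <- function(y, X = NULL) {
  n <- length(y)
  fit <- if (is.null(X)) lm(y ~ 1) else lm(y ~ X)
  s2 <- sum(residuals(fit)^2) / n  # ML variance
  -n / 2 * (log(2 * pi * s2) + 1)
}

test_that("BIC of the empty graph matches the closed-form Gaussian score", {
  set.seed(1)
  n <- 200
  tab <- trait_table(data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n)),
                     variety = rep("v", n))
  dag <- trait_dag(c("a", "b", "c"))
  expected <- sum(vapply(c("a", "b", "c"), function(nm) {
    oracle_local_loglik(tab$values[[nm]]) - (2 / 2) * log(n)
  }, numeric(1L)))
  expect_equal(bic_score(dag, tab), expected, tolerance = 1e-10)
})

test_that("adding the true parent strictly increases the score", {
  set.seed(2)
  n <- 500
  x <- rnorm(n); y <- 2 * x + rnorm(n, 0, 0.1)
  tab <- trait_table(data.frame(x = x, y = y), variety = rep("v", n))
  empty <- trait_dag(c("x", "y"))
  with_edge <- trait_dag(c("x", "y"), data.frame(parent = "x", child = "y"))
  expect_gt(bic_score(with_edge, tab), bic_score(empty, tab))
})

test_that("the network score decomposes over node-wise local scores", {
  set.seed(3)
  n <- 150
  x <- rnorm(n); y <- x + rnorm(n); z <- y + rnorm(n)
  tab <- trait_table(data.frame(x = x, y = y, z = z), variety = rep("v", n))
  dag <- chain_dag()
  local_sum <-
    (oracle_local_loglik(x) - 1 * log(n)) +
    (oracle_local_loglik(y, x) - 1.5 * log(n)) +
    (oracle_local_loglik(z, y) - 1.5 * log(n))
  expect_equal(bic_score(dag, tab), local_sum, tolerance = 1e-10)
})

test_that("tabu search finds the only informative edge of a two-trait system", {
  set.seed(4)
  n <- 300
  x <- rnorm(n); y <- 2 * x + rnorm(n, 0, 0.1)
  tab <- trait_table(data.frame(x = x, y = y), variety = rep("v", n))
  # exhaustive oracle over the three possible structures
  scores <- c(empty = bic_score(trait_dag(c("x", "y")), tab),
              xy = bic_score(trait_dag(c("x", "y"),
                                       data.frame(parent = "x", child = "y")), tab),
              yx = bic_score(trait_dag(c("x", "y"),
                                       data.frame(parent = "y", child = "x")), tab))
  expect_true(which.max(scores) != 1L)  # an edge is optimal
  found <- tabu_search(tab)
  expect_equal(nrow(found$edges), 1L)
  expect_setequal(c(found$edges$parent, found$edges$child), c("x", "y"))
  expect_equal(bic_score(found, tab), max(scores), tolerance = 1e-9)
})

test_that("constraints are always respected and checked for consistency", {
  sim <- generate_scm_table(example_trait_network(n_varieties = 40L), seed = 5)
  wl <- data.frame(parent = "SeedNumber", child = "SeedYield")
  bl <- data.frame(parent = "PlantHeight", child = "SeedYield")
  cons <- edge_constraints(wl, bl, tier_map = sim$truth$tiers)
  dag <- tabu_search(sim$table, cons)
  key <- paste(dag$edges$parent, dag$edges$child)
  expect_true("SeedNumber SeedYield" %in% key)
  expect_false("PlantHeight SeedYield" %in% key)
  # tier map forbids downhill edges
  tiers <- sim$truth$tiers
  expect_true(all(tiers[dag$edges$parent] <= tiers[dag$edges$child]))
  expect_error(edge_constraints(wl, wl), "overlap")
  expect_error(edge_constraints(data.frame(parent = c("a", "b"),
                                           child = c("b", "a"))), "cycle")
})

test_that("independent columns yield an empty graph beyond the whitelist", {
  empties <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 1000
    tab <- trait_table(data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n),
                                  d = rnorm(n)),
                       variety = rep("v", n))
    nrow(tabu_search(tab)$edges) == 0L
  }, logical(1L))
  expect_gte(mean(empties), 0.9)
})

test_that("every learnt graph is acyclic and scores at least the start graph", {
  for (s in 1:5) {
    sim <- generate_scm_table(example_trait_network(n_varieties = 30L), seed = s)
    wl <- data.frame(parent = "NumberFlowers", child = "NumberPods")
    cons <- edge_constraints(whitelist = wl, tier_map = sim$truth$tiers)
    dag <- tabu_search(sim$table, cons)
    expect_false(is.null(topological_order(dag)))
    start <- trait_dag(dag$nodes, wl)
    expect_gte(bic_score(dag, sim$table), bic_score(start, sim$table))
  }
})

test_that("bootstrap probabilities are frequencies with whitelisted arcs at 1", {
  sim <- generate_scm_table(example_trait_network(n_varieties = 60L), seed = 6)
  wl <- data.frame(parent = "SeedNumber", child = "SeedYield")
  cons <- edge_constraints(whitelist = wl, tier_map = sim$truth$tiers)
  dag <- bootstrap_arc_probabilities(sim$table, cons, replicates = 30L, seed = 7)
  tab <- attr(dag, "arc_prob_table")
  expect_true(all(tab$prob >= 0 & tab$prob <= 1))
  wl_prob <- tab$prob[tab$parent == "SeedNumber" & tab$child == "SeedYield"]
  expect_identical(wl_prob, 1)
  # returned edges are a subset of edges with nonzero probability
  key <- paste(tab$parent, tab$child)
  expect_true(all(paste(dag$edges$parent, dag$edges$child) %in% key))
})

test_that("a strong relationship is recovered with high bootstrap probability", {
  set.seed(8)
  n <- 500
  x <- rnorm(n); y <- 2 * x + rnorm(n, 0, 0.3)  # R^2 > 0.9
  tab <- trait_table(data.frame(x = x, y = y), variety = rep("v", n))
  dag <- bootstrap_arc_probabilities(tab, replicates = 100L, seed = 9)
  probs <- attr(dag, "arc_prob_table")
  expect_gte(sum(probs$prob), 0.9)  # the undirected link is near-certain
  expect_equal(nrow(dag$edges), 1L)
})

test_that("fold averaging returns per-fold models and a consensus subset", {
  sim <- generate_scm_table(example_trait_network(n_varieties = 40L), seed = 10)
  cons <- edge_constraints(tier_map = sim$truth$tiers)
  avg <- average_across_folds(sim$table, n_folds = 3L, constraints = cons,
                              replicates = 15L, seed = 11)
  expect_length(avg$folds, 3L)
  # consensus edges appear in the union of per-fold probability tables
  union_keys <- unique(unlist(lapply(avg$folds, function(f) {
    t <- attr(f, "arc_prob_table"); paste(t$parent, t$child)
  })))
  expect_true(all(paste(avg$consensus$edges$parent,
                        avg$consensus$edges$child) %in% union_keys))
  # fold split is stratified: a variety's plants never straddle folds
  split_tab <- table(sim$table$variety, avg$fold_assignment)
  expect_true(all(rowSums(split_tab > 0) == 1L))
})

test_that("near-noiseless data gives identical per-fold structures", {
  sp <- scm_spec(c("x", "y", "z"), c(x = 0L, y = 1L, z = 2L),
                 data.frame(parent = c("x", "y"), child = c("y", "z"),
                            fun = "linear", coef = c(2, 3)),
                 yield_node = "z", noise_sd = 1e-4, variety_effect_sd = 1,
                 n_varieties = 60L, reps_per_variety = 3L)
  sim <- generate_scm_table(sp, seed = 12)
  cons <- edge_constraints(tier_map = sp$tiers)
  avg <- average_across_folds(sim$table, n_folds = 3L, constraints = cons,
                              replicates = 10L, seed = 13)
  skels <- lapply(avg$folds, function(f)
    sort(paste(f$edges$parent, f$edges$child)))
  expect_identical(skels[[1L]], skels[[2L]])
  expect_identical(skels[[2L]], skels[[3L]])
})

test_that("DAGs round-trip through JSON and render as DOT", {
  dag <- trait_dag(c("a", "b"), data.frame(parent = "a", child = "b"),
                   arc_prob = 0.8)
  path <- withr::local_tempfile(fileext = ".json")
  write_dag_json(dag, path)
  back <- read_dag_json(path)
  expect_equal(back$edges, dag$edges)
  expect_equal(back$arc_prob, dag$arc_prob)
  dot <- dag_to_dot(dag)
  expect_match(dot, "\"a\" -> \"b\"")
  expect_match(dot, "0.80")
})
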