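#' Structural causal model specification for synthetic trait panels
#'
#' Defines the generative ground truth used by [generate_scm_table()]: a tiered
#' trait hierarchy (level 0 = architectural traits, the last level holds seed
#' yield), directed trait-trait edges with linear or saturating effect
#' functions, variety-level random intercepts shared across replicates, and
#' independent per-trait measurement noise. A designated yield node must be a
#' sink of the graph.
#'
#' @param nodes character vector of trait identifiers.
#' @param tiers named integer vector: hierarchy level of each node (0-based;
#'   edges may only run from a lower-or-equal tier to a node outside tier 0).
#' @param edges data.frame with columns `parent`, `child`, `fun` (one of
#'   `"linear"`, `"saturating"`) and `coef` (real). `linear` contributes
#'   `coef * parent`; `saturating` contributes `coef * tanh(z(parent))` where
#'   `z()` standardises the realised parent column, giving the bounded,
#'   monotone saturation shape seen in observed trait-yield responses.
#' @param yield_node name of the designated yield node (a sink).
#' @param noise_sd per-node Gaussian noise sd; scalar or named vector.
#' @param variety_effect_sd per-node sd of variety random intercepts; scalar
#'   or named vector (non-negative).
#' @param n_varieties,reps_per_variety panel dimensions. Defaults emulate a
#'   glasshouse diversity panel of 94 varieties with 5 replicates each.
#' @param missing_rate MCAR cell-masking probability in `[0, 1)` applied by
#'   [inject_missingness()] when requested through the pipeline.
#' @param group_coef_delta relative perturbation of edge coefficients in the
#'   second variety group (varieties are split into two equal groups so that
#'   fit-separate-models-per-group analyses have a real contrast). 0 disables
#'   the group contrast.
#' @return An object of class `scm_spec`.
#' @seealso [example_trait_network()] for a ready-made 8-node hierarchy.
#' @export
scm_spec <- function(nodes, tiers, edges, yield_node,
                     noise_sd = 0.5, variety_effect_sd = 0.5,
                     n_varieties = 94L, reps_per_variety = 5L,
                     missing_rate = 0, group_coef_delta = 0) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  if (!all(nodes %in% names(tiers))) stop("every node needs a tier")
  tiers <- vapply(nodes, function(nd) as.integer(tiers[[nd]]), integer(1L))
  if (any(tiers < 0)) stop("tiers must be non-negative")
  edges <- normalize_scm_edges(edges)
  if (nrow(edges)) {
    bad <- setdiff(c(edges$parent, edges$child), nodes)
    if (length(bad)) stop("edge endpoints not in node set: ", paste(bad, collapse = ", "))
    if (any(tiers[edges$child] < tiers[edges$parent])) {
      stop("edges must run from a lower-or-equal tier to a higher-or-equal tier")
    }
    if (any(tiers[edges$child] == 0L)) stop("no edges may point into tier 0")
  }
  if (!yield_node %in% nodes) stop("yield_node must be one of the nodes")
  if (yield_node %in% edges$parent) stop("the yield node must be a sink (no children)")
  n_varieties <- as.integer(n_varieties)
  reps_per_variety <- as.integer(reps_per_variety)
  if (n_varieties < 1L || reps_per_variety < 1L) stop("panel dimensions must be positive")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  noise_sd <- expand_per_node(noise_sd, nodes, "noise_sd")
  if (any(noise_sd <= 0)) stop("noise_sd must be positive")
  variety_effect_sd <- expand_per_node(variety_effect_sd, nodes, "variety_effect_sd")
  if (any(variety_effect_sd < 0)) stop("variety_effect_sd must be non-negative")
  spec <- structure(list(nodes = nodes, tiers = tiers, edges = edges,
                         yield_node = yield_node, noise_sd = noise_sd,
                         variety_effect_sd = variety_effect_sd,
                         n_varieties = n_varieties,
                         reps_per_variety = reps_per_variety,
                         missing_rate = missing_rate,
                         group_coef_delta = group_coef_delta),
                    class = "scm_spec")
  # acyclicity via the DAG constructor
  trait_dag(nodes, edges[, c("parent", "child")])
  spec
}

normalize_scm_edges <- function(edges) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    return(data.frame(parent = character(), child = character(),
                      fun = character(), coef = numeric(), stringsAsFactors = FALSE))
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("parent", "child", "fun", "coef")
  if (!all(need %in% names(edges))) {
    stop("edges need columns: ", paste(need, collapse = ", "))
  }
  if (!all(edges$fun %in% c("linear", "saturating"))) {
    stop("effect function must be 'linear' or 'saturating'")
  }
  data.frame(parent = as.character(edges$parent), child = as.character(edges$child),
             fun = as.character(edges$fun), coef = as.numeric(edges$coef),
             stringsAsFactors = FALSE)
}

expand_per_node <- function(x, nodes, what) {
  if (length(x) == 1L && is.null(names(x))) {
    return(structure(rep(as.numeric(x), length(nodes)), names = nodes))
  }
  if (!all(nodes %in% names(x))) stop(what, " must name every node")
  structure(as.numeric(x[nodes]), names = nodes)
}

#' @export
print.scm_spec <- function(x, ...) {
  cat("scm_spec:", length(x$nodes), "traits,", nrow(x$edges), "edges;",
      x$n_varieties, "varieties x", x$reps_per_variety, "reps; yield node:",
      x$yield_node, "\n")
  invisible(x)
}

#' Ground-truth DAG of an SCM specification
#' @param spec an [scm_spec()].
#' @return A [trait_dag()] over the spec's nodes and edges.
#' @export
scm_true_dag <- function(spec) {
  stopifnot(inherits(spec, "scm_spec"))
  trait_dag(spec$nodes, spec$edges[, c("parent", "child")])
}

#' An 8-node tiered trait network emulating an oilseed-rape yield hierarchy
#'
#' Architectural traits (secondary inflorescences, height) sit in tier 0,
#' flower production in tier 1, pod traits in tier 2 and seed traits plus
#' seed yield in tier 3. The network encodes the compensation motif (more
#' flowers give more but shorter pods) and the negative seed-number to
#' thousand-grain-weight trade-off, with saturating links into flower and pod
#' counts. Coefficients are strong (|coef| >= 1) relative to noise so that
#' the generating skeleton is recoverable from a few hundred plants.
#'
#' @inheritParams scm_spec
#' @param noise_sd per-node noise sd (scalar).
#' @return An [scm_spec()].
#' @export
example_trait_network <- function(n_varieties = 94L, reps_per_variety = 5L,
                                  noise_sd = 0.5, variety_effect_sd = 0.5,
                                  missing_rate = 0, group_coef_delta = 0) {
  nodes <- c("NumberSecondInfl", "PlantHeight", "NumberFlowers", "NumberPods",
             "PodLength", "SeedNumber", "TGW", "SeedYield")
  tiers <- c(NumberSecondInfl = 0L, PlantHeight = 0L, NumberFlowers = 1L,
             NumberPods = 2L, PodLength = 2L, SeedNumber = 3L, TGW = 3L,
             SeedYield = 3L)
  edges <- data.frame(
    parent = c("NumberSecondInfl", "PlantHeight", "NumberFlowers", "NumberFlowers",
               "NumberPods", "PodLength", "SeedNumber", "SeedNumber", "TGW"),
    child  = c("NumberFlowers", "NumberFlowers", "NumberPods", "PodLength",
               "SeedNumber", "SeedNumber", "TGW", "SeedYield", "SeedYield"),
    fun    = c("saturating", "linear", "saturating", "linear",
               "linear", "linear", "linear", "linear", "linear"),
    # TGW weighs in at 0.6 so seed number keeps a positive net yield effect
    # (1.2 direct - 1.0 x 0.6 via the trade-off) as observed in the field
    coef   = c(1.5, 1.0, 1.5, -1.0, 1.2, 1.0, -1.0, 1.2, 0.6),
    stringsAsFactors = FALSE)
  scm_spec(nodes, tiers, edges, yield_node = "SeedYield", noise_sd = noise_sd,
           variety_effect_sd = variety_effect_sd, n_varieties = n_varieties,
           reps_per_variety = reps_per_variety, missing_rate = missing_rate,
           group_coef_delta = group_coef_delta)
}

#' Generate a synthetic trait panel from a structural causal model
#'
#' Traits are generated in topological order of the ground-truth DAG. Each
#' trait value is the sum of its parent-edge contributions, a variety-level
#' random intercept (drawn once per variety and shared across replicates, so
#' that variety means carry a genetic signal), and independent Gaussian
#' noise; root traits are intercept plus noise. Varieties are split into two
#' equal groups; when `group_coef_delta != 0` edge coefficients in the second
#' group are scaled by `1 + group_coef_delta`.
#'
#' @param spec an [scm_spec()].
#' @param seed integer RNG seed; output is bitwise-reproducible given the seed.
#' @return A `sim_trait_data` list: `table` (a [trait_table()]), `truth` (the
#'   spec) and `variety_effects` (variety x trait matrix of drawn intercepts).
#' @examples
#' sim <- generate_scm_table(example_trait_network(n_varieties = 10), seed = 1)
#' sim$table
#' @export
generate_scm_table <- function(spec, seed) {
  stopifnot(inherits(spec, "scm_spec"))
  set.seed(as.integer(seed))
  nv <- spec$n_varieties; nr <- spec$reps_per_variety
  n <- nv * nr
  varieties <- sprintf("var_%03d", seq_len(nv))
  variety <- rep(varieties, each = nr)
  group_of_variety <- structure(rep(c("A", "B"), length.out = nv), names = varieties)
  group <- group_of_variety[variety]
  ve <- matrix(0, nv, length(spec$nodes), dimnames = list(varieties, spec$nodes))
  dag <- scm_true_dag(spec)
  ord <- canonical_topological_order(dag)
  vals <- matrix(NA_real_, n, length(spec$nodes),
                 dimnames = list(NULL, spec$nodes))
  coef_mult <- ifelse(group == "B", 1 + spec$group_coef_delta, 1)
  for (nd in ord) {
    # draws happen per node in canonical order, so the generated table does
    # not depend on the order nodes were declared in
    ve[, nd] <- spec$variety_effect_sd[nd] * stats::rnorm(nv)
    contrib <- ve[variety, nd] + stats::rnorm(n, 0, spec$noise_sd[nd])
    eix <- which(spec$edges$child == nd)
    for (i in eix) {
      p <- vals[, spec$edges$parent[i]]
      co <- spec$edges$coef[i] * coef_mult
      contrib <- contrib + switch(spec$edges$fun[i],
        linear = co * p,
        saturating = co * tanh((p - mean(p)) / stats::sd(p)))
    }
    vals[, nd] <- contrib
  }
  tab <- trait_table(as.data.frame(vals), variety = variety, group = group)
  structure(list(table = tab, truth = spec, variety_effects = ve),
            class = "sim_trait_data")
}

#' @export
print.sim_trait_data <- function(x, ...) {
  cat("sim_trait_data:\n  ")
  print(x$table)
  invisible(x)
}

#' Mask trait cells completely at random
#'
#' Each non-label cell is masked independently with probability `rate`
#' (missing completely at random). The mask is resampled (up to 100 attempts)
#' if any trait would lose all its observations or no fully complete plant
#' would remain, so downstream imputation always has donors.
#'
#' @param data a `sim_trait_data` (from [generate_scm_table()]) or a
#'   [trait_table()].
#' @param rate masking probability in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return Same class as `data`, with masked cells set to `NA`. The logical
#'   mask is attached as attribute `"missing_mask"` on the trait table.
#' @export
inject_missingness <- function(data, rate, seed) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  tab <- if (inherits(data, "sim_trait_data")) data$table else data
  stopifnot(inherits(tab, "trait_table"))
  vals <- as.matrix(tab$values)
  set.seed(as.integer(seed))
  if (rate == 0) {
    mask <- matrix(FALSE, nrow(vals), ncol(vals))
  } else {
    for (attempt in seq_len(100L)) {
      mask <- matrix(stats::runif(length(vals)) < rate, nrow(vals), ncol(vals))
      ok <- all(colSums(!mask) >= 1L) && any(rowSums(mask) == 0L)
      if (ok) break
    }
    if (!ok) stop("could not draw a mask keeping a complete row; lower the rate")
  }
  vals[mask] <- NA_real_
  out <- trait_table_replace(tab, vals)
  attr(out$values, "missing_mask") <- mask
  if (inherits(data, "sim_trait_data")) {
    data$table <- out
    data
  } else out
}

#' Serialise an SCM specification to JSON
#'
#' @param spec an [scm_spec()].
#' @param path file path.
#' @return `read_scm_spec_json` returns an `scm_spec`; the writer returns
#'   `path` invisibly.
#' @export
write_scm_spec_json <- function(spec, path) {
  obj <- list(nodes = spec$nodes, tiers = as.list(spec$tiers),
              edges = spec$edges, yield_node = spec$yield_node,
              noise_sd = as.list(spec$noise_sd),
              variety_effect_sd = as.list(spec$variety_effect_sd),
              n_varieties = spec$n_varieties,
              reps_per_variety = spec$reps_per_variety,
              missing_rate = spec$missing_rate,
              group_coef_delta = spec$group_coef_delta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scm_spec_json
#' @export
read_scm_spec_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scm_spec_from_list(obj)
}

# build an scm_spec from a plain list (JSON/YAML configs)
scm_spec_from_list <- function(obj) {
  scm_spec(nodes = obj$nodes, tiers = unlist(obj$tiers),
           edges = if (length(obj$edges)) as.data.frame(obj$edges) else NULL,
           yield_node = obj$yield_node,
           noise_sd = unlist(obj$noise_sd),
           variety_effect_sd = unlist(obj$variety_effect_sd),
           n_varieties = obj$n_varieties,
           reps_per_variety = obj$reps_per_variety,
           missing_rate = if (is.null(obj$missing_rate)) 0 else obj$missing_rate,
           group_coef_delta = if (is.null(obj$group_coef_delta)) 0 else obj$group_coef_delta)
}
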