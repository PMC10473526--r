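#' Hierarchy constraints for trait-network structure learning
#'
#' Encodes prior biological knowledge about permitted trait-trait
#' relationships: a whitelist of known links that must appear in every learnt
#' model, a blacklist of forbidden links, and an optional tier map (trait ->
#' hierarchy level) that automatically forbids edges running from a higher to
#' a strictly lower tier, and any edge into tier 0.
#'
#' @param whitelist,blacklist two-column (`parent`, `child`) data.frames,
#'   matrices, or NULL.
#' @param tier_map optional named integer vector of hierarchy levels.
#' @return An object of class `edge_constraints`.
#' @export
edge_constraints <- function(whitelist = NULL, blacklist = NULL, tier_map = NULL) {
  wl <- normalize_edges(whitelist)
  bl <- normalize_edges(blacklist)
  key <- function(e) paste(e$parent, e$child, sep = "\r")
  if (length(intersect(key(wl), key(bl)))) {
    stop("whitelist and blacklist overlap")
  }
  if (nrow(wl)) {
    nodes <- unique(c(wl$parent, wl$child))
    # validates acyclicity of the whitelist alone
    trait_dag(nodes, wl)
  }
  if (!is.null(tier_map)) {
    tier_map <- structure(as.integer(tier_map), names = names(tier_map))
    if (is.null(names(tier_map))) stop("tier_map must be named")
  }
  structure(list(whitelist = wl, blacklist = bl, tier_map = tier_map),
            class = "edge_constraints")
}

#' @export
print.edge_constraints <- function(x, ...) {
  cat("edge_constraints:", nrow(x$whitelist), "whitelisted,",
      nrow(x$blacklist), "blacklisted edges",
      if (!is.null(x$tier_map)) paste0("; ", length(x$tier_map), " tiered nodes"),
      "\n")
  invisible(x)
}

#' Read/write constraint edge lists as CSV
#'
#' Edge-list files have columns `parent`, `child` — one file for mandatory
#' links, one for forbidden links.
#'
#' @param constraints an [edge_constraints()].
#' @param whitelist_path,blacklist_path file paths (NULL to skip).
#' @param tier_map optional named tier vector to attach on read.
#' @return `read_edge_constraints` returns an `edge_constraints`.
#' @export
write_edge_constraints <- function(constraints, whitelist_path = NULL,
                                   blacklist_path = NULL) {
  if (!is.null(whitelist_path)) {
    utils::write.csv(constraints$whitelist, whitelist_path, row.names = FALSE)
  }
  if (!is.null(blacklist_path)) {
    utils::write.csv(constraints$blacklist, blacklist_path, row.names = FALSE)
  }
  invisible(constraints)
}

#' @rdname write_edge_constraints
#' @export
read_edge_constraints <- function(whitelist_path = NULL, blacklist_path = NULL,
                                  tier_map = NULL) {
  rd <- function(p) if (is.null(p)) NULL else utils::read.csv(p, stringsAsFactors = FALSE)
  edge_constraints(rd(whitelist_path), rd(blacklist_path), tier_map)
}

# ---- internal scoring machinery --------------------------------------------

# Precompute sufficient statistics for Gaussian local scores. Scores are
# memoised per (node, parent-set); for up to 16 nodes the parent set is
# bit-encoded into a dense numeric cache, otherwise a hashed environment.
make_score_context <- function(X) {
  n <- nrow(X)
  m <- ncol(X)
  Xc <- sweep(X, 2L, colMeans(X))
  ctx <- new.env(parent = emptyenv())
  ctx$C <- crossprod(Xc)
  ctx$n <- n
  ctx$m <- m
  if (m <= 16L) {
    ctx$bit <- 2^(seq_len(m) - 1L)
    ctx$dense <- rep(NA_real_, m * 2^m)
  } else {
    ctx$cache <- new.env(parent = emptyenv())
  }
  ctx
}

# BIC local score of node j given integer parent set S (may be empty).
# ll - (k/2) log n with k = |S| + 2 (coefficients + intercept + variance).
local_score <- function(ctx, j, S) {
  dense <- !is.null(ctx$dense)
  if (dense) {
    key <- (j - 1L) * length(ctx$dense) / ctx$m + sum(ctx$bit[S]) + 1
    hit <- ctx$dense[key]
    if (!is.na(hit)) return(hit)
  } else {
    key <- paste(j, paste(S, collapse = ","), sep = "|")
    hit <- ctx$cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  C <- ctx$C; n <- ctx$n
  rss <- if (length(S)) {
    b <- tryCatch(solve(C[S, S, drop = FALSE], C[S, j]), error = function(e) NULL)
    if (is.null(b)) NA_real_ else C[j, j] - sum(C[j, S] * b)
  } else C[j, j]
  val <- if (is.na(rss) || rss <= 1e-12 * max(C[j, j], 1)) {
    -Inf  # singular or perfectly collinear family
  } else {
    sigma2 <- rss / n
    -n / 2 * (log(2 * pi * sigma2) + 1) - (length(S) + 2) / 2 * log(n)
  }
  if (dense) ctx$dense[key] <- val else ctx$cache[[key]] <- val
  val
}

graph_score <- function(ctx, A) {
  s <- 0
  for (j in seq_len(ncol(A))) s <- s + local_score(ctx, j, which(A[, j]))
  s
}

#' BIC network score of a trait DAG
#'
#' The score of a Gaussian Bayesian network: the sum over nodes of the
#' maximised Gaussian log-likelihood of each node given its parents (ordinary
#' least squares) minus a `(k/2) log(n)` complexity penalty per node, where
#' `k` counts that node's free parameters (parent coefficients, intercept and
#' residual variance). Higher is better; the score decomposes additively over
#' nodes, which is what makes local search moves cheap to evaluate.
#'
#' @param dag a [trait_dag()] whose nodes are trait columns of `table`.
#' @param table a complete (imputed) [trait_table()].
#' @return The scalar network score.
#' @export
bic_score <- function(dag, table) {
  stopifnot(inherits(dag, "trait_dag"), inherits(table, "trait_table"))
  X <- trait_values(table, dag$nodes)
  if (anyNA(X)) stop("table must be complete (impute first)")
  for (nd in dag$nodes) {
    pa <- dag_parents(dag, nd)
    if (anyDuplicated(pa)) stop("duplicate parent columns for node '", nd, "'")
  }
  ctx <- make_score_context(X)
  A <- dag_adjacency(dag)
  total <- 0
  for (j in seq_along(dag$nodes)) {
    s <- local_score(ctx, j, which(A[, j]))
    if (!is.finite(s)) stop("singular local model for node '", dag$nodes[j], "'")
    total <- total + s
  }
  total
}

# Resolve constraints into whitelist/forbidden adjacency matrices over `nodes`.
resolve_constraints <- function(constraints, nodes) {
  m <- length(nodes)
  W <- matrix(FALSE, m, m, dimnames = list(nodes, nodes))
  B <- matrix(FALSE, m, m, dimnames = list(nodes, nodes))
  wl <- constraints$whitelist; bl <- constraints$blacklist
  if (nrow(wl)) {
    bad <- setdiff(c(wl$parent, wl$child), nodes)
    if (length(bad)) stop("whitelist refers to unknown traits: ", paste(bad, collapse = ", "))
    W[cbind(wl$parent, wl$child)] <- TRUE
  }
  if (nrow(bl)) {
    bl <- bl[bl$parent %in% nodes & bl$child %in% nodes, , drop = FALSE]
    if (nrow(bl)) B[cbind(bl$parent, bl$child)] <- TRUE
  }
  tm <- constraints$tier_map
  if (!is.null(tm)) {
    known <- intersect(nodes, names(tm))
    for (a in known) for (b in known) {
      # forbid edges running from a higher to a strictly lower tier
      if (a != b && tm[[b]] < tm[[a]]) B[a, b] <- TRUE
    }
  }
  if (any(W & B)) stop("constraints inconsistent: a whitelisted edge is forbidden")
  diag(B) <- TRUE
  list(W = W, B = B)
}

# boolean transitive closure by repeated squaring
transitive_closure <- function(A) {
  R <- A
  repeat {
    R2 <- (R %*% R + R) > 0
    if (identical(R2, R)) return(R)
    R <- R2
  }
}

# TRUE if adding edge i->j to A would create a directed cycle (j reaches i).
would_cycle <- function(A, i, j) {
  if (i == j) return(TRUE)
  stack <- j
  seen <- logical(nrow(A))
  seen[j] <- TRUE
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    ch <- which(A[v, ])
    if (any(ch == i)) return(TRUE)
    new <- ch[!seen[ch]]
    seen[new] <- TRUE
    stack <- c(stack, new)
  }
  FALSE
}

#' Learn a trait DAG by Tabu search over BIC-scored Gaussian networks
#'
#' Greedy hill climbing over single-edge additions, deletions and reversals
#' that respect the constraints and acyclicity, with a tabu list of recently
#' reversed moves: at every step the best non-tabu neighbour is accepted even
#' when it worsens the score (tabu moves are allowed only when they beat the
#' best score seen — the usual aspiration rule), which lets the search climb
#' out of local optima. The best-scoring DAG encountered is returned; the
#' search starts from the whitelist-only graph, so the result never scores
#' below it. Score ties between the two orientations of an edge are broken
#' towards the hierarchy direction when a tier map is available, then
#' lexicographically.
#'
#' @param table a complete [trait_table()].
#' @param constraints an [edge_constraints()].
#' @param tabu_length number of most recent moves kept tabu (default 10).
#' @param max_stall stop after this many accepted moves without improving the
#'   best score (default 15).
#' @param seed integer; kept for interface symmetry (the search itself is
#'   deterministic given the data).
#' @param nodes optional subset of trait columns to learn over.
#' @return A [trait_dag()].
#' @export
tabu_search <- function(table, constraints = edge_constraints(),
                        tabu_length = 10L, max_stall = 15L, seed = NULL,
                        nodes = NULL) {
  stopifnot(inherits(table, "trait_table"))
  if (is.null(nodes)) nodes <- table$trait_names
  X <- trait_values(table, nodes)
  if (anyNA(X)) stop("table must be complete (impute first)")
  ctx <- make_score_context(X)
  res <- resolve_constraints(constraints, nodes)
  A0 <- res$W
  if (!adjacency_is_acyclic(A0)) stop("whitelist is cyclic on these traits")
  A <- tabu_search_adjacency(ctx, A0, res$W, res$B, constraints$tier_map,
                             nodes, tabu_length, max_stall)
  trait_dag(nodes, adjacency_to_edges(A))
}

# core search on adjacency matrices; returns the best adjacency found.
# Moves are integer-encoded (type * m^2 + (i-1) * m + j, type 0/1/2 for
# add/delete/reverse) so the tabu test is numeric.
tabu_search_adjacency <- function(ctx, A, W, B, tier_map, nodes,
                                  tabu_length, max_stall) {
  m <- length(nodes)
  m2 <- m * m
  cur_local <- vapply(seq_len(m), function(j) local_score(ctx, j, which(A[, j])),
                      numeric(1L))
  cur <- sum(cur_local)
  best <- cur; bestA <- A
  tabu <- numeric(0)
  stall <- 0L
  max_iter <- 200L + 40L * m
  TierOK <- matrix(TRUE, m, m)
  if (!is.null(tier_map)) {
    known <- match(intersect(nodes, names(tier_map)), nodes)
    tv <- tier_map[nodes[known]]
    TierOK[known, known] <- outer(tv, tv, `<=`)
  }
  lexrank <- rank(nodes)
  cap <- 3L * m2
  c_type <- integer(cap); c_i <- integer(cap); c_j <- integer(cap)
  c_delta <- numeric(cap)
  for (iter in seq_len(max_iter)) {
    Reach <- transitive_closure(A)  # Reach[u, v]: v reachable from u
    nc <- 0L
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i == j) next
      if (A[i, j]) {
        pa_j <- which(A[, j])
        if (!W[i, j]) {  # delete i->j
          d <- local_score(ctx, j, pa_j[pa_j != i]) - cur_local[j]
          nc <- nc + 1L
          c_type[nc] <- 1L; c_i[nc] <- i; c_j[nc] <- j; c_delta[nc] <- d
        }
        if (!W[i, j] && !B[j, i] && !A[j, i]) {  # reverse i->j to j->i
          # safe iff i is unreachable from j once the edge itself is removed
          A[i, j] <- FALSE
          ok <- !transitive_closure(A)[j, i]
          A[i, j] <- TRUE
          if (ok) {
            d <- (local_score(ctx, j, pa_j[pa_j != i]) - cur_local[j]) +
                 (local_score(ctx, i, c(which(A[, i]), j)) - cur_local[i])
            nc <- nc + 1L
            c_type[nc] <- 2L; c_i[nc] <- i; c_j[nc] <- j; c_delta[nc] <- d
          }
        }
      } else if (!B[i, j] && !A[j, i] && !Reach[j, i]) {  # add i->j, no cycle
        d <- local_score(ctx, j, c(which(A[, j]), i)) - cur_local[j]
        nc <- nc + 1L
        c_type[nc] <- 0L; c_i[nc] <- i; c_j[nc] <- j; c_delta[nc] <- d
      }
    }
    if (nc == 0L) break
    sel <- seq_len(nc)
    ord <- sel[order(-c_delta[sel], !TierOK[cbind(c_i[sel], c_j[sel])],
                     lexrank[c_i[sel]], lexrank[c_j[sel]])]
    keys <- c_type[ord] * m2 + (c_i[ord] - 1L) * m + c_j[ord]
    is_tabu <- keys %in% tabu
    pick <- 0L
    for (k in seq_along(ord)) {
      if (!is.finite(c_delta[ord[k]])) next
      if (is_tabu[k] && cur + c_delta[ord[k]] <= best + 1e-12) next  # aspiration
      pick <- k
      break
    }
    if (pick == 0L) break
    idx <- ord[pick]
    type <- c_type[idx]; i <- c_i[idx]; j <- c_j[idx]
    if (type == 0L) {
      A[i, j] <- TRUE
    } else if (type == 1L) {
      A[i, j] <- FALSE
    } else {
      A[i, j] <- FALSE; A[j, i] <- TRUE
    }
    cur_local[j] <- local_score(ctx, j, which(A[, j]))
    if (type == 2L) cur_local[i] <- local_score(ctx, i, which(A[, i]))
    cur <- sum(cur_local)
    # forbid this move and its inverse for tabu_length steps
    inverse_key <- switch(type + 1L,
                          1 * m2 + (i - 1L) * m + j,   # undo add = delete
                          0 * m2 + (i - 1L) * m + j,   # undo delete = add
                          2 * m2 + (j - 1L) * m + i)   # undo reverse = reverse back
    tabu <- c(tabu, keys[pick], inverse_key)
    if (length(tabu) > 2L * tabu_length) {
      tabu <- tabu[(length(tabu) - 2L * tabu_length + 1L):length(tabu)]
    }
    if (cur > best + 1e-12) {
      best <- cur; bestA <- A; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= max_stall) break
    }
  }
  bestA
}

#' Bootstrap arc probabilities for trait-trait links
#'
#' Resamples plants with replacement, reruns the Tabu/BIC search on each
#' replicate, and estimates the probability of every directed link as the
#' fraction of replicate models containing it. The returned DAG keeps the
#' links whose probability reaches `threshold`, added in decreasing
#' probability and skipping any that would close a cycle; whitelisted links
#' are present in every replicate by construction, so their probability is
#' exactly 1.
#'
#' @inheritParams tabu_search
#' @param replicates number of bootstrap resamples (the reference analysis
#'   scale is 500; smaller values trade precision for speed).
#' @param seed integer RNG seed for the resampling.
#' @param threshold inclusion threshold on arc probability (default 0.5).
#' @return A [trait_dag()] with `arc_prob` filled in; the full table of every
#'   link seen in any replicate is attached as attribute `"arc_prob_table"`
#'   (data.frame `parent`, `child`, `prob`).
#' @export
bootstrap_arc_probabilities <- function(table, constraints = edge_constraints(),
                                        replicates = 500L, seed = 1L,
                                        threshold = 0.5, tabu_length = 10L,
                                        max_stall = 15L, nodes = NULL) {
  stopifnot(inherits(table, "trait_table"))
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1")
  if (is.null(nodes)) nodes <- table$trait_names
  X <- trait_values(table, nodes)
  if (anyNA(X)) stop("table must be complete (impute first)")
  res <- resolve_constraints(constraints, nodes)
  if (!adjacency_is_acyclic(res$W)) stop("whitelist is cyclic on these traits")
  m <- length(nodes)
  counts <- matrix(0L, m, m, dimnames = list(nodes, nodes))
  set.seed(as.integer(seed))
  for (r in seq_len(replicates)) {
    idx <- sample.int(nrow(X), nrow(X), replace = TRUE)
    ctx <- make_score_context(X[idx, , drop = FALSE])
    A <- tabu_search_adjacency(ctx, res$W, res$W, res$B, constraints$tier_map,
                               nodes, tabu_length, max_stall)
    counts <- counts + A
  }
  prob <- counts / replicates
  tab <- adjacency_to_edges(prob > 0)
  tab$prob <- if (nrow(tab)) prob[cbind(tab$parent, tab$child)] else numeric(0)
  dag <- threshold_probability_dag(prob, res, nodes, threshold)
  attr(dag, "arc_prob_table") <- tab[order(-tab$prob, tab$parent, tab$child), ]
  dag
}

# build an acyclic, constraint-consistent DAG from a probability matrix
threshold_probability_dag <- function(prob, res, nodes, threshold) {
  m <- length(nodes)
  A <- res$W  # whitelist always present
  cand <- which(prob >= threshold & !res$B & !A, arr.ind = TRUE)
  if (nrow(cand)) {
    ord <- order(-prob[cand], nodes[cand[, 1L]], nodes[cand[, 2L]])
    for (k in ord) {
      i <- cand[k, 1L]; j <- cand[k, 2L]
      if (!A[j, i] && !would_cycle(A, i, j)) A[i, j] <- TRUE
    }
  }
  edges <- adjacency_to_edges(A)
  ap <- if (nrow(edges)) prob[cbind(edges$parent, edges$child)] else NULL
  trait_dag(nodes, edges, arc_prob = ap)
}

#' Cross-fold model averaging of bootstrap trait networks
#'
#' Plants are partitioned into folds at random, stratified by variety so that
#' replicates of one variety never straddle folds; the bootstrap modelling
#' process is run independently on each fold, and a consensus network keeps
#' the links identified consistently across folds. Two consensus rules are
#' provided: `"majority"` (a link enters if its bootstrap probability reaches
#' `strength_threshold` in a majority of folds) and `"pooled"` (its mean
#' probability across folds reaches `strength_threshold`).
#'
#' @inheritParams bootstrap_arc_probabilities
#' @param n_folds number of folds (default 5).
#' @param strength_threshold per-fold arc-probability cut (default 0.5).
#' @param consensus `"majority"` or `"pooled"`.
#' @return A list with `folds` (per-fold [trait_dag()]s carrying their
#'   `arc_prob_table` attribute), `consensus` (a [trait_dag()] whose
#'   `arc_prob` is the mean across-fold probability), and `fold_assignment`.
#' @export
average_across_folds <- function(table, n_folds = 5L,
                                 constraints = edge_constraints(),
                                 replicates = 500L, seed = 1L,
                                 strength_threshold = 0.5,
                                 consensus = c("majority", "pooled"),
                                 tabu_length = 10L, max_stall = 15L,
                                 nodes = NULL) {
  stopifnot(inherits(table, "trait_table"))
  consensus <- match.arg(consensus)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (is.null(nodes)) nodes <- table$trait_names
  set.seed(as.integer(seed))
  varieties <- unique(table$variety)
  fold_of_variety <- structure(
    sample(rep_len(seq_len(n_folds), length(varieties))), names = varieties)
  fold <- fold_of_variety[table$variety]
  if (any(tabulate(fold, n_folds) < 10L)) {
    stop("each fold must retain at least 10 rows")
  }
  res <- resolve_constraints(constraints, nodes)
  m <- length(nodes)
  probs <- array(0, c(m, m, n_folds), dimnames = list(nodes, nodes, NULL))
  folds <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    sub <- trait_table_subset(table, fold == f)
    dag <- bootstrap_arc_probabilities(sub, constraints, replicates,
                                       seed = as.integer(seed) + f,
                                       threshold = strength_threshold,
                                       tabu_length = tabu_length,
                                       max_stall = max_stall, nodes = nodes)
    folds[[f]] <- dag
    tabf <- attr(dag, "arc_prob_table")
    if (nrow(tabf)) {
      probs[cbind(match(tabf$parent, nodes), match(tabf$child, nodes), f)] <- tabf$prob
    }
  }
  mean_prob <- apply(probs, c(1L, 2L), mean)
  if (consensus == "majority") {
    votes <- apply(probs >= strength_threshold, c(1L, 2L), sum)
    keep <- votes >= floor(n_folds / 2) + 1L
  } else {
    keep <- mean_prob >= strength_threshold
  }
  sel <- mean_prob * keep
  thr <- if (any(sel > 0)) min(sel[sel > 0]) else 1
  cons <- threshold_probability_dag(sel, res, nodes, threshold = thr)
  # arc_prob of consensus edges = mean across-fold probability
  if (nrow(cons$edges)) {
    cons$arc_prob <- mean_prob[cbind(cons$edges$parent, cons$edges$child)]
  }
  list(folds = folds, consensus = cons, fold_assignment = fold)
}

#' Skeleton precision/recall/F1 against a reference DAG
#'
#' Compares undirected edge sets (the skeleton), the usual structure-recovery
#' metric when orientation within a score-equivalence class is not
#' identifiable.
#'
#' @param dag,reference [trait_dag()]s over comparable node sets.
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
skeleton_f1 <- function(dag, reference) {
  und <- function(g) {
    if (!nrow(g$edges)) return(character(0))
    unique(paste(pmin(g$edges$parent, g$edges$child),
                 pmax(g$edges$parent, g$edges$child), sep = "\r"))
  }
  a <- und(dag); b <- und(reference)
  tp <- length(intersect(a, b))
  prec <- if (length(a)) tp / length(a) else (length(b) == 0) + 0
  rec <- if (length(b)) tp / length(b) else 1
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, f1 = f1)
}
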