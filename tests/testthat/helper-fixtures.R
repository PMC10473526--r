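# shared fixtures, all generated in code

# a linear chain x -> y -> z with y = 2x, z = 3y (total effect 6)
chain_table <- function(n = 150, noise = 0.05, seed = 1) {
  set.seed(seed)
  x <- stats::runif(n, -2, 2)
  y <- 2 * x + stats::rnorm(n, 0, noise)
  z <- 3 * y + stats::rnorm(n, 0, noise)
  trait_table(data.frame(x = x, y = y, z = z),
              variety = rep(sprintf("v%02d", seq_len(ceiling(n / 5))),
                            length.out = n))
}

chain_dag <- function() {
  trait_dag(c("x", "y", "z"),
            data.frame(parent = c("x", "y"), child = c("y", "z")))
}

# compensation motif: x raises u and lowers v equally; yield = u + v
compensation_table <- function(n = 150, noise = 0.05, seed = 1) {
  set.seed(seed)
  x <- stats::runif(n, -2, 2)
  u <- x + stats::rnorm(n, 0, noise)
  v <- -x + stats::rnorm(n, 0, noise)
  yield <- u + v + stats::rnorm(n, 0, noise)
  trait_table(data.frame(x = x, u = u, v = v, yield = yield),
              variety = rep(sprintf("v%02d", seq_len(ceiling(n / 5))),
                            length.out = n))
}

compensation_dag <- function() {
  trait_dag(c("x", "u", "v", "yield"),
            data.frame(parent = c("x", "x", "u", "v"),
                       child = c("u", "v", "yield", "yield")))
}

# draw a response from a known ARD GP
gp_sim <- function(n, rho, alpha = 1, sigma = 0.1, d = length(rho), seed = 1) {
  set.seed(seed)
  X <- matrix(stats::runif(n * d, -2, 2), n, d)
  hy <- ard_hyper(alpha, rho, sigma)
  K <- ard_kernel(X, X, hy, add_noise = TRUE)
  y <- drop(t(chol(K + diag(1e-8, n))) %*% stats::rnorm(n))
  list(X = X, y = y, hyper = hy,
       table = trait_table(
         data.frame(y = y, X), variety = rep("v", n)))
}

map_config <- function(seed = 1) gp_sampler_config("map", seed = seed)

# random DAG over m nodes with edge probability p (indices upper-triangular)
random_dag <- function(m = 10, p = 0.25, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(m))
  perm <- sample(m)
  edges <- NULL
  for (a in seq_len(m - 1)) for (b in (a + 1):m) {
    if (stats::runif(1) < p) {
      edges <- rbind(edges, data.frame(parent = nodes[perm[a]],
                                       child = nodes[perm[b]]))
    }
  }
  trait_dag(nodes, edges)
}
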