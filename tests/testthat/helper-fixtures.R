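# Shared fixtures, generated in code.

# small random -1/1 inbred-like genotype matrix
random_inbred_geno <- function(n, m, seed = 1) {
  set.seed(seed)
  g <- matrix(sample(c(-1, 1), n * m, replace = TRUE, prob = c(0.3, 0.7)), n, m)
  dimnames(g) <- list(sprintf("L%02d", seq_len(n)), sprintf("M%03d", seq_len(m)))
  g
}

# tiny observation set for GBLUP tests: p hybrids in q environments
tiny_gblup_data <- function(p = 15, q = 2, m = 60, s2A = 1, s2e = 1, seed = 1) {
  set.seed(seed)
  G <- random_inbred_geno(p, m, seed = seed + 1)
  rownames(G) <- paste0("h", seq_len(p))
  K <- additive_kernel(G)
  env <- rep(paste0("E", seq_len(q)), each = p)
  hyb <- rep(rownames(G), q)
  u <- drop(chol(K + diag(1e-6, p)) %*% rnorm(p, 0, sqrt(s2A)))
  y <- 2 + as.numeric(factor(env)) + u[match(hyb, rownames(G))] +
    rnorm(p * q, 0, sqrt(s2e))
  list(y = y, env = env, hybrid = hyb, K = K, G = G, u = u)
}

# direct GLS/BLUP oracle: X fixed incidence, list of n x n covariance kernels
# with variances s2 and residual s2e
blup_oracle <- function(y, X, K_list, s2, s2e) {
  n <- length(y)
  V <- diag(s2e, n)
  for (i in seq_along(K_list)) V <- V + s2[i] * K_list[[i]]
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  u <- lapply(seq_along(K_list), function(i) drop(s2[i] * K_list[[i]] %*% Vi %*% r))
  list(beta = drop(beta), u = u)
}
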