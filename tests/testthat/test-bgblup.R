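# Gibbs-sampled multi-kernel GBLUP: eigen preparation, oracle agreement,
# prediction, determinism

test_that("eigen preparation round-trips kernels and handles rank deficiency", {
  expect_equal(eigen_prepare(diag(4))$s, rep(1, 4))
  K <- additive_kernel(random_inbred_geno(8, 30, seed = 1))
  eg <- eigen_prepare(K)
  expect_equal(eg$U %*% (eg$s * t(eg$U)), K, ignore_attr = TRUE,
               tolerance = 1e-8)
  # duplicated hybrids: zero eigenvalues dropped, sampler still proper
  G2 <- random_inbred_geno(6, 30, seed = 2)[c(1, 1, 2:6), ]
  K2 <- additive_kernel(G2)
  eg2 <- eigen_prepare(K2)
  expect_lt(length(eg2$s), nrow(K2))
  expect_error(eigen_prepare(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
})

test_that("posterior means match closed-form BLUP with fixed variances", {
  d <- tiny_gblup_data(p = 20, q = 2, s2A = 1, s2e = 1, seed = 3)
  fit <- bgblup(d$y, d$env, d$hybrid, d$K, gxe = FALSE,
                niter = 6000, burnin = 1000, thin = 2, seed = 7,
                fixed_varcomp = c(A = 1, e = 1))
  X <- incidence_matrix(d$env)
  Z <- incidence_matrix(d$hybrid, rownames(d$K))
  Kobs <- Z %*% d$K %*% t(Z)
  oracle <- blup_oracle(d$y, X, list(Kobs), s2 = 1, s2e = 1)
  rms <- sqrt(mean((fit$u_mean$A - oracle$u[[1]])^2)) / sd(d$y)
  expect_lt(rms, 0.02)
  expect_equal(unname(fit$beta), oracle$beta, tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("constant response is absorbed by the fixed effects", {
  d <- tiny_gblup_data(p = 12, q = 2, seed = 4)
  y0 <- rep(3, length(d$y))
  fit <- bgblup(y0, d$env, d$hybrid, d$K, gxe = FALSE,
                niter = 1500, burnin = 300, seed = 5)
  expect_equal(unname(fit$beta), c(3, 3), tolerance = 0.05)
  expect_lt(max(abs(fit$u_mean$A)), 0.1)
})

test_that("variance components are recovered from the generative model", {
  # data simulated from the model: s2A = 1, s2D = 0.3, s2AE = 0.5, s2e = 1
  rel <- sapply(1:5, function(s) {
    set.seed(100 + s)
    p <- 80; q <- 3
    G <- random_inbred_geno(p, 150, seed = 200 + s)
    G[sample(length(G), length(G) * 0.1)] <- 0   # some heterozygosity
    rownames(G) <- paste0("h", 1:p)
    KA <- additive_kernel(G); KD <- dominance_kernel(G)
    env <- rep(paste0("E", 1:q), each = p); hyb <- rep(rownames(G), q)
    eA <- eigen(KA, symmetric = TRUE); eD <- eigen(KD, symmetric = TRUE)
    rmv <- function(e, s2) drop(e$vectors %*% (sqrt(pmax(e$values, 0) * s2) *
                                                 rnorm(length(e$values))))
    uA <- rmv(eA, 1)[match(hyb, rownames(G))]
    uD <- rmv(eD, 0.3)[match(hyb, rownames(G))]
    uAE <- as.vector(sapply(1:q, function(i) rmv(eA, 0.5)))
    y <- 5 + uA + uD + uAE + rnorm(p * q, 0, 1)
    fit <- bgblup(y, env, hyb, KA, KD, gxe = TRUE,
                  niter = 2500, burnin = 500, seed = 300 + s)
    fit$varcomp[c("A", "e")] / c(1, 1)
  })
  expect_lt(abs(median(rel["A", ]) - 1), 0.5)
  expect_lt(abs(median(rel["e", ]) - 1), 0.5)
})

test_that("prediction is consistent in-sample and exploits duplicates", {
  d <- tiny_gblup_data(p = 14, q = 2, seed = 6)
  # duplicate the first hybrid's genotype under a new id
  G2 <- rbind(d$G, h_dup = d$G[1, ])
  K2 <- additive_kernel(G2)
  fit <- bgblup(d$y, d$env, d$hybrid, K2, gxe = FALSE,
                niter = 2000, burnin = 400, seed = 8)
  # in-sample: prediction equals fitted value
  nd <- data.frame(env = d$env[1:4], hybrid = d$hybrid[1:4])
  expect_equal(predict(fit, nd), unname(fitted(fit)[1:4]), tolerance = 1e-10)
  # genetically identical untested hybrid gets the same prediction
  p_orig <- predict(fit, data.frame(env = "E1", hybrid = "h1"))
  p_dup <- predict(fit, data.frame(env = "E1", hybrid = "h_dup"))
  expect_equal(p_dup, p_orig, tolerance = 0.02 * sd(d$y))
  expect_error(predict(fit, data.frame(env = "E1", hybrid = "nope")),
               "missing from the kernels")
})

test_that("shrinkage limit: tiny additive variance collapses to env means", {
  d <- tiny_gblup_data(p = 12, q = 2, seed = 9)
  fit <- bgblup(d$y, d$env, d$hybrid, d$K, gxe = FALSE,
                niter = 1500, burnin = 300, seed = 10,
                fixed_varcomp = c(A = 1e-8, e = 1))
  em <- tapply(d$y, d$env, mean)
  expect_equal(unname(fitted(fit)), as.vector(em[d$env]), tolerance = 0.05)
})

test_that("chains are seed-deterministic and split-half stationary", {
  d <- tiny_gblup_data(p = 12, q = 2, seed = 11)
  f1 <- bgblup(d$y, d$env, d$hybrid, d$K, gxe = FALSE,
               niter = 800, burnin = 200, seed = 12)
  f2 <- bgblup(d$y, d$env, d$hybrid, d$K, gxe = FALSE,
               niter = 800, burnin = 200, seed = 12)
  expect_identical(f1$vc_draws, f2$vc_draws)
  expect_identical(f1$u_mean, f2$u_mean)

  f3 <- bgblup(d$y, d$env, d$hybrid, d$K, gxe = FALSE,
               niter = 4000, burnin = 1000, seed = 13)
  ch <- f3$vc_draws[, "A"]
  h1 <- ch[seq_len(length(ch) / 2)]; h2 <- ch[-seq_len(length(ch) / 2)]
  mcse <- sd(ch) / sqrt(length(ch) / 10)   # generous autocorrelation discount
  expect_lt(abs(mean(h1) - mean(h2)), 3 * mcse)
})

test_that("dominance kernel does not degrade a purely additive recovery", {
  d <- tiny_gblup_data(p = 30, q = 2, s2A = 1.5, s2e = 0.5, seed = 14)
  # dominance kernel from a version of the genotypes with some het cells
  set.seed(16)
  G2 <- d$G; G2[sample(length(G2), 60)] <- 0
  KD <- dominance_kernel(G2)
  fA <- bgblup(d$y, d$env, d$hybrid, d$K, gxe = FALSE,
               niter = 2000, burnin = 400, seed = 15)
  fAD <- bgblup(d$y, d$env, d$hybrid, d$K, K_D = KD, gxe = FALSE,
                niter = 2000, burnin = 400, seed = 15)
  truth <- d$u[match(d$hybrid, rownames(d$K))]
  accA <- cor(fA$u_mean$A, truth)
  accAD <- cor(fAD$u_mean$A + fAD$u_mean$D, truth)
  expect_gt(accAD, accA - 0.1)
})
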