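# BC1-NAM population simulator

test_that("genetic map construction obeys its contract", {
  map <- make_genetic_map(1, 1, 100)
  expect_equal(nrow(map), 1L)

  map <- make_genetic_map(10, 100, 150)
  expect_equal(nrow(map), 1000L)
  expect_true(all(table(map$chrom) == 100))
  expect_true(all(map$pos > 0 & map$pos <= 150))
  expect_true(all(tapply(map$pos, map$chrom, function(p) all(diff(p) > 0))))

  m1 <- make_genetic_map(2, 5, 50, seed = 3, spacing = "random")
  m2 <- make_genetic_map(2, 5, 50, seed = 3, spacing = "random")
  expect_identical(m1, m2)
  expect_error(make_genetic_map(0, 5, 50), "must be")
})

test_that("degenerate cross of identical parents returns the recurrent parent", {
  map <- make_genetic_map(3, 20, 100)
  rec <- stats::setNames(integer(nrow(map)), map$marker)
  fam <- simulate_bc1_family(rec, rec, map, 5, seed = 1)
  expect_true(all(fam$geno == 0))
  expect_equal(fam$ibd, rep(1, 5))
})

test_that("BC1 recurrent-parent genome fraction matches the Mendelian 3/4", {
  # single-marker gamete enumeration: the BC1F1 receives one recurrent allele
  # from the recurrent parent and, from the F1 gamete, the recurrent allele
  # with probability 1/2, so P(recurrent allele) = (1 + 1/2)/2 = 3/4
  expect_equal((1 + 1/2) / 2, 0.75)

  map <- make_genetic_map(10, 100, 150)
  f <- make_founders(map, 1, divergence = 1.0, seed = 2)
  fam <- simulate_bc1_family(f$recurrent, f$donors[1, ], map, 500,
                             selfing_generations = 0, seed = 3)
  se <- sqrt(0.75 * 0.25 / (500 * 1000))   # binomial SE bound, iid upper bound
  # linkage inflates the SE; allow 3 SE on the per-line mean with n_eff ~ lines
  se_line <- sd(fam$ibd) / sqrt(500)
  expect_lt(abs(mean(fam$ibd) - 0.75), 3 * se_line)
  expect_gt(se_line, se)  # linked markers: line-level spread exceeds iid SE
})

test_that("selection at major loci raises identity-by-descent above 3/4", {
  map <- make_genetic_map(10, 100, 150)
  f <- make_founders(map, 1, divergence = 1.0, seed = 2)
  sel <- map$marker[c(50, 250, 450, 650)]   # one locus on four chromosomes
  unsel <- simulate_bc1_family(f$recurrent, f$donors[1, ], map, 150,
                               selfing_generations = 3, seed = 9)
  sel_fam <- simulate_bc1_family(f$recurrent, f$donors[1, ], map, 150,
                                 selfing_generations = 3,
                                 selection_loci = sel, seed = 9)
  expect_gte(mean(sel_fam$ibd), 0.75)
  expect_gt(mean(sel_fam$ibd), mean(unsel$ibd))
  # selected loci are recurrent-homozygous in every line
  expect_true(all(sel_fam$geno[, sel] == 0))
})

test_that("selfing halves heterozygosity each generation", {
  map <- make_genetic_map(10, 50, 120)
  f <- make_founders(map, 1, divergence = 1.0, seed = 4)
  het <- sapply(c(0, 1, 3), function(g)
    mean(simulate_bc1_family(f$recurrent, f$donors[1, ], map, 200,
                             selfing_generations = g, seed = 5)$origin_het))
  # BC1F1 het = 1/2; each selfing halves it
  expect_equal(het[1], 0.5, tolerance = 0.05)
  expect_equal(het[2], 0.25, tolerance = 0.1)
  expect_equal(het[3], 0.0625, tolerance = 0.15)
})

test_that("impossible selection (donor-fixed loci) errors after bounded redraws", {
  map <- make_genetic_map(1, 5, 50)
  rec <- stats::setNames(integer(5), map$marker)
  don <- stats::setNames(rep(1L, 5), map$marker)
  # selecting recurrent homozygotes at all 5 tightly linked loci is possible;
  # bound attempts very low to trigger the failure path deterministically
  expect_error(
    simulate_bc1_family(rec, don, map, 50, selection_loci = map$marker,
                        seed = 1, max_attempts = 3),
    "attempts")
})

test_that("testcross pedigree enumerates, restricts and de-duplicates", {
  h <- make_testcross_hybrids(c("a", "b", "c"), c("T1", "T2"))
  expect_equal(nrow(h), 6L)
  h2 <- make_testcross_hybrids(c("a", "b"), c("T1", "T2"),
                               assignment = list(a = "T1", b = "T2"))
  expect_equal(nrow(h2), 2L)
  h3 <- make_testcross_hybrids("a", "T1", assignment = list(a = c("T1", "T1")))
  expect_equal(nrow(h3), 1L)
  expect_error(make_testcross_hybrids("a", "T1", assignment = list(zz = "T1")),
               "unknown lines")
})

test_that("trial simulation respects degenerate variance settings", {
  set.seed(1)
  G <- random_inbred_geno(12, 80, seed = 2)
  rownames(G) <- paste0("h", 1:12)
  hyb <- data.frame(hybrid = rownames(G), male = rownames(G), female = "T1")
  zero <- c(A = 0, D = 0, AE = 0, DE = 0, e = 0, mean = 10)
  sp <- trial_spec(c("E1", "E2"), design = "rcbd2",
                   traits = list(t = zero), env_effect_sd = 0,
                   design_sd = c(block = 0, range = 0, row = 0))
  out <- simulate_trial(hyb, G, sp, seed = 1)
  expect_true(all(out$plots$t == 10))
  expect_true(all(out$truth$t == 0))

  # residual-free replicates are identical within environment
  sp2 <- trial_spec(c("E1", "E2"), design = "rcbd2",
                    traits = list(t = c(A = 1, D = 0, AE = 0, DE = 0, e = 0,
                                        mean = 0)),
                    env_effect_sd = 0, design_sd = c(block = 0, range = 0, row = 0))
  out2 <- simulate_trial(hyb, G, sp2, seed = 2)
  spread <- tapply(out2$plots$t, paste(out2$plots$env, out2$plots$hybrid),
                   function(x) diff(range(x)))
  expect_true(all(spread < 1e-9))
  # and plot values recover the truth exactly when noise and design are off
  tr <- out2$truth
  key <- paste(out2$plots$env, out2$plots$hybrid)
  expect_equal(unname(out2$plots$t),
               tr$t[match(key, paste(tr$env, tr$hybrid))], tolerance = 1e-9)
})

test_that("kernel-architecture genetic variance matches the requested scale", {
  G <- random_inbred_geno(150, 300, seed = 3)
  rownames(G) <- paste0("h", seq_len(nrow(G)))
  hyb <- data.frame(hybrid = rownames(G), male = rownames(G), female = "T1")
  KA <- additive_kernel(G)
  sp <- trial_spec(paste0("E", 1:3), design = "rcbd2",
                   traits = list(t = c(A = 1, D = 0, AE = 0, DE = 0, e = 0,
                                       mean = 0)),
                   env_effect_sd = 0, design_sd = c(block = 0, range = 0, row = 0))
  out <- simulate_trial(hyb, G, sp, seed = 4)
  v <- var(out$truth$t[out$truth$env == "E1"])
  expect_equal(v, mean(diag(KA)), tolerance = 0.25 * mean(diag(KA)) + 0.25)
})

test_that("simulation is seed-deterministic", {
  map <- make_genetic_map(2, 30, 80)
  f <- make_founders(map, 2, divergence = 0.4, seed = 6)
  a <- simulate_bc1_family(f$recurrent, f$donors[1, ], map, 20, seed = 11)
  b <- simulate_bc1_family(f$recurrent, f$donors[1, ], map, 20, seed = 11)
  expect_identical(a, b)
  G <- random_inbred_geno(10, 50, seed = 1)
  rownames(G) <- paste0("h", 1:10)
  hyb <- data.frame(hybrid = rownames(G), male = rownames(G), female = "T")
  sp <- trial_spec("E1", traits = list(t = c(A = 1, D = 0.2, AE = 0.3, DE = 0.1,
                                             e = 1, mean = 5)))
  expect_identical(simulate_trial(hyb, G, sp, seed = 8),
                   simulate_trial(hyb, G, sp, seed = 8))
})
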