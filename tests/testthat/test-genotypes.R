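# Numeric coding, marker filtering, hybrids, Nei distance, ordination

test_that("allele calls are coded -1/0/1 with major-allele orientation", {
  calls <- cbind(m1 = c("AA", "AA", "AT", "TT"))
  m <- encode_numeric(calls)
  expect_equal(unname(m$geno[, 1]), c(1, 1, 0, -1))

  # all identical homozygous -> that allele is major, all coded 1
  m2 <- encode_numeric(cbind(m1 = c("GG", "GG", "GG")))
  expect_true(all(m2$geno == 1))

  # 50/50 tie broken toward the lexicographically smaller allele
  m3 <- encode_numeric(cbind(m1 = c("CC", "TT")))
  expect_equal(unname(m3$geno[, 1]), c(1, -1))

  # coded-matrix frequencies reproduce raw-call frequencies
  set.seed(2)
  raw <- matrix(sample(c("AA", "AT", "TT"), 120, TRUE, prob = c(.5, .2, .3)),
                20, 6, dimnames = list(NULL, paste0("m", 1:6)))
  mm <- encode_numeric(raw)
  freq_raw <- apply(raw, 2, function(x) {
    al <- c(substr(x, 1, 1), substr(x, 2, 2)); max(table(al)) / length(al)
  })
  expect_equal(unname(major_allele_freq(mm)), unname(freq_raw))

  # missing preserved; >2 alleles flagged
  m4 <- encode_numeric(cbind(m1 = c("AA", NA, "TT"), m2 = c("AG", "CT", "AA")))
  expect_true(is.na(m4$geno[2, 1]))
  expect_equal(attr(m4, "non_biallelic"), "m2")
})

test_that("the five filter rules drop one marker each on the hand-built fixture", {
  # 8 lines, first 4 parents; 6 markers engineered to fail exactly one rule
  # each (in rule order) plus one clean marker
  g <- matrix(1, 8, 6, dimnames = list(paste0("L", 1:8), paste0("m", 1:6)))
  g[1:4, 1] <- NA                                 # m1: called in 0/4 parents
  g[, 2] <- c(-1, 1, -1, NA, NA, NA, NA, NA)      # m2: 5/8 missing (>50%),
                                                  #     but 3/4 parents called
  g[, 3] <- c(1, -1, 1, -1, 1, -1, 1, -1)         # m3: indel-flagged below
  # m4: MAF 0 (monomorphic all 1) -> maf rule
  g[, 5] <- c(0, 0, 0, 0, 0, 1, 0, 0)             # m5: het 7/8 > 50%
  g[, 6] <- c(1, 1, -1, -1, 1, 1, -1, 1)          # m6: clean
  m <- marker_matrix(g, is_indel = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  res <- filter_markers(m, parents = paste0("L", 1:4))
  expect_equal(res$report$parent_call, 1)
  expect_equal(res$report$missingness, 1)
  expect_equal(res$report$indel, 1)
  expect_equal(res$report$maf, 1)
  expect_equal(res$report$heterozygosity, 1)
  expect_equal(res$report$retained, 1)
  expect_equal(colnames(res$matrix$geno), "m6")
})

test_that("borderline markers survive: 50% missing and clean matrices pass", {
  g <- matrix(c(1, -1, NA, NA,                     # exactly 50% missing: kept
                1, -1, 1, -1), 4, 2,
              dimnames = list(paste0("L", 1:4), c("m1", "m2")))
  m <- marker_matrix(g)
  res <- filter_markers(m, parents = paste0("L", 1:4))
  expect_equal(res$report$retained, 2)

  # filtering is idempotent: a second pass drops nothing
  g2 <- random_inbred_geno(10, 20, seed = 5)
  res2 <- filter_markers(marker_matrix(g2), parents = rownames(g2)[1:3])
  res3 <- filter_markers(res2$matrix, parents = rownames(g2)[1:3])
  expect_equal(res3$report$retained, res2$report$retained)
  expect_equal(res3$report$maf + res3$report$heterozygosity +
                 res3$report$missingness + res3$report$parent_call +
                 res3$report$indel, 0)
  expect_error(filter_markers(marker_matrix(g2), parents = character()),
               "non-empty")
})

test_that("simple imputation fills missing with the major homozygote", {
  g <- matrix(c(1, NA, -1, 1), 2, 2)
  m <- impute_simple(marker_matrix(g))
  expect_equal(m$geno[2, 1], 1)
  g2 <- matrix(c(1, -1), 2, 1)
  expect_identical(impute_simple(marker_matrix(g2))$geno,
                   marker_matrix(g2)$geno)
  expect_warning(impute_simple(marker_matrix(matrix(NA_real_, 3, 1))),
                 "no calls")
})

test_that("hybrid genotypes are parental averages and commute", {
  g <- rbind(p1 = c(1, 1, -1), p2 = c(-1, 1, -1))
  m <- marker_matrix(g)
  ped <- data.frame(hybrid = "h", male = "p1", female = "p2")
  expect_equal(unname(hybrid_genotype(m, ped)["h", ]), c(0, 1, -1))
  ped_rev <- data.frame(hybrid = "h", male = "p2", female = "p1")
  expect_equal(hybrid_genotype(m, ped)["h", ], hybrid_genotype(m, ped_rev)["h", ])
  # identical parents -> hybrid equals parent
  ped_self <- data.frame(hybrid = "s", male = "p1", female = "p1")
  expect_equal(unname(hybrid_genotype(m, ped_self)["s", ]), unname(g["p1", ]))
  # all pairs of homozygous lines stay in {-1, 0, 1}
  g3 <- random_inbred_geno(3, 30, seed = 7)
  ped3 <- expand.grid(male = rownames(g3), female = rownames(g3))
  ped3$hybrid <- paste(ped3$male, ped3$female)
  h3 <- hybrid_genotype(marker_matrix(g3), ped3)
  expect_true(all(h3 %in% c(-1, 0, 1)))
})

test_that("Nei distance reproduces the worked two-marker case and its axioms", {
  m <- marker_matrix(rbind(x = c(1, 1), y = c(1, -1)))
  D <- nei_distance(m)
  expect_equal(D["x", "y"], log(2))
  expect_equal(diag(D), c(x = 0, y = 0))
  expect_equal(D, t(D))

  # identical lines at distance zero; fully opposite lines hit the cap
  m2 <- marker_matrix(rbind(a = c(1, -1, 1), b = c(1, -1, 1), c = c(-1, 1, -1)))
  D2 <- nei_distance(m2)
  expect_equal(D2["a", "b"], 0)
  expect_equal(D2["a", "c"], log(1e6))
  expect_true(all(D2 >= 0))
})

test_that("principal coordinates recover planar configurations", {
  # points already in the plane: distances reproduce within 1e-8
  set.seed(9)
  pts <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(pts))
  out <- pcoa(d, k = 2)
  expect_equal(as.matrix(dist(out$points)), d, ignore_attr = TRUE,
               tolerance = 1e-8)

  # three equidistant lines: two equal eigenvalues, equilateral triangle
  d3 <- matrix(1, 3, 3) - diag(3)
  out3 <- pcoa(d3, k = 2)
  expect_equal(out3$eig[1], out3$eig[2], tolerance = 1e-9)
  side <- dist(out3$points)
  expect_equal(max(side) - min(side), 0, tolerance = 1e-9)

  # duplicated line lands on identical coordinates
  d4 <- as.matrix(dist(pts[c(1, 1, 2, 3), ]))
  out4 <- pcoa(d4, k = 2)
  expect_equal(out4$points[1, ], out4$points[2, ], tolerance = 1e-9)
  expect_warning(pcoa(d3, k = 3), "positive eigenvalue")
})

test_that("genotype CSV and VCF round-trip the coded matrix", {
  skip_if_not_installed("vcfR")
  g <- random_inbred_geno(6, 15, seed = 3)
  g[2, 5] <- 0; g[3, 7] <- NA
  map <- data.frame(marker = colnames(g), chrom = rep(1:3, each = 5),
                    pos = rep(seq(5, 25, 5), 3))
  m <- marker_matrix(g, map = map)
  csv <- tempfile(fileext = ".csv"); vcf <- tempfile(fileext = ".vcf")
  write_geno_csv(m, csv)
  expect_equal(read_geno_csv(csv)$geno, m$geno)
  write_geno_vcf(m, vcf)
  back <- read_geno_vcf(vcf)
  expect_equal(unname(back$geno[rownames(g), colnames(g)]), unname(m$geno))
})
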