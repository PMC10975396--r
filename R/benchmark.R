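# The packaged synthetic BC1-NAM benchmark: a scaled-down population + trial
# with known truth, used by the cross-validation experiments and examples.

#' Simulate the packaged BC1-NAM benchmark
#'
#' Generates a complete scaled-down study: a BC1-NAM population of
#' `n_families` families sharing one recurrent parent, testcross hybrids to a
#' common seed-parent tester pool, a multi-environment trial (one augmented
#' unreplicated environment plus replicated RCBD environments), within-
#' environment BLUEs and the hybrid kernels. Two traits are simulated: a
#' high-heritability trait (`anthesis`) and a low-heritability trait
#' (`yield`), with additive, dominance and genotype-by-environment variance.
#'
#' @param seed Integer master seed.
#' @param n_families Number of BC1 families (first two act as the core
#'   training families, mirroring the near-complete families of a real
#'   program).
#' @param lines_per_family Integer vector of lines per non-core family,
#'   recycled; the default sizes are heterogeneous, echoing the very uneven
#'   numbers of lines tested per family in a real program (some families
#'   contribute only 2 lines, others close to 20).
#' @param core_lines_per_family Lines in each of the two core families;
#'   larger, as the core families of the real program were phenotyped nearly
#'   completely while only a fraction of the other families was.
#' @param n_chrom,markers_per_chrom,chrom_length_cM Genetic map.
#' @param n_envs Number of environments (first is augmented, rest RCBD r=2).
#' @param n_testers Seed-parent testers; each line is crossed to one tester
#'   (rotating), checks to all.
#' @param n_bc1_plants BC1F1 plants per family (see [simulate_bc1_family()]);
#'   the default of 2 gives sibs the shared-segment structure of a real
#'   backcross family.
#' @param divergence Divergence of the exotic donors from the recurrent
#'   parent.
#' @param tester_divergence Divergence of the elite seed-parent testers from
#'   the recurrent parent; much smaller than `divergence`, as elite lines of
#'   complementary heterotic pools are far closer to each other than to
#'   unadapted accessions.
#' @param selfing_generations Selfing rounds after BC1F1 (default 3 = BC1F4).
#' @param traits Trait variance settings; see [trial_spec()].
#' @param genetic_arch,n_qtl Genetic architecture passed to [trial_spec()];
#'   the default finite-QTL architecture samples QTL among markers
#'   segregating on the male (line) side, so donor alleles private to one
#'   family carry real effects and family representation in the training set
#'   matters.
#' @param compute_blues Fit per-environment BLUEs (default TRUE; the slow
#'   step).
#' @return A list with `map`, `founders`, `pedigree` (line/family/donor),
#'   `lines` (marker_matrix of lines + checks + testers), `hybrids`,
#'   `hyb_geno`, `K_A`, `K_D`, `plots`, `truth`, `blues` (env x hybrid BLUE
#'   table with trait columns), `families` (named vector line -> family),
#'   `checks`, `core_families`, `seed`.
#' @export
nam_benchmark <- function(seed = 1L, n_families = 14L,
                          lines_per_family = c(2L, 5L, 6L, 8L, 11L, 13L, 14L,
                                               18L, 6L, 9L, 11L, 14L),
                          core_lines_per_family = 24L,
                          n_chrom = 10L, markers_per_chrom = 150L,
                          chrom_length_cM = 150,
                          n_envs = 3L, n_testers = 2L, n_bc1_plants = 2L,
                          divergence = 0.35,
                          tester_divergence = 0.08,
                          selfing_generations = 3L,
                          traits = list(
                            anthesis = c(A = 1, D = 0.05, AE = 0.1, DE = 0.05,
                                         F = 0.8, e = 0.3, mean = 72),
                            yield = c(A = 0.4, D = 0.1, AE = 0.4, DE = 0.1,
                                      F = 0.4, e = 2.0, mean = 7)),
                          genetic_arch = "mixed",
                          n_qtl = c(anthesis = 40L, yield = 80L),
                          qtl_private_frac = c(anthesis = 0.1, yield = 0.65),
                          compute_blues = TRUE) {
  map <- make_genetic_map(n_chrom, markers_per_chrom, chrom_length_cM)
  fam_ids <- sprintf("F%02d", seq_len(n_families))
  founders <- make_founders(map, n_families + n_testers,
                            divergence = c(rep(divergence, n_families),
                                           rep(tester_divergence, n_testers)),
                            seed = seed,
                            donor_ids = c(paste0("don_", fam_ids),
                                          sprintf("tester%02d", seq_len(n_testers))))
  M <- nrow(map)

  # BC1 families (donor-allele dosage), tracked IBD
  geno <- list(); ped <- list()
  noncore_sizes <- rep_len(lines_per_family, max(n_families - 2L, 0L))
  for (i in seq_len(n_families)) {
    n_i <- if (i <= 2) core_lines_per_family else noncore_sizes[i - 2L]
    fam <- simulate_bc1_family(founders$recurrent,
                               founders$donors[paste0("don_", fam_ids[i]), ],
                               map, n_i,
                               selfing_generations = selfing_generations,
                               n_bc1_plants = n_bc1_plants,
                               seed = seed + i, family_id = fam_ids[i])
    geno[[i]] <- fam$geno
    ped[[i]] <- data.frame(line = fam$line_ids, family = fam_ids[i],
                           donor = paste0("don_", fam_ids[i]),
                           ibd = fam$ibd, stringsAsFactors = FALSE)
  }
  dosage <- do.call(rbind, geno)
  pedigree <- do.call(rbind, ped)

  # checks: the recurrent parent itself enters the trial as a testcross male
  checks <- "R_check"
  dosage <- rbind(dosage, R_check = rep(0L, M))
  # testers come from the complementary (seed-parent) pool
  tester_ids <- sprintf("tester%02d", seq_len(n_testers))
  dosage <- rbind(dosage, founders$donors[tester_ids, , drop = FALSE] * 2L)

  # donor-allele dosage -> -1/0/1 with the recurrent allele as major
  lines_mm <- marker_matrix(1 - dosage, map = map)

  males <- c(pedigree$line, checks)
  assign <- stats::setNames(
    c(as.list(tester_ids[(seq_along(pedigree$line) - 1L) %% n_testers + 1L]),
      rep(list(tester_ids), length(checks))), males)
  hybrids <- make_testcross_hybrids(males, tester_ids, assign)
  hyb_geno <- hybrid_genotype(lines_mm, hybrids)
  K_A <- additive_kernel(hyb_geno)
  K_D <- dominance_kernel(hyb_geno)

  # QTL candidates: markers segregating among the BC1 lines themselves, so
  # trait loci live on the male side (donor introgressions), largely private
  # to single families
  # QTL pools among markers segregating on the male (line) side and absent
  # from the tester genomes: "shared" markers are carried by two or more
  # donors (their effects can be learned across families), "private" markers
  # by exactly one donor (learnable only from that family). The
  # high-heritability trait draws mostly shared QTL - its genetics transfer
  # across families, so little family representation is needed - while the
  # low-heritability trait leans on family-private introgressions.
  seg <- apply(lines_mm$geno[pedigree$line, , drop = FALSE], 2, stats::var) > 0
  tester_mono <- colSums(founders$donors[tester_ids, , drop = FALSE]) == 0
  donor_count <- colSums(founders$donors[paste0("don_", fam_ids), , drop = FALSE])
  core_carried <- colSums(founders$donors[paste0("don_", fam_ids[1:2]), ,
                                          drop = FALSE]) >= 1
  # shared pool: present in the core training families AND in several other
  # donors, so effects learned from the core transfer to most validation
  # families; private pool: exotic alleles unique to one non-core donor
  pool_shared <- colnames(lines_mm$geno)[seg & tester_mono & core_carried &
                                           donor_count >= 3]
  pool_private <- colnames(lines_mm$geno)[seg & tester_mono & donor_count == 1 &
                                            !core_carried]
  spec <- trial_spec(sprintf("E%d", seq_len(n_envs)),
                     design = c("augmented", rep("rcbd2", n_envs - 1L)),
                     check_hybrids = hybrids$hybrid[hybrids$male %in% checks],
                     traits = traits,
                     genetic_arch = genetic_arch, n_qtl = n_qtl,
                     qtl_candidates = pool_shared, qtl_private = pool_private,
                     qtl_private_frac = qtl_private_frac)
  trial <- simulate_trial(hybrids, hyb_geno, spec, seed = seed + 997L,
                          families = stats::setNames(pedigree$family,
                                                     pedigree$line))

  blues <- NULL
  if (compute_blues) {
    rows <- list()
    for (env in spec$environments) {
      per_trait <- lapply(names(traits), function(tr)
        fit_env_blues(trial$plots, env, tr))
      ids <- names(per_trait[[1]]$blue)
      df <- data.frame(env = env, hybrid = ids,
                       male = hybrids$male[match(ids, hybrids$hybrid)],
                       female = hybrids$female[match(ids, hybrids$hybrid)],
                       stringsAsFactors = FALSE)
      for (j in seq_along(traits))
        df[[names(traits)[j]]] <- unname(per_trait[[j]]$blue[ids])
      rows[[env]] <- df
    }
    blues <- do.call(rbind, rows)
    rownames(blues) <- NULL
  }

  list(map = map, founders = founders, pedigree = pedigree, lines = lines_mm,
       hybrids = hybrids, hyb_geno = hyb_geno, K_A = K_A, K_D = K_D,
       plots = trial$plots, truth = trial$truth, blues = blues,
       families = stats::setNames(pedigree$family, pedigree$line),
       checks = checks, core_families = fam_ids[1:2], seed = seed,
       trial_spec = spec)
}
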