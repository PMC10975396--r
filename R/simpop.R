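# Synthetic BC1-NAM populations: founders, Haldane meiosis, backcrossing,
# selfing with selection at major loci, testcross hybrids and multi-environment
# trial phenotypes with a hidden truth table.

#' Build a genetic map
#'
#' Creates a marker map over `n_chrom` chromosomes of equal genetic length.
#' Marker positions are either an evenly spaced grid or uniform random draws
#' (sorted within chromosome), controlled by `spacing`.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param markers_per_chrom Markers on each chromosome (>= 1).
#' @param chrom_length_cM Genetic length of every chromosome in centimorgans.
#' @param seed Integer seed used when `spacing = "random"`.
#' @param spacing `"grid"` for a deterministic evenly spaced layout or
#'   `"random"` for seeded uniform positions.
#' @return An object of class `genome_map`: a data frame with columns
#'   `marker`, `chrom`, `pos` (cM), plus a `chrom_length` attribute.
#' @examples
#' map <- make_genetic_map(2, 5, 50)
#' table(map$chrom)
#' @export
make_genetic_map <- function(n_chrom, markers_per_chrom, chrom_length_cM,
                             seed = 1L, spacing = c("grid", "random")) {
  spacing <- match.arg(spacing)
  if (n_chrom < 1 || markers_per_chrom < 1 || chrom_length_cM <= 0)
    stop("n_chrom and markers_per_chrom must be >= 1 and chrom_length_cM > 0")
  n_chrom <- as.integer(n_chrom)
  markers_per_chrom <- as.integer(markers_per_chrom)
  pos <- if (spacing == "grid") {
    # grid avoids position 0 so every marker sits strictly inside the chromosome
    rep(seq(chrom_length_cM / (markers_per_chrom + 1), by = chrom_length_cM / (markers_per_chrom + 1),
            length.out = markers_per_chrom), n_chrom)
  } else {
    withr_seed <- .with_seed(seed, {
      unlist(lapply(seq_len(n_chrom), function(i)
        sort(stats::runif(markers_per_chrom, 0, chrom_length_cM))))
    })
    withr_seed
  }
  chrom <- rep(seq_len(n_chrom), each = markers_per_chrom)
  map <- data.frame(
    marker = sprintf("S%d_%d", chrom, sequence(rep(markers_per_chrom, n_chrom))),
    chrom = chrom,
    pos = pos,
    stringsAsFactors = FALSE
  )
  attr(map, "chrom_length") <- chrom_length_cM
  class(map) <- c("genome_map", "data.frame")
  map
}

# Evaluate `expr` under a local RNG seed without disturbing the caller's stream.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Create founder lines for a BC1-NAM simulation
#'
#' The recurrent parent carries the reference allele (coded 0) at every marker;
#' each donor differs from it at a seeded random subset of markers so that the
#' realized divergence matches `divergence` per donor. All founders are fully
#' homozygous inbreds.
#'
#' @param map A `genome_map`.
#' @param n_donors Number of donor (unadapted) parents.
#' @param divergence Fraction of markers at which each donor carries the
#'   non-recurrent allele; recycled to `n_donors`.
#' @param seed Integer seed.
#' @param donor_ids Optional character ids for the donors.
#' @return A list with elements `recurrent` (haploid 0/1 vector), `donors`
#'   (matrix, donors x markers), `divergence` (realized fractions) and `map`.
#' @export
make_founders <- function(map, n_donors, divergence = 0.3, seed = 1L,
                          donor_ids = NULL) {
  stopifnot(inherits(map, "genome_map"), n_donors >= 1)
  M <- nrow(map)
  divergence <- rep_len(divergence, n_donors)
  if (is.null(donor_ids)) donor_ids <- sprintf("donor%02d", seq_len(n_donors))
  donors <- .with_seed(seed, {
    t(vapply(seq_len(n_donors), function(d) {
      k <- round(divergence[d] * M)
      hap <- integer(M)
      hap[sample.int(M, k)] <- 1L
      hap
    }, integer(M)))
  })
  rownames(donors) <- donor_ids
  colnames(donors) <- map$marker
  recurrent <- integer(M)
  names(recurrent) <- map$marker
  list(recurrent = recurrent, donors = donors,
       divergence = rowMeans(donors), map = map)
}

# One gamete from a diploid individual given as two parental-origin haplotypes
# (integer vectors over the map's markers). Haldane model: crossover count per
# chromosome ~ Poisson(length/100), positions uniform, no interference.
.gamete <- function(hap1, hap2, map) {
  out <- integer(length(hap1))
  chroms <- attr(map, "chrom_index")
  if (is.null(chroms)) chroms <- split(seq_len(nrow(map)), map$chrom)
  L <- attr(map, "chrom_length")
  for (idx in chroms) {
    pos <- map$pos[idx]
    ncx <- stats::rpois(1L, L / 100)
    # phase: which haplotype the gamete starts on
    cur <- if (stats::runif(1L) < 0.5) 0L else 1L
    if (ncx == 0L) {
      pick <- rep(cur, length(idx))
    } else {
      xo <- sort(stats::runif(ncx, 0, L))
      # number of crossovers before each marker determines the phase there
      nswitch <- findInterval(pos, xo)
      pick <- (cur + nswitch) %% 2L
    }
    out[idx] <- ifelse(pick == 0L, hap1[idx], hap2[idx])
  }
  out
}

#' Simulate one BC1-derived family
#'
#' Crosses a homozygous donor to the recurrent parent (F1), backcrosses the F1
#' to the recurrent parent (BC1F1), then selfs for `selfing_generations`
#' rounds (3 gives BC1F4). Meiosis follows the Haldane map function (Poisson
#' crossovers, no interference). Lines that are not homozygous for the
#' recurrent-parent allele at every locus in `selection_loci` are discarded
#' and redrawn, modelling selection for major dwarfing/maturity genes.
#'
#' Parental origin is tracked separately from allele state, so the realized
#' identity-by-descent fraction with the recurrent parent (`ibd`) is exact.
#'
#' @param recurrent Haploid 0/1 allele vector of the recurrent parent.
#' @param donor Haploid 0/1 allele vector of the donor parent.
#' @param map A `genome_map`.
#' @param n_lines Number of finished lines to return.
#' @param selfing_generations Number of selfing rounds after BC1F1 (default 3,
#'   i.e. BC1F4).
#' @param n_bc1_plants Number of distinct BC1F1 individuals the family
#'   descends from; 0 (the default) draws an independent BC1F1 for every
#'   line. A small positive number reproduces the familial structure of a
#'   real backcross program: each BC1F1 plant carries only half of the donor
#'   genome, so lines tracing to the same plant share which donor segments
#'   segregate at all.
#' @param selection_loci Character vector of marker ids at which only
#'   recurrent-parent homozygotes are kept (default none).
#' @param seed Integer seed.
#' @param family_id Family label used in line ids.
#' @param max_attempts Upper bound on total lines drawn before giving up on
#'   the selection screen.
#' @return A list of class `bc1_family` with elements `geno` (lines x markers
#'   donor-allele dosage 0/1/2), `origin_het` (per-line fraction of markers
#'   with mixed parental origin), `ibd` (per-line recurrent-parent origin
#'   fraction), `family_id`, `line_ids`, `map`.
#' @export
simulate_bc1_family <- function(recurrent, donor, map, n_lines,
                                selfing_generations = 3L,
                                n_bc1_plants = 0L,
                                selection_loci = character(),
                                seed = 1L, family_id = "fam1",
                                max_attempts = 200L * n_lines) {
  stopifnot(inherits(map, "genome_map"), n_lines >= 1,
            selfing_generations >= 0)
  M <- nrow(map)
  stopifnot(length(recurrent) == M, length(donor) == M)
  sel_idx <- match(selection_loci, map$marker)
  if (anyNA(sel_idx)) stop("selection loci not on the map: ",
                           paste(selection_loci[is.na(sel_idx)], collapse = ", "))
  # cache chromosome split on the map for the inner loop
  attr(map, "chrom_index") <- split(seq_len(M), map$chrom)

  .with_seed(seed, {
    geno <- matrix(0L, n_lines, M)
    ibd <- numeric(n_lines)
    ohet <- numeric(n_lines)
    kept <- 0L
    attempts <- 0L
    rec_origin <- integer(M)   # origin code 0 = recurrent
    don_origin <- rep(1L, M)
    # the family descends from a fixed set of BC1F1 plants: each carries the
    # recurrent haplotype plus one F1 gamete (half the donor genome)
    bc1_pool <- if (n_bc1_plants >= 1L)
      lapply(seq_len(n_bc1_plants), function(i)
        .gamete(rec_origin, don_origin, map)) else NULL
    while (kept < n_lines) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("selection screen not satisfiable within ", max_attempts,
             " attempts (are the selection loci fixed for the donor allele?)")
      # BC1F1: recurrent gamete + F1 gamete; the F1 is (recurrent, donor) so
      # an F1 gamete is a fresh recombinant of the two founder origins
      h1 <- integer(M)                       # from recurrent parent
      h2 <- if (is.null(bc1_pool))
        .gamete(rec_origin, don_origin, map)
      else bc1_pool[[(attempts - 1L) %% length(bc1_pool) + 1L]]
      for (g in seq_len(selfing_generations)) {
        n1 <- .gamete(h1, h2, map)
        n2 <- .gamete(h1, h2, map)
        h1 <- n1; h2 <- n2
      }
      if (length(sel_idx) &&
          any(h1[sel_idx] != 0L | h2[sel_idx] != 0L)) next
      kept <- kept + 1L
      # allele state: donor allele where origin is donor
      a1 <- ifelse(h1 == 1L, donor, recurrent)
      a2 <- ifelse(h2 == 1L, donor, recurrent)
      geno[kept, ] <- a1 + a2
      # recurrent-parent allele fraction in state (equals the origin-tracked
      # fraction when the donor differs everywhere; 1 for an identical donor)
      ibd[kept] <- mean(c(a1 == recurrent, a2 == recurrent))
      ohet[kept] <- mean(h1 != h2)
    }
    line_ids <- sprintf("%s_L%03d", family_id, seq_len(n_lines))
    rownames(geno) <- line_ids
    colnames(geno) <- map$marker
    structure(list(geno = geno, origin_het = ohet, ibd = ibd,
                   family_id = family_id, line_ids = line_ids, map = map),
              class = "bc1_family")
  })
}

#' Enumerate testcross hybrids
#'
#' Builds the hybrid pedigree for an (incomplete) factorial of male lines
#' crossed to female seed-parent testers. Duplicate (male, female) pairs are
#' collapsed.
#'
#' @param lines Character vector of male line ids.
#' @param testers Character vector of female tester ids.
#' @param assignment Optional named list mapping each line to the subset of
#'   testers it is crossed to; default is the full factorial.
#' @return A data frame with columns `hybrid`, `male`, `female`.
#' @export
make_testcross_hybrids <- function(lines, testers, assignment = NULL) {
  if (is.null(assignment)) assignment <- stats::setNames(
    rep(list(testers), length(lines)), lines)
  if (!all(names(assignment) %in% lines))
    stop("assignment names unknown lines: ",
         paste(setdiff(names(assignment), lines), collapse = ", "))
  bad <- setdiff(unlist(assignment), testers)
  if (length(bad)) stop("assignment references unknown testers: ",
                        paste(unique(bad), collapse = ", "))
  if (any(lengths(assignment) == 0L)) stop("every line needs >= 1 tester")
  ped <- do.call(rbind, lapply(names(assignment), function(l)
    data.frame(male = l, female = assignment[[l]], stringsAsFactors = FALSE)))
  ped <- unique(ped)
  ped$hybrid <- paste(ped$female, ped$male, sep = "/")
  rownames(ped) <- NULL
  ped[, c("hybrid", "male", "female")]
}

#' Specify a multi-environment testcross trial
#'
#' Collects the environment layout and per-trait variance components used by
#' [simulate_trial()]. Designs are `"rcbd2"` (randomized complete blocks, two
#' replications) or `"augmented"` (single unreplicated plot per hybrid).
#'
#' @param environments Character vector of environment ids.
#' @param design Design per environment, recycled; `"rcbd2"` or `"augmented"`.
#' @param traits Named list; each element a named numeric vector with entries
#'   `A`, `D`, `AE`, `DE`, `e` (variances) and `mean` (trait grand mean); an
#'   optional entry `F` adds a family main effect (the donor parent's general
#'   combining ability: exotic families differ in mean performance beyond
#'   what segregating markers track).
#' @param env_effect_sd Standard deviation of environment main effects.
#' @param design_sd Named numeric, standard deviations of random block, range
#'   and row effects.
#' @param check_hybrids Hybrid ids replicated in every block of augmented
#'   environments (the replicated checks that make the genotype model
#'   estimable there).
#' @param genetic_arch `"kernel"` draws genetic values directly from the
#'   relationship kernels (multivariate normal, the GBLUP generative model);
#'   `"qtl"` builds them from a finite set of marker QTL with i.i.d. effects,
#'   so rare family-private donor alleles carry full-sized effects that a
#'   genome-wide kernel under-weights; `"mixed"` combines a polygenic
#'   kernel-distributed component with a family-private QTL component in
#'   proportion `qtl_private_frac` — the architecture that makes family
#'   representation in the training set matter while keeping across-family
#'   prediction possible.
#' @param n_qtl Number of QTL per trait under the QTL architectures; a named
#'   vector gives each trait its own count (few loci = an oligogenic trait
#'   driven by major genes, many = polygenic).
#' @param qtl_candidates Optional marker ids eligible as QTL (default: all
#'   markers polymorphic among the hybrids).
#' @param qtl_private Optional marker ids forming a family-private pool
#'   (e.g. introgressions carried by a single donor); per trait, the
#'   fraction `qtl_private_frac` of its QTL is drawn from this pool and the
#'   rest from `qtl_candidates`.
#' @param qtl_private_frac Named numeric (one entry per trait, recycled),
#'   fraction of QTL drawn from the private pool.
#' @return A list of class `trial_spec`.
#' @export
trial_spec <- function(environments,
                       design = "rcbd2",
                       check_hybrids = character(),
                       genetic_arch = c("kernel", "qtl", "mixed"),
                       n_qtl = 40L, qtl_candidates = NULL,
                       qtl_private = NULL, qtl_private_frac = 0.5,
                       traits = list(
                         yield = c(A = 0.5, D = 0.15, AE = 0.35, DE = 0.1, e = 1.4, mean = 7.0),
                         height = c(A = 1.0, D = 0.1, AE = 0.15, DE = 0.05, e = 0.35, mean = 130),
                         anthesis = c(A = 1.0, D = 0.05, AE = 0.1, DE = 0.05, e = 0.3, mean = 72)),
                       env_effect_sd = 0.5,
                       design_sd = c(block = 0.3, range = 0.2, row = 0.2)) {
  design <- rep_len(design, length(environments))
  stopifnot(all(design %in% c("rcbd2", "augmented")))
  for (tr in names(traits)) {
    v <- traits[[tr]]
    stopifnot(all(c("A", "D", "AE", "DE", "e", "mean") %in% names(v)),
              all(v[c("A", "D", "AE", "DE", "e")] >= 0))
  }
  structure(list(environments = environments, design = design, traits = traits,
                 env_effect_sd = env_effect_sd, design_sd = design_sd,
                 check_hybrids = check_hybrids,
                 genetic_arch = match.arg(genetic_arch),
                 n_qtl = stats::setNames(
                   rep_len(as.integer(n_qtl),
                           if (is.null(names(n_qtl))) length(traits) else length(n_qtl)),
                   names(n_qtl) %||% names(traits)),
                 qtl_candidates = qtl_candidates,
                 qtl_private = qtl_private,
                 qtl_private_frac = if (is.null(names(qtl_private_frac)))
                   stats::setNames(rep_len(qtl_private_frac, length(traits)),
                                   names(traits)) else qtl_private_frac),
            class = "trial_spec")
}

# Draw one MVN vector with covariance s2 * K, flooring eigenvalues for PSD
# safety. `ek` is a precomputed eigen(K).
.mvn_from_eigen <- function(ek, s2) {
  lam <- pmax(ek$values, 1e-8)
  drop(ek$vectors %*% (sqrt(lam * s2) * stats::rnorm(length(lam))))
}

# Finite-QTL genetic values: i.i.d. N(0,1) effects at the QTL columns of the
# hybrid genotype matrix (dosage codes for additive, 1-|code| heterozygosity
# weights for dominance), rescaled so the realized variance across hybrids
# equals s2.
.qtl_effect <- function(geno, qtl, s2, dominance = FALSE) {
  X <- geno[, qtl, drop = FALSE]
  if (dominance) X <- 1 - abs(X)
  X <- sweep(X, 2, colMeans(X))   # effects act as deviations, mean zero
  v <- drop(X %*% stats::rnorm(length(qtl)))
  vv <- stats::var(v)
  if (vv > 0) v * sqrt(s2 / vv) else rep(0, length(v))
}

#' Simulate multi-environment testcross trial phenotypes
#'
#' Draws hybrid genetic values from the additive + dominance + GxE generative
#' model: main effects `u_A ~ N(0, K_A s2_A)` and `u_D ~ N(0, K_D s2_D)`
#' shared across environments, plus independent per-environment interaction
#' deviations with the same kernels, then adds environment means, random
#' block/range/row effects and i.i.d. plot residuals.
#'
#' @param hybrids Hybrid pedigree data frame from [make_testcross_hybrids()].
#' @param geno Numeric hybrid genotype matrix (hybrids x markers, codes in
#'   -1/0/1) whose rownames cover `hybrids$hybrid`.
#' @param spec A [trial_spec()].
#' @param seed Integer seed.
#' @param families Optional named vector mapping male line ids to family ids;
#'   required when any trait has a family (`F`) variance component. Males
#'   absent from the map (checks) get a zero family effect.
#' @return A list with `plots` (long TrialTable data frame: env, hybrid, male,
#'   female, block, range, row, one column per trait) and `truth` (hybrid x
#'   environment total genetic value per trait, long format).
#' @export
simulate_trial <- function(hybrids, geno, spec, seed = 1L, families = NULL) {
  stopifnot(inherits(spec, "trial_spec"))
  ids <- hybrids$hybrid
  miss <- setdiff(ids, rownames(geno))
  if (length(miss)) stop("hybrids without genotypes: ", paste(miss, collapse = ", "))
  geno <- geno[ids, , drop = FALSE]
  p <- length(ids); q <- length(spec$environments)
  KA <- additive_kernel(geno)
  KD <- tryCatch(dominance_kernel(geno), warning = function(w) {
    matrix(0, p, p, dimnames = list(ids, ids))
  })
  eA <- eigen(KA, symmetric = TRUE)
  eD <- if (any(KD != 0)) eigen(KD, symmetric = TRUE) else NULL

  .with_seed(seed, {
    envs <- spec$environments
    env_eff <- stats::setNames(stats::rnorm(q, 0, spec$env_effect_sd), envs)
    plots_env <- vector("list", q)
    truth_all <- vector("list", q)
    for (ei in seq_len(q)) {
      env <- envs[ei]
      if (spec$design[ei] == "rcbd2") {
        # two complete replications; block = rep
        ord <- c(sample.int(p), sample.int(p))
        block_id <- rep(1:2, each = p)
      } else {
        # unreplicated augmented: experimental entries once, checks in every
        # block (standard augmented layout keeping the genotype model
        # estimable)
        n_blk <- 4L
        chk <- match(intersect(spec$check_hybrids, ids), ids)
        exp_idx <- setdiff(seq_len(p), chk)
        blk_of_exp <- rep(seq_len(n_blk), length.out = length(exp_idx))
        ord <- integer(0); block_id <- integer(0)
        for (bkt in seq_len(n_blk)) {
          entries <- c(sample(exp_idx[blk_of_exp == bkt]), chk)
          entries <- sample(entries)
          ord <- c(ord, entries)
          block_id <- c(block_id, rep(bkt, length(entries)))
        }
      }
      n_plot <- length(ord)
      # field layout: plots filled column-major into a near-square grid
      n_row <- ceiling(sqrt(n_plot))
      plot_idx <- seq_len(n_plot)
      range_id <- ((plot_idx - 1L) %/% n_row) + 1L
      row_id <- ((plot_idx - 1L) %% n_row) + 1L
      hyb_plot <- ids[ord]
      base <- data.frame(env = env, hybrid = hyb_plot,
                         male = hybrids$male[ord], female = hybrids$female[ord],
                         block = paste0(env, "_b", block_id),
                         range = paste0(env, "_ra", range_id),
                         row = paste0(env, "_ro", row_id),
                         stringsAsFactors = FALSE)
      plots_env[[ei]] <- base
      truth_all[[ei]] <- data.frame(env = env, hybrid = ids,
                                    stringsAsFactors = FALSE)
    }
    plots <- do.call(rbind, plots_env)
    truth <- do.call(rbind, truth_all)

    arch <- spec$genetic_arch
    qtl_cand <- if (arch %in% c("qtl", "mixed")) {
      cand <- spec$qtl_candidates %||% colnames(geno)[apply(geno, 2, stats::var) > 0]
      match(intersect(cand, colnames(geno)), colnames(geno))
    } else integer()
    qtl_priv <- if (arch %in% c("qtl", "mixed") && !is.null(spec$qtl_private))
      match(intersect(spec$qtl_private, colnames(geno)), colnames(geno)) else integer()

    for (tr in names(spec$traits)) {
      v <- spec$traits[[tr]]
      pf <- spec$qtl_private_frac
      pf <- if (tr %in% names(pf)) pf[[tr]] else 0.5
      nq <- spec$n_qtl
      nq <- if (tr %in% names(nq)) nq[[tr]] else nq[[1]]
      if (arch == "qtl") {
        n_priv <- if (length(qtl_priv)) round(pf * nq) else 0L
        n_priv <- min(n_priv, length(qtl_priv))
        n_shared <- min(nq - n_priv, length(qtl_cand))
        qtl <- c(if (n_priv) sample(qtl_priv, n_priv),
                 if (n_shared) sample(qtl_cand, n_shared))
        drawA <- function(s2) .qtl_effect(geno, qtl, s2, dominance = FALSE)
        drawD <- function(s2) .qtl_effect(geno, qtl, s2, dominance = TRUE)
      } else if (arch == "mixed") {
        # polygenic kernel component (share 1 - pf) + family-private QTL
        # component (share pf); independent, variances add
        pool <- if (length(qtl_priv)) qtl_priv else qtl_cand
        qtl <- sample(pool, min(nq, length(pool)))
        drawA <- function(s2) .mvn_from_eigen(eA, (1 - pf) * s2) +
          .qtl_effect(geno, qtl, pf * s2, dominance = FALSE)
        drawD <- function(s2) if (is.null(eD)) numeric(p) else
          .mvn_from_eigen(eD, s2)
      } else {
        drawA <- function(s2) .mvn_from_eigen(eA, s2)
        drawD <- function(s2) if (is.null(eD)) numeric(p) else .mvn_from_eigen(eD, s2)
      }
      uA <- if (v[["A"]] > 0) drawA(v[["A"]]) else numeric(p)
      uD <- if (v[["D"]] > 0) drawD(v[["D"]]) else numeric(p)
      s2F <- if ("F" %in% names(v)) v[["F"]] else 0
      uF <- numeric(p)
      if (s2F > 0) {
        if (is.null(families))
          stop("trait '", tr, "' has a family variance but no family map given")
        fam_of <- unname(families[hybrids$male])   # NA for checks
        levs <- unique(stats::na.omit(fam_of))
        fe <- stats::setNames(stats::rnorm(length(levs), 0, sqrt(s2F)), levs)
        uF <- ifelse(is.na(fam_of), 0, fe[fam_of])
      }
      g_env <- matrix(0, p, q, dimnames = list(ids, envs))
      for (ei in seq_len(q)) {
        uAE <- if (v[["AE"]] > 0) drawA(v[["AE"]]) else numeric(p)
        uDE <- if (v[["DE"]] > 0) drawD(v[["DE"]]) else numeric(p)
        g_env[, ei] <- uA + uD + uF + uAE + uDE
      }
      truth[[tr]] <- g_env[cbind(match(truth$hybrid, ids), match(truth$env, envs))]
      # design effects drawn per level, i.i.d. normal
      blk <- stats::setNames(stats::rnorm(length(unique(plots$block)), 0, spec$design_sd[["block"]]),
                             unique(plots$block))
      ra <- stats::setNames(stats::rnorm(length(unique(plots$range)), 0, spec$design_sd[["range"]]),
                            unique(plots$range))
      ro <- stats::setNames(stats::rnorm(length(unique(plots$row)), 0, spec$design_sd[["row"]]),
                            unique(plots$row))
      gval <- g_env[cbind(match(plots$hybrid, ids), match(plots$env, envs))]
      plots[[tr]] <- v[["mean"]] + env_eff[plots$env] + blk[plots$block] +
        ra[plots$range] + ro[plots$row] + gval +
        stats::rnorm(nrow(plots), 0, sqrt(v[["e"]]))
    }
    rownames(plots) <- NULL
    list(plots = plots, truth = truth)
  })
}
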