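# Marker QC and numeric coding, in-silico hybrid genotypes, Nei genetic
# distance and principal coordinates of the parents.

#' Construct a marker matrix
#'
#' A light container for a lines x markers numeric genotype matrix coded
#' -1/0/1 (homozygous minor / heterozygote / homozygous major; NA = missing)
#' with marker metadata.
#'
#' @param geno Numeric matrix, lines x markers, values in -1/0/1/NA.
#' @param map Optional data frame with columns `marker`, `chrom`, `pos`
#'   matching the genotype columns.
#' @param is_indel Optional logical vector flagging indel markers.
#' @return An object of class `marker_matrix` (a list with `geno`, `map`,
#'   `is_indel`).
#' @export
marker_matrix <- function(geno, map = NULL, is_indel = NULL) {
  geno <- as.matrix(geno)
  ok <- geno %in% c(-1, 0, 1) | is.na(geno)
  if (!all(ok)) stop("genotype codes must be -1, 0, 1 or NA; first bad value: ",
                     geno[!ok][1])
  if (is.null(colnames(geno))) colnames(geno) <- sprintf("M%d", seq_len(ncol(geno)))
  if (is.null(rownames(geno))) rownames(geno) <- sprintf("L%d", seq_len(nrow(geno)))
  if (is.null(is_indel)) is_indel <- rep(FALSE, ncol(geno))
  if (!is.null(map)) stopifnot(nrow(map) == ncol(geno))
  structure(list(geno = geno, map = map, is_indel = is_indel),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("marker_matrix:", nrow(x$geno), "lines x", ncol(x$geno), "markers;",
      sum(is.na(x$geno)), "missing calls;", sum(x$is_indel), "indel-flagged\n")
  invisible(x)
}

#' Major-allele frequencies of a coded matrix
#'
#' @param m A `marker_matrix`.
#' @return Numeric vector, per-marker major-allele frequency in \[0.5, 1\]
#'   computed from the -1/0/1 codes over non-missing lines.
#' @export
major_allele_freq <- function(m) {
  colMeans((m$geno + 1) / 2, na.rm = TRUE)
}

#' Convert allele calls to the -1/0/1 numeric coding
#'
#' Per marker, the more frequent allele among non-missing calls is declared
#' major (ties broken towards the lexicographically smaller allele);
#' homozygous major is coded 1, heterozygote 0 and homozygous minor -1.
#' Missing calls are preserved as NA. Markers with more than two alleles are
#' flagged non-biallelic and coded NA throughout.
#'
#' @param calls Character matrix, lines x markers, of two-character genotype
#'   calls (e.g. `"AA"`, `"AT"`); `NA`, `""`, `"NN"` and `"--"` are missing.
#' @param map,is_indel Passed to [marker_matrix()].
#' @return A `marker_matrix`; markers failing the biallelic check are listed
#'   in attribute `non_biallelic`.
#' @examples
#' encode_numeric(rbind(c("AA"), c("AA"), c("AT"), c("TT")))$geno
#' @export
encode_numeric <- function(calls, map = NULL, is_indel = NULL) {
  calls <- as.matrix(calls)
  calls[calls %in% c("", "NN", "--", "..")] <- NA
  geno <- matrix(NA_real_, nrow(calls), ncol(calls),
                 dimnames = dimnames(calls))
  non_bi <- character()
  for (j in seq_len(ncol(calls))) {
    cj <- calls[, j]
    obs <- cj[!is.na(cj)]
    if (!length(obs)) next
    al <- c(substr(obs, 1, 1), substr(obs, 2, 2))
    tab <- table(al)
    if (length(tab) > 2) {
      non_bi <- c(non_bi, colnames(calls)[j] %||% as.character(j))
      next
    }
    # major = most frequent allele; lexicographic tie-break
    alleles <- names(sort(tab, decreasing = TRUE))
    if (length(tab) == 2 && tab[[1]] == tab[[2]]) alleles <- sort(names(tab))
    major <- alleles[1]
    dos <- (substr(cj, 1, 1) == major) + (substr(cj, 2, 2) == major)
    geno[, j] <- dos - 1
  }
  m <- marker_matrix(geno, map = map, is_indel = is_indel)
  attr(m, "non_biallelic") <- non_bi
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter markers by the retention rules
#'
#' Applies, in order: (1) markers called in fewer than 25% of the parental
#' lines are dropped; (2) markers with more than 50% missing calls overall are
#' dropped; (3) indel-flagged markers are dropped; (4) markers with minor
#' allele frequency below 0.05 are dropped; (5) markers with heterozygosity
#' above 50% are dropped. Each dropped marker is attributed to the first rule
#' it fails. Allele frequency and heterozygosity for rules 4-5 are computed
#' after simple major-allele imputation of the surviving missing calls,
#' mirroring a pipeline that imputes between the missingness and frequency
#' screens.
#'
#' @param m A `marker_matrix`.
#' @param parents Character vector of parental line ids (subset of rownames).
#' @param maf_min Minimum minor-allele frequency (default 0.05).
#' @param het_max Maximum heterozygous fraction (default 0.5).
#' @param parent_call_min Minimum fraction of parents with a call (default 0.25).
#' @param miss_max Maximum overall missing fraction, strict (default 0.5).
#' @return A list with `matrix` (filtered `marker_matrix`) and `report`
#'   (named drop counts per rule plus `retained`; class `filter_report`).
#' @export
filter_markers <- function(m, parents, maf_min = 0.05, het_max = 0.5,
                           parent_call_min = 0.25, miss_max = 0.5) {
  stopifnot(inherits(m, "marker_matrix"))
  if (length(parents) == 0) stop("parent set must be non-empty")
  bad <- setdiff(parents, rownames(m$geno))
  if (length(bad)) stop("unknown parental lines: ", paste(bad, collapse = ", "))
  g <- m$geno
  M <- ncol(g)
  rule <- rep(NA_character_, M)

  par_called <- colMeans(!is.na(g[parents, , drop = FALSE]))
  rule[is.na(rule) & par_called < parent_call_min] <- "parent_call"
  miss <- colMeans(is.na(g))
  rule[is.na(rule) & miss > miss_max] <- "missingness"
  rule[is.na(rule) & m$is_indel] <- "indel"
  # frequency screens on the imputed matrix (missing -> major homozygote)
  gi <- g
  gi[is.na(gi)] <- 1
  p <- colMeans((gi + 1) / 2)
  maf <- pmin(p, 1 - p)
  rule[is.na(rule) & maf < maf_min] <- "maf"
  het <- colMeans(gi == 0)
  rule[is.na(rule) & het > het_max] <- "heterozygosity"

  keep <- is.na(rule)
  report <- structure(list(
    parent_call = sum(rule == "parent_call", na.rm = TRUE),
    missingness = sum(rule == "missingness", na.rm = TRUE),
    indel = sum(rule == "indel", na.rm = TRUE),
    maf = sum(rule == "maf", na.rm = TRUE),
    heterozygosity = sum(rule == "heterozygosity", na.rm = TRUE),
    retained = sum(keep),
    input = M,
    order = c("parent_call", "missingness", "indel", "maf", "heterozygosity"),
    thresholds = c(parent_call_min = parent_call_min, miss_max = miss_max,
                   maf_min = maf_min, het_max = het_max)
  ), class = "filter_report")
  out <- marker_matrix(g[, keep, drop = FALSE],
                       map = if (!is.null(m$map)) m$map[keep, , drop = FALSE],
                       is_indel = m$is_indel[keep])
  list(matrix = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("marker filter:", x$input, "in,", x$retained, "retained\n")
  for (r in x$order) cat(sprintf("  dropped by %-14s %d\n", r, x[[r]]))
  invisible(x)
}

#' Simple major-allele imputation
#'
#' Replaces every missing call by the homozygous major-allele code (1). This
#' is a deliberately naive fallback; haplotype-aware imputation is out of
#' scope.
#'
#' @param m A `marker_matrix`.
#' @return The imputed `marker_matrix`. All-missing markers trigger a warning.
#' @export
impute_simple <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  g <- m$geno
  allmiss <- colSums(!is.na(g)) == 0
  if (any(allmiss))
    warning(sum(allmiss), " marker(s) with no calls imputed to the major homozygote")
  g[is.na(g)] <- 1
  m$geno <- g
  m
}

#' In-silico hybrid genotypes
#'
#' The genotype of each hybrid is the elementwise average of its two parental
#' inbred genotype rows, so (1, -1) -> 0 and (1, 1) -> 1.
#'
#' @param m A `marker_matrix` (no missing values) holding the parents.
#' @param pedigree Data frame with columns `hybrid`, `male`, `female` naming
#'   rows of `m`.
#' @return Numeric matrix, hybrids x markers.
#' @export
hybrid_genotype <- function(m, pedigree) {
  stopifnot(inherits(m, "marker_matrix"))
  if (anyNA(m$geno)) stop("impute missing values before building hybrids")
  bad <- setdiff(unique(c(pedigree$male, pedigree$female)), rownames(m$geno))
  if (length(bad)) stop("pedigree parents without genotypes: ",
                        paste(bad, collapse = ", "))
  h <- (m$geno[pedigree$male, , drop = FALSE] +
          m$geno[pedigree$female, , drop = FALSE]) / 2
  rownames(h) <- pedigree$hybrid
  h
}

#' Nei's standard genetic distance between lines
#'
#' Treats each line as a population with per-marker allele frequencies derived
#' from the -1/0/1 codes (major-allele frequency 1, 0.5 or 0). For lines x
#' and y, `D = -ln( Jxy / sqrt(Jx Jy) )` with `Jxy` the mean over markers of
#' the summed allele-frequency products and `Jx`, `Jy` the within-line
#' homozygosities. Infinite distances (no shared alleles anywhere) are capped
#' at `ln(1e6)` for downstream ordination stability.
#'
#' @param m A `marker_matrix` with no missing values.
#' @return Symmetric distance matrix with zero diagonal.
#' @examples
#' m <- marker_matrix(rbind(x = c(1, 1), y = c(1, -1)))
#' nei_distance(m)["x", "y"]   # log(2)
#' @export
nei_distance <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  if (anyNA(m$geno)) stop("nei_distance requires a complete matrix; impute first")
  p <- (m$geno + 1) / 2        # per-line major-allele frequency at each marker
  q <- 1 - p
  n <- nrow(p)
  # J_xy = mean_j (p_x p_y + q_x q_y); cross-products via matrix algebra
  M <- ncol(p)
  Jxy <- (p %*% t(p) + q %*% t(q)) / M
  Jx <- diag(Jxy)
  denom <- sqrt(outer(Jx, Jx))
  ratio <- Jxy / denom
  D <- -log(pmax(ratio, 1e-6))   # cap at ln(1e6)
  D[ratio >= 1] <- 0             # numeric guard
  diag(D) <- 0
  dimnames(D) <- list(rownames(m$geno), rownames(m$geno))
  (D + t(D)) / 2
}

#' Principal coordinates of a genetic distance matrix
#'
#' Classical metric multidimensional scaling: double-centre `-d^2/2`,
#' eigendecompose, and return the top-`k` coordinates scaled by the square
#' root of the eigenvalues. Negative eigenvalues are excluded from the
#' explained-variance shares.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @param k Number of axes requested.
#' @return A list with `points` (n x k coordinates), `eig` (all eigenvalues,
#'   descending) and `var_explained` (shares over positive eigenvalues, length
#'   k).
#' @export
pcoa <- function(d, k = 2) {
  d <- as.matrix(d)
  stopifnot(isSymmetric(unname(d), tol = 1e-8), all(abs(diag(d)) < 1e-12))
  npos_max <- nrow(d) - 1L
  fit <- stats::cmdscale(stats::as.dist(d), k = min(k, npos_max), eig = TRUE)
  eig <- sort(fit$eig, decreasing = TRUE)
  npos <- sum(eig > 1e-9)
  if (k > npos) {
    warning("only ", npos, " positive eigenvalue(s); returning ", npos, " axes")
    k <- npos
  }
  pts <- as.matrix(fit$points)[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("PCo", seq_len(k))
  list(points = pts, eig = eig,
       var_explained = eig[seq_len(k)] / sum(eig[eig > 0]))
}

#' Principal components of the coded genotypes
#'
#' Alternative ordination operating directly on the -1/0/1 matrix rather than
#' the distance matrix; provided for comparison with [pcoa()].
#'
#' @param m A `marker_matrix` with no missing values.
#' @param k Number of components.
#' @return A list with `points` and `var_explained`.
#' @export
parent_pca <- function(m, k = 2) {
  stopifnot(inherits(m, "marker_matrix"))
  pc <- stats::prcomp(m$geno, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  list(points = pc$x[, seq_len(k), drop = FALSE],
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}

# ---- IO -------------------------------------------------------------------

#' Write a coded genotype matrix as CSV
#' @param m A `marker_matrix`.
#' @param path Output file.
#' @export
write_geno_csv <- function(m, path) {
  df <- data.frame(line = rownames(m$geno), m$geno, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a coded genotype matrix from CSV
#' @param path CSV with a `line` id column and one -1/0/1 column per marker.
#' @param map Optional marker map.
#' @return A `marker_matrix`.
#' @export
read_geno_csv <- function(path, map = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  g <- as.matrix(df[, -1, drop = FALSE])
  rownames(g) <- df[[1]]
  marker_matrix(g, map = map)
}

#' Write genotypes as a minimal VCF
#'
#' One diploid sample per line; the major allele is REF. Codes 1/0/-1 map to
#' GT 0/0, 0/1 and 1/1; NA to "./.".
#'
#' @param m A `marker_matrix` (needs a map with `chrom` and `pos`).
#' @param path Output file.
#' @export
write_geno_vcf <- function(m, path) {
  map <- m$map
  if (is.null(map)) map <- data.frame(marker = colnames(m$geno),
                                      chrom = 1L, pos = seq_len(ncol(m$geno)))
  gt <- t(m$geno)
  gt_str <- matrix("./.", nrow(gt), ncol(gt))
  gt_str[!is.na(gt) & gt == 1] <- "0/0"
  gt_str[!is.na(gt) & gt == 0] <- "0/1"
  gt_str[!is.na(gt) & gt == -1] <- "1/1"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(m$geno)), collapse = "\t")), con)
  body <- cbind(map$chrom, round(map$pos * 1e4), map$marker, "A", "T", ".", ".",
                ".", "GT", gt_str)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read genotypes from a VCF into the numeric coding
#'
#' Uses vcfR to parse the GT field; allele dosages of REF are mapped to
#' 1/0/-1 with REF as the major allele. Multiallelic records are dropped with
#' a warning.
#'
#' @param path VCF file.
#' @return A `marker_matrix` with map from CHROM/POS.
#' @export
read_geno_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  multi <- grepl(",", vcfR::getALT(v))
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) dropped")
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 1
  dos[clean %in% c("0/1", "1/0")] <- 0
  dos[clean == "1/1"] <- -1
  map <- data.frame(marker = rownames(gt),
                    chrom = vcfR::getCHROM(v),
                    pos = vcfR::getPOS(v), stringsAsFactors = FALSE)
  marker_matrix(t(dos), map = map)
}
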