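# Genomic relationship kernels: VanRaden additive, classical dominance, and
# the environment-masked interaction kernels used by the multi-environment
# GBLUP model.

#' VanRaden additive relationship kernel
#'
#' Method-1 genomic relationship matrix on a -1/0/1 (or hybrid-averaged,
#' including the halves) genotype matrix: each marker is centred by its mean
#' and `K = W W' / (2 * sum_j p_j (1 - p_j))`, where `p_j` is the major-allele
#' frequency among the genotyped individuals.
#'
#' @param geno Numeric matrix, individuals x markers, no missing values.
#' @param p Optional per-marker major-allele frequencies; by default computed
#'   from the individuals entering the kernel.
#' @return Symmetric p x p kernel.
#' @examples
#' additive_kernel(matrix(c(1, -1), 2, 1))   # [[2,-2],[-2,2]]
#' @export
additive_kernel <- function(geno, p = NULL) {
  geno <- as.matrix(geno)
  if (anyNA(geno)) stop("additive_kernel requires a complete matrix")
  if (is.null(p)) p <- colMeans((geno + 1) / 2)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: additive kernel undefined")
  W <- sweep(geno, 2, 2 * p - 1)
  K <- tcrossprod(W) / denom
  (K + t(K)) / 2
}

#' Classical dominance relationship kernel
#'
#' Recodes each marker's genotype classes (major homozygote, heterozygote,
#' minor homozygote) to the classical dominance deviations
#' `(-2q^2, 2pq, -2p^2)` and scales: `K_D = H H' / sum_j (2 p_j q_j)^2`.
#' Heterozygotes are identified by the exact code 0. Fractional codes (as
#' produced by averaging parents with residual heterozygosity) are handled by
#' linear interpolation of the class codes, which reduces to the classical
#' recode at -1/0/1.
#'
#' @param geno Numeric matrix, individuals x markers, codes in \[-1, 1\].
#' @param p Optional per-marker major-allele frequencies; by default computed
#'   from the individuals entering the kernel.
#' @return Symmetric p x p kernel; all-homozygous input yields a zero kernel
#'   with a warning (no dominance information).
#' @export
dominance_kernel <- function(geno, p = NULL) {
  geno <- as.matrix(geno)
  if (anyNA(geno)) stop("dominance_kernel requires a complete matrix")
  if (any(geno < -1 | geno > 1))
    stop("dominance coding needs genotype codes in [-1, 1]")
  if (is.null(p)) p <- colMeans((geno + 1) / 2)
  q <- 1 - p
  denom <- sum((2 * p * q)^2)
  n <- nrow(geno)
  if (denom <= 0 || !any(abs(geno) < 1)) {
    warning("no heterozygous calls: dominance kernel is zero")
    return(matrix(0, n, n, dimnames = list(rownames(geno), rownames(geno))))
  }
  # class weights: P(major hom) = max(c, 0), P(minor hom) = max(-c, 0),
  # P(het) = 1 - |c|; exact for codes -1/0/1, interpolated between
  w_het <- 1 - abs(geno)
  w_maj <- pmax(geno, 0)
  w_min <- pmax(-geno, 0)
  H <- sweep(w_het, 2, 2 * p * q, `*`) +
    sweep(w_maj, 2, -2 * q^2, `*`) +
    sweep(w_min, 2, -2 * p^2, `*`)
  K <- tcrossprod(H) / denom
  (K + t(K)) / 2
}

#' 0/1 incidence matrix from a factor
#'
#' @param f Vector assigning each observation to a level.
#' @param levels Optional explicit level ordering.
#' @return n x q incidence matrix with unit row sums.
#' @export
incidence_matrix <- function(f, levels = NULL) {
  f <- as.character(f)
  if (is.null(levels)) levels <- unique(f)
  if (anyNA(match(f, levels))) stop("observations with no level assignment")
  Z <- matrix(0, length(f), length(levels),
              dimnames = list(NULL, levels))
  Z[cbind(seq_along(f), match(f, levels))] <- 1
  Z
}

#' Environment-interaction kernel
#'
#' Hadamard construction `(Z_E Z_E') * (Z_X K_X Z_X')`: the covariance between
#' observations i and j is `K_X[hyb(i), hyb(j)]` when they share an
#' environment and 0 otherwise.
#'
#' @param Z_E n x q environment incidence.
#' @param Z_X n x p genotype incidence.
#' @param K_X p x p genetic kernel.
#' @return n x n interaction kernel.
#' @export
interaction_kernel <- function(Z_E, Z_X, K_X) {
  stopifnot(nrow(Z_E) == nrow(Z_X), ncol(Z_X) == nrow(K_X))
  if (any(rowSums(Z_E) != 1)) stop("observations with no environment assignment")
  tcrossprod(Z_E) * (Z_X %*% K_X %*% t(Z_X))
}

#' Observation-level covariance of a genetic main effect
#'
#' Expands a p x p kernel to the n observations: the main effect of a hybrid
#' is shared across environments, so cov(i, j) = `K_X[hyb(i), hyb(j)]`
#' regardless of environment. Equals `Z_X K_X Z_X'`, which realizes
#' `J_q (x) K_X` under environment-sorted ordering.
#'
#' @inheritParams interaction_kernel
#' @return n x n covariance matrix.
#' @export
main_effect_expansion <- function(Z_X, K_X) {
  stopifnot(ncol(Z_X) == nrow(K_X))
  Z_X %*% K_X %*% t(Z_X)
}

#' Assemble the observation-level kernel set for the GBLUP model
#'
#' Builds main additive and dominance expansions plus the additive-by-
#' environment and dominance-by-environment interaction kernels over the
#' observation space defined by `env` and `hybrid`.
#'
#' @param env Environment id per observation.
#' @param hybrid Hybrid id per observation.
#' @param K_A Additive kernel over hybrids (dimnames required).
#' @param K_D Optional dominance kernel over hybrids.
#' @param gxe Include interaction kernels (default TRUE).
#' @return A named list of n x n kernels (`A`, and as applicable `D`, `AE`,
#'   `DE`), with attributes `env`, `hybrid`.
#' @export
kernel_set <- function(env, hybrid, K_A, K_D = NULL, gxe = TRUE) {
  ids <- rownames(K_A)
  if (is.null(ids)) stop("K_A needs hybrid ids as dimnames")
  miss <- setdiff(unique(hybrid), ids)
  if (length(miss)) stop("hybrids missing from K_A: ", paste(miss, collapse = ", "))
  Z_E <- incidence_matrix(env)
  Z_A <- incidence_matrix(hybrid, levels = ids)
  ks <- list(A = main_effect_expansion(Z_A, K_A))
  if (!is.null(K_D)) ks$D <- main_effect_expansion(Z_A, K_D)
  if (gxe) {
    ks$AE <- interaction_kernel(Z_E, Z_A, K_A)
    if (!is.null(K_D)) ks$DE <- interaction_kernel(Z_E, Z_A, K_D)
  }
  attr(ks, "env") <- as.character(env)
  attr(ks, "hybrid") <- as.character(hybrid)
  ks
}

#' Write / read a labeled kernel as CSV
#' @param K Symmetric kernel with dimnames.
#' @param path File path.
#' @export
write_kernel_csv <- function(K, path) {
  utils::write.csv(data.frame(id = rownames(K), K, check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kernel_csv
#' @export
read_kernel_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df[[1]]
  K
}
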