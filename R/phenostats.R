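# Per-environment trial adjustment: fixed-genotype BLUEs, all-random variance
# components (REML), repeatability, residual CV, and the multi-environment
# GCA model with male lines fixed.

# Keep only random terms whose factor has >= 2 levels and fewer levels than
# observations; returns a character vector of term labels like "(1|block)".
.usable_random <- function(df, factors) {
  ok <- vapply(factors, function(f) {
    nl <- length(unique(df[[f]]))
    nl >= 2 && nl < nrow(df)
  }, logical(1))
  factors[ok]
}

#' Per-environment genotype BLUEs
#'
#' Fits `trait ~ genotype + (1|block) + (1|range) + (1|row)` within one
#' environment with genotype fixed (REML for the design variance components)
#' and returns the genotype best linear unbiased estimators. Random design
#' terms with fewer than two levels are dropped with a message; with none
#' usable the model reduces to ordinary least squares. Unreplicated augmented
#' layouts stay estimable through the random design terms.
#'
#' @param records TrialTable data frame with columns `env`, `hybrid`,
#'   `block`, `range`, `row` and the trait column.
#' @param env Environment id to subset.
#' @param trait Name of the trait column.
#' @param genotype Column holding the genotype id (default `"hybrid"`).
#' @return A list of class `env_fit` with `blue` (named vector of genotype
#'   estimated means), `env_mean`, `varcomp` (design + residual variances from
#'   the fixed-genotype fit), `mse`, `n_plots`, `reps` (median plots per
#'   genotype), `env`, `trait`.
#' @export
fit_env_blues <- function(records, env, trait, genotype = "hybrid") {
  df <- records[records$env == env & !is.na(records[[trait]]), , drop = FALSE]
  if (nrow(df) == 0) stop("no data for trait ", trait, " in ", env)
  if (length(unique(df[[genotype]])) < 2)
    stop("need >= 2 genotypes with data in ", env)
  df$..g <- factor(df[[genotype]])
  df$..y <- df[[trait]]
  rterms <- .usable_random(df, intersect(c("block", "range", "row"), names(df)))
  fit <- NULL
  if (length(rterms)) {
    form <- stats::as.formula(paste("..y ~ 0 + ..g +",
                                    paste(sprintf("(1|%s)", rterms), collapse = " + ")))
    fit <- tryCatch(
      suppressWarnings(suppressMessages(lme4::lmer(form, data = df, REML = TRUE))),
      error = function(e) {
        message("mixed model failed in ", env, " (", conditionMessage(e),
                "); falling back to ordinary least squares")
        NULL
      })
  }
  if (!is.null(fit)) {
    b <- lme4::fixef(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp <- stats::setNames(vc$vcov, vc$grp)
    mse <- varcomp[["Residual"]]
  } else {
    fit <- stats::lm(..y ~ 0 + ..g, data = df)
    b <- stats::coef(fit)
    mse <- summary(fit)$sigma^2
    if (is.na(mse)) mse <- 0
    varcomp <- c(Residual = mse)
  }
  names(b) <- sub("^\\.\\.g", "", names(b))
  structure(list(blue = b, env_mean = mean(df$..y), varcomp = varcomp,
                 mse = mse, n_plots = nrow(df),
                 reps = stats::median(table(df$..g)),
                 env = env, trait = trait, model = fit),
            class = "env_fit")
}

#' @export
print.env_fit <- function(x, ...) {
  cat("env_fit:", x$env, "/", x$trait, "-", length(x$blue), "genotype BLUEs,",
      x$n_plots, "plots\n")
  cat("  env mean", signif(x$env_mean, 5), " MSE", signif(x$mse, 5),
      " repeatability",
      signif(repeatability(x$varcomp, x$mse, x$reps) %||% NA, 3), "\n")
  invisible(x)
}

#' Per-environment variance components (all factors random)
#'
#' REML fit of `trait ~ (1|genotype) + (1|block) + (1|range) + (1|row)`
#' within one environment. When genotypes are unreplicated (single plot each)
#' the genotype and residual variances are confounded; the result is then
#' flagged `identifiable = FALSE` and repeatability should be treated as
#' undefined.
#'
#' @inheritParams fit_env_blues
#' @return A list with `varcomp` (named: genotype, any usable design terms,
#'   Residual), `reps`, `identifiable`, `converged`.
#' @export
fit_env_varcomp <- function(records, env, trait, genotype = "hybrid") {
  df <- records[records$env == env & !is.na(records[[trait]]), , drop = FALSE]
  if (nrow(df) == 0) stop("no data for trait ", trait, " in ", env)
  df$..g <- factor(df[[genotype]])
  df$..y <- df[[trait]]
  reps <- stats::median(table(df$..g))
  identifiable <- any(table(df$..g) > 1)
  if (!identifiable) {
    # every genotype on a single plot: genotypic and residual variance are
    # confounded; repeatability is undefined
    return(list(varcomp = c(genotype = NA_real_, Residual = stats::var(df$..y)),
                reps = reps, identifiable = FALSE, converged = FALSE,
                env = env, trait = trait))
  }
  rterms <- .usable_random(df, intersect(c("block", "range", "row"), names(df)))
  form <- stats::as.formula(paste("..y ~ (1|..g)",
                                  if (length(rterms))
                                    paste("+", paste(sprintf("(1|%s)", rterms), collapse = " + "))
                                  else ""))
  fit <- suppressWarnings(suppressMessages(lme4::lmer(form, data = df, REML = TRUE)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- stats::setNames(vc$vcov, sub("^\\.\\.g$", "genotype", vc$grp))
  conv <- length(fit@optinfo$conv$lme4$messages %||% character()) == 0
  list(varcomp = varcomp, reps = reps, identifiable = identifiable,
       converged = conv, env = env, trait = trait)
}

#' Repeatability on an entry-mean basis
#'
#' `R = s2_g / (s2_g + s2_e / r)`, an upper bound on broad-sense heritability
#' for a trial with `r` replicate plots per genotype.
#'
#' @param s2g Genotypic variance (or a named varcomp vector containing
#'   `genotype` and `Residual`).
#' @param s2e Residual variance (ignored when `s2g` is a named vector).
#' @param r Number of replications (>= 1).
#' @return Repeatability in \[0, 1\], or NA when both variances are zero.
#' @examples
#' repeatability(2, 4, 2)   # 0.5
#' @export
repeatability <- function(s2g, s2e = NULL, r = 1) {
  if (length(s2g) > 1 && !is.null(names(s2g))) {
    s2e <- s2g[["Residual"]]
    s2g <- if ("genotype" %in% names(s2g)) s2g[["genotype"]] else return(NA_real_)
  }
  stopifnot(s2g >= 0, s2e >= 0, r >= 1)
  if (s2g + s2e == 0) return(NA_real_)
  s2g / (s2g + s2e / r)
}

#' Residual coefficient of variation
#'
#' `CVe = 100 * sqrt(MSE) / mean`, the root-mean-square error relative to the
#' trait mean, in percent — a standard experimental-quality metric.
#'
#' @param mse Residual mean square from the within-environment model.
#' @param mean Trait mean in that environment (> 0).
#' @return CVe in percent; NA when the mean is not positive.
#' @examples
#' cve(1, 10)   # 10
#' @export
cve <- function(mse, mean) {
  if (is.na(mean) || mean <= 0) return(NA_real_)
  100 * sqrt(mse) / mean
}

#' Multi-environment general combining ability of male lines
#'
#' Fits the unbalanced multi-environment testcross model with the male
#' (pollinator) line fixed and environment, nested design factors, female
#' testers and all interactions random:
#' `y ~ Mal + (1|Env) + (1|Blk:Env) + (1|Ra:Env) + (1|Ro:Env) + (1|Fem) +
#'  (1|Mal:Fem) + (1|Mal:Env) + (1|Fem:Env) + (1|Mal:Fem:Env)`.
#' The GCA of each male is its fixed-effect BLUE; each male is compared to a
#' named check by a Student's t-test on the BLUE contrast at `alpha`.
#'
#' @param records TrialTable data frame with columns `env`, `male`, `female`,
#'   `block`, `range`, `row` and the trait column.
#' @param trait Trait column name.
#' @param check Male id used as the comparison check.
#' @param alpha Per-comparison significance level (default 0.05).
#' @return A list of class `gca_fit`: `gca` data frame (male, blue, se,
#'   t vs check, p, higher/lower flags) and the fitted model.
#' @export
fit_gca_multienv <- function(records, trait, check, alpha = 0.05) {
  df <- records[!is.na(records[[trait]]), , drop = FALSE]
  if (length(unique(df$env)) < 2) stop("need >= 2 environments")
  if (!check %in% df$male) stop("check male '", check, "' has no data")
  df$..y <- df[[trait]]
  for (f in c("env", "male", "female", "block", "range", "row"))
    df[[f]] <- factor(df[[f]])
  # male first so the check is the reference level of the fixed factor
  df$male <- stats::relevel(df$male, ref = check)
  rand <- c("(1|env)", "(1|block)", "(1|range)", "(1|row)", "(1|female)",
            "(1|male:female)", "(1|male:env)", "(1|female:env)",
            "(1|male:female:env)")
  # block/range/row ids are already environment-specific labels, so plain
  # random intercepts realize the nested Blk(Env) etc. terms
  usable <- c(rand[1], sprintf("(1|%s)", .usable_random(df, c("block", "range", "row"))),
              rand[5:9])
  form <- stats::as.formula(paste("..y ~ male +", paste(usable, collapse = " + ")))
  fit <- suppressWarnings(suppressMessages(lme4::lmer(form, data = df, REML = TRUE)))
  b <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  males <- levels(df$male)
  intercept <- b[["(Intercept)"]]
  # BLUE of each male = intercept (+ its contrast); contrast vs check is the
  # male coefficient itself under treatment coding
  est <- c(0, b[paste0("male", males[-1])])
  se <- c(0, sqrt(diag(V)[paste0("male", males[-1])]))
  ndf <- nrow(df) - length(b)
  tval <- ifelse(se > 0, est / se, 0)
  pval <- 2 * stats::pt(-abs(tval), ndf)
  gca <- data.frame(male = males,
                    blue = intercept + est,
                    contrast_vs_check = est,
                    se = se,
                    t = tval, p = pval,
                    higher = est > 0 & pval <= alpha & males != check,
                    lower = est < 0 & pval <= alpha & males != check,
                    stringsAsFactors = FALSE)
  rownames(gca) <- NULL
  structure(list(gca = gca, check = check, trait = trait, alpha = alpha,
                 model = fit), class = "gca_fit")
}

#' @export
print.gca_fit <- function(x, ...) {
  cat("multi-environment GCA fit:", x$trait, "- check", x$check, "\n")
  cat(" ", nrow(x$gca), "males;", sum(x$gca$higher), "higher and",
      sum(x$gca$lower), "lower than the check at alpha =", x$alpha, "\n")
  invisible(x)
}

#' Per-environment trial quality summary
#'
#' Convenience wrapper running [fit_env_blues()] and [fit_env_varcomp()] for
#' every environment x trait combination, assembling the repeatability / CVe
#' table behind the radar-style trial-quality displays.
#'
#' @param records TrialTable data frame.
#' @param traits Character vector of trait columns.
#' @return Data frame with env, trait, env mean, MSE, reps, s2_g, s2_e,
#'   repeatability and CVe.
#' @export
trial_quality <- function(records, traits) {
  envs <- unique(records$env)
  out <- list()
  for (env in envs) for (tr in traits) {
    bl <- fit_env_blues(records, env, tr)
    vc <- fit_env_varcomp(records, env, tr)
    s2g <- if ("genotype" %in% names(vc$varcomp)) vc$varcomp[["genotype"]] else NA
    s2e <- vc$varcomp[["Residual"]]
    R <- if (vc$identifiable) repeatability(s2g, s2e, vc$reps) else NA_real_
    out[[length(out) + 1]] <- data.frame(
      env = env, trait = tr, mean = bl$env_mean, mse = bl$mse, reps = vc$reps,
      s2_g = s2g, s2_e = s2e, repeatability = R, cve = cve(bl$mse, bl$env_mean),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
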