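# Bayesian multi-kernel GBLUP via Gibbs sampling in the eigenbasis of each
# kernel. This is the package's central model fitter.

#' Eigen-prepare a kernel for sampling
#'
#' Decomposes a symmetric kernel `K = U S U'` and drops eigenvalues at or
#' below `floor`, so random effects can be sampled in the eigenbasis where
#' their full conditionals are diagonal.
#'
#' @param K Symmetric matrix.
#' @param floor Smallest retained eigenvalue (default 1e-10).
#' @return List with `U` (n x k orthonormal) and `s` (k positive eigenvalues).
#' @export
eigen_prepare <- function(K, floor = 1e-10) {
  if (max(abs(K - t(K))) > 1e-8) stop("kernel is not symmetric")
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  keep <- e$values > floor
  if (!any(keep)) stop("kernel has no positive eigenvalues")
  list(U = e$vectors[, keep, drop = FALSE], s = e$values[keep])
}

#' Fit a multi-environment Bayesian GBLUP model
#'
#' Fits `y = Z_E beta + u_A + u_D + u_AE + u_DE + e` by Gibbs sampling, where
#' the response is the vector of per-environment hybrid values (typically
#' within-environment BLUEs), `beta` holds fixed environment means (absorbing
#' the intercept), the main additive and dominance effects are shared across
#' environments with covariances `Z K_A Z' s2_A` and `Z K_D Z' s2_D`, and the
#' interaction terms use the environment-masked kernels of
#' [interaction_kernel()]. Residuals are i.i.d. normal.
#'
#' Each random vector is sampled in the eigenbasis of its observation-level
#' kernel (diagonal full conditionals). Variance components get scaled
#' inverse-chi-square full conditionals with prior degrees of freedom
#' `prior_df` and prior scales chosen so each variance's prior mean is an
#' equal share of `var(y)`; pass `fixed_varcomp` to clamp any of them.
#'
#' @param y Numeric response vector (NA entries are dropped from the fit).
#' @param env Environment id per observation.
#' @param hybrid Hybrid id per observation; must index rows of `K_A`.
#' @param K_A Additive kernel over hybrids (dimnames required).
#' @param K_D Optional dominance kernel over hybrids; NULL omits dominance.
#' @param gxe Include the environment-interaction kernels (default TRUE).
#' @param niter,burnin,thin Gibbs settings (defaults 10000 / 1000 / 2).
#' @param seed Integer seed; identical seeds give identical chains.
#' @param prior_df Prior degrees of freedom for every variance (default 5).
#' @param fixed_varcomp Optional named numeric fixing variances, e.g.
#'   `c(A = 1, e = 1)`; names among `A`, `D`, `AE`, `DE`, `e`.
#' @return An object of class `bgblup` with posterior summaries; see
#'   [predict.bgblup()], [summary.bgblup()].
#' @examples
#' K <- additive_kernel(matrix(rnorm(60) > 0, 6, 10) * 2 - 1)
#' rownames(K) <- colnames(K) <- paste0("h", 1:6)
#' y <- rnorm(12)
#' fit <- bgblup(y, rep(c("E1", "E2"), each = 6), rep(paste0("h", 1:6), 2),
#'               K, niter = 300, burnin = 50, seed = 1)
#' fit
#' @export
bgblup <- function(y, env, hybrid, K_A, K_D = NULL, gxe = TRUE,
                   niter = 10000L, burnin = 1000L, thin = 2L, seed = 1L,
                   prior_df = 5, fixed_varcomp = NULL) {
  cl <- match.call()
  env <- as.character(env); hybrid <- as.character(hybrid)
  stopifnot(length(y) == length(env), length(y) == length(hybrid),
            niter > burnin, thin >= 1)
  keep_obs <- !is.na(y)
  dropped <- which(!keep_obs)
  y_fit <- y[keep_obs]; env_fit <- env[keep_obs]; hyb_fit <- hybrid[keep_obs]
  n <- length(y_fit)
  if (n < 3) stop("need at least 3 non-missing observations")

  ks <- kernel_set(env_fit, hyb_fit, K_A, K_D = K_D, gxe = gxe)
  terms <- names(ks)
  eigs <- lapply(ks, eigen_prepare)
  Z_E <- incidence_matrix(env_fit)
  envs <- colnames(Z_E)
  n_env <- colSums(Z_E)

  vy <- stats::var(y_fit)
  if (!is.finite(vy) || vy == 0) vy <- 1
  share <- vy / (length(terms) + 1)
  nu <- prior_df
  S0 <- (nu - 2) / nu * share        # prior mean nu*S0/(nu-2) = share
  fixed <- names(fixed_varcomp %||% numeric())
  bad_fixed <- setdiff(fixed, c(terms, "e"))
  if (length(bad_fixed)) stop("fixed_varcomp names not in model: ",
                              paste(bad_fixed, collapse = ", "))

  n_keep <- floor((niter - burnin) / thin)
  vc_draws <- matrix(NA_real_, n_keep, length(terms) + 1,
                     dimnames = list(NULL, c(terms, "e")))
  beta_draws <- matrix(NA_real_, n_keep, length(envs),
                       dimnames = list(NULL, envs))
  u_mean <- stats::setNames(rep(list(numeric(n)), length(terms)), terms)
  alpha_mean <- lapply(eigs, function(eg) numeric(length(eg$s)))

  .with_seed(seed, {
    # initial values
    s2 <- stats::setNames(rep(share, length(terms) + 1), c(terms, "e"))
    for (nm in fixed) s2[nm] <- fixed_varcomp[[nm]]
    alpha <- lapply(eigs, function(eg) numeric(length(eg$s)))
    u <- stats::setNames(rep(list(numeric(n)), length(terms)), terms)
    beta <- stats::setNames(tapply(y_fit, factor(env_fit, levels = envs), mean), envs)
    e <- y_fit - beta[env_fit] - Reduce(`+`, u, numeric(n))
    kept <- 0L

    for (it in seq_len(niter)) {
      # fixed environment means
      resid_env <- e + beta[env_fit]
      mu_b <- tapply(resid_env, factor(env_fit, levels = envs), mean)
      beta_new <- mu_b + stats::rnorm(length(envs)) * sqrt(s2[["e"]] / n_env)
      e <- e + (beta - beta_new)[env_fit]
      beta <- stats::setNames(as.numeric(beta_new), envs)

      # random effects, one kernel term at a time, in the eigenbasis
      for (t in terms) {
        eg <- eigs[[t]]
        et <- e + u[[t]]
        proj <- crossprod(eg$U, et)           # k x 1
        d <- 1 / s2[["e"]] + 1 / (eg$s * s2[[t]])
        m <- (proj / s2[["e"]]) / d
        a <- m + stats::rnorm(length(d)) / sqrt(d)
        alpha[[t]] <- a
        u_new <- drop(eg$U %*% a)
        e <- et - u_new
        u[[t]] <- u_new
        if (!(t %in% fixed)) {
          ssq <- sum(a^2 / eg$s)
          s2[t] <- (ssq + nu * S0) / stats::rchisq(1L, length(a) + nu)
        }
      }
      if (!("e" %in% fixed))
        s2["e"] <- (sum(e^2) + nu * S0) / stats::rchisq(1L, n + nu)
      if (any(!is.finite(s2)) || any(s2 > 1e12))
        stop("variance draw diverged at iteration ", it,
             " (s2 = ", paste(signif(s2, 3), collapse = ", "), ")")

      if (it > burnin && (it - burnin) %% thin == 0) {
        kept <- kept + 1L
        vc_draws[kept, ] <- s2
        beta_draws[kept, ] <- beta
        for (t in terms) {
          u_mean[[t]] <- u_mean[[t]] + (u[[t]] - u_mean[[t]]) / kept
          alpha_mean[[t]] <- alpha_mean[[t]] + (alpha[[t]] - alpha_mean[[t]]) / kept
        }
      }
    }

    beta_hat <- colMeans(beta_draws)
    fitted_fit <- beta_hat[env_fit] + Reduce(`+`, u_mean, numeric(n))
    fitted <- rep(NA_real_, length(y))
    fitted[keep_obs] <- fitted_fit
    # per-hybrid genetic value: main additive + dominance posterior means
    main_terms <- intersect(c("A", "D"), terms)
    gmain <- Reduce(`+`, u_mean[main_terms], numeric(n))
    gv <- tapply(gmain, hyb_fit, mean)

    structure(list(
      call = cl, y = y, env = env, hybrid = hybrid, dropped = dropped,
      terms = terms, K_A = K_A, K_D = K_D, gxe = gxe,
      eigs = eigs, alpha_mean = alpha_mean, u_mean = u_mean,
      beta = beta_hat, beta_draws = beta_draws,
      varcomp = colMeans(vc_draws), vc_draws = vc_draws,
      fixed_varcomp = fixed_varcomp, prior = list(df = nu, scale = S0),
      fitted.values = fitted, genetic_value = gv,
      settings = list(niter = niter, burnin = burnin, thin = thin, seed = seed),
      train_env = env_fit, train_hybrid = hyb_fit
    ), class = "bgblup")
  })
}

#' @export
print.bgblup <- function(x, ...) {
  cat("Bayesian multi-kernel GBLUP fit\n")
  cat("  observations:", length(x$train_env), " environments:",
      length(unique(x$train_env)), " hybrids:", length(unique(x$train_hybrid)), "\n")
  cat("  kernels:", paste(x$terms, collapse = " + "), "\n")
  cat("  Gibbs: ", x$settings$niter, " iterations, burn-in ",
      x$settings$burnin, ", thin ", x$settings$thin, "\n", sep = "")
  cat("  posterior mean variance components:\n")
  print(round(x$varcomp, 4))
  invisible(x)
}

#' Summarize a Bayesian GBLUP fit
#'
#' @param object A `bgblup` fit.
#' @param ... Unused.
#' @return A list with posterior summaries of the variance components and
#'   environment means, printed as a table.
#' @export
summary.bgblup <- function(object, ...) {
  qs <- t(apply(object$vc_draws, 2, stats::quantile, c(0.025, 0.5, 0.975)))
  vc <- cbind(mean = object$varcomp, sd = apply(object$vc_draws, 2, stats::sd), qs)
  out <- list(varcomp = vc, beta = object$beta,
              settings = object$settings, terms = object$terms)
  class(out) <- "summary.bgblup"
  out
}

#' @export
print.summary.bgblup <- function(x, ...) {
  cat("Variance components (posterior):\n")
  print(round(x$varcomp, 4))
  cat("\nEnvironment means (posterior mean):\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
coef.bgblup <- function(object, ...) object$beta

#' @export
fitted.bgblup <- function(object, ...) object$fitted.values

#' @export
residuals.bgblup <- function(object, ...) object$y - object$fitted.values

#' Trace plots of the variance-component chains
#' @param x A `bgblup` fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.bgblup <- function(x, ...) {
  graphics::matplot(x$vc_draws, type = "l", lty = 1,
                    xlab = "thinned iteration", ylab = "variance draw", ...)
  graphics::legend("topright", colnames(x$vc_draws), col = seq_len(ncol(x$vc_draws)),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Predict hybrid performance for new observations
#'
#' Predicts `env` x `hybrid` combinations from the posterior means: the fixed
#' environment mean plus each kernel term's conditional expectation
#' `K_cross K_train^+ u_hat`, where the cross-covariance follows the same
#' main-effect / environment-masked construction used in fitting. Hybrids
#' never phenotyped borrow information purely through the kernel covariances;
#' they must be present in `K_A` (genotyped).
#'
#' @param object A `bgblup` fit.
#' @param newdata Data frame with columns `env` and `hybrid`. Default: the
#'   fit's own observations (returns fitted values).
#' @param ... Unused.
#' @return Numeric vector of predictions, one per row of `newdata`.
#' @export
predict.bgblup <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(object$fitted.values)
  env_new <- as.character(newdata$env)
  hyb_new <- as.character(newdata$hybrid)
  ids <- rownames(object$K_A)
  miss <- setdiff(hyb_new, ids)
  if (length(miss)) stop("target hybrids missing from the kernels: ",
                         paste(unique(miss), collapse = ", "))
  bad_env <- setdiff(env_new, names(object$beta))
  if (length(bad_env)) stop("environments not in the fit: ",
                            paste(unique(bad_env), collapse = ", "))
  pred <- object$beta[env_new]
  tr_hyb <- object$train_hybrid
  tr_env <- object$train_env
  for (t in object$terms) {
    eg <- object$eigs[[t]]
    # dual weights: K_train^+ u_hat in the retained eigenspace
    w <- drop(eg$U %*% (object$alpha_mean[[t]] / eg$s))
    Kp <- if (t %in% c("A", "AE")) object$K_A else object$K_D
    Kcross <- Kp[hyb_new, tr_hyb, drop = FALSE]
    if (t %in% c("AE", "DE"))
      Kcross <- Kcross * outer(env_new, tr_env, `==`)
    pred <- pred + drop(Kcross %*% w)
  }
  unname(pred)
}
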