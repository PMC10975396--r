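# Family-representation cross-validation (CV0-CV7): training sets built from
# core families + checks + k lines per remaining family, 50-repeat accuracy
# estimation and Tukey HSD comparison of schemes.

#' Build one family-representation CV scheme
#'
#' Training lines are: all lines of the core families, all check lines, and
#' `k` randomly selected lines from every remaining family (families with
#' fewer than `k` lines contribute all of them). Validation is every other
#' line; all hybrids of a line move together, so the split never leaks a line
#' across sets.
#'
#' @param families Named character vector mapping line id -> family id.
#' @param k Lines per non-core family added to training (0 gives CV0).
#' @param core_families Families fully in training (default `c("22", "48")`).
#' @param checks Character vector of check line ids always in training.
#' @param seed Integer seed.
#' @param repeat_id Repeat index; folded into the seed so each repeat draws a
#'   different selection while staying reproducible.
#' @return A list of class `cv_scheme` with `training`, `validation` (line
#'   ids), `scheme` (e.g. "CV2"), `k`, `repeat_id`, `seed`.
#' @export
build_scheme <- function(families, k, core_families = c("22", "48"),
                         checks = character(), seed = 1L, repeat_id = 1L) {
  if (k < 0) stop("k must be >= 0")
  lines <- names(families)
  if (is.null(lines)) stop("families must be a named vector (line -> family)")
  core <- lines[families %in% core_families]
  rest <- setdiff(lines, c(core, checks))
  fam_rest <- split(rest, families[rest])
  picked <- if (k == 0) character() else .with_seed(seed + 1009L * repeat_id, {
    unlist(lapply(fam_rest, function(ls) {
      if (length(ls) <= k) ls else sample(ls, k)
    }), use.names = FALSE)
  })
  training <- unique(c(core, checks, picked))
  validation <- setdiff(lines, training)
  if (!length(validation))
    stop("validation set is empty: every line is in training")
  structure(list(training = training, validation = validation,
                 scheme = paste0("CV", k), k = k,
                 repeat_id = repeat_id, seed = seed),
            class = "cv_scheme")
}

#' @export
print.cv_scheme <- function(x, ...) {
  cat(x$scheme, "(repeat", x$repeat_id, "):", length(x$training),
      "training lines,", length(x$validation), "validation lines\n")
  invisible(x)
}

#' Prediction accuracy
#'
#' Pearson correlation between predicted and observed values of the
#' validation observations, pooled within trait.
#'
#' @param pred,obs Numeric vectors of equal length (>= 3 pairs).
#' @return Correlation in \[-1, 1\]; NA with a warning when either side has
#'   zero variance.
#' @export
accuracy <- function(pred, obs) {
  ok <- !is.na(pred) & !is.na(obs)
  if (sum(ok) < 3) stop("need >= 3 paired values")
  if (stats::sd(pred[ok]) == 0 || stats::sd(obs[ok]) == 0) {
    warning("zero variance: accuracy undefined")
    return(NA_real_)
  }
  stats::cor(pred[ok], obs[ok])
}

#' Run the family-representation CV ladder
#'
#' For each trait, scheme and repeat: build the line split, fit [bgblup()] on
#' the training observations, predict the validation observations, and record
#' the pooled Pearson accuracy.
#'
#' @param blues Data frame of per-environment response values with columns
#'   `env`, `hybrid`, `male` (the line) and one column per trait.
#' @param K_A,K_D Kernels over all hybrids (computed once; sub-indexed per
#'   split).
#' @param families Named vector line -> family.
#' @param traits Character vector of trait columns in `blues`.
#' @param k_values Integer vector of schemes to run (default 0:7).
#' @param repeats Repeats per scheme (default 50).
#' @param core_families,checks Passed to [build_scheme()].
#' @param seed Master seed.
#' @param gxe,niter,burnin,thin Passed to [bgblup()].
#' @return A data frame of class `accuracy_table`: trait, scheme, k, repeat,
#'   r, n_valid.
#' @export
run_cv <- function(blues, K_A, K_D = NULL, families, traits,
                   k_values = 0:7, repeats = 50L,
                   core_families = c("22", "48"), checks = character(),
                   seed = 1L, gxe = TRUE,
                   niter = 2000L, burnin = 500L, thin = 2L) {
  res <- list()
  for (k in k_values) for (rep_i in seq_len(repeats)) {
    sch <- build_scheme(families, k, core_families = core_families,
                        checks = checks, seed = seed, repeat_id = rep_i + 100L * k)
    tr_rows <- blues$male %in% sch$training
    va_rows <- blues$male %in% sch$validation
    for (trt in traits) {
      fit <- tryCatch(
        bgblup(blues[[trt]][tr_rows], blues$env[tr_rows], blues$hybrid[tr_rows],
               K_A = K_A, K_D = K_D, gxe = gxe,
               niter = niter, burnin = burnin, thin = thin,
               seed = seed + 7919L * rep_i + 13L * k),
        error = function(e) {
          warning("fit failed (", trt, ", CV", k, ", repeat ", rep_i, "): ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(fit)) next
      pr <- predict(fit, newdata = blues[va_rows, c("env", "hybrid")])
      res[[length(res) + 1]] <- data.frame(
        trait = trt, scheme = paste0("CV", k), k = k, rep = rep_i,
        r = accuracy(pr, blues[[trt]][va_rows]), n_valid = sum(va_rows),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("accuracy_table", "data.frame")
  out
}

#' Tukey HSD comparison of CV schemes
#'
#' One-way layout of accuracies over schemes with repeats as replicates.
#' Uses the studentized range distribution with the Tukey-Kramer adjustment
#' for unequal repeat counts, and flags every scheme whose mean is not
#' significantly below the best scheme's mean.
#'
#' @param acc An `accuracy_table` from [run_cv()].
#' @param trait Trait to compare.
#' @param alpha Familywise level (default 0.05).
#' @return Data frame: scheme, mean accuracy, n, and `top_group` (TRUE for
#'   schemes statistically indistinguishable from the best), ordered by mean,
#'   with the critical studentized range in attribute `q_crit`.
#' @export
tukey_hsd <- function(acc, trait, alpha = 0.05) {
  d <- acc[acc$trait == trait & !is.na(acc$r), , drop = FALSE]
  schemes <- unique(d$scheme)
  if (length(schemes) < 2) stop("need >= 2 schemes")
  if (min(table(d$scheme)) < 2) stop("need >= 2 repeats per scheme")
  means <- tapply(d$r, d$scheme, mean)
  ns <- tapply(d$r, d$scheme, length)
  ss <- sum(tapply(d$r, d$scheme, function(x) sum((x - mean(x))^2)))
  df_err <- nrow(d) - length(schemes)
  s2 <- ss / df_err
  qcrit <- stats::qtukey(1 - alpha, length(schemes), df_err)
  best <- names(which.max(means))
  # Tukey-Kramer: compare each scheme to the best at its pairwise SE
  se_pair <- sqrt(s2 / 2 * (1 / ns + 1 / ns[[best]]))
  top <- (means[[best]] - means) <= qcrit * se_pair
  out <- data.frame(scheme = names(means), mean_r = as.numeric(means),
                    n = as.numeric(ns), top_group = as.logical(top),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_r), ]
  rownames(out) <- NULL
  attr(out, "q_crit") <- qcrit
  attr(out, "s2_within") <- s2
  out
}

#' Summarize an accuracy table
#' @param object An `accuracy_table`.
#' @param ... Unused.
#' @return Data frame of mean/sd accuracy per trait x scheme.
#' @export
summary.accuracy_table <- function(object, ...) {
  agg <- stats::aggregate(r ~ trait + scheme + k, data = object,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x),
                                              n = length(x)))
  out <- do.call(data.frame, agg)
  names(out) <- c("trait", "scheme", "k", "mean_r", "sd_r", "n")
  out[order(out$trait, out$k), ]
}
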