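# Saturated and independence (baseline) reference models, fitted by FIML
# so that likelihood-ratio statistics and incremental fit indices remain
# comparable under missing data.

# Saturated model for one group: unstructured mean vector and covariance
# matrix over the group's observed variables, parameterized through the
# Cholesky factor (log-diagonal) for unconstrained optimization. With a
# single complete-data pattern the closed-form ML moments are used
# directly.
.fit_saturated_group <- function(patterns, control = list()) {
  idx_all <- sort(unique(unlist(lapply(patterns, `[[`, "idx"))))
  k <- length(idx_all)
  # remap pattern indices into the observed set
  pats <- lapply(patterns, function(p) {
    list(zyg = p$zyg, idx = match(p$idx, idx_all), n = p$n, mean = p$mean,
         scatter = p$scatter)
  })
  n_tot <- sum(vapply(pats, `[[`, numeric(1), "n"))
  if (length(pats) == 1L && length(pats[[1]]$idx) == k) {
    mu <- pats[[1]]$mean
    S <- pats[[1]]$scatter
    ll <- -cpp_mvn_negll(mu, S, pats)
    return(list(mean = mu, cov = S, vars = idx_all,
                loglik = ll, n_free = k + k * (k + 1) / 2,
                converged = TRUE))
  }
  # starting values: per-variable moments, pairwise covariances floored to
  # positive definiteness
  mu0 <- numeric(k); v0 <- numeric(k)
  for (j in seq_len(k)) {
    ms <- unlist(lapply(pats, function(p) {
      pos <- match(j, p$idx)
      if (is.na(pos)) NULL else c(p$n, p$mean[pos],
                                  p$scatter[pos, pos] + p$mean[pos]^2)
    }))
    if (is.null(ms)) { mu0[j] <- 0; v0[j] <- 1; next }
    m3 <- matrix(ms, ncol = 3, byrow = TRUE)
    n_j <- sum(m3[, 1])
    mu0[j] <- sum(m3[, 1] * m3[, 2]) / n_j
    v0[j] <- max(sum(m3[, 1] * m3[, 3]) / n_j - mu0[j]^2, 1e-4)
  }
  S0 <- diag(v0, k)
  ee <- eigen(S0, symmetric = TRUE)
  S0 <- ee$vectors %*% diag(pmax(ee$values, 1e-4 * max(ee$values)), k) %*%
    t(ee$vectors)
  L0 <- t(chol(S0))
  th0 <- c(mu0, log(diag(L0)), L0[lower.tri(L0)])
  build <- function(th) {
    mu <- th[seq_len(k)]
    L <- diag(exp(th[k + seq_len(k)]), k)
    L[lower.tri(L)] <- th[-(seq_len(2 * k))]
    list(mu = mu, S = L %*% t(L))
  }
  obj <- function(th) {
    mS <- build(th)
    cpp_mvn_negll(mS$mu, mS$S, pats)
  }
  ctrl <- modifyList(list(iter.max = 1000L, eval.max = 3000L), control)
  ans <- nlminb(th0, obj,
                lower = c(rep(-1e6, k), rep(-15, k),
                          rep(-1e4, k * (k - 1) / 2)),
                upper = c(rep(1e6, k), rep(15, k),
                          rep(1e4, k * (k - 1) / 2)),
                control = ctrl)
  mS <- build(ans$par)
  list(mean = mS$mu, cov = mS$S, vars = idx_all, loglik = -ans$objective,
       n_free = k + k * (k + 1) / 2, converged = ans$convergence == 0L)
}

#' Fit the saturated model by FIML
#'
#' Unstructured per-zygosity-group mean vector and covariance matrix, with
#' no cross-group constraints; the reference model for likelihood-ratio
#' fit testing. Variables never observed in a group are excluded from that
#' group's parameterization and its free-parameter count is reduced
#' accordingly. For two groups of complete six-variable data the count is
#' `2 * (6 + 21) = 54`; when MZ twin PGS are exact duplicates (shared
#' genotypes) the degenerate entry is excluded from the MZ group, giving
#' `(5 + 15) + (6 + 21) = 47`.
#'
#' @inheritParams fit_transmission
#' @param control Control list for [stats::nlminb()] (used only for groups
#'   with genuinely incomplete data; complete groups have a closed form).
#' @return A `pgs_fit` whose `params` element is a per-group list with
#'   `mean`, `cov` and the indices of the observed variables.
#' @export
fit_saturated <- function(records, control = list()) {
  records <- validate_family_records(records)
  ps <- pattern_stats(records, keep_rows = FALSE)
  groups <- list(MZ = Filter(function(p) p$zyg == 0L, ps$patterns),
                 DZ = Filter(function(p) p$zyg == 1L, ps$patterns))
  groups <- Filter(function(g) length(g) > 0, groups)
  fits <- lapply(groups, .fit_saturated_group, control = control)
  structure(list(
    model = "saturated",
    params = fits,
    loglik = sum(vapply(fits, `[[`, numeric(1), "loglik")),
    n_free = as.integer(sum(vapply(fits, `[[`, numeric(1), "n_free"))),
    n_families = ps$n_families, n_mz = ps$n_mz, n_dz = ps$n_dz,
    converged = all(vapply(fits, `[[`, logical(1), "converged")),
    gradient_norm = NA_real_, boundary = FALSE,
    per_family_loglik = NULL,
    data_hash = ps$hash), class = "pgs_fit")
}

#' Fit the independence (baseline) model by FIML
#'
#' Free means and variances per variable and group, all covariances fixed
#' at zero. Because the likelihood then factorizes over variables, the ML
#' solution is the per-variable observed mean and ML (divisor n) variance
#' within each group; required as the null reference for CFI and TLI.
#'
#' @inheritParams fit_transmission
#' @return A `pgs_fit` whose `params` element holds per-group mean and
#'   variance vectors.
#' @export
fit_baseline <- function(records) {
  records <- validate_family_records(records)
  ps <- pattern_stats(records, keep_rows = FALSE)
  out <- list()
  ll <- 0; n_free <- 0L
  for (z in c("MZ", "DZ")) {
    zi <- if (z == "MZ") 0L else 1L
    pats <- Filter(function(p) p$zyg == zi, ps$patterns)
    if (!length(pats)) next
    means <- vars <- rep(NA_real_, 6)
    for (j in seq_len(6)) {
      # pool sufficient statistics for variable j over this group's
      # patterns (the independence likelihood factorizes per variable)
      agg <- c(n = 0, sx = 0, sxx = 0)
      for (p in pats) {
        pos <- match(j, p$idx)
        if (is.na(pos)) next
        agg <- agg + c(p$n, p$n * p$mean[pos],
                       p$n * (p$scatter[pos, pos] + p$mean[pos]^2))
      }
      if (agg["n"] == 0) next
      m <- agg[["sx"]] / agg[["n"]]
      v <- max(agg[["sxx"]] / agg[["n"]] - m^2, 0)
      means[j] <- m; vars[j] <- v
      ll <- ll - 0.5 * agg[["n"]] * (log(2 * pi) + log(v) + 1)
      n_free <- n_free + 2L
    }
    out[[z]] <- list(mean = setNames(means, .obs_vars),
                     var = setNames(vars, .obs_vars))
  }
  structure(list(
    model = "baseline", params = out, loglik = ll, n_free = n_free,
    n_families = ps$n_families, n_mz = ps$n_mz, n_dz = ps$n_dz,
    converged = TRUE, gradient_norm = NA_real_, boundary = FALSE,
    per_family_loglik = NULL, data_hash = ps$hash), class = "pgs_fit")
}

#' Likelihood-ratio test between nested FIML fits
#'
#' Computes `2 * (loglik_full - loglik_reduced)`, clamped at zero (tiny
#' negative or positive values below `tol`, which arise from optimizer
#' noise, are reported as exactly 0 with p = 1), with degrees of freedom
#' equal to the difference in free-parameter counts and the p-value from
#' the upper tail of the chi-square distribution.
#'
#' @param full,reduced `pgs_fit` objects on the same data, `reduced` nested
#'   in `full`.
#' @param tol Clamp threshold for the statistic (default 0.01).
#' @return An object of class `pgs_lrt`: list with `statistic`, `df`,
#'   `p_value`.
#' @examples
#' fam <- simulate_families(100, 150, study_params(), seed = 2)
#' lr_test(fit_transmission(fam), fit_no_nurture(fam))
#' @export
lr_test <- function(full, reduced, tol = 0.01) {
  stopifnot(inherits(full, "pgs_fit"), inherits(reduced, "pgs_fit"))
  if (reduced$n_free >= full$n_free)
    stop("'reduced' must have fewer free parameters than 'full'")
  if (!identical(full$data_hash, reduced$data_hash) ||
      full$n_families != reduced$n_families)
    stop("fits were not computed on the same data")
  stat <- 2 * (full$loglik - reduced$loglik)
  if (stat < tol) stat <- 0
  df <- full$n_free - reduced$n_free
  p <- if (stat == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p),
            class = "pgs_lrt")
}

#' @export
print.pgs_lrt <- function(x, ...) {
  cat(sprintf("LRT: chi-square = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' SEM fit indices against saturated and baseline models
#'
#' Computes the usual incremental and absolute fit indices from FIML
#' log-likelihoods: with `chisq_t = 2 * (loglik_sat - loglik_target)` and
#' `df_t` the free-parameter difference (likewise `_b` for the baseline),
#' `CFI = 1 - max(chisq_t - df_t, 0) / max(chisq_b - df_b, chisq_t - df_t, 0)`,
#' `TLI = ((chisq_b/df_b) - (chisq_t/df_t)) / ((chisq_b/df_b) - 1)`, and
#' `RMSEA = sqrt(max(chisq_t - df_t, 0) / (df_t * n))` with `n` the number
#' of families (the independent sampling units of the likelihood).
#'
#' @param target,saturated,baseline `pgs_fit` objects on the same data.
#' @return An object of class `pgs_fit_indices`: list with `cfi`, `tli`,
#'   `rmsea`, `chisq`, `df`. All indices are `NA` when `df_t <= 0`.
#' @export
fit_indices <- function(target, saturated, baseline) {
  for (f in list(target, saturated, baseline))
    stopifnot(inherits(f, "pgs_fit"))
  if (!identical(target$data_hash, saturated$data_hash) ||
      !identical(target$data_hash, baseline$data_hash))
    stop("fits were not computed on the same data")
  chisq_t <- max(2 * (saturated$loglik - target$loglik), 0)
  df_t <- saturated$n_free - target$n_free
  chisq_b <- max(2 * (saturated$loglik - baseline$loglik), 0)
  df_b <- saturated$n_free - baseline$n_free
  if (df_t <= 0) {
    warning("non-positive target degrees of freedom; indices undefined")
    return(structure(list(cfi = NA_real_, tli = NA_real_, rmsea = NA_real_,
                          chisq = chisq_t, df = df_t),
                     class = "pgs_fit_indices"))
  }
  num <- max(chisq_t - df_t, 0)
  den <- max(chisq_b - df_b, chisq_t - df_t, 0)
  cfi <- if (den == 0) 1 else max(0, min(1, 1 - num / den))
  tli <- if (df_b > 0 && (chisq_b / df_b) != 1)
    ((chisq_b / df_b) - (chisq_t / df_t)) / ((chisq_b / df_b) - 1)
  else NA_real_
  rmsea <- sqrt(max(chisq_t - df_t, 0) / (df_t * target$n_families))
  structure(list(cfi = cfi, tli = tli, rmsea = rmsea,
                 chisq = chisq_t, df = df_t),
            class = "pgs_fit_indices")
}

#' @export
print.pgs_fit_indices <- function(x, ...) {
  cat(sprintf("chi-square = %.3f (df = %d), CFI = %.3f, TLI = %.3f, RMSEA = %.3f\n",
              x$chisq, x$df, x$cfi, x$tli, x$rmsea))
  invisible(x)
}
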