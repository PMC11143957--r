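#' Family-level nonparametric bootstrap for the transmission model
#'
#' Resamples families with replacement, stratified by zygosity (the MZ and
#' DZ counts of the original data are preserved in every replicate), refits
#' the transmission model on each replicate starting from the base-fit
#' estimates (with one jittered fallback start), and collects the
#' standardized effects and variance-decomposition quantities. Percentile
#' confidence intervals are formed at each requested level and a quantity
#' is flagged significant at a level when its interval excludes zero.
#'
#' The default 10,000 replications and the level pair 95% / 99.2% follow
#' the convention of testing three PGS effects by two PGS (Bonferroni
#' `1 - 0.05/6`, see [multiplicity_level()]).
#'
#' Reproducible bit-for-bit given `(seed, n_reps, data)`: all resampling
#' indices are pre-drawn from the seed, so the result is also independent
#' of `jobs`.
#'
#' @param records Family records.
#' @param n_reps Number of bootstrap replicates (default 10000).
#' @param levels Confidence levels (default `c(0.95, 0.992)`).
#' @param seed Integer seed for the resampling stream.
#' @param base_fit Optional converged [fit_transmission()] fit of
#'   `records`; computed if missing.
#' @param jobs Parallel workers via `parallel::mclapply` (default 1;
#'   results are identical for any value).
#' @param keep_samples Keep the replicate-level estimates matrix.
#' @return An object of class `pgs_bootstrap`: list with `n_reps`,
#'   `levels`, `intervals` (per level, a matrix with `lower`/`upper` rows),
#'   `significant` (per level, logical), `estimate` (base-fit quantities),
#'   `n_failed`, `seed`, and optionally `samples`.
#' @examples
#' fam <- simulate_families(80, 120, study_params(), seed = 3)
#' bt <- bootstrap_transmission(fam, n_reps = 50, seed = 1)
#' bt
#' @export
bootstrap_transmission <- function(records, n_reps = 10000,
                                   levels = c(0.95, 0.992), seed = 1,
                                   base_fit = NULL, jobs = 1L,
                                   keep_samples = TRUE) {
  records <- validate_family_records(records)
  stopifnot(n_reps >= 2, all(levels > 0 & levels < 1))
  base_fit <- base_fit %||% fit_transmission(records, per_family = FALSE)
  if (!base_fit$converged)
    warning("base fit did not converge; bootstrap may be unreliable")
  theta0 <- params_to_theta(base_fit$params)

  M <- as.matrix(records[.obs_vars])
  storage.mode(M) <- "double"
  zyg01 <- ifelse(records$zygosity == "MZ", 0L, 1L)
  obs_code <- as.integer((!is.na(M)) %*% (2^(0:5))) + 64L * zyg01
  mz_rows <- which(zyg01 == 0L)
  dz_rows <- which(zyg01 == 1L)

  set.seed(seed)
  idx_mz <- if (length(mz_rows))
    matrix(mz_rows[sample.int(length(mz_rows),
                              length(mz_rows) * n_reps, replace = TRUE)],
           ncol = n_reps) else matrix(integer(), 0, n_reps)
  idx_dz <- if (length(dz_rows))
    matrix(dz_rows[sample.int(length(dz_rows),
                              length(dz_rows) * n_reps, replace = TRUE)],
           ncol = n_reps) else matrix(integer(), 0, n_reps)
  jitters <- matrix(rnorm(10L * n_reps, 0, 0.1), nrow = 10L)

  quantities <- c("g_tw_std", "g_m_std", "g_f_std",
                  "r2_total", "r2_gt", "r2_gn")
  one_rep <- function(r) {
    idx <- c(idx_mz[, r], idx_dz[, r])
    pats <- .boot_patterns(M, zyg01, obs_code, idx)
    core <- tryCatch(
      .boot_fit(pats, theta0, jitters[, r]),
      error = function(e) NULL)
    if (is.null(core) || !core$converged) return(rep(NA_real_, 6))
    d <- variance_decomposition(theta_to_params(core$theta))
    c(d$g_tw_std, d$g_m_std, d$g_f_std, d$r2_total, d$r2_gt, d$r2_gn)
  }
  reps <- if (jobs > 1L && requireNamespace("parallel", quietly = TRUE)) {
    parallel::mclapply(seq_len(n_reps), one_rep, mc.cores = jobs)
  } else {
    lapply(seq_len(n_reps), one_rep)
  }
  samples <- do.call(rbind, reps)
  colnames(samples) <- quantities
  failed <- rowSums(is.na(samples)) > 0
  n_failed <- sum(failed)
  if (n_failed > 0.2 * n_reps)
    warning("more than 20% of bootstrap replicates failed; ",
            "result flagged unreliable")
  ok <- samples[!failed, , drop = FALSE]
  intervals <- lapply(levels, function(l)
    vapply(quantities, function(q) {
      if (nrow(ok) < 2) return(c(lower = NA_real_, upper = NA_real_))
      unname(percentile_interval(ok[, q], l))
    }, c(lower = 0, upper = 0)))
  names(intervals) <- format(levels)
  significant <- lapply(intervals, function(ci)
    ci["lower", ] > 0 | ci["upper", ] < 0)
  d0 <- variance_decomposition(base_fit$params)
  estimate <- c(d0$g_tw_std, d0$g_m_std, d0$g_f_std,
                d0$r2_total, d0$r2_gt, d0$r2_gn)
  names(estimate) <- quantities
  structure(list(n_reps = n_reps, levels = levels, estimate = estimate,
                 intervals = intervals, significant = significant,
                 n_failed = n_failed, seed = seed,
                 samples = if (keep_samples) samples else NULL),
            class = "pgs_bootstrap")
}

# Pattern sufficient statistics for a resampled row index vector.
.boot_patterns <- function(M, zyg01, obs_code, idx) {
  code <- obs_code[idx]
  groups <- split(idx, code)
  lapply(groups, function(rows) {
    ob <- which(!is.na(M[rows[1], ]))
    X <- M[rows, ob, drop = FALSE]
    # same degenerate-MZ reduction as pattern_stats()
    if (zyg01[rows[1]] == 0L && all(c(3L, 4L) %in% ob)) {
      c3 <- match(3L, ob); c4 <- match(4L, ob)
      if (max(abs(X[, c3] - X[, c4])) <=
          1e-8 * (1 + max(abs(X[, c3])))) {
        ob <- ob[-c4]
        X <- X[, -c4, drop = FALSE]
      }
    }
    m <- colMeans(X)
    Xc <- sweep(X, 2, m)
    list(zyg = zyg01[rows[1]], idx = ob, n = nrow(X), mean = m,
         scatter = crossprod(Xc) / nrow(X))
  })
}

# Warm-started fit used inside the bootstrap loop: start at the base-fit
# estimates; one jittered fallback start if that fails.
.boot_fit <- function(pats, theta0, jitter) {
  obj <- function(tf) cpp_fiml_negll(tf, 1:10, theta0, pats)
  grd <- function(tf) cpp_fiml_grad(tf, 1:10, theta0, pats)
  ctrl <- list(iter.max = 300L, eval.max = 600L)
  for (attempt in 1:2) {
    st <- if (attempt == 1) theta0 else
      pmin(pmax(theta0 + jitter, .theta_lower), .theta_upper)
    ans <- tryCatch(
      nlminb(st, obj, gradient = grd, lower = .theta_lower,
             upper = .theta_upper, control = ctrl),
      error = function(e) NULL)
    if (!is.null(ans) && ans$convergence == 0L && ans$objective < 1e11)
      return(list(theta = ans$par, objective = ans$objective,
                  converged = TRUE))
  }
  list(theta = theta0, objective = NA_real_, converged = FALSE)
}

#' @export
print.pgs_bootstrap <- function(x, digits = 3, ...) {
  cat("Family-level bootstrap:", x$n_reps, "replicates,",
      x$n_failed, "failed\n")
  for (l in names(x$intervals)) {
    cat("  ", l, " intervals:\n", sep = "")
    ci <- x$intervals[[l]]
    for (q in colnames(ci))
      cat(sprintf("    %-9s %8.3f  [%8.3f; %8.3f]%s\n", q,
                  x$estimate[q], ci["lower", q], ci["upper", q],
                  if (x$significant[[l]][q]) " *" else ""))
  }
  invisible(x)
}

#' Percentile bootstrap interval
#'
#' Empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2`, linearly
#' interpolated between order statistics (the standard type-7 convention).
#' Non-finite samples are dropped with a count attached.
#'
#' @param samples Numeric vector of bootstrap estimates (at least 2
#'   finite).
#' @param level Confidence level in (0, 1).
#' @return Named vector `c(lower, upper)` with attribute `"n_dropped"`.
#' @examples
#' percentile_interval(1:100, 0.95)
#' @export
percentile_interval <- function(samples, level) {
  stopifnot(level > 0, level < 1)
  fin <- samples[is.finite(samples)]
  n_dropped <- length(samples) - length(fin)
  if (length(fin) < 2) stop("need at least 2 finite samples")
  alpha <- (1 - level) / 2
  q <- quantile(fin, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(c(lower = q[1], upper = q[2]), n_dropped = n_dropped)
}

#' Bonferroni-adjusted confidence level
#'
#' Level `1 - alpha / n_tests`, rounded to three decimals for reporting.
#' With the conventional `alpha = 0.05` and six tests (three PGS effects
#' times two PGS) this gives the 99.2% level.
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests Number of tests corrected for.
#' @return Scalar confidence level.
#' @examples
#' multiplicity_level(0.05, 6)
#' @export
multiplicity_level <- function(alpha = 0.05, n_tests = 1L) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  round(1 - alpha / n_tests, 3)
}
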