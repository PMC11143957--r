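# Model fitting: transmission model (full and no-nurture), saturated and
# independence (baseline) reference models, all by FIML.

# Box bounds on the unconstrained scale keep the optimizer away from
# degenerate regions (zero variances, |r| -> 1) while leaving generous room
# for any realistically scaled data.
.theta_lower <- c(-20, -7, -20, -7, -7, rep(-1e3, 3), rep(-1e6, 2))
.theta_upper <- c(20, 7, 20, 7, 7, rep(1e3, 3), rep(1e6, 2))

.fit_core <- function(patterns, theta_full, free_idx,
                      restarts = 2L, control = list(), jitter_sd = 0.25,
                      seed_jitter = NULL) {
  pats <- .strip_rows(patterns)
  obj <- function(tf) cpp_fiml_negll(tf, free_idx, theta_full, pats)
  grd <- function(tf) cpp_fiml_grad(tf, free_idx, theta_full, pats)
  lower <- .theta_lower[free_idx]
  upper <- .theta_upper[free_idx]
  ctrl <- modifyList(list(iter.max = 500L, eval.max = 1000L), control)
  start0 <- theta_full[free_idx]
  best <- NULL
  n_tried <- 0L
  for (r in 0:restarts) {
    st <- if (r == 0L) start0 else {
      if (!is.null(seed_jitter)) set.seed(seed_jitter + r)
      start0 + rnorm(length(start0), 0, jitter_sd)
    }
    st <- pmin(pmax(st, lower), upper)
    ans <- tryCatch(
      nlminb(st, obj, gradient = grd, lower = lower, upper = upper,
             control = ctrl),
      error = function(e) NULL)
    n_tried <- n_tried + 1L
    if (is.null(ans)) next
    if (is.null(best) || ans$objective < best$objective - 1e-9) best <- ans
    if (!is.null(best) && best$convergence == 0L && r >= 0L) break
  }
  if (is.null(best))
    stop("optimizer failed on every start")
  gnorm <- max(abs(grd(best$par)))
  at_bound <- any(abs(best$par - lower) < 1e-6 | abs(best$par - upper) < 1e-6)
  th <- theta_full
  th[free_idx] <- best$par
  list(theta = th, objective = best$objective,
       converged = best$convergence == 0L &&
         gnorm < 1e-3 * (1 + abs(best$objective)) && best$objective < 1e11,
       gradient_norm = gnorm, boundary = at_bound, n_starts = n_tried)
}

# Method-of-moments starting values from pairwise-complete sample moments.
moment_start <- function(records) {
  M <- as.matrix(records[.obs_vars])
  pgs <- as.vector(M[, 1:4])
  phe <- as.vector(M[, 5:6])
  mu_P <- mean(pgs, na.rm = TRUE)
  mu_A <- mean(phe, na.rm = TRUE)
  V <- var(pgs, na.rm = TRUE)
  VAraw <- var(phe, na.rm = TRUE)
  if (!is.finite(mu_P)) mu_P <- 0
  if (!is.finite(mu_A)) mu_A <- 0
  if (!is.finite(V) || V <= 0) V <- 1
  if (!is.finite(VAraw) || VAraw <= 0) VAraw <- 1
  clip <- function(x, lo = -0.9, hi = 0.9)
    if (is.finite(x)) min(max(x, lo), hi) else 0
  r_a <- clip(suppressWarnings(cor(M[, 1], M[, 2], use = "pairwise")))
  cor_tw_phe <- function(z) {
    r <- records$zygosity == z
    clip(suppressWarnings(cor(M[r, 5], M[r, 6], use = "pairwise")))
  }
  r_MZ <- cor_tw_phe("MZ")
  r_DZ <- cor_tw_phe("DZ")
  # g paths from pairwise-complete covariances and the implied PGS Gram
  # matrix (own twin, mother, father).
  cv <- function(i, j) {
    v <- suppressWarnings(cov(M[, i], M[, j], use = "pairwise"))
    if (is.finite(v)) v else 0
  }
  cTA <- mean(c(cv(3, 5), cv(4, 6)))
  cMA <- mean(c(cv(1, 5), cv(1, 6)))
  cFA <- mean(c(cv(2, 5), cv(2, 6)))
  cpc <- 0.5 * V * (1 + r_a)
  G <- matrix(c(V, cpc, cpc,
                cpc, V, r_a * V,
                cpc, r_a * V, V), 3, 3)
  g <- tryCatch(solve(G, c(cTA, cMA, cFA)), error = function(e) c(0, 0, 0))
  if (any(!is.finite(g))) g <- c(0, 0, 0)
  gvar <- as.numeric(t(g) %*% G %*% g)
  VA <- max(VAraw - gvar, 0.1 * VAraw)
  transmission_params(V_PGS = V, r_a = r_a, V_ADHD = VA,
                      r_MZ = r_MZ, r_DZ = r_DZ,
                      g_tw = g[1], g_m = g[2], g_f = g[3],
                      mu_PGS = mu_P, mu_ADHD = mu_A)
}

.make_fit <- function(model, params, core, ps, per_family) {
  structure(list(
    model = model,
    params = params,
    loglik = if (core$objective >= 1e11) -Inf else -core$objective,
    n_free = if (model == "transmission") 10L else 8L,
    n_families = ps$n_families,
    n_mz = ps$n_mz, n_dz = ps$n_dz,
    converged = core$converged,
    gradient_norm = core$gradient_norm,
    boundary = core$boundary,
    n_starts = core$n_starts,
    per_family_loglik = per_family,
    data_hash = ps$hash), class = "pgs_fit")
}

#' Fit the intergenerational transmission model by FIML
#'
#' Maximizes the summed per-family Gaussian log-likelihood over the ten
#' model parameters, with all parameters except the residual twin
#' correlations shared between the MZ and DZ groups and a fixed 0.5
#' transmission path from each parent's to each twin's PGS. Missing entries
#' are handled by marginalizing the implied Gaussian to each family's
#' observed sub-vector (full-information maximum likelihood); no
#' imputation. Optimization runs on an unconstrained scale (log variances,
#' atanh correlations) from method-of-moments starting values, with
#' jittered restarts on non-convergence.
#'
#' @param records Family records (validated internally; families with no
#'   observed data are dropped).
#' @param start Optional `transmission_params` starting values; default is
#'   method-of-moments.
#' @param restarts Maximum number of additional jittered starts (default
#'   2).
#' @param control Control list passed to [stats::nlminb()].
#' @param per_family Compute the per-family log-likelihood vector (default
#'   `TRUE`; turn off in tight simulation loops).
#' @return An object of class `pgs_fit` with elements `params` (the fitted
#'   [transmission_params()]), `loglik`, `n_free` (10), `n_families`,
#'   `converged`, `gradient_norm`, `boundary` (a boundary-solution flag)
#'   and `per_family_loglik`.
#' @examples
#' fam <- simulate_families(150, 250, study_params(), seed = 1)
#' fit <- fit_transmission(fam)
#' fit
#' @export
fit_transmission <- function(records, start = NULL, restarts = 2L,
                             control = list(), per_family = TRUE) {
  records <- validate_family_records(records)
  ps <- pattern_stats(records, keep_rows = per_family)
  start <- start %||% moment_start(records)
  core <- .fit_core(ps$patterns, params_to_theta(start), seq_len(10L),
                    restarts = restarts, control = control,
                    seed_jitter = NULL)
  params <- theta_to_params(core$theta)
  pf <- if (per_family) .per_family_ll(ps, params) else NULL
  .make_fit("transmission", params, core, ps, pf)
}

#' Fit the transmission model without genetic-nurture paths
#'
#' Same model as [fit_transmission()] with the parental paths fixed at
#' `g_m = g_f = 0`, leaving 8 free parameters. Comparing it to the full
#' model with [lr_test()] gives a 2-df test of genetic nurture.
#'
#' @inheritParams fit_transmission
#' @return A `pgs_fit` with `n_free = 8`.
#' @export
fit_no_nurture <- function(records, start = NULL, restarts = 2L,
                           control = list(), per_family = TRUE) {
  records <- validate_family_records(records)
  ps <- pattern_stats(records, keep_rows = per_family)
  start <- start %||% moment_start(records)
  th0 <- params_to_theta(start)
  th0[7:8] <- 0
  free_idx <- c(1:6, 9:10)
  core <- .fit_core(ps$patterns, th0, free_idx,
                    restarts = restarts, control = control)
  params <- theta_to_params(core$theta)
  pf <- if (per_family) .per_family_ll(ps, params) else NULL
  .make_fit("no_nurture", params, core, ps, pf)
}

#' @export
print.pgs_fit <- function(x, digits = 4, ...) {
  cat("FIML fit: ", x$model, " model\n", sep = "")
  cat("  families: ", x$n_families, " (", x$n_mz, " MZ, ", x$n_dz,
      " DZ)\n", sep = "")
  cat("  log-likelihood: ", format(x$loglik, digits = 10),
      "  free parameters: ", x$n_free, "\n", sep = "")
  cat("  converged: ", x$converged,
      if (isTRUE(x$boundary)) "  [boundary solution]" else "", "\n",
      sep = "")
  if (inherits(x$params, "transmission_params")) {
    print(x$params, digits = digits)
  }
  invisible(x)
}
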