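#' Simulate twin-family PGS and phenotype data
#'
#' Draws complete family records from the generative transmission model:
#' parental PGS are bivariate Gaussian with variance `V_PGS` and
#' correlation `r_a`; each twin's PGS is the mid-parent average plus a
#' Mendelian segregation deviation with variance `V_PGS * (1 - r_a) / 2`
#' (one shared deviation for MZ co-twins, independent deviations for DZ);
#' phenotype residuals are bivariate Gaussian with variance `V_ADHD` and
#' zygosity-specific correlation; and each twin's phenotype adds the three
#' PGS paths. Defaults mirror the scale of the motivating twin cohort:
#' 169 MZ and 246 DZ families with the [study_params()] parameter set.
#'
#' @param n_mz,n_dz Number of MZ and DZ families.
#' @param params Generative [transmission_params()] (default
#'   [study_params()]).
#' @param seed Optional integer seed. Missingness is injected separately by
#'   [inject_missingness()] with its own seed, so toggling missingness
#'   never changes the underlying complete data.
#' @return A data frame of complete family records.
#' @examples
#' fam <- simulate_families(5, 5, seed = 1)
#' fam
#' @export
simulate_families <- function(n_mz = 169, n_dz = 246,
                              params = study_params(), seed = NULL) {
  stopifnot(inherits(params, "transmission_params"),
            n_mz >= 0, n_dz >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- n_mz + n_dz
  zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
  V <- params$V_PGS; ra <- params$r_a; VA <- params$V_ADHD
  m <- rnorm(n, 0, sqrt(V))
  f <- ra * m + rnorm(n, 0, sqrt(V * (1 - ra^2)))
  seg_sd <- sqrt(V * (1 - ra) / 2)
  s1 <- rnorm(n, 0, seg_sd)
  s2 <- rnorm(n, 0, seg_sd)
  s2[zyg == "MZ"] <- s1[zyg == "MZ"]
  t1 <- 0.5 * (m + f) + s1
  t2 <- 0.5 * (m + f) + s2
  rz <- ifelse(zyg == "MZ", params$r_MZ, params$r_DZ)
  e1 <- rnorm(n, 0, sqrt(VA))
  e2 <- rz * e1 + sqrt(VA * (1 - rz^2)) * rnorm(n)
  lin <- function(t, e)
    params$mu_ADHD + params$g_tw * t + params$g_m * m + params$g_f * f + e
  data.frame(
    family_id = sprintf("fam%06d", seq_len(n)),
    zygosity = zyg,
    pgs_mother = m + params$mu_PGS,
    pgs_father = f + params$mu_PGS,
    pgs_twin1 = t1 + params$mu_PGS,
    pgs_twin2 = t2 + params$mu_PGS,
    pheno_twin1 = lin(t1, e1),
    pheno_twin2 = lin(t2, e2),
    stringsAsFactors = FALSE)
}

#' Inject missingness into simulated family records
#'
#' Two modes, combinable. Global-rate mode (`rate`) blanks each of the six
#' measurement cells independently with the given probability (missing
#' completely at random). Pattern mode assigns families to
#' parental-genotype patterns with fixed counts (`parent_patterns`, named
#' `both`/`one`/`none`; for `one` the blanked parent is chosen at random)
#' and optionally to twin-genotype patterns (`twin_patterns`, named
#' `both`/`one`), mirroring a cohort where a known number of families have
#' 2, 1 or 0 genotyped parents. In pattern mode, `pheno_rate` blanks
#' phenotype cells at an independent rate.
#'
#' @param records Family records.
#' @param rate Per-cell blanking probability in `[0, 1]` (global mode).
#' @param parent_patterns Named integer vector `c(both=, one=, none=)`
#'   summing to the number of families.
#' @param twin_patterns Optional named integer vector `c(both=, one=)`
#'   summing to the number of families.
#' @param pheno_rate Per-cell blanking probability for the two phenotype
#'   slots in pattern mode (default 0).
#' @param seed Optional integer seed for the missingness stream.
#' @return The records with the selected cells set to `NA`.
#' @examples
#' fam <- simulate_families(10, 10, seed = 1)
#' miss <- inject_missingness(fam, rate = 0.25, seed = 2)
#' @export
inject_missingness <- function(records, rate = NULL, parent_patterns = NULL,
                               twin_patterns = NULL, pheno_rate = 0,
                               seed = NULL) {
  records <- validate_family_records(records, drop_unusable = FALSE)
  n <- nrow(records)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(rate)) {
    stopifnot(rate >= 0, rate <= 1)
    for (v in .obs_vars)
      records[[v]][stats::runif(n) < rate] <- NA_real_
    return(records)
  }
  if (!is.null(parent_patterns)) {
    pp <- parent_patterns[c("both", "one", "none")]
    if (any(is.na(pp))) stop("parent_patterns needs counts both/one/none")
    if (sum(pp) != n)
      stop("parent_patterns counts must sum to the number of families (",
           n, ")")
    assign <- sample(rep(c("both", "one", "none"), pp))
    one_is_mother <- stats::runif(n) < 0.5
    records$pgs_mother[assign == "none"] <- NA_real_
    records$pgs_father[assign == "none"] <- NA_real_
    records$pgs_mother[assign == "one" & one_is_mother] <- NA_real_
    records$pgs_father[assign == "one" & !one_is_mother] <- NA_real_
  }
  if (!is.null(twin_patterns)) {
    tp <- twin_patterns[c("both", "one")]
    if (any(is.na(tp))) stop("twin_patterns needs counts both/one")
    if (sum(tp) != n)
      stop("twin_patterns counts must sum to the number of families")
    assign_tw <- sample(rep(c("both", "one"), tp))
    drop1 <- stats::runif(n) < 0.5
    records$pgs_twin1[assign_tw == "one" & drop1] <- NA_real_
    records$pgs_twin2[assign_tw == "one" & !drop1] <- NA_real_
  }
  if (pheno_rate > 0) {
    for (v in c("pheno_twin1", "pheno_twin2"))
      records[[v]][stats::runif(n) < pheno_rate] <- NA_real_
  }
  records
}

#' Study-scale missingness pattern counts
#'
#' The parental- and twin-genotype availability pattern counts of the
#' motivating 415-family twin cohort: 159 families with both parents
#' genotyped, 67 with one, 189 with none; 378 families with both twin
#' genotypes (counting MZ genotype sharing) and 37 with one.
#'
#' @return A list with `parent_patterns` and `twin_patterns` suitable for
#'   [inject_missingness()].
#' @export
study_missingness <- function() {
  list(parent_patterns = c(both = 159L, one = 67L, none = 189L),
       twin_patterns = c(both = 378L, one = 37L))
}

#' Simulate-and-refit parameter recovery experiment
#'
#' Repeatedly simulates datasets from known parameters, refits the
#' transmission model, and tabulates per-parameter bias, empirical SD,
#' RMSE and the Monte-Carlo standard error of the mean estimate. The
#' standardized child effect `g_tw_std` is tracked alongside the ten raw
#' parameters.
#'
#' @param n_mz,n_dz Families per group in each replicate.
#' @param params Generative truth (default [study_params()]).
#' @param n_replicates Number of simulate-fit replicates.
#' @param seed Integer seed; replicate r uses `seed + r` for the data and
#'   `seed + 500000 + r` for missingness.
#' @param missingness Optional list of arguments to [inject_missingness()].
#' @param restarts Restarts per fit (default 1 to keep large experiments
#'   fast).
#' @return An object of class `recovery_report`: data frame with one row
#'   per tracked quantity (`truth`, `mean`, `bias`, `sd`, `rmse`, `mc_se`)
#'   plus attributes `n_converged` and `n_replicates`.
#' @examples
#' rec <- recovery_experiment(100, 150, n_replicates = 5, seed = 1)
#' rec
#' @export
recovery_experiment <- function(n_mz, n_dz, params = study_params(),
                                n_replicates = 100, seed = 1,
                                missingness = NULL, restarts = 1L) {
  truth <- c(unlist(params),
             g_tw_std = unname(standardize_effects(params)["g_tw_std"]))
  est <- matrix(NA_real_, n_replicates, length(truth),
                dimnames = list(NULL, names(truth)))
  conv <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    fam <- simulate_families(n_mz, n_dz, params, seed = seed + r)
    if (!is.null(missingness))
      fam <- do.call(inject_missingness,
                     c(list(records = fam, seed = seed + 500000L + r),
                       missingness))
    fit <- fit_transmission(fam, restarts = restarts, per_family = FALSE)
    conv[r] <- fit$converged
    est[r, ] <- c(unlist(fit$params),
                  unname(standardize_effects(fit$params)["g_tw_std"]))
  }
  est_ok <- est[conv, , drop = FALSE]
  mean_est <- colMeans(est_ok)
  sds <- apply(est_ok, 2, sd)
  out <- data.frame(
    parameter = names(truth), truth = unname(truth),
    mean = unname(mean_est), bias = unname(mean_est - truth),
    sd = unname(sds),
    rmse = unname(sqrt(colMeans(sweep(est_ok, 2, truth)^2))),
    mc_se = unname(sds / sqrt(nrow(est_ok))),
    stringsAsFactors = FALSE)
  attr(out, "n_converged") <- sum(conv)
  attr(out, "n_replicates") <- n_replicates
  attr(out, "estimates") <- est
  class(out) <- c("recovery_report", "data.frame")
  out
}

#' @export
print.recovery_report <- function(x, digits = 4, ...) {
  cat("Parameter recovery over", attr(x, "n_converged"), "of",
      attr(x, "n_replicates"), "converged replicates:\n")
  print.data.frame(cbind(x["parameter"],
                         round(x[setdiff(names(x), "parameter")], digits)),
                   row.names = FALSE)
  invisible(x)
}
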