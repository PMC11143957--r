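#' Model-implied phenotype variance
#'
#' Total variance of a twin's phenotype under the transmission model:
#' `V_phen = (g_tw^2 + g_m^2 + g_f^2) V_PGS + 2 g_tw (g_m + g_f) c +
#' 2 g_m g_f r_a V_PGS + V_ADHD`, with `c = 0.5 V_PGS (1 + r_a)` the
#' parent-child PGS covariance.
#'
#' @param params A [transmission_params()] object.
#' @return Scalar implied phenotype variance.
#' @export
implied_phenotype_variance <- function(params) {
  stopifnot(inherits(params, "transmission_params"))
  V <- params$V_PGS; ra <- params$r_a
  cpc <- 0.5 * V * (1 + ra)
  with(params,
       (g_tw^2 + g_m^2 + g_f^2) * V + 2 * g_tw * (g_m + g_f) * cpc +
         2 * g_m * g_f * ra * V + V_ADHD)
}

#' Standardized PGS effects
#'
#' Rescales the raw paths to standardized effects
#' `g' = g * sqrt(V_PGS) / sqrt(V_phen)` using the model-implied (not
#' sample) variances, so the values are comparable across PGS and
#' phenotype scalings: `g'` is invariant to jointly rescaling the PGS and
#' the phenotype.
#'
#' @param params A [transmission_params()] object.
#' @return Named vector `c(g_tw_std, g_m_std, g_f_std)`.
#' @examples
#' standardize_effects(study_params())
#' @export
standardize_effects <- function(params) {
  v_phen <- implied_phenotype_variance(params)
  if (v_phen <= 0) stop("implied phenotype variance is non-positive")
  s <- sqrt(params$V_PGS / v_phen)
  c(g_tw_std = params$g_tw * s, g_m_std = params$g_m * s,
    g_f_std = params$g_f * s)
}

#' Variance decomposition into direct transmission and genetic nurture
#'
#' Splits the PGS-explained share of the phenotype variance into a direct
#' genetic transmission component and a genetic-nurture component:
#' `R2_total = (V_phen - V_ADHD) / V_phen` is the share explained by all
#' three PGS paths jointly; `R2_gt = g_tw^2 V_PGS / V_phen` is the share
#' explained after removing the direct parental-path effects (the child's
#' own path is retained, evaluated against the full-model `V_phen`); and
#' `R2_gn = R2_total - R2_gt` is everything that involves the parental
#' paths, including the child-parent cross-covariance terms. Because those
#' cross terms enter twice with the sign of `g_tw * (g_m + g_f)`, `R2_gn`
#' can be negative - a signature of negative passive gene-environment
#' correlation - in which case `R2_gt` exceeds `R2_total`.
#'
#' @param params A [transmission_params()] object.
#' @return An object of class `pgs_decomposition`: list with the
#'   standardized effects `g_tw_std`, `g_m_std`, `g_f_std`, the proportions
#'   `r2_total`, `r2_gt`, `r2_gn`, and `v_phen`.
#' @examples
#' variance_decomposition(study_params())
#' @export
variance_decomposition <- function(params) {
  v_phen <- implied_phenotype_variance(params)
  if (v_phen <= 0) stop("implied phenotype variance is non-positive")
  g <- standardize_effects(params)
  r2_total <- (v_phen - params$V_ADHD) / v_phen
  r2_gt <- params$g_tw^2 * params$V_PGS / v_phen
  structure(list(g_tw_std = unname(g["g_tw_std"]),
                 g_m_std = unname(g["g_m_std"]),
                 g_f_std = unname(g["g_f_std"]),
                 r2_total = r2_total, r2_gt = r2_gt,
                 r2_gn = r2_total - r2_gt,
                 v_phen = v_phen),
            class = "pgs_decomposition")
}

#' @export
print.pgs_decomposition <- function(x, ...) {
  cat("Standardized PGS effects:\n")
  cat(sprintf("  child g'_tw = %.3f   mother g'_m = %.3f   father g'_f = %.3f\n",
              x$g_tw_std, x$g_m_std, x$g_f_std))
  cat("Variance explained (% of phenotype variance):\n")
  cat(sprintf("  total %.1f%%   direct transmission %.1f%%   genetic nurture %.1f%%\n",
              100 * x$r2_total, 100 * x$r2_gt, 100 * x$r2_gn))
  invisible(x)
}
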