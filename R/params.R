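#' Parameters of the twin-family transmission model
#'
#' Container for the ten free parameters of the intergenerational
#' transmission model. All parameters except the residual twin phenotype
#' correlations `r_MZ` and `r_DZ` are shared between the MZ and DZ groups.
#'
#' @param V_PGS Variance of the polygenic score, shared by all family
#'   members. Must be strictly positive.
#' @param r_a Mother-father PGS correlation, absorbing assortative mating
#'   and residual population stratification. Strictly inside (-1, 1).
#' @param V_ADHD Residual variance of the phenotype score (the part not
#'   explained by the three PGS paths). Strictly positive.
#' @param r_MZ,r_DZ Residual phenotype correlation between twins in MZ and
#'   DZ families respectively. Strictly inside (-1, 1).
#' @param g_tw Regression of a twin's phenotype on their own PGS (direct
#'   genetic transmission path).
#' @param g_m,g_f Regression of a twin's phenotype on the mother's and
#'   father's PGS (genetic-nurture paths).
#' @param mu_PGS,mu_ADHD Means of the PGS and phenotype scores.
#'
#' @return An object of class `transmission_params`: a named list of the ten
#'   parameters.
#' @examples
#' p <- transmission_params(V_PGS = 1, r_a = 0.07, V_ADHD = 0.98,
#'                          r_MZ = 0.6, r_DZ = 0.3, g_tw = 0.15)
#' p
#' @export
transmission_params <- function(V_PGS = 1, r_a = 0, V_ADHD = 1,
                                r_MZ = 0, r_DZ = 0,
                                g_tw = 0, g_m = 0, g_f = 0,
                                mu_PGS = 0, mu_ADHD = 0) {
  p <- list(V_PGS = V_PGS, r_a = r_a, V_ADHD = V_ADHD,
            r_MZ = r_MZ, r_DZ = r_DZ,
            g_tw = g_tw, g_m = g_m, g_f = g_f,
            mu_PGS = mu_PGS, mu_ADHD = mu_ADHD)
  bad <- !vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                 logical(1))
  if (any(bad))
    stop("non-finite or non-scalar parameter(s): ",
         paste(names(p)[bad], collapse = ", "))
  if (p$V_PGS <= 0) stop("V_PGS must be strictly positive")
  if (p$V_ADHD <= 0) stop("V_ADHD must be strictly positive")
  for (r in c("r_a", "r_MZ", "r_DZ"))
    if (abs(p[[r]]) >= 1) stop(r, " must lie strictly inside (-1, 1)")
  structure(p, class = "transmission_params")
}

#' @export
print.transmission_params <- function(x, digits = 4, ...) {
  cat("Twin-family transmission model parameters:\n")
  v <- unlist(x)
  print(round(v, digits))
  invisible(x)
}

#' Study-scale default parameter set
#'
#' Default generative parameters used by the simulator. PGS and phenotype
#' scores are on the standardized scale (unit total variance). The direct
#' and nurture paths and the parental PGS correlation take the magnitudes
#' reported for an ADHD polygenic score predicting primary-school
#' hyperactivity in the motivating twin-family study (child path about
#' 0.16 SD, small negative parental paths, parent-parent PGS correlation
#' about 0.07); the residual twin correlations (0.6 MZ, 0.3 DZ) reflect the
#' high, largely genetic twin resemblance typical of childhood ADHD symptom
#' ratings. `V_ADHD` is set so that the implied phenotype variance is
#' exactly 1.
#'
#' @return A `transmission_params` object.
#' @examples
#' study_params()
#' @export
study_params <- function() {
  V <- 1; r_a <- 0.07
  g_tw <- 0.157; g_m <- -0.089; g_f <- -0.015
  cpc <- 0.5 * V * (1 + r_a)
  gvar <- (g_tw^2 + g_m^2 + g_f^2) * V + 2 * g_tw * (g_m + g_f) * cpc +
    2 * g_m * g_f * r_a * V
  transmission_params(V_PGS = V, r_a = r_a, V_ADHD = 1 - gvar,
                      r_MZ = 0.6, r_DZ = 0.3,
                      g_tw = g_tw, g_m = g_m, g_f = g_f,
                      mu_PGS = 0, mu_ADHD = 0)
}

# Order of the unconstrained parameter vector used by the optimizer.
.theta_names <- c("V_PGS", "r_a", "V_ADHD", "r_MZ", "r_DZ",
                  "g_tw", "g_m", "g_f", "mu_PGS", "mu_ADHD")

# Variances on the log scale, correlations on the atanh scale.
params_to_theta <- function(params) {
  stopifnot(inherits(params, "transmission_params"))
  c(log(params$V_PGS), atanh(params$r_a), log(params$V_ADHD),
    atanh(params$r_MZ), atanh(params$r_DZ),
    params$g_tw, params$g_m, params$g_f, params$mu_PGS, params$mu_ADHD)
}

theta_to_params <- function(theta) {
  stopifnot(is.numeric(theta), length(theta) == 10L)
  transmission_params(V_PGS = exp(theta[1]), r_a = tanh(theta[2]),
                      V_ADHD = exp(theta[3]), r_MZ = tanh(theta[4]),
                      r_DZ = tanh(theta[5]),
                      g_tw = theta[6], g_m = theta[7], g_f = theta[8],
                      mu_PGS = theta[9], mu_ADHD = theta[10])
}

.normalize_zygosity <- function(z) {
  zc <- toupper(trimws(as.character(z)))
  ok <- zc %in% c("MZ", "DZ")
  if (!all(ok))
    stop("unknown zygosity code(s) in row(s) ",
         paste(head(which(!ok), 5), collapse = ", "),
         ": ", paste(unique(zc[!ok]), collapse = ", "))
  zc
}
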