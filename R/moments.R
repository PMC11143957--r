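#' Model-implied moments by path-matrix algebra
#'
#' Builds the 6x6 model-implied covariance matrix and 6-vector of means for
#' one zygosity group using general path-model (RAM) algebra: an asymmetric
#' path matrix `A` holds the fixed 0.5 meiotic transmission paths from each
#' parent's PGS to each twin's PGS and the free `g` paths from the three PGS
#' to each twin phenotype; a symmetric matrix `S` holds the parental PGS
#' variances `V_PGS` and their covariance `r_a * V_PGS`, the Mendelian
#' segregation residual variance `V_PGS * (1 - r_a) / 2` (shared between MZ
#' co-twins, independent for DZ), and the phenotype residual block with
#' variance `V_ADHD` and correlation `r_MZ` or `r_DZ`. The implied
#' covariance is `(I - A)^-1 S (I - A)^-T`.
#'
#' Variable order is `(pgs_mother, pgs_father, pgs_twin1, pgs_twin2,
#' pheno_twin1, pheno_twin2)`.
#'
#' @param params A [transmission_params()] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return An object of class `implied_moments`: a list with elements
#'   `mean` (named 6-vector), `cov` (named symmetric 6x6 matrix) and
#'   `zygosity`.
#' @examples
#' m <- implied_moments(study_params(), "DZ")
#' round(cov2cor(m$cov), 3)
#' @seealso [closed_form_moments()] for the same moments from hard-coded
#'   scalar formulas (used as a mutual consistency check).
#' @export
implied_moments <- function(params, zygosity = c("MZ", "DZ")) {
  stopifnot(inherits(params, "transmission_params"))
  zygosity <- match.arg(zygosity)
  V <- params$V_PGS; ra <- params$r_a; VA <- params$V_ADHD
  rz <- if (zygosity == "MZ") params$r_MZ else params$r_DZ

  A <- matrix(0, 6, 6, dimnames = list(.obs_vars, .obs_vars))
  A["pgs_twin1", c("pgs_mother", "pgs_father")] <- 0.5
  A["pgs_twin2", c("pgs_mother", "pgs_father")] <- 0.5
  A["pheno_twin1", c("pgs_twin1", "pgs_mother", "pgs_father")] <-
    c(params$g_tw, params$g_m, params$g_f)
  A["pheno_twin2", c("pgs_twin2", "pgs_mother", "pgs_father")] <-
    c(params$g_tw, params$g_m, params$g_f)

  seg <- V * (1 - ra) / 2               # segregation residual variance
  S <- matrix(0, 6, 6, dimnames = list(.obs_vars, .obs_vars))
  S["pgs_mother", "pgs_mother"] <- V
  S["pgs_father", "pgs_father"] <- V
  S["pgs_mother", "pgs_father"] <- S["pgs_father", "pgs_mother"] <- ra * V
  S["pgs_twin1", "pgs_twin1"] <- seg
  S["pgs_twin2", "pgs_twin2"] <- seg
  if (zygosity == "MZ")
    S["pgs_twin1", "pgs_twin2"] <- S["pgs_twin2", "pgs_twin1"] <- seg
  S["pheno_twin1", "pheno_twin1"] <- VA
  S["pheno_twin2", "pheno_twin2"] <- VA
  S["pheno_twin1", "pheno_twin2"] <- S["pheno_twin2", "pheno_twin1"] <- rz * VA

  IA <- solve(diag(6) - A)
  cv <- IA %*% S %*% t(IA)
  cv <- (cv + t(cv)) / 2
  dimnames(cv) <- list(.obs_vars, .obs_vars)
  mean <- setNames(c(rep(params$mu_PGS, 4), rep(params$mu_ADHD, 2)),
                   .obs_vars)
  structure(list(mean = mean, cov = cv, zygosity = zygosity),
            class = "implied_moments")
}

#' Model-implied moments from closed-form scalar formulas
#'
#' Same contract as [implied_moments()], but each covariance entry is
#' written out as a hard-coded scalar expression with no matrix inversion:
#' `var(PGS) = V_PGS` for every member, `cov(mother, father) = r_a * V_PGS`,
#' `cov(parent, twin) = 0.5 * V_PGS * (1 + r_a)`, twin-twin PGS covariance
#' `V_PGS` (MZ) or `0.5 * V_PGS * (1 + r_a)` (DZ), and the phenotype rows by
#' substituting `pheno_i = g_tw * PGS_i + g_m * PGS_m + g_f * PGS_f + e_i`.
#' Kept deliberately independent of the path-algebra construction so the
#' two can serve as mutual oracles.
#'
#' @inheritParams implied_moments
#' @return An `implied_moments` object.
#' @export
closed_form_moments <- function(params, zygosity = c("MZ", "DZ")) {
  stopifnot(inherits(params, "transmission_params"))
  zygosity <- match.arg(zygosity)
  out <- cpp_implied_moments(params_to_theta(params),
                             if (zygosity == "MZ") 0L else 1L)
  mean <- setNames(as.numeric(out$mean), .obs_vars)
  cv <- out$cov
  dimnames(cv) <- list(.obs_vars, .obs_vars)
  structure(list(mean = mean, cov = cv, zygosity = zygosity),
            class = "implied_moments")
}

#' @export
print.implied_moments <- function(x, digits = 4, ...) {
  cat("Model-implied moments (", x$zygosity, " group)\n", sep = "")
  cat("means:\n"); print(round(x$mean, digits))
  cat("covariance:\n"); print(round(x$cov, digits))
  invisible(x)
}

#' Symbolic description of the implied covariance structure
#'
#' Returns (and prints) the implied covariance matrix of the transmission
#' model with entries written as formulas in the model parameters, for one
#' zygosity group. `c` abbreviates the parent-child PGS covariance
#' `0.5*V_PGS*(1+r_a)` and `V_phen` the implied phenotype variance.
#'
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return Invisibly, a character matrix of formulas.
#' @examples
#' describe_model("DZ")
#' @export
describe_model <- function(zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  ctt <- if (zygosity == "MZ") "V_PGS" else "c"
  rz <- if (zygosity == "MZ") "r_MZ" else "r_DZ"
  covMA <- "g_tw*c + g_m*V_PGS + g_f*r_a*V_PGS"
  covFA <- "g_tw*c + g_f*V_PGS + g_m*r_a*V_PGS"
  own <- "g_tw*V_PGS + (g_m+g_f)*c"
  co <- paste0("g_tw*", ctt, " + (g_m+g_f)*c")
  covAA <- paste0("g_tw^2*", ctt,
                  " + 2*g_tw*(g_m+g_f)*c + (g_m^2+g_f^2)*V_PGS",
                  " + 2*g_m*g_f*r_a*V_PGS + ", rz, "*V_ADHD")
  vphen <- paste0("(g_tw^2+g_m^2+g_f^2)*V_PGS + 2*g_tw*(g_m+g_f)*c",
                  " + 2*g_m*g_f*r_a*V_PGS + V_ADHD")
  M <- matrix("", 6, 6, dimnames = list(.obs_vars, .obs_vars))
  diag(M) <- c(rep("V_PGS", 4), rep("V_phen", 2))
  M["pgs_mother", "pgs_father"] <- "r_a*V_PGS"
  M["pgs_mother", c("pgs_twin1", "pgs_twin2")] <- "c"
  M["pgs_father", c("pgs_twin1", "pgs_twin2")] <- "c"
  M["pgs_twin1", "pgs_twin2"] <- ctt
  M["pgs_mother", c("pheno_twin1", "pheno_twin2")] <- covMA
  M["pgs_father", c("pheno_twin1", "pheno_twin2")] <- covFA
  M["pgs_twin1", "pheno_twin1"] <- own
  M["pgs_twin2", "pheno_twin2"] <- own
  M["pgs_twin1", "pheno_twin2"] <- co
  M["pgs_twin2", "pheno_twin1"] <- co
  M["pheno_twin1", "pheno_twin2"] <- covAA
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  diag(M)[5:6] <- vphen
  cat("Implied covariance, ", zygosity,
      " group (c = 0.5*V_PGS*(1+r_a)):\n", sep = "")
  for (i in seq_len(6)) for (j in i:6)
    cat(sprintf("  cov(%s, %s) = %s\n", .obs_vars[i], .obs_vars[j], M[i, j]))
  cat("  means: PGS -> mu_PGS, phenotype -> mu_ADHD\n")
  invisible(M)
}
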