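# Missingness-pattern bookkeeping for the FIML likelihood.
#
# Families sharing a zygosity group and an observed-variable pattern
# contribute through pattern-level sufficient statistics (n, mean, ML
# scatter), which makes one likelihood evaluation O(#patterns), not O(n).
# Identical by construction to naive per-family evaluation; the test suite
# checks this against a dense per-family oracle.

pattern_stats <- function(records, keep_rows = TRUE) {
  M <- as.matrix(records[.obs_vars])
  storage.mode(M) <- "double"
  zyg <- ifelse(records$zygosity == "MZ", 0L, 1L)
  obs <- !is.na(M)
  nobs <- rowSums(obs)
  usable <- nobs > 0
  code <- as.integer(obs %*% (2^(0:5))) + 64L * zyg
  groups <- split(which(usable), code[usable])
  patterns <- vector("list", length(groups))
  fam_pattern <- integer(nrow(M))
  for (i in seq_along(groups)) {
    rows <- groups[[i]]
    idx <- which(obs[rows[1], ])
    X <- M[rows, idx, drop = FALSE]
    # MZ co-twins carry identical genomes, so when both twin PGS are
    # observed and exactly duplicated the second entry is degenerate
    # (implied correlation 1) and carries no information: drop it from the
    # observed vector. Unequal values are kept and yield a singular-model
    # -Inf likelihood downstream.
    if (zyg[rows[1]] == 0L && all(c(3L, 4L) %in% idx)) {
      c3 <- match(3L, idx); c4 <- match(4L, idx)
      if (max(abs(X[, c3] - X[, c4])) <=
          1e-8 * (1 + max(abs(X[, c3])))) {
        idx <- idx[-c4]
        X <- X[, -c4, drop = FALSE]
      }
    }
    n <- nrow(X)
    m <- colMeans(X)
    Xc <- sweep(X, 2, m)
    patterns[[i]] <- list(zyg = zyg[rows[1]], idx = idx, n = n, mean = m,
                          scatter = crossprod(Xc) / n,
                          rows = if (keep_rows) X else NULL)
    fam_pattern[rows] <- i
  }
  list(patterns = patterns, n_families = sum(usable),
       n_mz = sum(zyg == 0L & usable), n_dz = sum(zyg == 1L & usable),
       fam_pattern = fam_pattern,
       hash = .data_hash(M))
}

.data_hash <- function(M) {
  paste(nrow(M), sum(!is.na(M)),
        format(sum(M, na.rm = TRUE), digits = 15),
        format(sum(M^2, na.rm = TRUE), digits = 15), sep = "|")
}

#' Log-likelihood contribution of one family
#'
#' FIML log-density of a family's observed sub-vector under the Gaussian
#' with the matching sub-mean and sub-covariance of the model-implied
#' moments. A family with no observed entry contributes exactly 0. If the
#' observed sub-covariance is singular the contribution is `-Inf` with a
#' warning (not an error).
#'
#' Because MZ co-twins carry identical genomes, the implied MZ twin-PGS
#' correlation is exactly 1; when both MZ twin PGS are observed and equal,
#' the duplicated entry is degenerate and the density is evaluated on the
#' reduced observed vector. Unequal observed MZ twin PGS (inconsistent with
#' the model) yield the singular `-Inf` path.
#'
#' @param record A one-row data frame of family records, or a named numeric
#'   vector over the six observed slots (`NA` = missing).
#' @param moments An `implied_moments` object for the family's zygosity
#'   group.
#' @return Scalar log-likelihood contribution.
#' @examples
#' m <- implied_moments(study_params(), "DZ")
#' family_loglik(c(pgs_mother = 0.2, pgs_father = NA, pgs_twin1 = 0.1,
#'                 pgs_twin2 = -0.3, pheno_twin1 = 1.1, pheno_twin2 = NA), m)
#' @export
family_loglik <- function(record, moments) {
  stopifnot(inherits(moments, "implied_moments"))
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    if ("zygosity" %in% names(record) &&
        .normalize_zygosity(record$zygosity) != moments$zygosity)
      stop("record zygosity does not match the implied moments group")
    x <- as.numeric(record[1, .obs_vars])
  } else {
    x <- as.numeric(record[.obs_vars])
  }
  idx <- which(!is.na(x))
  if (!length(idx)) return(0)
  # identical MZ twin PGS: the duplicate entry is degenerate, drop it
  if (moments$zygosity == "MZ" && all(c(3L, 4L) %in% idx) &&
      abs(x[3] - x[4]) <= 1e-8 * (1 + abs(x[3])))
    idx <- setdiff(idx, 4L)
  S <- moments$cov[idx, idx, drop = FALSE]
  d <- x[idx] - moments$mean[idx]
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular observed sub-covariance; -Inf contribution")
    return(-Inf)
  }
  z <- backsolve(ch, d, transpose = TRUE)
  -0.5 * (length(idx) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

#' Total FIML log-likelihood of a dataset under given parameters
#'
#' @param records Validated family records.
#' @param params A [transmission_params()] object.
#' @param per_family Also return the vector of per-family contributions.
#' @return The total log-likelihood; if `per_family = TRUE`, a list with
#'   `loglik` and `per_family` (ordered as the usable rows of `records`).
#' @export
fiml_loglik <- function(records, params, per_family = FALSE) {
  records <- validate_family_records(records)
  ps <- pattern_stats(records, keep_rows = per_family)
  nll <- cpp_fiml_negll(params_to_theta(params), seq_len(10L),
                        params_to_theta(params), .strip_rows(ps$patterns))
  ll <- if (nll >= 1e12) -Inf else -nll
  if (!per_family) return(ll)
  list(loglik = ll, per_family = .per_family_ll(ps, params))
}

.strip_rows <- function(patterns) {
  lapply(patterns, function(p) p[c("zyg", "idx", "n", "mean", "scatter")])
}

# Vectorized per-family log-densities, one Cholesky per pattern.
.per_family_ll <- function(ps, params) {
  mom <- list(closed_form_moments(params, "MZ"),
              closed_form_moments(params, "DZ"))
  out <- numeric(length(ps$fam_pattern))
  for (i in seq_along(ps$patterns)) {
    p <- ps$patterns[[i]]
    mo <- mom[[p$zyg + 1L]]
    S <- mo$cov[p$idx, p$idx, drop = FALSE]
    ch <- tryCatch(chol(S), error = function(e) NULL)
    rows <- which(ps$fam_pattern == i)
    if (is.null(ch)) { out[rows] <- -Inf; next }
    D <- sweep(p$rows, 2, mo$mean[p$idx])
    Z <- D %*% backsolve(ch, diag(length(p$idx)))
    out[rows] <- -0.5 * (length(p$idx) * log(2 * pi) +
                           2 * sum(log(diag(ch))) + rowSums(Z^2))
  }
  out[ps$fam_pattern == 0L] <- 0
  out
}
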