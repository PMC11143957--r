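#' Score a panel of symptom ratings into one period score
#'
#' Ratings are integers 0 ('never'), 1 ('sometimes'), 2 ('often') for a set
#' of symptom items rated at one or more measurement occasions within a
#' developmental period. The available items are averaged within each
#' occasion, and the occasion means are then averaged across occasions.
#' Occasions with no rated item are skipped; if no occasion has any rated
#' item the score is missing (`NA`), never zero.
#'
#' The result is invariant to the order of occasions and of items.
#'
#' @param ratings A numeric matrix (occasions x items) for one child and
#'   one period; `NA` marks unrated items. Values must be in `{0, 1, 2}`.
#' @return The period score (scalar in `[0, 2]`), or `NA_real_`.
#' @examples
#' score_symptoms(rbind(c(1, 1, 1), c(0, 1, NA)))  # occasion means 1, 0.5
#' @export
score_symptoms <- function(ratings) {
  ratings <- as.matrix(ratings)
  vals <- ratings[!is.na(ratings)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("ratings must be 0, 1 or 2")
  occ <- rowMeans(ratings, na.rm = TRUE)
  occ <- occ[!is.nan(occ)]
  if (!length(occ)) return(NA_real_)
  mean(occ)
}

#' Square-root transform and sex-adjust period scores
#'
#' Symptom period scores are right-skewed; each score is square-root
#' transformed and then adjusted for mean sex differences by taking the
#' residual of an ordinary least-squares regression of the transformed
#' score on an intercept and a sex indicator, with every child (twins
#' included as separate observations) entering the fit. When only one sex
#' is present the sex term is dropped and the adjustment is intercept-only.
#'
#' The adjusted scores have exactly zero empirical correlation with the sex
#' indicator.
#'
#' @param scores Non-negative numeric vector of period scores (`NA`
#'   allowed).
#' @param sex Factor or character vector of the same length (e.g. `"F"`,
#'   `"M"`); children with missing sex get `NA` adjusted scores.
#' @return Numeric vector of adjusted scores (residuals, mean zero over the
#'   fitted children).
#' @examples
#' transform_adjust(c(1, 0, 0.25), c("F", "F", "F"))
#' @export
transform_adjust <- function(scores, sex) {
  stopifnot(length(scores) == length(sex))
  if (any(scores < 0, na.rm = TRUE))
    stop("period scores must be non-negative")
  y <- sqrt(scores)
  sex <- as.factor(sex)
  out <- rep(NA_real_, length(y))
  use <- !is.na(y) & !is.na(sex)
  if (!any(use)) return(out)
  if (nlevels(droplevels(sex[use])) < 2L) {
    out[use] <- y[use] - mean(y[use])
  } else {
    fit <- lm(y ~ sex, subset = use, na.action = stats::na.exclude)
    out[use] <- y[use] - stats::fitted(fit)
  }
  out
}

#' Residualize polygenic scores on ancestry covariates
#'
#' Regresses each person's PGS on an intercept plus covariates (typically
#' the first 10 principal components of the genetic relatedness matrix,
#' guarding against population stratification) and re-standardizes the
#' residuals to mean 0, SD 1 over the non-missing persons. Parents and
#' twins are pooled into one fit and one scale, consistent with a single
#' PGS variance in the transmission model.
#'
#' @param pgs Numeric vector of polygenic scores (`NA` allowed).
#' @param covariates Numeric matrix or data frame, one row per person.
#'   Constant columns are dropped; remaining columns must be of full rank.
#'   Persons with a missing covariate get `NA` output (logged).
#' @return Numeric vector of adjusted, standardized scores.
#' @examples
#' pcs <- matrix(rnorm(30), 10, 3)
#' residualize_pgs(rnorm(10), pcs)
#' @export
residualize_pgs <- function(pgs, covariates) {
  X <- as.matrix(covariates)
  stopifnot(nrow(X) == length(pgs))
  storage.mode(X) <- "double"
  keep <- apply(X, 2, function(col) {
    col <- col[!is.na(col)]
    length(col) > 0 && max(col) - min(col) > 0
  })
  X <- X[, keep, drop = FALSE]
  cov_missing <- if (ncol(X)) rowSums(is.na(X)) > 0 else rep(FALSE, length(pgs))
  if (any(cov_missing & !is.na(pgs)))
    message(sum(cov_missing & !is.na(pgs)),
            " person(s) with missing covariates: PGS set missing")
  use <- !is.na(pgs) & !cov_missing
  out <- rep(NA_real_, length(pgs))
  if (!any(use)) return(out)
  if (ncol(X)) {
    Xu <- cbind(1, X[use, , drop = FALSE])
    colnames(Xu) <- c("(intercept)",
                      colnames(X) %||% paste0("cov", seq_len(ncol(X))))
    qrX <- qr(Xu)
    if (qrX$rank < ncol(Xu)) {
      dropped <- colnames(Xu)[-(qrX$pivot[seq_len(qrX$rank)])]
      stop("rank-deficient covariates; collinear column(s): ",
           paste(dropped, collapse = ", "))
    }
    res <- qr.resid(qrX, pgs[use])
  } else {
    res <- pgs[use] - mean(pgs[use])
  }
  s <- sd(res)
  if (!is.finite(s) || s <= 1e-10 * max(sd(pgs[use]), .Machine$double.xmin))
    stop("residual PGS has zero variance; cannot standardize")
  out[use] <- (res - mean(res)) / s
  out
}
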