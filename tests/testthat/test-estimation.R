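test_that("per-family likelihood equals dense marginal Gaussian densities", {
  set.seed(21)
  p <- study_params()
  momMZ <- implied_moments(p, "MZ")
  momDZ <- implied_moments(p, "DZ")
  # fully missing family contributes exactly zero
  expect_identical(family_loglik(rep(NA_real_, 6), momDZ), 0)
  # complete DZ record: 6-dimensional density
  fam <- simulate_families(20, 20, p, seed = 22)
  x_dz <- as.numeric(fam[40, 3:8])
  expect_equal(family_loglik(setNames(x_dz, names(fam)[3:8]), momDZ),
               oracle_family_ll(x_dz, momDZ$mean, momDZ$cov, "DZ"),
               tolerance = 1e-10)
  # record missing only the father's PGS: 5-dimensional marginal
  x5 <- x_dz; x5[2] <- NA
  expect_equal(family_loglik(setNames(x5, names(fam)[3:8]), momDZ),
               oracle_family_ll(x5, momDZ$mean, momDZ$cov, "DZ"),
               tolerance = 1e-10)
  # complete MZ record: the duplicated twin PGS entry is degenerate and the
  # density is evaluated on the reduced vector
  x_mz <- as.numeric(fam[1, 3:8])
  expect_equal(family_loglik(fam[1, ], momMZ),
               oracle_family_ll(x_mz, momMZ$mean, momMZ$cov, "MZ"),
               tolerance = 1e-10)
  # zygosity mismatch is an error
  expect_error(family_loglik(fam[1, ], momDZ), "zygosity")
})

test_that("pattern-grouped FIML equals naive per-family evaluation", {
  p <- study_params()
  fam <- simulate_families(60, 90, p, seed = 31)
  fam <- inject_missingness(fam, rate = 0.25, seed = 32)
  fam <- fam[rowSums(!is.na(fam[3:8])) > 0, ]
  ll <- fiml_loglik(fam, p, per_family = TRUE)
  expect_equal(ll$loglik, oracle_total_ll(fam, p), tolerance = 1e-8)
  expect_equal(sum(ll$per_family), ll$loglik, tolerance = 1e-8)
  # complete data too
  fam2 <- simulate_families(50, 50, p, seed = 33)
  expect_equal(fiml_loglik(fam2, p), oracle_total_ll(fam2, p),
               tolerance = 1e-8)
})

test_that("ML dominance, free-parameter counts and nesting hold on a fit", {
  p <- study_params()
  fam <- simulate_families(300, 450, p, seed = 41)
  fam <- inject_missingness(fam, rate = 0.2, seed = 42)
  full <- fit_transmission(fam)
  expect_true(full$converged)
  expect_identical(full$n_free, 10L)
  expect_gte(full$loglik, fiml_loglik(fam, p))     # beats the truth
  red <- fit_no_nurture(fam)
  expect_identical(red$n_free, 8L)
  expect_equal(red$params$g_m, 0)
  expect_equal(red$params$g_f, 0)
  expect_gte(full$loglik, red$loglik)              # nesting
  sat <- fit_saturated(fam)
  expect_gte(sat$loglik, full$loglik)              # saturated dominates
  base <- fit_baseline(fam)
  expect_gte(full$loglik, base$loglik)             # independence is worst
  lrt <- lr_test(full, red)
  expect_identical(lrt$df, 2L)
})

test_that("fits are invariant to row order, twin labels, and null families", {
  p <- study_params()
  fam <- simulate_families(80, 120, p, seed = 51)
  fam <- inject_missingness(fam, rate = 0.15, seed = 52)
  fam <- fam[rowSums(!is.na(fam[3:8])) > 0, ]
  f1 <- fit_transmission(fam, per_family = FALSE)
  # permuted rows
  f2 <- fit_transmission(fam[sample(nrow(fam)), ], per_family = FALSE)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-6)
  # swapped twin labels (both PGS and phenotype)
  sw <- fam
  sw[c("pgs_twin1", "pgs_twin2")] <- fam[c("pgs_twin2", "pgs_twin1")]
  sw[c("pheno_twin1", "pheno_twin2")] <- fam[c("pheno_twin2", "pheno_twin1")]
  f3 <- fit_transmission(sw, per_family = FALSE)
  expect_equal(f3$loglik, f1$loglik, tolerance = 1e-6)
  expect_equal(f3$params$g_tw, f1$params$g_tw, tolerance = 1e-4)
  # appending a fully missing family changes nothing (it is dropped)
  null_fam <- fam[1, ]
  null_fam$family_id <- "null"
  null_fam[3:8] <- NA_real_
  f4 <- suppressMessages(
    fit_transmission(rbind(fam, null_fam), per_family = FALSE))
  expect_equal(f4$loglik, f1$loglik, tolerance = 1e-8)
  expect_identical(f4$n_families, f1$n_families)
})

test_that("likelihood-ratio test clamps, validates nesting, and maps to chi-square", {
  stub <- function(loglik, n_free, hash = "h", n = 100) {
    structure(list(loglik = loglik, n_free = as.integer(n_free),
                   n_families = n, data_hash = hash), class = "pgs_fit")
  }
  # statistic 5.991 on 2 df sits at the 5% point
  out <- lr_test(stub(0, 10), stub(-5.991 / 2, 8))
  expect_equal(out$statistic, 5.991)
  expect_identical(out$df, 2L)
  expect_equal(out$p_value, 0.05, tolerance = 1e-3)
  # identical log-likelihoods: statistic 0, p = 1
  out0 <- lr_test(stub(-10, 10), stub(-10, 8))
  expect_identical(out0$statistic, 0)
  expect_identical(out0$p_value, 1)
  # float noise below the clamp threshold is reported as exactly zero
  outc <- lr_test(stub(-10, 10), stub(-10 - 0.0005, 8))
  expect_identical(outc$statistic, 0)
  expect_identical(outc$p_value, 1)
  # non-nested or mismatched-data inputs error
  expect_error(lr_test(stub(0, 8), stub(-1, 10)), "fewer free")
  expect_error(lr_test(stub(0, 10), stub(-1, 8, hash = "other")),
               "same data")
})

test_that("fit indices reproduce their defining formulas", {
  stub <- function(loglik, n_free, n = 415) {
    structure(list(loglik = loglik, n_free = as.integer(n_free),
                   n_families = n, data_hash = "h"), class = "pgs_fit")
  }
  sat <- stub(0, 54)
  target <- stub(-25, 10)     # chisq_t = 50, df_t = 44
  base <- stub(-250, 24)      # chisq_b = 500, df_b = 30
  idx <- fit_indices(target, sat, base)
  expect_equal(idx$chisq, 50)
  expect_identical(idx$df, 44L)
  expect_equal(idx$cfi, 0.987, tolerance = 1e-3)
  expect_equal(idx$tli, ((500 / 30) - (50 / 44)) / ((500 / 30) - 1))
  expect_equal(idx$rmsea, sqrt((50 - 44) / (44 * 415)))
  # perfect fit: CFI 1, RMSEA 0
  idx2 <- fit_indices(stub(0, 10), sat, base)
  expect_equal(idx2$cfi, 1)
  expect_equal(idx2$rmsea, 0)
  # chisq below df clamps the noncentrality: RMSEA 0
  idx3 <- fit_indices(stub(-20, 10), sat, base)  # chisq 40 < df 44
  expect_equal(idx3$rmsea, 0)
  expect_equal(idx3$cfi, 1)
})

test_that("saturated and baseline models hit closed forms and df counts", {
  # generic complete two-group data (no exact MZ duplication): 2 x 27 and
  # 2 x 12 free parameters
  fam <- generic_family_frame(40)
  sat <- fit_saturated(fam)
  expect_identical(sat$n_free, 54L)
  base <- fit_baseline(fam)
  expect_identical(base$n_free, 24L)
  # complete data, one group: ML mean and divisor-n covariance exactly
  dz <- fam[fam$zygosity == "DZ", ]
  satdz <- fit_saturated(dz)
  M <- as.matrix(dz[3:8])
  expect_equal(satdz$params$DZ$mean, colMeans(M), ignore_attr = TRUE)
  expect_equal(satdz$params$DZ$cov,
               crossprod(sweep(M, 2, colMeans(M))) / nrow(M),
               ignore_attr = TRUE)
  # baseline closed form: per-variable Gaussian fits
  expect_equal(base$params$DZ$mean[["pgs_mother"]], mean(M[, 1]))
  expect_equal(base$params$DZ$var[["pgs_mother"]],
               mean((M[, 1] - mean(M[, 1]))^2))
  # with shared MZ genotypes the degenerate entry leaves the count
  fam2 <- simulate_families(50, 50, study_params(), seed = 61)
  expect_identical(fit_saturated(fam2)$n_free, 47L)
  expect_identical(fit_baseline(fam2)$n_free, 22L)
  # saturated FIML under missingness still dominates the structured model
  fam3 <- inject_missingness(fam2, rate = 0.25, seed = 62)
  fam3 <- fam3[rowSums(!is.na(fam3[3:8])) > 0, ]
  sat3 <- fit_saturated(fam3)
  expect_true(sat3$converged)
  expect_gte(sat3$loglik, fit_transmission(fam3, per_family = FALSE)$loglik)
})

test_that("strong maternal nurture is detected by the 2-df LRT", {
  p <- study_params()
  p$g_m <- 0.3
  hits <- 0L
  for (r in 1:10) {
    fam <- simulate_families(1000, 1000, p, seed = 700 + r)
    full <- fit_transmission(fam, restarts = 1, per_family = FALSE)
    red <- fit_no_nurture(fam, restarts = 1, per_family = FALSE)
    hits <- hits + (lr_test(full, red)$p_value < 0.05)
  }
  expect_gte(hits, 8L)
})
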