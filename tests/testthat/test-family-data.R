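test_that("family CSV parsing handles missing cells, sentinels and schemas", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "family_id,zygosity,pgs_mother,pgs_father,pgs_twin1,pgs_twin2,pheno_twin1,pheno_twin2",
    "F1,MZ,0.1,,0.3,0.3,1.2,0.9",
    "F2,dz,-0.2,0.4,0.0,0.1,,0.5"), f)
  rec <- read_family_table(f, quiet = TRUE)
  expect_equal(nrow(rec), 2L)
  expect_true(is.na(rec$pgs_father[1]))
  expect_equal(rec$pgs_twin1[1], 0.3)
  expect_equal(rec$zygosity, c("MZ", "DZ"))  # codes normalized
  expect_true(is.na(rec$pheno_twin1[2]))

  # the declared "NA" sentinel parses to the same record as empty strings
  f2 <- tempfile(fileext = ".csv")
  writeLines(c(
    "family_id,zygosity,pgs_mother,pgs_father,pgs_twin1,pgs_twin2,pheno_twin1,pheno_twin2",
    "F1,MZ,0.1,NA,0.3,0.3,1.2,0.9"), f2)
  rec2 <- read_family_table(f2, quiet = TRUE)
  expect_equal(rec2[1, ], rec[1, ], ignore_attr = TRUE)

  # column-name mapping
  f3 <- tempfile(fileext = ".csv")
  writeLines(c("fid,zyg,mom,dad,t1,t2,p1,p2",
               "F1,MZ,0.1,,0.3,0.3,1.2,0.9"), f3)
  rec3 <- read_family_table(
    f3, schema = c(family_id = "fid", zygosity = "zyg", pgs_mother = "mom",
                   pgs_father = "dad", pgs_twin1 = "t1", pgs_twin2 = "t2",
                   pheno_twin1 = "p1", pheno_twin2 = "p2"),
    quiet = TRUE)
  expect_equal(rec3, rec[1, ], ignore_attr = TRUE)

  # empty file: empty collection plus a warning
  f4 <- tempfile(fileext = ".csv")
  writeLines("family_id,zygosity,pgs_mother,pgs_father,pgs_twin1,pgs_twin2,pheno_twin1,pheno_twin2",
             f4)
  expect_warning(empty <- read_family_table(f4, quiet = TRUE), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("validation rejects bad zygosity codes and duplicate ids", {
  fam <- generic_family_frame(3)
  fam$zygosity[2] <- "XX"
  expect_error(validate_family_records(fam), "zygosity.*2")
  fam2 <- generic_family_frame(3)
  fam2$family_id[2] <- fam2$family_id[1]
  expect_error(validate_family_records(fam2), "duplicated family_id")
  fam3 <- generic_family_frame(3)
  fam3[2, c("pgs_mother", "pgs_father", "pgs_twin1", "pgs_twin2",
            "pheno_twin1", "pheno_twin2")] <- NA
  expect_message(ok <- validate_family_records(fam3), "unusable")
  expect_equal(nrow(ok), 5L)
})

test_that("MZ genotype propagation copies to the co-twin, only for MZ", {
  fam <- data.frame(
    family_id = c("A", "B", "C", "D"),
    zygosity = c("MZ", "DZ", "MZ", "MZ"),
    pgs_mother = c(0, 0, 0, NA), pgs_father = c(0, 0, 0, NA),
    pgs_twin1 = c(0.42, 0.42, NA, NA), pgs_twin2 = c(NA, NA, NA, NA),
    pheno_twin1 = 1, pheno_twin2 = 1)
  out <- propagate_mz_genotypes(fam, quiet = TRUE)
  expect_equal(out$pgs_twin2[1], 0.42)      # MZ: copied
  expect_true(is.na(out$pgs_twin2[2]))      # DZ: untouched
  expect_true(is.na(out$pgs_twin1[3]))      # both missing: nothing to copy
  expect_equal(attr(out, "n_propagated"), 1L)
  # idempotent
  out2 <- propagate_mz_genotypes(out, quiet = TRUE)
  expect_equal(out2[names(fam)], out[names(fam)])
  expect_equal(attr(out2, "n_propagated"), 0L)
  # after propagation no MZ family has exactly one observed twin PGS
  one_obs <- with(out, zygosity == "MZ" &
                    (is.na(pgs_twin1) != is.na(pgs_twin2)))
  expect_false(any(one_obs))
  # unequal observed MZ twin PGS draws a warning, values kept
  fam$pgs_twin2[1] <- 0.9
  expect_warning(kept <- propagate_mz_genotypes(fam, quiet = TRUE),
                 "unequal")
  expect_equal(kept$pgs_twin2[1], 0.9)
})

test_that("symptom scoring averages items within and then across occasions", {
  expect_equal(score_symptoms(matrix(0, 3, 5)), 0)
  expect_equal(score_symptoms(matrix(2, 4, 3)), 2)
  # occasion means 1.0 and 0.4 -> period score 0.7
  occ <- rbind(c(1, 1, 1, 1, 1), c(0, 1, 0, 1, 0))
  expect_equal(score_symptoms(occ), 0.7)
  # invariant to occasion order and item order
  expect_equal(score_symptoms(occ[2:1, ]), 0.7)
  expect_equal(score_symptoms(occ[, 5:1]), 0.7)
  # missing items are skipped within occasions; empty occasions skipped
  expect_equal(score_symptoms(rbind(c(2, NA, NA), c(NA, NA, NA))), 2)
  # no rated item anywhere: missing, not zero
  expect_true(is.na(score_symptoms(matrix(NA_real_, 2, 3))))
  expect_error(score_symptoms(matrix(3, 1, 1)), "0, 1 or 2")
})

test_that("sqrt transform and sex adjustment return exact OLS residuals", {
  # constant scores, both sexes: all residuals zero
  expect_equal(transform_adjust(rep(1, 4), c("F", "F", "M", "M")),
               rep(0, 4))
  # sex fully explains the two group means
  expect_equal(transform_adjust(c(1, 1, 0.25, 0.25),
                                c("M", "M", "F", "F")), rep(0, 4))
  # single sex: residuals about the mean of the sqrt values
  expect_equal(transform_adjust(c(1, 0, 0.25), rep("F", 3)),
               c(0.5, -0.5, 0))
  expect_error(transform_adjust(c(-1, 1), c("F", "M")), "non-negative")
  # residuals are empirically uncorrelated with the sex indicator
  set.seed(5)
  sc <- rexp(60); sx <- sample(c("F", "M"), 60, replace = TRUE)
  adj <- transform_adjust(sc, sx)
  expect_lt(abs(cor(adj, as.numeric(factor(sx)))), 1e-10)
})

test_that("PGS residualization removes covariates and standardizes", {
  # all-zero covariate columns: output is the standardized input
  x <- c(1, 2, 4, 8)
  out <- residualize_pgs(x, matrix(0, 4, 2))
  expect_equal(out, (x - mean(x)) / sd(x))
  # hand OLS: residuals proportional to {0, -0.5, 0.5}
  out2 <- residualize_pgs(c(1, 2, 3), matrix(c(1, 0, 0), 3, 1))
  expect_equal(out2 / out2[3], c(0, -1, 1))
  # PGS an exact linear function of covariates: zero-variance error
  z <- rnorm(10)
  expect_error(residualize_pgs(2 * z + 1, cbind(z)), "zero variance")
  # rank-deficient covariates are named
  w <- rnorm(10)
  expect_error(residualize_pgs(rnorm(10), cbind(a = w, b = 2 * w)),
               "collinear")
  # missing covariates null the person's PGS, with a log message
  X <- matrix(rnorm(20), 10, 2)
  X[3, 1] <- NA
  expect_message(out3 <- residualize_pgs(rnorm(10), X), "missing covariates")
  expect_true(is.na(out3[3]))
  # residuals uncorrelated with every covariate column
  set.seed(11)
  X <- matrix(rnorm(300), 100, 3)
  out4 <- residualize_pgs(rnorm(100) + X %*% c(1, -2, 0.5), X)
  expect_true(all(abs(cor(out4, X)) < 1e-10))
  expect_equal(mean(out4), 0, tolerance = 1e-12)
  expect_equal(sd(out4), 1, tolerance = 1e-12)
})
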