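test_that("fixed meiotic path gives parent-child PGS correlation 0.5 at r_a = 0", {
  p <- transmission_params(V_PGS = 1, r_a = 0, V_ADHD = 1,
                           g_tw = 0.4, g_m = -0.2, g_f = 0.1)
  for (z in c("MZ", "DZ")) {
    m <- implied_moments(p, z)
    r <- cov2cor(m$cov)
    expect_equal(r["pgs_mother", "pgs_twin1"], 0.5)
    expect_equal(r["pgs_father", "pgs_twin2"], 0.5)
  }
  # and above 0.5 exactly when r_a > 0: corr = 0.5 * (1 + r_a)
  p2 <- transmission_params(r_a = 0.3)
  r2 <- cov2cor(implied_moments(p2, "DZ")$cov)
  expect_equal(r2["pgs_mother", "pgs_twin1"], 0.5 * 1.3)
})

test_that("MZ twins have implied PGS correlation exactly 1", {
  set.seed(1)
  for (i in 1:10) {
    m <- implied_moments(random_params(), "MZ")
    expect_equal(cov2cor(m$cov)["pgs_twin1", "pgs_twin2"], 1)
  }
})

test_that("with no genetic paths the phenotype block is pure residual", {
  p <- transmission_params(V_PGS = 2, r_a = 0.4, V_ADHD = 1.5,
                           r_MZ = 0.6, r_DZ = 0.25)
  for (z in c("MZ", "DZ")) {
    m <- implied_moments(p, z)
    rz <- if (z == "MZ") 0.6 else 0.25
    expect_equal(m$cov["pheno_twin1", "pheno_twin2"], rz * 1.5)
    expect_equal(m$cov["pheno_twin1", "pheno_twin1"], 1.5)
    expect_equal(max(abs(m$cov[1:4, 5:6])), 0)
  }
})

test_that("implied covariance entries match hand-derived closed forms (DZ)", {
  V <- 1; ra <- 0.2; gt <- 0.3; gm <- 0.1; gf <- -0.1; VA <- 1; rdz <- 0.15
  p <- transmission_params(V_PGS = V, r_a = ra, V_ADHD = VA, r_DZ = rdz,
                           g_tw = gt, g_m = gm, g_f = gf)
  cv <- implied_moments(p, "DZ")$cov
  cpc <- 0.5 * V * (1 + ra)
  expect_equal(diag(cv)[1:4], rep(V, 4), ignore_attr = TRUE)
  expect_equal(cv["pgs_mother", "pgs_father"], ra * V)
  expect_equal(cv["pgs_mother", "pgs_twin1"], cpc)
  expect_equal(cv["pgs_twin1", "pgs_twin2"], cpc)
  expect_equal(cv["pgs_mother", "pheno_twin1"], gt * cpc + gm * V + gf * ra * V)
  expect_equal(cv["pgs_father", "pheno_twin1"], gt * cpc + gf * V + gm * ra * V)
  expect_equal(cv["pgs_twin1", "pheno_twin1"], gt * V + (gm + gf) * cpc)
  expect_equal(cv["pgs_twin1", "pheno_twin2"], gt * cpc + (gm + gf) * cpc)
  vph <- (gt^2 + gm^2 + gf^2) * V + 2 * gt * (gm + gf) * cpc +
    2 * gm * gf * ra * V + VA
  expect_equal(cv["pheno_twin1", "pheno_twin1"], vph)
  expect_equal(cv["pheno_twin1", "pheno_twin2"],
               gt^2 * cpc + 2 * gt * (gm + gf) * cpc + (gm^2 + gf^2) * V +
                 2 * gm * gf * ra * V + rdz * VA)
})

test_that("path algebra and closed forms agree; implied matrices are PSD", {
  set.seed(42)
  for (i in 1:100) {
    p <- random_params()
    for (z in c("MZ", "DZ")) {
      a <- implied_moments(p, z)
      b <- closed_form_moments(p, z)
      expect_lt(max(abs(a$cov - b$cov)), 1e-10)
      expect_equal(a$mean, b$mean)
      expect_gt(min(eigen(a$cov, symmetric = TRUE,
                          only.values = TRUE)$values), -1e-10)
    }
  }
})

test_that("MZ and DZ implied matrices differ only where zygosity enters", {
  set.seed(3)
  p <- random_params()
  mz <- implied_moments(p, "MZ")$cov
  dz <- implied_moments(p, "DZ")$cov
  diff <- abs(mz - dz) > 1e-12
  allowed <- matrix(FALSE, 6, 6, dimnames = dimnames(mz))
  allowed["pgs_twin1", "pgs_twin2"] <- TRUE      # twin PGS covariance
  allowed["pgs_twin1", "pheno_twin2"] <- TRUE    # cross cov via twin PGS
  allowed["pgs_twin2", "pheno_twin1"] <- TRUE
  allowed["pheno_twin1", "pheno_twin2"] <- TRUE  # residual correlation
  allowed <- allowed | t(allowed)
  expect_true(all(!diff | allowed))
})

test_that("degenerate or invalid parameters are rejected before use", {
  expect_error(transmission_params(V_PGS = 0), "V_PGS")
  expect_error(transmission_params(V_ADHD = -1), "V_ADHD")
  expect_error(transmission_params(r_a = 1), "r_a")
  expect_error(transmission_params(g_tw = NA_real_), "g_tw")
  # perfect-assortment limit: parent-child covariance tends to V_PGS
  p <- transmission_params(V_PGS = 2, r_a = 1 - 1e-9)
  expect_equal(closed_form_moments(p, "DZ")$cov["pgs_mother", "pgs_twin1"],
               2, tolerance = 1e-8)
})

test_that("symbolic model description covers all unique entries", {
  M <- NULL
  out <- capture.output(M <- describe_model("DZ"))
  expect_true(any(grepl("r_a\\*V_PGS", out)))
  expect_true(any(grepl("mu_PGS", out)))
  expect_identical(dim(M), c(6L, 6L))
  expect_identical(M, t(M))
})
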