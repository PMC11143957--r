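# Independent oracles and fixture builders used across the test files.

# Dense Gaussian log-density of one family's observed sub-vector, computed
# with determinant() and solve() (no Cholesky, no sufficient statistics) so
# it is independent of the package's likelihood path. Applies the same
# degenerate-MZ reduction contract: an exactly duplicated MZ twin PGS entry
# is dropped from the observed vector.
oracle_family_ll <- function(x, mean, cov, zygosity) {
  x <- as.numeric(x)
  idx <- which(!is.na(x))
  if (!length(idx)) return(0)
  if (zygosity == "MZ" && all(c(3, 4) %in% idx) &&
      abs(x[3] - x[4]) <= 1e-8 * (1 + abs(x[3])))
    idx <- setdiff(idx, 4)
  S <- cov[idx, idx, drop = FALSE]
  d <- x[idx] - mean[idx]
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  -0.5 * (length(idx) * log(2 * pi) + ld + drop(t(d) %*% solve(S) %*% d))
}

# Total dataset log-likelihood by naive per-family evaluation against the
# path-algebra implied moments.
oracle_total_ll <- function(records, params) {
  mom <- list(MZ = implied_moments(params, "MZ"),
              DZ = implied_moments(params, "DZ"))
  M <- as.matrix(records[, c("pgs_mother", "pgs_father", "pgs_twin1",
                             "pgs_twin2", "pheno_twin1", "pheno_twin2")])
  sum(vapply(seq_len(nrow(M)), function(i) {
    z <- records$zygosity[i]
    oracle_family_ll(M[i, ], mom[[z]]$mean, mom[[z]]$cov, z)
  }, numeric(1)))
}

# Random admissible parameter draw over a broad box.
random_params <- function() {
  transmission_params(
    V_PGS = runif(1, 0.2, 3), r_a = runif(1, -0.9, 0.9),
    V_ADHD = runif(1, 0.2, 3),
    r_MZ = runif(1, -0.9, 0.9), r_DZ = runif(1, -0.9, 0.9),
    g_tw = runif(1, -1, 1), g_m = runif(1, -1, 1), g_f = runif(1, -1, 1),
    mu_PGS = runif(1, -2, 2), mu_ADHD = runif(1, -2, 2))
}

# Generic two-group dataset whose MZ twin PGS are NOT exact duplicates
# (e.g. raw pre-propagation data), so all six variables are non-degenerate
# in both groups.
generic_family_frame <- function(n_per_group = 40, seed = 99) {
  set.seed(seed)
  n <- 2 * n_per_group
  data.frame(
    family_id = paste0("g", seq_len(n)),
    zygosity = rep(c("MZ", "DZ"), each = n_per_group),
    pgs_mother = rnorm(n), pgs_father = rnorm(n),
    pgs_twin1 = rnorm(n), pgs_twin2 = rnorm(n),
    pheno_twin1 = rnorm(n), pheno_twin2 = rnorm(n),
    stringsAsFactors = FALSE)
}

# Family CSV writer for I/O tests.
write_family_csv <- function(records, path, na = "") {
  utils::write.csv(records, path, row.names = FALSE, na = na)
  path
}
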