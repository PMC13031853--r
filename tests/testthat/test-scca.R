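test_that("residualization removes covariates and standardizes", {
  set.seed(1)
  n <- 150
  age <- runif(n, 8, 20); sex <- rbinom(n, 1, 0.5)
  x <- cbind(a = 2 * age + rnorm(n), b = rnorm(n))
  r <- residualize(x, cbind(age, sex))
  expect_equal(unname(colMeans(r)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(r, 2, sd)), c(1, 1), tolerance = 1e-10)
  expect_lt(max(abs(cor(r, age))), 1e-10)
  expect_lt(max(abs(cor(r, sex))), 1e-10)
  # column already orthogonal to the covariates: unchanged up to z-scoring
  orth <- resid(lm(rnorm(n) ~ age + sex))
  expect_equal(unname(residualize(cbind(orth), cbind(age, sex))[, 1]),
               as.numeric(scale(orth)), tolerance = 1e-10)
  # column exactly linear in a covariate: degenerate, surfaced as an error
  expect_error(residualize(cbind(exact = 3 * age), cbind(age, sex)),
               "constant column")
})

test_that("soft thresholding follows its definition", {
  expect_equal(soft_threshold(c(2, -0.3), 0.5), c(1.5, 0))
  expect_equal(soft_threshold(c(2, -0.3), 0), c(2, -0.3))
  expect_equal(soft_threshold(c(2, -3), 5), c(0, 0))
  expect_error(soft_threshold(1, -1))
})

test_that("rank-1 PMD with inactive constraints equals the leading SVD pair", {
  # diagonal case: leading singular pair, constraints inactive
  r <- pmd_rank1(diag(c(3, 1)), 1, 1)
  expect_equal(abs(r$u), c(1, 0), tolerance = 1e-8)
  expect_equal(abs(r$v), c(1, 0), tolerance = 1e-8)
  expect_equal(r$d, 3, tolerance = 1e-8)
  # random matrices of several shapes up to 30 x 51
  set.seed(2)
  for (dims in list(c(10, 8), c(30, 51), c(5, 20))) {
    z <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    r <- pmd_rank1(z, 1, 1)
    sv <- svd(z, nu = 1, nv = 1)
    expect_lt(abs(r$d - sv$d[1]), 1e-6)
    expect_lt(min(max(abs(r$u - sv$u[, 1])), max(abs(r$u + sv$u[, 1]))),
              1e-6)
    expect_lt(min(max(abs(r$v - sv$v[, 1])), max(abs(r$v + sv$v[, 1]))),
              1e-6)
  }
  expect_error(pmd_rank1(matrix(0, 3, 3)), "zero")
})

test_that("a tiny L1 budget keeps exactly the dominant coordinate", {
  set.seed(3)
  for (i in 1:20) {
    z <- matrix(rnorm(80), 10, 8)
    r <- pmd_rank1(z, c1 = 0.1, c2 = 1)     # budget 0.1 * sqrt(10) < 1
    expect_equal(sum(abs(r$u) > 1e-12), 1)
    # brute force over single-support solutions: the best row of Z v
    j_best <- which.max(abs(drop(z %*% r$v)))
    expect_equal(which(abs(r$u) > 1e-12), j_best)
  }
})

test_that("returned weights satisfy the norm constraints", {
  set.seed(4)
  for (i in 1:15) {
    z <- matrix(rnorm(30 * 51), 30, 51)
    c1 <- runif(1, 0.2, 1); c2 <- runif(1, 0.2, 1)
    r <- suppressWarnings(pmd_rank1(z, c1, c2))
    expect_equal(sum(r$u^2), 1, tolerance = 1e-8)
    expect_equal(sum(r$v^2), 1, tolerance = 1e-8)
    expect_lte(sum(abs(r$u)), c1 * sqrt(30) + 1e-6)
    expect_lte(sum(abs(r$v)), c2 * sqrt(51) + 1e-6)
  }
})

test_that("successive deflated singular values are non-increasing", {
  set.seed(5)
  n <- 200
  x <- scale(matrix(rnorm(n * 12), n)); y <- scale(matrix(rnorm(n * 9), n))
  fit <- suppressWarnings(scca_fit(x, y, 4, 0.8, 0.8))
  expect_true(all(diff(fit$d) <= 1e-8))
})

test_that("planted modes are recovered from synthetic cohorts", {
  catalog <- tract_catalog()
  sys <- catalog$system[match(tract_pairs(), catalog$pair_id)]
  assoc <- sys %in% c("dorsal-association", "ventral-association")
  limbic <- sys %in% c("limbic", "thalamic", "corticostriatal")
  n_rep <- 10
  ok1 <- ok2 <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cc <- cohort_config(n_subjects = 2000, nodes_per_tract = 2,
                        seed = 400 + r)
    sim <- simulate_cohort(cc)
    X <- noisy_dev_matrix(sim, 1, seed = 500 + r)
    covs <- baseline_covariates(sim)
    Xr <- residualize(X, covs); Yr <- residualize(sim$behavior, covs)
    fit <- suppressWarnings(scca_fit(Xr, Yr, 2, 0.5, 0.5, sign_block = 1:20))
    s1 <- abs(fit$u[, 1]) > 1e-8
    jac <- sum(s1 & assoc) / sum(s1 | assoc)
    lcor <- cor(fit$loadings_x[, 1], cor(Xr, sim$truth$latent[, 1]))
    ok1[r] <- jac > 0.8 && lcor > 0.9
    # second mode: selected tracts lie in the subcortical/limbic mask
    s2 <- abs(fit$u[, 2]) > 1e-8
    ok2[r] <- sum(s2 & limbic) / sum(s2) > 0.8
  }
  expect_gte(mean(ok1), 0.8)
  expect_gte(mean(ok2), 0.8)
})

test_that("independent blocks give small correlations and null p-values", {
  set.seed(6)
  n <- 2000
  x <- scale(matrix(rnorm(n * 10), n)); y <- scale(matrix(rnorm(n * 8), n))
  fit <- suppressWarnings(scca_fit(x, y, 1, 0.7, 0.7))
  expect_lt(fit$cors[1], 0.15)
  pt <- permutation_test_modes(x, y, fit, n_perm = 100, seed = 1)
  expect_gt(pt$p[1], 0.05)
})

test_that("grid search prefers sparse settings for concentrated signal", {
  set.seed(7)
  n_rep <- 10
  picks <- vapply(seq_len(n_rep), function(r) {
    set.seed(700 + r)
    n <- 300
    lat <- rnorm(n)
    x <- matrix(rnorm(n * 30), n); x[, 1:3] <- x[, 1:3] + 1.5 * lat
    y <- matrix(rnorm(n * 10), n); y[, 1:3] <- y[, 1:3] + 1.5 * lat
    gs <- grid_search_sparsity(scale(x), scale(y), seed = r)
    gs$c1
  }, numeric(1))
  expect_gte(mean(picks <= 0.5), 0.8)
  # fixed seed: identical selection across runs
  set.seed(8)
  n <- 120; x <- scale(matrix(rnorm(n * 6), n)); y <- scale(matrix(rnorm(n * 5), n))
  g1 <- grid_search_sparsity(x, y, seed = 5)
  g2 <- grid_search_sparsity(x, y, seed = 5)
  expect_identical(g1, g2)
})

test_that("permuting behavior rows preserves column marginals", {
  set.seed(9)
  y <- matrix(rnorm(50 * 4), 50, 4)
  yp <- y[sample(50), ]
  for (j in 1:4) expect_identical(sort(yp[, j]), sort(y[, j]))
})

test_that("bootstrap alignment is invariant to overall sign flips", {
  set.seed(10)
  n <- 200
  lat <- rnorm(n)
  x <- scale(cbind(lat + rnorm(n), lat + rnorm(n), matrix(rnorm(n * 3), n)))
  y <- scale(cbind(lat + rnorm(n), lat + rnorm(n), matrix(rnorm(n * 3), n)))
  fit <- suppressWarnings(scca_fit(x, y, 2, 0.9, 0.9))
  flipped <- fit
  flipped$u <- -fit$u; flipped$v <- -fit$v
  al1 <- tractage:::.align_modes(x, fit$u, fit$u)
  al2 <- tractage:::.align_modes(x, fit$u, flipped$u)
  expect_identical(al1$index, al2$index)
  expect_identical(al1$sign, -al2$sign)
  # aligned loadings are unchanged by flipping all bootstrap signs
  expect_equal(al1$sign[1] * fit$loadings_x[, al1$index[1]],
               al2$sign[1] * -fit$loadings_x[, al2$index[1]])
})

test_that("near-deterministic data give near-zero-width bootstrap CIs", {
  set.seed(11)
  n <- 300
  lat <- rnorm(n)
  x <- scale(cbind(lat, 0.9 * lat + 0.01 * rnorm(n), rnorm(n)))
  y <- scale(cbind(lat, 0.8 * lat + 0.01 * rnorm(n), rnorm(n)))
  fit <- suppressWarnings(scca_fit(x, y, 1, 1, 1))
  bl <- bootstrap_loadings(x, y, fit, n_boot = 100, seed = 1)
  width <- bl$ci_y[1, 1, 2] - bl$ci_y[1, 1, 1]
  expect_lt(width, 0.02)
})

test_that("mode specificity uses the paired Cohen's d definition", {
  # identical distributions: d = 0, not specific
  b <- array(0, c(2, 2, 50))
  b[1, 1, ] <- rnorm(50); b[1, 2, ] <- b[1, 1, ]
  b[2, 1, ] <- rnorm(50); b[2, 2, ] <- rnorm(50)
  ms <- mode_specificity(b)
  expect_equal(ms$d[1], 0)
  expect_true(is.na(ms$specific_mode[1]))
  # mean difference equal to the SD of differences: d = 1, specific
  set.seed(12)
  diffs <- rnorm(200, 0, 0.05)
  diffs <- (diffs - mean(diffs)) / sd(diffs) * 0.05 + 0.05   # mean = sd
  b2 <- array(0, c(1, 2, 200))
  b2[1, 1, ] <- 0.5 + diffs; b2[1, 2, ] <- 0.5
  ms2 <- mode_specificity(b2)
  expect_equal(ms2$d[1], 1, tolerance = 1e-8)
  expect_equal(ms2$specific_mode[1], 1L)
})

test_that("mode-exclusive behavior variables are flagged to their mode", {
  n_rep <- 10
  ok <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cc <- cohort_config(n_subjects = 1200, nodes_per_tract = 2,
                        mode_coupling = c(0.4, 0.3), seed = 900 + r)
    sim <- simulate_cohort(cc)
    X <- noisy_dev_matrix(sim, 1, seed = 950 + r)
    covs <- baseline_covariates(sim)
    Xr <- residualize(X, covs); Yr <- residualize(sim$behavior, covs)
    fit <- suppressWarnings(scca_fit(Xr, Yr, 2, 0.5, 0.5, sign_block = 1:20))
    bl <- bootstrap_loadings(Xr, Yr, fit, n_boot = 60, seed = r)
    ms <- mode_specificity(bl$boot_y)
    # cognitive variables (mode-1 exclusive) should mostly flag mode 1
    flags <- ms$specific_mode[1:20]
    ok[r] <- mean(flags == 1, na.rm = TRUE) > 0.8 &&
      sum(!is.na(flags)) > 10
  }
  expect_gte(mean(ok), 0.9)
})

test_that("split-domain loadings agree with the full model on planted data", {
  cc <- cohort_config(n_subjects = 2000, nodes_per_tract = 2,
                      mode_coupling = c(0.4, 0.3), seed = 1300)
  sim <- simulate_cohort(cc)
  X <- noisy_dev_matrix(sim, 1, seed = 1301)
  covs <- baseline_covariates(sim)
  Xr <- residualize(X, covs); Yr <- residualize(sim$behavior, covs)
  full <- suppressWarnings(scca_fit(Xr, Yr, 1, 0.5, 0.5, sign_block = 1:20))
  cog_only <- suppressWarnings(
    scca_fit(Xr, Yr[, 1:20], 1, 0.5, 0.5, sign_block = 1:20))
  expect_gt(cor(full$loadings_x[, 1], cog_only$loadings_x[, 1]), 0.8)
})
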