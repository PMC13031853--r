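# 12-observation worked fixture used by the hand-computed oracles
worked_data <- function() {
  data.frame(
    bag = c(1.2, -0.5, 0.3, 2.1, -1.4, 0.8, 0.1, -0.9, 1.7, -0.2, 0.6, -1.1),
    beh = c(0.5, -0.2, 0.1, 1.3, -0.9, 0.4, 0.2, -0.6, 1.0, 0.0, 0.3, -0.8),
    age = c(9, 11, 13, 10, 14, 12, 9.5, 13.5, 10.5, 12.5, 11.5, 14.5),
    sex = c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1))
}

test_that("GLM t statistic matches the normal-equations oracle", {
  d <- worked_data()
  g <- glm_bag_behavior(d$bag, d$beh, d$age, d$sex)
  # oracle: direct matrix algebra
  X <- cbind(1, d$beh, d$age, d$sex)
  beta <- solve(t(X) %*% X, t(X) %*% d$bag)
  r <- d$bag - X %*% beta
  s2 <- sum(r^2) / (12 - 4)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(g$estimate, beta[2], tolerance = 1e-12)
  expect_equal(g$t, beta[2] / se, tolerance = 1e-12)
  expect_equal(g$df, 8)
  expect_equal(g$p, 2 * pt(abs(beta[2] / se), 8, lower.tail = FALSE),
               tolerance = 1e-12)
  # perfect association: extreme t, tiny p
  set.seed(1)
  b <- rnorm(200)
  gg <- suppressWarnings(glm_bag_behavior(b, b, rnorm(200), rbinom(200, 1, 0.5)))
  expect_lt(gg$p, 1e-10)
})

test_that("omnibus partial F matches its RSS definition", {
  set.seed(2)
  n <- 60
  grp <- factor(rep(c("0", "1", ">=2"), each = 20), c("0", "1", ">=2"))
  age <- runif(n, 9, 15); sex <- rbinom(n, 1, 0.5)
  bag <- 0.5 * (grp == ">=2") + 0.1 * age + rnorm(n)
  g <- glm_group_effect(bag, grp, age, sex)
  full <- lm(bag ~ grp + age + sex)
  red <- lm(bag ~ age + sex)
  rss_f <- sum(resid(full)^2); rss_r <- sum(resid(red)^2)
  F_oracle <- ((rss_r - rss_f) / 2) / (rss_f / (n - 5))
  expect_equal(g$F, F_oracle, tolerance = 1e-10)
  expect_equal(g$df1, 2)
  expect_equal(g$df2, n - 5)
  # identical value multisets in every group: between-group SS = 0, F = 0
  v <- rnorm(20)
  g0 <- glm_group_effect(rep(v, 3), factor(rep(c("a", "b", "c"), each = 20)))
  expect_equal(g0$F, 0, tolerance = 1e-12)
  expect_error(glm_group_effect(bag[1:21], grp[1:21], age[1:21], sex[1:21]),
               "< 2 members")
})

test_that("Tukey p-values follow the studentized-range distribution", {
  set.seed(3)
  n <- 40
  grp <- factor(rep(c("A", "B"), c(25, 15)))
  age <- runif(n, 9, 15); sex <- rbinom(n, 1, 0.5)
  bag <- 0.8 * (grp == "B") + rnorm(n)
  g <- glm_group_effect(bag, grp, age, sex)
  # two groups: Tukey reduces to the studentized-range transform of the
  # pairwise statistic
  ph <- g$posthoc
  q <- abs(ph$estimate) / (ph$se / sqrt(2))
  expect_equal(ph$p_tukey, ptukey(q, 2, n - 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # with 2 groups, Tukey p equals the partial-F / t-test p
  expect_equal(ph$p_tukey, g$p, tolerance = 1e-8)
})

test_that("adjusted means and Tukey contrasts match emmeans", {
  set.seed(4)
  n <- 90
  grp <- factor(sample(c("0", "1", ">=2"), n, TRUE, prob = c(0.6, 0.25, 0.15)),
                c("0", "1", ">=2"))
  age <- runif(n, 9, 15); sex <- rbinom(n, 1, 0.5)
  bag <- -0.7 * (grp == ">=2") + 0.2 * age + rnorm(n)
  g <- glm_group_effect(bag, grp, age, sex)
  fit <- lm(bag ~ group + age + sex,
            data = data.frame(bag, group = grp, age, sex))
  # adjusted means = model predictions at the observed covariate means
  nd <- data.frame(group = factor(levels(grp), levels(grp)),
                   age = mean(age), sex = mean(sex))
  expect_equal(unname(g$adjusted_means), unname(predict(fit, nd)),
               tolerance = 1e-10)
  em <- emmeans::emmeans(fit, "group")
  pr <- summary(emmeans::contrast(em, "pairwise"), adjust = "tukey")
  expect_equal(g$posthoc$estimate, pr$estimate, tolerance = 1e-8)
  expect_equal(g$posthoc$se, pr$SE, tolerance = 1e-8)
  expect_equal(g$posthoc$p_tukey, pr$p.value, tolerance = 1e-6)
})

test_that("higher diagnosis load goes with lower adjusted BAG on planted data", {
  n_rep <- 20
  ok <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cc <- cohort_config(n_subjects = 1500, catalog = small_catalog(),
                        nodes_per_tract = 2, liability_weight = 0.3,
                        seed = 1500 + r)
    sim <- simulate_cohort(cc)
    # association-system BAG measure: planted deviation plus estimation noise
    set.seed(1600 + r)
    bagm <- rowMeans(sim$truth$dev_system[, c("dorsal-association",
                                              "ventral-association")]) +
      rnorm(1500, 0, 1)
    cb <- sim$cohort[sim$cohort$visit == "baseline", ]
    g <- glm_group_effect(bagm, sim$diagnosis$class_baseline, cb$age, cb$sex)
    ok[r] <- which.min(g$adjusted_means) == 3
  }
  expect_gte(mean(ok), 0.9)
})

test_that("GAM delta R-squared behaves at the null and at saturation", {
  set.seed(5)
  n <- 1000
  age <- runif(n, 8, 20); sex <- rbinom(n, 1, 0.5)
  # null: outcome independent of BAG
  d0 <- vapply(1:20, function(i) {
    out <- 0.3 * age + rnorm(n)
    gam_delta_r2(out, rnorm(n), age, sex)$delta_r2_pct
  }, numeric(1))
  expect_lt(abs(median(d0)), 0.1)
  # saturation: outcome equals the BAG exactly
  bag <- rnorm(n)
  gs <- suppressWarnings(gam_delta_r2(bag, bag, age, sex))
  expect_gt(gs$delta_r2_pct, 95)
  # linear age effect: GAM and linear-model delta R2 agree closely
  out <- 0.5 * age + 0.4 * bag + rnorm(n)
  gg <- gam_delta_r2(out, bag, age, sex)
  r2 <- function(f) summary(f)$adj.r.squared
  lin <- 100 * (r2(lm(out ~ bag + age + sex)) - r2(lm(out ~ age + sex)))
  expect_lt(abs(gg$delta_r2_pct - lin), 0.2)
})

test_that("mixed model recovers planted effects and degenerates to OLS", {
  set.seed(6)
  n <- 400
  subj <- rep(sprintf("s%03d", 1:n), each = 2)
  tp <- rep(c("baseline", "followup"), n)
  age <- rep(runif(n, 9, 12), each = 2) + (tp == "followup") * 2
  sex <- rep(rbinom(n, 1, 0.5), each = 2)
  pred <- rnorm(2 * n)
  # zero between-subject variance: fixed effects match OLS
  bag0 <- 0.3 * pred + 0.1 * age + rnorm(2 * n)
  f0 <- lmm_developmental(bag0, pred, age, sex, tp, subj)
  ols <- coef(summary(lm(bag0 ~ pred + age + sex + tp)))["pred", ]
  expect_lt(f0$ranef_var, 0.05)
  expect_equal(f0$estimate, ols["Estimate"], tolerance = 0.01,
               ignore_attr = TRUE)
  # planted beta1 = 0.3 with real between-subject variance
  n2 <- 2000
  subj2 <- rep(sprintf("t%04d", 1:n2), each = 2)
  tp2 <- rep(c("baseline", "followup"), n2)
  age2 <- rep(runif(n2, 9, 12), each = 2) + (tp2 == "followup") * 2
  sex2 <- rep(rbinom(n2, 1, 0.5), each = 2)
  pred2 <- rnorm(2 * n2)
  u <- rep(rnorm(n2, 0, 1), each = 2)
  bag1 <- 0.3 * pred2 + u + rnorm(2 * n2, 0, 0.7)
  f1 <- lmm_developmental(bag1, pred2, age2, sex2, tp2, subj2)
  expect_lt(abs(f1$estimate - 0.3), 0.05)
  expect_gt(f1$ranef_var, 0.5)
  expect_error(lmm_developmental(rnorm(5), rnorm(5), rnorm(5),
                                 rbinom(5, 1, 0.5), rep("b", 5),
                                 paste0("s", 1:5)), "repeated visits")
})

test_that("balanced-design LMM fixed effects match the closed-form GLS", {
  set.seed(7)
  n <- 150
  subj <- rep(sprintf("s%03d", 1:n), each = 2)
  pred <- rnorm(2 * n)
  u <- rep(rnorm(n, 0, 1), each = 2)
  bag <- 0.4 * pred + u + rnorm(2 * n, 0.5)
  tp <- rep(c("baseline", "followup"), n)
  age <- rep(runif(n, 9, 12), each = 2); sex <- rep(rbinom(n, 1, 0.5), each = 2)
  f <- lmm_developmental(bag, pred, age, sex, tp, subj)
  # GLS with the fitted variance components
  vc <- as.data.frame(lme4::VarCorr(f$model))
  s2u <- vc$vcov[vc$grp == "subject"]; s2e <- vc$vcov[vc$grp == "Residual"]
  V <- kronecker(diag(n), matrix(s2u, 2, 2) + diag(s2e, 2))
  X <- model.matrix(~ pred + age + sex + tp)
  Vi <- solve(V)
  beta_gls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% bag)
  expect_equal(f$estimate, beta_gls["pred", 1], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("PDS sums map onto the five pubertal stages", {
  # males
  expect_equal(as.character(pds_categorize(1, 12)), "postpubertal")
  expect_equal(as.character(pds_categorize(1, 3)), "prepubertal")
  expect_equal(as.character(pds_categorize(1, c(4, 5))),
               rep("early", 2))
  expect_equal(as.character(pds_categorize(1, 6:8)), rep("mid", 3))
  expect_equal(as.character(pds_categorize(1, 9:11)), rep("late", 3))
  # females
  expect_equal(as.character(pds_categorize(0, 2, menarche = 0)),
               "prepubertal")
  expect_equal(as.character(pds_categorize(0, 3, menarche = 0)), "early")
  expect_equal(as.character(pds_categorize(0, 5, menarche = 0)), "mid")
  expect_equal(as.character(pds_categorize(0, 7, menarche = 1)), "late")
  expect_equal(as.character(pds_categorize(0, 8, menarche = 1)),
               "postpubertal")
  expect_error(pds_categorize(1, 13), "out of range")
  expect_error(pds_categorize(0, 9), "out of range")
})

test_that("Spearman similarity matches brute-force enumeration", {
  a <- c(3.2, 1.5, 4.4, 2.2, 5.0, 0.7)
  b <- c(2.9, 2.0, 3.1, 1.2, 4.8, 1.1)
  r <- effect_pattern_similarity(a, b)
  # independent oracle: all 720 permutations, rho via the 6*sum(d^2) formula
  ra <- rank(a); rb <- rank(b); n <- 6
  rho_d <- function(x, y) 1 - 6 * sum((x - y)^2) / (n * (n^2 - 1))
  rho_obs <- rho_d(ra, rb)
  perm_one <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perm_one(v[-i]), function(w) c(v[i], w)))
    out
  }
  rhos <- vapply(perm_one(ra), rho_d, numeric(1), y = rb)
  expect_equal(r$rho, rho_obs, tolerance = 1e-12)
  expect_equal(r$p, mean(abs(rhos) >= abs(rho_obs) - 1e-12),
               tolerance = 1e-12)
  expect_equal(r$method, "exact permutation")
  # extremes
  expect_equal(effect_pattern_similarity(a, a)$rho, 1)
  expect_equal(effect_pattern_similarity(a, -a)$rho, -1)
  # long vectors switch to the t approximation
  set.seed(8)
  long <- effect_pattern_similarity(rnorm(25), rnorm(25))
  expect_equal(long$method, "t approximation")
  expect_error(effect_pattern_similarity(rep(1, 6), a), "constant")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.01, 0.04, 0.2, 0.9)
  adj <- bh_fdr(p)
  expect_true(all(diff(adj[order(p)]) >= 0))     # monotone
  expect_true(all(adj >= p))                     # never below raw
})

test_that("null rejection rates stay at the nominal level", {
  set.seed(9)
  n_rep <- 200
  rej_glm <- rej_F <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    n <- 60
    age <- runif(n, 9, 15); sex <- rbinom(n, 1, 0.5)
    bag <- 0.2 * age + rnorm(n)
    rej_glm[r] <- glm_bag_behavior(bag, rnorm(n), age, sex)$p < 0.05
    grp <- factor(sample(c("a", "b", "c"), n, TRUE))
    rej_F[r] <- glm_group_effect(bag, grp, age, sex)$p < 0.05
  }
  ci <- qbinom(c(0.005, 0.995), n_rep, 0.05) / n_rep
  expect_gte(mean(rej_glm), ci[1]); expect_lte(mean(rej_glm), ci[2])
  expect_gte(mean(rej_F), ci[1]); expect_lte(mean(rej_F), ci[2])
})
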