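#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR adjustment (wrapper over `stats::p.adjust(method = "BH")`),
#' monotone non-decreasing in the raw p and never below it.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' GLM association between a BAG measure and a behavioral score
#'
#' `BAG = b0 + b1 Behavior + b2 Age + b3 Sex` by OLS on complete cases; the
#' t statistic for `b1` is reported. FDR correction over the full family of
#' tested (model x behavior) pairs is the caller's responsibility (see
#' [bh_fdr()]).
#'
#' @param bag BAG values.
#' @param behavior behavioral scores.
#' @param age,sex covariates.
#' @return List: `estimate`, `se`, `t`, `df`, `p`, `n`.
#' @export
glm_bag_behavior <- function(bag, behavior, age, sex) {
  cc <- stats::complete.cases(bag, behavior, age, sex)
  if (sum(cc) <= 10) stop("need > 10 complete cases")
  fit <- stats::lm(bag ~ behavior + age + sex, subset = cc)
  if (fit$rank < 4) stop("rank-deficient design")
  s <- summary(fit)$coefficients
  list(estimate = s["behavior", 1], se = s["behavior", 2],
       t = s["behavior", 3], df = fit$df.residual, p = s["behavior", 4],
       n = sum(cc))
}

#' Covariate-adjusted group effect on a BAG measure with Tukey post-hocs
#'
#' Omnibus test of a group factor (diagnosis-count class 0/1/>=2 or
#' diagnostic-transition class HH/PH/HP/PP) on a BAG measure, controlling
#' for age and sex: partial F comparing the models with and without the
#' factor columns. Post-hoc pairwise comparisons use Tukey's HSD on
#' covariate-adjusted means via the studentized-range distribution, with
#' unequal group sizes handled by the Tukey-Kramer form (the pairwise SE
#' comes from the covariance of the adjusted-mean contrast).
#'
#' @param bag BAG values.
#' @param group factor of group labels (every group needs >= 2 members).
#' @param age,sex covariates; set both to `NULL` for raw (unadjusted) group
#'   means.
#' @return List: `F`, `df1`, `df2`, `p`, `adjusted_means` (named), and
#'   `posthoc` data.frame (`contrast`, `estimate`, `se`, `z`, `p_tukey`).
#' @export
glm_group_effect <- function(bag, group, age = NULL, sex = NULL) {
  group <- droplevels(factor(group))
  k <- nlevels(group)
  if (k < 2) stop("need >= 2 groups")
  if (any(table(group) < 2)) stop("a group has < 2 members")
  dat <- data.frame(bag = bag, group = group)
  covs <- character(0)
  if (!is.null(age)) { dat$age <- age; covs <- c(covs, "age") }
  if (!is.null(sex)) { dat$sex <- sex; covs <- c(covs, "sex") }
  dat <- dat[stats::complete.cases(dat), ]
  rhs_red <- if (length(covs)) paste(covs, collapse = " + ") else "1"
  full <- stats::lm(stats::as.formula(paste("bag ~ group +", rhs_red)),
                    data = dat)
  red <- stats::lm(stats::as.formula(paste("bag ~", rhs_red)), data = dat)
  rss_f <- sum(stats::resid(full)^2)
  rss_r <- sum(stats::resid(red)^2)
  df1 <- full$rank - red$rank
  df2 <- full$df.residual
  Fstat <- max(rss_r - rss_f, 0) / df1 / (rss_f / df2)
  pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)

  # adjusted means: predictions at the observed covariate means
  cf <- stats::coef(full)
  V <- stats::vcov(full)
  lvl <- levels(dat$group)
  Cmat <- matrix(0, k, length(cf), dimnames = list(lvl, names(cf)))
  Cmat[, "(Intercept)"] <- 1
  for (g in lvl[-1]) Cmat[g, paste0("group", g)] <- 1
  for (cv in covs) Cmat[, cv] <- mean(dat[[cv]])
  adj <- drop(Cmat %*% cf)

  pairs <- utils::combn(lvl, 2)
  ph <- data.frame(contrast = apply(pairs, 2, paste, collapse = " - "),
                   estimate = NA_real_, se = NA_real_, z = NA_real_,
                   p_tukey = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    cvec <- Cmat[pairs[1, j], ] - Cmat[pairs[2, j], ]
    est <- sum(cvec * cf)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    q <- abs(est) / (se / sqrt(2))
    ph$estimate[j] <- est; ph$se[j] <- se; ph$z[j] <- est / se
    ph$p_tukey[j] <- stats::ptukey(q, nmeans = k, df = full$df.residual,
                                   lower.tail = FALSE)
  }
  list(F = Fstat, df1 = df1, df2 = df2, p = pval,
       adjusted_means = adj, posthoc = ph, n = nrow(dat))
}

#' GAM effect size of a BAG predictor on an outcome
#'
#' Fits a covariates-only GAM (penalized cubic spline in age, REML
#' smoothing, basis dimension `k_basis`, plus sex) and the same model with a
#' linear BAG term; reports the change in adjusted R-squared as a
#' percentage, `100 * (R2adj_full - R2adj_null)`, together with the F
#' statistic and p for the added term.
#'
#' @param outcome outcome scores (e.g. follow-up cognition).
#' @param bag BAG predictor.
#' @param age,sex covariates.
#' @param k_basis spline basis dimension.
#' @return List: `delta_r2_pct`, `F`, `p`, `r2_null`, `r2_full`, `n`.
#' @export
gam_delta_r2 <- function(outcome, bag, age, sex, k_basis = 10) {
  cc <- stats::complete.cases(outcome, bag, age, sex)
  if (sum(cc) <= 50) stop("need > 50 complete cases")
  dat <- data.frame(outcome = outcome, bag = bag, age = age, sex = sex)[cc, ]
  null <- mgcv::gam(outcome ~ s(age, k = k_basis, bs = "cs") + sex,
                    data = dat, method = "REML")
  full <- mgcv::gam(outcome ~ bag + s(age, k = k_basis, bs = "cs") + sex,
                    data = dat, method = "REML")
  sf <- summary(full); sn <- summary(null)
  tval <- sf$p.table["bag", "t value"]
  list(delta_r2_pct = 100 * (sf$r.sq - sn$r.sq),
       F = tval^2, p = sf$p.table["bag", "Pr(>|t|)"],
       r2_null = sn$r.sq, r2_full = sf$r.sq, n = nrow(dat))
}

#' Random-intercept mixed model for developmental predictors of BAG
#'
#' `BAG ~ predictor + age + sex + timepoint (+ collection covariates) +
#' (1 | subject)` fit by REML with Satterthwaite degrees of freedom for the
#' predictor's t statistic (the pubertal-stage and hormone models).
#'
#' @param bag BAG values, one per subject-visit row.
#' @param predictor pubertal stage (numeric/ordered) or hormone level.
#' @param age,sex,timepoint covariates per row.
#' @param subject subject identifiers (repeated across visits).
#' @param extra_covariates optional data.frame of additional fixed effects
#'   (e.g. caffeine intake, physical activity, collection time/duration,
#'   freeze time for the hormone models).
#' @return List: `estimate`, `se`, `t`, `df` (Satterthwaite), `p`,
#'   `ranef_var`, `singular`, `n`, and the fitted `model`.
#' @export
lmm_developmental <- function(bag, predictor, age, sex, timepoint, subject,
                              extra_covariates = NULL) {
  dat <- data.frame(bag = bag, predictor = predictor, age = age, sex = sex,
                    timepoint = timepoint, subject = subject)
  rhs <- "predictor + age + sex + timepoint"
  if (!is.null(extra_covariates)) {
    extra_covariates <- as.data.frame(extra_covariates)
    dat <- cbind(dat, extra_covariates)
    rhs <- paste(rhs, "+", paste(names(extra_covariates), collapse = " + "))
  }
  dat <- dat[stats::complete.cases(dat), ]
  if (!any(duplicated(dat$subject)))
    stop("need repeated visits for at least some subjects")
  fml <- stats::as.formula(paste("bag ~", rhs, "+ (1 | subject)"))
  fit <- lmerTest::lmer(fml, data = dat, REML = TRUE)
  singular <- lme4::isSingular(fit)
  s <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  rv <- vc$vcov[vc$grp == "subject"]
  list(estimate = s["predictor", "Estimate"], se = s["predictor", "Std. Error"],
       t = s["predictor", "t value"], df = s["predictor", "df"],
       p = s["predictor", "Pr(>|t|)"], ranef_var = rv,
       singular = singular, n = nrow(dat), model = fit)
}

#' Categorize Pubertal Development Scale sums into pubertal stages
#'
#' Deterministic 5-level staging from the sex-specific PDS category sums.
#' Males (3 items, sum 3-12): prepubertal (3), early (4-5), mid (6-8),
#' late (9-11), postpubertal (12). Females (2 items, sum 2-8): prepubertal
#' (2), early (3, no menarche), mid (>3, no menarche), late (<= 7 with
#' menarche), postpubertal (8 with menarche).
#'
#' @param sex 1 = male, 0 = female (vectorized).
#' @param pds_sum sex-specific PDS category sum.
#' @param menarche menarche indicator (females; ignored for males).
#' @return Ordered factor with levels `prepubertal < early < mid < late <
#'   postpubertal`.
#' @export
pds_categorize <- function(sex, pds_sum, menarche = NA) {
  n <- length(pds_sum)
  sex <- rep_len(sex, n); menarche <- rep_len(menarche, n)
  male <- sex == 1
  bad <- (male & (pds_sum < 3 | pds_sum > 12)) |
    (!male & (pds_sum < 2 | pds_sum > 8))
  if (any(bad, na.rm = TRUE))
    stop("PDS sum out of range for ", sum(bad, na.rm = TRUE), " subject(s)")
  stage <- rep(NA_character_, n)
  stage[male & pds_sum == 3] <- "prepubertal"
  stage[male & pds_sum %in% 4:5] <- "early"
  stage[male & pds_sum >= 6 & pds_sum <= 8] <- "mid"
  stage[male & pds_sum >= 9 & pds_sum <= 11] <- "late"
  stage[male & pds_sum == 12] <- "postpubertal"
  fem <- !male
  stage[fem & pds_sum == 2] <- "prepubertal"
  stage[fem & pds_sum == 3 & menarche %in% 0] <- "early"
  stage[fem & pds_sum > 3 & menarche %in% 0] <- "mid"
  stage[fem & pds_sum <= 7 & pds_sum > 2 & menarche %in% 1] <- "late"
  stage[fem & pds_sum == 8 & menarche %in% 1] <- "postpubertal"
  factor(stage, levels = c("prepubertal", "early", "mid", "late",
                           "postpubertal"), ordered = TRUE)
}

# all permutations of 1..n as a matrix (n! rows); used by the exact
# Spearman permutation p — n is expected to be small (<= 10)
.perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Spearman similarity between two tract-wise effect patterns
#'
#' Spearman rank correlation with average ranks for ties; two-sided p by
#' exact permutation enumeration when the vectors have <= `exact_max`
#' elements, otherwise by the t approximation.
#'
#' @param effects_a,effects_b numeric vectors over the same tracts (length
#'   >= 5).
#' @param exact_max maximum length for exact enumeration (n! permutations).
#' @return List: `rho`, `p`, `method`.
#' @export
effect_pattern_similarity <- function(effects_a, effects_b, exact_max = 10L) {
  stopifnot(length(effects_a) == length(effects_b), length(effects_a) >= 5)
  if (stats::sd(effects_a) == 0 || stats::sd(effects_b) == 0)
    stop("constant effect vector")
  n <- length(effects_a)
  ra <- rank(effects_a); rb <- rank(effects_b)
  rho <- stats::cor(ra, rb)
  if (n <= exact_max) {
    pm <- .perms(n)
    rhos <- as.numeric(stats::cor(rb, t(matrix(ra[pm], nrow(pm), n))))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
    method <- "t approximation"
  }
  list(rho = rho, p = p, method = method)
}
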