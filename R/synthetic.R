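#' Configure a synthetic developmental cohort
#'
#' Builds a fully specified generative configuration for a synthetic cohort
#' whose statistical structure mirrors what the downstream analysis stages
#' assume: sigmoidal FA maturation along tract nodes, additive/multiplicative
#' site effects, subject-level maturational deviations shared within tract
#' systems, two latent modes coupling those deviations to behavior blocks,
#' liability-threshold diagnosis counts at two visits, and puberty/hormone
#' variables correlated with age and deviation.
#'
#' All per-feature parameters (growth curves, site effects) are drawn once,
#' deterministically, from `seed` at configuration time, so a config is a
#' concrete, reproducible parameterization.
#'
#' @param n_subjects number of subjects.
#' @param age_range baseline age range in years, `c(min, max)`.
#' @param n_sites number of acquisition sites.
#' @param catalog tract catalog (see [tract_catalog()]); may be a subset for
#'   reduced problem sizes.
#' @param nodes_per_tract along-tract nodes per unilateral tract (>= 2).
#' @param deviation_sd SD (years) of the tract-system maturational deviation —
#'   the planted ground-truth brain-age gap.
#' @param system_cor correlation induced between the deviations of systems
#'   belonging to the same latent mode (association systems co-mature, and
#'   likewise the subcortical/limbic systems; this shared factor is what the
#'   mode's latent score captures).
#' @param tract_jitter_sd SD (years) of the small tract-level jitter added on
#'   top of the system deviation.
#' @param noise_sd_fa SD of i.i.d. FA measurement noise per node.
#' @param site_shift_sd SD of per-site, per-feature additive shifts (FA units);
#'   0 disables location effects.
#' @param site_scale_range range of per-site multiplicative noise-scale
#'   factors; `c(1, 1)` disables scale effects.
#' @param n_cognitive,n_psychopathology number of behavioral measures per block.
#' @param mode_coupling target correlation between each latent mode score and
#'   its behavior-block composite (mode 1: association systems vs cognition;
#'   mode 2: limbic/subcortical systems vs psychopathology).
#' @param noise_sd_behavior SD of behavioral measurement noise.
#' @param liability_weight correlation weight linking (negative) standardized
#'   association-system deviation to the diagnosis liability.
#' @param class_probs_baseline,class_probs_followup marginal probabilities of
#'   the 0 / 1 / >=2 diagnosis-count classes at each visit.
#' @param followup_liability_cor correlation between baseline and follow-up
#'   liabilities (drives the HH/PH/HP/PP transition cell sizes).
#' @param followup_fraction fraction of subjects with a 2-year follow-up visit.
#' @param seed integer seed; all randomness in configuration and simulation
#'   derives from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 600,
                          age_range = c(5.6, 21.9),
                          n_sites = 4,
                          catalog = tract_catalog(),
                          nodes_per_tract = 100,
                          deviation_sd = 2,
                          system_cor = 0.5,
                          tract_jitter_sd = 0.3,
                          noise_sd_fa = 0.03,
                          site_shift_sd = 0.02,
                          site_scale_range = c(0.8, 1.2),
                          n_cognitive = 20,
                          n_psychopathology = 31,
                          mode_coupling = c(0.3, 0.2),
                          noise_sd_behavior = 1,
                          liability_weight = 0.3,
                          class_probs_baseline = c(0.752, 0.156, 0.092),
                          class_probs_followup = c(0.793, 0.142, 0.065),
                          followup_liability_cor = 0.6,
                          followup_fraction = 0.67,
                          seed = 1L) {
  stopifnot(n_subjects >= 1, length(age_range) == 2, age_range[1] < age_range[2],
            n_sites >= 1, nodes_per_tract >= 2,
            deviation_sd >= 0, noise_sd_fa >= 0,
            system_cor >= 0, system_cor < 1,
            all(abs(mode_coupling) < 1), length(mode_coupling) == 2,
            abs(liability_weight) <= 1,
            abs(followup_liability_cor) < 1,
            abs(sum(class_probs_baseline) - 1) < 1e-8,
            abs(sum(class_probs_followup) - 1) < 1e-8)

  args <- list(n_subjects = n_subjects, age_range = age_range,
               n_sites = n_sites, nodes_per_tract = nodes_per_tract,
               deviation_sd = deviation_sd, system_cor = system_cor,
               tract_jitter_sd = tract_jitter_sd,
               noise_sd_fa = noise_sd_fa, site_shift_sd = site_shift_sd,
               site_scale_range = site_scale_range,
               n_cognitive = n_cognitive,
               n_psychopathology = n_psychopathology,
               mode_coupling = mode_coupling,
               noise_sd_behavior = noise_sd_behavior,
               liability_weight = liability_weight,
               class_probs_baseline = class_probs_baseline,
               class_probs_followup = class_probs_followup,
               followup_liability_cor = followup_liability_cor,
               followup_fraction = followup_fraction, seed = as.integer(seed))

  features <- .feature_index(catalog, nodes_per_tract)
  p <- nrow(features)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed) + 1000L)

  # smooth per-tract growth parameters with mild along-tract modulation
  tracts <- unique(features$pair_key)
  growth <- matrix(NA_real_, p, 4,
                   dimnames = list(NULL, c("f0", "f1", "k", "t0")))
  for (tk in tracts) {
    idx <- which(features$pair_key == tk)
    nd <- features$node[idx]
    f0 <- stats::runif(1, 0.25, 0.4)
    df <- stats::runif(1, 0.1, 0.2)
    k  <- stats::runif(1, 0.2, 0.5)
    t0 <- stats::runif(1, 9, 15)
    phase <- stats::runif(1, 0, 2 * pi)
    mod <- 0.03 * sin(2 * pi * nd / max(nd) + phase)
    growth[idx, "f0"] <- pmax(f0 + mod, 0.05)
    growth[idx, "f1"] <- pmin(f0 + df + mod, 0.95)
    growth[idx, "k"]  <- k
    growth[idx, "t0"] <- t0 + 2 * sin(2 * pi * nd / max(nd) + phase)
  }

  site_loc <- matrix(stats::rnorm(n_sites * p, 0, site_shift_sd), n_sites, p)
  site_scale <- matrix(stats::runif(n_sites * p, site_scale_range[1],
                                    site_scale_range[2]), n_sites, p)
  if (n_sites >= 1) {            # site 1 is the reference site
    site_loc[1, ] <- 0
    site_scale[1, ] <- 1
  }

  mode_spec <- list(
    list(systems = c("dorsal-association", "ventral-association"),
         block = "cognitive", r = mode_coupling[1]),
    list(systems = c("limbic", "thalamic", "corticostriatal"),
         block = "psychopathology", r = mode_coupling[2])
  )

  structure(list(args = args, catalog = catalog, features = features,
                 growth_params = growth, site_loc = site_loc,
                 site_scale = site_scale, mode_spec = mode_spec),
            class = "cohort_config")
}

.feature_index <- function(catalog, nodes_per_tract) {
  out <- catalog[rep(seq_len(nrow(catalog)), each = nodes_per_tract), ]
  out$node <- rep(seq_len(nodes_per_tract), nrow(catalog))
  out$pair_key <- paste(out$tract, out$hemisphere, sep = "_")
  out$feature <- paste(out$pair_key, out$node, sep = "_n")
  rownames(out) <- NULL
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Sigmoidal FA growth curve
#'
#' Logistic maturation curve for node-level fractional anisotropy:
#' `f0 + (f1 - f0) / (1 + exp(-k (age - t0)))`. Monotone increasing in age
#' with floor `f0`, ceiling `f1`, rate `k` (1/years) and midpoint `t0` (years).
#'
#' @param age age in years (vectorized).
#' @param params numeric vector or list with elements `f0`, `f1`, `k`, `t0`.
#' @return FA value(s) in `[f0, f1]`.
#' @export
#' @examples
#' growth_curve(12, c(f0 = 0.2, f1 = 0.6, k = 1, t0 = 12))  # 0.4
growth_curve <- function(age, params) {
  params <- as.list(params)
  f0 <- params$f0; f1 <- params$f1; k <- params$k; t0 <- params$t0
  vals <- c(f0, f1, k, t0)
  if (any(!is.finite(vals))) stop("growth_curve: non-finite parameters")
  if (k <= 0) stop("growth_curve: rate k must be > 0")
  f0 + (f1 - f0) / (1 + exp(-k * (age - t0)))
}

#' Simulate a synthetic cohort with planted developmental structure
#'
#' Generates subject covariates, along-tract FA profiles, behavioral measures
#' and two-visit diagnosis counts from a [cohort_config()]. Profiles follow
#' `growth_curve(age + system deviation + tract jitter)` plus site
#' location/scale effects and i.i.d. noise, clipped to the valid FA range
#' `[0, 1]`. Behavior blocks are linear in the standardized mean deviation of
#' the mode's tract systems; diagnosis counts come from thresholding a
#' liability negatively weighted on the association-system deviation, with a
#' correlated liability re-thresholded at follow-up to create the
#' HH/PH/HP/PP transition classes.
#'
#' @param config a `cohort_config`.
#' @return An object of class `cohort_sim`: a list with elements
#'   \describe{
#'     \item{cohort}{data.frame, one row per subject-visit (age, sex, site,
#'       visit, diagnosis count/class).}
#'     \item{profiles}{a `tract_profiles` object (values, feature index,
#'       subject keys); `attr(,"n_clipped")` records post-noise clipping.}
#'     \item{behavior}{subjects x 51 matrix (baseline visit), columns
#'       `cog_*` then `psy_*`.}
#'     \item{diagnosis}{per-subject table of the two visit classes and the
#'       transition class (NA transition without follow-up).}
#'     \item{truth}{planted ground truth: per-system and per-tract deviations
#'       (years), latent mode scores, behavior loading vectors.}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  a <- config$args
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(a$seed)

  n <- a$n_subjects
  feats <- config$features
  p <- nrow(feats)
  systems <- unique(config$catalog$system)

  subject_id <- sprintf("sub%04d", seq_len(n))
  age0 <- stats::runif(n, a$age_range[1], a$age_range[2])
  sex <- stats::rbinom(n, 1, 0.5)
  site <- sample(paste0("site", seq_len(a$n_sites)), n, replace = TRUE)
  has_fu <- stats::runif(n) < a$followup_fraction
  if (!any(has_fu)) has_fu[1] <- TRUE   # each analysis path needs >=1 follow-up

  # planted deviations (years): systems belonging to the same latent mode
  # share a common factor (correlation system_cor), plus a system-specific
  # part; other systems are independent; small tract-level jitter on top
  dev_sys <- matrix(NA_real_, n, length(systems),
                    dimnames = list(subject_id, systems))
  mode_of <- rep(NA_integer_, length(systems))
  for (m in seq_along(config$mode_spec))
    mode_of[systems %in% config$mode_spec[[m]]$systems] <- m
  common <- matrix(stats::rnorm(n * length(config$mode_spec)), n)
  for (s in seq_along(systems)) {
    eps <- stats::rnorm(n)
    z <- if (is.na(mode_of[s])) eps else
      sqrt(a$system_cor) * common[, mode_of[s]] + sqrt(1 - a$system_cor) * eps
    dev_sys[, s] <- a$deviation_sd * z
  }
  pairs <- unique(config$catalog$pair_id)
  pair_sys <- config$catalog$system[match(pairs, config$catalog$pair_id)]
  dev_tract <- dev_sys[, pair_sys, drop = FALSE] +
    matrix(stats::rnorm(n * length(pairs), 0, a$tract_jitter_sd), n, length(pairs))
  colnames(dev_tract) <- pairs

  # subject-visit roster
  cohort <- data.frame(
    subject_id = c(subject_id, subject_id[has_fu]),
    visit = c(rep("baseline", n), rep("followup2y", sum(has_fu))),
    stringsAsFactors = FALSE)
  ix <- match(cohort$subject_id, subject_id)
  cohort$age <- age0[ix] + ifelse(cohort$visit == "followup2y", 2, 0)
  cohort$sex <- sex[ix]
  cohort$site <- site[ix]

  # FA profiles per subject-visit
  values <- matrix(NA_real_, nrow(cohort), p)
  site_idx <- match(cohort$site, paste0("site", seq_len(a$n_sites)))
  for (tk in unique(feats$pair_key)) {
    fidx <- which(feats$pair_key == tk)
    pair <- feats$pair_id[fidx[1]]
    age_eff <- cohort$age + dev_tract[ix, pair]
    gp <- config$growth_params[fidx, , drop = FALSE]
    # nodes in columns: logistic evaluated on the outer (subject, node) grid
    d <- sweep(outer(age_eff, gp[, "t0"], "-"), 2, gp[, "k"], "*")
    sig <- 1 / (1 + exp(-d))
    values[, fidx] <- sweep(sweep(sig, 2, gp[, "f1"] - gp[, "f0"], "*"),
                            2, gp[, "f0"], "+")
  }
  eps <- matrix(stats::rnorm(length(values), 0, a$noise_sd_fa),
                nrow(values), ncol(values))
  values <- values + config$site_loc[site_idx, , drop = FALSE] +
    config$site_scale[site_idx, , drop = FALSE] * eps
  n_clipped <- sum(values < 0 | values > 1)
  values[values < 0] <- 0
  values[values > 1] <- 1
  colnames(values) <- feats$feature
  rownames(values) <- paste(cohort$subject_id, cohort$visit, sep = ".")

  profiles <- tract_profiles(values, feats,
                             subjects = cohort[, c("subject_id", "visit")])
  attr(profiles, "n_clipped") <- n_clipped

  # latent mode scores and behavior (baseline)
  truth_latent <- sapply(config$mode_spec, function(m) {
    sys_cols <- intersect(m$systems, colnames(dev_sys))
    s <- rowMeans(dev_sys[, sys_cols, drop = FALSE])
    as.numeric(scale(s))
  })
  colnames(truth_latent) <- c("mode1", "mode2")

  q1 <- a$n_cognitive; q2 <- a$n_psychopathology
  beh_names <- c(sprintf("cog_%02d", seq_len(q1)), sprintf("psy_%02d", seq_len(q2)))
  W <- matrix(0, q1 + q2, 2, dimnames = list(beh_names, c("mode1", "mode2")))
  W[seq_len(q1), 1] <- 1 / sqrt(q1)
  W[q1 + seq_len(q2), 2] <- 1 / sqrt(q2)
  # scale s.t. cor(w' y, latent) = r given unit-norm w and noise sd
  r <- a$mode_coupling
  s_mode <- ifelse(abs(r) > 0, a$noise_sd_behavior * r / sqrt(1 - r^2), 0)
  B <- sweep(W, 2, s_mode, "*")
  behavior <- truth_latent %*% t(B) +
    matrix(stats::rnorm(n * (q1 + q2), 0, a$noise_sd_behavior), n, q1 + q2)
  dimnames(behavior) <- list(subject_id, beh_names)

  # liability-threshold diagnosis counts, two visits
  assoc <- rowMeans(dev_sys[, intersect(c("dorsal-association",
                                          "ventral-association"), systems),
                            drop = FALSE])
  z_assoc <- as.numeric(scale(assoc))
  w <- a$liability_weight
  L1 <- -w * z_assoc + sqrt(1 - w^2) * stats::rnorm(n)
  rho <- a$followup_liability_cor
  L2 <- rho * L1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cls1 <- .threshold_liability(L1, a$class_probs_baseline)
  cls2 <- .threshold_liability(L2, a$class_probs_followup)
  count1 <- c(0L, 1L, 2L)[cls1]
  count2 <- c(0L, 1L, 2L)[cls2]
  transition <- ifelse(count1 == 0,
                       ifelse(count2 == 0, "HH", "HP"),
                       ifelse(count2 == 0, "PH", "PP"))
  transition[!has_fu] <- NA_character_
  diagnosis <- data.frame(subject_id = subject_id,
                          class_baseline = factor(cls1, 1:3, c("0", "1", ">=2")),
                          class_followup = factor(cls2, 1:3, c("0", "1", ">=2")),
                          count_baseline = count1, count_followup = count2,
                          transition = factor(transition,
                                              c("HH", "PH", "HP", "PP")),
                          has_followup = has_fu, stringsAsFactors = FALSE)

  cohort$diagnosis_count <- ifelse(cohort$visit == "baseline",
                                   count1[ix], count2[ix])
  cohort$diagnosis_class <- factor(ifelse(cohort$diagnosis_count >= 2, ">=2",
                                          as.character(cohort$diagnosis_count)),
                                   levels = c("0", "1", ">=2"))

  out <- list(cohort = cohort, profiles = profiles, behavior = behavior,
              diagnosis = diagnosis,
              truth = list(dev_system = dev_sys, dev_tract = dev_tract,
                           latent = truth_latent, behavior_loadings = W,
                           liability = cbind(baseline = L1, followup = L2)),
              config = config)
  class(out) <- "cohort_sim"
  out
}

.threshold_liability <- function(L, probs) {
  thr <- stats::qnorm(cumsum(probs))[1:2]
  findInterval(L, thr) + 1L       # 1: none, 2: one, 3: >=2 diagnoses
}

#' Along-tract FA profile matrix
#'
#' Container pairing a subjects-by-features FA matrix with its feature index
#' (tract, hemisphere, node, system) and subject-visit keys.
#'
#' @param values numeric matrix, rows = subject-visits, columns = features.
#' @param features data.frame with columns `tract`, `hemisphere`, `node`,
#'   `system`, `pair_id` (one row per column of `values`).
#' @param subjects data.frame with columns `subject_id`, `visit`.
#' @return An object of class `tract_profiles`.
#' @export
tract_profiles <- function(values, features, subjects) {
  stopifnot(is.matrix(values), nrow(features) == ncol(values),
            nrow(subjects) == nrow(values),
            all(c("tract", "hemisphere", "node", "system", "pair_id")
                %in% names(features)))
  if (anyNA(values)) stop("tract_profiles: missing FA values")
  structure(list(values = values, features = features, subjects = subjects),
            class = "tract_profiles")
}

#' @export
print.tract_profiles <- function(x, ...) {
  cat(sprintf("tract_profiles: %d subject-visits x %d features (%d tracts x %d nodes)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$features$pair_key %||% paste(x$features$tract,
                                                           x$features$hemisphere))),
              max(x$features$node)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Augment a simulated cohort with puberty and hormone variables
#'
#' Adds Pubertal Development Scale (PDS) item scores, a menarche indicator,
#' salivary hormone levels (DHEA, testosterone; estradiol for females), and
#' saliva-collection covariates to each subject-visit row. PDS items increase
#' stochastically with age and with the planted association-system deviation;
#' hormones are log-normal in age and deviation, truncated to the standard
#' biological plausibility ranges (DHEA 5-1000, testosterone 5-500, estradiol
#' 0-1500 pg/ml).
#'
#' @param sim a `cohort_sim`.
#' @param age_slope per-year slopes of the latent puberty score and of
#'   log-hormone levels; named list with `puberty`, `dhea`, `testosterone`,
#'   `estradiol` (set to 0 to decouple from age).
#' @param deviation_coupling slope of latent puberty / log-hormones on the
#'   standardized association-system deviation.
#' @param seed integer seed (defaults to the cohort seed + 1).
#' @return The `cohort_sim` with augmented `$cohort` columns: `pds_item1..3`,
#'   `menarche`, `pds_sum`, `dhea`, `testosterone`, `estradiol`,
#'   `caffeine_intake`, `physical_activity`, `collection_time`,
#'   `collection_duration`, `freeze_time`.
#' @export
simulate_puberty_hormones <- function(sim,
                                      age_slope = list(puberty = 0.5,
                                                       dhea = 0.18,
                                                       testosterone = 0.25,
                                                       estradiol = 0.15),
                                      deviation_coupling = 0.2,
                                      seed = NULL) {
  stopifnot(inherits(sim, "cohort_sim"))
  co <- sim$cohort
  if (is.null(seed)) seed <- sim$config$args$seed + 1L
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  n <- nrow(co)
  sid <- match(co$subject_id, rownames(sim$truth$dev_system))
  zdev <- as.numeric(scale(rowMeans(
    sim$truth$dev_system[, intersect(c("dorsal-association",
                                       "ventral-association"),
                                     colnames(sim$truth$dev_system)),
                         drop = FALSE])))[sid]

  latent <- age_slope$puberty * (co$age - 12) + deviation_coupling * zdev +
    stats::rnorm(n, 0, 0.8)
  item <- function() pmin(pmax(round(2.5 + 0.6 * latent +
                                       stats::rnorm(n, 0, 0.5)), 1), 4)
  co$pds_item1 <- item(); co$pds_item2 <- item()
  co$pds_item3 <- ifelse(co$sex == 1, item(), NA_integer_)  # males: 3 items
  co$menarche <- ifelse(co$sex == 0,
                        as.integer(stats::runif(n) <
                                     stats::plogis(1.2 * (latent - 0.5))), NA)
  co$pds_sum <- ifelse(co$sex == 1,
                       co$pds_item1 + co$pds_item2 + co$pds_item3,
                       co$pds_item1 + co$pds_item2)

  draw_hormone <- function(mu0, slope, lo, hi, sdlog = 0.6, female_only = FALSE) {
    m <- mu0 + slope * (co$age - 12) + deviation_coupling * zdev
    h <- exp(stats::rnorm(n, m, sdlog))
    for (i in 1:50) {             # resample out-of-range draws, then clamp
      bad <- h < lo | h > hi
      if (!any(bad)) break
      h[bad] <- exp(stats::rnorm(sum(bad), m[bad], sdlog))
    }
    h <- pmin(pmax(h, lo), hi)
    if (female_only) h[co$sex == 1] <- NA_real_
    h
  }
  co$dhea <- draw_hormone(log(60), age_slope$dhea, 5, 1000)
  co$testosterone <- draw_hormone(log(40), age_slope$testosterone, 5, 500)
  co$estradiol <- draw_hormone(log(100), age_slope$estradiol, 0.5, 1500,
                               sdlog = 0.7, female_only = TRUE)

  co$caffeine_intake <- stats::rbinom(n, 1, 0.3)
  co$physical_activity <- stats::rbinom(n, 1, 0.5)
  co$collection_time <- stats::runif(n, 420, 1140)     # minutes since midnight
  co$collection_duration <- stats::runif(n, 2, 10)
  co$freeze_time <- stats::runif(n, 30, 600)

  sim$cohort <- co
  sim
}

#' Behavior-block composite score
#'
#' The generator's block composite: the loading-weighted combination of a
#' behavior block, against which the mode coupling `r` is defined.
#'
#' @param sim a `cohort_sim`.
#' @param mode 1 or 2.
#' @return Numeric vector, one value per subject.
#' @export
behavior_composite <- function(sim, mode = 1) {
  W <- sim$truth$behavior_loadings[, mode]
  as.numeric(sim$behavior %*% W)
}
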