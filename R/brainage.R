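#' Assemble model features from tract profiles
#'
#' Builds the feature matrix for one brain-age model unit: a bilateral pair
#' (left nodes 1..N then right nodes 1..N, p = 2N), a callosal tract (p = N),
#' or the whole-brain concatenation of all tracts (p = n_tracts x N).
#'
#' @param profiles a `tract_profiles` object.
#' @param tract a pair id from [tract_pairs()], or `"whole-brain"`.
#' @return List with `x` (subjects x p matrix, deterministic column order),
#'   `tract`, and `rule` (one of `"bilateral"`, `"callosal"`,
#'   `"whole-brain"`).
#' @export
assemble_features <- function(profiles, tract) {
  stopifnot(inherits(profiles, "tract_profiles"))
  f <- profiles$features
  if (identical(tract, "whole-brain")) {
    ord <- order(match(f$pair_id, unique(f$pair_id)),
                 match(f$hemisphere, c("L", "R", "M")), f$node)
    return(list(x = profiles$values[, ord, drop = FALSE], tract = tract,
                rule = "whole-brain"))
  }
  rows <- which(f$pair_id == tract)
  if (!length(rows)) stop("tract not present in profiles: ", tract)
  hemis <- unique(f$hemisphere[rows])
  if (setequal(hemis, c("L", "R"))) {
    ord <- rows[order(match(f$hemisphere[rows], c("L", "R")), f$node[rows])]
    rule <- "bilateral"
  } else if (identical(hemis, "M")) {
    ord <- rows[order(f$node[rows])]
    rule <- "callosal"
  } else stop("missing hemisphere for tract ", tract, ": have ",
              paste(hemis, collapse = ","))
  list(x = profiles$values[, ord, drop = FALSE], tract = tract, rule = rule)
}

# squared Euclidean distances between rows of a and rows of b
.sqdist <- function(a, b = a) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

.gp_nll <- function(theta, d2, y) {
  n <- length(y)
  sf2 <- exp(theta[1]); l2 <- exp(2 * theta[2]); sn2 <- exp(theta[3])
  E <- exp(-d2 / (2 * l2))
  K <- sf2 * E + diag(sn2, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(list(value = 1e10, grad = c(0, 0, 0)))
  alpha <- backsolve(L, forwardsolve(t(L), y))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(L)
  A <- Kinv - tcrossprod(alpha)       # grad_j = 0.5 tr(A dK/dtheta_j)
  dK_sf2 <- sf2 * E
  dK_l <- sf2 * E * d2 / l2
  g <- c(0.5 * sum(A * dK_sf2), 0.5 * sum(A * dK_l), 0.5 * sum(diag(A)) * sn2)
  list(value = nll, grad = g)
}

#' Fit an exact Gaussian-process age regressor
#'
#' Exact GP regression with an RBF (squared-exponential) kernel plus a
#' white-noise term on internally standardized features. Kernel
#' hyperparameters (signal variance, length-scale, noise variance) are set by
#' marginal-likelihood maximization with multiple seeded restarts;
#' predictions are posterior means `k*' (K + sigma_n^2 I)^-1 y`.
#'
#' @param x subjects x p feature matrix (training set only; standardization
#'   statistics are derived from it).
#' @param age training ages (years).
#' @param restarts number of optimization restarts.
#' @param seed seed for restart jitter.
#' @param maxit L-BFGS-B iteration cap per restart.
#' @param hyperparams optional fixed `list(sf2, ls, sn2)` (signal variance,
#'   length-scale on standardized features, noise variance); skips
#'   optimization when supplied.
#' @return Object of class `gpr_model`.
#' @export
fit_gpr <- function(x, age, restarts = 2L, seed = 1L, maxit = 50L,
                    hyperparams = NULL) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite features")
  n <- nrow(x)
  if (is.null(hyperparams) && n < 20) stop("need n >= 20 training subjects")
  if (stats::sd(age) == 0) stop("constant training ages")
  xm <- colMeans(x); xs <- apply(x, 2, stats::sd)
  xs[xs < 1e-12] <- 1
  xz <- sweep(sweep(x, 2, xm), 2, xs, "/")
  ym <- mean(age); yc <- age - ym

  d2 <- .sqdist(xz)
  med <- stats::median(sqrt(d2[upper.tri(d2)]))
  if (!is.finite(med) || med <= 0) med <- 1
  vy <- stats::var(yc)

  if (is.null(hyperparams)) {
    lower <- c(log(vy * 1e-4), log(med * 1e-2), log(vy * 1e-6))
    upper <- c(log(vy * 1e4), log(med * 1e3), log(vy * 1e2))
    inits <- list(c(log(vy), log(med), log(0.1 * vy)))
    if (restarts > 1) {
      old <- .save_rng(); on.exit(.restore_rng(old))
      set.seed(as.integer(seed))
      for (r in seq_len(restarts - 1))
        inits[[r + 1]] <- inits[[1]] + stats::rnorm(3, 0, 1)
    }
    best <- NULL
    for (init in inits) {
      fit <- tryCatch(
        stats::optim(pmin(pmax(init, lower), upper),
                     fn = function(th) .gp_nll(th, d2, yc)$value,
                     gr = function(th) .gp_nll(th, d2, yc)$grad,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = maxit)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
    if (is.null(best)) stop("GP hyperparameter optimization failed")
    theta <- best$par
    hyperparams <- list(sf2 = exp(theta[1]), ls = exp(theta[2]),
                        sn2 = exp(theta[3]))
  }
  sf2 <- hyperparams$sf2; ls <- hyperparams$ls; sn2 <- hyperparams$sn2
  if (sn2 <= 0) stop("noise variance must be > 0")
  K <- sf2 * exp(-d2 / (2 * ls^2)) + diag(sn2, n)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yc))

  structure(list(xmean = xm, xsd = xs, ymean = ym, xtrain = xz,
                 alpha = alpha, hyperparams = hyperparams, n_train = n),
            class = "gpr_model")
}

#' Posterior-mean predictions from a fitted GP age model
#'
#' @param object a `gpr_model`.
#' @param newdata subjects x p feature matrix on the original scale.
#' @param ... unused.
#' @return Predicted ages (posterior means), in years.
#' @export
predict.gpr_model <- function(object, newdata, ...) {
  xz <- sweep(sweep(as.matrix(newdata), 2, object$xmean), 2, object$xsd, "/")
  h <- object$hyperparams
  kstar <- h$sf2 * exp(-.sqdist(xz, object$xtrain) / (2 * h$ls^2))
  drop(kstar %*% object$alpha) + object$ymean
}

#' Age-stratified cross-validation folds
#'
#' Fold assignment stratified by age decile so every fold spans the age
#' range; seeded and deterministic.
#'
#' @param age numeric ages.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer fold labels in `1..k`.
#' @export
age_stratified_folds <- function(age, k = 5L, seed = 1L) {
  stopifnot(k >= 2)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  dec <- cut(rank(age, ties.method = "first"), breaks = 10, labels = FALSE)
  fold <- integer(length(age))
  for (d in unique(dec)) {
    idx <- which(dec == d)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

.cv_predict <- function(x, age, k, seed, engine = "gpr", restarts = 2L,
                        maxit = 50L) {
  fold <- age_stratified_folds(age, k, seed)
  pred <- rep(NA_real_, length(age))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    if (sum(te) < 2 || sum(tr) < 2) stop("fold with < 2 subjects")
    if (engine == "gpr") {
      m <- fit_gpr(x[tr, , drop = FALSE], age[tr], restarts = restarts,
                   seed = seed + f, maxit = maxit)
      pred[te] <- predict(m, x[te, , drop = FALSE])
    } else {
      cf <- stats::lm.fit(cbind(1, x[tr, , drop = FALSE]), age[tr])$coefficients
      cf[is.na(cf)] <- 0
      pred[te] <- drop(cbind(1, x[te, , drop = FALSE]) %*% cf)
    }
  }
  list(pred = pred, fold = fold)
}

#' Cross-validated brain-age prediction performance
#'
#' k-fold cross-validation with age-decile-stratified, seeded fold
#' assignment. Pearson R and RMSE are computed on the concatenated
#' out-of-fold predictions (always from uncorrected predicted ages).
#'
#' @param x subjects x p feature matrix.
#' @param age chronological ages.
#' @param k number of folds.
#' @param seed integer seed.
#' @param engine `"gpr"` (default) or `"lm"` (fast linear engine, used e.g.
#'   for permutation calibration studies).
#' @param restarts,maxit GP optimizer settings (engine `"gpr"`).
#' @return List with `predictions` (out-of-fold), `fold`, and `performance`
#'   (`R`, `RMSE`, `k`, `seed`).
#' @export
crossval_brain_age <- function(x, age, k = 5L, seed = 1L, engine = "gpr",
                               restarts = 2L, maxit = 50L) {
  cv <- .cv_predict(as.matrix(x), age, k, seed, engine, restarts, maxit)
  list(predictions = cv$pred, fold = cv$fold,
       performance = list(R = stats::cor(cv$pred, age),
                          RMSE = sqrt(mean((cv$pred - age)^2)),
                          k = k, seed = seed))
}

#' Permutation test of cross-validated prediction accuracy
#'
#' Null distribution of cross-validated R built by permuting chronological
#' ages across participants and re-establishing the prediction model on each
#' permuted dataset. `p = (count(R_perm >= R_obs) + 1) / (n_perm + 1)`.
#'
#' @inheritParams crossval_brain_age
#' @param n_perm number of permutations (>= 100 recommended for reporting).
#' @return List with `R_obs`, `R_perm`, `p`.
#' @export
permutation_test_R <- function(x, age, n_perm = 1000L, seed = 1L, k = 5L,
                               engine = "gpr", restarts = 1L, maxit = 30L) {
  x <- as.matrix(x)
  obs <- crossval_brain_age(x, age, k, seed, engine, restarts, maxit)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed) + 1L)
  rperm <- vapply(seq_len(n_perm), function(i) {
    ap <- sample(age)
    .cv_R_safe(x, ap, k, seed + i, engine, restarts, maxit)
  }, numeric(1))
  p <- (sum(rperm >= obs$performance$R, na.rm = TRUE) + 1) / (n_perm + 1)
  list(R_obs = obs$performance$R, R_perm = rperm, p = p)
}

.cv_R_safe <- function(x, age, k, seed, engine, restarts, maxit) {
  tryCatch({
    cv <- .cv_predict(x, age, k, seed, engine, restarts, maxit)
    stats::cor(cv$pred, age)
  }, error = function(e) NA_real_)
}

#' Fit the linear age-bias correction
#'
#' OLS regression of the raw brain-age gap on chronological age in the
#' training set: `BAG = alpha * Age + beta`. The fitted line is later
#' subtracted from raw BAGs ([apply_bias_correction()]), removing the
#' regression-dilution-induced age dependence.
#'
#' @param train_ages training chronological ages.
#' @param train_bags training raw BAGs (predicted minus chronological age).
#' @return Named numeric vector `c(alpha, beta)`.
#' @export
fit_bias_correction <- function(train_ages, train_bags) {
  if (length(train_ages) < 3) stop("need >= 3 training subjects")
  if (stats::var(train_ages) == 0) stop("degenerate age variance")
  fit <- stats::lm(train_bags ~ train_ages)
  c(alpha = unname(stats::coef(fit)[2]), beta = unname(stats::coef(fit)[1]))
}

#' Apply the age-bias correction
#'
#' `BAG_corrected = BAG_raw - (alpha * age + beta)`.
#'
#' @param alpha,beta bias-correction coefficients from
#'   [fit_bias_correction()].
#' @param age chronological ages.
#' @param bag_raw raw BAGs.
#' @return Corrected BAGs (years).
#' @export
apply_bias_correction <- function(alpha, beta, age, bag_raw) {
  stopifnot(all(is.finite(c(alpha, beta))))
  bag_raw - (alpha * age + beta)
}

#' Fit brain-age models across tracts
#'
#' For each requested tract unit (and optionally the whole-brain
#' concatenation): hold out a stratified test fraction, run k-fold CV on the
#' remainder (performance from out-of-fold uncorrected predictions), fit the
#' final GP on the full training portion, and fit the age-bias correction on
#' the out-of-fold training BAGs. Standardization, hyperparameters and
#' (alpha, beta) derive from training subjects only.
#'
#' @param profiles a `tract_profiles` (typically harmonized, baseline visit).
#' @param age chronological ages aligned with `profiles` rows.
#' @param tracts character vector of pair ids and/or `"whole-brain"`;
#'   defaults to all pairs plus whole-brain.
#' @param k CV folds.
#' @param seed integer seed.
#' @param holdout_frac held-out test fraction (0 disables the hold-out path).
#' @param restarts,maxit GP optimizer settings.
#' @return Object of class `brainage_fit`: per-tract `gpr_model`s with bias
#'   coefficients, a `performance` data.frame (CV and hold-out R/RMSE), and
#'   the split definition.
#' @export
brainage_fit <- function(profiles, age, tracts = NULL, k = 5L, seed = 1L,
                         holdout_frac = 0.2, restarts = 2L, maxit = 50L) {
  stopifnot(inherits(profiles, "tract_profiles"))
  if (is.null(tracts))
    tracts <- c(tract_pairs(profiles$features), "whole-brain")
  n <- nrow(profiles$values)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  if (holdout_frac > 0) {
    dec <- cut(rank(age, ties.method = "first"), 10, labels = FALSE)
    hold <- logical(n)
    for (d in unique(dec)) {
      idx <- which(dec == d)
      hold[sample(idx, max(1, round(holdout_frac * length(idx))))] <- TRUE
    }
  } else hold <- logical(n)

  models <- list()
  perf <- NULL
  for (tr in tracts) {
    fa <- assemble_features(profiles, tr)
    xtr <- fa$x[!hold, , drop = FALSE]; atr <- age[!hold]
    cv <- crossval_brain_age(xtr, atr, k = k, seed = seed, engine = "gpr",
                             restarts = restarts, maxit = maxit)
    final <- fit_gpr(xtr, atr, restarts = restarts, seed = seed,
                     maxit = maxit)
    bc <- fit_bias_correction(atr, cv$predictions - atr)
    row <- data.frame(tract = tr, R_cv = cv$performance$R,
                      RMSE_cv = cv$performance$RMSE,
                      R_holdout = NA_real_, RMSE_holdout = NA_real_,
                      stringsAsFactors = FALSE)
    if (any(hold)) {
      ph <- predict(final, fa$x[hold, , drop = FALSE])
      row$R_holdout <- stats::cor(ph, age[hold])
      row$RMSE_holdout <- sqrt(mean((ph - age[hold])^2))
    }
    perf <- rbind(perf, row)
    models[[tr]] <- list(gpr = final, alpha = bc["alpha"], beta = bc["beta"],
                         tract = tr)
  }
  structure(list(models = models, performance = perf, holdout = hold,
                 k = k, seed = seed), class = "brainage_fit")
}

#' Predict brain-age gaps for new subjects
#'
#' Applies each fitted tract model to new profiles and tabulates predicted
#' age, raw BAG (`predicted - chronological`, exactly) and bias-corrected
#' BAG, one row per subject x model.
#'
#' @param fit a `brainage_fit`.
#' @param profiles `tract_profiles` for the subjects to score.
#' @param age their chronological ages.
#' @return A `data.frame` (BAG table): `subject_id`, `visit`, `tract`,
#'   `age`, `predicted_age`, `bag_raw`, `bag_corrected`.
#' @export
brainage_bags <- function(fit, profiles, age) {
  stopifnot(inherits(fit, "brainage_fit"), inherits(profiles, "tract_profiles"))
  out <- NULL
  for (tr in names(fit$models)) {
    m <- fit$models[[tr]]
    fa <- assemble_features(profiles, tr)
    pred <- predict(m$gpr, fa$x)
    raw <- pred - age
    out <- rbind(out, data.frame(
      subject_id = profiles$subjects$subject_id,
      visit = profiles$subjects$visit, tract = tr, age = age,
      predicted_age = pred, bag_raw = raw,
      bag_corrected = apply_bias_correction(m$alpha, m$beta, age, raw),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Reshape a BAG table to a subjects x models matrix
#'
#' @param bags a BAG table from [brainage_bags()].
#' @param value `"bag_corrected"`, `"bag_raw"`, or `"predicted_age"`.
#' @param visit which visit to extract.
#' @return Matrix, rows = subjects, columns = tract models.
#' @export
bag_matrix <- function(bags, value = "bag_corrected", visit = "baseline") {
  b <- bags[bags$visit == visit, ]
  tracts <- unique(b$tract)
  subj <- unique(b$subject_id)
  m <- matrix(NA_real_, length(subj), length(tracts),
              dimnames = list(subj, tracts))
  m[cbind(match(b$subject_id, subj), match(b$tract, tracts))] <- b[[value]]
  m
}
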