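#' Fit empirical-Bayes ComBat site harmonization
#'
#' Estimates parametric empirical-Bayes ComBat location/scale site effects on
#' a feature matrix while preserving designated biological covariates (for
#' tract profiles: typically age, sex and diagnosis class). Features are
#' standardized against the covariate-adjusted grand mean and pooled
#' variance; per-site location (gamma) and scale (delta^2) estimates are
#' shrunk via normal / inverse-gamma priors with method-of-moments
#' hyperparameters, iterated to convergence.
#'
#' @param x numeric matrix, subjects x features (or a `tract_profiles`
#'   object, in which case its value matrix is used).
#' @param site site/batch labels, length `nrow(x)`; every site needs >= 2
#'   subjects.
#' @param covariates numeric design matrix of biological covariates to
#'   preserve (no intercept, no site columns), or `NULL`.
#' @param conv relative convergence tolerance of the EB iterations.
#' @param max_iter maximum EB iterations per site.
#' @return An object of class `combat_model` with elements `sites`, `n_site`,
#'   `grand_mean`, `beta_cov`, `var_pooled`, `gamma_hat`, `delta_hat`,
#'   `gamma_star`, `delta_star` (site x feature matrices, standardized
#'   units), and `iterations`.
#' @seealso [apply_combat()]
#' @export
fit_combat <- function(x, site, covariates = NULL, conv = 1e-4,
                       max_iter = 100L) {
  if (inherits(x, "tract_profiles")) x <- x$values
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  site <- factor(site)
  if (length(site) != n) stop("site labels must match rows of x")
  ni <- table(site)
  if (any(ni < 2)) stop("every site needs >= 2 subjects (scale undefined for: ",
                        paste(names(ni)[ni < 2], collapse = ", "), ")")
  nb <- nlevels(site)

  bdes <- outer(site, levels(site), `==`) * 1
  colnames(bdes) <- paste0("site", levels(site))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    design <- cbind(bdes, covariates)
  } else design <- bdes
  if (qr(design)$rank < ncol(design))
    stop("singular design: covariates confounded with site or each other")

  bhat <- solve(crossprod(design), crossprod(design, x))
  wts <- as.numeric(ni) / n
  grand_mean <- drop(wts %*% bhat[seq_len(nb), , drop = FALSE])
  fitted <- design %*% bhat
  var_pooled <- colMeans((x - fitted)^2)
  if (any(var_pooled < 1e-12))
    stop("zero residual variance in ", sum(var_pooled < 1e-12), " feature(s)")

  stand_mean <- matrix(grand_mean, n, p, byrow = TRUE)
  beta_cov <- NULL
  if (!is.null(covariates)) {
    beta_cov <- bhat[-seq_len(nb), , drop = FALSE]
    stand_mean <- stand_mean + covariates %*% beta_cov
  }
  z <- (x - stand_mean) / matrix(sqrt(var_pooled), n, p, byrow = TRUE)

  gamma_hat <- delta_hat <- gamma_star <- delta_star <-
    matrix(NA_real_, nb, p, dimnames = list(levels(site), colnames(x)))
  iterations <- integer(nb)

  identity_fit <- nb == 1L   # single site: nothing to remove
  for (b in seq_len(nb)) {
    rows <- which(site == levels(site)[b])
    zb <- z[rows, , drop = FALSE]
    g_hat <- colMeans(zb)
    d_hat <- apply(zb, 2, stats::var)
    gamma_hat[b, ] <- g_hat
    delta_hat[b, ] <- d_hat
    if (identity_fit) {
      gamma_star[b, ] <- 0
      delta_star[b, ] <- 1
      next
    }
    g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
    m <- mean(d_hat); s2 <- stats::var(d_hat)
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    nib <- length(rows)
    g_old <- g_hat; d_old <- d_hat
    it <- 0L
    repeat {
      it <- it + 1L
      if (is.finite(t2) && t2 > 1e-12) {
        g_new <- (t2 * nib * g_hat + d_old * g_bar) / (t2 * nib + d_old)
      } else g_new <- rep(g_bar, p)
      if (is.finite(s2) && s2 > 1e-12) {
        sum2 <- colSums(sweep(zb, 2, g_new)^2)
        d_new <- (0.5 * sum2 + b_prior) / (nib / 2 + a_prior - 1)
      } else d_new <- d_hat
      change <- max(abs(g_new - g_old) / abs(g_old),
                    abs(d_new - d_old) / abs(d_old), na.rm = TRUE)
      g_old <- g_new; d_old <- d_new
      if (change < conv || it >= max_iter) break
    }
    iterations[b] <- it
    gamma_star[b, ] <- g_old
    delta_star[b, ] <- d_old
  }

  structure(list(sites = levels(site), n_site = as.integer(ni),
                 grand_mean = grand_mean, beta_cov = beta_cov,
                 var_pooled = var_pooled, gamma_hat = gamma_hat,
                 delta_hat = delta_hat, gamma_star = gamma_star,
                 delta_star = delta_star, iterations = iterations,
                 identity_fit = identity_fit),
            class = "combat_model")
}

#' Apply a fitted ComBat model
#'
#' Standardizes new data with the model's grand mean, covariate coefficients
#' and pooled variance, removes the shrunk site location/scale effects, and
#' restores the biological signal:
#' `(z - gamma*) / delta*` back-transformed to the original scale.
#'
#' @param model a `combat_model` from [fit_combat()].
#' @param x subjects x features matrix or `tract_profiles`.
#' @param site site labels (must all be in the model's roster).
#' @param covariates covariate matrix matching the one used at fit time (or
#'   `NULL` if none was used).
#' @return Harmonized data of the same class and shape as `x`.
#' @export
apply_combat <- function(model, x, site, covariates = NULL) {
  stopifnot(inherits(model, "combat_model"))
  prof <- NULL
  if (inherits(x, "tract_profiles")) { prof <- x; x <- x$values }
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  site <- as.character(site)
  unseen <- setdiff(unique(site), model$sites)
  if (length(unseen)) stop("unseen site label(s): ",
                           paste(unseen, collapse = ", "))
  if (p != length(model$grand_mean)) stop("feature count mismatch")

  stand_mean <- matrix(model$grand_mean, n, p, byrow = TRUE)
  if (!is.null(model$beta_cov)) {
    if (is.null(covariates)) stop("model was fit with covariates; supply them")
    covariates <- as.matrix(covariates)
    stand_mean <- stand_mean + covariates %*% model$beta_cov
  }
  sv <- matrix(sqrt(model$var_pooled), n, p, byrow = TRUE)
  z <- (x - stand_mean) / sv
  bi <- match(site, model$sites)
  z_adj <- (z - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta_star[bi, , drop = FALSE])
  out <- z_adj * sv + stand_mean
  dimnames(out) <- dimnames(x)
  if (!is.null(prof)) {
    prof$values <- out
    return(prof)
  }
  out
}

#' Serialize / restore a ComBat model as JSON
#'
#' @param model a `combat_model`.
#' @param path file path.
#' @export
write_combat_json <- function(model, path) {
  stopifnot(inherits(model, "combat_model"))
  obj <- unclass(model)
  obj$gamma_hat <- as.data.frame(obj$gamma_hat)
  obj$delta_hat <- as.data.frame(obj$delta_hat)
  obj$gamma_star <- as.data.frame(obj$gamma_star)
  obj$delta_star <- as.data.frame(obj$delta_star)
  if (!is.null(obj$beta_cov)) obj$beta_cov <- as.data.frame(obj$beta_cov)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_combat_json
#' @export
read_combat_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("gamma_hat", "delta_hat", "gamma_star", "delta_star")) {
    obj[[nm]] <- as.matrix(obj[[nm]])
    rownames(obj[[nm]]) <- obj$sites
  }
  if (!is.null(obj$beta_cov)) obj$beta_cov <- as.matrix(obj$beta_cov)
  obj$grand_mean <- as.numeric(obj$grand_mean)
  obj$var_pooled <- as.numeric(obj$var_pooled)
  structure(obj, class = "combat_model")
}
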