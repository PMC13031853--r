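#' Residualize covariates out of a matrix and z-score
#'
#' Per-column OLS residualization against a covariate design (with
#' intercept), followed by z-scoring. Used to remove age and sex from both
#' the BAG and behavioral blocks before sparse CCA.
#'
#' @param x subjects x variables numeric matrix.
#' @param covariates subjects x c covariate matrix (intercept added
#'   internally).
#' @return Matrix of class-free z-scored residuals; each column has mean 0,
#'   sd 1, and is orthogonal to the covariates.
#' @export
residualize <- function(x, covariates) {
  x <- as.matrix(x)
  d <- cbind(1, as.matrix(covariates))
  if (qr(d)$rank < ncol(d)) stop("covariate design not full rank")
  q <- qr.Q(qr(d))
  res <- x - q %*% crossprod(q, x)
  s <- apply(res, 2, stats::sd)
  if (any(s < 1e-12))
    stop("constant column after residualization: ",
         paste(colnames(x)[s < 1e-12], collapse = ", "))
  scale(res, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

#' Soft-thresholding operator
#'
#' `S(a, c) = sign(a) * max(|a| - c, 0)`, elementwise — the proximal operator
#' of the L1 penalty used inside the penalized matrix decomposition.
#'
#' @param a numeric vector.
#' @param c threshold (>= 0).
#' @return Thresholded vector.
#' @export
soft_threshold <- function(a, c) {
  stopifnot(c >= 0)
  sign(a) * pmax(abs(a) - c, 0)
}

# L1-constrained unit-L2 projection: the unit vector S(a, lam)/||S(a, lam)||_2
# whose L1 norm equals the budget (lam = 0 when the unconstrained unit vector
# already satisfies it). The threshold is found in closed form: with the k
# largest |a| active, the L1/L2 ratio f(lam) = (s1 - k lam)/sqrt(s2 - 2 s1 lam
# + k lam^2) is piecewise analytic in lam and f = budget reduces to a
# quadratic per piece; bisection is kept as a numerical fallback.
.l1_project <- function(a, budget) {
  n2 <- sqrt(sum(a^2))
  if (n2 == 0) return(a)
  u <- a / n2
  if (sum(abs(u)) <= budget + 1e-12) return(u)
  if (budget <= 1 + 1e-12) {      # infeasible below 1: single-support vector
    s <- numeric(length(a))
    j <- which.max(abs(a))
    s[j] <- sign(a[j])
    return(s)
  }
  ab <- abs(a)
  av <- sort(ab, decreasing = TRUE)
  s1 <- cumsum(av); s2 <- cumsum(av^2)
  c2 <- budget^2
  lam <- NA_real_
  for (k in seq_along(av)) {
    lo <- if (k < length(av)) av[k + 1] else 0
    hi <- av[k]
    A <- k * (k - c2); B <- -2 * s1[k] * (k - c2); C <- s1[k]^2 - c2 * s2[k]
    if (abs(A) < .Machine$double.eps) next
    disc <- B^2 - 4 * A * C
    if (disc < 0) next
    roots <- (-B + c(1, -1) * sqrt(disc)) / (2 * A)
    for (r in roots) {
      if (r >= lo - 1e-9 && r <= hi + 1e-9 && r >= 0) {
        s <- pmax(av - r, 0)
        ns <- sqrt(sum(s^2))
        if (ns == 0) next
        f <- sum(s) / ns
        if (abs(f - budget) < 1e-6) { lam <- r; break }
      }
    }
    if (!is.na(lam)) break
  }
  if (is.na(lam)) {               # fallback: bisection
    lo <- 0; hi <- max(ab)
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      s <- pmax(ab - mid, 0)
      ns <- sqrt(sum(s^2))
      if (ns > 0 && sum(s) / ns > budget) lo <- mid else hi <- mid
    }
    lam <- hi
  }
  s <- soft_threshold(a, lam)
  s / sqrt(sum(s^2))
}

#' Rank-1 penalized matrix decomposition
#'
#' Alternating soft-threshold updates for
#' `max u' Z v  s.t. ||u||_2 = ||v||_2 = 1, ||u||_1 <= C1 sqrt(p),
#' ||v||_1 <= C2 sqrt(q)`; the L1 budget is the `C * sqrt(dim)` fraction of
#' the maximal feasible L1 norm under the unit L2 constraint. The threshold
#' is found by bisection each update (`lambda = 0` when the unconstrained
#' update already satisfies the budget). Initialized from the leading
#' singular vector of `Z`.
#'
#' @param z p x q cross-product matrix (`X'Y`).
#' @param c1,c2 sparsity constants in `(0, 1]`.
#' @param tol convergence tolerance on successive `u` iterates.
#' @param max_iter iteration cap.
#' @return List `u`, `v`, `d = u' Z v`, `iterations`, `converged`.
#' @export
pmd_rank1 <- function(z, c1 = 1, c2 = 1, tol = 1e-6, max_iter = 200L) {
  stopifnot(c1 > 0, c1 <= 1, c2 > 0, c2 <= 1)
  if (all(z == 0)) stop("zero cross-product matrix")
  p <- nrow(z); q <- ncol(z)
  b1 <- c1 * sqrt(p); b2 <- c2 * sqrt(q)
  sv <- svd(z, nu = 1, nv = 1)
  v <- sv$v[, 1]
  u <- numeric(p)
  it <- 0L; converged <- FALSE
  history <- numeric(0)
  repeat {
    it <- it + 1L
    u_new <- .l1_project(drop(z %*% v), b1)
    v_new <- .l1_project(drop(crossprod(z, u_new)), b2)
    delta <- if (it == 1) Inf else sqrt(sum((u_new - u)^2))
    u <- u_new; v <- v_new
    history <- c(history, delta)
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!converged)
    warning("pmd_rank1 did not converge in ", max_iter,
            " iterations (last delta ", signif(utils::tail(history, 1), 3), ")")
  list(u = u, v = v, d = drop(crossprod(u, z %*% v)), iterations = it,
       converged = converged)
}

#' Sparse canonical correlation via penalized matrix decomposition
#'
#' Extracts successive sparse canonical modes of `X'Y` by rank-1 PMD with
#' deflation `Z <- Z - d u v'`. Canonical correlations are
#' `R_k = cor(X u_k, Y v_k)`; structure loadings (correlation of each
#' variable with its own block's canonical variate) are reported alongside
#' raw sparse weights. Each mode is oriented by a deterministic sign
#' convention: the sum of `v` loadings over `sign_block` (by default all Y
#' variables) is non-negative.
#'
#' @param x,y residualized, z-scored matrices (subjects x p, subjects x q).
#' @param n_modes number of modes to extract.
#' @param c1,c2 sparsity constants in `(0, 1]`.
#' @param sign_block optional column indices of `y` whose summed loadings are
#'   oriented positive (e.g. the cognitive block).
#' @return Object of class `scca_model`: `u`, `v` (p x K, q x K weight
#'   matrices), `d`, `cors`, `loadings_x`, `loadings_y`, `c1`, `c2`.
#' @export
scca_fit <- function(x, y, n_modes = 2L, c1 = 1, c2 = 1, sign_block = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  p <- ncol(x); q <- ncol(y)
  if (n_modes > min(p, q)) stop("n_modes exceeds min(p, q)")
  if (is.null(sign_block)) sign_block <- seq_len(q)
  z <- crossprod(x, y)
  U <- matrix(0, p, n_modes); V <- matrix(0, q, n_modes)
  d <- numeric(n_modes); cors <- numeric(n_modes)
  for (k in seq_len(n_modes)) {
    r1 <- pmd_rank1(z, c1, c2)
    U[, k] <- r1$u; V[, k] <- r1$v; d[k] <- r1$d
    z <- z - r1$d * tcrossprod(r1$u, r1$v)
  }
  lx <- matrix(0, p, n_modes); ly <- matrix(0, q, n_modes)
  for (k in seq_len(n_modes)) {
    xs <- drop(x %*% U[, k]); ys <- drop(y %*% V[, k])
    ly[, k] <- suppressWarnings(stats::cor(y, ys))
    # orient: summed sign-block structure loadings non-negative
    s <- sum(ly[sign_block, k], na.rm = TRUE)
    if (is.na(s) || s == 0) s <- V[which.max(abs(V[, k])), k]
    if (s < 0) {
      U[, k] <- -U[, k]; V[, k] <- -V[, k]
      xs <- -xs; ys <- -ys
      ly[, k] <- -ly[, k]
    }
    lx[, k] <- suppressWarnings(stats::cor(x, xs))
    cors[k] <- stats::cor(xs, ys)
  }
  ly[is.na(ly)] <- 0; lx[is.na(lx)] <- 0
  rownames(U) <- rownames(lx) <- colnames(x)
  rownames(V) <- rownames(ly) <- colnames(y)
  structure(list(u = U, v = V, d = d, cors = cors,
                 loadings_x = lx, loadings_y = ly,
                 c1 = c1, c2 = c2, n_modes = n_modes,
                 sign_block = sign_block),
            class = "scca_model")
}

#' Grid search for the sCCA sparsity constants
#'
#' Evaluates the `{0.1, ..., 1.0}^2` grid (100 combinations; 0 is excluded as
#' it forces a zero weight vector). For each combination the first-mode
#' canonical correlation is averaged over `n_resample` random two-thirds
#' subsamples; the argmax combination is returned.
#'
#' @param x,y residualized matrices.
#' @param n_resample number of two-thirds subsamples.
#' @param seed integer seed.
#' @param grid candidate values for both constants.
#' @return List `c1`, `c2`, and the full `grid` data.frame of mean first-mode
#'   correlations.
#' @export
grid_search_sparsity <- function(x, y, n_resample = 10L, seed = 1L,
                                 grid = seq(0.1, 1, by = 0.1)) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  stopifnot(n >= 30)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  subs <- lapply(seq_len(n_resample),
                 function(i) sample(n, size = floor(2 * n / 3)))
  res <- expand.grid(c1 = grid, c2 = grid)
  res$mean_cor <- NA_real_
  for (i in seq_len(nrow(res))) {
    cors <- vapply(subs, function(s) {
      fit <- tryCatch(suppressWarnings(
        scca_fit(x[s, , drop = FALSE], y[s, , drop = FALSE],
                 n_modes = 1L, c1 = res$c1[i], c2 = res$c2[i])),
        error = function(e) NULL)
      if (is.null(fit)) NA_real_ else fit$cors[1]
    }, numeric(1))
    res$mean_cor[i] <- mean(cors, na.rm = TRUE)
  }
  best <- which.max(res$mean_cor)
  list(c1 = res$c1[best], c2 = res$c2[best], grid = res)
}

#' Permutation test of sCCA mode significance
#'
#' Shuffles the rows of the behavioral block (keeping subjects' brain rows
#' fixed), refits the model each iteration, and compares observed canonical
#' correlations against the null distribution per mode:
#' `p_k = (count(R_perm,k >= R_obs,k) + 1) / (n_perm + 1)`, BH-FDR-adjusted
#' across modes.
#'
#' @param x,y residualized matrices.
#' @param model fitted `scca_model` (defines modes and sparsity).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return List `p`, `p_fdr`, `r_obs`, `r_perm` (n_perm x K).
#' @export
permutation_test_modes <- function(x, y, model, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(model, "scca_model"))
  x <- as.matrix(x); y <- as.matrix(y)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  K <- model$n_modes
  rp <- matrix(NA_real_, n_perm, K)
  for (i in seq_len(n_perm)) {
    yp <- y[sample(nrow(y)), , drop = FALSE]
    # slow-convergence warnings are expected for null refits
    fit <- tryCatch(suppressWarnings(
      scca_fit(x, yp, K, model$c1, model$c2,
               sign_block = model$sign_block)),
      error = function(e) NULL)
    if (!is.null(fit)) rp[i, ] <- fit$cors
  }
  p <- vapply(seq_len(K), function(k)
    (sum(rp[, k] >= model$cors[k], na.rm = TRUE) + 1) / (n_perm + 1),
    numeric(1))
  list(p = p, p_fdr = bh_fdr(p), r_obs = model$cors, r_perm = rp)
}

# align bootstrap modes to reference modes by maximal |cor| of X-variate
# scores on the original sample, with sign flip; returns index + sign
.align_modes <- function(x, u_ref, u_boot) {
  K <- ncol(u_ref)
  s_ref <- x %*% u_ref; s_boot <- x %*% u_boot
  cm <- suppressWarnings(stats::cor(s_boot, s_ref))
  cm[is.na(cm)] <- 0
  idx <- integer(K); sgn <- numeric(K)
  avail <- rep(TRUE, K)
  for (k in seq_len(K)) {
    j <- which.max(ifelse(avail, abs(cm[, k]), -Inf))
    ties <- sum(abs(abs(cm[avail, k]) - max(abs(cm[avail, k]))) < 1e-12)
    if (ties > 1)
      message("bootstrap mode-matching tie for reference mode ", k)
    idx[k] <- j
    sgn[k] <- sign(cm[j, k] + .Machine$double.eps)
    avail[j] <- FALSE
  }
  list(index = idx, sign = sgn)
}

#' Bootstrap confidence intervals for sCCA loadings
#'
#' Resamples subjects with replacement, refits the model, aligns each
#' bootstrap mode to the reference mode by maximal absolute correlation of
#' canonical variate scores (with sign flip), and forms percentile 95% CIs
#' per structure loading. A loading is significant iff its CI excludes zero.
#'
#' @param x,y residualized matrices.
#' @param model fitted reference `scca_model`.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @param level CI level.
#' @return List with arrays `boot_x`, `boot_y` (variables x modes x n_boot),
#'   `ci_x`, `ci_y` (variables x modes x 2), and logical `sig_x`, `sig_y`.
#' @export
bootstrap_loadings <- function(x, y, model, n_boot = 1000L, seed = 1L,
                               level = 0.95) {
  stopifnot(inherits(model, "scca_model"))
  x <- as.matrix(x); y <- as.matrix(y)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  n <- nrow(x); K <- model$n_modes
  bx <- array(NA_real_, c(ncol(x), K, n_boot))
  by <- array(NA_real_, c(ncol(y), K, n_boot))
  for (b in seq_len(n_boot)) {
    s <- sample(n, replace = TRUE)
    fit <- tryCatch(suppressWarnings(
      scca_fit(x[s, , drop = FALSE], y[s, , drop = FALSE],
               K, model$c1, model$c2, sign_block = model$sign_block)),
      error = function(e) NULL)
    if (is.null(fit)) next
    al <- .align_modes(x, model$u, fit$u)
    for (k in seq_len(K)) {
      bx[, k, b] <- al$sign[k] * fit$loadings_x[, al$index[k]]
      by[, k, b] <- al$sign[k] * fit$loadings_y[, al$index[k]]
    }
  }
  a <- (1 - level) / 2
  ci <- function(arr) {
    out <- array(NA_real_, c(dim(arr)[1], K, 2))
    for (k in seq_len(K))
      out[, k, ] <- t(apply(arr[, k, , drop = FALSE], 1, stats::quantile,
                            probs = c(a, 1 - a), na.rm = TRUE))
    out
  }
  cix <- ci(bx); ciy <- ci(by)
  list(boot_x = bx, boot_y = by, ci_x = cix, ci_y = ciy,
       sig_x = cix[, , 1] * cix[, , 2] > 0,
       sig_y = ciy[, , 1] * ciy[, , 2] > 0)
}

#' Mode specificity of behavioral loadings
#'
#' For each variable, the paired bootstrap distributions of absolute loadings
#' on two modes are compared by a paired t-test; the variable is specific to
#' the mode with the larger mean absolute loading iff the paired Cohen's d
#' (mean difference over SD of differences) is at least `d_threshold`.
#'
#' @param boot 3-d array of bootstrap loadings (variables x modes x n_boot),
#'   e.g. `bootstrap_loadings()$boot_y`.
#' @param modes pair of mode indices to compare.
#' @param d_threshold Cohen's d threshold for specificity.
#' @return data.frame with `d` (signed, positive favors `modes[1]`),
#'   `t`, `p`, and `specific_mode` (1, 2 or NA).
#' @export
mode_specificity <- function(boot, modes = c(1, 2), d_threshold = 0.5) {
  stopifnot(length(dim(boot)) == 3, dim(boot)[2] >= max(modes))
  nv <- dim(boot)[1]
  out <- data.frame(variable = dimnames(boot)[[1]] %||% seq_len(nv),
                    d = NA_real_, t = NA_real_, p = NA_real_,
                    specific_mode = NA_integer_)
  for (j in seq_len(nv)) {
    diffs <- abs(boot[j, modes[1], ]) - abs(boot[j, modes[2], ])
    diffs <- diffs[is.finite(diffs)]
    sdd <- stats::sd(diffs)
    d <- if (sdd > 0) mean(diffs) / sdd else 0
    out$d[j] <- d
    if (sdd > 0) {
      tt <- stats::t.test(diffs)
      out$t[j] <- unname(tt$statistic); out$p[j] <- tt$p.value
    }
    if (abs(d) >= d_threshold)
      out$specific_mode[j] <- if (d > 0) modes[1] else modes[2]
  }
  out
}
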