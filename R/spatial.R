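#' Construct a tract probability atlas
#'
#' Bundles per-tract 3D probability volumes on a shared voxel grid, computes
#' probability-weighted tract centroids (mm, via the shared affine) and their
#' pairwise Euclidean distance matrix — the geometry the surrogate null
#' generator uses.
#'
#' @param volumes named list of 3D arrays (probabilities in `[0, 1]`), or of
#'   NIfTI file paths (read with `RNifti`). All volumes must share dimensions
#'   (and affine, when read from file — checked bit-exactly; no silent
#'   resampling).
#' @param affine optional 4x4 voxel-to-mm affine; identity (1 mm isotropic,
#'   zero origin) if omitted and volumes are plain arrays.
#' @return Object of class `tract_atlas`: `volumes`, `affine`, `centroids`
#'   (tracts x 3, mm), `dist` (tracts x tracts).
#' @export
tract_atlas <- function(volumes, affine = NULL) {
  stopifnot(is.list(volumes), length(volumes) >= 1, !is.null(names(volumes)))
  if (is.character(volumes[[1]])) {
    paths <- volumes
    volumes <- lapply(paths, function(p) {
      img <- RNifti::readNifti(p)
      a <- RNifti::xform(img)
      arr <- as.array(img)
      attr(arr, "affine") <- a
      arr
    })
    affs <- lapply(volumes, attr, "affine")
    if (is.null(affine)) affine <- affs[[1]]
    ok <- vapply(affs, function(a) identical(unclass(a)[1:16],
                                             unclass(affine)[1:16]),
                 logical(1))
    if (!all(ok)) stop("affine mismatch across atlas volumes")
    volumes <- lapply(volumes, function(v) { attributes(v) <- list(dim = dim(v)); v })
  }
  dims <- lapply(volumes, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("grid mismatch across atlas volumes")
  rng <- range(unlist(lapply(volumes, range)))
  if (rng[1] < 0 || rng[2] > 1) stop("probabilities must lie in [0, 1]")
  if (is.null(affine)) affine <- diag(4)

  cent <- t(vapply(volumes, function(v) {
    idx <- which(v > 0, arr.ind = TRUE)
    w <- v[v > 0]
    vox <- colSums(idx * w) / sum(w) - 1       # 0-based voxel coordinates
    drop(affine %*% c(vox, 1))[1:3]
  }, numeric(3)))
  rownames(cent) <- names(volumes)
  d <- as.matrix(stats::dist(cent))
  structure(list(volumes = volumes, affine = affine, centroids = cent,
                 dist = d), class = "tract_atlas")
}

#' Tract-wise profile of a volumetric map
#'
#' For each tract, the mean of the map over voxels whose tract probability
#' is at least `prob_threshold` (optionally restricted to a grey-matter
#' mask), z-scored across tracts.
#'
#' @param map 3D array (or NIfTI path) on the atlas grid.
#' @param atlas a `tract_atlas`.
#' @param prob_threshold tract probability threshold.
#' @param gm_mask optional logical/0-1 3D array; voxels outside are excluded.
#' @return data.frame: `tract`, `mean_value`, `z`, `n_voxels`.
#' @export
tract_map_profile <- function(map, atlas, prob_threshold = 0.5,
                              gm_mask = NULL) {
  stopifnot(inherits(atlas, "tract_atlas"))
  if (is.character(map)) map <- as.array(RNifti::readNifti(map))
  map <- as.array(map)
  if (!identical(dim(map), dim(atlas$volumes[[1]])))
    stop("grid mismatch between map and atlas")
  if (!is.null(gm_mask) && !identical(dim(gm_mask), dim(map)))
    stop("grid mismatch between GM mask and atlas")
  out <- data.frame(tract = names(atlas$volumes), mean_value = NA_real_,
                    n_voxels = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(atlas$volumes)) {
    sel <- atlas$volumes[[i]] >= prob_threshold
    if (!is.null(gm_mask)) sel <- sel & (gm_mask > 0)
    if (!any(sel)) stop("empty mask after thresholding for tract ",
                        names(atlas$volumes)[i])
    out$mean_value[i] <- mean(map[sel])
    out$n_voxels[i] <- sum(sel)
  }
  s <- stats::sd(out$mean_value)
  out$z <- if (s > 0) as.numeric(scale(out$mean_value)) else 0
  out[, c("tract", "mean_value", "z", "n_voxels")]
}

#' Tissue and mitochondrial respiratory capacity
#'
#' `TRC = (sqrt(CI) + sqrt(CII) + sqrt(CIV)) / 3` and `MRC = TRC / MitoD`,
#' elementwise, from mitochondrial complex activity maps (CI, CII, CIV) and
#' mitochondrial density (MitoD).
#'
#' @param ci,cii,civ non-negative complex activity values (per tract or per
#'   voxel).
#' @param mitod mitochondrial density; where 0, MRC is returned as `NA` and
#'   flagged.
#' @return List `trc`, `mrc`, `mrc_undefined` (logical).
#' @export
derive_trc_mrc <- function(ci, cii, civ, mitod = NULL) {
  stopifnot(all(ci >= 0), all(cii >= 0), all(civ >= 0))
  trc <- (sqrt(ci) + sqrt(cii) + sqrt(civ)) / 3
  mrc <- NULL; undef <- NULL
  if (!is.null(mitod)) {
    undef <- mitod == 0
    if (any(undef)) warning("MitoD = 0: MRC undefined for ", sum(undef),
                            " element(s)")
    mrc <- ifelse(undef, NA_real_, trc / mitod)
  }
  list(trc = trc, mrc = mrc, mrc_undefined = undef)
}

#' Spearman correlation between loadings and a spatial profile
#'
#' Spearman rho (average ranks for ties) between a tract-wise loading
#' pattern and a tract-wise map profile in matched tract order.
#'
#' @param loadings per-tract loading vector.
#' @param profile per-tract profile vector (same order, length >= 5).
#' @return Spearman rho.
#' @export
spearman_decode <- function(loadings, profile) {
  stopifnot(length(loadings) == length(profile), length(loadings) >= 5)
  if (stats::sd(loadings) == 0 || stats::sd(profile) == 0)
    stop("constant input")
  stats::cor(loadings, profile, method = "spearman")
}

.variogram <- function(x, d, breaks) {
  ut <- upper.tri(d)
  g <- 0.5 * (outer(x, x, "-")^2)[ut]
  h <- d[ut]
  bin <- findInterval(h, breaks, rightmost.closed = TRUE)
  vapply(seq_len(length(breaks) - 1),
         function(b) if (any(bin == b)) mean(g[bin == b]) else NA_real_,
         numeric(1))
}

#' Variogram-matched surrogate maps
#'
#' Generates surrogate tract-wise profiles that preserve the empirical
#' spatial autocorrelation of the input: each surrogate starts from a random
#' permutation, is smoothed by distance-weighted kernels over a ladder of
#' neighbourhood sizes, and the smoothed field is linearly recombined with
#' white noise so its variogram best matches the empirical variogram across
#' distance bins; the best-matching neighbourhood size is selected per
#' surrogate. Surrogates are rescaled to the observed mean and SD. With
#' fewer than 10 tracts the generator falls back to plain permutation with a
#' warning.
#'
#' @param values per-tract statistic (e.g. a map profile).
#' @param dist symmetric tract-distance matrix with zero diagonal (e.g.
#'   `tract_atlas()$dist`).
#' @param n_surr number of surrogates.
#' @param seed integer seed.
#' @param n_bins number of variogram distance bins.
#' @param knn candidate smoothing neighbourhood sizes.
#' @return Matrix `n_surr` x tracts of surrogate profiles, with attributes
#'   `method` and `variogram_bins`.
#' @export
variogram_surrogates <- function(values, dist, n_surr = 1000L, seed = 1L,
                                 n_bins = 25L, knn = NULL) {
  n <- length(values)
  stopifnot(nrow(dist) == n, ncol(dist) == n,
            max(abs(dist - t(dist))) < 1e-8, all(diag(dist) == 0))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  if (stats::sd(values) == 0)
    return(structure(matrix(values[1], n_surr, n), method = "constant"))

  if (n < 10) {
    warning("fewer than 10 tracts: falling back to plain permutation")
    out <- t(vapply(seq_len(n_surr), function(i) values[sample(n)],
                    numeric(n)))
    return(structure(out, method = "permutation"))
  }

  if (is.null(knn)) knn <- unique(pmin(c(2L, 3L, 5L, 8L, 12L), n - 1L))
  ut <- upper.tri(dist)
  breaks <- stats::quantile(dist[ut], probs = seq(0, 1, length.out = n_bins + 1))
  breaks[1] <- 0
  g_emp <- .variogram(values, dist, breaks)

  # distance-kernel smoothers, one per neighbourhood size
  smoothers <- lapply(knn, function(k) {
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(dist[i, ])[2:(k + 1)]
      w <- 1 / pmax(dist[i, nb], .Machine$double.eps)
      W[i, nb] <- w / sum(w)
    }
    W
  })

  mu <- mean(values); sdv <- stats::sd(values)
  out <- matrix(NA_real_, n_surr, n)
  for (s in seq_len(n_surr)) {
    xp <- values[sample(n)]
    best <- NULL; best_sse <- Inf
    for (W in smoothers) {
      sm <- drop(W %*% xp)
      noise <- stats::rnorm(n, 0, stats::sd(sm))
      g_sm <- .variogram(sm, dist, breaks)
      ok <- is.finite(g_emp) & is.finite(g_sm)
      # match variograms: g_emp ~ beta * g_sm + alpha
      fit <- stats::lm.fit(cbind(1, g_sm[ok]), g_emp[ok])
      alpha <- max(fit$coefficients[1], 0)
      beta <- max(fit$coefficients[2], 0)
      cand <- sqrt(beta) * sm + sqrt(alpha) * noise
      sse <- sum((g_emp[ok] - (beta * g_sm[ok] + alpha))^2)
      if (sse < best_sse) { best_sse <- sse; best <- cand }
    }
    best <- (best - mean(best)) / max(stats::sd(best), .Machine$double.eps)
    out[s, ] <- mu + sdv * best
  }
  structure(out, method = "variogram-matched", variogram_bins = breaks)
}

#' One-sided surrogate p-value
#'
#' `p = (count(stat_surr >= stat_obs) + 1) / (n + 1)`. Use [bh_fdr()] to
#' adjust across a family of maps.
#'
#' @param observed observed statistic (e.g. Spearman rho).
#' @param surrogate numeric vector of surrogate statistics (>= 100).
#' @return p-value.
#' @export
surrogate_pvalue <- function(observed, surrogate) {
  stopifnot(length(surrogate) >= 100)
  (sum(surrogate >= observed, na.rm = TRUE) + 1) / (length(surrogate) + 1)
}

#' Decode tract loadings against a set of volumetric maps
#'
#' For each map: tract-wise profile, Spearman correlation with the loading
#' pattern, and a one-sided surrogate p from variogram-matched nulls built
#' on the same profile; BH-FDR across maps.
#'
#' @param loadings named per-tract loading vector (tract order must match
#'   the atlas).
#' @param maps named list of 3D arrays or NIfTI paths.
#' @param atlas a `tract_atlas`.
#' @param n_surr surrogates per map.
#' @param seed integer seed.
#' @param prob_threshold,gm_mask passed to [tract_map_profile()].
#' @return data.frame: `map`, `rho`, `p`, `p_fdr`.
#' @export
decode_maps <- function(loadings, maps, atlas, n_surr = 1000L, seed = 1L,
                        prob_threshold = 0.5, gm_mask = NULL) {
  stopifnot(length(loadings) == length(atlas$volumes))
  res <- data.frame(map = names(maps), rho = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(maps)) {
    prof <- tract_map_profile(maps[[i]], atlas, prob_threshold, gm_mask)
    rho <- spearman_decode(loadings, prof$z)
    surr <- variogram_surrogates(prof$z, atlas$dist, n_surr,
                                 seed = seed + i)
    rho_null <- apply(surr, 1, function(sv)
      suppressWarnings(stats::cor(loadings, sv, method = "spearman")))
    res$rho[i] <- rho
    res$p[i] <- surrogate_pvalue(rho, rho_null)
  }
  res$p_fdr <- bh_fdr(res$p)
  res
}

#' Network composition of a tract set
#'
#' Proportions of the thresholded voxels of a set of tracts (e.g. the tracts
#' significant in an sCCA mode) falling in each label of a cortical network
#' parcellation. Proportions are over labelled voxels and sum to 1.
#'
#' @param atlas a `tract_atlas`.
#' @param parcellation integer-labelled 3D array on the atlas grid (0 =
#'   unlabelled).
#' @param tracts tract names to pool (default: all).
#' @param prob_threshold tract probability threshold.
#' @return Named numeric vector of proportions per network label.
#' @export
network_overlap_proportions <- function(atlas, parcellation, tracts = NULL,
                                        prob_threshold = 0.5) {
  stopifnot(inherits(atlas, "tract_atlas"))
  parcellation <- as.array(parcellation)
  if (!identical(dim(parcellation), dim(atlas$volumes[[1]])))
    stop("grid mismatch between parcellation and atlas")
  if (is.null(tracts)) tracts <- names(atlas$volumes)
  sel <- Reduce(`|`, lapply(atlas$volumes[tracts],
                            function(v) v >= prob_threshold))
  labs <- parcellation[sel]
  labs <- labs[labs > 0]
  if (!length(labs)) stop("no labelled overlap for the selected tracts")
  tab <- table(labs)
  out <- as.numeric(tab) / sum(tab)
  names(out) <- paste0("network", names(tab))
  out
}
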