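#' Synthetic tract probability atlas
#'
#' Builds a small synthetic atlas of Gaussian-blob "tracts" on a shared
#' grid, for exercising the spatial decoding stage and for tests. Blob
#' centres are seeded and spread across the volume; probabilities are
#' `exp(-d^2 / (2 r^2))`.
#'
#' @param tract_names names for the synthetic tracts.
#' @param dim grid dimensions.
#' @param radius blob radius in voxels.
#' @param seed integer seed.
#' @return A `tract_atlas`.
#' @export
synthetic_atlas <- function(tract_names, dim = c(24L, 24L, 24L), radius = 3,
                            seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  grid <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                      z = seq_len(dim[3]))
  vols <- lapply(seq_along(tract_names), function(i) {
    ctr <- stats::runif(3, 0.2, 0.8) * dim
    d2 <- (grid$x - ctr[1])^2 + (grid$y - ctr[2])^2 + (grid$z - ctr[3])^2
    array(exp(-d2 / (2 * radius^2)), dim)
  })
  names(vols) <- tract_names
  tract_atlas(vols)
}

#' Synthetic volumetric map with controllable spatial autocorrelation
#'
#' A linear spatial gradient mixed with white noise; `smoothness` in `[0, 1]`
#' interpolates from pure noise to pure gradient.
#'
#' @param dim grid dimensions.
#' @param smoothness mixing weight of the gradient component.
#' @param seed integer seed.
#' @return 3D array.
#' @export
synthetic_map <- function(dim = c(24L, 24L, 24L), smoothness = 0.7,
                          seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  grid <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                      z = seq_len(dim[3]))
  gradient <- as.numeric(scale(grid$x + 0.5 * grid$y - 0.3 * grid$z))
  noise <- stats::rnorm(prod(dim))
  array(smoothness * gradient + (1 - smoothness) * noise, dim)
}
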