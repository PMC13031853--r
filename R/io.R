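#' Write / read cohort tables as TSV
#'
#' One row per subject-visit; all columns are preserved verbatim.
#'
#' @param cohort data.frame as in `cohort_sim$cohort`.
#' @param path file path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  co <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("diagnosis_class" %in% names(co))
    co$diagnosis_class <- factor(co$diagnosis_class, c("0", "1", ">=2"))
  co
}

#' Write / read tract profiles as long-format TSV
#'
#' Long format: columns `subject_id`, `visit`, `tract`, `hemisphere`,
#' `system`, `pair_id`, `node`, `fa`. Round-trips exactly through
#' [read_profiles_tsv()].
#'
#' @param profiles a `tract_profiles` object.
#' @param path file path.
#' @export
write_profiles_tsv <- function(profiles, path) {
  stopifnot(inherits(profiles, "tract_profiles"))
  f <- profiles$features
  nfeat <- nrow(f)
  nobs <- nrow(profiles$values)
  long <- data.frame(
    subject_id = rep(profiles$subjects$subject_id, each = nfeat),
    visit = rep(profiles$subjects$visit, each = nfeat),
    tract = rep(f$tract, nobs), hemisphere = rep(f$hemisphere, nobs),
    system = rep(f$system, nobs), pair_id = rep(f$pair_id, nobs),
    node = rep(f$node, nobs),
    fa = as.vector(t(profiles$values)), stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_tsv
#' @export
read_profiles_tsv <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  key <- paste(long$subject_id, long$visit, sep = ".")
  ukey <- unique(key)
  f <- unique(long[, c("tract", "hemisphere", "system", "pair_id", "node")])
  f$pair_key <- paste(f$tract, f$hemisphere, sep = "_")
  f$feature <- paste(f$pair_key, f$node, sep = "_n")
  rownames(f) <- NULL
  first <- key == ukey[1]
  ford <- paste(long$tract[first], long$hemisphere[first], long$node[first])
  stopifnot(identical(ford, paste(f$tract, f$hemisphere, f$node)))
  values <- matrix(long$fa, nrow = length(ukey), ncol = nrow(f), byrow = TRUE)
  colnames(values) <- f$feature
  rownames(values) <- ukey
  subj <- unique(long[, c("subject_id", "visit")])
  rownames(subj) <- NULL
  tract_profiles(values, f, subj)
}

#' Write / read a behavior matrix as TSV
#'
#' @param behavior numeric matrix with subject ids as rownames.
#' @param path file path.
#' @export
write_behavior_tsv <- function(behavior, path) {
  df <- data.frame(subject_id = rownames(behavior), behavior,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior_tsv
#' @export
read_behavior_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$subject_id
  m
}

#' Serialize / restore a cohort configuration as YAML
#'
#' Only the scalar construction arguments and the seed are stored; the derived
#' per-feature arrays are regenerated deterministically on read, so the
#' round-tripped config is identical to the original.
#'
#' @param config a `cohort_config`.
#' @param path file path.
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  obj <- config$args
  obj$catalog_tracts <- config$catalog$tract
  obj$catalog_hemis <- config$catalog$hemisphere
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  full <- tract_catalog()
  keep <- match(paste(obj$catalog_tracts, obj$catalog_hemis),
                paste(full$tract, full$hemisphere))
  catalog <- full[keep, ]
  rownames(catalog) <- NULL
  obj$catalog_tracts <- NULL
  obj$catalog_hemis <- NULL
  obj$age_range <- as.numeric(obj$age_range)
  obj$site_scale_range <- as.numeric(obj$site_scale_range)
  obj$mode_coupling <- as.numeric(obj$mode_coupling)
  obj$class_probs_baseline <- as.numeric(obj$class_probs_baseline)
  obj$class_probs_followup <- as.numeric(obj$class_probs_followup)
  do.call(cohort_config, c(obj, list(catalog = catalog)))
}
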