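#' Default pipeline run configuration
#'
#' Assembles the configuration driving [run_pipeline()]: per-stage toggles,
#' per-stage seeds derived from a master seed, and model settings. Any field
#' can be overridden; the whole object can be round-tripped through YAML.
#'
#' @param seed master seed; every stochastic stage derives its own seed from
#'   it.
#' @param cohort named list of [cohort_config()] overrides.
#' @param stages named logical list toggling `simulate`, `harmonize`,
#'   `brainage`, `scca`, `group_models`, `decoding`.
#' @param brainage settings: `tracts` (NULL = all pairs + whole-brain), `k`,
#'   `holdout_frac`, `restarts`, `maxit`, `n_perm` (0 disables the GP age
#'   permutation test).
#' @param scca settings: `n_modes`, `grid` (logical), `c1`, `c2` (used when
#'   `grid = FALSE`), `n_perm`, `n_boot`.
#' @param decoding settings: `n_maps`, `n_surr`, `dim`.
#' @return Object of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            cohort = list(),
                            stages = list(),
                            brainage = list(),
                            scca = list(),
                            decoding = list()) {
  def_stages <- list(simulate = TRUE, harmonize = TRUE, brainage = TRUE,
                     scca = TRUE, group_models = TRUE, decoding = TRUE)
  def_brainage <- list(tracts = NULL, k = 5L, holdout_frac = 0.2,
                       restarts = 1L, maxit = 40L, n_perm = 0L)
  def_scca <- list(n_modes = 2L, grid = FALSE, c1 = 0.5, c2 = 0.5,
                   n_perm = 200L, n_boot = 200L)
  def_decoding <- list(n_maps = 3L, n_surr = 200L, dim = c(24L, 24L, 24L))
  merge <- function(def, user) { def[names(user)] <- user; def }
  structure(list(seed = as.integer(seed),
                 cohort = merge(list(seed = as.integer(seed)), cohort),
                 stages = merge(def_stages, stages),
                 brainage = merge(def_brainage, brainage),
                 scca = merge(def_scca, scca),
                 decoding = merge(def_decoding, decoding)),
            class = "run_config")
}

.config_hash <- function(x) {
  tools::md5sum(.write_temp_json(x))[[1]]
}
.write_temp_json <- function(x) {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(x, f, digits = NA, auto_unbox = TRUE, null = "null")
  f
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the stage chain simulate -> harmonize -> brain-age -> sCCA ->
#' group models -> spatial decoding from a single [pipeline_config()],
#' passing data between stages only through serialized TSV/JSON artifacts in
#' `outdir`. Stages whose outputs already exist under an identical config
#' hash are skipped ("cached"); a stage failure halts the run after writing
#' a manifest recording the completed stages.
#'
#' @param config a `run_config`, or a path to a YAML file of one.
#' @param outdir output directory (created if needed).
#' @return The run manifest (also written to `manifest.json`): config hash,
#'   per-stage status, output checksums and wall times, and versions.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = "tractage_run") {
  if (is.character(config)) {
    obj <- yaml::read_yaml(config)
    config <- pipeline_config(seed = obj$seed,
                              cohort = obj$cohort %||% list(),
                              stages = obj$stages %||% list(),
                              brainage = obj$brainage %||% list(),
                              scca = obj$scca %||% list(),
                              decoding = obj$decoding %||% list())
  }
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  chash <- .config_hash(unclass(config))
  manifest <- list(config_hash = chash,
                   versions = list(r = R.version.string,
                                   tractage = as.character(
                                     utils::packageVersion("tractage"))),
                   stages = list())
  mpath <- file.path(outdir, "manifest.json")
  prev <- if (file.exists(mpath))
    tryCatch(jsonlite::read_json(mpath, simplifyVector = TRUE),
             error = function(e) NULL) else NULL
  cached_ok <- !is.null(prev) && identical(prev$config_hash, chash)

  path <- function(...) file.path(outdir, ...)
  record <- function(name, status, files = character(0), secs = NA_real_) {
    sums <- if (length(files)) as.list(tools::md5sum(files)) else list()
    names(sums) <- basename(files)
    manifest$stages[[name]] <<- list(status = status, seconds = secs,
                                     checksums = sums)
    jsonlite::write_json(manifest, mpath, digits = NA, auto_unbox = TRUE)
  }
  run_stage <- function(name, outputs, fun) {
    if (!isTRUE(config$stages[[name]])) { record(name, "skipped"); return() }
    outs <- path(outputs)
    if (cached_ok && all(file.exists(outs)) &&
        identical(prev$stages[[name]]$status, "done")) {
      record(name, "cached", outs)
      return()
    }
    t0 <- proc.time()[3]
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      record(name, paste("failed:", conditionMessage(e)))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    record(name, "done", outs, round(proc.time()[3] - t0, 2))
  }

  run_stage("simulate",
            c("cohort.tsv", "profiles.tsv", "behavior.tsv", "diagnosis.tsv",
              "truth_deviation.tsv", "cohort_config.yaml"), function() {
    cc <- do.call(cohort_config, config$cohort)
    sim <- simulate_cohort(cc)
    sim <- simulate_puberty_hormones(sim)
    write_cohort_tsv(sim$cohort, path("cohort.tsv"))
    write_profiles_tsv(sim$profiles, path("profiles.tsv"))
    write_behavior_tsv(sim$behavior, path("behavior.tsv"))
    utils::write.table(sim$diagnosis, path("diagnosis.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    dev <- data.frame(subject_id = rownames(sim$truth$dev_tract),
                      sim$truth$dev_tract, check.names = FALSE)
    utils::write.table(dev, path("truth_deviation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_config_yaml(cc, path("cohort_config.yaml"))
  })

  run_stage("harmonize",
            c("profiles_harmonized.tsv", "combat_model.json"), function() {
    prof <- read_profiles_tsv(path("profiles.tsv"))
    co <- read_cohort_tsv(path("cohort.tsv"))
    key <- paste(co$subject_id, co$visit, sep = ".")
    stopifnot(identical(key, rownames(prof$values)))
    dg <- co$diagnosis_class
    covs <- cbind(age = co$age, sex = co$sex,
                  diag1 = as.numeric(dg == "1"),
                  diag2 = as.numeric(dg == ">=2"))
    if (length(unique(co$site)) > 1) {
      model <- fit_combat(prof, co$site, covs)
      prof_h <- apply_combat(model, prof, co$site, covs)
      write_combat_json(model, path("combat_model.json"))
    } else {
      prof_h <- prof
      jsonlite::write_json(list(note = "single site; identity"),
                           path("combat_model.json"), auto_unbox = TRUE)
    }
    write_profiles_tsv(prof_h, path("profiles_harmonized.tsv"))
  })

  run_stage("brainage",
            c("bags.tsv", "brainage_performance.tsv"), function() {
    prof <- read_profiles_tsv(path("profiles_harmonized.tsv"))
    co <- read_cohort_tsv(path("cohort.tsv"))
    base <- co$visit == "baseline"
    prof_b <- tract_profiles(prof$values[base, , drop = FALSE],
                             prof$features, prof$subjects[base, ])
    ba <- config$brainage
    fit <- brainage_fit(prof_b, co$age[base], tracts = ba$tracts, k = ba$k,
                        seed = config$seed + 10L,
                        holdout_frac = ba$holdout_frac,
                        restarts = ba$restarts, maxit = ba$maxit)
    perf <- fit$performance
    if (ba$n_perm > 0) {
      perf$p_perm <- NA_real_
      for (i in seq_len(nrow(perf))) {
        fa <- assemble_features(prof_b, perf$tract[i])
        pt <- permutation_test_R(fa$x[!fit$holdout, , drop = FALSE],
                                 co$age[base][!fit$holdout],
                                 n_perm = ba$n_perm,
                                 seed = config$seed + 20L + i, k = ba$k,
                                 restarts = ba$restarts, maxit = ba$maxit)
        perf$p_perm[i] <- pt$p
      }
      perf$p_perm_fdr <- bh_fdr(perf$p_perm)
    }
    bags <- brainage_bags(fit, prof, co$age)
    utils::write.table(bags, path("bags.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(perf, path("brainage_performance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  run_stage("scca",
            c("scca_loadings_x.tsv", "scca_loadings_y.tsv",
              "scca_summary.json"), function() {
    bags <- utils::read.delim(path("bags.tsv"), stringsAsFactors = FALSE)
    beh <- read_behavior_tsv(path("behavior.tsv"))
    co <- read_cohort_tsv(path("cohort.tsv"))
    X <- bag_matrix(bags, "bag_corrected", "baseline")
    beh <- beh[rownames(X), , drop = FALSE]
    cb <- co[co$visit == "baseline", ]
    cb <- cb[match(rownames(X), cb$subject_id), ]
    covs <- cbind(age = cb$age, sex = cb$sex)
    Xr <- residualize(X, covs)
    Yr <- residualize(beh, covs)
    sc <- config$scca
    if (isTRUE(sc$grid)) {
      gs <- grid_search_sparsity(Xr, Yr, seed = config$seed + 30L)
      c1 <- gs$c1; c2 <- gs$c2
    } else { c1 <- sc$c1; c2 <- sc$c2 }
    cog <- grep("^cog_", colnames(Yr))
    model <- scca_fit(Xr, Yr, sc$n_modes, c1, c2,
                      sign_block = if (length(cog)) cog else NULL)
    perm <- permutation_test_modes(Xr, Yr, model, sc$n_perm,
                                   seed = config$seed + 31L)
    boot <- bootstrap_loadings(Xr, Yr, model, sc$n_boot,
                               seed = config$seed + 32L)
    spec <- if (sc$n_modes >= 2) mode_specificity(boot$boot_y) else NULL
    lx <- data.frame(variable = rownames(model$loadings_x),
                     weight = model$u, loading = model$loadings_x,
                     sig = boot$sig_x)
    ly <- data.frame(variable = rownames(model$loadings_y),
                     weight = model$v, loading = model$loadings_y,
                     sig = boot$sig_y)
    utils::write.table(lx, path("scca_loadings_x.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(ly, path("scca_loadings_y.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(c1 = c1, c2 = c2, cors = model$cors,
                              d = model$d, p = perm$p, p_fdr = perm$p_fdr,
                              specificity = spec),
                         path("scca_summary.json"), digits = NA,
                         auto_unbox = TRUE)
  })

  run_stage("group_models",
            c("glm_behavior.tsv", "glm_groups.tsv", "gam_results.tsv",
              "lmm_results.tsv"), function() {
    bags <- utils::read.delim(path("bags.tsv"), stringsAsFactors = FALSE)
    beh <- read_behavior_tsv(path("behavior.tsv"))
    co <- read_cohort_tsv(path("cohort.tsv"))
    dg <- utils::read.delim(path("diagnosis.tsv"), stringsAsFactors = FALSE)
    X <- bag_matrix(bags, "bag_corrected", "baseline")
    beh <- beh[rownames(X), , drop = FALSE]
    cb <- co[co$visit == "baseline", ]
    cb <- cb[match(rownames(X), cb$subject_id), ]
    dg <- dg[match(rownames(X), dg$subject_id), ]

    res <- NULL
    for (tr in colnames(X)) for (bv in colnames(beh)) {
      g <- glm_bag_behavior(X[, tr], beh[, bv], cb$age, cb$sex)
      res <- rbind(res, data.frame(tract = tr, behavior = bv,
                                   t = g$t, p = g$p))
    }
    res$p_fdr <- bh_fdr(res$p)
    utils::write.table(res, path("glm_behavior.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    grp <- NULL
    factors <- list(baseline_class = factor(dg$class_baseline,
                                            c("0", "1", ">=2")),
                    followup_class = factor(dg$class_followup,
                                            c("0", "1", ">=2")),
                    transition = factor(dg$transition,
                                        c("HH", "PH", "HP", "PP")))
    for (tr in colnames(X)) for (fn in names(factors)) {
      g <- tryCatch(glm_group_effect(X[, tr], factors[[fn]], cb$age, cb$sex),
                    error = function(e) NULL)
      if (is.null(g)) next
      grp <- rbind(grp, data.frame(tract = tr, grouping = fn, F = g$F,
                                   df1 = g$df1, df2 = g$df2, p = g$p))
    }
    grp$p_fdr <- stats::ave(grp$p, grp$grouping, FUN = bh_fdr)
    utils::write.table(grp, path("glm_groups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    gam <- NULL
    outcomes <- colnames(beh)[seq_len(min(3, ncol(beh)))]
    for (tr in colnames(X)) for (ov in outcomes) {
      g <- gam_delta_r2(beh[, ov], X[, tr], cb$age, cb$sex)
      gam <- rbind(gam, data.frame(tract = tr, outcome = ov,
                                   delta_r2_pct = g$delta_r2_pct,
                                   F = g$F, p = g$p))
    }
    gam$p_fdr <- bh_fdr(gam$p)
    utils::write.table(gam, path("gam_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    lmm <- NULL
    wb <- bags[bags$tract == utils::tail(unique(bags$tract), 1), ]
    wb <- wb[match(paste(co$subject_id, co$visit),
                   paste(wb$subject_id, wb$visit)), ]
    stage <- suppressWarnings(
      as.integer(pds_categorize(co$sex, co$pds_sum, co$menarche)))
    preds <- list(pds_stage = stage, dhea = co$dhea,
                  testosterone = co$testosterone, estradiol = co$estradiol)
    extras <- co[, c("caffeine_intake", "physical_activity",
                     "collection_time", "collection_duration", "freeze_time")]
    for (pn in names(preds)) {
      extra <- if (pn == "pds_stage") NULL else extras
      fit <- tryCatch(
        lmm_developmental(wb$bag_corrected, preds[[pn]], co$age, co$sex,
                          co$visit, co$subject_id, extra),
        error = function(e) NULL)
      if (is.null(fit)) next
      lmm <- rbind(lmm, data.frame(predictor = pn, estimate = fit$estimate,
                                   t = fit$t, df = fit$df, p = fit$p,
                                   ranef_var = fit$ranef_var,
                                   singular = fit$singular, n = fit$n))
    }
    lmm$p_fdr <- bh_fdr(lmm$p)
    utils::write.table(lmm, path("lmm_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  run_stage("decoding", c("decoding_results.tsv"), function() {
    lx <- utils::read.delim(path("scca_loadings_x.tsv"),
                            stringsAsFactors = FALSE)
    dc <- config$decoding
    tracts <- lx$variable[lx$variable != "whole-brain"]
    atlas <- synthetic_atlas(tracts, dim = dc$dim, seed = config$seed + 40L)
    maps <- lapply(seq_len(dc$n_maps), function(i)
      synthetic_map(dc$dim, smoothness = 0.6, seed = config$seed + 41L + i))
    names(maps) <- paste0("map", seq_len(dc$n_maps))
    lvec <- lx$loading.1[lx$variable != "whole-brain"]
    res <- decode_maps(lvec, maps, atlas, n_surr = dc$n_surr,
                       seed = config$seed + 50L, prob_threshold = 0.5)
    utils::write.table(res, path("decoding_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  manifest
}

#' Serialize a run configuration to YAML
#'
#' @param config a `run_config`.
#' @param path file path.
#' @export
write_run_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
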