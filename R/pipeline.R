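# Pipeline orchestration: simulate -> fit -> features -> stats ->
# classify over a shared output directory, with JSON config/manifest,
# content-hash caching and deterministic seeding per stage.

PIPELINE_STAGES <- c("simulate", "fit", "features", "stats", "classify")

#' Build a pipeline configuration
#'
#' @param out_dir output directory (created if missing).
#' @param seed global seed; every stochastic stage derives its own
#'   stream from it.
#' @param n_regions,density synthetic connectome size and edge density.
#' @param cohort a [synth_cohort_spec()] (its `seed` is overridden by
#'   the derived simulate-stage seed).
#' @param fit a [fit_config()] (its `seed` is likewise overridden).
#' @param cv a [cv_config()].
#' @param stages which stages to run, in canonical order.
#' @param log_level `"info"` or `"quiet"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1, n_regions = 20,
                            density = 0.35,
                            cohort = synth_cohort_spec(n_per_group = 10),
                            fit = fit_config(maxiter = 40),
                            cv = cv_config(),
                            stages = PIPELINE_STAGES,
                            log_level = c("info", "quiet")) {
  stopifnot(all(stages %in% PIPELINE_STAGES))
  structure(list(out_dir = out_dir, seed = seed, n_regions = n_regions,
                 density = density, cohort = cohort, fit = fit, cv = cv,
                 stages = stages[order(match(stages, PIPELINE_STAGES))],
                 log_level = match.arg(log_level)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Scalar fields of the JSON override the defaults of
#' [pipeline_config()]; nested `cohort`, `fit` and `cv` sections
#' override fields of their respective sub-configs.
#'
#' @param path JSON file.
#' @param out_dir optional override of the output directory.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config(out_dir = out_dir %||% j$out_dir %||% ".")
  for (k in c("seed", "n_regions", "density", "stages", "log_level"))
    if (!is.null(j[[k]])) cfg[[k]] <- j[[k]]
  for (sec in c("cohort", "fit", "cv"))
    if (!is.null(j[[sec]]))
      cfg[[sec]] <- modifyList(cfg[[sec]], as.list(j[[sec]]))
  cfg$stages <- cfg$stages[order(match(cfg$stages, PIPELINE_STAGES))]
  cfg
}

json_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = 12, force = TRUE)
  unname(tools::md5sum(f))
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE, force = TRUE)
}

stage_outputs <- function(stage) {
  switch(stage,
         simulate = c("connectome_weights.csv", "connectome_distances.csv",
                      "cortical_mask.csv", "cohort.csv", "psds.csv"),
         fit = "fits.csv",
         features = "features.csv",
         stats = "stats.json",
         classify = "classify.json")
}

stage_deps <- function(stage) {
  switch(stage,
         simulate = character(0),
         fit = c(simulate = "psds.csv", simulate = "connectome_weights.csv"),
         features = c(simulate = "psds.csv"),
         stats = c(simulate = "cohort.csv", fit = "fits.csv"),
         classify = c(simulate = "cohort.csv", fit = "fits.csv"))
}

# Config subsection that determines a stage's output.
stage_config <- function(cfg, stage) {
  base <- list(seed = cfg$seed, n_regions = cfg$n_regions,
               density = cfg$density)
  switch(stage,
         simulate = c(base, list(cohort = unclass(cfg$cohort))),
         fit = c(base, list(fit = unclass(cfg$fit))),
         features = base,
         stats = base,
         classify = c(base, list(cv = unclass(cfg$cv))))
}

read_pipeline_connectome <- function(out) {
  mask <- read.csv(file.path(out, "cortical_mask.csv"))$cortical
  load_connectome(file.path(out, "connectome_weights.csv"),
                  file.path(out, "connectome_distances.csv"),
                  cortical_mask = as.logical(mask))
}

read_pipeline_psds <- function(out) {
  df <- read.csv(file.path(out, "psds.csv"), check.names = FALSE)
  freqs <- as.numeric(sub("^f", "", colnames(df)[-(1:2)]))
  lapply(split(df, df$subject), function(d) {
    m <- as.matrix(d[, -(1:2), drop = FALSE])
    rownames(m) <- d$region
    regional_psd(freqs, m, subject_id = d$subject[1])
  })
}

run_stage <- function(cfg, stage, log) {
  out <- cfg$out_dir
  if (stage == "simulate") {
    conn <- gen_connectome(cfg$n_regions, cfg$density,
                           seed = derive_seed(cfg$seed, "connectome"))
    spec <- cfg$cohort
    spec$seed <- derive_seed(cfg$seed, "simulate")
    coh <- gen_cohort(spec, conn)
    write_connectome(conn, file.path(out, "connectome_weights.csv"),
                     file.path(out, "connectome_distances.csv"))
    write.csv(data.frame(region = conn$labels,
                         cortical = conn$cortical_mask),
              file.path(out, "cortical_mask.csv"), row.names = FALSE)
    write.csv(coh$subjects, file.path(out, "cohort.csv"), row.names = FALSE)
    long <- do.call(rbind, lapply(names(coh$psds), function(id) {
      p <- coh$psds[[id]]
      data.frame(subject = id, region = rownames(p$psd_db), p$psd_db,
                 check.names = FALSE, stringsAsFactors = FALSE)
    }))
    colnames(long) <- c("subject", "region",
                        sprintf("f%g", coh$psds[[1]]$frequencies))
    write.csv(long, file.path(out, "psds.csv"), row.names = FALSE)
  } else if (stage == "fit") {
    conn <- read_pipeline_connectome(out)
    psds <- read_pipeline_psds(out)
    fcfg <- cfg$fit
    fcfg$seed <- derive_seed(cfg$seed, "fit")
    rows <- lapply(names(psds), function(id) {
      fr <- fit_subject(psds[[id]], conn, fcfg, subject_id = id)
      if (!isTRUE(fr$converged)) stop("fit failed for subject ", id)
      log("fitted ", id, " (spectral r = ", round(fr$spectral_corr, 3), ")")
      data.frame(id = id, as.data.frame(fr$params),
                 spectral_corr = fr$spectral_corr,
                 spatial_corr = fr$spatial_corr,
                 stage_used = fr$stage_used, start_index = fr$start_index,
                 stringsAsFactors = FALSE)
    })
    write.csv(do.call(rbind, rows), file.path(out, "fits.csv"),
              row.names = FALSE)
  } else if (stage == "features") {
    psds <- read_pipeline_psds(out)
    rows <- lapply(names(psds), function(id) {
      p <- psds[[id]]
      ps <- parameterize_spectrum(colMeans(p$psd_db), p$frequencies)
      data.frame(id = id, aperiodic_exponent = ps$aperiodic_exponent,
                 aperiodic_offset = ps$aperiodic_offset,
                 first_cf = ps$first_cf, second_cf = ps$second_cf,
                 n_peaks = ps$n_peaks, stringsAsFactors = FALSE)
    })
    write.csv(do.call(rbind, rows), file.path(out, "features.csv"),
              row.names = FALSE)
  } else if (stage == "stats") {
    tab <- merge(read.csv(file.path(out, "cohort.csv")),
                 read.csv(file.path(out, "fits.csv")), by = "id")
    gs <- group_compare(tab)
    # cognition regressions need enough scored subjects; degrade to a
    # recorded message on tiny cohorts
    safely <- function(expr) tryCatch(expr, error = function(e)
      list(skipped = conditionMessage(e)))
    reg <- safely(regress_cognition(tab, "mmse", "univariate"))
    mult <- safely(regress_cognition(tab, "mmse", "multivariate"))
    write_json_out(list(group_compare = gs, mmse_univariate = reg,
                        mmse_multivariate = mult),
                   file.path(out, "stats.json"))
  } else if (stage == "classify") {
    tab <- merge(read.csv(file.path(out, "cohort.csv")),
                 read.csv(file.path(out, "fits.csv")), by = "id")
    cv <- cfg$cv
    cv$seed <- derive_seed(cfg$seed, "classify")
    rep <- classify_cohort(tab[, c(SGM_PARAM_NAMES, "age")], tab$group, cv)
    write_json_out(list(auroc_mean = rep$auroc_mean,
                        auroc_sd = rep$auroc_sd, accuracy = rep$accuracy,
                        precision = rep$precision, recall = rep$recall,
                        f1 = rep$f1,
                        feature_importances = as.list(rep$feature_importances),
                        confusion_matrix = rep$confusion_matrix),
                   file.path(out, "classify.json"))
  }
  invisible(NULL)
}

#' Run the synthetic SGM analysis pipeline
#'
#' Executes the requested stages in order, writing per-stage outputs and
#' a run manifest (config hashes, seeds, file checksums, wall times) to
#' the output directory. Re-runs with an unchanged configuration reuse
#' cached stage outputs after verifying their checksums; a corrupted
#' cached file raises a checksum-mismatch error naming the file.
#'
#' @param cfg a [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- if (cfg$log_level == "info")
    function(...) message("[sgm] ", ...) else function(...) invisible(NULL)

  man_path <- file.path(out, "manifest.json")
  prev <- if (file.exists(man_path))
    jsonlite::read_json(man_path, simplifyVector = TRUE) else NULL
  manifest <- list(seed = cfg$seed, stages = list())

  for (stage in cfg$stages) {
    deps <- stage_deps(stage)
    for (k in seq_along(deps)) {
      dp <- file.path(out, deps[k])
      if (!file.exists(dp))
        stop("missing dependency '", deps[k], "' for stage '", stage,
             "'; run stage '", names(deps)[k], "' first")
      rec <- prev$stages[[names(deps)[k]]]
      if (!is.null(rec)) {
        want <- rec$checksums[[deps[k]]]
        got <- unname(tools::md5sum(dp))
        if (!is.null(want) && want != got)
          stop("checksum mismatch for cached file '", deps[k],
               "' (expected ", want, ", found ", got, ")")
      }
    }
    chash <- json_hash(stage_config(cfg, stage))
    outs <- file.path(out, stage_outputs(stage))
    cached <- !is.null(prev$stages[[stage]]) &&
      identical(prev$stages[[stage]]$config_hash, chash) &&
      all(file.exists(outs)) &&
      identical(unname(tools::md5sum(outs)),
                unlist(prev$stages[[stage]]$checksums, use.names = FALSE))
    if (cached) {
      log("stage ", stage, ": cached, skipping")
      manifest$stages[[stage]] <- prev$stages[[stage]]
      manifest$stages[[stage]]$cached <- TRUE
      next
    }
    log("stage ", stage, ": running")
    t0 <- Sys.time()
    run_stage(cfg, stage, log)
    manifest$stages[[stage]] <- list(
      config_hash = chash,
      seed = derive_seed(cfg$seed, stage),
      wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      checksums = as.list(setNames(unname(tools::md5sum(outs)),
                                   stage_outputs(stage))),
      cached = FALSE)
  }
  # carry over earlier stages' records so later partial runs can verify
  for (s in names(prev$stages))
    if (is.null(manifest$stages[[s]])) manifest$stages[[s]] <- prev$stages[[s]]
  manifest$stages <- manifest$stages[
    order(match(names(manifest$stages), PIPELINE_STAGES))]
  write_json_out(manifest, man_path)
  invisible(manifest)
}
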