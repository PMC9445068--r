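## End-to-end orchestration: simulate -> extract -> anova -> classify -> rsa.

#' Run configuration
#'
#' A fully serialisable description of one reproducible run. The top-level
#' seed fans out deterministically into per-stage child seeds so stages can
#' be re-run in isolation.
#'
#' @param seed master seed.
#' @param out_dir run directory.
#' @param archetypes per-emotion \code{\link{archetype_params}}.
#' @param n_scenes_per_emotion scenes per emotion (default 12).
#' @param frames,fps scene geometry.
#' @param rater passed to \code{\link{rater_model}} (its seed is derived
#'   from the master seed).
#' @param n_trees classifier ensemble size.
#' @param n_perm permutations for the model-vs-feature tests.
#' @param jitter_sd dataset parameter jitter.
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(seed = 1L, out_dir = "dyadkin_run",
                       archetypes = default_archetypes(),
                       n_scenes_per_emotion = 12L, frames = 400L, fps = 100,
                       rater = list(n_raters = 31L),
                       n_trees = 200L, n_perm = 1000L, jitter_sd = 0.08) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 archetypes = archetypes,
                 n_scenes_per_emotion = as.integer(n_scenes_per_emotion),
                 frames = as.integer(frames), fps = fps, rater = rater,
                 n_trees = as.integer(n_trees), n_perm = as.integer(n_perm),
                 jitter_sd = jitter_sd),
            class = "run_config")
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  writeLines(msg, con)
  invisible(msg)
}

write_num_csv <- function(df, path) {
  for (j in seq_along(df)) if (is.numeric(df[[j]]))
    df[[j]] <- formatC(df[[j]], format = "g", digits = 12)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the whole analysis pipeline
#'
#' Generates the synthetic dataset, extracts the 20-feature table, runs the
#' per-feature ANOVAs, cross-validates the M1/M2/M3 classifiers, and runs
#' the RSA stage (model, feature and behavioural RDMs, noise ceilings),
#' writing every stage's outputs plus a machine-readable \code{summary.json}
#' under \code{config$out_dir}. A stage failure aborts with a stage-named
#' error; outputs of completed stages are retained.
#'
#' @param config a \code{\link{run_config}}.
#' @return The summary list, invisibly.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  con <- file(logf, open = "wt")
  on.exit(close(con))
  seeds <- derive_seeds(config$seed, 4L)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      log_line(con, "stage %s FAILED: %s", name, conditionMessage(e))
      stop_dyadkin("stage '%s' failed: %s", name, conditionMessage(e))
    })
    log_line(con, "stage %s done in %.1fs", name,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }
  log_line(con, "run seed %d (stage seeds %s)", config$seed,
           paste(seeds, collapse = ", "))

  scenes <- stage("simulate", {
    sc <- generate_dataset(config$archetypes, config$n_scenes_per_emotion,
                           seed = seeds[1], jitter_sd = config$jitter_sd,
                           frames = config$frames, fps = config$fps)
    write_dataset(sc, file.path(config$out_dir, "scenes"))
    sc
  })

  features <- stage("features", {
    ft <- extract_features(scenes)
    write_num_csv(ft, file.path(config$out_dir, "features.csv"))
    ft
  })

  anovas <- stage("anova", {
    res <- suppressWarnings(feature_anova_table(features))
    tab <- do.call(rbind, lapply(res, function(a) {
      data.frame(feature = a$feature_name, F = a$F, df1 = a$df[1],
                 df2 = a$df[2], p = a$p, eta_sq = a$eta_sq,
                 stringsAsFactors = FALSE)
    }))
    write_num_csv(tab, file.path(config$out_dir, "anova.csv"))
    res
  })

  cls <- stage("classify", {
    specs <- lapply(c("M1", "M2", "M3"), model_spec,
                    n_trees = config$n_trees, seed = seeds[2])
    cmp <- compare_models(features, features$emotion, specs)
    dir.create(file.path(config$out_dir, "classify"), showWarnings = FALSE)
    for (nm in names(cmp$reports)) {
      r <- cmp$reports[[nm]]
      jsonlite::write_json(
        list(model = nm, overall_accuracy = r$overall_accuracy,
             per_class_accuracy = as.list(r$per_class_accuracy),
             importance_mean = as.list(r$importance_mean),
             importance_std = as.list(r$importance_std),
             fold_predictions = r$fold_predictions),
        file.path(config$out_dir, "classify", paste0(nm, ".json")),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
    cmp
  })

  rsa_res <- stage("rsa", {
    ratings <- simulate_ratings(scenes, do.call(rater_model, c(
      config$rater, list(seed = seeds[3]))))
    beh <- behavioural_rdms(ratings)
    frdms <- suppressWarnings(feature_rdms(features))
    mrdm <- list(emotion = model_rdm(features$emotion, features$scene_id))
    m2f <- relate_models_to_features(mrdm, frdms, n_perm = config$n_perm,
                                     seed = seeds[4])
    emo <- relate_features_to_behaviour(frdms, beh$emotion, "tau_a")
    val <- relate_features_to_behaviour(frdms, beh$valence, "pearson")
    dir.create(file.path(config$out_dir, "rsa"), showWarnings = FALSE)
    utils::write.csv(m2f$tau, file.path(config$out_dir, "rsa", "tau_matrix.csv"))
    write_num_csv(m2f$comparisons,
                  file.path(config$out_dir, "rsa", "model_vs_feature.csv"))
    if (!is.null(m2f$mds))
      utils::write.csv(m2f$mds, file.path(config$out_dir, "rsa", "mds.csv"))
    write_num_csv(emo$table, file.path(config$out_dir, "rsa", "emotion_fit.csv"))
    write_num_csv(val$table, file.path(config$out_dir, "rsa", "valence_fit.csv"))
    list(ratings = ratings, emotion = emo, valence = val, m2f = m2f)
  })

  summary <- list(
    seed = config$seed,
    n_scenes = length(scenes),
    frames = n_frames(scenes[[1]]),
    accuracies = stats::setNames(
      lapply(cls$reports, function(r) r$overall_accuracy), names(cls$reports)),
    top_emotion_feature = rsa_res$emotion$table$feature[1],
    top_valence_feature = rsa_res$valence$table$feature[1],
    emotion_ceiling = rsa_res$emotion$ceiling,
    valence_ceiling = rsa_res$valence$ceiling,
    recognition = recognition_vs_chance(rsa_res$ratings)$accuracy)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line(con, "run complete")
  invisible(summary)
}
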