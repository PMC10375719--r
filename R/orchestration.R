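#' Configuration of an end-to-end experiment
#'
#' Bundles the synthetic-cohort parameters, the preprocessing variants to
#' build, the model profile, the patient-wise split fractions and the seeds
#' into one reproducible description of a run.
#'
#' @param out_dir Output directory for all artifacts.
#' @param synth A [synth_params()] describing the cohort.
#' @param variants Integer vector within 1-4: which preprocessing
#'   variants to run (1 raw, 2 artifact removal, 3 standardization, 4 both).
#' @param model `"reference"`, `"scaled_down"`, or a [model_config()].
#' @param split Named fractions `c(train=, val=, test=)` of patients.
#' @param k Folds for [incremental_kfold()] plans recorded in the manifest.
#' @param seed Master seed for splitting, balancing and training.
#' @param threshold Window decision threshold.
#' @param with_artifacts Inject heavy artifacts into the synthetic records.
#' @param run_cv Record and run the incremental cross-validation stage.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(out_dir,
                              synth = synth_params(),
                              variants = 4L,
                              model = "scaled_down",
                              split = c(train = 0.7, val = 0.2, test = 0.1),
                              k = 5L, seed = 1L, threshold = 0.5,
                              with_artifacts = TRUE, run_cv = FALSE) {
  stopifnot(all(variants %in% 1:4), abs(sum(split) - 1) < 1e-9)
  structure(list(out_dir = out_dir, synth = synth, variants = variants,
                 model = model, split = split, k = as.integer(k),
                 seed = as.integer(seed), threshold = threshold,
                 with_artifacts = with_artifacts, run_cv = run_cv),
            class = "experiment_config")
}

resolve_model_config <- function(model, seed) {
  if (inherits(model, "model_config")) return(model)
  switch(model,
         reference = reference_config(seed = seed),
         scaled_down = scaled_down_config(seed = seed),
         abort(sprintf("unknown model profile '%s'", model),
               class = "osadetect_config_error"))
}

experiment_log <- function(stage, msg, t0) {
  message(sprintf("[%s] %s (%.1fs elapsed)", stage, msg,
                  as.numeric(Sys.time()) - t0))
}

#' Run a full experiment
#'
#' Chains the pipeline stages — cohort synthesis, preprocessing variants,
#' training, test evaluation, AHI reporting and a Grad-CAM gallery — writing
#' every stage's artifacts plus a manifest (config hash, seeds, versions,
#' stage timings) under `config$out_dir`. Deterministic stages reproduce
#' bit-identically when rerun with the same config.
#'
#' @param config An [experiment_config()].
#' @return The experiment directory path, invisibly.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(Sys.time())
  timings <- list()
  manifest_path <- file.path(config$out_dir, "manifest.json")
  stage <- "init"
  persist_manifest <- function(status = "running") {
    cfg <- config
    cfg$synth$target_ahi_sampler <- NULL     # closures are not serializable
    jsonlite::write_json(
      list(status = status, stage = stage,
           config_hash = rlang::hash(cfg),
           seed = config$seed, variants = config$variants,
           model = if (is.character(config$model)) config$model else "custom",
           package_version = as.character(utils::packageVersion("osadetect")),
           r_version = R.version.string,
           timings_s = timings),
      manifest_path, auto_unbox = TRUE, digits = NA)
  }
  run_stage <- function(name, expr) {
    stage <<- name
    persist_manifest()
    st <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      persist_manifest(status = paste0("failed:", name))
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "osadetect_stage_error", parent = e)
    })
    timings[[name]] <<- round(as.numeric(Sys.time()) - as.numeric(st), 3)
    experiment_log(name, "done", t0)
    out
  }

  cohort <- run_stage("synth", generate_cohort(config$synth,
                                               with_artifacts = config$with_artifacts))
  splits <- run_stage("split", split_patients(cohort$patient_id,
                                              config$split, config$seed))
  jsonlite::write_json(splits, file.path(config$out_dir, "splits.json"),
                       auto_unbox = FALSE)

  model_cfg <- resolve_model_config(config$model, config$seed)
  results <- list()
  for (v in config$variants) {
    vdir <- file.path(config$out_dir, sprintf("variant%d", v))
    dir.create(vdir, showWarnings = FALSE)
    sub <- function(ids) cohort[cohort$patient_id %in% ids, , drop = FALSE]

    ws <- run_stage(sprintf("preprocess_v%d", v), {
      list(train = build_dataset_variant(sub(splits$train), v, config$seed),
           val = build_dataset_variant(sub(splits$val), v, config$seed + 1L),
           test = build_dataset_variant(sub(splits$test), v, config$seed + 2L))
    })
    write_window_set(ws$train, file.path(vdir, "windows_train"))

    fit <- run_stage(sprintf("train_v%d", v),
                     train(build_model(model_cfg), ws$train, ws$val, model_cfg))
    save_model(fit, file.path(vdir, "model.rds"))
    utils::write.csv(fit$history, file.path(vdir, "training_log.csv"),
                     row.names = FALSE)

    metrics <- run_stage(sprintf("evaluate_v%d", v), {
      pred <- predict_windows(fit, ws$test, config$threshold)
      binary_metrics(pred$label, pred$probability, config$threshold)
    })
    jsonlite::write_json(c(as.list(metrics),
                           list(variant = v,
                                variant_flags = ws$test$variant_flags,
                                test_patients = sort(splits$test))),
                         file.path(vdir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)

    report <- run_stage(sprintf("ahi_v%d", v), {
      test_cohort <- sub(splits$test)
      flags <- ws$test$variant_flags
      full <- build_variant(test_cohort, flags$artifacts_removed,
                            flags$standardized, config$seed, balance = FALSE)
      pred <- predict_windows(fit, full, config$threshold)
      per_pat <- dplyr::summarise(
        dplyr::group_by(pred, .data$patient_id),
        est = estimate_ahi(.data$prediction,
                           trt_hours = dplyr::n() / 60), .groups = "drop")
      per_pat <- dplyr::left_join(
        per_pat, test_cohort[, c("patient_id", "true_ahi")], by = "patient_id")
      if (nrow(per_pat) >= 2) {
        ahi_report(per_pat$est, per_pat$true_ahi, per_pat$patient_id)
      } else NULL
    })
    if (!is.null(report)) {
      jsonlite::write_json(c(as.list(glance(report)),
                             list(confusion = report$confusion)),
                           file.path(vdir, "ahi_report.json"),
                           auto_unbox = TRUE, digits = NA)
      utils::write.csv(tidy(report), file.path(vdir, "ahi_scatter.csv"),
                       row.names = FALSE)
      utils::write.csv(report$confusion,
                       file.path(vdir, "severity_confusion.csv"))
    }

    run_stage(sprintf("explain_v%d", v), {
      pred <- predict_windows(fit, ws$test, config$threshold)
      outcomes <- list(TP = pred$label == 1 & pred$prediction == 1,
                       FP = pred$label == 0 & pred$prediction == 1,
                       TN = pred$label == 0 & pred$prediction == 0,
                       FN = pred$label == 1 & pred$prediction == 0)
      for (nm in names(outcomes)) {
        i <- which(outcomes[[nm]])[1]
        if (is.na(i)) next
        w <- ws$test$windows[i, , ]
        rm_ <- grad_cam(fit, w)
        render_overlay(w, rm_, file.path(vdir, sprintf("overlay_%s.png", nm)),
                       true_label = pred$label[i])
      }
      invisible(NULL)
    })
    results[[as.character(v)]] <- metrics
  }

  if (config$run_cv) {
    run_stage("cv", {
      plan <- incremental_kfold(cohort$patient_id, config$k,
                                seed = config$seed)
      cv_rows <- purrr::map(seq_len(nrow(plan)), function(i) {
        tr <- build_variant(cohort[cohort$patient_id %in% plan$train_ids[[i]], ],
                            TRUE, TRUE, config$seed)
        va <- build_variant(cohort[cohort$patient_id %in% plan$val_ids[[i]], ],
                            TRUE, TRUE, config$seed + 1L)
        fit <- train(build_model(model_cfg), tr, va, model_cfg)
        dplyr::mutate(glance(fit), fold = i, .before = 1)
      })
      utils::write.csv(dplyr::bind_rows(cv_rows),
                       file.path(config$out_dir, "cv_results.csv"),
                       row.names = FALSE)
    })
  }

  stage <- "done"
  persist_manifest(status = "complete")
  invisible(config$out_dir)
}

#' Compare completed variant runs
#'
#' Reads each run's `metrics.json` and assembles one row per variant with
#' the full window-level metrics; refuses to compare runs evaluated on
#' different test patients.
#'
#' @param dirs Character vector of variant directories (each containing a
#'   `metrics.json`).
#' @return A tibble, one row per run, plus a CSV-ready structure.
#' @export
compare_variants <- function(dirs) {
  stopifnot(length(dirs) >= 2)
  rows <- lapply(dirs, function(d) {
    path <- file.path(d, "metrics.json")
    if (!file.exists(path)) {
      abort(sprintf("missing metrics.json in %s", d),
            class = "osadetect_comparability_error")
    }
    jsonlite::read_json(path, simplifyVector = TRUE)
  })
  test_sets <- lapply(rows, function(r) sort(unlist(r$test_patients)))
  if (length(unique(vapply(test_sets, paste, "", collapse = ","))) > 1) {
    abort("runs were evaluated on different test patients",
          class = "osadetect_comparability_error")
  }
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(variant = r$variant,
                   artifacts_removed = r$variant_flags$artifacts_removed,
                   standardized = r$variant_flags$standardized,
                   accuracy = r$accuracy, sensitivity = r$sensitivity,
                   specificity = r$specificity, precision = r$precision,
                   npv = r$npv, f1 = r$f1, auc = r$auc,
                   lr_positive = r$lr_positive, loss = r$loss,
                   threshold = r$threshold)
  }))
}
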