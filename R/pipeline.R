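## End-to-end orchestration with a YAML config, per-stage sub-seeds, and a
## reproducibility manifest.

PIPELINE_STAGES <- c("simulate", "preprocess", "primitives", "label",
                     "fit-label-model", "train", "evaluate")

default_pipeline_config <- function() {
  list(
    cohort = list(n = 60, prevalence = 0.06),
    preprocess = list(crop_size = 32, half_width = 7),
    label = list(t = 6),
    aggregate = list(hi = 0.9, lo = 0.5),
    label_model = list(epochs = 250, step_size = 0.05, gibbs_sweeps = 2),
    train = list(size = 40, val_fraction = 0.3),
    classifier = list()
  )
}

read_pipeline_config <- function(config) {
  base <- default_pipeline_config()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  utils::modifyList(base, config)
}

#' Run the weak-supervision pipeline end to end
#'
#' Executes the requested stages in order, reading inputs from and writing
#' artifacts to `out_dir`, and records a run manifest (config snapshot,
#' seeds, per-stage summaries including the weak-label discard fraction).
#' Stages are deterministic given identical inputs and seed.
#'
#' @param config Path to a YAML config, a config list, or `NULL` for
#'   defaults.
#' @param stages Subset of `simulate`, `preprocess`, `primitives`, `label`,
#'   `fit-label-model`, `train`, `evaluate` (in pipeline order).
#' @param seed Global seed; per-stage sub-seeds are derived from it.
#' @param out_dir Working directory for all artifacts.
#' @return The run manifest (list), invisibly written to
#'   `manifest_run.json`.
#' @export
run_pipeline <- function(config = NULL, stages = PIPELINE_STAGES, seed = 1L,
                         out_dir = "valveweak_run") {
  cfg <- read_pipeline_config(config)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state_path <- function(...) file.path(out_dir, ...)
  manifest <- list(config = cfg, seed = as.integer(seed),
                   package_version = as.character(
                     utils::packageVersion("valveweak")),
                   stages = list())
  need <- function(path, stage, producer) {
    if (!file.exists(path)) {
      stop(sprintf("stage '%s' requires '%s'; run stage '%s' first",
                   stage, path, producer), call. = FALSE)
    }
  }

  if ("simulate" %in% stages) {
    specs <- sample_cohort_specs(cfg$cohort$n, cfg$cohort$prevalence,
                                 seed = derive_seed(seed, 1, 21))
    utils::write.csv(data.frame(specs), state_path("cohort_specs.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort_manifest(specs), state_path("manifest.csv"),
                     row.names = FALSE)
    manifest$stages$simulate <- list(n = cfg$cohort$n,
                                     prevalence = cfg$cohort$prevalence,
                                     n_bav = sum(specs$truth == "BAV"))
  }

  load_specs <- function(stage) {
    need(state_path("cohort_specs.csv"), stage, "simulate")
    df <- utils::read.csv(state_path("cohort_specs.csv"),
                          stringsAsFactors = FALSE)
    attr(df, "base_spec") <- phantom_spec()
    class(df) <- c("cohort_spec", "data.frame")
    df
  }

  if ("preprocess" %in% stages) {
    specs <- load_specs("preprocess")
    aligned <- preprocess_cohort(specs, crop_size = cfg$preprocess$crop_size,
                                 half_width = cfg$preprocess$half_width)
    adir <- state_path("aligned")
    for (a in aligned) write_aligned(a, adir)
    saveRDS(aligned, state_path("aligned.rds"))
    manifest$stages$preprocess <- list(
      n = length(aligned),
      crop_size = cfg$preprocess$crop_size,
      half_width = cfg$preprocess$half_width)
  }

  load_aligned <- function(stage) {
    need(state_path("aligned.rds"), stage, "preprocess")
    readRDS(state_path("aligned.rds"))
  }

  if ("primitives" %in% stages) {
    aligned <- load_aligned("primitives")
    primn <- normalize_primitives(compute_primitives(aligned))
    utils::write.csv(primn, state_path("primitives.csv"), row.names = FALSE)
    manifest$stages$primitives <- list(
      rows = nrow(primn),
      undefined_frames = sum(!primn$defined_area))
  }

  if ("label" %in% stages) {
    need(state_path("primitives.csv"), "label", "primitives")
    primn <- utils::read.csv(state_path("primitives.csv"),
                             stringsAsFactors = FALSE)
    aligned <- load_aligned("label")
    peaks <- vapply(aligned, `[[`, integer(1), "peak_frame_original")
    names(peaks) <- vapply(aligned, `[[`, "", "patient_id")
    lfs <- make_default_lfs(cfg$label$lf_config %||% NULL)
    L <- apply_lfs(primn, lfs, peaks, t = cfg$label$t)
    write_label_matrix(L, state_path("label_matrix.csv"))
    manifest$stages$label <- list(
      rows = nrow(L), lfs = colnames(L),
      coverage = as.list(round(lf_coverage(L), 4)),
      conflict = as.list(round(lf_conflict(L), 4)))
  }

  if ("fit-label-model" %in% stages) {
    need(state_path("label_matrix.csv"), "fit-label-model", "label")
    L <- read_label_matrix(state_path("label_matrix.csv"))
    lfs <- make_default_lfs(cfg$label$lf_config %||% NULL)
    model <- label_model(L, deps = infer_dependencies(lfs),
                         epochs = cfg$label_model$epochs,
                         step_size = cfg$label_model$step_size,
                         gibbs_sweeps = cfg$label_model$gibbs_sweeps,
                         seed = derive_seed(seed, 2, 21))
    write_label_model(model, state_path("label_model.json"))
    probs <- marginals(model, L, use_prior = FALSE)
    plabels <- aggregate_patients(probs, attr(L, "frame_map"),
                                  hi = cfg$aggregate$hi,
                                  lo = cfg$aggregate$lo)
    utils::write.csv(plabels, state_path("patient_labels.csv"),
                     row.names = FALSE)
    manifest$stages$`fit-label-model` <- list(
      patients = nrow(plabels),
      discarded = sum(plabels$provenance == "discarded"),
      discard_fraction = mean(plabels$provenance == "discarded"))
  }

  if ("train" %in% stages) {
    need(state_path("patient_labels.csv"), "train", "fit-label-model")
    plabels <- utils::read.csv(state_path("patient_labels.csv"),
                               stringsAsFactors = FALSE)
    aligned <- load_aligned("train")
    man <- utils::read.csv(state_path("manifest.csv"),
                           stringsAsFactors = FALSE)
    n <- length(aligned)
    nval <- max(4L, round(cfg$train$val_fraction * n))
    vidx <- with_seed(derive_seed(seed, 3, 21), sample(n, nval))
    val_truth <- as.integer(man$truth[vidx] == "BAV")
    ts <- build_training_set(aligned[-vidx],
                             plabels[plabels$patient_id %in%
                                       names(aligned)[-vidx], ],
                             mode = "weak-balanced", size = cfg$train$size,
                             seed = derive_seed(seed, 4, 21))
    ccfg <- do.call(classifier_config, cfg$classifier)
    mdl <- train_classifier(ts, aligned[vidx], val_truth, config = ccfg,
                            seed = derive_seed(seed, 5, 21))
    saveRDS(mdl, state_path("classifier.rds"))
    utils::write.csv(mdl$log, state_path("training_log.csv"),
                     row.names = FALSE)
    val_pred <- predict(mdl, aligned[vidx])
    th <- tryCatch(tune_threshold(val_pred$prob, val_truth),
                   error = function(e) 0.5)
    jsonlite::write_json(list(threshold = th, val_f1 = mdl$val_f1),
                         state_path("threshold.json"), auto_unbox = TRUE,
                         digits = NA)
    manifest$stages$train <- list(train_size = length(ts$sequences),
                                  val_size = nval, best_epoch = mdl$best_epoch,
                                  val_f1 = mdl$val_f1, threshold = th)
  }

  if ("evaluate" %in% stages) {
    need(state_path("classifier.rds"), "evaluate", "train")
    mdl <- readRDS(state_path("classifier.rds"))
    aligned <- load_aligned("evaluate")
    man <- utils::read.csv(state_path("manifest.csv"),
                           stringsAsFactors = FALSE)
    th <- jsonlite::read_json(state_path("threshold.json"))$threshold
    pred <- predict(mdl, aligned)
    truth <- as.integer(man$truth[match(pred$patient_id,
                                        man$patient_id)] == "BAV")
    pred$predicted_class <- ifelse(pred$prob > th, "BAV", "TAV")
    pred$threshold <- th
    emb <- as.data.frame(attr(pred, "embeddings"))
    names(emb) <- paste0("e", seq_along(emb))
    utils::write.csv(cbind(patient_id = pred$patient_id, emb),
                     state_path("embeddings.csv"), row.names = FALSE)
    utils::write.csv(pred, state_path("predictions.csv"), row.names = FALSE)
    mr <- classification_metrics(truth, pred$prob, th)
    jsonlite::write_json(unclass(mr), state_path("metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$evaluate <- unclass(mr)
  }

  jsonlite::write_json(manifest, state_path("manifest_run.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}
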