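# End-to-end orchestration: a validated nested run configuration, a single
# run_experiment() driver (generate-or-load -> split -> train -> evaluate ->
# explain -> iou-eval), the ablation grid, and delta reporting.

RUN_SCHEMA <- list(
  seed = NULL,
  data = c("manifest", "n_subjects", "canvas_size", "noise_sd", "severity"),
  split = c("fractions"),
  label = c("cutoff", "center", "mode"),
  model = c("variant", "inputs", "backbone", "input_size", "n_layers",
            "hidden_dim", "ffn_dim"),
  training = c("learning_rate", "beta1", "beta2", "epsilon", "epochs",
               "batch_size", "augment_shift", "select"),
  explain = c("k_percent", "n_subjects"),
  evaluate = c("k_values", "roi_shape", "roi_margin")
)

#' Default run configuration
#'
#' Nested configuration for [run_experiment()]; any subset of keys may be
#' overridden (unknown keys are rejected).  `data$manifest` switches from
#' synthetic generation to loading an existing cohort.
#'
#' @param ... named overrides, e.g. `model = list(backbone = "toy")`.
#' @return nested configuration list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    data = list(manifest = NULL, n_subjects = 60, canvas_size = 128,
                noise_sd = 1, severity = "uniform"),
    split = list(fractions = c(0.70, 0.15, 0.15)),
    label = list(cutoff = 25, center = 24.5, mode = "soft"),
    model = list(variant = "conv_att", inputs = TASKS, backbone = "toy",
                 input_size = 64, n_layers = 2, hidden_dim = 32,
                 ffn_dim = 64),
    training = list(learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.99,
                    epsilon = 1e-7, epochs = 20, batch_size = 32,
                    augment_shift = 4, select = "best_auc"),
    explain = list(k_percent = 20, n_subjects = 6),
    evaluate = list(k_values = seq(10, 80, 10), roi_shape = "circle",
                    roi_margin = 5)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(RUN_SCHEMA))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(over)) {
    if (sec == "seed") { cfg$seed <- over$seed; next }
    bad <- setdiff(names(over[[sec]]), RUN_SCHEMA[[sec]])
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
    cfg[[sec]] <- utils::modifyList(cfg[[sec]], over[[sec]],
                                    keep.null = TRUE)
  }
  structure(cfg, class = "run_config")
}

severity_sampler <- function(spec) {
  if (is.numeric(spec)) return(spec)
  switch(as.character(spec),
         uniform = stats::runif,
         stop("unknown severity distribution: ", spec))
}

run_log <- function(dir, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  cat(line, "\n", file = file.path(dir, "run.log"), append = TRUE)
  cat(jsonlite::toJSON(list(stage = stage, message = msg),
                       auto_unbox = TRUE),
      "\n", file = file.path(dir, "run.jsonl"), append = TRUE)
  invisible(line)
}

stage_try <- function(dir, stage, expr) {
  run_log(dir, stage, "start")
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run one full experiment
#'
#' Executes generate-or-load, stratified split, training, test-set
#' evaluation, heat-map explanation, and IoU scoring, writing every
#' artifact (resolved config, split CSV, training history, checkpoint,
#' metrics JSON, heat-map grids and overlays, IoU curves, logs) under
#' `out_dir`, each stamped with the configuration hash and global seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory for the run.
#' @return invisible list with the fitted model, metrics, IoU curves and
#'   artifact paths.
#' @export
run_experiment <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(unclass(config))
  yaml::write_yaml(c(unclass(config), list(config_hash = cfg_hash)),
                   file.path(out_dir, "resolved_config.yaml"))
  seed <- config$seed

  manifest_path <- stage_try(out_dir, "generate", {
    if (!is.null(config$data$manifest)) config$data$manifest else {
      generate_cohort(config$data$n_subjects,
                      severity_sampler(config$data$severity),
                      file.path(out_dir, "data"),
                      rng_seed = derive_seed(seed, "generate"),
                      canvas_size = config$data$canvas_size,
                      noise_sd = config$data$noise_sd)
      file.path(out_dir, "data", "manifest.csv")
    }
  })
  records <- load_manifest(manifest_path)

  split <- stage_try(out_dir, "split", {
    s <- stratified_split(records, config$split$fractions,
                          seed = derive_seed(seed, "split"),
                          cutoff = config$label$cutoff)
    write.csv(cbind(s, seed = attr(s, "seed")),
              file.path(out_dir, "split.csv"), row.names = FALSE)
    s
  })

  mcfg <- conv_att_config(
    variant = if (config$model$variant == "pooling_baseline") "pooling"
              else config$model$variant,
    inputs = config$model$inputs, backbone = config$model$backbone,
    input_size = config$model$input_size, n_layers = config$model$n_layers,
    hidden_dim = config$model$hidden_dim, ffn_dim = config$model$ffn_dim,
    seed = derive_seed(seed, "init"))
  tcfg <- train_config(
    learning_rate = config$training$learning_rate,
    beta1 = config$training$beta1, beta2 = config$training$beta2,
    epsilon = config$training$epsilon, epochs = config$training$epochs,
    batch_size = config$training$batch_size,
    label_mode = config$label$mode, cutoff = config$label$cutoff,
    center = config$label$center,
    augment_shift = config$training$augment_shift,
    select = config$training$select, seed = derive_seed(seed, "train"))

  fit <- stage_try(out_dir, "train", {
    f <- conv_att(records, split, mcfg, tcfg)
    write.csv(f$history, file.path(out_dir, "history.csv"),
              row.names = FALSE)
    saveRDS(list(params = model_params(f$model), config = mcfg,
                 training = tcfg, seed = seed, config_hash = cfg_hash),
            file.path(out_dir, "checkpoint.rds"))
    f
  })

  idx_test <- partition_indices(records, split, "test")
  metrics <- stage_try(out_dir, "evaluate", {
    p <- predict_proba(fit, records[idx_test])
    labs <- hard_label(vapply(records[idx_test],
                              function(r) r$moca_score, numeric(1)),
                       config$label$cutoff)
    m <- as.list(classification_metrics(p, labs))
    jsonlite::write_json(c(m, list(n_test = length(idx_test), seed = seed,
                                   config_hash = cfg_hash)),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    m
  })

  heatmap_sets <- stage_try(out_dir, "explain", {
    hdir <- file.path(out_dir, "heatmaps")
    dir.create(hdir, showWarnings = FALSE)
    sel <- idx_test[seq_len(min(config$explain$n_subjects,
                                length(idx_test)))]
    sets <- list()
    for (i in sel) {
      images <- load_and_resize(records[[i]], mcfg$input_size)
      hms <- if (mcfg$variant == "conv_att")
        rollout_heatmaps(fit, images) else grad_cam(fit, images)
      for (task in names(hms)) {
        base <- file.path(hdir, paste0(records[[i]]$subject_id, "_", task))
        write_heatmap(hms[[task]], paste0(base, ".txt"),
                      paste0(base, ".png"), 1 - images[[task]][, , 1])
      }
      sets[[records[[i]]$subject_id]] <- list(images = images, hms = hms)
    }
    sets
  })

  iou_tab <- stage_try(out_dir, "iou-eval", {
    rows <- list()
    for (id in names(heatmap_sets)) {
      s <- heatmap_sets[[id]]
      rec <- Filter(function(r) r$subject_id == id, records)[[1]]
      masks <- load_masks(rec, mcfg$input_size)
      for (task in names(s$hms)) {
        roi_w <- whole_drawing_roi(1 - s$images[[task]][, , 1],
                                   config$evaluate$roi_shape,
                                   config$evaluate$roi_margin)
        cu <- iou_curve(s$hms[task], list(roi_w), config$evaluate$k_values)
        cu$roi_type <- "whole_drawing"; cu$subject_id <- id; cu$task <- task
        rows[[length(rows) + 1L]] <- cu
        if (!is.null(masks) && !is.null(masks[[task]]) &&
            any(masks[[task]])) {
          ce <- iou_curve(s$hms[task], masks[task],
                          config$evaluate$k_values)
          ce$roi_type <- "expert"; ce$subject_id <- id; ce$task <- task
          rows[[length(rows) + 1L]] <- ce
        }
      }
    }
    tab <- do.call(rbind, rows)
    write.csv(tab, file.path(out_dir, "iou_curves.csv"), row.names = FALSE)
    tab
  })

  artifacts <- list(config = "resolved_config.yaml", split = "split.csv",
                    history = "history.csv", checkpoint = "checkpoint.rds",
                    metrics = "metrics.json", heatmaps = "heatmaps",
                    iou_curves = "iou_curves.csv")
  jsonlite::write_json(c(artifacts, list(config_hash = cfg_hash,
                                         seed = seed)),
                       file.path(out_dir, "artifacts.json"),
                       auto_unbox = TRUE)
  run_log(out_dir, "done", "all stages complete")
  invisible(list(fit = fit, metrics = metrics, iou = iou_tab,
                 out_dir = out_dir, config_hash = cfg_hash))
}

#' The ablation grid
#'
#' The nine model rows of the comparison: three single-input pooling
#' baselines, the multi-input pooling baseline, three single-input
#' conv-att models, the multi-input conv-att model (all hard-label), and
#' the multi-input conv-att model with soft labels.
#'
#' @return data frame with columns `model`, `variant`, `inputs`
#'   (comma-separated), `label_mode`.
#' @export
ablation_grid <- function() {
  rows <- list(
    list("vgg_clock", "pooling", "clock", "hard"),
    list("vgg_cube", "pooling", "cube", "hard"),
    list("vgg_trail", "pooling", "trail", "hard"),
    list("vgg_multi", "pooling", "clock,cube,trail", "hard"),
    list("conv_att_clock", "conv_att", "clock", "hard"),
    list("conv_att_cube", "conv_att", "cube", "hard"),
    list("conv_att_trail", "conv_att", "trail", "hard"),
    list("conv_att_multi", "conv_att", "clock,cube,trail", "hard"),
    list("conv_att_multi_soft", "conv_att", "clock,cube,trail", "soft"))
  do.call(rbind, lapply(rows, function(r)
    data.frame(model = r[[1]], variant = r[[2]], inputs = r[[3]],
               label_mode = r[[4]], stringsAsFactors = FALSE)))
}

#' Train and evaluate every ablation-grid row
#'
#' Fits each of the nine grid variants on the same records and split and
#' returns their test-set metrics, one row per model.
#'
#' @param records subject records.
#' @param split split assignment shared by all rows.
#' @param base_config template [conv_att_config()] whose backbone/size/
#'   dimensions every variant inherits.
#' @param training template [train_config()].
#' @return data frame: `model`, `accuracy`, `f1`, `auc`.
#' @export
run_ablation <- function(records, split, base_config = conv_att_config(),
                         training = train_config()) {
  grid <- ablation_grid()
  idx_test <- partition_indices(records, split, "test")
  labs <- hard_label(vapply(records[idx_test], function(r) r$moca_score,
                            numeric(1)), training$cutoff)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cfg <- base_config
    cfg$variant <- if (g$variant == "pooling") "pooling" else "conv_att"
    cfg$inputs <- strsplit(g$inputs, ",")[[1]]
    tr <- training
    tr$label_mode <- g$label_mode
    fit <- conv_att(records, split, cfg, tr)
    m <- classification_metrics(predict_proba(fit, records[idx_test]), labs)
    data.frame(model = g$model, accuracy = m["accuracy"], f1 = m["f1"],
               auc = m["auc"], row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Absolute and relative deltas against a baseline row
#'
#' For each metric column, reports `delta = value - baseline` and
#' `rel = 100 * delta / baseline` (percent) for every row, relative to the
#' named baseline row.
#'
#' @param metric_rows data frame with a `model` column and numeric metric
#'   columns (e.g. accuracy, f1, auc).
#' @param baseline value of `model` identifying the baseline row.
#' @return data frame with the original metrics plus `delta_*` and `rel_*`
#'   columns (relative deltas in percent).
#' @export
report_ablation <- function(metric_rows, baseline) {
  if (!"model" %in% names(metric_rows))
    stop("metric_rows must have a 'model' column")
  b <- which(metric_rows$model == baseline)
  if (length(b) != 1L)
    stop("baseline row '", baseline, "' not found")
  out <- metric_rows
  for (mcol in setdiff(names(metric_rows), "model")) {
    if (!is.numeric(metric_rows[[mcol]])) next
    base_val <- metric_rows[[mcol]][b]
    out[[paste0("delta_", mcol)]] <- metric_rows[[mcol]] - base_val
    out[[paste0("rel_", mcol)]] <-
      100 * (metric_rows[[mcol]] - base_val) / base_val
  }
  out
}
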