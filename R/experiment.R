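# End-to-end experiment protocol: one fixed architecture applied to
# several binary adulterant datasets (pure + one colorant each). Per
# dataset: SPXY split, fresh seed-fixed training, validation metrics,
# JSON report. Mirrors the transfer protocol in which the architecture
# optimized on one colorant is re-trained on the others.

#' Experiment configuration
#'
#' @param design a [synthetic_design()] used to generate the spectra, or
#'   `NULL` when `data_csv` is given.
#' @param data_csv optional path to a spectra CSV read with
#'   [read_spectra_csv()] instead of generating data.
#' @param ratio SPXY calibration fraction (default 0.75).
#' @param model a [smafnet_config()], shared by all datasets.
#' @param train a [train_config()]; each dataset re-trains from a fresh
#'   initialization with this same seed.
#' @param datasets list of `list(name =, colorant =)` entries; each dataset
#'   is the pure samples plus one colorant's samples. `NULL` means one
#'   dataset per colorant present in the data.
#' @param out_dir output directory for metrics JSON, resolved config and
#'   run log.
#' @export
experiment_config <- function(design = synthetic_design(), data_csv = NULL,
                              ratio = 0.75, model = smafnet_config(),
                              train = train_config(), datasets = NULL,
                              out_dir = "smafnet_run") {
  if (is.null(design) && is.null(data_csv)) {
    stop("either design or data_csv is required", call. = FALSE)
  }
  if (!is.null(design)) stopifnot(inherits(design, "synthetic_design"))
  stopifnot(inherits(model, "smafnet_config"), inherits(train, "train_config"))
  if (!is.null(datasets)) {
    nms <- vapply(datasets, `[[`, character(1), "name")
    if (anyDuplicated(nms)) stop("dataset names must be unique", call. = FALSE)
  }
  structure(list(design = design, data_csv = data_csv, ratio = ratio,
                 model = model, train = train, datasets = datasets,
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Run the multi-dataset experiment
#'
#' For each listed dataset: subset the pure samples plus one colorant,
#' split with [spxy_split()], train the shared architecture from a fresh
#' seed-fixed initialization, evaluate on the validation split, and write
#' `<name>_metrics.json` (metrics plus raw confusion counts and split
#' sizes). Also writes `resolved_config.yaml` (all defaults materialized)
#' and `run.log` (seed, package version, per-stage timings). Metric JSON
#' files are byte-identical across reruns of the same config.
#'
#' @param cfg an [experiment_config()].
#' @return named list of per-dataset results (`split`, `fit`, `confusion`,
#'   `metrics`), invisibly.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                               append = TRUE)
  cat("", file = log_path)  # truncate
  logline("smafnet %s", as.character(utils::packageVersion("smafnet")))
  logline("train seed: %d", cfg$train$seed)

  t0 <- proc.time()[["elapsed"]]
  data <- if (!is.null(cfg$data_csv)) read_spectra_csv(cfg$data_csv)
          else generate_dataset(cfg$design)
  logline("data: %d samples x %d points (%.2fs)", n_samples(data),
          ncol(data$absorbance), proc.time()[["elapsed"]] - t0)

  datasets <- cfg$datasets
  if (is.null(datasets)) {
    present <- setdiff(unique(data$colorant), "none")
    datasets <- lapply(present, function(cl) list(name = cl, colorant = cl))
  }

  yaml::write_yaml(.resolve_config(cfg), file.path(cfg$out_dir,
                                                   "resolved_config.yaml"))

  results <- list()
  for (ds in datasets) {
    t1 <- proc.time()[["elapsed"]]
    keep <- data$colorant %in% c("none", ds$colorant)
    sub <- data[keep]
    if (length(unique(sub$labels)) < 2L) {
      stop("dataset '", ds$name, "' does not contain both classes",
           call. = FALSE)
    }
    split <- spxy_split(sub, ratio = cfg$ratio)
    fit <- train_model(cfg$model, cfg$train, sub[split$calibration_idx],
                       sub[split$validation_idx])
    ev <- evaluate_model(fit, sub[split$validation_idx])
    report <- list(
      dataset = ds$name,
      colorant = ds$colorant,
      n_calibration = length(split$calibration_idx),
      n_validation = length(split$validation_idx),
      confusion = ev$confusion[c("TP", "TN", "FP", "FN")],
      metrics = list(ACC = ev$metrics$ACC, PRE = ev$metrics$PRE,
                     REC = ev$metrics$REC, F1 = ev$metrics$F1),
      seed = cfg$train$seed
    )
    jsonlite::write_json(report,
                         file.path(cfg$out_dir,
                                   paste0(ds$name, "_metrics.json")),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
    logline("dataset %s: ACC %.2f%%, F1 %s (%.2fs)", ds$name, ev$metrics$ACC,
            formatC(ev$metrics$F1, format = "f", digits = 4),
            proc.time()[["elapsed"]] - t1)
    results[[ds$name]] <- list(split = split, fit = fit,
                               confusion = ev$confusion,
                               metrics = ev$metrics)
  }
  invisible(results)
}

# Materialize every default into plain lists for the resolved-config dump.
.resolve_config <- function(cfg) {
  strip <- function(x) {
    if (inherits(x, c("synthetic_design", "spm_config", "msfem_config",
                      "csafm_config", "smafnet_config", "train_config"))) {
      lapply(unclass(x), strip)
    } else if (is.list(x)) {
      lapply(x, strip)
    } else x
  }
  list(design = if (is.null(cfg$design)) NULL else strip(cfg$design),
       data_csv = cfg$data_csv,
       ratio = cfg$ratio,
       model = strip(cfg$model),
       train = strip(cfg$train),
       datasets = cfg$datasets,
       out_dir = cfg$out_dir)
}

#' Load an experiment configuration from YAML
#'
#' Recognised top-level keys: `design` (fields of [synthetic_design()]),
#' `data_csv`, `ratio`, `model` (with `input_length`, `head_hidden` and
#' nested `spm`, `msfem`, `csafm` blocks), `train` (fields of
#' [train_config()]), `datasets`, `out_dir`. Missing keys take the package
#' defaults.
#'
#' @param path YAML file path.
#' @return an [experiment_config()].
#' @export
experiment_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(block, fn) {
    if (is.null(block)) return(fn())
    args <- block[intersect(names(block), names(formals(fn)))]
    do.call(fn, args)
  }
  model <- if (is.null(y$model)) smafnet_config() else {
    mb <- y$model
    args <- list(spm = take(mb$spm, spm_config),
                 msfem = take(mb$msfem, msfem_config),
                 csafm = take(mb$csafm, csafm_config))
    if (!is.null(mb$input_length)) args$input_length <- mb$input_length
    if (!is.null(mb$head_hidden)) args$head_hidden <- mb$head_hidden
    do.call(smafnet_config, args)
  }
  experiment_config(
    design = if (is.null(y$design) && !is.null(y$data_csv)) NULL
             else take(y$design, synthetic_design),
    data_csv = y$data_csv,
    ratio = if (is.null(y$ratio)) 0.75 else y$ratio,
    model = model,
    train = take(y$train, train_config),
    datasets = y$datasets,
    out_dir = if (is.null(y$out_dir)) "smafnet_run" else y$out_dir)
}
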