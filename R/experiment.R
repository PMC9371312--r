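# One-command experiment runner: generate phantoms -> fit -> evaluate,
# with a self-describing results directory. Configs are YAML with
# sections `phantom`, `model`, `train`, `experiment`.

#' Read an experiment configuration
#'
#' @param path YAML file with sections `phantom` (arguments of
#'   [phantom_config()]), `model` (top-level and nested arguments of
#'   [ctg_config()]), `train` (overrides of the `train` block) and
#'   `experiment` (`n_train`, `n_val`, `n_test`, `seed`).
#' @return Nested list.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  yaml::read_yaml(path)
}

build_configs <- function(cf, seed = NULL) {
  ph <- cf$phantom %||% list()
  ex <- cf$experiment %||% list()
  if (!is.null(seed)) ex$seed <- as.integer(seed)
  ex$seed <- ex$seed %||% 1L
  ex$n_train <- ex$n_train %||% 200L
  ex$n_val <- ex$n_val %||% 50L
  ex$n_test <- ex$n_test %||% 50L
  ph$seed <- ph$seed %||% ex$seed
  pcfg <- do.call(phantom_config, ph)
  md <- cf$model %||% list()
  md$desk_profile <- md$desk_profile %||% TRUE
  md$image_size <- md$image_size %||% pcfg$image_height
  md$num_classes <- md$num_classes %||%
    (if (pcfg$classes == "threeclass") 3L else 2L)
  tr <- cf$train %||% list()
  if (length(tr)) md$train <- utils::modifyList(md$train %||% list(), tr)
  mcfg <- do.call(ctg_config, md)
  mcfg$train$seed <- ex$seed
  list(phantom = pcfg, model = mcfg, experiment = ex)
}

#' Run a complete phantom experiment
#'
#' Generates seeded train/validation/test phantoms, fits the network, and
#' evaluates all eleven metrics on the held-out test set. Writes
#' `metrics.csv`, the per-epoch `log.csv`, a copy of the resolved
#' configuration and a `run_info.txt` into `out_dir`.
#'
#' @param config path to a YAML config (see [read_experiment_config()]) or
#'   an equivalent nested list.
#' @param out_dir results directory (created; default a tempdir subdir).
#' @param seed optional seed overriding the config's experiment seed.
#' @param verbose print training progress.
#' @return Invisibly, a list with `fit`, `metrics` (one-row data.frame),
#'   `eval`, and `paths`.
#' @export
run_experiment <- function(config, out_dir = tempfile("ctgnet_run_"),
                           seed = NULL, verbose = FALSE) {
  cf <- if (is.character(config)) read_experiment_config(config) else config
  cfs <- build_configs(cf, seed)
  pcfg <- cfs$phantom; mcfg <- cfs$model; ex <- cfs$experiment
  train <- generate_dataset(pcfg, ex$n_train, start_index = 0L)
  val <- generate_dataset(pcfg, ex$n_val, start_index = ex$n_train)
  test <- generate_dataset(pcfg, ex$n_test,
                           start_index = ex$n_train + ex$n_val)
  attr(train, "phantom_config") <- pcfg
  fit <- ctgnet_fit(train, val, config = mcfg, seed = ex$seed,
                    verbose = verbose)
  ev <- evaluate_model(fit, test)
  metrics <- ev$summary[, c("dsc", "ji", "tpr", "fpr", "tfpr", "auc",
                            "acc", "sen", "spc", "pre", "f1")]
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    metrics = file.path(out_dir, "metrics.csv"),
    log = file.path(out_dir, "log.csv"),
    config = file.path(out_dir, "config.yaml"),
    info = file.path(out_dir, "run_info.txt"))
  utils::write.csv(metrics, paths$metrics, row.names = FALSE)
  utils::write.csv(fit$log, paths$log, row.names = FALSE)
  yaml::write_yaml(list(phantom = unclass(pcfg),
                        model = strip_cfg(mcfg),
                        experiment = ex), paths$config)
  writeLines(c(sprintf("run id: %s", format(Sys.time(), "%Y%m%d-%H%M%S")),
               sprintf("seed: %d", ex$seed),
               sprintf("epochs run: %d (best %d)", fit$epochs_run,
                       fit$best_epoch),
               utils::capture.output(print(metrics, row.names = FALSE))),
             paths$info)
  invisible(list(fit = fit, metrics = metrics, eval = ev, paths = paths))
}

strip_cfg <- function(cfg) {
  x <- unclass(cfg)
  rapply(x, function(v) v, how = "replace")
}

#' Save / load a fitted model
#'
#' The checkpoint embeds the configuration; [load_ctgnet()] refuses a
#' checkpoint whose configuration disagrees with an explicitly requested
#' one.
#'
#' @param object a `"ctgnet"` fit.
#' @param path file path (RDS).
#' @export
save_ctgnet <- function(object, path) {
  stopifnot(inherits(object, "ctgnet"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_ctgnet
#' @param config optional [ctg_config()] that the checkpoint must match.
#' @export
load_ctgnet <- function(path, config = NULL) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (!inherits(obj, "ctgnet")) stop("not a ctgnet checkpoint: ", path)
  if (!is.null(config) && !identical(strip_cfg(obj$config),
                                     strip_cfg(config)))
    stop("checkpoint/config mismatch:\n  checkpoint: ",
         paste(deparse(strip_cfg(obj$config)), collapse = ""),
         "\n  requested: ", paste(deparse(strip_cfg(config)), collapse = ""))
  obj
}
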