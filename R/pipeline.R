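# End-to-end orchestration: simulate -> preprocess -> label -> train ->
# evaluate, with one master seed fanning out to every stage and all
# artifacts persisted as plain text.

# FNV-1a over a string; used to fingerprint a run configuration so a run
# directory can be matched to the exact config that produced it
.config_fingerprint <- function(cfg) {
  s <- jsonlite::toJSON(.config_as_list(cfg), auto_unbox = TRUE, digits = 12)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte since b < 256; stay in doubles
    low <- bitwXor(h %% 256, b)
    h <- (((h %/% 256) * 256 + low) * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

.config_as_list <- function(cfg) {
  strip <- function(x) { attributes(x) <- NULL; x }
  list(sim = strip(unclass(cfg$sim)), wavelet = unclass(cfg$wavelet),
       model = unclass(cfg$model), train = unclass(cfg$train),
       fs_out = cfg$fs_out, duration_s = cfg$duration_s, seed = cfg$seed)
}

#' Configuration of a full pipeline run
#'
#' Composes the stage configurations and derives every stage seed from one
#' master seed, so a run is one reproducible unit.
#'
#' @param sim A [sim_config()].
#' @param wavelet A [wavelet_spec()].
#' @param model A [model_config()]; the desk-scale hidden size 64 is the
#'   default here.
#' @param train A [train_config()].
#' @param fs_out ECG rate after downsampling, Hz.
#' @param duration_s Segment length, seconds.
#' @param out_dir Output directory for artifacts.
#' @param seed Master seed; overrides the `sim` and `train` seeds.
#' @return Object of class `bp_run_config`.
#' @export
run_config <- function(sim = sim_config(), wavelet = wavelet_spec(),
                       model = model_config(hidden_size = 64L),
                       train = train_config(), fs_out = 100, duration_s = 10,
                       out_dir = tempfile("bp_run_"), seed = 1L) {
  sim$seed <- .derive_seed(seed, 11L)
  train$seed <- .derive_seed(seed, 13L)
  structure(list(sim = sim, wavelet = wavelet, model = model, train = train,
                 fs_out = fs_out, duration_s = duration_s,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "bp_run_config")
}

#' Run the full pipeline
#'
#' Executes simulate, preprocess+label, train and evaluate in order on
#' synthetic data (or a supplied `bp_dataset`), persisting the manifest,
#' the labeled dataset, the per-epoch training log, test-set predictions,
#' and the evaluation report under `cfg$out_dir`. A second run with the
#' same config writes identical artifacts.
#'
#' @param cfg A [run_config()].
#' @param dataset Optional pre-built `bp_dataset`; defaults to simulating
#'   from `cfg$sim`.
#' @param quiet Suppress stage messages.
#' @return The `bp_eval_report` for the test split, invisibly annotated
#'   with artifact paths (`attr(, "paths")`).
#' @export
run_bp_pipeline <- function(cfg, dataset = NULL, quiet = FALSE) {
  stopifnot(inherits(cfg, "bp_run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  fp <- .config_fingerprint(cfg)
  jsonlite::write_json(c(.config_as_list(cfg), list(fingerprint = fp)),
                       file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = 12)

  say("[simulate] %d records x %gs (fingerprint %s)", cfg$sim$n_records,
      cfg$sim$duration_s, fp)
  if (is.null(dataset)) dataset <- make_dataset(cfg$sim)
  utils::write.csv(dataset$manifest, file.path(cfg$out_dir, "manifest.csv"),
                   row.names = FALSE)

  say("[label] preprocessing and quality-gating segments")
  labeled <- build_labeled_dataset(dataset, cfg$wavelet, cfg$fs_out,
                                   cfg$duration_s)
  write_labeled_data(labeled, file.path(cfg$out_dir, "labeled.csv"))
  usable <- labeled$qc
  if (!any(usable))
    stop("empty dataset: every segment was discarded by the ABP quality gate",
         call. = FALSE)
  say("[label] %d/%d segments passed the skewness gate",
      sum(usable), length(usable))

  say("[train] %d epochs, hidden %d", cfg$train$max_epochs,
      cfg$model$hidden_size)
  model <- train_bp_model(labeled, cfg$model, cfg$train)
  utils::write.csv(model$log, file.path(cfg$out_dir, "train_log.csv"),
                   row.names = FALSE)

  te <- labeled$qc & labeled$meta$split == "test"
  if (!any(te))
    stop("empty dataset: no test segments passed the quality gate",
         call. = FALSE)
  tasks <- model$model_cfg$tasks
  truth <- labeled$y[te, tasks, drop = FALSE]
  pred <- predict(model, labeled$x[te, , drop = FALSE])
  write_predictions(truth, pred, tasks,
                    file.path(cfg$out_dir, "predictions.csv"))

  say("[evaluate] %d test segments", sum(te))
  report <- evaluate_bp(truth, pred, tasks)
  write_eval_report(report, cfg$out_dir)
  attr(report, "paths") <- list(
    dir = cfg$out_dir,
    report = file.path(cfg$out_dir, "report.json"),
    predictions = file.path(cfg$out_dir, "predictions.csv"),
    train_log = file.path(cfg$out_dir, "train_log.csv"))
  attr(report, "fingerprint") <- fp
  report
}

#' Write / read a long-format predictions table
#'
#' Rows of `(segment_id, task, truth, pred)`, the exchange format between
#' the training and evaluation stages.
#'
#' @param truth,pred `n x k` matrices, mmHg.
#' @param tasks Task names (columns).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(truth, pred, tasks, path) {
  n <- nrow(truth)
  df <- do.call(rbind, lapply(seq_along(tasks), function(k)
    data.frame(segment_id = seq_len(n), task = tasks[k],
               truth = truth[, k], pred = pred[, k])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path)
  tasks <- unique(df$task)
  truth <- sapply(tasks, function(tk) df$truth[df$task == tk])
  pred <- sapply(tasks, function(tk) df$pred[df$task == tk])
  list(truth = as.matrix(truth), pred = as.matrix(pred), tasks = tasks)
}
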