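# End-to-end orchestration: simulate -> extract -> standardize -> train and
# evaluate all models on shared folds -> nonparametric comparison.

#' Experiment configuration
#'
#' Bundles everything a full run depends on; a run is fully determined by
#' `(config, seed)`. Wrapper and RFE budgets default to reduced,
#' single-CPU-friendly values (the study's own budgets are unpublished);
#' raise them through `model_params` for closer-to-exhaustive searches.
#'
#' @param gel A [gel_config()] for the simulation stage.
#' @param models Models to run (subset of NB, SVM, MKL, FSMKL, SVM-RFE,
#'   GA-SVM, PSO-SVM).
#' @param k Cross-validation folds.
#' @param alpha Significance level of the comparison stage.
#' @param scaling `"global"` or `"per-fold"` standardization.
#' @param Ng Grey levels for quantization.
#' @param model_params Named list of per-model parameter lists, merged
#'   over the defaults.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(gel = gel_config(),
                              models = c("NB", "SVM", "MKL", "FSMKL",
                                         "SVM-RFE", "GA-SVM", "PSO-SVM"),
                              k = 10, alpha = 0.05,
                              scaling = c("global", "per-fold"),
                              Ng = 64L, model_params = list()) {
  scaling <- match.arg(scaling)
  defaults <- list(
    "SVM" = list(C_grid = c(0.1, 1, 10, 100), gamma_scales = c(0.1, 1, 10),
                 inner_k = 3),
    "FSMKL" = list(subset_sizes = c(1, 2, 3, 5, 8, 13, Inf), C = 10),
    "SVM-RFE" = list(step_fraction = 0.1, inner_k = 3, C = 10,
                     switch_at = 30),
    "GA-SVM" = list(population = 16, iterations = 12, inner_k = 3),
    "PSO-SVM" = list(population = 16, iterations = 12, inner_k = 3))
  for (m in names(model_params))
    defaults[[m]] <- utils::modifyList(defaults[[m]] %||% list(),
                                       model_params[[m]])
  structure(list(gel = gel, models = models, k = k, alpha = alpha,
                 scaling = scaling, Ng = as.integer(Ng),
                 model_params = defaults),
            class = "experiment_config")
}

build_model_list <- function(config) {
  mp <- config$model_params
  constructors <- list(
    "NB" = model_nb(),
    "SVM" = do.call(model_svm, mp[["SVM"]]),
    "MKL" = model_group_mkl(),
    "FSMKL" = do.call(model_fsmkl, mp[["FSMKL"]]),
    "SVM-RFE" = do.call(model_svm_rfe, mp[["SVM-RFE"]]),
    "GA-SVM" = do.call(model_wrapper,
                       c(list(engine = "GA"), mp[["GA-SVM"]])),
    "PSO-SVM" = do.call(model_wrapper,
                        c(list(engine = "PSO"), mp[["PSO-SVM"]])))
  unknown <- setdiff(config$models, names(constructors))
  if (length(unknown)) stop("unknown models: ", paste(unknown, collapse = ", "))
  constructors[config$models]
}

#' Run a complete experiment
#'
#' Executes the four phases of the study design — data extraction
#' (simulation + texture features), preprocessing (z-scoring), learning
#' (all models on shared stratified folds) and model selection (the
#' nonparametric decision workflow) — and optionally writes every result
#' table plus a provenance record to `out`.
#'
#' @param config An [experiment_config()].
#' @param seed Integer seed driving simulation, folds and searches.
#' @param out Optional output directory.
#' @param table Optional precomputed feature table (skips simulation and
#'   extraction; e.g. the deposited real-data table).
#' @param quiet Suppress per-stage progress messages?
#' @return List of class `gel_experiment`: `dataset`, `table`, `results`
#'   (fold tibble), `comparison` (`model_comparison`), `fsmkl_importance`
#'   (from a final full-data FSMKL fit, when FSMKL is among the models),
#'   `timings`, `config`, `seed`.
#' @export
run_experiment <- function(config = experiment_config(), seed = 1L,
                           out = NULL, table = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- as.integer(seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  timings <- c()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- tryCatch(force(expr), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e)))
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    say("%-10s %.1fs", stage, timings[[stage]])
    v
  }
  dataset <- NULL
  if (is.null(table)) {
    dataset <- clock("simulate", generate_dataset(config$gel, seed))
    table <- clock("extract", build_feature_table(dataset, Ng = config$Ng))
  }
  models <- build_model_list(config)
  results <- clock("evaluate",
                   evaluate_models(table, models, k = config$k,
                                   seed = seed, scaling = config$scaling))
  comparison <- clock("compare",
                      decision_workflow(results, alpha = config$alpha))
  importance <- NULL
  if ("FSMKL" %in% config$models) {
    importance <- clock("importance", {
      std <- standardize(table, "global")
      inv <- feature_inventory()
      present <- inv[inv$name %in% names(std), ]
      groups <- split(present$name, present$group)[unique(present$group)]
      bank <- build_kernel_bank(std, groups,
                                subset_sizes = config$model_params$FSMKL$subset_sizes)
      fit <- fsmkl_train(bank, C = config$model_params$FSMKL$C)
      report_importance(fit)
    })
  }
  bundle <- structure(list(dataset = dataset, table = table,
                           results = results, comparison = comparison,
                           fsmkl_importance = importance,
                           timings = timings, config = config, seed = seed),
                      class = "gel_experiment")
  if (!is.null(out)) write_experiment(bundle, out)
  bundle
}

#' Write an experiment bundle to disk
#'
#' Emits the feature table, the tidy per-fold results, averaged ROC
#' curves, the Finner comparison report, the FSMKL importance tables and a
#' provenance JSON (config hash, seed, package version, timings). Reruns
#' with the same `(config, seed)` are bit-identical.
#'
#' @param bundle A `gel_experiment`.
#' @param out Output directory.
#' @return `out`, invisibly.
#' @export
write_experiment <- function(bundle, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$table, file.path(out, "features.csv"))
  readr::write_csv(dplyr::select(bundle$results, -"roc"),
                   file.path(out, "results.csv"))
  curves <- bundle$results |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(curve = list(mean_roc(.data$roc)), .groups = "drop") |>
    tidyr::unnest("curve")
  readr::write_csv(curves, file.path(out, "roc_curves.csv"))
  readr::write_csv(bundle$comparison$finner$comparisons,
                   file.path(out, "finner_report.csv"))
  if (!is.null(bundle$fsmkl_importance)) {
    readr::write_csv(bundle$fsmkl_importance$kernels,
                     file.path(out, "fsmkl_kernels.csv"))
    readr::write_csv(bundle$fsmkl_importance$features,
                     file.path(out, "fsmkl_features.csv"))
  }
  prov <- list(seed = bundle$seed,
               config_hash = rlang::hash(bundle$config),
               package_version = as.character(utils::packageVersion("geltexture")),
               r_version = paste(R.version$major, R.version$minor, sep = "."),
               timings = as.list(bundle$timings),
               winner = bundle$comparison$winner)
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  summary_lines <- utils::capture.output(print(bundle$comparison))
  writeLines(summary_lines, file.path(out, "summary.txt"))
  invisible(out)
}

#' @export
print.gel_experiment <- function(x, ...) {
  cat("gel texture experiment (seed", x$seed, ")\n")
  agg <- x$results |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mean_auroc = mean(.data$auroc),
                     sd_auroc = stats::sd(.data$auroc),
                     median_features = stats::median(.data$n_features),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_auroc))
  print(as.data.frame(agg), digits = 3)
  cat("Winner:", x$comparison$winner, "\n")
  invisible(x)
}
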