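# End-to-end orchestration: simulate -> pretrain -> train -> calibrate ->
# predict -> evaluate -> sweep -> explain, writing every artifact with an
# embedded config hash and seed for reproducible runs.

#' Assemble a pipeline run configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Mandatory integer seed; no wall-clock default.
#' @param synth [synth_config()] for simulated inputs, or \code{NULL} when
#'   reading files.
#' @param trials_path,ontology_path Input files, used when \code{synth} is
#'   NULL.
#' @param model [hint_config()] model hyperparameters.
#' @param alpha,beta Selective-classification guarantee parameters.
#' @param split_date,validation_fraction Temporal split settings; the split
#'   date defaults to the synth config's.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(out_dir, seed, synth = synth_config(seed = seed),
                       trials_path = NULL, ontology_path = NULL,
                       model = hint_config(seed = seed),
                       alpha = 0.1, beta = 0.1,
                       split_date = NULL, validation_fraction = 0.15) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(synth) && (is.null(trials_path) || is.null(ontology_path)))
    stop("either a synth config or trials_path + ontology_path is required")
  if (!is.null(trials_path) && !file.exists(trials_path))
    stop("no such file: ", trials_path)
  if (!is.null(ontology_path) && !file.exists(ontology_path))
    stop("no such file: ", ontology_path)
  if (is.null(split_date))
    split_date <- if (!is.null(synth)) synth$split_date else
      stop("split_date is required when reading trials from a file")
  structure(list(out_dir = out_dir, seed = as.integer(seed), synth = synth,
                 trials_path = trials_path, ontology_path = ontology_path,
                 model = model, alpha = alpha, beta = beta,
                 split_date = as.Date(split_date),
                 validation_fraction = validation_fraction),
            class = "run_config")
}

#' Run the full prediction + selective-classification pipeline
#'
#' Simulates (or reads) trials, splits temporally, trains the interaction
#' network on the training fold, calibrates the abstention threshold on the
#' validation fold, applies it to the test fold, and writes six artifacts
#' to \code{out_dir}: checkpoint.json, calibration.json, decisions.csv,
#' metrics.json, sweep.csv and attention.dot.  Each artifact embeds the
#' config hash and seed.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the model, calibration, metrics and
#'   artifact paths.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  stage <- "setup"
  note <- function(...) if (verbose) message("[", stage, "] ", ...)
  tryCatch({
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    # hash the scientific configuration only, not the output location
    prov <- paste0("config=",
                   config_hash(unclass(config)[setdiff(names(config),
                                                       "out_dir")]),
                   " seed=", config$seed)

    stage <- "simulate"
    if (!is.null(config$synth)) {
      gen <- gen_trials(config$synth)
      trials <- gen$trials; onto <- gen$ontology
      admet <- gen_admet_tables(config$synth, gen$truth)
      note("generated ", nrow(trials), " trials")
    } else {
      trials <- read_trials(config$trials_path)
      onto <- read_ontology(config$ontology_path)
      admet <- NULL
      note("read ", nrow(trials), " trials")
    }

    stage <- "split"
    sp <- temporal_split(trials, config$split_date,
                         config$validation_fraction, seed = config$seed)
    note(nrow(sp$train), " train / ", nrow(sp$validation), " validation / ",
         nrow(sp$test), " test")

    stage <- "train"
    model <- train_hint(sp$train, onto, config$model, admet_tables = admet,
                        verbose = verbose)
    ck <- file.path(config$out_dir, "checkpoint.json")
    save_model(model, ck)

    stage <- "calibrate"
    val_pred <- predict(model, sp$validation)
    cal <- calibrate(scored_samples(val_pred$prob_success,
                                    sp$validation$label),
                     alpha = config$alpha, beta = config$beta)
    cj <- file.path(config$out_dir, "calibration.json")
    write_calibration(cal, cj, provenance = prov)
    note(if (cal$feasible) paste0("lam_hat = ", signif(cal$lam_hat, 6))
         else "infeasible; abstaining on all")

    stage <- "predict"
    test_pred <- predict(model, sp$test)
    dec <- apply_selective(test_pred$prob_success,
                           if (cal$feasible) cal$lam_hat else Inf)
    dc <- file.path(config$out_dir, "decisions.csv")
    write_decisions(dec, sp$test$trial_id, dc, provenance = prov)

    stage <- "evaluate"
    full <- metrics_report(test_pred$prob_success, sp$test$label,
                           seed = config$seed)
    sel <- metrics_report(test_pred$prob_success, sp$test$label,
                          kept = dec$kept, seed = config$seed)
    mj <- file.path(config$out_dir, "metrics.json")
    write_metrics(list(full_coverage = unclass(full),
                       selective = unclass(sel)), mj, provenance = prov)
    note(sprintf("test ROC-AUC %.4f; selective accuracy %.4f at retain %.4f",
                 full$roc_auc, sel$accuracy, sel$retain_rate))

    stage <- "sweep"
    sw <- lambda_sweep(scored_samples(test_pred$prob_success, sp$test$label))
    sc <- file.path(config$out_dir, "sweep.csv")
    con <- file(sc, "w"); writeLines(paste0("# ", prov), con)
    utils::write.csv(sw, con, row.names = FALSE); close(con)

    stage <- "explain"
    ar <- attention_report(model, sp$test[1, , drop = FALSE])
    ad <- file.path(config$out_dir, "attention.dot")
    write_attention_dot(ar$edges, ad)

    invisible(list(model = model, calibration = cal,
                   metrics = list(full = full, selective = sel),
                   sweep = sw,
                   paths = c(checkpoint = ck, calibration = cj,
                             decisions = dc, metrics = mj, sweep = sc,
                             attention = ad)))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}
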