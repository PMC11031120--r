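# File formats: trial tables (CSV, semicolon-joined multi-valued cells,
# criteria as embedded JSON), ontology edge lists, ADMET tables, calibration
# and metrics JSON, decisions CSV, DOT attention export, and a version-
# tagged JSON checkpoint for model parameters.

TRIAL_COLUMNS <- c("trial_id", "smiles", "icd_codes", "criteria", "phase",
                   "start_date", "completion_date")

# polynomial rolling hash of a config object, for artifact provenance
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a trial table to CSV
#' @param trials Trial data.frame.
#' @param path Output file.
#' @param provenance Optional string embedded as a leading comment line.
#' @export
write_trials <- function(trials, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.csv(trials, con, row.names = FALSE)
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Validates mandatory columns and per-row content: rows with unparseable
#' dates or empty drug/disease cells are skipped with their line numbers
#' messaged; the read fails if more than 10% of rows are skipped.
#'
#' @param path CSV path ('#' comment lines ignored).
#' @return Validated trial data.frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing_cols <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("trial table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) {
    warning("empty trial table: ", path)
    return(df)
  }
  st <- as.Date(df$start_date, optional = TRUE)
  en <- as.Date(df$completion_date, optional = TRUE)
  bad <- is.na(st) | is.na(en) | !nzchar(df$smiles) | !nzchar(df$icd_codes)
  if (any(bad)) {
    message("skipping ", sum(bad), " malformed row(s) at line(s): ",
            paste(utils::head(which(bad) + 1L, 10), collapse = ", "))
    if (mean(bad) > 0.10)
      stop("more than 10% of rows are malformed; refusing to continue")
    df <- df[!bad, , drop = FALSE]
  }
  df
}

#' Write an ontology as a child/parent edge list
#' @param onto A \code{trial_ontology}.
#' @param path Output file.
#' @export
write_ontology <- function(onto, path) {
  stopifnot(inherits(onto, "trial_ontology"))
  lines <- c("# disease ontology edge list: child parent",
             unlist(lapply(names(onto$parents), function(ch)
               paste(ch, onto$parents[[ch]]))))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ontology edge list
#'
#' Two whitespace-separated columns (child, parent); '#' comments and blank
#' lines ignored.  The DAG is validated: a cycle or multiple roots is fatal.
#'
#' @param path Edge-list file.
#' @return A \code{trial_ontology}.
#' @export
read_ontology <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("ontology file has no edges: ", path)
  parts <- strsplit(lines, "\\s+")
  if (any(lengths(parts) != 2))
    stop("malformed ontology line: '", lines[which(lengths(parts) != 2)[1]], "'")
  m <- do.call(rbind, parts)
  ontology(data.frame(child = m[, 1], parent = m[, 2]))
}

#' Write calibration result (threshold + risk/coverage curve) as JSON
#' @param calib A \code{trial_calibration}.
#' @param path Output JSON file.
#' @param provenance Optional provenance string.
#' @export
write_calibration <- function(calib, path, provenance = NULL) {
  stopifnot(inherits(calib, "trial_calibration"))
  obj <- list(lam_hat = calib$lam_hat, alpha = calib$alpha,
              beta = calib$beta, feasible = calib$feasible,
              curve = calib$curve)
  if (!is.null(provenance)) obj$provenance <- provenance
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Read a calibration JSON back into a \code{trial_calibration}
#' @param path JSON file written by [write_calibration()].
#' @return A \code{trial_calibration}.
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(lam_hat = if (is.null(obj$lam_hat)) NA_real_ else obj$lam_hat,
                 alpha = obj$alpha, beta = obj$beta,
                 feasible = obj$feasible,
                 curve = as.data.frame(obj$curve)),
            class = "trial_calibration")
}

#' Write selective decisions to CSV
#' @param decisions Output of [apply_selective()].
#' @param trial_ids Trial identifiers, same length.
#' @param path Output CSV.
#' @param provenance Optional provenance comment.
#' @export
write_decisions <- function(decisions, trial_ids, path, provenance = NULL) {
  stopifnot(nrow(decisions) == length(trial_ids))
  out <- data.frame(trial_id = trial_ids,
                    decision = decisions$decision,
                    confidence = decisions$confidence)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Export an attention report as a Graphviz DOT graph
#'
#' One directed edge per interaction-graph edge, penwidth scaled by the
#' attention weight, ready for Graphviz rendering.
#'
#' @param edges Data.frame (src, dst, weight), e.g. from
#'   [attention_report()].
#' @param path Output .dot file.
#' @export
write_attention_dot <- function(edges, path) {
  stopifnot(all(c("src", "dst", "weight") %in% names(edges)))
  body <- sprintf('  "%s" -> "%s" [label="%.3f", penwidth=%.2f];',
                  edges$src, edges$dst, edges$weight,
                  0.5 + 3 * edges$weight)
  writeLines(c("digraph interaction {", "  rankdir=BT;", body, "}"), path)
  invisible(path)
}

CHECKPOINT_FORMAT <- "trialselect-checkpoint/1"

#' Save a model checkpoint (JSON, version-tagged)
#'
#' Parameters are stored flattened with their dimensions alongside the
#' config, ontology codes and training history, so [load_model()] restores
#' a bit-identical model on any platform.
#'
#' @param model A \code{hint_model}.
#' @param path Output .json file.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "hint_model"))
  par <- lapply(model$params, function(p)
    list(dim = if (is.null(dim(p))) length(p) else dim(p),
         values = as.numeric(p)))
  obj <- list(format = CHECKPOINT_FORMAT,
              config = unclass(model$config),
              codes = model$codes,
              anc_idx = model$anc_idx,
              history = model$history,
              params = par)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#' @param path Checkpoint written by [save_model()].
#' @return A \code{hint_model}.
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("corrupt checkpoint (not parseable JSON): ", path,
                         call. = FALSE))
  if (is.null(obj$format) || !identical(obj$format, CHECKPOINT_FORMAT))
    stop("checkpoint version mismatch: expected '", CHECKPOINT_FORMAT,
         "', found '", if (is.null(obj$format)) "<none>" else obj$format, "'")
  params <- lapply(obj$params, function(p) {
    if (length(p$dim) > 1) array(p$values, dim = p$dim) else p$values
  })
  config <- structure(obj$config, class = "hint_config")
  config$kernel_sizes <- as.numeric(config$kernel_sizes)
  anc <- lapply(obj$anc_idx, as.integer)
  structure(list(params = params, config = config, nodes = NODE_NAMES,
                 J = hint_adjacency(), codes = obj$codes,
                 anc_idx = anc, history = obj$history),
            class = "hint_model")
}

#' Write a metrics report as JSON
#' @param report A \code{metrics_report} (or plain named list).
#' @param path Output JSON file.
#' @param provenance Optional provenance string.
#' @export
write_metrics <- function(report, path, provenance = NULL) {
  obj <- unclass(report)
  if (!is.null(provenance)) obj$provenance <- provenance
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
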