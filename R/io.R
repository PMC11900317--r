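# File formats: .smi libraries, activity CSV tables, curated dataset CSV,
# JSON reports.

#' Read a SMILES (.smi) file
#'
#' One molecule per line: `SMILES<whitespace>identifier`; the identifier
#' defaults to `SMI<line>` when absent. Blank lines and `#` comments are
#' skipped.
#'
#' @param path file path.
#' @return data.frame `compound_id`, `smiles`.
#' @export
kp_read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\\s+")
  data.frame(
    compound_id = vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) > 1L) parts[[i]][2] else sprintf("SMI%d", i), ""),
    smiles = vapply(parts, `[[`, "", 1L),
    stringsAsFactors = FALSE)
}

#' Write a SMILES (.smi) file
#' @param x data.frame with `smiles` (or `smiles_std`) and `compound_id`.
#' @param path output path.
#' @export
kp_write_smi <- function(x, path) {
  smi <- if ("smiles_std" %in% names(x)) x$smiles_std else x$smiles
  writeLines(paste(smi, x$compound_id), path)
}

#' Read an activity table
#'
#' CSV with columns `compound_id`, `smiles`, `target_id`, `activity_type`
#' (IC50/Ki/Kd/EC50), `value_nM` (> 0), `confidence` (0-9). Invalid rows
#' raise an error naming the problem.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
kp_read_activities <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "smiles", "target_id", "activity_type",
            "value_nM", "confidence")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("activity table missing columns: ",
                         paste(miss, collapse = ", "))
  bad_type <- !x$activity_type %in% c("IC50", "Ki", "Kd", "EC50")
  if (any(bad_type)) stop("bad activity_type in rows: ",
                          paste(utils::head(which(bad_type), 5), collapse = ", "))
  if (any(!is.finite(x$value_nM) | x$value_nM <= 0))
    stop("value_nM must be positive")
  if (any(x$confidence < 0 | x$confidence > 9))
    stop("confidence must lie in [0, 9]")
  x
}

#' Write a curated dataset CSV
#' @param dataset labeled dataset data.frame.
#' @param path output path.
#' @export
kp_write_dataset <- function(dataset, path) {
  out <- dataset[, intersect(c("compound_id", "smiles_std", "label"),
                             names(dataset)), drop = FALSE]
  out$source_tag <- attr(dataset, "source_tag") %||% NA_character_
  utils::write.csv(out, path, row.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the curation report as JSON
#' @param report output of [kp_curation_report()].
#' @param path output path.
#' @export
kp_write_curation_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
}

#' Write a split as JSON
#' @param split a `kp_split`.
#' @param path output path.
#' @export
kp_write_split <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE, pretty = TRUE)
}

#' Read a split JSON
#' @param path path written by [kp_write_split()].
#' @return a `kp_split`.
#' @export
kp_read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train_indices = as.integer(x$train_indices),
                 test_indices = as.integer(x$test_indices),
                 train_fraction = x$train_fraction,
                 seed = as.integer(x$seed)),
            class = "kp_split")
}

#' Write a model card as JSON
#'
#' Serializes the spec, seed, grid-search log (if any), CV summary and a
#' hash manifest of the training structures (the fitted state itself is an
#' in-memory R object; persist it with `saveRDS` when needed).
#'
#' @param model a `kp_model`.
#' @param path output path.
#' @param cv_summary optional `kp_metric_summary` to embed.
#' @param grid_results optional grid-search results data.frame to embed.
#' @export
kp_write_model_card <- function(model, path, cv_summary = NULL,
                                grid_results = NULL) {
  card <- list(
    algorithm = model$spec$algorithm,
    fingerprint_kind = model$spec$fingerprint_kind,
    hyperparams = model$spec$hyperparams,
    seed = model$spec$seed,
    n_features = model$n_features,
    decision_threshold = model$decision_threshold,
    train_manifest_size = length(model$train_manifest),
    train_manifest = model$train_manifest)
  if (!is.null(cv_summary)) card$cv_summary <- cv_summary$summary
  if (!is.null(grid_results)) card$grid_results <- grid_results
  jsonlite::write_json(card, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
}

#' Write screening hits CSV
#' @param hits a `kp_screening_hits` (clustered or not).
#' @param path output path.
#' @export
kp_write_hits <- function(hits, path) {
  utils::write.csv(as.data.frame(hits), path, row.names = FALSE)
}
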