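# Per-kinase datasets and random-forest models: the 10 uM activity label,
# the 100-compound eligibility rule, the 0.75 decision threshold, the
# inactive-ratio imbalance flag (< 0.25) and ensemble-level reporting.

#' Build per-target datasets from activity records
#'
#' One dataset per target with at least `min_n` curated compounds. The
#' per-compound label for a target follows its most potent record there:
#' active when the best `value_nM` is at most 10 uM, inactive otherwise.
#' The confidence filter (>= 9) is applied here for robustness even though
#' upstream extraction normally already enforced it.
#'
#' @param activities RawActivityRecord data.frame (`compound_id`,
#'   `target_id`, `value_nM`, `confidence`, ...).
#' @param curated MoleculeRecord data.frame of kept compounds
#'   (`compound_id`, `smiles_std`).
#' @param min_n eligibility threshold (default 100).
#' @param value_cutoff_nM activity cutoff (default 10000).
#' @param min_confidence minimum confidence (default 9).
#' @return list of `kp_target_dataset` objects (one per eligible target);
#'   attribute `excluded` names targets below `min_n` with their counts.
#' @export
kp_build_target_datasets <- function(activities, curated, min_n = 100L,
                                     value_cutoff_nM = 10000,
                                     min_confidence = 9L) {
  keep <- if ("status" %in% names(curated))
    curated[curated$status == "kept", , drop = FALSE] else curated
  act <- activities[activities$confidence >= min_confidence &
                      activities$compound_id %in% keep$compound_id, ,
                    drop = FALSE]
  smiles_of <- stats::setNames(keep$smiles_std, keep$compound_id)
  out <- list(); excluded <- list()
  for (tid in sort(unique(act$target_id))) {
    sub <- act[act$target_id == tid, , drop = FALSE]
    best <- tapply(sub$value_nM, sub$compound_id, min)
    ids <- names(best)
    label <- ifelse(unname(best) <= value_cutoff_nM, "active", "inactive")
    records <- data.frame(compound_id = ids,
                          smiles_std = unname(smiles_of[ids]),
                          label = label, best_value_nM = unname(best),
                          stringsAsFactors = FALSE)
    if (nrow(records) < min_n) {
      excluded[[tid]] <- nrow(records)
      next
    }
    n_active <- sum(label == "active"); n_inactive <- sum(label == "inactive")
    out[[tid]] <- structure(
      list(target_id = tid, records = records, n_active = n_active,
           n_inactive = n_inactive,
           inactive_ratio = if (n_active >= 1L) n_inactive / n_active
                            else NA_real_),
      class = "kp_target_dataset")
  }
  attr(out, "excluded") <- excluded
  out
}

#' @export
print.kp_target_dataset <- function(x, ...) {
  cat(sprintf("<kp_target_dataset %s: %d active / %d inactive (ratio %.3f)>\n",
              x$target_id, x$n_active, x$n_inactive, x$inactive_ratio))
  invisible(x)
}

#' Train one target-specific random-forest model
#'
#' RF with 100 trees and balanced class weights; evaluation by 5 repeated
#' stratified 70/30 resplits with the fixed probability threshold 0.75
#' (probability >= 0.75 classifies active). Datasets with an inactive
#' ratio below 0.25 are flagged highly imbalanced on the card.
#'
#' @param dataset a `kp_target_dataset`.
#' @param fingerprint_kind features for the model (default `"morgan"`).
#' @param seed integer seed.
#' @param n_repeats CV repeats (default 5).
#' @param decision_threshold fixed at 0.75 by the protocol.
#' @param imbalance_cutoff flag boundary (default 0.25, strict `<`).
#' @return object of class `kp_target_model_card`.
#' @export
kp_train_target_model <- function(dataset, fingerprint_kind = "morgan",
                                  seed = 1L, n_repeats = 5L,
                                  decision_threshold = 0.75,
                                  imbalance_cutoff = 0.25) {
  stopifnot(inherits(dataset, "kp_target_dataset"))
  if (dataset$n_active == 0L || dataset$n_inactive == 0L)
    stop("single-class target dataset: ", dataset$target_id)
  X <- kp_featurize_dataset(dataset$records, fingerprint_kind)
  y <- dataset$records$label
  spec <- kp_model_spec("random_forest", fingerprint_kind,
                        list(n_estimators = 100L, max_features = "sqrt",
                             class_weight = "balanced"), seed = seed)
  reps <- lapply(seq_len(n_repeats), function(r) {
    sp <- .kp_stratified_split(y, 0.7, seed * 1000L + r)
    spec_r <- spec; spec_r$seed <- spec$seed + r
    m <- kp_fit(spec_r, X[sp$train, , drop = FALSE], y[sp$train],
                decision_threshold = decision_threshold)
    pred <- kp_classify(m, X[sp$test, , drop = FALSE])
    kp_metrics_from_labels(y[sp$test] == "active", pred == "active")
  })
  model <- kp_fit(spec, X, y, smiles_std = dataset$records$smiles_std,
                  decision_threshold = decision_threshold)
  structure(list(target_id = dataset$target_id,
                 n_active = dataset$n_active,
                 n_inactive = dataset$n_inactive,
                 inactive_ratio = dataset$inactive_ratio,
                 imbalance_flag = dataset$inactive_ratio < imbalance_cutoff,
                 cv_summary = kp_summarize_repeats(reps),
                 decision_threshold = decision_threshold,
                 fingerprint_kind = attr(X, "kind"),
                 seed = as.integer(seed), model = model),
            class = "kp_target_model_card")
}

#' @export
print.kp_target_model_card <- function(x, ...) {
  cat(sprintf(
    "<kp_target_model_card %s: ratio %.3f%s | cv MCC %s | threshold %.2f>\n",
    x$target_id, x$inactive_ratio,
    if (x$imbalance_flag) " [imbalanced]" else "",
    formatC(kp_summary_mean(x$cv_summary, "mcc"), digits = 2, format = "f"),
    x$decision_threshold))
  invisible(x)
}

#' Ensemble-level performance report
#'
#' Mean and population standard deviation of every metric's CV mean across
#' model cards, computed both over all cards and over the subset without
#' the imbalance flag (the inactive-ratio < 0.25 filter).
#'
#' @param cards list of `kp_target_model_card`.
#' @param exclude_flagged if `TRUE` the `summary` field reports the
#'   filtered ensemble, otherwise the full one; `comparison` always holds
#'   both.
#' @return object of class `kp_ensemble_report`: `summary` (data.frame
#'   metric/mean/sd/n_models) and `comparison` (both ensembles side by
#'   side).
#' @export
kp_ensemble_report <- function(cards, exclude_flagged = FALSE) {
  stopifnot(length(cards) > 0,
            all(vapply(cards, inherits, logical(1), "kp_target_model_card")))
  flagged <- vapply(cards, `[[`, logical(1), "imbalance_flag")
  if (exclude_flagged && all(flagged))
    stop("all cards are imbalance-flagged; nothing left to report")
  per_metric <- function(sub) {
    do.call(rbind, lapply(.kp_metric_names, function(nm) {
      v <- vapply(sub, function(cd) kp_summary_mean(cd$cv_summary, nm),
                  numeric(1))
      ok <- !is.na(v)
      mu <- if (any(ok)) mean(v[ok]) else NA_real_
      data.frame(metric = nm, mean = mu,
                 sd = if (any(ok)) sqrt(mean((v[ok] - mu)^2)) else NA_real_,
                 n_models = sum(ok))
    }))
  }
  all_tab <- per_metric(cards)
  filt_tab <- if (any(!flagged)) per_metric(cards[!flagged]) else NULL
  comparison <- all_tab[, c("metric", "mean", "sd")]
  names(comparison)[2:3] <- c("mean_all", "sd_all")
  comparison$mean_filtered <- if (is.null(filt_tab)) NA_real_ else filt_tab$mean
  comparison$sd_filtered <- if (is.null(filt_tab)) NA_real_ else filt_tab$sd
  comparison$n_all <- length(cards)
  comparison$n_filtered <- sum(!flagged)
  structure(list(summary = if (exclude_flagged) filt_tab else all_tab,
                 comparison = comparison,
                 exclude_flagged = exclude_flagged),
            class = "kp_ensemble_report")
}

#' @export
print.kp_ensemble_report <- function(x, ...) {
  cat(sprintf("Ensemble report (%d models; filtered: %d)\n",
              x$comparison$n_all[1], x$comparison$n_filtered[1]))
  print(x$comparison[, c("metric", "mean_all", "mean_filtered")],
        row.names = FALSE)
  invisible(x)
}

#' Predict a compound x target panel
#'
#' Runs every card's model on every compound with the 0.75 rule.
#'
#' @param cards list of fitted `kp_target_model_card`.
#' @param compounds data.frame with `compound_id`, `smiles_std`.
#' @param experimental optional logical/0-1 matrix (compounds x targets)
#'   of experimental outcomes, attached as the panel's second layer.
#' @return object of class `kp_panel`: `predicted` (0/1 matrix compounds x
#'   targets) and `experimental` (same shape or `NULL`).
#' @export
kp_predict_panel <- function(cards, compounds, experimental = NULL) {
  stopifnot(length(cards) > 0)
  for (cd in cards) if (is.null(cd$model)) stop("card without fitted model: ",
                                                cd$target_id)
  tids <- vapply(cards, `[[`, "", "target_id")
  pred <- matrix(0L, nrow(compounds), length(cards),
                 dimnames = list(compounds$compound_id, tids))
  if (nrow(compounds)) {
    for (j in seq_along(cards)) {
      cd <- cards[[j]]
      X <- kp_featurize_dataset(compounds, cd$fingerprint_kind)
      pred[, j] <- as.integer(kp_classify(cd$model, X) == "active")
    }
  }
  if (!is.null(experimental)) {
    experimental <- as.matrix(experimental) * 1L
    if (!all(dim(experimental) == dim(pred)))
      stop("experimental layer shape does not match predictions")
    dimnames(experimental) <- dimnames(pred)
  }
  structure(list(predicted = pred, experimental = experimental),
            class = "kp_panel")
}

#' Binarize a percent-inhibition panel
#'
#' @param inhibition numeric matrix of percent inhibition at 10 uM.
#' @param cutoff activity call boundary (default 50, `>=` is active).
#' @return 0/1 integer matrix of the same shape.
#' @export
kp_panel_from_inhibition <- function(inhibition, cutoff = 50) {
  out <- (as.matrix(inhibition) >= cutoff) * 1L
  out
}

#' Per-compound panel success rates
#'
#' Percentage of targets whose predicted call matches the experimental
#' call, per compound.
#'
#' @param panel a `kp_panel` with both layers.
#' @return data.frame `compound_id`, `n_correct`, `n_targets`,
#'   `success_rate` (percent).
#' @export
kp_score_panel <- function(panel) {
  stopifnot(inherits(panel, "kp_panel"))
  if (is.null(panel$experimental)) stop("panel has no experimental layer")
  agree <- panel$predicted == panel$experimental
  data.frame(compound_id = rownames(panel$predicted),
             n_correct = rowSums(agree),
             n_targets = ncol(panel$predicted),
             success_rate = vapply(rowSums(agree), kp_success_rate,
                                   numeric(1), n_total = ncol(panel$predicted)),
             row.names = NULL, stringsAsFactors = FALSE)
}
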