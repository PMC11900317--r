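# Virtual screening with the family model and sphere-exclusion clustering
# of the hits on Morgan-fingerprint Tanimoto distance.

#' Screen a compound library
#'
#' Scores every library compound with the model and flags predicted hits
#' at the probability threshold. The library must be curated by the same
#' pipeline and structure-subtracted from the training data: any overlap
#' with the model's training manifest is an error.
#'
#' @param model fitted `kp_model`.
#' @param library MoleculeRecord data.frame (kept rows) or any data.frame
#'   with `compound_id`, `smiles_std`.
#' @param threshold decision threshold (default the model's).
#' @return data.frame of class `kp_screening_hits`, sorted by descending
#'   probability: `compound_id`, `smiles_std`, `probability`, `predicted`.
#' @export
kp_screen_library <- function(model, library, threshold = NULL) {
  stopifnot(inherits(model, "kp_model"))
  if ("status" %in% names(library)) {
    if (any(library$status != "kept"))
      stop("library contains un-curated records; run kp_curate first")
  }
  if (is.null(threshold)) threshold <- model$decision_threshold
  overlap <- intersect(library$smiles_std, model$train_manifest)
  if (length(overlap)) {
    stop("library overlaps the model's training data: ",
         paste(utils::head(overlap, 5), collapse = ", "),
         if (length(overlap) > 5) sprintf(" (and %d more)", length(overlap) - 5)
         else "")
  }
  X <- kp_featurize_dataset(library, model$spec$fingerprint_kind)
  p <- kp_predict_proba(model, X)
  out <- data.frame(compound_id = library$compound_id,
                    smiles_std = library$smiles_std,
                    probability = p, predicted = p >= threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$probability, out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("kp_screening_hits", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' Cluster screening hits by structural similarity
#'
#' Sphere-exclusion (leader) clustering on Tanimoto distance of Morgan
#' fingerprints: hits are processed in descending probability order; each
#' unassigned hit becomes a leader and captures all unassigned hits within
#' `distance_cutoff`. The representative of each cluster is its centroid
#' (maximal mean similarity to the other members; ties to the higher
#' probability, then lexicographic id).
#'
#' @param hits a `kp_screening_hits` (or data.frame with `compound_id`,
#'   `smiles_std`, `probability`), typically the `predicted` subset.
#' @param distance_cutoff Tanimoto distance radius (default 0.4).
#' @return the hits with `cluster_id` and `is_representative` columns.
#' @export
kp_cluster_hits <- function(hits, distance_cutoff = 0.4) {
  if (!nrow(hits)) stop("empty hit list")
  ord <- order(-hits$probability, hits$compound_id)
  hits <- hits[ord, , drop = FALSE]
  n <- nrow(hits)
  fps <- lapply(hits$smiles_std, function(s) kp_morgan_fp(s)$bits)
  sim <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      sim[i, j] <- sim[j, i] <- kp_tanimoto(fps[[i]], fps[[j]])
    }
  }
  cluster <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(cluster[i])) next
    cid <- cid + 1L
    members <- which(is.na(cluster) & (1 - sim[i, ]) <= distance_cutoff)
    cluster[members] <- cid
    cluster[i] <- cid
  }
  rep_flag <- logical(n)
  for (cl in seq_len(cid)) {
    members <- which(cluster == cl)
    score <- vapply(members, function(i) mean(sim[i, members]), numeric(1))
    best <- members[order(-score, -hits$probability[members],
                          hits$compound_id[members])[1]]
    rep_flag[best] <- TRUE
  }
  hits$cluster_id <- cluster
  hits$is_representative <- rep_flag
  rownames(hits) <- NULL
  hits
}
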