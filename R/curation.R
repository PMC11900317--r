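# Dataset curation: structure standardization, physicochemical filters,
# deduplication, activity labeling, decoy balancing and train/test splits.

#' Run code with a temporary RNG seed
#' @noRd
.kp_with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

.kp_record <- function(compound_id, smiles_raw, smiles_std = NA_character_,
                       heavy_atoms = NA_integer_, mol_weight = NA_real_,
                       status = "rejected", reject_reason = NA_character_) {
  data.frame(compound_id = compound_id, smiles_raw = smiles_raw,
             smiles_std = smiles_std, heavy_atoms = heavy_atoms,
             mol_weight = mol_weight, status = status,
             reject_reason = reject_reason, stringsAsFactors = FALSE)
}

#' Standardize one structure
#'
#' Open replacement for vendor washing/re-ionization: (1) keep the largest
#' fragment by heavy-atom count (ties: larger molecular weight, then
#' lexicographically smaller canonical SMILES); (2) neutralize charges
#' where a proton can be added or removed; (3) re-ionize with a fixed
#' pH 7.4 rule table (carboxylic/sulfonic/phosphonic acids to anions,
#' aliphatic amines and amidines/guanidines to cations); (4) emit the
#' canonical SMILES. Failures never raise: they return a rejected record
#' with `reject_reason` `parse_error` or `valence_error`.
#'
#' @param smiles raw SMILES string.
#' @param compound_id identifier carried through (defaults to the SMILES).
#' @return one-row data.frame (MoleculeRecord): `compound_id`,
#'   `smiles_raw`, `smiles_std`, `heavy_atoms`, `mol_weight`, `status`
#'   (kept/rejected), `reject_reason`.
#' @examples
#' kp_standardize_structure("CC(=O)[O-].[Na+]")$smiles_std
#' kp_standardize_structure("C1CC")$reject_reason   # parse_error
#' @export
kp_standardize_structure <- function(smiles, compound_id = smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    return(.kp_record(compound_id, if (is.character(smiles) && length(smiles))
      smiles else NA_character_, reject_reason = "parse_error"))
  }
  mol <- tryCatch(kp_parse_smiles(smiles), error = function(e) e)
  if (inherits(mol, "kp_valence_error"))
    return(.kp_record(compound_id, smiles, reject_reason = "valence_error"))
  if (inherits(mol, "condition"))
    return(.kp_record(compound_id, smiles, reject_reason = "parse_error"))
  frags <- kp_fragments(mol)
  if (length(frags) > 1L) {
    # larger heavy count first, then larger MW, then smaller canonical string
    ord <- order(-vapply(frags, `[[`, 0L, "n"),
                 -vapply(frags, kp_mol_weight, 0),
                 vapply(frags, kp_canonical_smiles, ""))
    mol <- frags[[ord[1]]]
  }
  mol <- .kp_neutralize(mol)
  mol <- .kp_reionize(mol)
  std <- tryCatch(kp_canonical_smiles(mol), error = function(e) NULL)
  if (is.null(std))
    return(.kp_record(compound_id, smiles, reject_reason = "parse_error"))
  .kp_record(compound_id, smiles, smiles_std = std,
             heavy_atoms = kp_heavy_atoms(mol),
             mol_weight = kp_mol_weight(mol), status = "kept")
}

#' Apply element / size / weight filters to a standardized record
#'
#' Keep rules: all elements within H, B, C, N, O, F, Si, P, S, Cl, Se, Br,
#' I; molecular weight at most 800 Da (inclusive); at least 15 heavy atoms
#' (inclusive). Idempotent; records already rejected pass through.
#'
#' @param record one-row MoleculeRecord data.frame.
#' @param min_heavy,max_mw boundary values (defaults 15 and 800).
#' @return the record with `status`/`reject_reason` updated.
#' @export
kp_apply_filters <- function(record, min_heavy = 15L, max_mw = 800) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  if (record$status == "rejected") return(record)
  mol <- kp_parse_smiles(record$smiles_std)
  if (!all(mol$atoms$symbol %in% .kp_allowed_elements)) {
    record$status <- "rejected"; record$reject_reason <- "disallowed_element"
  } else if (record$mol_weight > max_mw) {
    record$status <- "rejected"; record$reject_reason <- "mw_too_high"
  } else if (record$heavy_atoms < min_heavy) {
    record$status <- "rejected"; record$reject_reason <- "too_few_heavy_atoms"
  }
  record
}

#' Mark duplicate structures
#'
#' First occurrence of each canonical standardized SMILES is kept; later
#' occurrences are rejected with reason `duplicate`. Order is stable;
#' already-rejected records are passed through untouched.
#'
#' @param records MoleculeRecord data.frame (0 or more rows).
#' @return the same data.frame with duplicates marked.
#' @export
kp_deduplicate <- function(records) {
  if (!nrow(records)) return(records)
  seen <- character(0)
  for (i in seq_len(nrow(records))) {
    if (records$status[i] != "kept") next
    s <- records$smiles_std[i]
    if (s %in% seen) {
      records$status[i] <- "rejected"
      records$reject_reason[i] <- "duplicate"
    } else seen <- c(seen, s)
  }
  records
}

#' Curate a vector of structures
#'
#' standardize -> filter -> deduplicate, returning the full record table
#' (kept and rejected rows).
#'
#' @param smiles character vector of raw SMILES.
#' @param compound_id identifiers (defaults to the SMILES strings).
#' @param min_heavy,max_mw filter boundaries.
#' @return MoleculeRecord data.frame with one row per input.
#' @export
kp_curate <- function(smiles, compound_id = smiles, min_heavy = 15L,
                      max_mw = 800) {
  stopifnot(length(smiles) == length(compound_id))
  recs <- do.call(rbind, lapply(seq_along(smiles), function(i)
    kp_apply_filters(kp_standardize_structure(smiles[i], compound_id[i]),
                     min_heavy = min_heavy, max_mw = max_mw)))
  kp_deduplicate(recs)
}

#' Curation report
#'
#' @param records MoleculeRecord data.frame.
#' @return list: `n_input`, `n_kept`, `rejected` (named per-reason counts).
#'   Counts always sum to the input count.
#' @export
kp_curation_report <- function(records) {
  rej <- records$reject_reason[records$status == "rejected"]
  reasons <- c("parse_error", "valence_error", "disallowed_element",
               "mw_too_high", "too_few_heavy_atoms", "duplicate")
  counts <- vapply(reasons, function(r) sum(rej == r, na.rm = TRUE), integer(1))
  list(n_input = nrow(records), n_kept = sum(records$status == "kept"),
       rejected = as.list(counts))
}

#' Family-level activity label for one compound
#'
#' A compound joins the kinase-family positive class when at least one of
#' its activity records has `value_nM <= 10000` (10 uM) and
#' `confidence >= 9`; otherwise it is excluded from the family dataset.
#'
#' @param activity data.frame of RawActivityRecords for one compound
#'   (columns `value_nM`, `confidence`; extra columns ignored).
#' @param value_cutoff_nM activity threshold, default 10000 nM.
#' @param min_confidence minimum confidence score, default 9.
#' @return `"active"` or `"excluded"`.
#' @export
kp_label_family_active <- function(activity, value_cutoff_nM = 10000,
                                   min_confidence = 9L) {
  if (is.null(activity) || !nrow(activity)) return("excluded")
  if (length(unique(activity$compound_id)) > 1L)
    stop("records must all refer to one compound")
  hit <- activity$value_nM <= value_cutoff_nM &
    activity$confidence >= min_confidence
  if (any(hit, na.rm = TRUE)) "active" else "excluded"
}

#' Build a balanced family dataset
#'
#' Combines the active compounds with an equal number of decoys sampled
#' uniformly without replacement (no property matching), labeled inactive.
#'
#' @param actives MoleculeRecord data.frame of kept actives.
#' @param decoy_pool MoleculeRecord data.frame of kept, curated decoys.
#' @param seed integer RNG seed for decoy sampling.
#' @param source_tag free-text provenance tag stored on the result.
#' @return labeled dataset: data.frame (`compound_id`, `smiles_std`,
#'   `label`) with attributes `class_counts` and `source_tag`.
#' @export
kp_build_family_dataset <- function(actives, decoy_pool, seed,
                                    source_tag = "family") {
  stopifnot(all(actives$status == "kept"), all(decoy_pool$status == "kept"))
  n_act <- nrow(actives)
  if (nrow(decoy_pool) < n_act) {
    stop(sprintf("decoy pool too small: need %d, have %d (short by %d)",
                 n_act, nrow(decoy_pool), n_act - nrow(decoy_pool)))
  }
  pick <- .kp_with_seed(seed, sample(nrow(decoy_pool), n_act))
  ds <- rbind(
    data.frame(compound_id = actives$compound_id,
               smiles_std = actives$smiles_std, label = "active",
               stringsAsFactors = FALSE),
    data.frame(compound_id = decoy_pool$compound_id[pick],
               smiles_std = decoy_pool$smiles_std[pick], label = "inactive",
               stringsAsFactors = FALSE))
  if (anyDuplicated(ds$smiles_std))
    stop("actives and sampled decoys share structures; curate jointly first")
  attr(ds, "class_counts") <- c(active = n_act, inactive = n_act)
  attr(ds, "source_tag") <- source_tag
  ds
}

# Stratified index split: |train| = floor(fraction * N) overall, per-class
# allocation by floor + largest fractional remainder.
.kp_stratified_split <- function(labels, train_fraction, seed) {
  N <- length(labels)
  n_train <- floor(train_fraction * N)
  classes <- sort(unique(labels))
  per <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  raw <- train_fraction * per
  base <- floor(raw)
  short <- n_train - sum(base)
  if (short > 0) {
    add <- order(-(raw - base), classes)[seq_len(short)]
    base[add] <- base[add] + 1L
  } else if (short < 0) {
    cut <- order(raw - base, classes)[seq_len(-short)]
    base[cut] <- base[cut] - 1L
  }
  train_idx <- .kp_with_seed(seed, {
    unlist(lapply(seq_along(classes), function(j) {
      idx <- which(labels == classes[j])
      sample(idx, base[j])
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  list(train = train_idx, test = setdiff(seq_len(N), train_idx))
}

#' Stratified train/test split of a labeled dataset
#'
#' `|train| = floor(train_fraction * N)`; stratified by label so each
#' class's train fraction is within one item of the target.
#'
#' @param dataset labeled dataset data.frame with a `label` column.
#' @param train_fraction fraction in (0, 1), default 0.8.
#' @param seed integer RNG seed.
#' @return object of class `kp_split`: list with `train_indices`,
#'   `test_indices`, `train_fraction`, `seed`.
#' @export
kp_make_split <- function(dataset, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  N <- nrow(dataset)
  if (N < 2L) stop("need at least 2 records to split")
  sp <- .kp_stratified_split(dataset$label, train_fraction, seed)
  structure(list(train_indices = sp$train, test_indices = sp$test,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "kp_split")
}

#' Remove library structures present in a reference set
#'
#' Set difference on standardized canonical SMILES; both sides must have
#' been curated by the same pipeline.
#'
#' @param library,reference MoleculeRecord data.frames (or any data.frame
#'   with a `smiles_std` column).
#' @return the library rows whose `smiles_std` is absent from reference.
#' @export
kp_subtract_by_structure <- function(library, reference) {
  library[!(library$smiles_std %in% reference$smiles_std), , drop = FALSE]
}
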