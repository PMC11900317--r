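# Deterministic synthetic chemistry fixtures: planted-substructure actives
# versus decoys, plus per-target activity tables. Molecules are enumerated
# combinatorially from fragment sets (substituent x linker x core), so the
# generators are exactly reproducible and every product passes the curation
# filters by construction (>= 15 heavy atoms, MW <= 800, allowed elements,
# no ionizable groups that standardization would rewrite).

# Default planted motif: a 7-azaindole-like fused bicycle, the classic
# kinase hinge-binding chemotype. Any substituted active contains it;
# no decoy core does.
.KP_FIXTURE_MOTIF <- "c1ccc2[nH]ccc2n1"

# Fragment sets: substituents and linkers are SMILES prefixes whose last
# atom bonds to the first core atom.
.KP_FIXTURE_SUBS <- c(
  "CCOCCC", "CCCCCCC", "CC(C)CCC", "CCSCCC", "COCCCC", "CCOCC(C)",
  "CC(C)OCC", "CCCOCCC", "CCSCC(C)", "COCCOCC", "CCCC(C)CC", "CCOCCOC",
  "CC(C)CC(C)C", "CCCSCCC", "COCC(C)CC", "CCOCCCC", "CCCCOCC", "CC(CC)CCC",
  "COCCCCC", "CCSCCCC", "CC(C)COCC", "CCOC(C)CC", "CCCCSCC", "COCCSCC",
  "CC(C)OCCC", "CCCOC(C)C", "CCCCCOC", "CCSC(C)CC", "COC(C)CCC", "CCOCCSC")
.KP_FIXTURE_LINKERS <- c("CC", "CCC", "OC", "OCC", "SC", "C(C)C", "CC(C)", "OC(C)")
.KP_FIXTURE_DECOY_CORES <- c(
  "c1ccccc1", "c1ccc2ccccc2c1", "C1CCCCC1", "c1ccncc1", "C1CCNCC1",
  "c1ccc2ncccc12", "c1ccc2occc2c1", "c1ccc2sccc2c1", "C1CCOC1", "c1cncnc1")

#' Fixture specification
#'
#' @param n_active,n_inactive class sizes (defaults 200/200, the desk-scale
#'   stand-in for the balanced family dataset).
#' @param motif planted substructure pattern (default: azaindole bicycle).
#' @param label_noise fraction of labels flipped after construction, in
#'   `[0, 1)` (default 0).
#' @param seed integer seed (default 42).
#' @return object of class `kp_fixture_spec`.
#' @export
kp_fixture_spec <- function(n_active = 200L, n_inactive = 200L,
                            motif = .KP_FIXTURE_MOTIF, label_noise = 0,
                            seed = 42L) {
  stopifnot(n_active >= 1L, n_inactive >= 0L,
            label_noise >= 0, label_noise < 1)
  structure(list(n_active = as.integer(n_active),
                 n_inactive = as.integer(n_inactive), motif = motif,
                 subs = .KP_FIXTURE_SUBS, linkers = .KP_FIXTURE_LINKERS,
                 decoy_cores = .KP_FIXTURE_DECOY_CORES,
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "kp_fixture_spec")
}

# Enumerate sub x linker x core products as canonical SMILES, in a fixed
# deterministic order; stops early once n are collected.
.kp_enumerate_products <- function(subs, linkers, cores, n, require_motif,
                                   motif) {
  out <- character(0)
  pat <- kp_parse_pattern(motif)
  for (core in cores) for (li in linkers) for (su in subs) {
    if (length(out) >= n) return(out)
    smi <- paste0(su, li, core)
    mol <- tryCatch(kp_parse_smiles(smi), error = function(e) NULL)
    if (is.null(mol)) next
    if (kp_heavy_atoms(mol) < 15L || kp_mol_weight(mol) > 800) next
    has <- kp_has_substructure(mol, pat)
    if (require_motif != has) next
    can <- kp_canonical_smiles(mol)
    if (can %in% out) next    # different fragment combos can collide
    out <- c(out, can)
  }
  out
}

#' Generate the planted-motif family fixture
#'
#' Actives are enumerated as substituent-linker-motif products, inactives
#' as substituent-linker-decoy products; all molecules pass the curation
#' filters by construction and are emitted in standardized canonical form.
#' Rows are shuffled deterministically and label noise (if any) flips
#' exactly `round(label_noise * N)` seeded labels last.
#'
#' @param spec a `kp_fixture_spec`.
#' @return labeled dataset data.frame (`compound_id`, `smiles_std`,
#'   `label`, `true_label`) with attributes `motif` and `class_counts`.
#' @export
kp_generate_family_fixture <- function(spec = kp_fixture_spec()) {
  stopifnot(inherits(spec, "kp_fixture_spec"))
  actives <- .kp_enumerate_products(spec$subs, spec$linkers, spec$motif,
                                    spec$n_active, TRUE, spec$motif)
  if (length(actives) < spec$n_active)
    stop(sprintf("fragment sets yield only %d motif actives (need %d)",
                 length(actives), spec$n_active))
  decoys <- .kp_enumerate_products(spec$subs, spec$linkers, spec$decoy_cores,
                                   spec$n_inactive, FALSE, spec$motif)
  if (length(decoys) < spec$n_inactive)
    stop(sprintf("fragment sets yield only %d decoys (need %d)",
                 length(decoys), spec$n_inactive))
  smiles <- c(actives, decoys)
  label <- c(rep("active", spec$n_active), rep("inactive", spec$n_inactive))
  N <- length(smiles)
  ord <- .kp_with_seed(spec$seed, sample(N))
  smiles <- smiles[ord]; label <- label[ord]
  true_label <- label
  n_flip <- round(spec$label_noise * N)
  if (n_flip > 0L) {
    flip <- .kp_with_seed(spec$seed + 1L, sample(N, n_flip))
    label[flip] <- ifelse(label[flip] == "active", "inactive", "active")
  }
  ds <- data.frame(compound_id = sprintf("FX%04d", seq_len(N)),
                   smiles_std = smiles, label = label,
                   true_label = true_label, stringsAsFactors = FALSE)
  attr(ds, "motif") <- spec$motif
  attr(ds, "class_counts") <- c(active = sum(label == "active"),
                                inactive = sum(label == "inactive"))
  attr(ds, "source_tag") <- "synthetic_family_fixture"
  ds
}

#' Generate a per-target activity-table fixture
#'
#' Builds one shared compound pool and, per target, samples motif-bearing
#' compounds as actives (`value_nM` log-uniform in `[10, 10^4]`) and
#' motif-free compounds as inactives (log-uniform in `(10^4, 10^6]`), all
#' with confidence 9. The per-target `inactive_ratio` is controlled so the
#' class-imbalance analysis can be exercised.
#'
#' @param n_targets number of targets.
#' @param n_active actives per target (scalar or vector).
#' @param inactive_ratio per-target ratio `n_inactive / n_active` (scalar
#'   or vector, recycled).
#' @param value_noise fraction of records (per target) whose value is
#'   re-drawn from the opposite activity range, emulating assay noise and
#'   imperfect structure-activity coupling; 0 gives perfectly separable
#'   targets.
#' @param seed integer seed.
#' @return list: `activities` (RawActivityRecord data.frame: `compound_id`,
#'   `smiles`, `target_id`, `activity_type`, `value_nM`, `confidence`) and
#'   `compounds` (the pooled compound table with a `has_motif` column).
#' @export
kp_generate_target_fixture <- function(n_targets = 20L, n_active = 120L,
                                       inactive_ratio = 1.0,
                                       value_noise = 0, seed = 42L) {
  stopifnot(value_noise >= 0, value_noise < 1)
  n_active <- rep_len(as.integer(n_active), n_targets)
  inactive_ratio <- rep_len(inactive_ratio, n_targets)
  n_inactive <- as.integer(round(inactive_ratio * n_active))
  need_act <- max(n_active); need_inact <- max(n_inactive)
  fx <- kp_generate_family_fixture(kp_fixture_spec(
    n_active = need_act, n_inactive = max(need_inact, 1L),
    label_noise = 0, seed = seed))
  pool_act <- fx$smiles_std[fx$true_label == "active"]
  pool_inact <- fx$smiles_std[fx$true_label == "inactive"]
  if (length(pool_inact) < need_inact)
    stop(sprintf("requested inactive_ratio needs %d decoys, pool has %d",
                 need_inact, length(pool_inact)))
  compounds <- data.frame(
    compound_id = sprintf("CP%04d", seq_along(c(pool_act, pool_inact))),
    smiles = c(pool_act, pool_inact),
    has_motif = rep(c(TRUE, FALSE), c(length(pool_act), length(pool_inact))),
    stringsAsFactors = FALSE)
  types <- c("IC50", "Ki", "Kd", "EC50")
  rows <- .kp_with_seed(seed + 7L, {
    do.call(rbind, lapply(seq_len(n_targets), function(t) {
      act <- sample(which(compounds$has_motif), n_active[t])
      ina <- if (n_inactive[t] > 0L)
        sample(which(!compounds$has_motif), n_inactive[t]) else integer(0)
      idx <- c(act, ina)
      val <- c(10^stats::runif(length(act), 1, 4),
               10^stats::runif(length(ina), 4.0001, 6))
      if (value_noise > 0) {
        n_flip <- round(value_noise * length(idx))
        if (n_flip > 0L) {
          flip <- sample(length(idx), n_flip)
          lo <- val[flip] <= 1e4
          val[flip][lo] <- 10^stats::runif(sum(lo), 4.0001, 6)
          val[flip][!lo] <- 10^stats::runif(sum(!lo), 1, 4)
        }
      }
      data.frame(compound_id = compounds$compound_id[idx],
                 smiles = compounds$smiles[idx],
                 target_id = sprintf("T%02d", t),
                 activity_type = sample(types, length(idx), replace = TRUE),
                 value_nM = val, confidence = 9L, stringsAsFactors = FALSE)
    }))
  })
  rownames(rows) <- NULL
  list(activities = rows, compounds = compounds)
}
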