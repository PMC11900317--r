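# Graph-level operations: fragment handling, molecular properties,
# charge standardization, substructure matching, SDF input.

.kp_subset_mol <- function(mol, atoms) {
  atoms <- sort(unique(atoms))
  map <- integer(mol$n); map[atoms] <- seq_along(atoms)
  keep_b <- mol$bonds$a1 %in% atoms & mol$bonds$a2 %in% atoms
  sub <- list(
    n = length(atoms),
    atoms = mol$atoms[atoms, , drop = FALSE],
    bonds = data.frame(a1 = map[mol$bonds$a1[keep_b]],
                       a2 = map[mol$bonds$a2[keep_b]],
                       order = mol$bonds$order[keep_b],
                       aromatic = mol$bonds$aromatic[keep_b],
                       any = mol$bonds$any[keep_b])
  )
  rownames(sub$atoms) <- NULL
  sub <- .kp_adjacency(sub)
  class(sub) <- "kp_mol"
  kp_perceive_aromaticity(sub)
}

#' Split a molecule into connected fragments
#' @param mol a `kp_mol`.
#' @return list of `kp_mol`, one per connected component.
#' @export
kp_fragments <- function(mol) {
  comp <- .kp_components(mol)
  lapply(seq_len(max(comp)), function(ci) .kp_subset_mol(mol, which(comp == ci)))
}

#' Heavy-atom count
#' @param mol a `kp_mol`.
#' @return integer: number of non-hydrogen atoms.
#' @export
kp_heavy_atoms <- function(mol) mol$n

#' Average molecular weight (Da), implicit hydrogens included
#' @param mol a `kp_mol`.
#' @return numeric scalar.
#' @export
kp_mol_weight <- function(mol) {
  sum(.kp_atomic_mass(mol$atoms$symbol)) + sum(mol$atoms$nH) * 1.008
}

#' Element counts including implicit hydrogens
#' @param mol a `kp_mol`.
#' @return named integer vector (element symbol -> count).
#' @export
kp_element_counts <- function(mol) {
  counts <- table(mol$atoms$symbol)
  out <- stats::setNames(as.integer(counts), names(counts))
  h <- sum(mol$atoms$nH)
  out["H"] <- (if ("H" %in% names(out)) out[["H"]] else 0L) + h
  out
}

# ---- charge standardization -------------------------------------------------

# Neutralize formal charges where a proton can be added/removed without a
# valence error; charge-separated groups bonded to an opposite charge
# (nitro, N-oxide) are left alone.
.kp_neutralize <- function(mol) {
  for (a in seq_len(mol$n)) {
    chg <- mol$atoms$charge[a]
    if (chg == 0L) next
    nbr_charges <- mol$atoms$charge[mol$adj[[a]]]
    if (chg < 0L) {
      if (any(nbr_charges > 0L)) next             # ylide/nitro-like
      mol$atoms$charge[a] <- chg + 1L
      mol$atoms$nH[a] <- mol$atoms$nH[a] + 1L
    } else {
      if (mol$atoms$nH[a] < 1L) next              # quaternary: keep
      if (any(nbr_charges < 0L)) next
      mol$atoms$charge[a] <- chg - 1L
      mol$atoms$nH[a] <- mol$atoms$nH[a] - 1L
    }
  }
  mol
}

# Fixed pH 7.4 re-ionization rule table:
#  * acidic O-H on C(=O)OH, S(=O)(=O)OH, P(=O)(OH)n -> O(-)  (all such OHs,
#    which keeps the outcome independent of the input atom order);
#  * aliphatic amines (sp3 N, no aromatic neighbor, not amide/amidine) and
#    the =N of amidines/guanidines -> N(+).
.kp_reionize <- function(mol) {
  dbl_to <- function(a, sym) {
    bids <- mol$badj[[a]]; nbrs <- mol$adj[[a]]
    nbrs[!is.na(mol$bonds$order[bids]) & mol$bonds$order[bids] == 2 &
         mol$atoms$symbol[nbrs] == sym]
  }
  # acidic hydroxyls
  for (a in seq_len(mol$n)) {
    if (mol$atoms$symbol[a] != "O" || mol$atoms$nH[a] < 1L ||
        mol$atoms$charge[a] != 0L || mol$atoms$aromatic[a]) next
    nbrs <- mol$adj[[a]]
    if (length(nbrs) != 1L) next
    x <- nbrs[1]; xs <- mol$atoms$symbol[x]
    acidic <- (xs == "C" && !mol$atoms$aromatic[x] && length(dbl_to(x, "O")) >= 1L) ||
              (xs == "S" && length(dbl_to(x, "O")) >= 2L) ||
              (xs == "P" && length(dbl_to(x, "O")) >= 1L)
    if (acidic) {
      mol$atoms$charge[a] <- -1L
      mol$atoms$nH[a] <- mol$atoms$nH[a] - 1L
    }
  }
  # basic nitrogens
  for (a in seq_len(mol$n)) {
    if (mol$atoms$symbol[a] != "N" || mol$atoms$charge[a] != 0L ||
        mol$atoms$aromatic[a]) next
    bids <- mol$badj[[a]]; nbrs <- mol$adj[[a]]
    orders <- mol$bonds$order[bids]
    if (any(mol$atoms$aromatic[nbrs])) next                     # anilines stay
    has_double_C <- any(!is.na(orders) & orders == 2 &
                        mol$atoms$symbol[nbrs] == "C")
    if (all(!is.na(orders) & orders == 1)) {
      # sp3 amine; skip amides/sulfonamides/amidine N-C(=X)
      bad_nbr <- vapply(nbrs, function(x) {
        xs <- mol$atoms$symbol[x]
        (xs %in% c("C", "S")) &&
          length(c(dbl_to(x, "O"), dbl_to(x, "S"), dbl_to(x, "N"))) >= 1L
      }, logical(1))
      if (any(bad_nbr)) next
      if (length(nbrs) > 3L) next
      mol$atoms$charge[a] <- 1L
      mol$atoms$nH[a] <- mol$atoms$nH[a] + 1L
    } else if (has_double_C) {
      # amidine/guanidine imine nitrogen: protonate if the doubly bonded C
      # carries another nitrogen
      cx <- nbrs[!is.na(orders) & orders == 2 & mol$atoms$symbol[nbrs] == "C"][1]
      other_n <- setdiff(mol$adj[[cx]], a)
      if (any(mol$atoms$symbol[other_n] == "N" & !mol$atoms$aromatic[other_n])) {
        mol$atoms$charge[a] <- 1L
        mol$atoms$nH[a] <- mol$atoms$nH[a] + 1L
      }
    }
  }
  mol
}

# ---- substructure matching --------------------------------------------------

#' Parse a substructure pattern
#'
#' Patterns use SMILES syntax plus the `~` any-bond query. Bracket pattern
#' atoms constrain charge (exactly) and hydrogen count (at least); bare
#' atoms constrain element and aromaticity only.
#'
#' @param smiles pattern string.
#' @return a `kp_mol` flagged as pattern.
#' @export
kp_parse_pattern <- function(smiles) {
  mol <- .kp_parse_graph(smiles, pattern = TRUE)
  # no implicit-H fill, no valence check: NA nH means unconstrained
  mol <- .kp_adjacency(mol)
  class(mol) <- "kp_mol"
  mol <- kp_perceive_aromaticity(mol)
  mol$is_pattern <- TRUE
  mol
}

.kp_atom_compatible <- function(pat, p, target, t) {
  if (pat$atoms$symbol[p] != target$atoms$symbol[t]) return(FALSE)
  if (pat$atoms$aromatic[p] != target$atoms$aromatic[t]) return(FALSE)
  if (pat$atoms$bracket[p]) {
    if (pat$atoms$charge[p] != target$atoms$charge[t]) return(FALSE)
    h <- pat$atoms$nH[p]
    if (!is.na(h) && h > 0L && target$atoms$nH[t] < h) return(FALSE)
  }
  TRUE
}

.kp_bond_compatible <- function(pat, pk, target, tk) {
  if (pat$bonds$any[pk]) return(TRUE)
  if (pat$bonds$aromatic[pk]) return(target$bonds$aromatic[tk])
  if (target$bonds$aromatic[tk]) return(FALSE)
  isTRUE(pat$bonds$order[pk] == target$bonds$order[tk])
}

#' Find substructure matches
#'
#' Backtracking subgraph isomorphism of a pattern into a target molecule.
#'
#' @param mol target `kp_mol`.
#' @param pattern a pattern (`kp_parse_pattern()` output or pattern string).
#' @param max_matches stop after this many matches.
#' @param unique_atoms if `TRUE`, keep one match per distinct matched atom
#'   set (collapses automorphic images of symmetric patterns).
#' @return list of integer vectors mapping pattern atom index -> target atom
#'   index; empty list if no match.
#' @export
kp_substructure_match <- function(mol, pattern, max_matches = Inf,
                                  unique_atoms = TRUE) {
  if (is.character(pattern)) pattern <- kp_parse_pattern(pattern)
  np <- pattern$n
  # DFS order over the pattern so each new atom (after the first) connects
  # to an already-mapped one
  order <- integer(0); seen <- logical(np)
  anchor <- vector("list", np)       # list of (prev atom idx, pattern bond)
  for (s in seq_len(np)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      order <- c(order, cur)
      nb <- pattern$adj[[cur]]
      for (x in nb[!seen[nb]]) { seen[x] <- TRUE; queue <- c(queue, x) }
    }
  }
  matches <- list(); seen_sets <- character(0)
  map <- integer(np)
  used <- logical(mol$n)

  check_bonds <- function(p, t) {
    nb <- pattern$adj[[p]]; bk <- pattern$badj[[p]]
    for (j in seq_along(nb)) {
      q <- nb[j]
      if (map[q] == 0L) next
      tt <- map[q]
      tb <- mol$badj[[t]][match(tt, mol$adj[[t]])]
      if (is.na(tb)) return(FALSE)
      if (!.kp_bond_compatible(pattern, bk[j], mol, tb)) return(FALSE)
    }
    TRUE
  }

  rec <- function(pos) {
    if (length(matches) >= max_matches) return()
    if (pos > np) {
      key <- paste(sort(map), collapse = ",")
      if (!unique_atoms || !key %in% seen_sets) {
        matches[[length(matches) + 1L]] <<- map
        seen_sets <- c(seen_sets, key)
        seen_sets <<- seen_sets
      }
      return()
    }
    p <- order[pos]
    for (t in seq_len(mol$n)) {
      if (used[t]) next
      if (!.kp_atom_compatible(pattern, p, mol, t)) next
      map[p] <<- t
      if (check_bonds(p, t)) {
        used[t] <<- TRUE
        rec(pos + 1L)
        used[t] <<- FALSE
      }
      map[p] <<- 0L
      if (length(matches) >= max_matches) return()
    }
  }
  rec(1L)
  matches
}

#' Test for a substructure
#' @inheritParams kp_substructure_match
#' @return logical scalar.
#' @export
kp_has_substructure <- function(mol, pattern) {
  length(kp_substructure_match(mol, pattern, max_matches = 1)) > 0L
}

# ---- SDF input --------------------------------------------------------------

#' Read molecules from an SDF (V2000) file
#'
#' Minimal MDL SD reader: atom block (element), bond block (order; type 4
#' taken as aromatic), `M  CHG` charge lines. Coordinates and other
#' properties are ignored.
#'
#' @param path file path.
#' @return data.frame with columns `compound_id` (molfile title or `MOL<i>`)
#'   and `smiles` (canonical SMILES of the parsed structure).
#' @export
kp_read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  breaks <- c(0L, which(trimws(lines) == "$$$$"))
  ids <- character(0); smiles <- character(0)
  for (i in seq_len(length(breaks) - 1L)) {
    block <- lines[(breaks[i] + 1L):(breaks[i + 1L] - 1L)]
    block <- block[cumsum(nzchar(trimws(block))) > 0L | nzchar(trimws(block))]
    if (length(block) < 4L) next
    title <- trimws(block[1])
    counts <- block[4]
    na <- as.integer(substr(counts, 1, 3)); nb <- as.integer(substr(counts, 4, 6))
    if (is.na(na) || is.na(nb)) next
    atom_lines <- block[5:(4L + na)]
    bond_lines <- if (nb > 0L) block[(5L + na):(4L + na + nb)] else character(0)
    symbol <- trimws(substr(atom_lines, 32, 34))
    mol <- list(
      n = na,
      atoms = data.frame(symbol = symbol, aromatic = FALSE, charge = 0L,
                         nH = NA_integer_, bracket = FALSE,
                         stringsAsFactors = FALSE),
      bonds = data.frame(
        a1 = as.integer(substr(bond_lines, 1, 3)),
        a2 = as.integer(substr(bond_lines, 4, 6)),
        order = as.numeric(substr(bond_lines, 7, 9)),
        aromatic = FALSE, any = FALSE)
    )
    arom4 <- !is.na(mol$bonds$order) & mol$bonds$order == 4
    if (any(arom4)) {
      mol$bonds$order[arom4] <- 1.5
      mol$bonds$aromatic[arom4] <- TRUE
      mol$atoms$aromatic[unique(c(mol$bonds$a1[arom4], mol$bonds$a2[arom4]))] <- TRUE
    }
    for (ln in grep("^M  CHG", block, value = TRUE)) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      nchg <- f[1]
      for (j in seq_len(nchg)) {
        mol$atoms$charge[f[2 * j]] <- f[2 * j + 1L]
      }
    }
    smi <- tryCatch({
      m <- .kp_finish_mol(mol, check_valence = TRUE)
      kp_canonical_smiles(kp_perceive_aromaticity(m))
    }, error = function(e) NA_character_)
    ids <- c(ids, if (nzchar(title)) title else paste0("MOL", i))
    smiles <- c(smiles, smi)
  }
  data.frame(compound_id = ids, smiles = smiles, stringsAsFactors = FALSE)
}
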