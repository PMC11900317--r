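# Canonical atom ranking and SMILES generation.
#
# Ranking is Morgan-style partition refinement over atom invariants
# (atomic number, heavy degree, hydrogen count, charge, aromaticity, ring
# membership) followed by individualization of the first tied cell, choosing
# the candidate whose refined partition has the lexicographically smallest
# index-free signature. Atoms left tied by identical signatures are treated
# as symmetry-equivalent, which holds for drug-like graphs.

.kp_bond_code <- function(bonds, k) {
  if (bonds$aromatic[k]) "a" else as.character(bonds$order[k])
}

# One refinement step: new key = old rank + sorted (bond, neighbor rank)
# multiset. Cells only ever split, so the partition is stable once the
# number of distinct ranks stops growing.
.kp_refine_ranks <- function(mol, ranks) {
  bond_codes <- vapply(seq_len(nrow(mol$bonds)), function(k)
    .kp_bond_code(mol$bonds, k), character(1))
  repeat {
    keys <- vapply(seq_len(mol$n), function(a) {
      nb <- mol$adj[[a]]; bk <- mol$badj[[a]]
      nbr_keys <- if (length(nb))
        sort(paste0(bond_codes[bk], ":", formatC(ranks[nb], width = 5, flag = "0")))
      else character(0)
      paste(formatC(ranks[a], width = 5, flag = "0"),
            paste(nbr_keys, collapse = "|"))
    }, character(1))
    new_ranks <- match(keys, sort(unique(keys)))
    if (length(unique(new_ranks)) == length(unique(ranks))) return(new_ranks)
    ranks <- new_ranks
  }
}

# Index-free signature of a partition: sorted multiset of per-atom
# (rank | sorted neighbor bond:rank) keys.
.kp_partition_signature <- function(mol, ranks) {
  bond_codes <- vapply(seq_len(nrow(mol$bonds)), function(k)
    .kp_bond_code(mol$bonds, k), character(1))
  keys <- vapply(seq_len(mol$n), function(a) {
    nb <- mol$adj[[a]]; bk <- mol$badj[[a]]
    nbr_keys <- if (length(nb))
      sort(paste0(bond_codes[bk], ":", formatC(ranks[nb], width = 5, flag = "0")))
    else character(0)
    paste(formatC(ranks[a], width = 5, flag = "0"),
          paste(nbr_keys, collapse = "|"))
  }, character(1))
  paste(sort(keys), collapse = ";")
}

#' Canonical atom ranks
#'
#' @param mol a `kp_mol`.
#' @return integer vector of distinct ranks in `1:n`, invariant to the atom
#'   order of the input SMILES.
#' @export
kp_canonical_ranks <- function(mol) {
  if (is.null(mol$in_ring)) mol <- kp_perceive_aromaticity(mol)
  inv0 <- paste(
    formatC(.kp_atomic_number(mol$atoms$symbol), width = 3, flag = "0"),
    lengths(mol$adj), mol$atoms$nH, mol$atoms$charge + 10L,
    as.integer(mol$atoms$aromatic), as.integer(mol$in_ring)
  )
  ranks <- match(inv0, sort(unique(inv0)))
  ranks <- .kp_refine_ranks(mol, ranks)
  guard <- 0L
  while (length(unique(ranks)) < mol$n) {
    guard <- guard + 1L
    if (guard > mol$n + 1L) stop("canonical ranking failed to converge")
    tied_vals <- sort(unique(ranks[duplicated(ranks)]))
    cell_val <- tied_vals[1]
    cell <- which(ranks == cell_val)
    sigs <- vapply(cell, function(a) {
      r <- ranks * 2L; r[a] <- r[a] - 1L
      .kp_partition_signature(mol, .kp_refine_ranks(mol, r))
    }, character(1))
    pick <- cell[order(sigs)[1]]
    r <- ranks * 2L; r[pick] <- r[pick] - 1L
    ranks <- .kp_refine_ranks(mol, r)
  }
  ranks
}

# Implicit hydrogen count an organic-subset atom would get from its bonds;
# used to decide whether a bracket is required when writing SMILES.
.kp_default_nH <- function(mol, a) {
  sym <- mol$atoms$symbol[a]
  if (!sym %in% .kp_organic_subset) return(NA_integer_)
  bids <- mol$badj[[a]]
  bsum <- if (length(bids)) {
    o <- mol$bonds$order[bids]; o[is.na(o)] <- 1
    ceiling(sum(o) - 1e-9)
  } else 0
  vals <- .kp_allowed_valences(sym, 0L)
  fit <- vals[vals >= bsum]
  if (length(fit)) as.integer(fit[1] - bsum) else 0L
}

.kp_atom_token <- function(mol, a) {
  sym <- mol$atoms$symbol[a]
  arom <- mol$atoms$aromatic[a]
  chg <- mol$atoms$charge[a]
  nH <- mol$atoms$nH[a]
  base <- if (arom) tolower(sym) else sym
  plain <- sym %in% .kp_organic_subset && chg == 0L &&
    identical(nH, .kp_default_nH(mol, a))
  if (plain) return(base)
  h <- if (nH == 0L) "" else if (nH == 1L) "H" else paste0("H", nH)
  c_tok <- if (chg == 0L) "" else {
    s <- if (chg > 0L) "+" else "-"
    if (abs(chg) == 1L) s else paste0(s, abs(chg))
  }
  paste0("[", base, h, c_tok, "]")
}

.kp_bond_token <- function(mol, k, a_from, a_to) {
  if (mol$bonds$aromatic[k]) {
    # omitted between two aromatic atoms
    if (mol$atoms$aromatic[a_from] && mol$atoms$aromatic[a_to]) return("")
    return(":")
  }
  o <- mol$bonds$order[k]
  if (is.na(o)) return("~")
  if (o == 2) return("=")
  if (o == 3) return("#")
  # explicit single between two aromatic atoms (biphenyl)
  if (mol$atoms$aromatic[a_from] && mol$atoms$aromatic[a_to]) return("-")
  ""
}

# Write one connected component as SMILES following the given atom priority
# (lower value visited first).  Neighbors are processed sequentially: a
# neighbor already visited at its turn is a ring closure (opened from
# whichever side saw the other first); closure digits are monotonically
# numbered, never reused, and attached directly after the atom token.
.kp_write_component <- function(mol, root, priority) {
  visited <- logical(mol$n)
  ring_num <- 0L
  ring_open <- list()          # bond index (as character) -> number

  order_nbrs <- function(a, exclude_bond) {
    nb <- mol$adj[[a]]; bk <- mol$badj[[a]]
    keep <- if (is.na(exclude_bond)) seq_along(nb) else which(bk != exclude_bond)
    nb <- nb[keep]; bk <- bk[keep]
    ord <- order(priority[nb])
    list(atoms = nb[ord], bonds = bk[ord])
  }

  rec <- function(a, from_bond) {
    visited[a] <<- TRUE
    nbrs <- order_nbrs(a, from_bond)
    closures <- character(0)
    branches <- character(0)
    for (j in seq_along(nbrs$atoms)) {
      b <- nbrs$atoms[j]; k <- nbrs$bonds[j]
      key <- as.character(k)
      if (visited[b]) {
        if (!is.null(ring_open[[key]])) {
          closures <- c(closures, .kp_ring_digit(ring_open[[key]]))
          ring_open[[key]] <<- NULL
        } else {
          ring_num <<- ring_num + 1L
          ring_open[[key]] <<- ring_num
          closures <- c(closures,
                        paste0(.kp_bond_token(mol, k, a, b),
                               .kp_ring_digit(ring_num)))
        }
      } else {
        sub <- rec(b, k)
        branches <- c(branches, paste0(.kp_bond_token(mol, k, a, b), sub))
      }
    }
    body <- if (length(branches)) {
      nb <- length(branches)
      paste0(paste0(vapply(branches[-nb], function(s) paste0("(", s, ")"),
                           character(1)), collapse = ""),
             branches[nb])
    } else ""
    paste0(.kp_atom_token(mol, a), paste(closures, collapse = ""), body)
  }
  rec(root, NA_integer_)
}

.kp_ring_digit <- function(num) {
  if (num < 10L) as.character(num) else paste0("%", formatC(num, width = 2, flag = "0"))
}

.kp_components <- function(mol) {
  comp <- rep(NA_integer_, mol$n); cid <- 0L
  for (s in seq_len(mol$n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L; comp[s] <- cid; queue <- s
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in mol$adj[[cur]]) {
        if (is.na(comp[nb])) { comp[nb] <- cid; queue <- c(queue, nb) }
      }
    }
  }
  comp
}

#' Canonical SMILES of a molecule
#'
#' Deterministic, atom-order-independent SMILES string: canonical ranks
#' drive the DFS, aromatic rings are written in lowercase form, and
#' fragments are joined with `.` ordered by their canonical strings.
#'
#' @param mol a `kp_mol` (aromaticity-perceived; [kp_parse_smiles()] output).
#' @return character scalar.
#' @examples
#' kp_canonical_smiles(kp_parse_smiles("C1=CC=CC=C1"))  # same as "c1ccccc1"
#' @export
kp_canonical_smiles <- function(mol) {
  if (is.null(mol$in_ring)) mol <- kp_perceive_aromaticity(mol)
  ranks <- kp_canonical_ranks(mol)
  comp <- .kp_components(mol)
  parts <- vapply(seq_len(max(comp)), function(ci) {
    atoms <- which(comp == ci)
    root <- atoms[which.min(ranks[atoms])]
    .kp_write_component(mol, root, ranks)
  }, character(1))
  paste(sort(parts), collapse = ".")
}

#' Random SMILES spelling of a molecule
#'
#' Writes the same molecular graph with a random DFS (random root, random
#' neighbor order). Used to test atom-order invariance of canonicalization
#' and fingerprints.
#'
#' @param mol a `kp_mol`.
#' @return character scalar; parses back to the same molecule.
#' @export
kp_random_smiles <- function(mol) {
  if (is.null(mol$in_ring)) mol <- kp_perceive_aromaticity(mol)
  priority <- sample(mol$n)
  comp <- .kp_components(mol)
  parts <- vapply(seq_len(max(comp)), function(ci) {
    atoms <- which(comp == ci)
    root <- sample(atoms, 1)
    .kp_write_component(mol, root, priority)
  }, character(1))
  paste(parts, collapse = ".")
}
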