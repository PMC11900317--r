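# Molecular fingerprints with bit -> atom provenance.
#
# Three kinds:
#   morgan           - hashed circular atom environments, radius 0..2,
#                      folded to 2048 bits
#   path_subgraph    - hashed connected bond subgraphs (1..7 bonds),
#                      folded to 2048 bits
#   substructure_keys- fixed 881-key dictionary (element counts, ring
#                      census, bonded atom pairs, substructure patterns)
#
# Every set bit records the atom set of each environment / subgraph / match
# that fired it, which downstream Shapley retro-mapping redistributes onto
# atoms. Count-type keys (element counts) carry no atom provenance and are
# excluded from retro-mapping.

.KP_HASH_MOD <- 2147483647

# Deterministic 31-bit polynomial hash of an integer vector (exact in
# doubles: intermediate products stay far below 2^53).
.kp_hash31 <- function(ints) {
  h <- 5381
  for (x in ints) h <- (h * 33 + as.numeric(x) + 1) %% .KP_HASH_MOD
  h
}

.kp_bond_code_int <- function(bonds, k) {
  if (bonds$aromatic[k]) 15L else as.integer(round(bonds$order[k] * 10))
}

.kp_atom_invariants <- function(mol) {
  vapply(seq_len(mol$n), function(a) .kp_hash31(c(
    .kp_atomic_number(mol$atoms$symbol[a]),
    length(mol$adj[[a]]),
    mol$atoms$nH[a],
    mol$atoms$charge[a] + 10L,
    as.integer(mol$atoms$aromatic[a]),
    as.integer(mol$in_ring[a])
  )), numeric(1))
}

.kp_new_fp <- function(kind, nbits, n_atoms = NA_integer_) {
  structure(list(kind = kind, nbits = nbits, n_atoms = n_atoms,
                 bits = integer(nbits), bit_atoms = list()),
            class = "kp_fingerprint")
}

.kp_fp_add <- function(fp, bit, atoms, meta = NULL) {
  fp$bits[bit] <- 1L
  key <- as.character(bit)
  entry <- c(list(atoms = as.integer(atoms)), meta)
  fp$bit_atoms[[key]] <- c(fp$bit_atoms[[key]], list(entry))
  fp
}

#' @export
print.kp_fingerprint <- function(x, ...) {
  cat(sprintf("<kp_fingerprint %s: %d/%d bits set>\n",
              x$kind, sum(x$bits), x$nbits))
  invisible(x)
}

# Identifier of the circular environment of `center` at `radius`,
# recomputable in isolation (used as the provenance-soundness oracle).
#' Hash of one circular atom environment
#'
#' Recomputes the Morgan environment identifier of `center` at `radius`
#' from scratch; `kp_morgan_fp()` sets bit `id %% nbits + 1` for it.
#'
#' @param mol a `kp_mol`.
#' @param center atom index.
#' @param radius environment radius (bonds).
#' @return numeric identifier in `[0, 2^31)`.
#' @export
kp_morgan_env_hash <- function(mol, center, radius) {
  if (is.null(mol$in_ring)) mol <- kp_perceive_aromaticity(mol)
  inv <- .kp_atom_invariants(mol)
  if (radius == 0L) return(inv[center])
  for (r in seq_len(radius)) {
    inv_new <- inv
    for (a in seq_len(mol$n)) {
      nb <- mol$adj[[a]]; bk <- mol$badj[[a]]
      if (!length(nb)) next
      codes <- vapply(bk, function(k) .kp_bond_code_int(mol$bonds, k), integer(1))
      ord <- order(codes, inv[nb])
      inv_new[a] <- .kp_hash31(c(r, inv[a], rbind(codes[ord], inv[nb][ord])))
    }
    inv <- inv_new
  }
  inv[center]
}

#' Morgan (circular) fingerprint
#'
#' Hashed circular environments of every atom at radius `0..radius`,
#' folded to `nbits`. Atom invariants: atomic number, heavy degree,
#' hydrogen count, formal charge, aromaticity, ring membership (no
#' chirality; binary bits). Each set bit's provenance lists, per firing
#' environment, the atoms within the environment radius of its center.
#'
#' @param mol a `kp_mol` or SMILES string.
#' @param radius maximum environment radius in bonds (default 2).
#' @param nbits folded length (default 2048).
#' @return a `kp_fingerprint`.
#' @examples
#' fp <- kp_morgan_fp("c1ccccc1O")
#' sum(fp$bits)
#' @export
kp_morgan_fp <- function(mol, radius = 2L, nbits = 2048L) {
  if (is.character(mol)) mol <- kp_parse_smiles(mol)
  if (mol$n < 1L) stop("empty molecule")
  if (is.null(mol$in_ring)) mol <- kp_perceive_aromaticity(mol)
  fp <- .kp_new_fp("morgan", nbits, mol$n)
  inv <- .kp_atom_invariants(mol)
  dist <- lapply(seq_len(mol$n), function(a) .kp_bfs_dist(mol, a, radius))
  for (r in 0:radius) {
    if (r > 0L) {
      inv_new <- inv
      for (a in seq_len(mol$n)) {
        nb <- mol$adj[[a]]; bk <- mol$badj[[a]]
        if (!length(nb)) next
        codes <- vapply(bk, function(k) .kp_bond_code_int(mol$bonds, k), integer(1))
        ord <- order(codes, inv[nb])
        inv_new[a] <- .kp_hash31(c(r, inv[a], rbind(codes[ord], inv[nb][ord])))
      }
      inv <- inv_new
    }
    for (a in seq_len(mol$n)) {
      bit <- (inv[a] %% nbits) + 1L
      atoms <- which(!is.na(dist[[a]]) & dist[[a]] <= r)
      fp <- .kp_fp_add(fp, bit, atoms,
                       meta = list(center = a, radius = r, id = inv[a]))
    }
  }
  fp
}

# All connected bond subgraphs with min_size..max_size bonds, as lists of
# bond-index vectors. Classic restricted-growth enumeration: subgraphs
# containing bond b never include a bond with smaller index.
.kp_bond_subgraphs <- function(mol, min_size, max_size) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(list())
  # bond adjacency (bonds sharing an atom)
  bond_nbrs <- lapply(seq_len(nb), function(k) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    setdiff(unique(c(mol$badj[[a]], mol$badj[[b]])), k)
  })
  out <- list()
  emit <- function(S) if (length(S) >= min_size) out[[length(out) + 1L]] <<- S
  rec <- function(S, ext, base) {
    emit(S)
    if (length(S) >= max_size) return()
    while (length(ext)) {
      e <- ext[1]; ext <- ext[-1]
      new_ext <- c(ext, Filter(function(x) x > base &&
                                 !x %in% S && !x %in% ext,
                               bond_nbrs[[e]]))
      rec(c(S, e), new_ext, base)
    }
  }
  for (b in seq_len(nb)) {
    ext <- Filter(function(x) x > b, bond_nbrs[[b]])
    rec(b, ext, b)
  }
  out
}

# Order-invariant hash of the subgraph spanned by a bond set.
#' Hash of one bond subgraph
#'
#' Recomputes the path/subgraph fingerprint identifier of a bond set
#' (atom element/aromaticity codes, bond codes with endpoint elements,
#' internal degree sequence); `kp_path_fp()` sets bit `id %% nbits + 1`.
#'
#' @param mol a `kp_mol`.
#' @param bond_ids bond indices forming a connected subgraph.
#' @return numeric identifier in `[0, 2^31)`.
#' @export
kp_subgraph_hash <- function(mol, bond_ids) {
  atoms <- sort(unique(c(mol$bonds$a1[bond_ids], mol$bonds$a2[bond_ids])))
  acode <- sort(vapply(atoms, function(a)
    .kp_atomic_number(mol$atoms$symbol[a]) * 2 +
      as.integer(mol$atoms$aromatic[a]), numeric(1)))
  bcode <- sort(vapply(bond_ids, function(k) {
    e <- sort(c(.kp_atomic_number(mol$atoms$symbol[mol$bonds$a1[k]]),
                .kp_atomic_number(mol$atoms$symbol[mol$bonds$a2[k]])))
    .kp_bond_code_int(mol$bonds, k) * 10000 + e[1] * 100 + e[2]
  }, numeric(1)))
  deg <- sort(tabulate(match(c(mol$bonds$a1[bond_ids], mol$bonds$a2[bond_ids]),
                             atoms), nbins = length(atoms)))
  .kp_hash31(c(length(bond_ids), acode, 0L, bcode, 0L, deg))
}

#' Path/subgraph fingerprint
#'
#' Enumerates every connected bond subgraph within a size range, hashes
#' each by an order-invariant code, and folds into `nbits`. Provenance
#' records the atom (and bond) set of each contributing subgraph.
#'
#' @param mol a `kp_mol` or SMILES string.
#' @param nbits folded length (default 2048).
#' @param min_size,max_size subgraph size range in bonds (defaults 1 and 7).
#' @return a `kp_fingerprint`.
#' @export
kp_path_fp <- function(mol, nbits = 2048L, min_size = 1L, max_size = 7L) {
  if (is.character(mol)) mol <- kp_parse_smiles(mol)
  if (mol$n < 1L) stop("empty molecule")
  if (is.null(mol$in_ring)) mol <- kp_perceive_aromaticity(mol)
  fp <- .kp_new_fp("path_subgraph", nbits, mol$n)
  for (S in .kp_bond_subgraphs(mol, min_size, max_size)) {
    id <- kp_subgraph_hash(mol, S)
    bit <- (id %% nbits) + 1L
    atoms <- unique(c(mol$bonds$a1[S], mol$bonds$a2[S]))
    fp <- .kp_fp_add(fp, bit, atoms, meta = list(bonds = as.integer(S), id = id))
  }
  fp
}

#' Substructure-key fingerprint definition table
#'
#' The 881-slot key dictionary evaluated by [kp_keys881_fp()]. Slots
#' 1-115: hierarchic element counts (count-type, no atom provenance);
#' 116-263: ring census (size 3-10 by aromaticity/heteroatom content and
#' multiplicity); 264-328: bonded element pairs; 329 onward: substructure
#' patterns in the package's pattern syntax. Slots without a definition
#' are reserved and always zero (the published CACTVS table cannot be
#' redistributed; the layout here is package-defined with the same
#' sectioning and length).
#'
#' @return data.frame with columns `bit`, `type`, `spec`.
#' @export
kp_keys881_table <- function() .kp_keys881_def()

.kp_keys881_def <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    defs <- list()
    add <- function(type, spec) defs[[length(defs) + 1L]] <<- list(type = type, spec = spec)
    # section 1: element counts (55 defined of 115)
    ecounts <- list(
      H = c(4, 8, 16, 32), Li = c(1, 2), B = c(1, 2, 4), C = c(2, 4, 8, 16, 32),
      N = c(1, 2, 4, 8), O = c(1, 2, 4, 8, 16), F = c(1, 2, 4), Na = c(1, 2),
      Si = c(1, 2), P = c(1, 2, 4), S = c(1, 2, 4, 8), Cl = c(1, 2, 4, 8),
      K = c(1, 2), Br = c(1, 2, 4), I = c(1, 2, 4), Zn = 1, Ca = 1, Fe = 1,
      As = 1, Se = 1, Mg = 1)
    for (el in names(ecounts)) for (th in ecounts[[el]])
      add("element_count", paste0(el, ">=", th))
    while (length(defs) < 115L) add("reserved", NA_character_)
    # section 2: ring census
    for (size in 3:10) {
      for (prop in c("any", "any2", "aromatic", "aromatic2", "saturated_carbon",
                     "nitrogen", "heteroatom")) add("ring", paste0(size, ":", prop))
    }   # 8 x 7 = 56
    add("ring", "total>=1"); add("ring", "total>=2"); add("ring", "total>=3")
    add("ring", "total>=4"); add("ring", "aromatic_total>=1")
    add("ring", "aromatic_total>=2"); add("ring", "aromatic_total>=3")
    add("ring", "aromatic_total>=4")
    while (length(defs) < 263L) add("reserved", NA_character_)
    # section 3: bonded element pairs (single/any bond between elements)
    pairs <- c("C-C", "C-N", "C-O", "C-S", "C-F", "C-Cl", "C-Br", "C-I",
               "C-P", "C-B", "C-Si", "C-Se", "N-N", "N-O", "N-S", "N-P",
               "O-O", "O-S", "O-P", "S-S", "C=C", "C=N", "C=O", "C=S",
               "N=N", "N=O", "S=O", "P=O", "C#C", "C#N",
               "c:c", "c:n", "n:n", "c:o", "c:s")
    for (p in pairs) add("atom_pair", p)
    while (length(defs) < 328L) add("reserved", NA_character_)
    # section 4+: substructure patterns (package pattern syntax)
    pats <- c(
      # oxygen functions
      "C=O", "CC(=O)C", "C(=O)O", "C(=O)OC", "C(=O)N", "NC(=O)N", "NC(=O)O",
      "OCO", "COC", "CCO", "OC(=O)C(=O)O", "CC(=O)Cl",
      # nitrogen functions
      "C#N", "N=O", "[N+](=O)[O-]", "NN", "C=NN", "NC=N", "NC(=N)N", "N=C=O",
      "CNC", "CN(C)C", "CCN", "c1ccccc1N", "C=N",
      # sulfur / phosphorus
      "CS", "CSC", "S=O", "O=S=O", "NS(=O)=O", "OS(=O)=O", "C=S", "SS",
      "OP(=O)O", "P(=O)(O)O",
      # halogens on carbon frameworks
      "ClC(Cl)Cl", "FC(F)F", "Clc1ccccc1", "Fc1ccccc1", "Brc1ccccc1",
      "Ic1ccccc1", "ClCC", "FCC", "BrCC",
      # carbon skeletons
      "CCCC", "CCCCC", "CCCCCC", "CC(C)C", "CC(C)(C)C", "C=CC", "C=CC=C",
      "C#CC", "CC=O", "C1CC1", "C1CCC1", "C1CCCC1", "C1CCCCC1", "C1CCCCCC1",
      # aromatics & heteroaromatics
      "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "Oc1ccccc1", "COc1ccccc1",
      "Nc1ccccc1", "c1ccccc1-c1ccccc1", "Cc1ccccc1C", "Cc1ccc(C)cc1",
      "c1ccc2ccccc2c1", "c1ccncc1", "c1ccnnc1", "c1cncnc1",
      "c1cc[nH]c1", "c1ccoc1", "c1ccsc1", "c1cnc[nH]1", "c1cn[nH]c1",
      "c1ocnc1", "c1scnc1",
      "c1ccc2[nH]ccc2c1", "c1ccc2occc2c1", "c1ccc2sccc2c1",
      "c1ccc2ncccc12", "c1ccc2[nH]ccc2n1",
      # mixed / linker motifs
      "c1ccccc1C=O", "c1ccccc1C(=O)O", "c1ccccc1C(=O)N", "c1ccccc1OC",
      "c1ccccc1CN", "c1ccccc1CC=O", "c1ccccc1S", "c1ccccc1CO",
      "O=C1CCCCC1", "O=C1CCCC1", "N1CCOCC1", "C1CCNCC1", "N1CCNCC1",
      "C1CCOC1", "O1CCOCC1", "C1CCSC1",
      "NCC(=O)O", "NC(C)C(=O)O", "OCC(O)CO", "OCCO", "OCCN", "NCCN",
      "ClCCCl", "CC(O)C", "CC(N)C", "C(F)(F)F"
    )
    for (p in pats) add("pattern", p)
    while (length(defs) < 881L) add("reserved", NA_character_)
    cache <<- data.frame(
      bit = seq_along(defs),
      type = vapply(defs, `[[`, "", "type"),
      spec = vapply(defs, `[[`, "", "spec"),
      stringsAsFactors = FALSE)
    cache
  }
})

# compiled pattern cache for the key table
.kp_keys881_patterns <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tab <- .kp_keys881_def()
      idx <- which(tab$type == "pattern")
      cache <<- stats::setNames(lapply(tab$spec[idx], kp_parse_pattern),
                                as.character(tab$bit[idx]))
    }
    cache
  }
})

.kp_ring_props <- function(mol, ring) {
  syms <- mol$atoms$symbol[ring]
  arom <- all(mol$atoms$aromatic[ring])
  list(
    aromatic = arom,
    saturated_carbon = all(syms == "C") && !arom &&
      all(vapply(ring, function(a) {
        bids <- mol$badj[[a]]
        all(mol$bonds$order[bids][mol$adj[[a]] %in% ring] == 1)
      }, logical(1))),
    nitrogen = any(syms == "N"),
    heteroatom = any(syms != "C")
  )
}

#' 881-key substructure fingerprint
#'
#' Evaluates the fixed key dictionary from [kp_keys881_table()]. Pattern,
#' ring and atom-pair keys carry atom provenance; element-count keys do
#' not and are skipped by atom retro-mapping.
#'
#' @param mol a `kp_mol` or SMILES string.
#' @return a `kp_fingerprint` of length 881.
#' @export
kp_keys881_fp <- function(mol) {
  if (is.character(mol)) mol <- kp_parse_smiles(mol)
  if (mol$n < 1L) stop("empty molecule")
  if (is.null(mol$in_ring)) mol <- kp_perceive_aromaticity(mol)
  fp <- .kp_new_fp("substructure_keys", 881L, mol$n)
  tab <- .kp_keys881_def()
  counts <- kp_element_counts(mol)
  rings <- mol$rings
  ring_props <- lapply(rings, function(r) .kp_ring_props(mol, r))
  pats <- .kp_keys881_patterns()

  for (i in seq_len(nrow(tab))) {
    type <- tab$type[i]; spec <- tab$spec[i]; bit <- tab$bit[i]
    if (type == "element_count") {
      f <- strsplit(spec, ">=", fixed = TRUE)[[1]]
      cnt <- if (f[1] %in% names(counts)) counts[[f[1]]] else 0L
      if (cnt >= as.integer(f[2])) fp$bits[bit] <- 1L
    } else if (type == "ring") {
      if (grepl("^total>=", spec)) {
        if (length(rings) >= as.integer(sub("total>=", "", spec)))
          fp$bits[bit] <- 1L
      } else if (grepl("^aromatic_total>=", spec)) {
        if (sum(vapply(ring_props, `[[`, logical(1), "aromatic")) >=
            as.integer(sub("aromatic_total>=", "", spec))) fp$bits[bit] <- 1L
      } else {
        f <- strsplit(spec, ":", fixed = TRUE)[[1]]
        size <- as.integer(f[1]); prop <- f[2]
        need2 <- prop %in% c("any2", "aromatic2")
        base_prop <- sub("2$", "", prop)
        hit <- which(vapply(seq_along(rings), function(j) {
          length(rings[[j]]) == size &&
            (base_prop == "any" || isTRUE(ring_props[[j]][[base_prop]]))
        }, logical(1)))
        if (length(hit) >= (if (need2) 2L else 1L)) {
          for (j in hit) fp <- .kp_fp_add(fp, bit, rings[[j]])
        }
      }
    } else if (type == "atom_pair") {
      el1 <- sub("^([A-Za-z]+).*", "\\1", spec)
      bsym <- sub(paste0("^", el1), "", spec)
      el2 <- substring(bsym, 2)
      bch <- substr(bsym, 1, 1)
      want_arom <- bch == ":"
      want_order <- switch(bch, "-" = 1, "=" = 2, "#" = 3, NA)
      s1 <- if (want_arom) toupper(substr(el1, 1, 1)) else el1
      s2 <- if (want_arom) toupper(substr(el2, 1, 1)) else el2
      for (k in seq_len(nrow(mol$bonds))) {
        if (want_arom != mol$bonds$aromatic[k]) next
        if (!want_arom && mol$bonds$order[k] != want_order) next
        a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
        syms <- c(mol$atoms$symbol[a], mol$atoms$symbol[b])
        aroms <- c(mol$atoms$aromatic[a], mol$atoms$aromatic[b])
        if (want_arom && !all(aroms)) next
        if (!want_arom && any(aroms)) next   # uppercase spec = aliphatic atoms
        if ((syms[1] == s1 && syms[2] == s2) || (syms[1] == s2 && syms[2] == s1))
          fp <- .kp_fp_add(fp, bit, c(a, b))
      }
    } else if (type == "pattern") {
      ms <- kp_substructure_match(mol, pats[[as.character(bit)]])
      for (m in ms) fp <- .kp_fp_add(fp, bit, m)
    }
  }
  fp
}

#' Compute a fingerprint of a given kind
#'
#' @param mol a `kp_mol` or SMILES string.
#' @param kind one of `"morgan"`, `"path_subgraph"`, `"substructure_keys"`
#'   (aliases: `"path"`, `"keys881"`).
#' @param ... passed to the specific fingerprint function.
#' @return a `kp_fingerprint`.
#' @export
kp_fingerprint <- function(mol, kind = c("morgan", "path_subgraph",
                                         "substructure_keys", "path", "keys881"),
                           ...) {
  kind <- match.arg(kind)
  switch(kind,
         morgan = kp_morgan_fp(mol, ...),
         path = , path_subgraph = kp_path_fp(mol, ...),
         keys881 = , substructure_keys = kp_keys881_fp(mol, ...))
}

.kp_fp_length <- function(kind) {
  if (kind %in% c("substructure_keys", "keys881")) 881L else 2048L
}

#' Featurize a labeled dataset into a binary matrix
#'
#' @param dataset data.frame with columns `compound_id`, `smiles_std` (a
#'   curated dataset; see [kp_build_family_dataset()]).
#' @param kind fingerprint kind (see [kp_fingerprint()]).
#' @param ... passed to the fingerprint function.
#' @return numeric 0/1 matrix, one row per compound in dataset order, with
#'   `compound_id` rownames and attribute `kind`.
#' @export
kp_featurize_dataset <- function(dataset, kind = "morgan", ...) {
  stopifnot(is.data.frame(dataset), all(c("compound_id", "smiles_std") %in%
                                          names(dataset)))
  if (any(is.na(dataset$smiles_std))) {
    bad <- dataset$compound_id[is.na(dataset$smiles_std)][1]
    stop("dataset contains a record without a standardized structure: ", bad)
  }
  kind <- match.arg(kind, c("morgan", "path_subgraph", "substructure_keys",
                            "path", "keys881"))
  L <- .kp_fp_length(kind)
  X <- matrix(0, nrow(dataset), L)
  for (i in seq_len(nrow(dataset))) {
    fp <- tryCatch(kp_fingerprint(dataset$smiles_std[i], kind, ...),
                   error = function(e) stop("featurization failed for ",
                                            dataset$compound_id[i], ": ",
                                            conditionMessage(e)))
    X[i, ] <- fp$bits
  }
  rownames(X) <- dataset$compound_id
  attr(X, "kind") <- if (kind == "path") "path_subgraph"
                     else if (kind == "keys881") "substructure_keys" else kind
  X
}

#' Tanimoto similarity between two bit vectors
#' @param a,b binary vectors of equal length (or `kp_fingerprint`s).
#' @return similarity in `[0, 1]`; 1 when both are empty.
#' @export
kp_tanimoto <- function(a, b) {
  if (inherits(a, "kp_fingerprint")) a <- a$bits
  if (inherits(b, "kp_fingerprint")) b <- b$bits
  inter <- sum(a & b); uni <- sum(a | b)
  if (uni == 0) 1 else inter / uni
}
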