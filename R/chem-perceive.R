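# Ring perception and aromaticity.
#
# Rings are found as the smallest cycle through every ring bond (BFS on the
# graph with that bond removed), which recovers the SSSR-like ring set for
# fused drug-like systems. Aromaticity uses a pragmatic Hueckel rule on
# 5- and 6-membered rings evaluated on the Kekule bond orders:
#   * an atom with a double bond to another ring atom contributes 1 pi
#     electron;
#   * a heteroatom (N, O, S, Se, P) or anionic carbon with no double bond
#     contributes its lone pair (2);
#   * anything else (sp3 carbon, carbonyl carbon whose double bond points
#     out of the ring system) disqualifies the ring.
# A ring is aromatic when the contributions sum to 6. This covers benzene,
# pyridine, pyrrole/furan/thiophene, (aza)indoles, imidazoles and fused
# benzo systems; exocyclic-tautomer aromatics (2-pyridone) stay Kekule,
# a documented limitation.

.kp_ring_bonds <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(logical(0))
  out <- logical(nb)
  for (k in seq_len(nb)) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    # BFS from a to b without bond k
    seen <- logical(mol$n); seen[a] <- TRUE; queue <- a
    found <- FALSE
    while (length(queue) && !found) {
      cur <- queue[1]; queue <- queue[-1]
      nbrs <- mol$adj[[cur]]; bids <- mol$badj[[cur]]
      for (j in seq_along(nbrs)) {
        if (bids[j] == k || seen[nbrs[j]]) next
        if (nbrs[j] == b) { found <- TRUE; break }
        seen[nbrs[j]] <- TRUE; queue <- c(queue, nbrs[j])
      }
    }
    out[k] <- found
  }
  out
}

# Smallest cycle (as atom index vector) through bond k, or NULL.
.kp_smallest_cycle_through <- function(mol, k) {
  a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
  prev <- rep(NA_integer_, mol$n)
  seen <- logical(mol$n); seen[a] <- TRUE; queue <- a
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    if (cur == b) break
    nbrs <- mol$adj[[cur]]; bids <- mol$badj[[cur]]
    for (j in seq_along(nbrs)) {
      if (bids[j] == k || seen[nbrs[j]]) next
      seen[nbrs[j]] <- TRUE; prev[nbrs[j]] <- cur
      queue <- c(queue, nbrs[j])
    }
  }
  if (!seen[b]) return(NULL)
  path <- b
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  path                                    # a ... b; bond k closes the cycle
}

#' Ring systems of a molecule
#'
#' @param mol a `kp_mol`.
#' @return list of integer vectors, each one ring (atom indices); the
#'   smallest ring through each ring bond, deduplicated.
#' @export
kp_rings <- function(mol) {
  rb <- which(.kp_ring_bonds(mol))
  rings <- list(); keys <- character(0)
  for (k in rb) {
    cyc <- .kp_smallest_cycle_through(mol, k)
    if (is.null(cyc)) next
    key <- paste(sort(cyc), collapse = ",")
    if (!key %in% keys) { rings[[length(rings) + 1L]] <- cyc; keys <- c(keys, key) }
  }
  rings
}

#' Perceive aromatic rings on a Kekule-form graph
#'
#' Marks qualifying 5/6-membered rings (and their atoms/bonds) aromatic so
#' that Kekule and aromatic SMILES spellings of a molecule canonicalize
#' identically. Also annotates ring membership (`mol$in_ring`,
#' `mol$ring_bond`) and caches the ring list in `mol$rings`.
#'
#' @param mol a `kp_mol`.
#' @return the annotated `kp_mol`.
#' @export
kp_perceive_aromaticity <- function(mol) {
  ring_bond <- .kp_ring_bonds(mol)
  mol$ring_bond <- ring_bond
  in_ring <- logical(mol$n)
  if (any(ring_bond)) {
    in_ring[unique(c(mol$bonds$a1[ring_bond], mol$bonds$a2[ring_bond]))] <- TRUE
  }
  mol$in_ring <- in_ring
  rings <- kp_rings(mol)
  mol$rings <- rings
  if (!length(rings)) return(mol)

  has_double_to_ring <- vapply(seq_len(mol$n), function(a) {
    nbrs <- mol$adj[[a]]; bids <- mol$badj[[a]]
    any(!is.na(mol$bonds$order[bids]) & mol$bonds$order[bids] == 2 &
        in_ring[nbrs])
  }, logical(1))

  aromatic_rings <- Filter(function(ring) {
    size <- length(ring)
    if (!size %in% c(5L, 6L)) return(FALSE)
    total <- 0L
    for (a in ring) {
      sym <- mol$atoms$symbol[a]
      if (has_double_to_ring[a] || mol$atoms$aromatic[a]) {
        total <- total + 1L
      } else if (sym %in% c("N", "O", "S", "Se", "P") ||
                 (sym == "C" && mol$atoms$charge[a] == -1L)) {
        total <- total + 2L
      } else {
        return(FALSE)
      }
    }
    total == 6L
  }, rings)

  if (length(aromatic_rings)) {
    arom_atoms <- unique(unlist(aromatic_rings))
    mol$atoms$aromatic[arom_atoms] <- TRUE
    for (ring in aromatic_rings) {
      for (i in seq_along(ring)) {
        a <- ring[i]; b <- ring[if (i == length(ring)) 1L else i + 1L]
        hit <- which((mol$bonds$a1 == a & mol$bonds$a2 == b) |
                     (mol$bonds$a1 == b & mol$bonds$a2 == a))
        if (length(hit)) {
          mol$bonds$aromatic[hit] <- TRUE
          mol$bonds$order[hit] <- 1.5
        }
      }
    }
  }
  mol
}

# Graph distances from one atom (BFS), used for Morgan environments.
.kp_bfs_dist <- function(mol, from, max_dist = Inf) {
  d <- rep(NA_integer_, mol$n); d[from] <- 0L; queue <- from
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    if (d[cur] >= max_dist) next
    for (nb in mol$adj[[cur]]) {
      if (is.na(d[nb])) { d[nb] <- d[cur] + 1L; queue <- c(queue, nb) }
    }
  }
  d
}
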