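# SMILES reader producing the package's molecular graph ("kp_mol").
#
# Supported syntax: organic-subset and bracket atoms, aromatic lowercase
# forms, bond symbols - = # : ~ (~ is a query bond used only in patterns),
# branches, ring closures (digits and %nn), and '.'-separated fragments.
# Stereo markers (/ \ @ @@) and isotope labels are parsed and dropped: the
# pipeline standardizes to constitution-level canonical form.
#
# Parse failures signal a classed condition:
#   kp_parse_error   - malformed string (unclosed ring/branch, bad token)
#   kp_valence_error - graph parsed but an atom exceeds its allowed valence

.kp_parse_error <- function(msg) {
  stop(structure(class = c("kp_parse_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.kp_valence_error <- function(msg) {
  stop(structure(class = c("kp_valence_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# Tokenize + build the atom/bond tables.  Returns an unfinished mol; callers
# go through kp_parse_smiles() which adds hydrogens and checks valence.
.kp_parse_graph <- function(smiles, pattern = FALSE) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    .kp_parse_error("empty or non-scalar SMILES")
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)

  atom_symbol <- character(0); atom_arom <- logical(0)
  atom_charge <- integer(0); atom_nH <- integer(0)   # NA = implicit
  atom_bracket <- logical(0)
  bond_a1 <- integer(0); bond_a2 <- integer(0)
  bond_order <- numeric(0); bond_arom <- logical(0); bond_any <- logical(0)

  prev <- NA_integer_
  stack <- integer(0)
  pending <- NULL               # pending bond symbol
  rings <- list()               # ring-closure bookkeeping

  add_atom <- function(symbol, aromatic, charge, nH, bracket = FALSE) {
    atom_symbol[length(atom_symbol) + 1L] <<- symbol
    atom_arom[length(atom_arom) + 1L] <<- aromatic
    atom_charge[length(atom_charge) + 1L] <<- charge
    atom_nH[length(atom_nH) + 1L] <<- nH
    atom_bracket[length(atom_bracket) + 1L] <<- bracket
    length(atom_symbol)
  }
  add_bond <- function(a1, a2, sym) {
    if (is.na(a1)) return(invisible())
    ord <- 1; arom <- FALSE; any <- FALSE
    if (is.null(sym)) {
      if (atom_arom[a1] && atom_arom[a2]) { arom <- TRUE; ord <- 1.5 }
    } else if (sym == "-") {
    } else if (sym == "=") ord <- 2
    else if (sym == "#") ord <- 3
    else if (sym == ":") { arom <- TRUE; ord <- 1.5 }
    else if (sym == "~") {
      if (!pattern) .kp_parse_error("'~' bond only allowed in patterns")
      any <- TRUE; ord <- NA_real_
    } else .kp_parse_error(paste0("bad bond symbol '", sym, "'"))
    bond_a1[length(bond_a1) + 1L] <<- a1
    bond_a2[length(bond_a2) + 1L] <<- a2
    bond_order[length(bond_order) + 1L] <<- ord
    bond_arom[length(bond_arom) + 1L] <<- arom
    bond_any[length(bond_any) + 1L] <<- any
    invisible()
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (is.na(prev)) .kp_parse_error("branch before any atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) .kp_parse_error("unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "~")) {
      pending <- ch; i <- i + 1L
    } else if (ch %in% c("/", "\\")) {
      i <- i + 1L                       # stereo bond -> plain single
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- NULL; i <- i + 1L
    } else if (grepl("[0-9%]", ch)) {
      if (is.na(prev)) .kp_parse_error("ring closure before any atom")
      if (ch == "%") {
        if (i + 2L > n || !grepl("^[0-9]{2}", paste0(chars[i + 1L], chars[i + 2L])))
          .kp_parse_error("bad %nn ring closure")
        key <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else { key <- ch; i <- i + 1L }
      if (is.null(rings[[key]])) {
        rings[[key]] <- list(atom = prev, bond = pending)
      } else {
        op <- rings[[key]]
        sym <- if (!is.null(pending)) pending else op$bond
        if (op$atom == prev) .kp_parse_error("self ring closure")
        add_bond(op$atom, prev, sym)
        rings[[key]] <- NULL
      }
      pending <- NULL
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) .kp_parse_error("unclosed bracket atom")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)(se|si|[A-Z][a-z]?|as|[bcnops])(@{0,2})(H([0-9]*))?((\\+{1,3}|-{1,3})([0-9]*)?)?(:[0-9]+)?$",
        body))[[1]]
      if (!length(m)) .kp_parse_error(paste0("bad bracket atom [", body, "]"))
      raw_sym <- m[3]
      aromatic <- raw_sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
      symbol <- if (aromatic) {
        paste0(toupper(substr(raw_sym, 1, 1)), substring(raw_sym, 2))
      } else raw_sym
      if (!symbol %in% rownames(.kp_elements))
        .kp_parse_error(paste0("unknown element '", symbol, "'"))
      if (aromatic && !symbol %in% c(.kp_aromatic_ok, "As"))
        .kp_parse_error(paste0("element '", symbol, "' cannot be aromatic"))
      nH <- if (is.na(m[5]) || m[5] == "") 0L
            else if (m[6] == "") 1L else as.integer(m[6])
      charge <- 0L
      if (!is.na(m[7]) && nzchar(m[7])) {
        sign <- if (substr(m[8], 1, 1) == "+") 1L else -1L
        mag <- if (!is.na(m[9]) && nzchar(m[9])) as.integer(m[9])
               else nchar(m[8])
        charge <- sign * mag
      }
      a <- add_atom(symbol, aromatic, charge, nH, bracket = TRUE)
      add_bond(prev, a, pending); pending <- NULL; prev <- a
      i <- j + 1L
    } else {
      # organic subset (one or two letters), aromatic lowercase
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) { symbol <- two; aromatic <- FALSE; i <- i + 2L }
      else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        symbol <- ch; aromatic <- FALSE; i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        symbol <- toupper(ch); aromatic <- TRUE; i <- i + 1L
      } else {
        .kp_parse_error(paste0("unexpected character '", ch, "' at ", i))
      }
      a <- add_atom(symbol, aromatic, 0L, NA_integer_)
      add_bond(prev, a, pending); pending <- NULL; prev <- a
    }
  }
  if (length(stack)) .kp_parse_error("unclosed branch")
  if (length(rings)) .kp_parse_error("unclosed ring bond")
  if (!length(atom_symbol)) .kp_parse_error("no atoms")

  list(
    n = length(atom_symbol),
    atoms = data.frame(symbol = atom_symbol, aromatic = atom_arom,
                       charge = atom_charge, nH = atom_nH,
                       bracket = atom_bracket, stringsAsFactors = FALSE),
    bonds = data.frame(a1 = bond_a1, a2 = bond_a2, order = bond_order,
                       aromatic = bond_arom, any = bond_any)
  )
}

# Neighbor lists (atom index and parallel bond index).
.kp_adjacency <- function(mol) {
  adj <- vector("list", mol$n)
  badj <- vector("list", mol$n)
  for (k in seq_len(nrow(mol$bonds))) {
    a1 <- mol$bonds$a1[k]; a2 <- mol$bonds$a2[k]
    adj[[a1]] <- c(adj[[a1]], a2); badj[[a1]] <- c(badj[[a1]], k)
    adj[[a2]] <- c(adj[[a2]], a1); badj[[a2]] <- c(badj[[a2]], k)
  }
  mol$adj <- adj; mol$badj <- badj
  mol
}

# Sum of bond orders at each atom; aromatic bonds count 1.5 and the total is
# rounded up (benzene carbon: 2 x 1.5 -> 3).
.kp_bond_order_sum <- function(mol) {
  s <- numeric(mol$n)
  for (k in seq_len(nrow(mol$bonds))) {
    o <- mol$bonds$order[k]
    if (is.na(o)) o <- 1
    s[mol$bonds$a1[k]] <- s[mol$bonds$a1[k]] + o
    s[mol$bonds$a2[k]] <- s[mol$bonds$a2[k]] + o
  }
  ceiling(s - 1e-9)
}

# Fill implicit hydrogens for organic-subset atoms and check valences.
.kp_finish_mol <- function(mol, check_valence = TRUE) {
  bsum <- .kp_bond_order_sum(mol)
  for (a in seq_len(mol$n)) {
    sym <- mol$atoms$symbol[a]
    if (is.na(mol$atoms$nH[a])) {
      vals <- .kp_allowed_valences(sym, mol$atoms$charge[a])
      fit <- vals[vals >= bsum[a]]
      mol$atoms$nH[a] <- if (length(fit)) as.integer(fit[1] - bsum[a]) else 0L
    }
  }
  if (check_valence) {
    # sigma-counting for the check: aromatic bonds count 1, so bracket
    # aromatic atoms donating a lone pair (pyrrole [nH]) pass
    o <- mol$bonds$order; o[is.na(o)] <- 1; o[mol$bonds$aromatic] <- 1
    bsig <- numeric(mol$n)
    for (k in seq_len(nrow(mol$bonds))) {
      bsig[mol$bonds$a1[k]] <- bsig[mol$bonds$a1[k]] + o[k]
      bsig[mol$bonds$a2[k]] <- bsig[mol$bonds$a2[k]] + o[k]
    }
    for (a in seq_len(mol$n)) {
      sym <- mol$atoms$symbol[a]
      vals <- .kp_allowed_valences(sym, mol$atoms$charge[a])
      if (!length(vals)) next          # exotic element: no valence model
      eff <- (if (mol$atoms$aromatic[a]) bsig[a] else bsum[a]) + mol$atoms$nH[a]
      if (eff > max(vals)) {
        .kp_valence_error(sprintf(
          "atom %d (%s, charge %+d) has valence %d > max %d",
          a, sym, mol$atoms$charge[a], eff, max(vals)))
      }
    }
  }
  mol <- .kp_adjacency(mol)
  class(mol) <- "kp_mol"
  mol
}

#' Parse a SMILES string into a molecular graph
#'
#' Builds the package's internal molecular graph: atom table (element,
#' aromatic flag, formal charge, hydrogen count), bond table, and adjacency
#' lists. Aromaticity of Kekule-form input is perceived from ring analysis
#' so that `c1ccccc1` and `C1=CC=CC=C1` yield the same graph.
#'
#' @param smiles SMILES string.
#' @param perceive if `TRUE` (default), run ring/aromaticity perception.
#' @return An object of class `kp_mol`.
#' @examples
#' m <- kp_parse_smiles("c1ccccc1O")
#' m$n
#' @export
kp_parse_smiles <- function(smiles, perceive = TRUE) {
  mol <- .kp_parse_graph(smiles, pattern = FALSE)
  mol <- .kp_finish_mol(mol, check_valence = TRUE)
  if (perceive) mol <- kp_perceive_aromaticity(mol)
  mol
}

#' @export
print.kp_mol <- function(x, ...) {
  cat(sprintf("<kp_mol: %d atoms, %d bonds> %s\n", x$n, nrow(x$bonds),
              tryCatch(kp_canonical_smiles(x), error = function(e) "")))
  invisible(x)
}
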