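# Kernel SHAP over fingerprint bits and retro-mapping onto atoms.
#
# Only the bits set in the query molecule are treated as explainable
# features; unset bits take the background's values in every synthetic
# coalition. base_value is the mean model output over the background and
# model_output the mean output with every set bit present, so the Shapley
# local-accuracy identity base + sum(phi) = model_output holds exactly (it
# is enforced as the constraint of the weighted regression). When the
# coalition space is small enough to enumerate with full background
# averaging, the estimates are the exact Shapley values.

#' Kernel SHAP attribution over fingerprint bits
#'
#' @param model a fitted `kp_model`, or a function `X -> probability`.
#' @param fingerprint `kp_fingerprint` of the query molecule.
#' @param background feature matrix of background compounds (same length
#'   as the fingerprint).
#' @param n_samples coalition budget; default `2 * M + 2048` for `M` set
#'   bits. When `2^M - 2 <= n_samples` all coalitions are enumerated.
#' @param seed integer seed (coalition sampling and background pairing).
#' @param max_background_evals model-evaluation budget; it sets how many
#'   background rows each coalition's expectation is averaged over
#'   (the full background when it fits, default budget 50000).
#' @return object of class `kp_bit_attribution`: `phi` (full fingerprint
#'   length; zero outside the set bits), `base_value`, `model_output`,
#'   `point_output` (model on the query fingerprint itself), `set_bits`.
#' @export
kp_kernel_shap <- function(model, fingerprint, background, n_samples = NULL,
                           seed = 1L, max_background_evals = 50000) {
  stopifnot(inherits(fingerprint, "kp_fingerprint"))
  if (is.null(dim(background)) || nrow(background) == 0L)
    stop("background must be a non-empty matrix")
  L <- fingerprint$nbits
  if (ncol(background) != L) stop("background width does not match fingerprint")
  x <- fingerprint$bits
  S <- which(x == 1L)
  M <- length(S)
  phi <- numeric(L)
  base_value <- mean(kp_predict_proba(model, background))
  point_output <- as.numeric(kp_predict_proba(model, matrix(as.numeric(x), 1)))
  if (M == 0L) {
    return(structure(list(phi = phi, base_value = base_value,
                          model_output = base_value,
                          point_output = point_output,
                          set_bits = integer(0)),
                     class = "kp_bit_attribution"))
  }
  if (is.null(n_samples)) n_samples <- 2L * M + 2048L
  B <- nrow(background)

  full_on <- background
  full_on[, S] <- 1
  model_output <- mean(kp_predict_proba(model, full_on))
  if (M == 1L) {
    phi[S] <- model_output - base_value
    return(structure(list(phi = phi, base_value = base_value,
                          model_output = model_output,
                          point_output = point_output, set_bits = S),
                     class = "kp_bit_attribution"))
  }

  # coalition matrix over the M set bits (TRUE = present)
  Z <- .kp_with_seed(seed, {
    if (2^M - 2 <= n_samples) {
      zz <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), M)))
      sz <- rowSums(zz)
      zz[sz > 0 & sz < M, , drop = FALSE]
    } else {
      rows <- list()
      budget <- n_samples
      # enumerate complete size shells from the outside in while they fit
      s <- 1L
      while (s <= floor((M - 1) / 2)) {
        shell <- choose(M, s) * (if (s != M - s) 2 else 1)
        if (shell > budget - length(rows)) break
        cmb <- utils::combn(M, s)
        for (ci in seq_len(ncol(cmb))) {
          z1 <- logical(M); z1[cmb[, ci]] <- TRUE
          rows[[length(rows) + 1L]] <- z1
          if (s != M - s) rows[[length(rows) + 1L]] <- !z1
        }
        s <- s + 1L
      }
      # random tail, sampled by the SHAP kernel's size distribution
      sizes <- s:(M - s)
      if (length(rows) < budget && length(sizes)) {
        pk <- (M - 1) / (sizes * (M - sizes))
        pk <- pk / sum(pk)
        extra <- budget - length(rows)
        draw_sizes <- sample(sizes, extra, replace = TRUE, prob = pk)
        for (ds in draw_sizes) {
          z1 <- logical(M); z1[sample.int(M, ds)] <- TRUE
          rows[[length(rows) + 1L]] <- z1
        }
      }
      do.call(rbind, rows)
    }
  })
  ncoal <- nrow(Z)
  sz <- rowSums(Z)
  w <- (M - 1) / (choose(M, sz) * sz * (M - sz))

  # model expectation per coalition, averaged over k background rows
  # (k = full background when the evaluation budget allows, otherwise a
  # seeded subsample per pass)
  k_bg <- max(1L, min(B, floor(max_background_evals / ncoal)))
  fvals <- .kp_with_seed(seed + 1L, {
    acc <- numeric(ncoal)
    if (k_bg == B) {
      for (b in seq_len(B)) {
        H <- matrix(rep(background[b, ], each = ncoal), ncoal, L)
        H[, S][Z] <- 1
        acc <- acc + kp_predict_proba(model, H)
      }
    } else {
      for (j in seq_len(k_bg)) {
        bg_pick <- sample.int(B, ncoal, replace = TRUE)
        H <- background[bg_pick, , drop = FALSE]
        Hs <- H[, S, drop = FALSE]
        Hs[Z] <- 1
        H[, S] <- Hs
        acc <- acc + kp_predict_proba(model, H)
      }
    }
    acc / k_bg
  })

  # weighted least squares with the local-accuracy equality constraint:
  # phi_M is eliminated via sum(phi) = model_output - base_value
  gap <- model_output - base_value
  Zn <- matrix(as.numeric(Z), ncoal, M)
  A <- Zn[, -M, drop = FALSE] - Zn[, M]
  yv <- fvals - base_value - Zn[, M] * gap
  WA <- A * w
  XtX <- crossprod(WA, A)
  diag(XtX) <- diag(XtX) + 1e-10
  beta <- solve(XtX, crossprod(WA, yv))
  phi_s <- c(beta, gap - sum(beta))
  phi[S] <- phi_s
  structure(list(phi = phi, base_value = base_value,
                 model_output = model_output, point_output = point_output,
                 set_bits = S),
            class = "kp_bit_attribution")
}

#' @export
print.kp_bit_attribution <- function(x, ...) {
  cat(sprintf("<kp_bit_attribution: %d set bits | base %.4f -> output %.4f>\n",
              length(x$set_bits), x$base_value, x$model_output))
  invisible(x)
}

#' Retro-map bit attributions onto atoms
#'
#' Each set bit's Shapley value is split equally across its provenance
#' occurrences and, within an occurrence, equally across its atoms; an
#' atom's weight is the sum over all bits. Bits without atom provenance
#' (count-type substructure keys) are skipped; their total attribution is
#' reported in `skipped_phi`. Conservation: `sum(atom_weights)` equals the
#' summed phi of all retro-mapped bits.
#'
#' @param attribution a `kp_bit_attribution`.
#' @param fingerprint the `kp_fingerprint` it was computed for.
#' @param normalization `"raw"` (default) or `"max_abs"` (weights scaled
#'   into `[-1, 1]`).
#' @return object of class `kp_atom_attribution`: `atom_weights` (one per
#'   heavy atom), `normalization`, `skipped_phi`, `mapped_phi`.
#' @export
kp_retro_map <- function(attribution, fingerprint,
                         normalization = c("raw", "max_abs")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(attribution, "kp_bit_attribution"),
            inherits(fingerprint, "kp_fingerprint"))
  if (length(attribution$phi) != fingerprint$nbits)
    stop("attribution and fingerprint lengths differ")
  w <- numeric(fingerprint$n_atoms)
  skipped <- 0; mapped <- 0
  for (bit in attribution$set_bits) {
    phi_b <- attribution$phi[bit]
    entries <- fingerprint$bit_atoms[[as.character(bit)]]
    entries <- Filter(function(e) length(e$atoms) > 0L, entries)
    if (!length(entries)) { skipped <- skipped + phi_b; next }
    mapped <- mapped + phi_b
    share_occ <- phi_b / length(entries)
    for (e in entries) w[e$atoms] <- w[e$atoms] + share_occ / length(e$atoms)
  }
  raw <- w
  if (normalization == "max_abs") {
    mx <- max(abs(w))
    if (mx > 0) w <- w / mx
  }
  structure(list(atom_weights = w, raw_weights = raw,
                 normalization = normalization, skipped_phi = skipped,
                 mapped_phi = mapped, source = attribution),
            class = "kp_atom_attribution")
}

# Simple deterministic 2-D spring layout (no plotting dependency).
.kp_layout_2d <- function(mol, iterations = 400L) {
  n <- mol$n
  theta <- 2 * pi * (seq_len(n) - 1) / n
  pos <- cbind(cos(theta), sin(theta)) * sqrt(n)
  if (n == 1L) return(matrix(0, 1, 2))
  edges <- cbind(mol$bonds$a1, mol$bonds$a2)
  for (it in seq_len(iterations)) {
    step <- 0.08 * (1 - it / (iterations + 1))
    disp <- matrix(0, n, 2)
    # repulsion
    for (a in seq_len(n)) {
      d <- sweep(pos, 2, pos[a, ])
      dist2 <- pmax(rowSums(d^2), 1e-4)
      rep_f <- sweep(d, 1, dist2, `/`)
      disp[a, ] <- disp[a, ] - colSums(rep_f) * 0.8
    }
    # springs (ideal length 1)
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      d <- pos[b, ] - pos[a, ]
      len <- sqrt(sum(d^2)) + 1e-9
      f <- (len - 1) * d / len
      disp[a, ] <- disp[a, ] + f
      disp[b, ] <- disp[b, ] - f
    }
    pos <- pos + step * disp
  }
  pos
}

#' Render an atom attribution as an SVG depiction
#'
#' Writes a 2-D depiction with per-atom circles shaded orange in
#' proportion to positive normalized weight (negative weights shade
#' blue), plus a per-atom CSV next to it.
#'
#' @param mol the molecule (`kp_mol` or SMILES).
#' @param atoms a `kp_atom_attribution`.
#' @param path output SVG path; the CSV is written with extension `.csv`.
#' @return invisibly, the paths written.
#' @export
kp_render_attribution <- function(mol, atoms, path) {
  if (is.character(mol)) mol <- kp_parse_smiles(mol)
  stopifnot(inherits(atoms, "kp_atom_attribution"))
  w <- atoms$atom_weights
  if (length(w) != mol$n) stop("attribution does not match molecule size")
  mx <- max(abs(w))
  wn <- if (mx > 0) w / mx else w
  pos <- .kp_layout_2d(mol)
  # scale into a viewbox
  rng <- apply(pos, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-6)
  sc <- 360 / max(span)
  xy <- sweep(sweep(pos, 2, rng[1, ]), 2, c(sc, sc), `*`) + 40
  svg <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
    440L, 440L), "<rect width='100%' height='100%' fill='white'/>")
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    wd <- if (!mol$bonds$aromatic[k] && mol$bonds$order[k] >= 2) 3.5 else 1.5
    dash <- if (mol$bonds$aromatic[k]) " stroke-dasharray='6,2'" else ""
    svg <- c(svg, sprintf(
      "<line x1='%.1f' y1='%.1f' x2='%.1f' y2='%.1f' stroke='black' stroke-width='%.1f'%s/>",
      xy[a, 1], xy[a, 2], xy[b, 1], xy[b, 2], wd, dash))
  }
  for (a in seq_len(mol$n)) {
    v <- wn[a]
    fill <- if (v > 0) sprintf("rgba(255,140,0,%.3f)", min(1, v))
            else if (v < 0) sprintf("rgba(30,100,255,%.3f)", min(1, -v))
            else "none"
    if (fill != "none")
      svg <- c(svg, sprintf("<circle cx='%.1f' cy='%.1f' r='13' fill='%s'/>",
                            xy[a, 1], xy[a, 2], fill))
    svg <- c(svg, sprintf(
      "<text x='%.1f' y='%.1f' font-size='11' text-anchor='middle' dy='4'>%s</text>",
      xy[a, 1], xy[a, 2], mol$atoms$symbol[a]))
  }
  svg <- c(svg, "</svg>")
  ok <- tryCatch({ writeLines(svg, path); TRUE },
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e)))
  csv_path <- sub("\\.svg$", ".csv", path)
  if (identical(csv_path, path)) csv_path <- paste0(path, ".csv")
  utils::write.csv(data.frame(atom = seq_len(mol$n),
                              element = mol$atoms$symbol,
                              weight = atoms$atom_weights,
                              normalized = wn),
                   csv_path, row.names = FALSE)
  invisible(c(svg = path, csv = csv_path))
}
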