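# Classifiers over binary fingerprint features: random forest, Gaussian
# naive Bayes and a multi-layer perceptron, with MCC-scored grid search,
# repeated stratified hold-out cross-validation and external validation.
# All three are implemented in vectorised base R (no compiled ML
# dependency is available offline); training is deterministic under the
# spec seed.

# ---- model spec -------------------------------------------------------------

#' Model specification
#'
#' @param algorithm `"random_forest"`, `"gaussian_nb"` or `"mlp"`.
#' @param fingerprint_kind fingerprint kind the model consumes.
#' @param hyperparams named list; see [kp_hyperparameter_grid()] for the
#'   tunable keys per algorithm.
#' @param seed integer seed controlling fit-time randomness.
#' @return object of class `kp_model_spec`.
#' @export
kp_model_spec <- function(algorithm = c("random_forest", "gaussian_nb", "mlp"),
                          fingerprint_kind = "morgan",
                          hyperparams = list(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    random_forest = list(n_estimators = 100L, max_features = "sqrt",
                         class_weight = "none"),
    gaussian_nb = list(var_smoothing = 1e-9),
    mlp = list(hidden_layer_sizes = c(100L), max_epochs = 200L,
               batch_size = 32L, learning_rate = 1e-3,
               validation_fraction = 0.1, patience = 10L))
  bad <- setdiff(names(hyperparams), names(defaults))
  if (length(bad)) stop("unknown hyperparameters for ", algorithm, ": ",
                        paste(bad, collapse = ", "))
  hp <- utils::modifyList(defaults, hyperparams)
  structure(list(algorithm = algorithm, fingerprint_kind = fingerprint_kind,
                 hyperparams = hp, seed = as.integer(seed)),
            class = "kp_model_spec")
}

#' @export
print.kp_model_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparams),
              vapply(x$hyperparams, function(v) paste(v, collapse = "x"), ""),
              sep = "=", collapse = ", ")
  cat(sprintf("<kp_model_spec %s / %s | %s | seed %d>\n",
              x$algorithm, x$fingerprint_kind, hp, x$seed))
  invisible(x)
}

#' Hyperparameter grid per algorithm
#'
#' Random forest: `n_estimators` in \{100, 500\} by `max_features` in
#' \{sqrt, all, log2\} (6 points). Gaussian NB: `var_smoothing` in
#' \{1e-9, 1e-8, 1e-7, 1e-6\}. MLP: hidden architectures over \{100, 200,
#' 1000\} neurons with 1 or 2 layers (all width combinations; 12 points).
#' Grid order is canonical: ties in grid search resolve to the first row.
#'
#' @param algorithm algorithm name.
#' @return list of hyperparameter lists, in canonical order.
#' @export
kp_hyperparameter_grid <- function(algorithm = c("random_forest",
                                                 "gaussian_nb", "mlp")) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    random_forest = {
      g <- expand.grid(n_estimators = c(100L, 500L),
                       max_features = c("sqrt", "all", "log2"),
                       stringsAsFactors = FALSE)
      lapply(seq_len(nrow(g)), function(i)
        list(n_estimators = g$n_estimators[i], max_features = g$max_features[i]))
    },
    gaussian_nb = lapply(c(1e-9, 1e-8, 1e-7, 1e-6),
                         function(v) list(var_smoothing = v)),
    mlp = {
      widths <- c(100L, 200L, 1000L)
      c(lapply(widths, function(w) list(hidden_layer_sizes = w)),
        unlist(lapply(widths, function(w1) lapply(widths, function(w2)
          list(hidden_layer_sizes = c(w1, w2)))), recursive = FALSE))
    })
}

# ---- random forest ----------------------------------------------------------

.kp_mtry <- function(max_features, p) {
  switch(max_features,
         sqrt = max(1L, floor(sqrt(p))),
         log2 = max(1L, floor(log2(p))),
         all = p,
         stop("unknown max_features: ", max_features))
}

# Grow one CART-style tree on binary features; returns flat node arrays.
.kp_grow_tree <- function(X, y, w, mtry, max_depth = 30L) {
  feat <- integer(0); left <- integer(0); right <- integer(0)
  prob <- numeric(0)
  new_node <- function() {
    feat[length(feat) + 1L] <<- NA_integer_
    left[length(left) + 1L] <<- 0L; right[length(right) + 1L] <<- 0L
    prob[length(prob) + 1L] <<- NA_real_
    length(feat)
  }
  p <- ncol(X)
  build <- function(idx, depth) {
    node <- new_node()
    W <- sum(w[idx]); POS <- sum(w[idx] * y[idx])
    prob[node] <<- POS / W
    if (POS == 0 || POS == W || depth >= max_depth || length(idx) < 2L)
      return(node)
    S <- if (mtry >= p) seq_len(p) else sample.int(p, mtry)
    Xs <- X[idx, S, drop = FALSE]
    w1 <- as.vector(crossprod(Xs, w[idx]))
    p1 <- as.vector(crossprod(Xs, w[idx] * y[idx]))
    w0 <- W - w1; p0 <- POS - p1
    ok <- w0 > 0 & w1 > 0
    if (!any(ok)) return(node)
    gini <- function(wt, pos) {
      q <- pos / wt
      wt * (1 - q^2 - (1 - q)^2)
    }
    score <- ifelse(ok, gini(w0, p0) + gini(w1, p1), Inf)
    parent <- gini(W, POS)
    best <- which.min(score)
    if (score[best] >= parent - 1e-12) return(node)
    f <- S[best]
    feat[node] <<- f
    go_right <- X[idx, f] == 1
    left[node] <<- build(idx[!go_right], depth + 1L)
    right[node] <<- build(idx[go_right], depth + 1L)
    node
  }
  root <- build(seq_len(nrow(X)), 0L)
  list(feat = feat, left = left, right = right, prob = prob, root = root)
}

.kp_tree_predict <- function(tree, X) {
  n <- nrow(X)
  out <- numeric(n)
  stack <- list(list(node = tree$root, rows = seq_len(n)))
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    node <- top$node; rows <- top$rows
    if (!length(rows)) next
    f <- tree$feat[node]
    if (is.na(f)) { out[rows] <- tree$prob[node]; next }
    go_right <- X[rows, f] == 1
    stack <- c(stack, list(list(node = tree$left[node], rows = rows[!go_right]),
                           list(node = tree$right[node], rows = rows[go_right])))
  }
  out
}

.kp_fit_rf <- function(X, y, hp, seed) {
  n <- nrow(X)
  mtry <- .kp_mtry(hp$max_features, ncol(X))
  w_class <- if (identical(hp$class_weight, "balanced")) {
    n / (2 * c(`0` = sum(y == 0), `1` = sum(y == 1)))
  } else c(`0` = 1, `1` = 1)
  trees <- .kp_with_seed(seed, {
    lapply(seq_len(hp$n_estimators), function(t) {
      idx <- sample.int(n, n, replace = TRUE)
      .kp_grow_tree(X[idx, , drop = FALSE], y[idx],
                    w_class[as.character(y[idx])], mtry)
    })
  })
  list(trees = trees)
}

.kp_predict_rf <- function(fit, X) {
  pred <- vapply(fit$trees, function(tr) .kp_tree_predict(tr, X),
                 numeric(nrow(X)))
  if (is.null(dim(pred))) pred <- matrix(pred, nrow = nrow(X))
  rowMeans(pred)
}

# ---- Gaussian naive Bayes ---------------------------------------------------

.kp_fit_gnb <- function(X, y, hp) {
  classes <- c(0, 1)
  stats_by <- lapply(classes, function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    mu <- colMeans(Xc)
    va <- colMeans(Xc^2) - mu^2
    list(mu = mu, va = va, prior = nrow(Xc) / nrow(X))
  })
  eps <- hp$var_smoothing * max(vapply(stats_by, function(s) max(s$va), 0), 1e-12)
  for (i in seq_along(stats_by)) stats_by[[i]]$va <- stats_by[[i]]$va + eps
  list(stats = stats_by)
}

.kp_predict_gnb <- function(fit, X) {
  ll <- vapply(fit$stats, function(s) {
    # sum of log N(x; mu, va) across features, vectorised over rows
    const <- -0.5 * sum(log(2 * pi * s$va))
    Xc <- sweep(X, 2, s$mu)
    const - 0.5 * as.vector(Xc^2 %*% (1 / s$va)) + log(s$prior)
  }, numeric(nrow(X)))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = nrow(X))
  m <- pmax(ll[, 1], ll[, 2])
  exp(ll[, 2] - m) / (exp(ll[, 1] - m) + exp(ll[, 2] - m))
}

# ---- multi-layer perceptron -------------------------------------------------

# ReLU network with sigmoid output, Adam optimizer, mini-batches, early
# stopping on a held-out validation fraction.
.kp_fit_mlp <- function(X, y, hp, seed) {
  sizes <- c(ncol(X), hp$hidden_layer_sizes, 1L)
  L <- length(sizes) - 1L
  .kp_with_seed(seed, {
    Wts <- lapply(seq_len(L), function(l)
      matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1L]))
    Bs <- lapply(seq_len(L), function(l) numeric(sizes[l + 1L]))
    n <- nrow(X)
    n_val <- max(1L, floor(hp$validation_fraction * n))
    vidx <- sample.int(n, n_val)
    tidx <- setdiff(seq_len(n), vidx)
    Xt <- X[tidx, , drop = FALSE]; yt <- y[tidx]
    Xv <- X[vidx, , drop = FALSE]; yv <- y[vidx]
    mW <- lapply(Wts, function(w) w * 0); vW <- mW
    mB <- lapply(Bs, function(b) b * 0); vB <- mB
    b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8; lr <- hp$learning_rate
    tstep <- 0
    best_loss <- Inf; best_W <- Wts; best_B <- Bs; wait <- 0L
    forward <- function(Xb) {
      As <- vector("list", L + 1L); As[[1]] <- Xb
      for (l in seq_len(L)) {
        Z <- sweep(As[[l]] %*% Wts[[l]], 2, Bs[[l]], `+`)
        As[[l + 1L]] <- if (l < L) pmax(Z, 0) else 1 / (1 + exp(-Z))
      }
      As
    }
    val_loss <- function() {
      p <- forward(Xv)[[L + 1L]]
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -mean(yv * log(p) + (1 - yv) * log(1 - p))
    }
    for (epoch in seq_len(hp$max_epochs)) {
      ord <- sample(length(tidx))
      batches <- split(ord, ceiling(seq_along(ord) / hp$batch_size))
      for (bi in batches) {
        Xb <- Xt[bi, , drop = FALSE]; yb <- yt[bi]
        As <- forward(Xb)
        delta <- (As[[L + 1L]] - yb) / length(bi)   # dL/dZ_out for BCE+sigmoid
        for (l in rev(seq_len(L))) {
          gW <- crossprod(As[[l]], delta)
          gB <- colSums(delta)
          if (l > 1L) delta <- (delta %*% t(Wts[[l]])) * (As[[l]] > 0)
          tstep <- tstep + 1
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
          mB[[l]] <- b1 * mB[[l]] + (1 - b1) * gB
          vB[[l]] <- b2 * vB[[l]] + (1 - b2) * gB^2
          corr1 <- 1 - b1^ (tstep); corr2 <- 1 - b2^(tstep)
          Wts[[l]] <- Wts[[l]] - lr * (mW[[l]] / corr1) /
            (sqrt(vW[[l]] / corr2) + epsA)
          Bs[[l]] <- Bs[[l]] - lr * (mB[[l]] / corr1) /
            (sqrt(vB[[l]] / corr2) + epsA)
        }
      }
      vl <- val_loss()
      if (vl < best_loss - 1e-6) {
        best_loss <- vl; best_W <- Wts; best_B <- Bs; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= hp$patience) break
      }
    }
    list(W = best_W, B = best_B, L = L)
  })
}

.kp_predict_mlp <- function(fit, X) {
  A <- X
  for (l in seq_len(fit$L)) {
    Z <- sweep(A %*% fit$W[[l]], 2, fit$B[[l]], `+`)
    A <- if (l < fit$L) pmax(Z, 0) else 1 / (1 + exp(-Z))
  }
  as.vector(A)
}

# ---- unified fit / predict --------------------------------------------------

.kp_as_y01 <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.integer(as.character(labels) == "active")
  } else as.integer(labels)
}

#' Fit a classifier
#'
#' @param spec a `kp_model_spec`.
#' @param X binary feature matrix (rows = compounds). If it carries a
#'   `kind` attribute it must match the spec's fingerprint kind.
#' @param labels labels: `"active"`/`"inactive"`, or 0/1 with 1 = active.
#' @param smiles_std optional vector of training structures, stored as the
#'   model's leak-guard manifest.
#' @param decision_threshold probability cutoff for [kp_classify()]
#'   (default 0.5).
#' @return object of class `kp_model`.
#' @export
kp_fit <- function(spec, X, labels, smiles_std = NULL,
                   decision_threshold = 0.5) {
  stopifnot(inherits(spec, "kp_model_spec"))
  y <- .kp_as_y01(labels)
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  kind <- attr(X, "kind")
  if (!is.null(kind) && kind != spec$fingerprint_kind)
    stop(sprintf("fingerprint kind mismatch: features are %s, spec wants %s",
                 kind, spec$fingerprint_kind))
  fit <- switch(spec$algorithm,
    random_forest = .kp_fit_rf(X, y, spec$hyperparams, spec$seed),
    gaussian_nb = .kp_fit_gnb(X, y, spec$hyperparams),
    mlp = .kp_fit_mlp(X, y, spec$hyperparams, spec$seed))
  structure(list(spec = spec, fit = fit, n_features = ncol(X),
                 decision_threshold = decision_threshold,
                 train_manifest = sort(unique(smiles_std))),
            class = "kp_model")
}

#' @export
print.kp_model <- function(x, ...) {
  cat(sprintf("<kp_model %s / %s | %d features | threshold %.2f>\n",
              x$spec$algorithm, x$spec$fingerprint_kind, x$n_features,
              x$decision_threshold))
  invisible(x)
}

#' Predicted probability of the active class
#'
#' @param model a fitted `kp_model`, or any function `X -> probabilities`
#'   (useful for oracle models in tests).
#' @param X feature matrix matching the training fingerprint kind/length.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
kp_predict_proba <- function(model, X) {
  if (is.function(model)) return(model(X))
  stopifnot(inherits(model, "kp_model"))
  if (is.null(model$fit)) stop("model is not fitted")
  if (ncol(X) != model$n_features)
    stop(sprintf("feature length %d does not match model's %d",
                 ncol(X), model$n_features))
  kind <- attr(X, "kind")
  if (!is.null(kind) && kind != model$spec$fingerprint_kind)
    stop(sprintf("fingerprint kind mismatch: features are %s, model wants %s",
                 kind, model$spec$fingerprint_kind))
  switch(model$spec$algorithm,
         random_forest = .kp_predict_rf(model$fit, X),
         gaussian_nb = .kp_predict_gnb(model$fit, X),
         mlp = .kp_predict_mlp(model$fit, X))
}

#' Classify with the model's decision threshold
#'
#' @inheritParams kp_predict_proba
#' @param threshold overrides the model's stored threshold; predictions are
#'   active when probability >= threshold.
#' @return character vector `"active"`/`"inactive"`.
#' @export
kp_classify <- function(model, X, threshold = NULL) {
  if (is.null(threshold)) {
    threshold <- if (inherits(model, "kp_model")) model$decision_threshold else 0.5
  }
  p <- kp_predict_proba(model, X)
  ifelse(p >= threshold, "active", "inactive")
}

# ---- grid search & cross-validation -----------------------------------------

# k-fold stratified fold assignment (deterministic under seed).
.kp_stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  .kp_with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Exhaustive grid search scored by cross-validated MCC
#'
#' Every grid point is evaluated with 3-fold stratified cross-validation;
#' the point with the highest mean MCC wins, ties resolving to the first
#' point in canonical grid order.
#'
#' @param algorithm algorithm whose grid to search.
#' @param X,labels training features and labels.
#' @param fingerprint_kind recorded on the returned spec.
#' @param seed integer seed (folds and per-point fits).
#' @param n_folds folds for the inner CV (default 3).
#' @param grid optional list of hyperparameter lists; defaults to
#'   [kp_hyperparameter_grid()].
#' @return list: `best_spec` (a `kp_model_spec`), `results` (data.frame of
#'   grid point, mean MCC, rank).
#' @export
kp_grid_search <- function(algorithm, X, labels, fingerprint_kind = "morgan",
                           seed = 1L, n_folds = 3L, grid = NULL) {
  y <- .kp_as_y01(labels)
  if (length(unique(y)) < 2L) stop("grid search needs both classes")
  if (is.null(grid)) grid <- kp_hyperparameter_grid(algorithm)
  if (!length(grid)) stop("empty grid")
  fold <- .kp_stratified_folds(y, n_folds, seed)
  scores <- vapply(seq_along(grid), function(gi) {
    spec <- kp_model_spec(algorithm, fingerprint_kind, grid[[gi]],
                          seed = seed + gi)
    mccs <- vapply(seq_len(n_folds), function(f) {
      tr <- fold != f; te <- fold == f
      if (length(unique(y[tr])) < 2L) return(NA_real_)
      m <- kp_fit(spec, X[tr, , drop = FALSE], y[tr])
      pred <- kp_classify(m, X[te, , drop = FALSE])
      kp_metrics_from_labels(y[te] == 1L, pred == "active")$mcc
    }, numeric(1))
    if (all(is.na(mccs))) -Inf else mean(mccs, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(scores)          # first maximum wins: canonical order
  results <- data.frame(
    point = vapply(grid, function(g)
      paste(names(g), vapply(g, function(v) paste(v, collapse = "x"), ""),
            sep = "=", collapse = ","), ""),
    mean_mcc = scores)
  results$rank <- rank(-results$mean_mcc, ties.method = "first")
  list(best_spec = kp_model_spec(algorithm, fingerprint_kind, grid[[best]],
                                 seed = seed),
       results = results)
}

#' Cross-validation protocol
#'
#' @param n_repeats number of repeated random resplits (default 10).
#' @param test_fraction held-out fraction per repeat (default 0.3).
#' @param stratified stratify resplits by label (default `TRUE`).
#' @param scoring headline metric name (default `"mcc"`).
#' @param seed integer seed.
#' @return object of class `kp_cv_protocol`.
#' @export
kp_cv_protocol <- function(n_repeats = 10L, test_fraction = 0.3,
                           stratified = TRUE, scoring = "mcc", seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            scoring %in% .kp_metric_names)
  structure(list(n_repeats = as.integer(n_repeats),
                 test_fraction = test_fraction, stratified = stratified,
                 scoring = scoring, seed = as.integer(seed)),
            class = "kp_cv_protocol")
}

#' Repeated hold-out cross-validation
#'
#' The "k-fold CV" of this workflow is k independent random stratified
#' resplits with `test_fraction` held out per repeat (70/30 by default),
#' not canonical k-fold partitioning. Each repeat refits the spec on the
#' train part and scores the test part; undefined metrics are carried into
#' the summary's exclusion counts rather than dropped silently.
#'
#' @param spec a `kp_model_spec`.
#' @param X,labels features and labels.
#' @param protocol a `kp_cv_protocol`.
#' @return a `kp_metric_summary` across repeats.
#' @export
kp_cross_validate <- function(spec, X, labels,
                              protocol = kp_cv_protocol()) {
  y <- .kp_as_y01(labels)
  if (length(unique(y)) < 2L) stop("cross-validation needs both classes")
  reps <- lapply(seq_len(protocol$n_repeats), function(r) {
    sp <- if (protocol$stratified) {
      .kp_stratified_split(y, 1 - protocol$test_fraction,
                           protocol$seed * 1000L + r)
    } else {
      n_train <- floor((1 - protocol$test_fraction) * length(y))
      tr <- .kp_with_seed(protocol$seed * 1000L + r,
                          sort(sample(length(y), n_train)))
      list(train = tr, test = setdiff(seq_along(y), tr))
    }
    spec_r <- spec; spec_r$seed <- spec$seed + r
    m <- kp_fit(spec_r, X[sp$train, , drop = FALSE], y[sp$train])
    pred <- kp_classify(m, X[sp$test, , drop = FALSE])
    kp_metrics_from_labels(y[sp$test] == 1L, pred == "active")
  })
  kp_summarize_repeats(reps)
}

#' External validation on an untouched dataset
#'
#' Refuses evaluation when any external structure occurs in the model's
#' training manifest (enforce disjointness with
#' [kp_subtract_by_structure()] upstream).
#'
#' @param model fitted `kp_model` with a training manifest.
#' @param X features of the external set.
#' @param labels external labels.
#' @param smiles_std external structures (canonical).
#' @return a `kp_metrics` from the single evaluation pass.
#' @export
kp_external_validate <- function(model, X, labels, smiles_std) {
  if (!nrow(X)) stop("empty external set")
  overlap <- intersect(smiles_std, model$train_manifest)
  if (length(overlap)) {
    stop("external set overlaps training data: ",
         paste(utils::head(overlap, 5), collapse = ", "),
         if (length(overlap) > 5) sprintf(" (and %d more)", length(overlap) - 5)
         else "")
  }
  pred <- kp_classify(model, X)
  kp_metrics_from_labels(.kp_as_y01(labels) == 1L, pred == "active")
}
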