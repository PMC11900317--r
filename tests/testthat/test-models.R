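# Classifiers, grid search, repeated-holdout CV, external validation.

test_that("hyperparameter grids are exactly the documented sets", {
  rf <- kp_hyperparameter_grid("random_forest")
  expect_length(rf, 6L)
  expect_setequal(vapply(rf, `[[`, 0L, "n_estimators"), c(100L, 500L))
  expect_setequal(unique(vapply(rf, `[[`, "", "max_features")),
                  c("sqrt", "all", "log2"))
  expect_length(kp_hyperparameter_grid("gaussian_nb"), 4L)
  mlp <- kp_hyperparameter_grid("mlp")
  expect_length(mlp, 12L)   # 3 one-layer + 9 two-layer architectures
})

test_that("fit/predict contracts: kinds, thresholds, determinism", {
  fx <- fx_small()
  X <- fx_small_X()
  spec <- kp_model_spec("random_forest", "morgan",
                        list(n_estimators = 50L), seed = 3)
  m <- kp_fit(spec, X, fx$label, smiles_std = fx$smiles_std)
  p <- kp_predict_proba(m, X)
  expect_true(all(p >= 0 & p <= 1))
  # same seed + data => identical predictions, all algorithms
  for (algo in c("random_forest", "gaussian_nb", "mlp")) {
    hp <- switch(algo, random_forest = list(n_estimators = 20L),
                 mlp = list(hidden_layer_sizes = 16L, max_epochs = 15L),
                 list())
    s <- kp_model_spec(algo, "morgan", hp, seed = 9)
    p1 <- kp_predict_proba(kp_fit(s, X, fx$label), X)
    p2 <- kp_predict_proba(kp_fit(s, X, fx$label), X)
    expect_identical(p1, p2, info = algo)
  }
  # training actives separate from decoys on the planted fixture
  expect_true(all(p[fx$label == "active"] > 0.5))
  # degenerate threshold guard
  expect_equal(sum(kp_classify(m, X, threshold = 1.01) == "active"), 0L)
  # fingerprint-kind mismatch
  X881 <- kp_featurize_dataset(fx[1:4, ], "keys881")
  expect_error(kp_predict_proba(m, X881), "mismatch|match")
  expect_error(kp_fit(kp_model_spec("random_forest", "substructure_keys"),
                      X, fx$label), "mismatch")
  # single-class labels
  expect_error(kp_fit(spec, X[fx$label == "active", ],
                      rep("active", sum(fx$label == "active"))),
               "single class")
})

test_that("grid search: exhaustive scoring, argmax, determinism", {
  fx <- fx_small()
  X <- fx_small_X()
  grid <- list(list(n_estimators = 20L, max_features = "sqrt"),
               list(n_estimators = 40L, max_features = "log2"))
  gs <- kp_grid_search("random_forest", X, fx$label, seed = 4, grid = grid)
  expect_equal(nrow(gs$results), 2L)
  # winning spec's score is maximal among all evaluated points
  best_score <- max(gs$results$mean_mcc)
  expect_equal(gs$results$mean_mcc[gs$results$rank == 1], best_score)
  # planted fixture is separable: winner reaches CV MCC 1
  expect_equal(best_score, 1.0)
  gs2 <- kp_grid_search("random_forest", X, fx$label, seed = 4, grid = grid)
  expect_identical(gs$best_spec$hyperparams, gs2$best_spec$hyperparams)
  expect_error(kp_grid_search("random_forest", X,
                              rep("active", nrow(X)), seed = 1),
               "both classes")
})

test_that("cross_validate: separable fixture, single repeat, permuted null", {
  fx <- fx_small()
  X <- fx_small_X()
  spec <- kp_model_spec("random_forest", "morgan",
                        list(n_estimators = 30L), seed = 5)
  cv <- kp_cross_validate(spec, X, fx$label,
                          kp_cv_protocol(n_repeats = 5L, seed = 17))
  expect_equal(kp_summary_mean(cv, "mcc"), 1.0)
  expect_equal(cv$summary$sd[cv$summary$metric == "mcc"], 0.0)

  cv1 <- kp_cross_validate(spec, X, fx$label,
                           kp_cv_protocol(n_repeats = 1L, seed = 17))
  expect_equal(kp_summary_mean(cv1, "mcc"), cv1$repeats$mcc[1])

  # label-permutation null: mean MCC statistically indistinguishable from 0
  yp <- withr::with_seed(31, sample(fx$label))
  cvp <- kp_cross_validate(spec, X, yp,
                           kp_cv_protocol(n_repeats = 8L, seed = 19))
  mu <- kp_summary_mean(cvp, "mcc")
  sd <- cvp$summary$sd[cvp$summary$metric == "mcc"]
  expect_lt(abs(mu), max(3 * sd / sqrt(cvp$n_repeats), 0.15))
})

test_that("label noise degrades CV MCC monotonically", {
  mccs <- vapply(c(0, 0.1, 0.2, 0.3), function(noise) {
    fx <- kp_generate_family_fixture(
      kp_fixture_spec(n_active = 60L, n_inactive = 60L,
                      label_noise = noise, seed = 42L))
    X <- kp_featurize_dataset(fx, "morgan")
    spec <- kp_model_spec("gaussian_nb", "morgan", seed = 2)
    cv <- kp_cross_validate(spec, X, fx$label,
                            kp_cv_protocol(n_repeats = 5L, seed = 23))
    kp_summary_mean(cv, "mcc")
  }, numeric(1))
  expect_true(all(diff(mccs) <= 1e-9))
})

test_that("external validation guards and scaffold generalization", {
  fx <- fx_small()
  X <- fx_small_X()
  spec <- kp_model_spec("random_forest", "morgan",
                        list(n_estimators = 50L), seed = 6)
  model <- kp_fit(spec, X, fx$label, smiles_std = fx$smiles_std)
  # overlap with training is an error naming compounds
  expect_error(kp_external_validate(model, X, fx$label, fx$smiles_std),
               "overlap")
  expect_error(kp_external_validate(model, X[0, , drop = FALSE],
                                    character(0), character(0)), "empty")
  # unseen substituent combinations: the motif, not the scaffold, carries
  # the label
  ext <- kp_generate_family_fixture(
    kp_fixture_spec(n_active = 100L, n_inactive = 100L, seed = 77L))
  ext <- ext[!(ext$smiles_std %in% fx$smiles_std), ]
  Xe <- kp_featurize_dataset(ext, "morgan")
  met <- kp_external_validate(model, Xe, ext$label, ext$smiles_std)
  expect_gte(met$mcc, 0.8)
})

test_that("mlp and gnb learn the separable fixture", {
  fx <- fx_small()
  X <- fx_small_X()
  gnb <- kp_fit(kp_model_spec("gaussian_nb", "morgan"), X, fx$label)
  expect_equal(unname(kp_metrics_from_labels(
    fx$label == "active", kp_classify(gnb, X) == "active")$mcc), 1.0)
  mlp <- kp_fit(kp_model_spec("mlp", "morgan",
                              list(hidden_layer_sizes = 32L,
                                   max_epochs = 40L), seed = 8),
                X, fx$label)
  m <- kp_metrics_from_labels(fx$label == "active",
                              kp_classify(mlp, X) == "active")
  expect_gte(m$mcc, 0.95)
})
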