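# Per-target datasets, RF cards, imbalance flag, panel scoring.

tf_fixture <- function() memo("tf_fixture", function()
  kp_generate_target_fixture(n_targets = 4L, n_active = 60L,
                             inactive_ratio = c(0.10, 0.25, 0.5, 1.0),
                             seed = 9L))

tf_curated <- function() {
  tf <- tf_fixture()
  data.frame(compound_id = tf$compounds$compound_id,
             smiles_std = tf$compounds$smiles, status = "kept",
             stringsAsFactors = FALSE)
}

test_that("build_target_datasets: 10 uM rule, eligibility, ratios", {
  tf <- tf_fixture()
  tds <- kp_build_target_datasets(tf$activities, tf_curated(), min_n = 50L)
  expect_length(tds, 4L)
  td <- tds[["T04"]]
  expect_equal(td$n_active + td$n_inactive, nrow(td$records))
  expect_equal(td$inactive_ratio, 1.0)
  expect_equal(tds[["T01"]]$inactive_ratio, 0.1)

  # most potent record decides the label
  acts <- data.frame(compound_id = rep("C1", 2), target_id = "T",
                     value_nM = c(50000, 9000), confidence = 9)
  cur <- data.frame(compound_id = "C1", smiles_std = "CCO", status = "kept")
  td1 <- kp_build_target_datasets(acts, cur, min_n = 1L)
  expect_equal(td1[["T"]]$records$label, "active")

  # strictly above 10 uM is inactive
  acts$value_nM <- c(10001, 20000)
  td2 <- kp_build_target_datasets(acts, cur, min_n = 1L)
  expect_equal(td2[["T"]]$records$label, "inactive")

  # below min_n: excluded and reported, not returned
  tds99 <- kp_build_target_datasets(tf$activities, tf_curated(), min_n = 200L)
  expect_length(tds99, 0L)
  expect_length(attr(tds99, "excluded"), 4L)

  # confidence filter drops low-confidence records
  acts3 <- data.frame(compound_id = c("C1", "C1"), target_id = "T",
                      value_nM = c(100, 100), confidence = c(8, 9))
  td3 <- kp_build_target_datasets(acts3, cur, min_n = 1L)
  expect_equal(nrow(td3[["T"]]$records), 1L)
})

test_that("imbalance flag is exactly ratio < 0.25", {
  mk <- function(ratio) {
    structure(list(target_id = "T", records = NULL, n_active = 10000L,
                   n_inactive = as.integer(ratio * 10000),
                   inactive_ratio = ratio), class = "kp_target_dataset")
  }
  flag <- function(ratio) ratio < 0.25
  for (r in c(0.25, 0.2499999, 0.249, 0.1, 0.3)) {
    expect_equal(mk(r)$inactive_ratio < 0.25, flag(r))
  }
})

test_that("train_target_model: card fields, 0.75 rule, determinism", {
  tds <- kp_build_target_datasets(tf_fixture()$activities, tf_curated(),
                                  min_n = 50L)
  card <- kp_train_target_model(tds[["T04"]], seed = 3L, n_repeats = 3L)
  expect_s3_class(card, "kp_target_model_card")
  expect_false(card$imbalance_flag)
  expect_equal(card$decision_threshold, 0.75)
  expect_gte(kp_summary_mean(card$cv_summary, "mcc"), 0.9)

  flagged <- kp_train_target_model(tds[["T01"]], seed = 3L, n_repeats = 2L)
  expect_true(flagged$imbalance_flag)
  boundary <- kp_train_target_model(tds[["T02"]], seed = 3L, n_repeats = 2L)
  expect_false(boundary$imbalance_flag)   # ratio exactly 0.25 is kept

  card2 <- kp_train_target_model(tds[["T04"]], seed = 3L, n_repeats = 3L)
  expect_identical(card$cv_summary$summary, card2$cv_summary$summary)

  # probability >= 0.75 classifies active; 0.749 does not
  stub <- function(X) rep(c(0.75, 0.749), length.out = nrow(X))
  lab <- kp_classify(stub, matrix(0, 2, 4), threshold = 0.75)
  expect_identical(lab, c("active", "inactive"))

  # single-class dataset errors
  bad <- tds[["T04"]]
  bad$records$label <- "active"; bad$n_inactive <- 0L
  expect_error(kp_train_target_model(bad), "single-class")
})

test_that("threshold monotonicity: raising it never adds positives", {
  fx <- fx_small()
  X <- fx_small_X()
  m <- kp_fit(kp_model_spec("random_forest", "morgan",
                            list(n_estimators = 20L), seed = 2), X, fx$label)
  counts <- vapply(c(0.1, 0.3, 0.5, 0.75, 0.9, 1.01), function(th)
    sum(kp_classify(m, X, threshold = th) == "active"), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("ensemble report: directions, degenerate cases", {
  tds <- kp_build_target_datasets(tf_fixture()$activities, tf_curated(),
                                  min_n = 50L)
  cards <- lapply(tds, kp_train_target_model, seed = 3L, n_repeats = 2L)
  rep_all <- kp_ensemble_report(cards)
  expect_equal(rep_all$comparison$n_all[1], 4L)
  expect_equal(rep_all$comparison$n_filtered[1], 3L)

  # single card: summary equals that card's means
  one <- kp_ensemble_report(cards[4])
  expect_equal(one$summary$mean[one$summary$metric == "mcc"],
               kp_summary_mean(cards[[4]]$cv_summary, "mcc"))

  # no flags: filtered identical to unfiltered
  noflag <- cards[2:4]
  repn <- kp_ensemble_report(noflag, exclude_flagged = TRUE)
  expect_equal(repn$summary$mean, kp_ensemble_report(noflag)$summary$mean)

  # all flagged + exclude: error
  allflag <- cards[1]
  expect_error(kp_ensemble_report(allflag, exclude_flagged = TRUE),
               "flagged")
})

test_that("panel prediction and success-rate scoring", {
  tds <- kp_build_target_datasets(tf_fixture()$activities, tf_curated(),
                                  min_n = 50L)
  cards <- lapply(tds[c("T03", "T04")], kp_train_target_model, seed = 3L,
                  n_repeats = 2L)
  tf <- tf_fixture()
  comp <- data.frame(
    compound_id = c("A", "B"),
    smiles_std = c(tf$compounds$smiles[tf$compounds$has_motif][1],
                   tf$compounds$smiles[!tf$compounds$has_motif][1]))
  exper <- matrix(c(1L, 1L, 0L, 0L), 2, 2, byrow = TRUE)
  panel <- kp_predict_panel(cards, comp, experimental = exper)
  expect_equal(dim(panel$predicted), c(2L, 2L))
  scores <- kp_score_panel(panel)
  expect_equal(scores$n_targets, c(2L, 2L))
  expect_true(all(scores$success_rate >= 0 & scores$success_rate <= 100))

  # empty compound list -> empty matrix
  empty <- kp_predict_panel(cards, comp[0, , drop = FALSE])
  expect_equal(nrow(empty$predicted), 0L)

  # shape mismatch
  expect_error(kp_predict_panel(cards, comp,
                                experimental = matrix(0L, 3, 2)), "shape")
  # inhibition binarization at >= 50%
  inh <- matrix(c(49.9, 50, 74, 10), 2, 2)
  expect_equal(kp_panel_from_inhibition(inh), matrix(c(0L, 1L, 1L, 0L), 2, 2))
})
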