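# Standardization, filters, deduplication, labeling, balancing, splits.

test_that("standardize_structure: canonical output, salts, failures", {
  r <- kp_standardize_structure("c1ccccc1")
  expect_equal(r$status, "kept")
  expect_equal(r$heavy_atoms, 6L)
  expect_identical(r$smiles_std, "c1ccccc1")

  # frozen regression of the documented pH 7.4 rule table
  r2 <- kp_standardize_structure("CC(=O)[O-].[Na+]")
  expect_equal(r2$status, "kept")
  expect_identical(r2$smiles_std, "CC(=O)[O-]")     # Na dropped, acid anion
  expect_identical(kp_standardize_structure("CC(=O)O")$smiles_std,
                   "CC(=O)[O-]")                    # neutral acid re-ionized
  expect_identical(kp_standardize_structure("CCN")$smiles_std, "CC[NH3+]")
  # amides and anilines are not basic
  expect_identical(kp_standardize_structure("CCNC(C)=O")$smiles_std,
                   "CCNC(C)=O")
  expect_false(grepl("\\+", kp_standardize_structure("Nc1ccccc1")$smiles_std))

  expect_equal(kp_standardize_structure("C1CC")$reject_reason, "parse_error")
  expect_equal(kp_standardize_structure("")$reject_reason, "parse_error")
  expect_equal(kp_standardize_structure("C(C)(C)(C)(C)C")$reject_reason,
               "valence_error")
})

test_that("standardization is spelling-invariant", {
  base <- kp_standardize_structure("OC(=O)c1ccccc1CN(C)C")$smiles_std
  withr::with_seed(11, {
    m <- kp_parse_smiles("OC(=O)c1ccccc1CN(C)C")
    for (i in 1:100) {
      sp <- kp_random_smiles(m)
      expect_identical(kp_standardize_structure(sp)$smiles_std, base,
                       info = sp)
    }
  })
})

test_that("apply_filters enforces element, weight and size rules", {
  # arsenic: parses but element disallowed
  as_rec <- kp_standardize_structure("CCCCCCCCCCCCCC[As](C)C")
  expect_equal(as_rec$status, "kept")
  expect_equal(kp_apply_filters(as_rec)$reject_reason, "disallowed_element")

  # 14 heavy atoms: one short of the boundary
  r14 <- kp_standardize_structure(paste(rep("C", 14), collapse = ""))
  expect_equal(kp_apply_filters(r14)$reject_reason, "too_few_heavy_atoms")
  r15 <- kp_standardize_structure(paste(rep("C", 15), collapse = ""))
  expect_equal(kp_apply_filters(r15)$status, "kept")

  # MW boundary is inclusive: exactly at the cutoff stays
  r <- kp_standardize_structure("CCCCCCCCCCCCCCCC")
  r$mol_weight <- 800.0
  expect_equal(kp_apply_filters(r)$status, "kept")
  r$mol_weight <- 800.1
  expect_equal(kp_apply_filters(r)$reject_reason, "mw_too_high")

  # idempotence over a batch of records, kept or rejected
  recs <- kp_curate(c("c1ccccc1CCCCCCCCCC", "CCO", "C1CC", "CC(C)CCCCCCCCCCCCC"))
  for (i in seq_len(nrow(recs))) {
    once <- recs[i, , drop = FALSE]
    expect_identical(kp_apply_filters(once), once)
  }
})

test_that("deduplicate keeps first spelling and is stable", {
  recs <- do.call(rbind, lapply(
    c("CCO", "OCC", "CCC", "C(C)C", "CCO"),
    kp_standardize_structure))
  out <- kp_deduplicate(recs)
  expect_equal(sum(out$status == "kept"), 2L)   # ethanol + propane
  expect_equal(out$status[1], "kept")
  expect_equal(out$reject_reason[2], "duplicate")
  expect_equal(out$reject_reason[5], "duplicate")
  expect_identical(kp_deduplicate(recs[0, ]), recs[0, ])
})

test_that("curation report counts are conserved", {
  smis <- c("c1ccccc1CCCCCCCCCC", "C1CC", "CCO", "CCO",
            "CCCCCCCCCCCCCC[As](C)C", "C(C)(C)(C)(C)C",
            "c1ccccc1CCCCCCCCCC")
  recs <- kp_curate(smis)
  rep <- kp_curation_report(recs)
  expect_equal(rep$n_kept + sum(unlist(rep$rejected)), rep$n_input)
  expect_equal(rep$n_input, length(smis))
  expect_equal(rep$rejected$duplicate, 1L)        # repeated benzene-chain
  expect_equal(rep$rejected$too_few_heavy_atoms, 2L)  # both CCO copies
})

test_that("family activity labeling follows the 10 uM / confidence-9 rule", {
  rec <- function(val, conf) data.frame(compound_id = "X", value_nM = val,
                                        confidence = conf)
  expect_equal(kp_label_family_active(rec(5000, 9)), "active")
  expect_equal(kp_label_family_active(rec(20000, 9)), "excluded")
  expect_equal(kp_label_family_active(rec(100, 8)), "excluded")
  expect_equal(kp_label_family_active(rec(10000, 9)), "active")  # boundary
  # any qualifying record suffices
  two <- rbind(rec(50000, 9), rec(900, 9))
  expect_equal(kp_label_family_active(two), "active")
  expect_equal(kp_label_family_active(
    data.frame(compound_id = character(0), value_nM = numeric(0),
               confidence = integer(0))), "excluded")
  expect_error(kp_label_family_active(
    data.frame(compound_id = c("A", "B"), value_nM = 1, confidence = 9)))
})

test_that("build_family_dataset balances classes deterministically", {
  fx <- fx_small()
  act <- data.frame(compound_id = fx$compound_id[fx$label == "active"][1:30],
                    smiles_std = fx$smiles_std[fx$label == "active"][1:30],
                    status = "kept")
  pool <- data.frame(compound_id = fx$compound_id[fx$label == "inactive"],
                     smiles_std = fx$smiles_std[fx$label == "inactive"],
                     status = "kept")
  ds <- kp_build_family_dataset(act, pool, seed = 5)
  expect_equal(nrow(ds), 60L)
  expect_equal(unname(attr(ds, "class_counts")), c(30L, 30L))
  expect_identical(ds, kp_build_family_dataset(act, pool, seed = 5))
  ds2 <- kp_build_family_dataset(act, pool, seed = 6)
  expect_false(identical(ds$compound_id, ds2$compound_id))
  expect_error(kp_build_family_dataset(pool, act, seed = 1), "too small")
})

test_that("make_split arithmetic, stratification and conservation", {
  fx <- fx_small()
  ds10 <- fx[1:10, ]
  sp <- kp_make_split(ds10, 0.8, seed = 1)
  expect_length(sp$train_indices, 8L)
  expect_length(sp$test_indices, 2L)

  # the 80:20 arithmetic at full published scale (labels only)
  big <- rep(c("active", "inactive"), 59408)
  spb <- kinasepred:::.kp_stratified_split(big, 0.8, 1)
  expect_length(spb$train, 95052L)
  expect_length(spb$test, 23764L)

  # floor convention at awkward N
  sp11 <- kp_make_split(fx[1:11, ], 0.8, seed = 2)
  expect_length(sp11$train_indices, 8L)
  expect_length(sp11$test_indices, 3L)

  # stratification and conservation over several seeds
  for (seed in 1:5) {
    s <- kp_make_split(fx, 0.8, seed = seed)
    expect_length(intersect(s$train_indices, s$test_indices), 0L)
    expect_equal(length(s$train_indices) + length(s$test_indices), nrow(fx))
    for (cl in c("active", "inactive")) {
      n_cl <- sum(fx$label == cl)
      n_tr <- sum(fx$label[s$train_indices] == cl)
      expect_lte(abs(n_tr - 0.8 * n_cl), 1)
    }
  }
  expect_error(kp_make_split(fx[1, , drop = FALSE], 0.8, 1), "at least 2")
})

test_that("subtract_by_structure is a set difference on canonical strings", {
  fx <- fx_small()
  lib <- fx[1:5, ]
  expect_equal(nrow(kp_subtract_by_structure(lib, fx)), 0L)
  other <- data.frame(smiles_std = c("ZZZ", "YYY"))
  expect_equal(nrow(kp_subtract_by_structure(lib, other)), 5L)
  ref <- fx[c(1, 3), ]
  expect_equal(nrow(kp_subtract_by_structure(lib, ref)), 3L)
})
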