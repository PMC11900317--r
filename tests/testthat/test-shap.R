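# Kernel SHAP estimates and atom retro-mapping.

test_that("single-feature indicator model gets the exact Shapley value", {
  fp <- make_fp(64, 5, lapply(c(3L, 10L, 17L, 30L, 44L, 60L),
                              function(b) list(bit = b, atoms = 1:2)))
  bg <- matrix(0, 8, 64)
  ind <- function(X) as.numeric(X[, 17] == 1)
  att <- kp_kernel_shap(ind, fp, bg, seed = 3)
  expect_equal(att$phi[17], 1.0, tolerance = 1e-8)
  expect_lt(max(abs(att$phi[-17])), 1e-6)
  expect_equal(att$base_value + sum(att$phi), att$model_output,
               tolerance = 1e-9)
})

test_that("constant model attributes nothing", {
  fp <- make_fp(32, 3, list(list(bit = 2L, atoms = 1L),
                            list(bit = 9L, atoms = 2:3)))
  att <- kp_kernel_shap(function(X) rep(0.7, nrow(X)), fp,
                        matrix(0, 4, 32), seed = 1)
  expect_lt(max(abs(att$phi)), 1e-9)
  expect_equal(att$model_output, 0.7)
})

test_that("local accuracy holds by construction, also when sampling", {
  fx <- fx_small()
  X <- fx_small_X()
  model <- kp_fit(kp_model_spec("gaussian_nb", "morgan"), X, fx$label)
  bg <- X[1:20, , drop = FALSE]
  for (i in c(2, 7)) {
    fp <- kp_morgan_fp(fx$smiles_std[i])
    att <- kp_kernel_shap(model, fp, bg, n_samples = 200, seed = 5,
                          max_background_evals = 1000)   # force sampled mode
    expect_equal(att$base_value + sum(att$phi), att$model_output,
                 tolerance = 1e-9)
  }
})

test_that("kernel SHAP is deterministic under its seed", {
  fx <- fx_small()
  X <- fx_small_X()
  model <- kp_fit(kp_model_spec("gaussian_nb", "morgan"), X, fx$label)
  fp <- kp_morgan_fp(fx$smiles_std[3])
  a1 <- kp_kernel_shap(model, fp, X[1:15, ], n_samples = 150, seed = 11)
  a2 <- kp_kernel_shap(model, fp, X[1:15, ], n_samples = 150, seed = 11)
  expect_identical(a1$phi, a2$phi)
  # a smooth model makes the sampled-coalition estimates seed-sensitive
  # (saturated classifiers can mask the sampling difference)
  wvec <- sin(seq_len(ncol(X)))
  smooth <- function(Z) 1 / (1 + exp(-(Z %*% wvec) / 10))
  s1 <- kp_kernel_shap(smooth, fp, X[1:15, ], n_samples = 150, seed = 11)
  s2 <- kp_kernel_shap(smooth, fp, X[1:15, ], n_samples = 150, seed = 12)
  expect_false(identical(s1$phi, s2$phi))
  expect_identical(
    s1$phi, kp_kernel_shap(smooth, fp, X[1:15, ], n_samples = 150,
                           seed = 11)$phi)
  expect_error(kp_kernel_shap(model, fp, X[0, , drop = FALSE]), "background")
})

test_that("retro-mapping partitions phi over occurrences and atoms", {
  fp <- make_fp(16, 4, list(list(bit = 5L, atoms = c(1L, 2L, 3L)),
                            list(bit = 9L, atoms = c(2L, 4L))))
  att <- structure(list(phi = replace(numeric(16), c(5, 9), c(0.3, 0.06)),
                        base_value = 0, model_output = 0.36,
                        point_output = 0.36, set_bits = c(5L, 9L)),
                   class = "kp_bit_attribution")
  am <- kp_retro_map(att, fp)
  expect_equal(am$atom_weights, c(0.1, 0.13, 0.1, 0.03))
  expect_equal(sum(am$atom_weights), am$mapped_phi)

  # all-zero phi
  att0 <- att; att0$phi[] <- 0
  expect_equal(kp_retro_map(att0, fp)$atom_weights, numeric(4))

  # bits without provenance are skipped and accounted
  fpc <- make_fp(16, 4, list(list(bit = 5L, atoms = c(1L, 2L))))
  fpc$bits[9] <- 1L   # set bit with no atom provenance (count-type key)
  attc <- att
  amc <- kp_retro_map(attc, fpc)
  expect_equal(amc$skipped_phi, 0.06)
  expect_equal(sum(amc$atom_weights), 0.3, tolerance = 1e-12)

  # length mismatch
  fp8 <- make_fp(8, 4, list(list(bit = 5L, atoms = 1L)))
  expect_error(kp_retro_map(att, fp8), "lengths differ")
})

test_that("conservation across a real model/fingerprint pair", {
  fx <- fx_small()
  X <- fx_small_X()
  model <- kp_fit(kp_model_spec("gaussian_nb", "morgan"), X, fx$label)
  fp <- kp_morgan_fp(fx$smiles_std[1])
  att <- kp_kernel_shap(model, fp, X[1:15, ], n_samples = 300, seed = 2)
  am <- kp_retro_map(att, fp)
  mapped_bits <- Filter(function(b) {
    es <- fp$bit_atoms[[as.character(b)]]
    any(vapply(es, function(e) length(e$atoms) > 0, logical(1)))
  }, att$set_bits)
  expect_equal(sum(am$atom_weights), sum(att$phi[mapped_bits]),
               tolerance = 1e-9)
  # normalization bounds
  amn <- kp_retro_map(att, fp, "max_abs")
  expect_true(all(abs(amn$atom_weights) <= 1 + 1e-12))
})

test_that("rendering writes SVG + CSV and survives degenerate weights", {
  m <- kp_parse_smiles("CCOc1ccc2[nH]ccc2n1")
  fp <- kp_morgan_fp(m)
  att <- structure(list(phi = numeric(2048), base_value = 0,
                        model_output = 0, point_output = 0,
                        set_bits = integer(0)),
                   class = "kp_bit_attribution")
  zero <- kp_retro_map(att, fp)
  path <- tempfile(fileext = ".svg")
  out <- kp_render_attribution(m, zero, path)        # zero weights: no failure
  expect_true(file.exists(out["svg"]))
  expect_true(file.exists(out["csv"]))
  csv <- read.csv(out["csv"])
  expect_equal(nrow(csv), m$n)
  # uniform weights shade uniformly (all circles share one fill value)
  uni <- zero; uni$atom_weights <- rep(0.5, m$n)
  p2 <- tempfile(fileext = ".svg")
  kp_render_attribution(m, uni, p2)
  fills <- regmatches(readLines(p2), regexpr("rgba\\([0-9,. ]+\\)",
                                             readLines(p2)))
  expect_equal(length(unique(fills)), 1L)
  expect_error(suppressWarnings(
    kp_render_attribution(m, uni, file.path(tempdir(), "no_dir_x",
                                            "a", "b.svg"))))
})
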