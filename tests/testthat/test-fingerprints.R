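# Fingerprint lengths, invariance, provenance soundness, key semantics.

test_that("fingerprint lengths and basic contracts", {
  m <- chem_mols()[[1]]
  expect_length(kp_morgan_fp(m)$bits, 2048L)
  expect_length(kp_path_fp(m)$bits, 2048L)
  expect_length(kp_keys881_fp(m)$bits, 881L)
  # set-bit provenance keys are set bits
  for (fp in list(kp_morgan_fp(m), kp_path_fp(m), kp_keys881_fp(m))) {
    bits <- as.integer(names(fp$bit_atoms))
    expect_true(all(fp$bits[bits] == 1L))
    for (es in fp$bit_atoms) for (e in es)
      expect_true(all(e$atoms >= 1L & e$atoms <= m$n))
  }
})

test_that("fingerprints are invariant to atom reordering", {
  withr::with_seed(5, {
    for (m in chem_mols()[1:3]) {
      ref <- list(kp_morgan_fp(m)$bits, kp_path_fp(m)$bits,
                  kp_keys881_fp(m)$bits)
      for (i in 1:5) {
        mm <- kp_parse_smiles(kp_random_smiles(m))
        expect_identical(kp_morgan_fp(mm)$bits, ref[[1]])
        expect_identical(kp_path_fp(mm)$bits, ref[[2]])
        expect_identical(kp_keys881_fp(mm)$bits, ref[[3]])
      }
    }
  })
})

test_that("morgan: methane has only its radius-0 environment", {
  fp <- kp_morgan_fp("C")
  expect_equal(sum(fp$bits), 1L)
  entries <- fp$bit_atoms[[1]]
  expect_true(all(vapply(entries, function(e) identical(e$atoms, 1L),
                         logical(1))))
})

test_that("morgan provenance soundness: env hash reproduces the owning bit", {
  for (m in chem_mols()[1:2]) {
    fp <- kp_morgan_fp(m)
    for (key in names(fp$bit_atoms)) {
      for (e in fp$bit_atoms[[key]]) {
        id <- kp_morgan_env_hash(m, e$center, e$radius)
        expect_equal(id, e$id)
        expect_equal((id %% 2048) + 1, as.integer(key))
        # atoms are exactly the radius-neighborhood of the center
        d <- kinasepred:::.kp_bfs_dist(m, e$center, e$radius)
        expect_identical(sort(e$atoms), which(!is.na(d) & d <= e$radius))
      }
    }
  }
})

test_that("path fingerprint: hashes recompute, fragments collapse, sizes", {
  m <- chem_mols()[[1]]
  fp <- kp_path_fp(m)
  for (key in names(fp$bit_atoms)) {
    for (e in fp$bit_atoms[[key]]) {
      expect_equal((kp_subgraph_hash(m, e$bonds) %% 2048) + 1,
                   as.integer(key))
    }
  }
  # duplicate disconnected fragments give the same set of hashed subgraphs
  expect_identical(kp_path_fp("CCO.CCO")$bits, kp_path_fp("CCO")$bits)
  # single atom with min_size 1 bond: nothing qualifies
  expect_equal(sum(kp_path_fp("C", min_size = 1)$bits), 0L)
  # size range is honoured: ethane has exactly one 1-bond subgraph
  expect_equal(sum(kp_path_fp("CC")$bits), 1L)
})

test_that("881-key fingerprint semantics", {
  tab <- kp_keys881_table()
  expect_equal(nrow(tab), 881L)
  fb <- kp_keys881_fp("c1ccccc1")
  # aromatic six-ring key fires with full ring provenance
  bit6a <- tab$bit[tab$type == "ring" & tab$spec == "6:aromatic"]
  expect_equal(fb$bits[bit6a], 1L)
  expect_length(fb$bit_atoms[[as.character(bit6a)]][[1]]$atoms, 6L)
  # benzene pattern key fires on benzene
  bitbz <- tab$bit[tab$type == "pattern" & tab$spec == "c1ccccc1"]
  expect_equal(fb$bits[bitbz], 1L)
  # methane: every ring key unset; element-count keys carry no provenance
  fm <- kp_keys881_fp("C")
  expect_true(all(fm$bits[tab$bit[tab$type == "ring"]] == 0L))
  hbit <- tab$bit[tab$type == "element_count" & tab$spec == "H>=4"]
  expect_equal(fm$bits[hbit], 1L)
  expect_null(fm$bit_atoms[[as.character(hbit)]])
})

test_that("monotone containment of pattern keys on constructed pairs", {
  tab <- kp_keys881_table()
  pat_bits <- tab$bit[tab$type == "pattern"]
  pairs <- list(c("c1ccccc1", "Cc1ccccc1"),
                c("CC(=O)N", "CC(=O)Nc1ccc(O)cc1"),
                c("c1ccncc1", "CCOc1ccncc1"),
                c("CCO", "CCOC(=O)c1ccccc1"))
  for (p in pairs) {
    a <- kp_keys881_fp(p[1])$bits[pat_bits]
    b <- kp_keys881_fp(p[2])$bits[pat_bits]
    expect_true(all(b[a == 1L] == 1L), info = paste(p, collapse = " < "))
  }
})

test_that("featurize_dataset shapes, determinism, failure naming", {
  fx <- fx_small()[1:6, ]
  X <- kp_featurize_dataset(fx, "morgan")
  expect_equal(dim(X), c(6L, 2048L))
  expect_identical(rownames(X), fx$compound_id)
  expect_identical(X, kp_featurize_dataset(fx, "morgan"))
  expect_equal(attr(kp_featurize_dataset(fx[1:2, ], "keys881"), "kind"),
               "substructure_keys")
  bad <- fx
  bad$smiles_std[3] <- NA
  expect_error(kp_featurize_dataset(bad, "morgan"), bad$compound_id[3])
})

test_that("tanimoto similarity basics", {
  a <- c(1, 1, 0, 0); b <- c(1, 0, 1, 0)
  expect_equal(kp_tanimoto(a, b), 1 / 3)
  expect_equal(kp_tanimoto(a, a), 1)
  expect_equal(kp_tanimoto(numeric(4), numeric(4)), 1)
  f1 <- kp_morgan_fp("CCO")
  expect_equal(kp_tanimoto(f1, f1), 1)
})
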