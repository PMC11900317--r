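# Shared fixtures, built once per test run (all synthetic, generated in
# code; no files shipped).

.fx_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fx_cache[[key]])) .fx_cache[[key]] <- build()
  .fx_cache[[key]]
}

fx_small <- function() memo("fx_small", function()
  kp_generate_family_fixture(kp_fixture_spec(n_active = 60L, n_inactive = 60L,
                                             seed = 42L)))

fx_small_X <- function() memo("fx_small_X", function()
  kp_featurize_dataset(fx_small(), "morgan"))

# a handful of parsed drug-like molecules for chem-level tests
chem_mols <- function() memo("chem_mols", function() {
  smis <- c("CC(=O)Nc1ccc(O)cc1",          # acetaminophen-like
            "c1ccc2[nH]ccc2n1",            # azaindole
            "O=C(O)c1ccccc1OC(C)=O",       # aspirin-like
            "Cn1cnc2c1c(=O)n(C)c(=O)n2C",  # caffeine-like
            "CCN(CC)CCNC(=O)c1ccc(N)cc1")  # procainamide-like
  lapply(smis, kp_parse_smiles)
})

# tiny synthetic fingerprint with chosen set bits / provenance
make_fp <- function(nbits, n_atoms, entries) {
  fp <- kinasepred:::.kp_new_fp("morgan", as.integer(nbits),
                                as.integer(n_atoms))
  for (e in entries) fp <- kinasepred:::.kp_fp_add(fp, e$bit, e$atoms)
  fp
}
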