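# Shared, lazily built fixtures. The compound fixture is expensive (it runs
# Open Babel over the whole candidate universe), so one small instance is
# cached per test session.

.fixture_cache <- new.env(parent = emptyenv())

small_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    .fixture_cache$fx <- make_compound_fixture(
      fixture_spec(seed = 42L, n_actives = 8L, decoys_per_active = 6L))
  }
  .fixture_cache$fx
}

small_decoys <- function() {
  if (is.null(.fixture_cache$dg)) {
    fx <- small_fixture()
    .fixture_cache$dg <- generate_decoys(fx$actives, fx$universe,
                                         decoy_spec(decoys_per_active = 6L, seed = 42L))
  }
  .fixture_cache$dg
}

pocket_fixture <- function() {
  if (is.null(.fixture_cache$pocket)) {
    dir <- file.path(tempdir(), "kappascreen-pocket")
    dir.create(dir, showWarnings = FALSE)
    .fixture_cache$pocket <- make_pocket_fixture(dir)
  }
  .fixture_cache$pocket
}

# small named SMILES test set parsed once
test_molecules <- function() {
  if (is.null(.fixture_cache$mols)) {
    smi <- c(
      acetone = "CC(=O)C",
      benzene = "c1ccccc1",
      methane = "C",
      water = "O",
      butane = "CCCC",
      nma = "CC(=O)NC",                     # N-methylacetamide
      ethyl_benzoate = "CCOC(=O)c1ccccc1",
      furan = "c1ccoc1",
      pyridine = "c1ccncc1",
      aniline = "Nc1ccccc1",
      ethylamine = "NCC",
      tma = "C[N+](C)(C)C",                 # tetramethylammonium
      guanidine = "NC(=N)N",
      morphine = "CN1CC[C@]23c4c5ccc(O)c4O[C@H]2[C@@H](O)C=C[C@H]3[C@H]1C5"
    )
    recs <- parse_smiles(unname(smi), names(smi))
    names(recs) <- vapply(recs, `[[`, "", "id")
    .fixture_cache$mols <- recs
  }
  .fixture_cache$mols
}

# give a molecule a deterministic conformer when feature geometry is needed
with_conformer <- function(mol, seed = 1L) {
  if (length(mol$conformers)) mol else toy_embed(mol, seed)
}

# a small rigid 4-point pharmacophore query for matcher tests
toy_query <- function(kinds = c("HBA", "HY", "HY", "AR"),
                      centers = rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0), c(2.5, 2.5, 1)),
                      radius = 1.5, exclusion = NULL) {
  pharmacophore_query(data.frame(
    kind = kinds, x = centers[, 1], y = centers[, 2], z = centers[, 3],
    radius = radius, label = paste0("F", seq_along(kinds))), exclusion)
}
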