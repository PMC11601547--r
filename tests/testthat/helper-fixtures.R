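# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_cache))
    assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

fx_chiral <- function() fixture("chiral", function()
  makeToyComplex(toySpec(ligand = "chiral_R")))

fx_stereo <- function() fixture("stereo", function()
  makeToyComplex(toySpec(ligand = "stereo_E")))

fx_stereoZ <- function() fixture("stereoZ", function()
  makeToyComplex(toySpec(ligand = "stereo_Z")))

fx_dimer <- function() fixture("dimer", function()
  makeToyComplex(toySpec(n_chains = 2, chain_length = 6,
                         symmetric = TRUE)))

fx_hetero <- function() fixture("hetero", function()
  makeToyComplex(toySpec(n_chains = 2, symmetric = FALSE)))

fx_covalent <- function() fixture("covalent", function()
  makeToyComplex(toySpec(n_chains = 1, ligand = "chiral_R",
                         covalent_link = TRUE)))

fx_pocket <- function() fixture("pocket", function()
  makeToyComplex(toySpec(n_chains = 1, chain_length = 6,
                         ligand = "chiral_R", ligand_gap = 4)))

# every violation kind with its fixture and the energy component /
# quality check it must hit
violation_cases <- function() list(
  chiral_flip = list(fx = fx_chiral(), component = "chiral",
                     check = "chirality_ok"),
  stereo_flip = list(fx = fx_stereo(), component = "stereo",
                     check = "stereo_ok"),
  nonplanar = list(fx = fx_stereo(), component = "planar", check = NA),
  bond_stretch = list(fx = fx_stereo(), component = "geom",
                      check = "bond_lengths_ok"),
  internal_clash = list(fx = fx_stereo(), component = "geom",
                        check = "internal_clash_ok"),
  interchain_clash = list(fx = fx_hetero(), component = "clash",
                          check = "interchain_clash_ok"),
  chain_overlap = list(fx = fx_dimer(), component = "overlap", check = NA),
  covalent_break = list(fx = fx_covalent(), component = "covalent",
                        check = NA))

extdata <- function(f) system.file("extdata", f, package = "steerkit")

# quiet wrapper around parseStructure (bio3d's cif reader tags itself beta)
parseQuiet <- function(...) suppressWarnings(parseStructure(...))

centroid_separation <- function(x, sym_pair) {
  sqrt(sum((colMeans(x[sym_pair$A, , drop = FALSE]) -
            colMeans(x[sym_pair$B, , drop = FALSE]))^2))
}
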