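# a small complex with an anchor chain and a 4-membered carbon ring ligand
# (cyclobutane-like), whose bonded graph has 8 automorphisms
ring_fixture <- function() {
  ring <- cbind(c(1.1, 0, -1.1, 0), c(0, 1.1, 0, -1.1), 0)
  anchor <- cbind(c(0, 2, 4, 6), 8, c(0, 1, 0, 1))
  atoms <- data.frame(
    atom_name = c(paste0("CA"), "CA", "CA", "CA", paste0("C", 1:4)),
    element = "C",
    x = c(anchor[, 1], ring[, 1]),
    y = c(anchor[, 2], ring[, 2]),
    z = c(anchor[, 3], ring[, 3]),
    chain_id = rep(c("P", "RNG"), each = 4),
    res_idx = c(1:4, rep(1L, 4)),
    res_name = rep(c("ALA", "LIG"), each = 4))
  bonds <- data.frame(i = c(5, 6, 7, 8, 1, 2, 3),
                      j = c(6, 7, 8, 5, 2, 3, 4))
  complexStructure(atoms, bonds = bonds,
                   entity_types = c(RNG = "nonpolymer"))
}

test_that("LDDT is 1 for identity, 0 for destroyed geometry", {
  x <- coords(fx_dimer()$complex)
  res <- atoms(fx_dimer()$complex)$res_idx
  key <- as.integer(factor(paste(atoms(fx_dimer()$complex)$chain_id, res)))
  expect_equal(lddt(x, x, key), 1)
  set.seed(8)
  blown <- x * 40 + matrix(rnorm(length(x), sd = 30), nrow(x))
  expect_lt(lddt(blown, x, key), 0.05)
  expect_error(lddt(x[1:2, ], x[1:2, ], c(1L, 1L)), "no qualifying")
})

test_that("LDDT of a hand-computable 3-atom case", {
  ref <- rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0))
  pred <- ref; pred[3, 1] <- 7.5
  # inclusion radius 5: pairs (1,2) and (2,3) qualify; (1,3) excluded.
  # (2,3) is off by 1.5 -> passes thresholds 2 and 4 only.
  # per-threshold fractions (1/2, 1/2, 1, 1) -> 0.75
  expect_equal(lddt(pred, ref, 1:3, inclusion_radius = 5), 0.75)
})

test_that("symmetry correction is the identity without symmetric entities", {
  fx <- fx_hetero()
  sc <- greedySymmetryCorrection(fx$complex, fx$complex)
  expect_equal(unname(sc$chain_map), names(sc$chain_map))
  expect_equal(sc$lddt, sc$lddt_identity)
  expect_equal(sc$lddt, 1)
  expect_error(greedySymmetryCorrection(fx$complex, fx$complex,
                                        chain_cap = 0), "caps")
})

test_that("a swapped homodimer is recovered by the chain stage", {
  fx <- fx_dimer()
  ref <- fx$complex
  pred <- ref
  xyz <- coords(ref)
  A <- which(atoms(ref)$chain_id == "A")
  B <- which(atoms(ref)$chain_id == "B")
  x2 <- xyz; x2[A, ] <- xyz[B, ]; x2[B, ] <- xyz[A, ]
  coords(pred) <- x2
  sc <- greedySymmetryCorrection(pred, ref)
  expect_lt(sc$lddt_identity, 0.95)
  expect_equal(sc$lddt, 1)
  expect_equal(unname(sc$chain_map[c("A", "B")]), c("B", "A"))
  # brute force over both assignments agrees
  expect_gte(sc$lddt, sc$lddt_identity)
})

test_that("ligand automorphisms are found and equal exhaustive search", {
  x <- ring_fixture()
  ref <- x
  pred <- x
  xyz <- coords(x)
  ring <- which(atoms(x)$chain_id == "RNG")
  # flip the ring: traverse backwards (1,4,3,2) - a graph automorphism
  flip <- c(1L, 4L, 3L, 2L)
  x2 <- xyz; x2[ring, ] <- xyz[ring[flip], ]
  coords(pred) <- x2
  sc <- greedySymmetryCorrection(pred, ref)
  expect_equal(sc$lddt, 1)
  expect_lt(sc$lddt_identity, 1)

  # exhaustive oracle over all automorphisms of the ring graph
  auts <- steerkit:::.ligandAutomorphisms(ref, "RNG", 1000L)
  expect_equal(length(auts), 8L)
  res_key <- as.integer(factor(paste(atoms(ref)$chain_id,
                                     atoms(ref)$res_idx)))
  best <- max(vapply(auts, function(aut) {
    p <- seq_len(nAtoms(ref)); p[ring] <- ring[aut]
    lddt(coords(pred)[p, ], coords(ref), res_key)
  }, 1))
  expect_equal(sc$lddt, best)
})

test_that("greedy equals brute force on small instances with few permutations", {
  # homodimer (2 chain assignments) x identity ligand: <= 6 permutations
  fx <- fx_dimer()
  ref <- fx$complex
  res_key <- as.integer(factor(paste(atoms(ref)$res_idx,
                                     atoms(ref)$chain_id)))
  set.seed(31)
  for (rep in 1:5) {
    pred <- ref
    coords(pred) <- coords(ref) + 0.4 * matrix(rnorm(3 * nAtoms(ref)),
                                               nAtoms(ref))
    maybe_swap <- sample(c(TRUE, FALSE), 1)
    if (maybe_swap) {
      xyz <- coords(pred)
      A <- which(atoms(ref)$chain_id == "A")
      B <- which(atoms(ref)$chain_id == "B")
      x2 <- xyz; x2[A, ] <- xyz[B, ]; x2[B, ] <- xyz[A, ]
      coords(pred) <- x2
    }
    sc <- greedySymmetryCorrection(pred, ref)
    key <- as.integer(factor(paste(atoms(ref)$chain_id,
                                   atoms(ref)$res_idx)))
    A <- which(atoms(ref)$chain_id == "A")
    B <- which(atoms(ref)$chain_id == "B")
    swap_perm <- seq_len(nAtoms(ref)); swap_perm[A] <- B; swap_perm[B] <- A
    brute <- max(lddt(coords(pred), coords(ref), key),
                 lddt(coords(pred)[swap_perm, ], coords(ref), key))
    expect_equal(sc$lddt, brute, tolerance = 1e-12)
    expect_gte(sc$lddt, sc$lddt_identity)
  }
})

test_that("incremental LDDT updates equal full recomputation", {
  fx <- fx_dimer()
  ref <- coords(fx$complex)
  key <- as.integer(factor(paste(atoms(fx$complex)$chain_id,
                                 atoms(fx$complex)$res_idx)))
  st <- steerkit:::.lddtState(ref, key)
  npairs <- length(st$i) * length(st$thresholds)
  set.seed(12)
  pred <- ref + 0.3 * matrix(rnorm(length(ref)), nrow(ref))
  hits <- steerkit:::.lddtHits(st, pred)$hits
  for (rep in 1:100) {
    sub <- sample(nrow(ref), sample(1:6, 1))
    pred[sub, ] <- pred[sub, ] + 0.5 * matrix(rnorm(3 * length(sub)),
                                              length(sub))
    upd <- steerkit:::.lddtHits(st, pred, subset = sub)
    hits[upd$idx] <- upd$hits
    expect_equal(sum(hits) / npairs, lddt(pred, ref, key),
                 tolerance = 1e-9)
  }
})

test_that("quality report flags exactly the injected defect", {
  for (nm in names(violation_cases())) {
    vc <- violation_cases()[[nm]]
    if (is.na(vc$check)) next
    x2 <- injectViolation(vc$fx, nm)
    ck <- qualityChecks(qualityReport(x2, vc$fx$constraints))
    expect_false(ck[[vc$check]], info = nm)
    expect_true(all(ck[setdiff(names(ck), vc$check)] %in% TRUE),
                info = nm)
  }
  # clean fixtures pass everything
  for (fx in list(fx_chiral(), fx_stereo(), fx_covalent()))
    expect_true(overallPass(qualityReport(fx$complex, fx$constraints)))
  # a ligand without bounds makes geometry checks not-evaluable
  fx <- fx_chiral()
  ann <- fx$manifest$annotations
  ann$L$bounds <- NULL
  cs2 <- buildConstraints(fx$complex, ann)
  ck <- qualityChecks(qualityReport(fx$complex, cs2))
  expect_true(is.na(ck[["bond_lengths_ok"]]))
  expect_true(is.na(ck[["internal_clash_ok"]]))
  expect_false(is.na(ck[["chirality_ok"]]))
})

test_that("interchain clash check flips at 0.75 of summed radii", {
  fx <- fx_hetero()
  for (s in c(0.74, 0.5)) {
    x2 <- injectViolation(fx, "interchain_clash", magnitude = s)
    expect_false(qualityChecks(qualityReport(x2,
                                             fx$constraints))[["interchain_clash_ok"]])
  }
  x3 <- injectViolation(fx, "interchain_clash", magnitude = 0.76)
  expect_true(qualityChecks(qualityReport(x3,
                                          fx$constraints))[["interchain_clash_ok"]])
})

test_that("pocket-aligned RMSD measures ligand displacement", {
  fx <- fx_pocket()
  ref <- fx$complex
  expect_equal(pocketAlignedRmsd(ref, ref, "L"), 0, tolerance = 1e-12)
  # rigid 3 A ligand translation with an exact pocket
  pred <- ref
  xyz <- coords(ref)
  lig <- which(atoms(ref)$chain_id == "L")
  xyz[lig, 1] <- xyz[lig, 1] + 3
  coords(pred) <- xyz
  expect_equal(pocketAlignedRmsd(pred, ref, "L"), 3, tolerance = 1e-9)
  expect_error(pocketAlignedRmsd(pred, ref, "ZZZ"), "not found")

  # flipped symmetric ligand scores 0 after automorphism minimization
  rf <- ring_fixture()
  pred2 <- rf
  xyz2 <- coords(rf)
  ring <- which(atoms(rf)$chain_id == "RNG")
  xyz2[ring, ] <- xyz2[ring[c(1, 4, 3, 2)], ]
  coords(pred2) <- xyz2
  expect_equal(pocketAlignedRmsd(pred2, rf, "RNG", pocket_radius = 20), 0,
               tolerance = 1e-9)
})
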