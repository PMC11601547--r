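test_that("the chain-overlap schedule matches its closed form", {
  expect_equal(overlapSchedule(0), 5)
  expect_equal(overlapSchedule(1), 1)
  expect_equal(overlapSchedule(0.5),
               1 + 4 * (exp(-1) - 1) / (exp(-2) - 1))
  grid <- seq(0, 1, length.out = 1000)
  expect_true(all(diff(overlapSchedule(grid)) < 0))
  expect_error(overlapSchedule(-0.01), "\\[0, 1\\]")
  expect_error(overlapSchedule(1.01), "\\[0, 1\\]")
})

test_that("buildConstraints assembles the right constraint classes", {
  fx <- fx_dimer()
  cs <- fx$constraints
  expect_equal(nrow(cs@chiralR) + nrow(cs@chiralS) + nrow(cs@stereoE) +
               nrow(cs@stereoZ) + nrow(cs@planar), 0L)
  a <- atoms(fx$complex)
  nA <- sum(a$chain_id == "A"); nB <- sum(a$chain_id == "B")
  expect_equal(nrow(cs@crossPairs), nA * nB)
  expect_equal(length(cs@symPairs), 1L)   # homodimer: one symmetric pair

  expect_equal(nrow(fx_chiral()$constraints@chiralR), 1L)

  # covalent cross-chain bonds excluded from clash pairs
  fv <- fx_covalent()
  cb <- fv$constraints@covalentBonds
  expect_equal(nrow(cb), 1L)
  key <- paste(pmin(cb[, 1], cb[, 2]), pmax(cb[, 1], cb[, 2]))
  cp <- fv$constraints@crossPairs
  expect_false(key %in% paste(pmin(cp$i, cp$j), pmax(cp$i, cp$j)))

  # malformed annotations
  ann <- fx_chiral()$manifest$annotations
  ann$L$chiral_R[1, 1] <- 99999L
  expect_error(buildConstraints(fx_chiral()$complex, ann), "missing atom")
  ann <- fx_chiral()$manifest$annotations
  ann$L$bounds$L[2, 3] <- ann$L$bounds$U[2, 3] + 1
  expect_error(buildConstraints(fx_chiral()$complex, ann), "L > U")
})

test_that("satisfied fixtures have exactly zero energy in every component", {
  for (fx in list(fx_chiral(), fx_stereo(), fx_stereoZ(), fx_dimer(),
                  fx_hetero(), fx_covalent()))
    for (t in c(0, 0.25, 0.5, 1))
      expect_true(all(energyComponents(coords(fx$complex),
                                       fx$constraints, t) == 0))
})

test_that("hinge thresholds reproduce the printed closed forms", {
  # two-atom cross-chain system at a controlled multiple of r_i + r_j
  two <- function(s) {
    rsum <- 2 * vdwRadius("C")
    a <- data.frame(atom_name = "CA", element = "C",
                    x = c(0, s * rsum), y = 0, z = 0,
                    chain_id = c("A", "B"), res_idx = 1L, res_name = "ALA")
    x <- complexStructure(a)
    energyComponents(coords(x), buildConstraints(x), 0)[["clash"]]
  }
  rsum <- 2 * vdwRadius("C")
  expect_equal(two(0.725), 0)
  expect_equal(two(0.5), 0.225 * rsum)
  expect_equal(two(0.3625), 0.3625 * rsum)
  expect_gt(two(0.7249), 0)

  # covalent hinge at 2 A; unit-weight total 1.0 at 3 A
  fx <- fx_covalent()
  cb <- fx$constraints@covalentBonds[1, ]
  xyz <- coords(fx$complex)
  u <- (xyz[cb[2], ] - xyz[cb[1], ])
  u <- u / sqrt(sum(u^2))
  stretch <- function(d) {
    x2 <- xyz
    lig <- which(atoms(fx$complex)$chain_id == "L")
    x2[lig, ] <- sweep(x2[lig, , drop = FALSE], 2,
                       (d - sqrt(sum((xyz[cb[2], ] - xyz[cb[1], ])^2))) * u,
                       "+")
    x2
  }
  expect_equal(energyComponents(stretch(3), fx$constraints, 0)[["covalent"]],
               1.0)
  expect_equal(energyComponents(stretch(1.99),
                                fx$constraints, 0)[["covalent"]], 0)

  # coincident symmetric chains: overlap equals b_t exactly
  fd <- fx_dimer()
  xo <- coords(injectViolation(fd, "chain_overlap", magnitude = 0))
  for (t in c(0, 0.4, 1))
    expect_equal(energyComponents(xo, fd$constraints, t)[["overlap"]],
                 overlapSchedule(t))
})

test_that("the clash term is gated to t < t_clash in the total", {
  fx <- fx_hetero()
  x2 <- coords(injectViolation(fx, "interchain_clash"))
  w <- potentialWeights()     # t_clash = 0.5
  expect_gt(totalEnergy(x2, fx$constraints, w, t = 0.49), 0)
  expect_equal(totalEnergy(x2, fx$constraints, w, t = 0.5), 0)
  expect_equal(totalEnergy(x2, fx$constraints, w, t = 0.9), 0)
  # components themselves report the ungated value
  expect_gt(energyComponents(x2, fx$constraints, 0.9)[["clash"]], 0)
})

test_that("components are rigid invariants and monotone in violation size", {
  fx <- fx_stereo()
  x <- coords(injectViolation(fx, "stereo_flip"))
  set.seed(11)
  e0 <- energyComponents(x, fx$constraints, 0.3)
  for (rep in 1:10) {
    R <- randomRotation(); tv <- rnorm(3, sd = 5)
    e1 <- energyComponents(sweep(x %*% t(R), 2, tv, "+"),
                           fx$constraints, 0.3)
    expect_equal(e1, e0, tolerance = 1e-9)
  }
  # monotonicity: growing a single covalent stretch never lowers its term
  fv <- fx_covalent()
  lig <- which(atoms(fv$complex)$chain_id == "L")
  es <- vapply(seq(0, 4, length.out = 30), function(d) {
    x2 <- coords(injectViolation(fv, "covalent_break", magnitude = d))
    energyComponents(x2, fv$constraints, 0)[["covalent"]]
  }, 1)
  expect_true(all(diff(es) >= -1e-12))
  # and a deepening clash never lowers the clash term
  ec <- vapply(seq(0.7, 0.2, length.out = 20), function(s) {
    x2 <- coords(injectViolation(fx_hetero(), "interchain_clash",
                                 magnitude = s))
    energyComponents(x2, fx_hetero()$constraints, 0)[["clash"]]
  }, 1)
  expect_true(all(diff(ec) >= -1e-12))
})

test_that("every injected violation raises exactly its own component", {
  for (nm in names(violation_cases())) {
    vc <- violation_cases()[[nm]]
    x2 <- injectViolation(vc$fx, nm)
    e <- energyComponents(coords(x2), vc$fx$constraints, 0.3)
    expect_gt(e[[vc$component]], 0)
    expect_true(all(e[setdiff(names(e), vc$component)] < 1e-9),
                info = nm)
  }
})

test_that("analytic gradients match finite differences off the hinge set", {
  h <- 1e-6
  w <- potentialWeights()
  for (nm in c("stereo_flip", "chain_overlap", "covalent_break",
               "interchain_clash")) {
    vc <- violation_cases()[[nm]]
    x <- coords(injectViolation(vc$fx, nm))
    set.seed(7)
    x <- x + 0.03 * matrix(rnorm(length(x)), nrow(x))  # move off kinks
    g <- gradTotalEnergy(x, vc$fx$constraints, w, t = 0.3)
    idx <- sample(nrow(x), min(10, nrow(x)))
    for (i in idx) for (d in 1:3) {
      xp <- x; xp[i, d] <- xp[i, d] + h
      xm <- x; xm[i, d] <- xm[i, d] - h
      num <- (totalEnergy(xp, vc$fx$constraints, w, 0.3) -
              totalEnergy(xm, vc$fx$constraints, w, 0.3)) / (2 * h)
      expect_equal(g[i, d], num, tolerance = 1e-4 * max(1, abs(num)))
    }
  }
})

test_that("the gradient vanishes on satisfied fixtures and points along bonds", {
  fx <- fx_covalent()
  expect_true(all(gradTotalEnergy(coords(fx$complex), fx$constraints,
                                  t = 0.3) == 0))
  # stretched covalent bond: equal and opposite forces along the bond axis
  x2 <- coords(injectViolation(fx, "covalent_break"))
  cb <- fx$constraints@covalentBonds[1, ]
  lig_only <- new("ConstraintSet", chiralR = matrix(integer(0), ncol = 4),
                  chiralS = matrix(integer(0), ncol = 4),
                  stereoE = matrix(integer(0), ncol = 4),
                  stereoZ = matrix(integer(0), ncol = 4),
                  planar = matrix(integer(0), ncol = 4),
                  ligands = list(),
                  crossPairs = data.frame(i = integer(0), j = integer(0),
                                          rsum = numeric(0)),
                  symPairs = list(), covalentBonds = rbind(cb))
  g <- gradTotalEnergy(x2, lig_only, potentialWeights(), t = 0.3)
  u <- unname(x2[cb[2], ] - x2[cb[1], ]); u <- u / sqrt(sum(u^2))
  expect_equal(g[cb[1], ], -u, tolerance = 1e-9)
  expect_equal(g[cb[2], ], u, tolerance = 1e-9)
  expect_true(all(g[-c(cb), ] == 0))
})
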