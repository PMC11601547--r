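## The seven flat-bottom constraint potentials, their time-weighted sum,
## and analytic gradients.

#' Potential weights
#'
#' Weights of the combined steering potential.  The steric-clash term is
#' gated to late diffusion times (\code{t < t_clash}); the chain-overlap
#' term carries its own time dependence through \code{\link{overlapSchedule}}.
#'
#' @param alpha_chiral,alpha_stereo,alpha_planar,alpha_geom,alpha_clash,alpha_overlap,alpha_covalent
#'   non-negative component weights (default 1).
#' @param t_clash diffusion time below which the clash term is active
#'   (default 0.5, the schedule midpoint).
#' @param lambda global tilt strength of the steered target distribution
#'   (default 2).
#' @return list of class \code{potential_weights}
#' @export
potentialWeights <- function(alpha_chiral = 1, alpha_stereo = 1,
                             alpha_planar = 1, alpha_geom = 1,
                             alpha_clash = 1, alpha_overlap = 1,
                             alpha_covalent = 1, t_clash = 0.5,
                             lambda = 2) {
  w <- list(alpha_chiral = alpha_chiral, alpha_stereo = alpha_stereo,
            alpha_planar = alpha_planar, alpha_geom = alpha_geom,
            alpha_clash = alpha_clash, alpha_overlap = alpha_overlap,
            alpha_covalent = alpha_covalent, t_clash = t_clash,
            lambda = lambda)
  stopifnot(all(unlist(w[1:7]) >= 0), lambda >= 0)
  structure(w, class = "potential_weights")
}

#' Chain-overlap distance schedule
#'
#' Minimum allowed centroid separation between symmetric chains as a
#' function of diffusion time, b_t = 1 + 4 (exp(-2(1-t)) - 1) /
#' (exp(-2) - 1): monotone from 5 Angstrom at t = 0 (data end) to 1
#' Angstrom at t = 1 (noise end).
#'
#' @param t diffusion time(s) in [0, 1].
#' @return b_t in Angstrom.
#' @export
overlapSchedule <- function(t) {
  if (any(t < 0 | t > 1)) stop("t must lie in [0, 1]")
  1 + 4 * (exp(-2 * (1 - t)) - 1) / (exp(-2) - 1)
}

#' Build a ConstraintSet from a complex and ligand annotations
#'
#' Assembles every constraint class the potentials need: the annotated
#' chirality/stereo/planarity quadruples and distance-geometry bounds per
#' ligand; all resolved heavy-atom pairs across distinct, non-bonded chains
#' (bonded pairs, including covalent cross-chain bonds, are excluded) with
#' their summed Van der Waals radii; pairs of symmetric chains (same
#' entity, more than one atom); and inter-chain covalent bonds taken from
#' the complex's bond table.
#'
#' @param x a \linkS4class{ComplexStructure}.
#' @param ligand_annotations named list (by ligand chain id); each element
#'   may contain \code{chiral_R}, \code{chiral_S}, \code{stereo_E},
#'   \code{stereo_Z}, \code{planar} (k x 4 matrices of atom row indices)
#'   and \code{bounds} = list(\code{L}, \code{U}, \code{bond_pairs},
#'   \code{angle_pairs}) over the ligand's heavy atoms in chain order.
#' @return a \linkS4class{ConstraintSet}
#' @export
buildConstraints <- function(x, ligand_annotations = list()) {
  a <- atoms(x)
  n <- nrow(a)
  quads <- list(chiral_R = emptyQuad(), chiral_S = emptyQuad(),
                stereo_E = emptyQuad(), stereo_Z = emptyQuad(),
                planar = emptyQuad())
  ligands <- list()
  for (cid in names(ligand_annotations)) {
    ann <- ligand_annotations[[cid]]
    for (nm in names(quads)) {
      q <- ann[[nm]]
      if (!is.null(q) && nrow(q)) {
        if (any(q < 1 | q > n))
          stop("quadruple in ", nm, " references a missing atom")
        quads[[nm]] <- rbind(quads[[nm]], q)
      }
    }
    if (!is.null(ann$bounds)) {
      b <- ann$bounds
      if (any(b$L > b$U + 1e-9)) stop("bounds with L > U for ligand ", cid)
      lig_atoms <- which(a$chain_id == cid & a$is_heavy)
      ligands[[cid]] <- list(atom_idx = lig_atoms, L = b$L, U = b$U,
                             bond_pairs = b$bond_pairs,
                             angle_pairs = b$angle_pairs)
    }
  }

  # cross-chain non-bonded resolved heavy pairs
  bnd <- bonds(x)
  bonded_key <- if (nrow(bnd))
    paste(pmin(bnd$i, bnd$j), pmax(bnd$i, bnd$j)) else character(0)
  keep <- which(a$is_heavy & a$is_resolved)
  cross <- data.frame(i = integer(0), j = integer(0), rsum = numeric(0))
  if (length(keep) > 1) {
    cid <- a$chain_id[keep]
    pr <- which(outer(cid, cid, "!=") & upper.tri(diag(length(keep))),
                arr.ind = TRUE)
    if (nrow(pr)) {
      i <- keep[pr[, 1]]; j <- keep[pr[, 2]]
      key <- paste(pmin(i, j), pmax(i, j))
      ok <- !(key %in% bonded_key)
      cross <- data.frame(i = i[ok], j = j[ok],
                          rsum = a$vdw_radius[i[ok]] + a$vdw_radius[j[ok]])
    }
  }

  # symmetric chain pairs: same entity, > 1 atom
  ch <- chains(x)
  sym <- list()
  for (eid in unique(ch$entity_id)) {
    ids <- ch$chain_id[ch$entity_id == eid]
    if (length(ids) < 2) next
    for (u in seq_along(ids)) for (v in seq_len(u - 1L)) {
      A <- which(a$chain_id == ids[v] & a$is_resolved & a$is_heavy)
      B <- which(a$chain_id == ids[u] & a$is_resolved & a$is_heavy)
      if (length(A) > 1 && length(B) > 1)
        sym[[length(sym) + 1L]] <- list(A = A, B = B, chainA = ids[v],
                                        chainB = ids[u])
    }
  }

  cov <- if (nrow(bnd)) as.matrix(bnd[bnd$inter_chain, c("i", "j"),
                                      drop = FALSE])
         else matrix(integer(0), ncol = 2)
  new("ConstraintSet", chiralR = quads$chiral_R, chiralS = quads$chiral_S,
      stereoE = quads$stereo_E, stereoZ = quads$stereo_Z,
      planar = quads$planar, ligands = ligands, crossPairs = cross,
      symPairs = sym, covalentBonds = unname(cov))
}

.pairDist <- function(x, ij) {
  d <- x[ij[, 1], , drop = FALSE] - x[ij[, 2], , drop = FALSE]
  sqrt(rowSums(d * d))
}

# angle magnitude |phi| for quadruple rows
.quadAngles <- function(x, q) {
  vapply(seq_len(nrow(q)), function(k)
    dihedralAngle(x[q[k, 1], ], x[q[k, 2], ], x[q[k, 3], ], x[q[k, 4], ]),
    1)
}

# Distance-geometry hinge for one ligand: sum over all heavy-atom pairs of
# max(d - 1.2 U, 0) + max(0.8 L - d, 0).  Identical hinge for the bond,
# angle and remaining pair classes; the class split only matters for the
# quality checks.
.ligandGeomEnergy <- function(x, lg) {
  sub <- x[lg$atom_idx, , drop = FALSE]
  D <- as.matrix(stats::dist(sub))
  up <- upper.tri(D)
  over <- ifelse(is.finite(lg$U), pmax(D - 1.2 * lg$U, 0), 0)
  under <- pmax(0.8 * lg$L - D, 0)
  sum((over + under)[up])
}

#' Per-component constraint energies
#'
#' Evaluates the seven flat-bottom potentials at coordinates \code{x}.
#' Every component is non-negative and exactly zero when its constraints
#' are satisfied.  Dihedral-based terms: the chiral improper keeps its sign
#' (R centers require phi >= pi/6, S centers phi <= -pi/6); stereo and
#' planarity use the torsion magnitude (E: |phi| >= 5 pi/6, Z: |phi| <=
#' pi/6, planar: |phi| <= pi/12).  The geometry term hinges at 0.8 L and
#' 1.2 U of the distance-geometry bounds; clash at 0.725 of the summed Van
#' der Waals radii; chain overlap at the time-dependent centroid distance
#' \code{\link{overlapSchedule}}; covalent cross-chain bonds at 2 Angstrom.
#'
#' @param x N x 3 coordinate matrix.
#' @param constraints a \linkS4class{ConstraintSet}.
#' @param t diffusion time in [0, 1] (enters only the overlap schedule).
#' @return named numeric vector: \code{chiral}, \code{stereo},
#'   \code{planar}, \code{geom}, \code{clash}, \code{overlap},
#'   \code{covalent}.
#' @export
energyComponents <- function(x, constraints, t = 0) {
  cs <- constraints
  e <- c(chiral = 0, stereo = 0, planar = 0, geom = 0, clash = 0,
         overlap = 0, covalent = 0)
  if (nrow(cs@chiralR))
    e["chiral"] <- e["chiral"] +
      sum(pmax(pi / 6 - .quadAngles(x, cs@chiralR), 0))
  if (nrow(cs@chiralS))
    e["chiral"] <- e["chiral"] +
      sum(pmax(pi / 6 + .quadAngles(x, cs@chiralS), 0))
  if (nrow(cs@stereoE))
    e["stereo"] <- e["stereo"] +
      sum(pmax(5 * pi / 6 - abs(.quadAngles(x, cs@stereoE)), 0))
  if (nrow(cs@stereoZ))
    e["stereo"] <- e["stereo"] +
      sum(pmax(abs(.quadAngles(x, cs@stereoZ)) - pi / 6, 0))
  if (nrow(cs@planar))
    e["planar"] <- sum(pmax(abs(.quadAngles(x, cs@planar)) - pi / 12, 0))
  for (lg in cs@ligands)
    e["geom"] <- e["geom"] + .ligandGeomEnergy(x, lg)
  if (nrow(cs@crossPairs)) {
    d <- .pairDist(x, as.matrix(cs@crossPairs[, c("i", "j")]))
    e["clash"] <- sum(pmax(0.725 * cs@crossPairs$rsum - d, 0))
  }
  if (length(cs@symPairs)) {
    bt <- overlapSchedule(t)
    for (sp in cs@symPairs) {
      d <- sqrt(sum((colMeans(x[sp$A, , drop = FALSE]) -
                     colMeans(x[sp$B, , drop = FALSE]))^2))
      e["overlap"] <- e["overlap"] + max(bt - d, 0)
    }
  }
  if (nrow(cs@covalentBonds)) {
    d <- .pairDist(x, cs@covalentBonds)
    e["covalent"] <- sum(pmax(d - 2, 0))
  }
  e
}

#' Combined steering potential
#'
#' Weighted sum of the component energies; the clash term only
#' contributes while \code{t < t_clash}.
#'
#' @inheritParams energyComponents
#' @param weights a \code{\link{potentialWeights}} list.
#' @return scalar energy.
#' @export
totalEnergy <- function(x, constraints, weights = potentialWeights(),
                        t = 0) {
  e <- energyComponents(x, constraints, t)
  w <- weights
  w$alpha_chiral * e[["chiral"]] + w$alpha_stereo * e[["stereo"]] +
    w$alpha_planar * e[["planar"]] + w$alpha_geom * e[["geom"]] +
    (if (t < w$t_clash) w$alpha_clash else 0) * e[["clash"]] +
    w$alpha_overlap * e[["overlap"]] + w$alpha_covalent * e[["covalent"]]
}

# accumulate the gradient of a hinge on the distance between atoms i and j:
# dE/dd = slope when active
.accumPairGrad <- function(g, x, i, j, slope) {
  u <- x[i, ] - x[j, ]
  dn <- sqrt(sum(u * u))
  if (dn < 1e-12) return(g)        # subgradient 0 at coincident points
  u <- u / dn
  g[i, ] <- g[i, ] + slope * u
  g[j, ] <- g[j, ] - slope * u
  g
}

.accumQuadGrad <- function(g, x, q, dEdphi_fun) {
  for (k in seq_len(nrow(q))) {
    idx <- q[k, ]
    phi <- dihedralAngle(x[idx[1], ], x[idx[2], ], x[idx[3], ], x[idx[4], ])
    s <- dEdphi_fun(phi)
    if (s != 0) {
      dg <- .dihedralGrad(x[idx[1], ], x[idx[2], ], x[idx[3], ], x[idx[4], ])
      g[idx, ] <- g[idx, ] + s * dg
    }
  }
  g
}

#' Gradient of the combined steering potential
#'
#' Analytic gradient of \code{\link{totalEnergy}} with respect to all
#' coordinates; exactly zero inside the feasible region, with the
#' subgradient 0 chosen at hinge kinks.
#'
#' @inheritParams totalEnergy
#' @return N x 3 gradient matrix.
#' @export
gradTotalEnergy <- function(x, constraints, weights = potentialWeights(),
                            t = 0) {
  cs <- constraints
  w <- weights
  g <- matrix(0, nrow(x), 3)
  if (w$alpha_chiral > 0) {
    g <- .accumQuadGrad(g, x, cs@chiralR, function(phi)
      if (phi < pi / 6) -w$alpha_chiral else 0)
    g <- .accumQuadGrad(g, x, cs@chiralS, function(phi)
      if (phi > -pi / 6) w$alpha_chiral else 0)
  }
  if (w$alpha_stereo > 0) {
    g <- .accumQuadGrad(g, x, cs@stereoE, function(phi)
      if (abs(phi) < 5 * pi / 6) -w$alpha_stereo * sign(phi) else 0)
    g <- .accumQuadGrad(g, x, cs@stereoZ, function(phi)
      if (abs(phi) > pi / 6) w$alpha_stereo * sign(phi) else 0)
  }
  if (w$alpha_planar > 0)
    g <- .accumQuadGrad(g, x, cs@planar, function(phi)
      if (abs(phi) > pi / 12) w$alpha_planar * sign(phi) else 0)
  if (w$alpha_geom > 0) for (lg in cs@ligands) {
    ai <- lg$atom_idx
    nl <- length(ai)
    for (p in seq_len(nl - 1)) for (q in seq(p + 1, nl)) {
      d <- sqrt(sum((x[ai[p], ] - x[ai[q], ])^2))
      slope <- 0
      if (is.finite(lg$U[p, q]) && d > 1.2 * lg$U[p, q])
        slope <- slope + 1
      if (d < 0.8 * lg$L[p, q]) slope <- slope - 1
      if (slope != 0)
        g <- .accumPairGrad(g, x, ai[p], ai[q], w$alpha_geom * slope)
    }
  }
  if (t < w$t_clash && w$alpha_clash > 0 && nrow(cs@crossPairs)) {
    d <- .pairDist(x, as.matrix(cs@crossPairs[, c("i", "j")]))
    act <- which(d < 0.725 * cs@crossPairs$rsum)
    for (k in act)
      g <- .accumPairGrad(g, x, cs@crossPairs$i[k], cs@crossPairs$j[k],
                          -w$alpha_clash)
  }
  if (w$alpha_overlap > 0 && length(cs@symPairs)) {
    bt <- overlapSchedule(t)
    for (sp in cs@symPairs) {
      cA <- colMeans(x[sp$A, , drop = FALSE])
      cB <- colMeans(x[sp$B, , drop = FALSE])
      dv <- cA - cB
      dn <- sqrt(sum(dv * dv))
      if (dn < bt && dn > 1e-12) {
        u <- dv / dn
        g[sp$A, ] <- g[sp$A, ] +
          matrix(-w$alpha_overlap * u / length(sp$A), length(sp$A), 3,
                 byrow = TRUE)
        g[sp$B, ] <- g[sp$B, ] +
          matrix(w$alpha_overlap * u / length(sp$B), length(sp$B), 3,
                 byrow = TRUE)
      }
    }
  }
  if (w$alpha_covalent > 0 && nrow(cs@covalentBonds)) {
    d <- .pairDist(x, cs@covalentBonds)
    act <- which(d > 2)
    for (k in act)
      g <- .accumPairGrad(g, x, cs@covalentBonds[k, 1],
                          cs@covalentBonds[k, 2], w$alpha_covalent)
  }
  g
}
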