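## Synthetic fixtures: toy complexes with known constraint annotations,
## surgical violation injection, and toy denoisers.  Everything here is
## deterministic under a seed, and every generated fixture satisfies its
## own ConstraintSet exactly (all seven energy components zero).

.rotZ <- function(theta)
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1),
         3, 3)

# Rotation about an arbitrary axis (Rodrigues).
.rotAxis <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Idealized helical C-alpha + sidechain-centroid chain: radius 2.3 A,
# rise 1.5 A and 100 degrees per residue; CB sits 1.5 A radially out.
.helixChain <- function(length, chain_id) {
  ang <- (seq_len(length) - 1) * 100 * pi / 180
  z <- (seq_len(length) - 1) * 1.5
  ca <- cbind(2.3 * cos(ang), 2.3 * sin(ang), z)
  cb <- cbind(3.8 * cos(ang), 3.8 * sin(ang), z)
  atoms <- data.frame(
    atom_name = rep(c("CA", "CB"), length),
    element = "C",
    x = as.vector(rbind(ca[, 1], cb[, 1])),
    y = as.vector(rbind(ca[, 2], cb[, 2])),
    z = as.vector(rbind(ca[, 3], cb[, 3])),
    chain_id = chain_id,
    res_idx = rep(seq_len(length), each = 2),
    res_name = "ALA", stringsAsFactors = FALSE)
  bonds <- rbind(
    cbind(seq(1, 2 * length, 2), seq(2, 2 * length, 2)),      # CA-CB
    if (length > 1) cbind(seq(1, 2 * (length - 1), 2),
                          seq(3, 2 * length, 2)))             # CA-CA
  list(atoms = atoms, bonds = bonds)
}

# In-plane sp2 substituent position: bond of given length from parent P,
# at ~110 degrees from the P->G bond, pointing away from atom `away`.
.armPosition <- function(P, G, away, bond_length) {
  v <- (G - P) / sqrt(sum((G - P)^2))
  cand <- lapply(c(110, -110) * pi / 180, function(th)
    P + bond_length * as.vector(.rotZ(th) %*% v))
  d <- vapply(cand, function(p) sum((p - away)^2), 1)
  cand[[which.max(d)]]
}

# Ligand templates in a local frame.  Returns atoms (element, coords),
# bonds (local k x 2), and local quadruples per constraint class.
.ligandTemplate <- function(kind) {
  if (kind %in% c("chiral_R", "chiral_S")) {
    # tetrahedral center Z with substituents Cl > O > N > C (CIP order)
    dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                  c(-1, -1, 1)) / sqrt(3)
    xyz <- rbind(c(0, 0, 0), 1.8 * dirs)
    elements <- c("C", "Cl", "O", "N", "C")
    quad <- matrix(c(2L, 3L, 4L, 1L), 1)        # (A, B, C, Z)
    phi <- dihedralAngle(xyz[2, ], xyz[3, ], xyz[4, ], xyz[1, ])
    want_pos <- kind == "chiral_R"
    if ((phi > 0) != want_pos) xyz[, 3] <- -xyz[, 3]
    list(elements = elements, xyz = xyz,
         bonds = cbind(1L, 2:5),
         quads = if (want_pos) list(chiral_R = quad)
                 else list(chiral_S = quad),
         link_atom = 5L)
  } else if (kind %in% c("stereo_E", "stereo_Z", "planar")) {
    # C1=C2 with substituents O3 (A1), C4 (B1) on C1 and O5 (A2), C6 (B2)
    # on C2, plus arms N7 on C4 and O8 on C6 (for clash/stretch probes)
    C1 <- c(0, 0, 0); C2 <- c(1.33, 0, 0)
    O3 <- 1.35 * c(cos(2 * pi / 3), sin(2 * pi / 3), 0)
    C4 <- 1.50 * c(cos(4 * pi / 3), sin(4 * pi / 3), 0)
    if (kind == "stereo_Z") {       # higher-priority O atoms cis
      O5 <- C2 + 1.35 * c(cos(pi / 3), sin(pi / 3), 0)
      C6 <- C2 + 1.50 * c(cos(-pi / 3), sin(-pi / 3), 0)
    } else {                        # E: O atoms trans
      O5 <- C2 + 1.35 * c(cos(-pi / 3), sin(-pi / 3), 0)
      C6 <- C2 + 1.50 * c(cos(pi / 3), sin(pi / 3), 0)
    }
    N7 <- .armPosition(C4, C1, C2, 1.47)
    O8 <- .armPosition(C6, C2, C1, 1.43)
    xyz <- rbind(C1, C2, O3, C4, O5, C6, N7, O8)
    rownames(xyz) <- NULL
    stereoq <- rbind(c(3L, 1L, 2L, 5L),         # (A1, Z1, Z2, A2)
                     c(4L, 1L, 2L, 6L))         # (B1, Z1, Z2, B2)
    planarq <- rbind(c(3L, 4L, 2L, 1L),         # (A1, B1, C2, C1)
                     c(5L, 6L, 1L, 2L))         # (A2, B2, C1, C2)
    quads <- list(planar = planarq)
    if (kind == "stereo_Z") quads$stereo_Z <- stereoq
    else quads$stereo_E <- stereoq
    list(elements = c("C", "C", "O", "C", "O", "C", "N", "O"),
         xyz = xyz,
         bonds = rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 5L),
                       c(2L, 6L), c(4L, 7L), c(6L, 8L)),
         quads = quads, link_atom = 4L)
  } else stop("unknown ligand template: ", kind)
}

# Distance-geometry bounds from a template's ideal geometry: bonds exact,
# 1-3 (angle) pairs with 10% slack, remaining pairs lower-bounded at 3.0 A
# (a typical non-bonded floor) with no upper bound.
.templateBounds <- function(xyz, bonds) {
  n <- nrow(xyz)
  D <- as.matrix(stats::dist(xyz))
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  sp <- igraph::distances(g)
  L <- matrix(0, n, n); U <- matrix(Inf, n, n)
  L[sp == 1] <- D[sp == 1];      U[sp == 1] <- D[sp == 1]
  L[sp == 2] <- 0.9 * D[sp == 2]; U[sp == 2] <- 1.1 * D[sp == 2]
  L[sp > 2] <- 3.0
  diag(L) <- 0; diag(U) <- 0
  pairs_of <- function(k) {
    w <- which(sp == k & upper.tri(sp), arr.ind = TRUE)
    matrix(as.integer(w), ncol = 2)
  }
  list(L = L, U = U, bond_pairs = pairs_of(1), angle_pairs = pairs_of(2))
}

#' Toy-complex specification
#'
#' @param n_chains number of protein chains (>= 1).
#' @param chain_length residues per chain (each residue contributes a
#'   C-alpha and a sidechain-centroid pseudo-atom).
#' @param symmetric if TRUE all chains are identical copies (one entity);
#'   otherwise chain k has \code{chain_length + k - 1} residues (distinct
#'   entities).
#' @param ligand \code{"none"} or one of the annotated templates
#'   \code{"chiral_R"}, \code{"chiral_S"}, \code{"stereo_E"},
#'   \code{"stereo_Z"}, \code{"planar"}.
#' @param covalent_link covalently bond the ligand to the last sidechain
#'   atom of chain A (places the ligand at bond distance)?
#' @param separation distance between consecutive chain axes (Angstrom).
#' @param ligand_gap approximate gap between the ligand and its nearest
#'   chain atom (Angstrom; ignored for covalent fixtures).
#' @param seed integer seed (bitwise reproducibility).
#' @return list of class \code{toy_spec}
#' @export
toySpec <- function(n_chains = 2L, chain_length = 8L, symmetric = TRUE,
                    ligand = "none", covalent_link = FALSE,
                    separation = 12, ligand_gap = 5, seed = 1L) {
  stopifnot(n_chains >= 1, chain_length >= 2, separation >= 0,
            ligand_gap >= 0)
  if (covalent_link && ligand == "none")
    stop("covalent_link requires a ligand")
  structure(list(n_chains = as.integer(n_chains),
                 chain_length = as.integer(chain_length),
                 symmetric = symmetric, ligand = ligand,
                 covalent_link = covalent_link, separation = separation,
                 ligand_gap = ligand_gap, seed = as.integer(seed)),
            class = "toy_spec")
}

#' Generate a toy complex with its constraints
#'
#' Builds an idealized multi-chain complex (helical pseudo-protein chains,
#' optionally one annotated ligand), its \linkS4class{ConstraintSet}, and a
#' manifest of ground-truth labels.  The generated pose satisfies every
#' constraint: all seven energy components evaluate to zero and the
#' physical-quality report passes.
#'
#' @param spec a \code{\link{toySpec}}.
#' @return list with \code{complex} (\linkS4class{ComplexStructure}),
#'   \code{constraints} (\linkS4class{ConstraintSet}) and \code{manifest}
#'   (chain ids, entity grouping, ligand annotation summary, token count).
#' @export
makeToyComplex <- function(spec = toySpec()) {
  chains <- list()
  chain_ids <- LETTERS[seq_len(spec$n_chains)]
  for (k in seq_len(spec$n_chains)) {
    len <- if (spec$symmetric) spec$chain_length
           else spec$chain_length + (k - 1L)
    ch <- .helixChain(len, chain_ids[k])
    ch$atoms$x <- ch$atoms$x + (k - 1) * spec$separation
    chains[[k]] <- ch
  }
  atoms <- do.call(rbind, lapply(chains, `[[`, "atoms"))
  offs <- cumsum(c(0, vapply(chains, function(c) nrow(c$atoms), 1)))
  bonds <- do.call(rbind, lapply(seq_along(chains), function(k)
    chains[[k]]$bonds + offs[k]))

  annotations <- list()
  manifest <- list(chain_ids = chain_ids, ligand_chain = NULL,
                   ligand_kind = spec$ligand,
                   covalent_link = spec$covalent_link)
  if (spec$ligand != "none") {
    tpl <- .ligandTemplate(spec$ligand)
    lig_xyz <- tpl$xyz
    n_prot <- nrow(atoms)
    if (spec$covalent_link) {
      # place the link atom 1.9 A radially out from chain A's last CB
      cb <- as.numeric(atoms[2 * spec$chain_length, c("x", "y", "z")])
      u <- c(cb[1], cb[2], 0)               # radial dir from chain A axis
      u <- u / sqrt(sum(u^2))
      target <- cb + 1.9 * u
      shift <- target - lig_xyz[tpl$link_atom, ]
      # orient so the ligand extends outward
      ctr <- colMeans(lig_xyz)
      out <- ctr - lig_xyz[tpl$link_atom, ]
      R <- .alignVec(out, u)
      lig_xyz <- sweep(lig_xyz, 2, lig_xyz[tpl$link_atom, ]) %*% t(R)
      lig_xyz <- sweep(lig_xyz, 2, target, "+")
    } else {
      # put the ligand centroid out along +y of chain A, leaving roughly
      # ligand_gap of empty space to the nearest chain atom
      ctr <- colMeans(lig_xyz)
      lig_xyz <- sweep(lig_xyz, 2, ctr)
      zmid <- mean(range(atoms$z))
      reach <- max(rowNorms(lig_xyz))
      target <- c(0, 3.8 + spec$ligand_gap + reach, zmid)
      lig_xyz <- sweep(lig_xyz, 2, target, "+")
    }
    lig_atoms <- data.frame(
      atom_name = paste0(tpl$elements, seq_along(tpl$elements)),
      element = tpl$elements,
      x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
      chain_id = "L", res_idx = 1L, res_name = "LIG",
      stringsAsFactors = FALSE)
    atoms <- rbind(atoms, lig_atoms)
    bonds <- rbind(bonds, tpl$bonds + n_prot)
    if (spec$covalent_link)
      bonds <- rbind(bonds, c(2L * spec$chain_length,
                              n_prot + tpl$link_atom))
    quads_global <- lapply(tpl$quads, function(q) q + n_prot)
    annotations$L <- c(quads_global,
                         list(bounds = .templateBounds(tpl$xyz, tpl$bonds)))
    manifest$ligand_chain <- "L"
    manifest$link_atoms <- if (spec$covalent_link)
      c(2L * spec$chain_length, n_prot + tpl$link_atom) else NULL
  }

  cmplx <- complexStructure(
    atoms, bonds = data.frame(i = bonds[, 1], j = bonds[, 2]),
    entity_types = if (spec$ligand != "none") c(L = "nonpolymer"))
  constraints <- buildConstraints(cmplx, annotations)
  manifest$entity_ids <- chains(cmplx)$entity_id
  manifest$n_tokens <- if (spec$ligand != "none")
    sum(vapply(chains, function(c) max(c$atoms$res_idx), 1)) +
      sum(.ligandTemplate(spec$ligand)$elements != "H")
  else sum(vapply(chains, function(c) max(c$atoms$res_idx), 1))
  manifest$annotations <- annotations
  list(complex = cmplx, constraints = constraints, manifest = manifest)
}

# rotation taking unit(a) to unit(b)
.alignVec <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite: rotate pi about any perpendicular
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- c(a[2] * p[3] - a[3] * p[2], a[3] * p[1] - a[1] * p[3],
           a[1] * p[2] - a[2] * p[1])
    return(.rotAxis(v, pi))
  }
  .rotAxis(v, atan2(s, cth))
}

#' Inject a single physical violation into a toy complex
#'
#' Perturbs the coordinates so that exactly the targeted energy component
#' becomes positive while all others stay zero (verified by the test
#' suite's post-hoc component checks).  Kinds:
#' \describe{
#'   \item{chiral_flip}{mirror the ligand through a plane (an isometry:
#'     internal distances untouched), inverting its chiral center.}
#'   \item{stereo_flip}{rotate one end of the double bond 180 degrees
#'     about the bond axis (E <-> Z).}
#'   \item{nonplanar}{rotate one sp2 substituent out of plane by
#'     \code{magnitude} degrees (default 30).}
#'   \item{bond_stretch}{stretch a terminal ligand bond by factor
#'     \code{magnitude} (default 1.5).}
#'   \item{internal_clash}{rotate a ligand arm in-plane so it approaches a
#'     non-bonded ligand atom below the distance floor.}
#'   \item{interchain_clash}{translate the last chain toward the first
#'     until the closest cross-chain pair sits at \code{magnitude} times
#'     the summed Van der Waals radii (default 0.5; needs asymmetric
#'     chains so no overlap term exists).}
#'   \item{chain_overlap}{slide the symmetric copy along the helix axis to
#'     centroid separation \code{magnitude} (default 2.6 A: inside the
#'     overlap schedule but with interleaved atoms, so no steric clash;
#'     0 gives exactly coincident centroids).}
#'   \item{covalent_break}{translate the ligand \code{magnitude} A
#'     (default 2.5) along the covalent-bond axis.}
#' }
#'
#' @param fixture list from \code{\link{makeToyComplex}}.
#' @param kind violation kind (see Details).
#' @param magnitude kind-specific size; NULL for the default.
#' @return the perturbed \linkS4class{ComplexStructure}.
#' @export
injectViolation <- function(fixture, kind, magnitude = NULL) {
  x <- fixture$complex
  cs <- fixture$constraints
  a <- atoms(x)
  xyz <- coords(x)
  lig <- which(a$chain_id == "L")
  need_lig <- c("chiral_flip", "stereo_flip", "nonplanar", "bond_stretch",
                "internal_clash", "covalent_break")
  if (kind %in% need_lig && !length(lig))
    stop("no ligand in fixture for violation kind ", kind)

  if (kind == "chiral_flip") {
    if (!nrow(cs@chiralR) && !nrow(cs@chiralS))
      stop("no chiral center in fixture")
    anchor <- if (!is.null(fixture$manifest$link_atoms))
      xyz[fixture$manifest$link_atoms[2], ] else colMeans(xyz[lig, ])
    xyz[lig, 3] <- 2 * anchor[3] - xyz[lig, 3]
  } else if (kind == "stereo_flip") {
    if (!nrow(cs@stereoE) && !nrow(cs@stereoZ))
      stop("no stereo bond in fixture")
    C1 <- xyz[lig[1], ]; C2 <- xyz[lig[2], ]
    side <- lig[c(5, 6, 8)]                    # O5, C6 and its arm O8
    R <- .rotAxis(C2 - C1, pi)
    xyz[side, ] <- sweep(sweep(xyz[side, , drop = FALSE], 2, C2) %*% t(R),
                         2, C2, "+")
  } else if (kind == "nonplanar") {
    if (!nrow(cs@planar)) stop("no planar bond in fixture")
    mag <- (magnitude %||% 30) * pi / 180
    C2 <- xyz[lig[2], ]; C6 <- xyz[lig[6], ]
    R <- .rotAxis(C6 - C2, mag)
    xyz[lig[5], ] <- as.vector((xyz[lig[5], ] - C2) %*% t(R)) + C2
  } else if (kind == "bond_stretch") {
    if (!length(cs@ligands)) stop("no ligand bounds in fixture")
    mag <- magnitude %||% 1.5
    lg <- cs@ligands[[1]]
    # stretch the last bond pair (a terminal arm bond)
    bp <- lg$bond_pairs[nrow(lg$bond_pairs), ]
    i <- lg$atom_idx[bp[1]]; j <- lg$atom_idx[bp[2]]
    term <- if (sum(bonds(x)$i == j | bonds(x)$j == j) == 1) j else i
    base <- if (term == j) i else j
    u <- xyz[term, ] - xyz[base, ]
    xyz[term, ] <- xyz[base, ] + mag * u
  } else if (kind == "internal_clash") {
    if (!length(cs@ligands)) stop("no ligand bounds in fixture")
    if (length(lig) < 7) stop("fixture ligand has no rotatable arm")
    C1 <- xyz[lig[1], ]; C4 <- xyz[lig[4], ]
    R <- .rotAxis(C1 - C4, pi)                 # flip arm N7 in-plane
    xyz[lig[7], ] <- as.vector((xyz[lig[7], ] - C4) %*% t(R)) + C4
  } else if (kind == "interchain_clash") {
    frac <- magnitude %||% 0.5
    ch <- chains(x)$chain_id
    if (length(ch) < 2) stop("need two chains")
    A <- which(a$chain_id == ch[1] & a$is_heavy)
    B <- which(a$chain_id == ch[length(ch)] & a$is_heavy)
    DA <- xyz[A, , drop = FALSE]; DB <- xyz[B, , drop = FALSE]
    D <- sqrt(outer(rowSums(DB^2), rowSums(DA^2), "+") -
              2 * tcrossprod(DB, DA))
    w <- which(D == min(D), arr.ind = TRUE)[1, ]
    bi <- B[w[1]]; ai <- A[w[2]]
    rsum <- a$vdw_radius[bi] + a$vdw_radius[ai]
    u <- (xyz[ai, ] - xyz[bi, ]) / sqrt(sum((xyz[ai, ] - xyz[bi, ])^2))
    shift <- (min(D) - frac * rsum) * u
    rows <- which(a$chain_id == ch[length(ch)])
    xyz[rows, ] <- sweep(xyz[rows, , drop = FALSE], 2, shift, "+")
  } else if (kind == "chain_overlap") {
    if (!length(cs@symPairs)) stop("no symmetric chain pair in fixture")
    sep <- magnitude %||% 2.6
    sp <- cs@symPairs[[1]]
    cA <- colMeans(xyz[sp$A, , drop = FALSE])
    cB <- colMeans(xyz[sp$B, , drop = FALSE])
    rows <- which(a$chain_id == sp$chainB)
    # move copy B's centroid onto A's, offset `sep` along the helix axis
    shift <- (cA + c(0, 0, sep)) - cB
    xyz[rows, ] <- sweep(xyz[rows, , drop = FALSE], 2, shift, "+")
  } else if (kind == "covalent_break") {
    if (!nrow(cs@covalentBonds)) stop("no covalent cross-chain bond")
    mag <- magnitude %||% 2.5
    cb <- cs@covalentBonds[1, ]
    u <- xyz[cb[2], ] - xyz[cb[1], ]
    u <- u / sqrt(sum(u^2))
    xyz[lig, ] <- sweep(xyz[lig, , drop = FALSE], 2, mag * u, "+")
  } else stop("unknown violation kind: ", kind)

  coords(x) <- xyz
  x
}

#' Toy denoisers
#'
#' Builds a denoiser closure \code{f(x, t)} for steering and
#' reverse-diffusion experiments.
#' \describe{
#'   \item{ideal}{always returns \code{target}.}
#'   \item{noisy_ideal}{returns \code{target} plus Gaussian jitter of
#'     scale \code{jitter} (deterministic in \code{(x, t)}).}
#'   \item{dirac_pathological}{returns \code{target} when the input lies
#'     within \code{delta * sigma(t)} (Frobenius norm after optimal rigid
#'     alignment) of the target, the zero structure otherwise -- the
#'     construction showing that a denoiser can be perfect under an
#'     aligned training loss yet collapse under unaligned reverse
#'     diffusion.}
#' }
#'
#' @param kind one of \code{"ideal"}, \code{"dirac_pathological"},
#'   \code{"noisy_ideal"}.
#' @param target N x 3 target coordinates.
#' @param schedule \code{\link{noiseSchedule}} (needed to map t to
#'   sigma for the pathological trigger).
#' @param delta trigger width in noise standard deviations (default 10).
#' @param jitter sd of the noisy-ideal jitter (Angstrom, default 0.1).
#' @param seed base seed for the jitter.
#' @return function \code{f(x, t)} returning N x 3 coordinates.
#' @export
makeDenoiser <- function(kind = c("ideal", "dirac_pathological",
                                  "noisy_ideal"),
                         target, schedule = NULL, delta = 10,
                         jitter = 0.1, seed = 0L) {
  kind <- match.arg(kind)
  stopifnot(all(is.finite(target)))
  if (kind == "ideal") {
    function(x, t) target
  } else if (kind == "noisy_ideal") {
    function(x, t) {
      h <- abs(sum(x * seq_along(x))) + 1e3 * t + seed
      withSeed(as.integer(h %% 2147483647),
               target + jitter * matrix(stats::rnorm(length(target)),
                                        nrow(target), 3))
    }
  } else {
    if (is.null(schedule))
      stop("dirac_pathological denoiser needs a noise schedule")
    function(x, t) {
      sigma <- stats::approx(schedule$tvals, schedule$sigmas, xout = t,
                             rule = 2)$y
      resid <- tryCatch({
        fit <- kabschAlign(x, target)
        sqrt(sum((fit$transform(x) - target)^2))
      }, error = function(e) Inf)
      if (resid < delta * sigma) target else target * 0
    }
  }
}

#' Plain reverse diffusion with a toy denoiser
#'
#' Iterates \code{\link{alignedReverseStep}} from pure noise down the
#' schedule, optionally with random rigid augmentation of the noisy input
#' at every step (the regime a non-equivariant denoiser sees) and with or
#' without the Kabsch alignment of the denoised estimate.
#'
#' @param denoiser function \code{f(x, t)}.
#' @param schedule a \code{\link{noiseSchedule}}.
#' @param n_atoms structure size.
#' @param align use the Kabsch-aligned interpolation?
#' @param augment random rigid augmentation per step?
#' @param seed integer seed.
#' @return final N x 3 coordinates.
#' @export
reverseDiffusion <- function(denoiser, schedule, n_atoms, align = TRUE,
                             augment = TRUE, seed = NULL) {
  sig <- schedule$sigmas
  tv <- schedule$tvals
  withSeed(seed, {
    x <- sig[1] * matrix(stats::rnorm(n_atoms * 3), n_atoms, 3)
    for (s in seq_len(schedule$num_steps)) {
      xhat <- denoiser(x, tv[s])
      x <- alignedReverseStep(x, xhat, sig[s], sig[s + 1], align = align,
                              augment = augment)
    }
    x
  })
}
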