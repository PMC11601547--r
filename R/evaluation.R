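## Symmetry-aware structure scoring and physical-quality checks.

# Precompute the LDDT pair state: qualifying pairs (reference distance
# below the inclusion radius, atoms in different residues) and their
# reference distances.
.lddtState <- function(ref, residue_index, inclusion_radius = 15,
                       thresholds = c(0.5, 1, 2, 4)) {
  D <- as.matrix(stats::dist(ref))
  sel <- which(upper.tri(D) & D < inclusion_radius &
               outer(residue_index, residue_index, "!="), arr.ind = TRUE)
  if (!nrow(sel)) stop("no qualifying atom pairs for LDDT")
  list(i = sel[, 1], j = sel[, 2],
       dref = D[sel], thresholds = thresholds)
}

.lddtHits <- function(state, pred, subset = NULL) {
  idx <- if (is.null(subset)) seq_along(state$i)
         else which(state$i %in% subset | state$j %in% subset)
  dp <- sqrt(rowSums((pred[state$i[idx], , drop = FALSE] -
                      pred[state$j[idx], , drop = FALSE])^2))
  err <- abs(dp - state$dref[idx])
  hits <- vapply(state$thresholds, function(th) as.numeric(err < th),
                 numeric(length(idx)))
  if (length(idx) == 1L) hits <- matrix(hits, nrow = 1)
  list(idx = idx, hits = rowSums(hits))
}

#' All-atom local distance difference test (LDDT)
#'
#' Superposition-free score: the fraction of reference interatomic
#' distances (below the inclusion radius, between atoms of different
#' residues) reproduced within each tolerance threshold, averaged over the
#' thresholds.  Standard parameters: 15 Angstrom inclusion radius,
#' thresholds 0.5 / 1 / 2 / 4 Angstrom.
#'
#' @param pred,ref N x 3 coordinate matrices with corresponding rows.
#' @param residue_index integer vector assigning each atom to a residue
#'   (pairs within one residue are excluded).
#' @param inclusion_radius Angstrom.
#' @param thresholds Angstrom tolerances.
#' @return score in [0, 1].
#' @export
lddt <- function(pred, ref, residue_index, inclusion_radius = 15,
                 thresholds = c(0.5, 1, 2, 4)) {
  stopifnot(all(dim(pred) == dim(ref)),
            nrow(pred) == length(residue_index))
  st <- .lddtState(ref, residue_index, inclusion_radius, thresholds)
  h <- .lddtHits(st, pred)
  sum(h$hits) / (length(st$i) * length(thresholds))
}

# All automorphisms of a ligand's bonded graph (element-colored), capped.
.ligandAutomorphisms <- function(x, chain_id, cap = 1000L) {
  a <- atoms(x)
  rows <- which(a$chain_id == chain_id & a$is_heavy)
  if (length(rows) <= 1) return(list(seq_along(rows)))
  b <- bonds(x)
  eb <- b[b$i %in% rows & b$j %in% rows, , drop = FALSE]
  g <- igraph::graph_from_edgelist(
    cbind(match(eb$i, rows), match(eb$j, rows)), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(rows) - igraph::vcount(g)))
  col <- as.integer(factor(a$element[rows]))
  maps <- igraph::graph.get.isomorphisms.vf2(g, g, vertex.color1 = col,
                                             vertex.color2 = col)
  maps <- lapply(maps, as.integer)
  # identity first, then lexicographic, truncated at the cap
  key <- vapply(maps, function(m) paste(m, collapse = ","), "")
  maps <- maps[order(key)]
  idp <- which(vapply(maps, function(m)
    all(m == seq_along(rows)), TRUE))
  maps <- c(maps[idp], maps[-idp])
  maps[seq_len(min(length(maps), cap))]
}

# Lexicographic permutations of 1..n (full enumeration; used for chain
# groups, which are small).
.permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in .permutations(n - 1L))
    for (pos in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, pos - 1L)
  # generate in lexicographic order
  out[order(vapply(out, function(p) paste(sprintf("%03d", p),
                                          collapse = ""), ""))]
}

#' Greedy symmetry correction
#'
#' Finds the chain assignment and per-ligand atom permutations that
#' maximize the global all-atom LDDT of a prediction against a reference,
#' accounting for interchangeable symmetric chains and graph automorphisms
#' of ligands.  Stage 1 evaluates up to \code{chain_cap} candidate chain
#' assignments (permutations within each symmetric-chain group,
#' lexicographic order, inner atom order fixed) and keeps the best.  Stage
#' 2 walks the ligands one at a time, evaluates up to \code{atom_cap}
#' bonded-graph automorphisms for each, and greedily applies the best;
#' scoring is incremental, touching only the distance-matrix rows and
#' columns that change.  Ties keep the first candidate in enumeration
#' order.
#'
#' @param pred,ref \linkS4class{ComplexStructure}s with identical atom
#'   layout (symmetric copies must have identical per-chain atom order).
#' @param chain_cap,atom_cap enumeration caps (paper defaults 100 and
#'   1000).
#' @param inclusion_radius,thresholds LDDT parameters.
#' @return list with \code{chain_map} (named character, pred chain ->
#'   ref chain slot), \code{ligand_perms} (named list of local
#'   permutations), \code{atom_perm} (full row permutation applied to the
#'   prediction), \code{lddt} (achieved score) and \code{lddt_identity}
#'   (score of the uncorrected assignment).
#' @export
greedySymmetryCorrection <- function(pred, ref, chain_cap = 100L,
                                     atom_cap = 1000L,
                                     inclusion_radius = 15,
                                     thresholds = c(0.5, 1, 2, 4)) {
  if (chain_cap < 1 || atom_cap < 1) stop("caps must be >= 1")
  a <- atoms(ref)
  res_key <- as.integer(factor(paste(a$chain_id, a$res_idx)))
  mask <- a$is_resolved & atoms(pred)$is_resolved
  st <- .lddtState(coords(ref)[mask, , drop = FALSE],
                   res_key[mask], inclusion_radius, thresholds)
  npairs <- length(st$i) * length(st$thresholds)
  pc <- coords(pred)

  score_of <- function(perm) {
    sum(.lddtHits(st, pc[perm, , drop = FALSE][mask, , drop = FALSE])$hits) /
      npairs
  }

  ch <- chains(ref)
  chain_rows <- lapply(ch$chain_id, function(cid) which(a$chain_id == cid))
  names(chain_rows) <- ch$chain_id

  # ---- stage 1: chain assignment ----
  groups <- split(ch$chain_id, ch$entity_id)
  groups <- groups[vapply(groups, length, 1L) > 1]
  cand <- list(stats::setNames(ch$chain_id, ch$chain_id))  # identity
  for (grp in groups) {
    perms <- .permutations(length(grp))
    new_cand <- list()
    for (cm in cand) for (p in perms) {
      cm2 <- cm
      cm2[grp] <- grp[p]
      new_cand[[length(new_cand) + 1L]] <- cm2
      if (length(new_cand) >= chain_cap) break
    }
    cand <- unique(new_cand)
    cand <- cand[seq_len(min(length(cand), chain_cap))]
  }
  perm_of_map <- function(cm) {
    perm <- seq_len(nrow(a))
    for (cpred in names(cm)) {
      # pred chain cpred is placed into ref slot cm[[cpred]]
      perm[chain_rows[[cm[[cpred]]]]] <- chain_rows[[cpred]]
    }
    perm
  }
  id_score <- score_of(seq_len(nrow(a)))
  best_score <- -Inf; best_map <- cand[[1]]; best_perm <- seq_len(nrow(a))
  for (cm in cand) {
    p <- perm_of_map(cm)
    s <- score_of(p)
    if (s > best_score + 1e-12) { best_score <- s; best_map <- cm
                                  best_perm <- p }
  }

  # ---- stage 2: greedy ligand automorphisms, incremental scoring ----
  # Only pairs touching the permuted ligand's rows are re-evaluated.
  mask_idx <- which(mask)
  cur_hits <- .lddtHits(st, pc[best_perm, , drop = FALSE][mask, ,
                                                          drop = FALSE])$hits
  total <- sum(cur_hits)
  lig_perms <- list()
  lig_chains <- ch$chain_id[ch$entity_type == "nonpolymer"]
  for (cid in lig_chains) {
    auts <- .ligandAutomorphisms(ref, cid, atom_cap)
    if (length(auts) <= 1) next
    ref_slot <- chain_rows[[best_map[[cid]]]]
    ref_slot <- ref_slot[a$is_heavy[ref_slot]]
    slot_m <- match(intersect(ref_slot, mask_idx), mask_idx)
    best_aut <- auts[[1]]; best_s <- best_score; best_upd <- NULL
    for (aut in auts) {
      p2 <- best_perm
      p2[ref_slot] <- best_perm[ref_slot][aut]
      upd <- .lddtHits(st, pc[p2, , drop = FALSE][mask, , drop = FALSE],
                       subset = slot_m)
      s <- (total - sum(cur_hits[upd$idx]) + sum(upd$hits)) / npairs
      if (s > best_s + 1e-12) { best_s <- s; best_aut <- aut
                                best_upd <- upd }
    }
    if (!is.null(best_upd)) {
      best_perm[ref_slot] <- best_perm[ref_slot][best_aut]
      best_score <- best_s
      cur_hits[best_upd$idx] <- best_upd$hits
      total <- sum(cur_hits)
    }
    lig_perms[[cid]] <- best_aut
  }

  list(chain_map = best_map, ligand_perms = lig_perms,
       atom_perm = best_perm, lddt = best_score,
       lddt_identity = id_score)
}

#' Physical-quality report
#'
#' PoseBusters-style checks.  Ligand internal geometry is tested against
#' the distance-geometry bounds (bond pairs, 1-3 angle pairs, and all
#' remaining pairs against the lower bound); chirality and stereochemistry
#' by the sign/side of the annotated quadruple dihedrals; inter-chain
#' clashes by requiring every non-bonded atom pair between chains with
#' more than one atom to lie above 0.75 times the summed Van der Waals
#' radii.  A ligand present without bounds makes the three geometric
#' checks not-evaluable (NA), distinct from failure.
#'
#' @param x a \linkS4class{ComplexStructure}.
#' @param constraints a \linkS4class{ConstraintSet} for \code{x}.
#' @return a \linkS4class{QualityReport}
#' @export
qualityReport <- function(x, constraints) {
  cs <- constraints
  xyz <- coords(x)
  a <- atoms(x)

  n_lig_chains <- sum(chains(x)$entity_type == "nonpolymer")
  have_bounds <- length(cs@ligands) > 0
  geo <- c(bond = TRUE, angle = TRUE, clash = TRUE)
  if (n_lig_chains > 0 && !have_bounds) {
    geo <- c(bond = NA, angle = NA, clash = NA)
  } else {
    for (lg in cs@ligands) {
      sub <- xyz[lg$atom_idx, , drop = FALSE]
      D <- as.matrix(stats::dist(sub))
      cls <- matrix("other", nrow(D), ncol(D))
      if (!is.null(lg$bond_pairs) && nrow(lg$bond_pairs)) {
        cls[lg$bond_pairs] <- "bond"
        cls[lg$bond_pairs[, c(2, 1), drop = FALSE]] <- "bond"
      }
      if (!is.null(lg$angle_pairs) && nrow(lg$angle_pairs)) {
        cls[lg$angle_pairs] <- "angle"
        cls[lg$angle_pairs[, c(2, 1), drop = FALSE]] <- "angle"
      }
      up <- upper.tri(D)
      in_rng <- function(w) {
        sel <- up & cls == w
        all(D[sel] >= 0.8 * lg$L[sel] &
            (!is.finite(lg$U[sel]) | D[sel] <= 1.2 * lg$U[sel]))
      }
      geo["bond"] <- geo["bond"] && in_rng("bond")
      geo["angle"] <- geo["angle"] && in_rng("angle")
      sel <- up & cls == "other"
      geo["clash"] <- geo["clash"] && all(D[sel] >= 0.8 * lg$L[sel])
    }
  }

  chi <- TRUE
  if (nrow(cs@chiralR)) chi <- chi && all(.quadAngles(xyz, cs@chiralR) > 0)
  if (nrow(cs@chiralS)) chi <- chi && all(.quadAngles(xyz, cs@chiralS) < 0)
  ste <- TRUE
  if (nrow(cs@stereoE))
    ste <- ste && all(abs(.quadAngles(xyz, cs@stereoE)) > pi / 2)
  if (nrow(cs@stereoZ))
    ste <- ste && all(abs(.quadAngles(xyz, cs@stereoZ)) < pi / 2)

  inter <- TRUE
  if (nrow(cs@crossPairs)) {
    sizes <- table(a$chain_id[a$is_heavy])
    multi <- names(sizes)[sizes > 1]
    sel <- a$chain_id[cs@crossPairs$i] %in% multi &
           a$chain_id[cs@crossPairs$j] %in% multi
    if (any(sel)) {
      d <- .pairDist(xyz, as.matrix(cs@crossPairs[sel, c("i", "j")]))
      inter <- all(d > 0.75 * cs@crossPairs$rsum[sel])
    }
  }

  new("QualityReport", checks = c(
    bond_lengths_ok = unname(geo["bond"]),
    bond_angles_ok = unname(geo["angle"]),
    internal_clash_ok = unname(geo["clash"]),
    chirality_ok = chi, stereo_ok = ste,
    interchain_clash_ok = inter))
}

#' Pocket-aligned ligand RMSD
#'
#' Aligns the prediction onto the reference using the backbone center
#' atoms (C-alpha / C1') of the reference pocket -- the polymer residues
#' with a resolved heavy atom within \code{pocket_radius} of the ligand --
#' then reports the ligand heavy-atom RMSD, minimized over the ligand's
#' bonded-graph automorphisms.
#'
#' @param pred,ref \linkS4class{ComplexStructure}s with identical layout.
#' @param ligand_chain chain id of the ligand.
#' @param pocket_radius Angstrom (default 10).
#' @return RMSD in Angstrom.
#' @export
pocketAlignedRmsd <- function(pred, ref, ligand_chain, pocket_radius = 10) {
  a <- atoms(ref)
  lig <- which(a$chain_id == ligand_chain & a$is_heavy & a$is_resolved)
  if (!length(lig)) stop("ligand chain not found: ", ligand_chain)
  rxyz <- coords(ref); pxyz <- coords(pred)
  pol_chains <- chains(ref)$chain_id[chains(ref)$entity_type != "nonpolymer"]
  tok <- tokenize(ref)
  tok <- tok[tok$asym_id %in% pol_chains & tok$is_resolved, , drop = FALSE]
  dmin <- .tokenBinderDistance(tok, ref, lig)
  pocket <- tok[dmin < pocket_radius, , drop = FALSE]
  anchors <- pocket$center_atom[!is.na(pocket$center_atom)]
  if (length(anchors) < 3) stop("empty (or too small) pocket within ",
                                pocket_radius, " Angstrom")
  fit <- kabschAlign(pxyz, rxyz, mask = anchors)
  pfit <- fit$transform(pxyz)
  auts <- .ligandAutomorphisms(ref, ligand_chain, 1000L)
  min(vapply(auts, function(aut)
    sqrt(mean(rowSums((pfit[lig, , drop = FALSE][aut, , drop = FALSE] -
                       rxyz[lig, , drop = FALSE])^2))), 1))
}
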