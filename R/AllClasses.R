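#' @import methods
NULL

#' ComplexStructure: an all-atom biomolecular complex
#'
#' The central container every algorithm in the package operates on.  Atoms
#' are kept in file order in a data frame; chain-level metadata (entity type,
#' polymer sequence, symmetric-copy group) lives in \code{chains}; covalent
#' bonds reference atom rows by index.
#'
#' @slot atoms data.frame with columns \code{atom_id}, \code{atom_name},
#'   \code{element}, \code{x}, \code{y}, \code{z} (Angstrom),
#'   \code{vdw_radius} (Angstrom), \code{chain_id}, \code{res_idx},
#'   \code{res_name}, \code{is_resolved}, \code{is_heavy}.
#' @slot chains data.frame with columns \code{chain_id}, \code{entity_type}
#'   (one of \code{"protein"}, \code{"rna"}, \code{"dna"},
#'   \code{"nonpolymer"}), \code{sequence}, \code{entity_id} (chains sharing
#'   an \code{entity_id} are symmetric copies of the same molecule).
#' @slot bonds data.frame with integer columns \code{i}, \code{j} (atom row
#'   indices) and logical \code{inter_chain}.
#'
#' @export
setClass("ComplexStructure",
  representation(atoms = "data.frame", chains = "data.frame",
                 bonds = "data.frame"))

setValidity("ComplexStructure", function(object) {
  a <- object@atoms
  need <- c("atom_id", "atom_name", "element", "x", "y", "z", "vdw_radius",
            "chain_id", "res_idx", "res_name", "is_resolved", "is_heavy")
  miss <- setdiff(need, names(a))
  if (length(miss))
    return(paste("atoms missing columns:", paste(miss, collapse = ", ")))
  cneed <- c("chain_id", "entity_type", "sequence", "entity_id")
  miss <- setdiff(cneed, names(object@chains))
  if (length(miss))
    return(paste("chains missing columns:", paste(miss, collapse = ", ")))
  res <- a$is_resolved
  xyz <- as.matrix(a[res, c("x", "y", "z")])
  if (length(xyz) && !all(is.finite(xyz)))
    return("resolved atoms must have finite coordinates")
  if (any(a$is_heavy & !(a$vdw_radius > 0)))
    return("heavy atoms must have vdw_radius > 0")
  if (!all(a$chain_id %in% object@chains$chain_id))
    return("atom chain_id not present in chains table")
  b <- object@bonds
  if (nrow(b)) {
    if (any(b$i < 1 | b$i > nrow(a) | b$j < 1 | b$j > nrow(a)))
      return("bond references a non-existent atom")
  }
  et <- object@chains$entity_type
  if (!all(et %in% c("protein", "rna", "dna", "nonpolymer")))
    return("unknown entity_type")
  TRUE
})

#' ConstraintSet: physical constraints for the steering potentials
#'
#' Indices are atom row indices into the associated
#' \linkS4class{ComplexStructure}.  Quadruple matrices hold one constraint
#' per row.  Ligand entries carry distance-geometry bounds matrices over the
#' ligand's own atoms with local bond (1-2) and angle (1-3) pair classes.
#'
#' @slot chiralR,chiralS integer matrices (k x 4), improper-torsion
#'   quadruples for R- and S-configured chiral centers (substituents in
#'   decreasing CIP priority, center last).
#' @slot stereoE,stereoZ integer matrices (k x 4), torsion quadruples across
#'   E- and Z-configured double bonds.
#' @slot planar integer matrix (k x 4), improper quadruples for planar
#'   double bonds.
#' @slot ligands list; each element a list with \code{atom_idx} (global
#'   indices), \code{L}, \code{U} (n x n Angstrom bounds), \code{bond_pairs},
#'   \code{angle_pairs} (m x 2 local index matrices).
#' @slot crossPairs data.frame \code{i}, \code{j}, \code{rsum}: non-bonded
#'   inter-chain atom pairs with the summed Van der Waals radii.
#' @slot symPairs list of lists \code{A}, \code{B} (atom index vectors of two
#'   symmetric chains, each with > 1 atom), \code{chainA}, \code{chainB}.
#' @slot covalentBonds integer matrix (k x 2) of inter-chain bonded pairs.
#' @export
setClass("ConstraintSet",
  representation(chiralR = "matrix", chiralS = "matrix",
                 stereoE = "matrix", stereoZ = "matrix",
                 planar = "matrix", ligands = "list",
                 crossPairs = "data.frame", symPairs = "list",
                 covalentBonds = "matrix"))

setValidity("ConstraintSet", function(object) {
  for (nm in c("chiralR", "chiralS", "stereoE", "stereoZ", "planar")) {
    m <- slot(object, nm)
    if (nrow(m) && ncol(m) != 4) return(paste(nm, "must have 4 columns"))
  }
  for (lg in object@ligands) {
    if (any(lg$L > lg$U + 1e-9))
      return("ligand bounds violate L <= U")
    n <- length(lg$atom_idx)
    if (!all(dim(lg$L) == c(n, n)) || !all(dim(lg$U) == c(n, n)))
      return("ligand bounds matrices must be n x n over atom_idx")
  }
  if (nrow(object@covalentBonds) && ncol(object@covalentBonds) != 2)
    return("covalentBonds must have 2 columns")
  TRUE
})

#' MSA: one chain's multiple sequence alignment with taxonomy labels
#'
#' @slot rows data.frame with columns \code{sequence} (aligned, uppercase
#'   match columns only), \code{chain_id}, \code{taxonomy_id} (NA when the
#'   sequence has no taxonomy annotation).
#' @export
setClass("MSA", representation(rows = "data.frame"))

setValidity("MSA", function(object) {
  r <- object@rows
  need <- c("sequence", "chain_id", "taxonomy_id")
  if (!all(need %in% names(r)))
    return("rows must have sequence, chain_id, taxonomy_id")
  for (cid in unique(r$chain_id)) {
    w <- nchar(r$sequence[r$chain_id == cid])
    if (length(unique(w)) > 1)
      return(paste("aligned sequences of chain", cid, "differ in length"))
  }
  TRUE
})

#' PairedMSA: taxonomy-paired multi-chain alignment
#'
#' Row 0 (R index 1) is the query complex itself with every pairing flag 1.
#' Empty cells are the empty string.
#'
#' @slot pairing character matrix, rows x chains; colnames are chain ids.
#' @slot isPaired integer matrix of the same shape; 1 where the cell came
#'   from a taxonomy match (or is the query), 0 otherwise.
#' @export
setClass("PairedMSA",
  representation(pairing = "matrix", isPaired = "matrix"))

setValidity("PairedMSA", function(object) {
  if (!all(dim(object@pairing) == dim(object@isPaired)))
    return("pairing and isPaired shape mismatch")
  if (is.null(colnames(object@pairing)))
    return("pairing must carry chain ids as colnames")
  if (nrow(object@pairing) >= 1 && !all(object@isPaired[1, ] == 1L))
    return("query row must be fully paired")
  TRUE
})

#' QualityReport: PoseBusters-style physical-validity booleans
#'
#' Each check is TRUE (pass), FALSE (fail) or NA (not evaluable, e.g. a
#' ligand without bounds).  \code{overallPass(x)} is the conjunction over the
#' six checks, treating NA as pass-through (NA propagates).
#'
#' @slot checks named logical vector with elements
#'   \code{bond_lengths_ok}, \code{bond_angles_ok}, \code{internal_clash_ok},
#'   \code{chirality_ok}, \code{stereo_ok}, \code{interchain_clash_ok}.
#' @export
setClass("QualityReport", representation(checks = "logical"))

setValidity("QualityReport", function(object) {
  need <- c("bond_lengths_ok", "bond_angles_ok", "internal_clash_ok",
            "chirality_ok", "stereo_ok", "interchain_clash_ok")
  if (!identical(sort(names(object@checks)), sort(need)))
    return("checks must be exactly the six named physical checks")
  TRUE
})
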