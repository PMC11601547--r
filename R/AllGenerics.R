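#' @title Accessor generics
#' @description Accessors for the package's S4 containers.
#' @param x an object
#' @param value replacement value
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("chains", function(x) standardGeneric("chains"))

#' @rdname accessors
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("msaRows", function(x) standardGeneric("msaRows"))

#' @rdname accessors
#' @export
setGeneric("pairing", function(x) standardGeneric("pairing"))

#' @rdname accessors
#' @export
setGeneric("isPaired", function(x) standardGeneric("isPaired"))

#' @rdname accessors
#' @export
setGeneric("qualityChecks", function(x) standardGeneric("qualityChecks"))

#' @rdname accessors
#' @export
setGeneric("overallPass", function(x) standardGeneric("overallPass"))

#' @rdname accessors
setMethod("atoms", "ComplexStructure", function(x) x@atoms)

#' @rdname accessors
setMethod("chains", "ComplexStructure", function(x) x@chains)

#' @rdname accessors
setMethod("bonds", "ComplexStructure", function(x) x@bonds)

#' @rdname accessors
setMethod("coords", "ComplexStructure", function(x) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  dimnames(m) <- list(x@atoms$atom_id, c("x", "y", "z"))
  m
})

#' @rdname accessors
setMethod("coords<-", "ComplexStructure", function(x, value) {
  stopifnot(is.matrix(value), nrow(value) == nrow(x@atoms), ncol(value) == 3)
  x@atoms$x <- value[, 1]
  x@atoms$y <- value[, 2]
  x@atoms$z <- value[, 3]
  validObject(x)
  x
})

#' @rdname accessors
setMethod("nAtoms", "ComplexStructure", function(x) nrow(x@atoms))

#' @rdname accessors
setMethod("msaRows", "MSA", function(x) x@rows)

#' @rdname accessors
setMethod("pairing", "PairedMSA", function(x) x@pairing)

#' @rdname accessors
setMethod("isPaired", "PairedMSA", function(x) x@isPaired)

#' @rdname accessors
setMethod("qualityChecks", "QualityReport", function(x) x@checks)

#' @rdname accessors
setMethod("overallPass", "QualityReport", function(x) all(x@checks))

setMethod("show", "ComplexStructure", function(object) {
  ch <- object@chains
  cat("ComplexStructure with", nrow(object@atoms), "atoms in",
      nrow(ch), "chains\n")
  for (k in seq_len(nrow(ch)))
    cat(sprintf("  chain %s [%s, entity %s]: %d atoms\n",
                ch$chain_id[k], ch$entity_type[k], ch$entity_id[k],
                sum(object@atoms$chain_id == ch$chain_id[k])))
  if (nrow(object@bonds))
    cat(" ", nrow(object@bonds), "bonds (",
        sum(object@bonds$inter_chain), "inter-chain )\n")
})

setMethod("show", "ConstraintSet", function(object) {
  cat("ConstraintSet:\n")
  cat(sprintf("  chiral R/S quadruples : %d / %d\n",
              nrow(object@chiralR), nrow(object@chiralS)))
  cat(sprintf("  stereo E/Z quadruples : %d / %d\n",
              nrow(object@stereoE), nrow(object@stereoZ)))
  cat(sprintf("  planar quadruples     : %d\n", nrow(object@planar)))
  cat(sprintf("  ligands with bounds   : %d\n", length(object@ligands)))
  cat(sprintf("  cross-chain pairs     : %d\n", nrow(object@crossPairs)))
  cat(sprintf("  symmetric chain pairs : %d\n", length(object@symPairs)))
  cat(sprintf("  covalent cross bonds  : %d\n", nrow(object@covalentBonds)))
})

setMethod("show", "MSA", function(object) {
  cat("MSA with", nrow(object@rows), "rows,",
      sum(!is.na(object@rows$taxonomy_id)), "taxonomy-labelled\n")
})

setMethod("show", "PairedMSA", function(object) {
  cat("PairedMSA:", nrow(object@pairing), "rows x",
      ncol(object@pairing), "chains;",
      sum(rowSums(object@isPaired) >= 2) - 1, "paired rows beyond query\n")
})

setMethod("show", "QualityReport", function(object) {
  cat("QualityReport (overall", if (isTRUE(all(object@checks))) "PASS"
      else "FAIL", ")\n")
  for (nm in names(object@checks))
    cat(sprintf("  %-20s %s\n", nm,
                ifelse(is.na(object@checks[[nm]]), "not-evaluable",
                       ifelse(object@checks[[nm]], "pass", "FAIL"))))
})
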