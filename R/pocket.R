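## Robust pocket conditioning: training-time featurization and the
## inference-mode variant with user-specified binder/pocket.

#' Pocket-conditioning configuration
#'
#' @param pocket_conditioned_prop probability that a training iteration is
#'   pocket-conditioned at all (default 0.3).
#' @param pocket_cutoff Angstrom; residues whose nearest resolved heavy
#'   atom lies within this distance of the binder are pocket candidates
#'   (default 6).
#' @param pocket_geometric_p success probability of the geometric draw
#'   governing how many pocket residues are revealed (default 0.3).
#' @return list of class \code{pocket_config}
#' @export
pocketConfig <- function(pocket_conditioned_prop = 0.3, pocket_cutoff = 6,
                         pocket_geometric_p = 0.3) {
  stopifnot(pocket_conditioned_prop > 0, pocket_conditioned_prop <= 1,
            pocket_cutoff > 0, pocket_geometric_p > 0,
            pocket_geometric_p <= 1)
  structure(list(pocket_conditioned_prop = pocket_conditioned_prop,
                 pocket_cutoff = pocket_cutoff,
                 pocket_geometric_p = pocket_geometric_p),
            class = "pocket_config")
}

# min distance from each token's resolved heavy atoms to any binder atom
.tokenBinderDistance <- function(tokens, x, binder_atoms) {
  xyz <- coords(x)
  a <- atoms(x)
  b <- xyz[binder_atoms, , drop = FALSE]
  vapply(seq_len(nrow(tokens)), function(k) {
    ai <- tokens$atom_idx[[k]]
    ai <- ai[a$is_resolved[ai] & a$is_heavy[ai]]
    if (!length(ai)) return(Inf)
    p <- xyz[ai, , drop = FALSE]
    min(sqrt(outer(rowSums(p^2), rowSums(b^2), "+") -
             2 * tcrossprod(p, b)))
  }, 1)
}

#' Training-time pocket featurization
#'
#' With probability \code{1 - pocket_conditioned_prop} all tokens stay
#' \code{UNSPECIFIED}.  Otherwise a binder chain is drawn uniformly among
#' the non-polymer (ligand) chains present in the tokens -- among all
#' chains if there is no ligand -- and every token of another chain whose
#' nearest resolved heavy atom lies within \code{pocket_cutoff} of the
#' binder becomes a pocket candidate.  N = min(#candidates, 1 + M)
#' candidates are revealed as \code{POCKET}, where M is geometric with
#' support {1, 2, ...} and success probability \code{pocket_geometric_p};
#' binder tokens become \code{BINDER} and everything else
#' \code{UNSELECTED}.
#'
#' @param tokens token table from \code{\link{tokenize}}.
#' @param x the \linkS4class{ComplexStructure}.
#' @param config a \code{\link{pocketConfig}}.
#' @param seed integer seed or NULL.
#' @return the token table with \code{pocket_feature} filled in.
#' @export
featurizePocket <- function(tokens, x, config = pocketConfig(),
                            seed = NULL) {
  if (!nrow(tokens)) stop("empty token list")
  withSeed(seed, {
    tokens$pocket_feature <- "UNSPECIFIED"
    r <- stats::runif(1)
    if (r >= config$pocket_conditioned_prop) return(tokens)
    binder_ids <- unique(tokens$asym_id[tokens$entity_type == "nonpolymer"])
    if (!length(binder_ids)) binder_ids <- unique(tokens$asym_id)
    binder <- binder_ids[sample.int(length(binder_ids), 1L)]
    a <- atoms(x)
    batoms <- which(a$chain_id == binder & a$is_resolved & a$is_heavy)
    dist <- .tokenBinderDistance(tokens, x, batoms)
    cand <- which(tokens$asym_id != binder & dist < config$pocket_cutoff)
    tokens$pocket_feature <- "UNSELECTED"
    tokens$pocket_feature[tokens$asym_id == binder] <- "BINDER"
    if (length(cand)) {
      m <- stats::rgeom(1, config$pocket_geometric_p) + 1L
      n <- min(length(cand), 1L + m)
      pick <- cand[sample.int(length(cand), n)]
      tokens$pocket_feature[pick] <- "POCKET"
    }
    tokens
  })
}

#' Inference-mode pocket featurization
#'
#' Deterministic variant for the common use case where the user knows the
#' binder and some key interacting residues: the named binder chain is
#' marked \code{BINDER}, the listed residues \code{POCKET}, everything
#' else \code{UNSELECTED}.  No distance test is applied -- a partial or
#' approximate residue list is expected.
#'
#' @param tokens token table.
#' @param binder_asym binder chain id.
#' @param pocket_residues data.frame with columns \code{asym_id},
#'   \code{res_idx} (or character vector \code{"A:45"}-style).
#' @return token table with \code{pocket_feature} set.
#' @export
featurizePocketManual <- function(tokens, binder_asym, pocket_residues) {
  if (!binder_asym %in% tokens$asym_id)
    stop("unknown binder chain: ", binder_asym)
  if (is.character(pocket_residues)) {
    parts <- strsplit(pocket_residues, ":", fixed = TRUE)
    pocket_residues <- data.frame(
      asym_id = vapply(parts, `[`, "", 1L),
      res_idx = as.integer(vapply(parts, `[`, "", 2L)))
  }
  tokens$pocket_feature <- "UNSELECTED"
  tokens$pocket_feature[tokens$asym_id == binder_asym] <- "BINDER"
  sel <- paste(tokens$asym_id, tokens$res_idx) %in%
    paste(pocket_residues$asym_id, pocket_residues$res_idx)
  tokens$pocket_feature[sel & tokens$asym_id != binder_asym] <- "POCKET"
  tokens
}

#' One-hot encoding of pocket features
#'
#' Fixed column order \code{UNSPECIFIED, BINDER, POCKET, UNSELECTED}.
#'
#' @param tokens token table with \code{pocket_feature}.
#' @return integer matrix, one row per token.
#' @export
pocketFeatureOneHot <- function(tokens) {
  lev <- c("UNSPECIFIED", "BINDER", "POCKET", "UNSELECTED")
  m <- matrix(0L, nrow(tokens), length(lev), dimnames = list(NULL, lev))
  m[cbind(seq_len(nrow(tokens)), match(tokens$pocket_feature, lev))] <- 1L
  m
}
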