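## Tokenization: amino acids / nucleic bases are one token per residue,
## non-polymer heavy atoms one token each.

#' Tokenize a complex
#'
#' Produces the token table used by cropping, pocket conditioning and the
#' steering pipeline.  Protein residues and nucleic-acid bases map to one
#' token each; every heavy atom of a non-polymer entity is its own token.
#' Token order follows chain order, then residue (or atom) order within the
#' chain.
#'
#' Token centers are the C-alpha atom for protein residues, the C1' atom for
#' nucleic bases (falling back to the first resolved heavy atom when the
#' canonical center is absent), and the atom itself for non-polymer tokens.
#' A token whose residue has no resolved heavy atom is emitted with
#' \code{is_resolved = FALSE} and an NA center.
#'
#' @param x a \linkS4class{ComplexStructure}
#' @return data.frame with columns \code{token_idx}, \code{asym_id},
#'   \code{res_idx}, \code{entity_type}, \code{center_atom} (atom row index
#'   or NA), \code{atom_idx} (list column of atom row indices),
#'   \code{n_atoms}, \code{is_resolved}, \code{pocket_feature}.
#' @export
tokenize <- function(x) {
  a <- atoms(x)
  ch <- chains(x)
  out <- list()
  for (k in seq_len(nrow(ch))) {
    cid <- ch$chain_id[k]
    et <- ch$entity_type[k]
    rows <- which(a$chain_id == cid)
    if (et == "nonpolymer") {
      rows <- rows[a$is_heavy[rows]]
      for (r in rows) {
        out[[length(out) + 1L]] <- list(
          asym_id = cid, res_idx = a$res_idx[r], entity_type = et,
          center_atom = if (a$is_resolved[r]) r else NA_integer_,
          atom_idx = r, is_resolved = a$is_resolved[r])
      }
    } else {
      for (ri in unique(a$res_idx[rows])) {
        rr <- rows[a$res_idx[rows] == ri]
        heavy <- rr[a$is_heavy[rr]]
        resolved <- heavy[a$is_resolved[heavy]]
        cname <- if (et == "protein") "CA" else "C1'"
        center <- resolved[a$atom_name[resolved] == cname]
        if (!length(center)) center <- resolved
        out[[length(out) + 1L]] <- list(
          asym_id = cid, res_idx = ri, entity_type = et,
          center_atom = if (length(center)) center[1] else NA_integer_,
          atom_idx = rr, is_resolved = length(resolved) > 0)
      }
    }
  }
  data.frame(
    token_idx = seq_along(out),
    asym_id = vapply(out, `[[`, "", "asym_id"),
    res_idx = vapply(out, function(t) as.integer(t$res_idx), 1L),
    entity_type = vapply(out, `[[`, "", "entity_type"),
    center_atom = vapply(out, function(t) as.integer(t$center_atom), 1L),
    atom_idx = I(lapply(out, `[[`, "atom_idx")),
    n_atoms = vapply(out, function(t) length(t$atom_idx), 1L),
    is_resolved = vapply(out, `[[`, TRUE, "is_resolved"),
    pocket_feature = "UNSPECIFIED",
    stringsAsFactors = FALSE)
}
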