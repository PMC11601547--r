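## Dense taxonomy-based MSA pairing.

#' Pair per-chain MSAs by taxonomy
#'
#' Builds a paired multi-chain alignment that preserves MSA density.  Rows
#' of different chains are joined when they share a taxonomy label:
#' taxonomies seen in at least two distinct chains are processed in
#' descending order of the number of distinct chains they cover (ties broken
#' by taxonomy id, lexicographically, for determinism).  Within a taxonomy a
#' chain with fewer sequences than the row count cycles through its
#' sequences (index mod count).  Chains missing from a taxonomy are filled
#' from their per-chain queue of unpaired sequences (popped without
#' replacement, original file order) with pairing flag 0.  After the
#' taxonomy list is exhausted, remaining unpaired sequences are appended
#' until every queue is empty or the row cap is reached.  Row 1 of the
#' output is always the query complex itself, fully paired.
#'
#' @param query data.frame with columns \code{sequence}, \code{chain_id}
#'   (one row per chain; duplicate chain ids are an error).
#' @param msas list of \linkS4class{MSA} objects (any chains; rows are
#'   pooled).  A chain with no rows is legal.
#' @param max_rows row cap including the query row (default 16384, the
#'   depth cap used for precomputed alignments).
#' @return a \linkS4class{PairedMSA}
#' @export
pairMSAs <- function(query, msas = list(), max_rows = 16384L) {
  if (anyDuplicated(query$chain_id))
    stop("duplicate chain_id in query")
  chains <- query$chain_id
  pool <- do.call(rbind, c(list(
    data.frame(sequence = character(0), chain_id = character(0),
               taxonomy_id = character(0), stringsAsFactors = FALSE)),
    lapply(msas, function(m) msaRows(m)[, c("sequence", "chain_id",
                                            "taxonomy_id")])))
  pool <- pool[pool$chain_id %in% chains, , drop = FALSE]

  rows_pairing <- list(stats::setNames(query$sequence, chains))
  rows_flags <- list(stats::setNames(rep(1L, length(chains)), chains))

  # group by taxonomy; keep taxonomies covering >= 2 distinct chains
  has_tax <- !is.na(pool$taxonomy_id)
  tax_split <- split(which(has_tax), pool$taxonomy_id[has_tax])
  n_chain <- vapply(tax_split, function(ix)
    length(unique(pool$chain_id[ix])), 1L)
  keep <- names(tax_split)[n_chain >= 2L]
  keep <- keep[order(-n_chain[keep], keep)]

  in_tax <- rep(FALSE, nrow(pool))
  for (tx in keep) in_tax[tax_split[[tx]]] <- TRUE
  avail <- lapply(stats::setNames(nm = chains), function(cid)
    pool$sequence[!in_tax & pool$chain_id == cid])

  full <- function() length(rows_pairing) >= max_rows
  pop <- function(cid) {
    q <- avail[[cid]]
    if (!length(q)) return("")
    avail[[cid]] <<- q[-1]
    q[[1]]
  }

  for (tx in keep) {
    if (full()) break
    ix <- tax_split[[tx]]
    by_chain <- split(pool$sequence[ix], pool$chain_id[ix])
    n_max <- max(vapply(by_chain, length, 1L))
    for (i in seq_len(n_max) - 1L) {
      rp <- stats::setNames(rep("", length(chains)), chains)
      rf <- stats::setNames(rep(0L, length(chains)), chains)
      for (cid in names(by_chain)) {
        sqs <- by_chain[[cid]]
        rp[[cid]] <- sqs[(i %% length(sqs)) + 1L]
        rf[[cid]] <- 1L
      }
      for (cid in setdiff(chains, names(by_chain)))
        rp[[cid]] <- pop(cid)
      rows_pairing[[length(rows_pairing) + 1L]] <- rp
      rows_flags[[length(rows_flags) + 1L]] <- rf
      if (full()) break
    }
  }

  while (!full() && any(vapply(avail, length, 1L) > 0L)) {
    rp <- stats::setNames(vapply(chains, pop, ""), chains)
    rf <- stats::setNames(rep(0L, length(chains)), chains)
    rows_pairing[[length(rows_pairing) + 1L]] <- rp
    rows_flags[[length(rows_flags) + 1L]] <- rf
  }

  new("PairedMSA",
      pairing = do.call(rbind, rows_pairing),
      isPaired = do.call(rbind, rows_flags))
}
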