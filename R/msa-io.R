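## A3M reading/writing and taxonomy maps.

#' Read an A3M alignment
#'
#' Parses an A3M file into an \linkS4class{MSA}.  Lowercase letters denote
#' insertions relative to the query and are removed, as are '.' gap-fill
#' characters, so that all returned sequences have equal (match-column)
#' length.  Taxonomy ids are attached from a sequence-id -> taxonomy map
#' when available, NA otherwise.
#'
#' @param path A3M file.
#' @param chain_id chain the alignment belongs to.
#' @param taxonomy_map named character vector (names = sequence ids) or NULL.
#' @return an \linkS4class{MSA}
#' @export
readA3M <- function(path, chain_id, taxonomy_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no sequences in A3M file ", path)
  ids <- sub("^>(\\S*).*", "\\1", lines[hdr])
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(k) {
    if (hdr[k] + 1L > ends[k]) stop("A3M header without sequence: ",
                                    lines[hdr[k]])
    paste(lines[(hdr[k] + 1L):ends[k]], collapse = "")
  }, "")
  # strip insertion (lowercase) and '.' columns
  seqs <- gsub("[a-z.]", "", seqs)
  w <- nchar(seqs)
  if (length(unique(w)) > 1)
    stop("A3M aligned lengths differ after removing insertion columns (",
         paste(unique(w), collapse = ", "), ") in ", path)
  tax <- rep(NA_character_, length(ids))
  if (!is.null(taxonomy_map) && length(taxonomy_map)) {
    hit <- match(ids, names(taxonomy_map))
    tax[!is.na(hit)] <- unname(taxonomy_map[hit[!is.na(hit)]])
  }
  new("MSA", rows = data.frame(sequence = seqs, chain_id = chain_id,
                               taxonomy_id = tax, seq_id = ids,
                               stringsAsFactors = FALSE))
}

#' Read a taxonomy map
#'
#' Two-column tab-separated file: sequence id, taxonomy id.
#'
#' @param path TSV file
#' @return named character vector (sequence id -> taxonomy id)
#' @export
readTaxonomyMap <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("seq_id", "taxonomy_id"),
                          colClasses = "character")
  stats::setNames(tb$taxonomy_id, tb$seq_id)
}

#' Construct an MSA in code
#'
#' @param sequences character vector of aligned sequences (equal length).
#' @param chain_id chain identifier.
#' @param taxonomy_id character vector (NA where unlabelled), recycled.
#' @return an \linkS4class{MSA}
#' @export
msa <- function(sequences, chain_id, taxonomy_id = NA_character_) {
  n <- length(sequences)
  new("MSA", rows = data.frame(
    sequence = as.character(sequences),
    chain_id = rep_len(chain_id, n),
    taxonomy_id = rep_len(taxonomy_id, n),
    seq_id = if (n) paste0(chain_id, "_", seq_len(n)) else character(0),
    stringsAsFactors = FALSE))
}

#' Write one chain of a PairedMSA as A3M (plus paired-flag sidecar)
#'
#' Empty cells are written as all-gap rows so row indices stay aligned
#' across the per-chain files.
#'
#' @param pm a \linkS4class{PairedMSA}
#' @param chain_id which chain to write
#' @param path output A3M path
#' @param flags_path optional TSV sidecar (row, chain, is_paired)
#' @return \code{path}, invisibly
#' @export
writePairedA3M <- function(pm, chain_id, path, flags_path = NULL) {
  p <- pairing(pm)
  if (!chain_id %in% colnames(p)) stop("unknown chain: ", chain_id)
  col <- p[, chain_id]
  width <- max(nchar(col))
  col[!nzchar(col)] <- strrep("-", width)
  out <- character(2L * length(col))
  out[c(TRUE, FALSE)] <- paste0(">", chain_id, "_row", seq_along(col) - 1L)
  out[c(FALSE, TRUE)] <- col
  writeLines(out, path)
  if (!is.null(flags_path)) {
    utils::write.table(
      data.frame(row = seq_along(col) - 1L, chain = chain_id,
                 is_paired = isPaired(pm)[, chain_id]),
      flags_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
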