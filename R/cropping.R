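## Unified spatial <-> contiguous cropping over token lists.

#' Crop configuration
#'
#' @param max_tokens token budget (training default 384).
#' @param max_atoms atom budget (training default 3456).
#' @param neighborhood_sizes candidate contiguous-window sizes; the default
#'   \code{seq(0, 40, 2)} interpolates from pure spatial (0) to wide
#'   contiguous windows.
#' @return list of class \code{crop_config}
#' @export
cropConfig <- function(max_tokens = 384L, max_atoms = 3456L,
                       neighborhood_sizes = seq(0L, 40L, by = 2L)) {
  stopifnot(max_tokens > 0, max_atoms > 0, all(neighborhood_sizes >= 0))
  structure(list(max_tokens = as.integer(max_tokens),
                 max_atoms = as.integer(max_atoms),
                 neighborhood_sizes = as.integer(neighborhood_sizes)),
            class = "crop_config")
}

#' Unified crop around a center token
#'
#' Tokens are visited in ascending distance of their center atom from the
#' center token's center atom (ties broken by token index; unresolved
#' tokens are skipped in the visiting order but may enter through a
#' window).  For each visited token its neighborhood -- the same-chain
#' contiguous residue-index window grown symmetrically until it holds at
#' least \code{neighborhood_size} tokens, the whole chain when the chain is
#' smaller, or the whole entity for non-polymers -- is added atomically;
#' when adding a neighborhood would exceed the token or atom budget the
#' loop stops.  Size 0 reduces to a pure spatial crop, a size of half the
#' token budget on a single chain to a contiguous crop.
#'
#' @param tokens token table from \code{\link{tokenize}}.
#' @param x the \linkS4class{ComplexStructure} the tokens refer to.
#' @param center_token \code{token_idx} of the crop center (must have a
#'   resolved center atom).
#' @param neighborhood_size non-negative integer.
#' @param config a \code{\link{cropConfig}}.
#' @return integer vector of selected \code{token_idx}, ascending.
#' @export
unifiedCrop <- function(tokens, x, center_token, neighborhood_size,
                        config = cropConfig()) {
  if (!nrow(tokens)) stop("empty token list")
  ci <- match(center_token, tokens$token_idx)
  if (is.na(ci)) stop("unknown center token: ", center_token)
  if (is.na(tokens$center_atom[ci]))
    stop("center token has no resolved center atom")
  xyz <- coords(x)
  centers <- tokens$center_atom
  ok <- !is.na(centers) & tokens$is_resolved
  d <- rep(Inf, nrow(tokens))
  d[ok] <- rowNorms(xyz[centers[ok], , drop = FALSE] -
                    matrix(xyz[centers[ci], ], nrow = sum(ok), ncol = 3,
                           byrow = TRUE))
  visit <- order(d, tokens$token_idx)
  visit <- visit[is.finite(d[visit])]

  selected <- logical(nrow(tokens))
  n_tok <- 0L; n_atm <- 0L
  for (v in visit) {
    cid <- tokens$asym_id[v]
    chain_rows <- which(tokens$asym_id == cid)
    if (length(chain_rows) <= neighborhood_size) {
      sel <- chain_rows
    } else {
      lo <- hi <- tokens$res_idx[v]
      sel <- chain_rows[tokens$res_idx[chain_rows] >= lo &
                        tokens$res_idx[chain_rows] <= hi]
      while (length(sel) < neighborhood_size) {
        lo <- lo - 1L; hi <- hi + 1L
        sel <- chain_rows[tokens$res_idx[chain_rows] >= lo &
                          tokens$res_idx[chain_rows] <= hi]
      }
    }
    new <- sel[!selected[sel]]
    if (!length(new)) next
    add_atoms <- sum(tokens$n_atoms[new])
    if (n_tok + length(new) > config$max_tokens ||
        n_atm + add_atoms > config$max_atoms) break
    selected[new] <- TRUE
    n_tok <- n_tok + length(new)
    n_atm <- n_atm + add_atoms
  }
  tokens$token_idx[selected]
}

#' Sample a training crop
#'
#' Draws the neighborhood size uniformly from the configured candidates and
#' the center token uniformly among the resolved tokens of the given chain
#' (or of either chain of an interface id \code{"A|B"}), then delegates to
#' \code{\link{unifiedCrop}}.  Reproducible under \code{seed}.
#'
#' @inheritParams unifiedCrop
#' @param chain_id chain identifier, or two chain ids joined by \code{"|"}.
#' @param seed integer seed or NULL.
#' @return integer vector of selected \code{token_idx}.
#' @export
sampleCrop <- function(tokens, x, chain_id, config = cropConfig(),
                       seed = NULL) {
  ids <- strsplit(chain_id, "|", fixed = TRUE)[[1]]
  if (!all(ids %in% tokens$asym_id)) stop("unknown chain id: ", chain_id)
  cand <- which(tokens$asym_id %in% ids & tokens$is_resolved &
                !is.na(tokens$center_atom))
  if (!length(cand)) stop("no resolved tokens in chain ", chain_id)
  withSeed(seed, {
    size <- sample(config$neighborhood_sizes, 1L)
    center <- tokens$token_idx[cand[sample.int(length(cand), 1L)]]
    out <- unifiedCrop(tokens, x, center, size, config)
    attr(out, "neighborhood_size") <- size
    attr(out, "center_token") <- center
    out
  })
}
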