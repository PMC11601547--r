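# Shared small helpers (internal).

# Bondi (1964) Van der Waals radii in Angstrom, with a generic fallback for
# elements outside the table.
.BONDI <- c(H = 1.20, He = 1.40, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
            Ne = 1.54, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88,
            As = 1.85, Se = 1.90, Br = 1.85, Kr = 2.02, Te = 2.06, I = 1.98,
            Xe = 2.16, Zn = 1.39, Cu = 1.40, Ni = 1.63, Mg = 1.73, Na = 2.27,
            K = 2.75, Li = 1.82, Ga = 1.87, In = 1.93, Sn = 2.17, Tl = 1.96,
            Pb = 2.02)

#' Van der Waals radius lookup
#'
#' Bondi element radii, with 1.5 Angstrom for elements outside the table.
#'
#' @param element character vector of element symbols (e.g. \code{"C"}).
#' @return numeric vector of radii in Angstrom.
#' @export
vdwRadius <- function(element) {
  r <- .BONDI[element]
  r[is.na(r)] <- 1.5
  unname(r)
}

# Seeded evaluation that restores the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Row-wise Euclidean norms of an n x 3 matrix.
rowNorms <- function(m) sqrt(rowSums(m * m))

emptyQuad <- function() matrix(integer(0), ncol = 4)

# log-sum-exp
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
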