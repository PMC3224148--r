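# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# IUPAC nucleotide codes as base bitmasks: A=1, C=2, G=4, T=8.
.iupac_mask <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

.iupac_complement <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

iupac_chars <- function(s) {
  x <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  if (!all(x %in% names(.iupac_mask)))
    stop("invalid IUPAC code in '", s, "'", call. = FALSE)
  x
}

# Does each target base (A/C/G/T only) fall within the degeneracy of the
# corresponding pattern code?  Gaps and ambiguity codes in the target never match.
iupac_match <- function(pattern_chars, target_chars) {
  pm <- .iupac_mask[pattern_chars]
  tm <- .iupac_mask[target_chars]
  ok <- !is.na(tm) & tm %in% c(1L, 2L, 4L, 8L)
  ok & bitwAnd(ifelse(is.na(pm), 0L, pm), ifelse(is.na(tm), 0L, tm)) > 0L
}

reverse_complement <- function(s) {
  x <- rev(iupac_chars(s))
  paste(.iupac_complement[x], collapse = "")
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a
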