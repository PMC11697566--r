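# Internal helpers shared across modules.

#' Reverse complement of a DNA string
#'
#' Thin character-in/character-out wrapper around
#' [Biostrings::reverseComplement()].
#'
#' @param x Single character string over the ACGTN alphabet.
#' @return Character string, the reverse complement of `x`.
#' @export
#' @examples
#' revcomp("ATGC")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. Used wherever the contract promises seed determinism.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a global fixture seed
#'
#' The simulator expands one user seed into per-component seeds by a fixed
#' counter scheme, so that adding a new simulated output never perturbs the
#' streams of existing ones. Component `k` gets
#' `(seed mod 1000003) * 1009 + k, mod (2^31 - 1)`.
#'
#' @param seed Integer global seed.
#' @param k Integer component counter (>= 0).
#' @return Integer seed below 2^31.
#' @export
child_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), is.numeric(k), k >= 0)
  as.integer(((as.numeric(seed) %% 1000003) * 1009 + as.numeric(k)) %% 2147483647)
}

# assert a scalar string
chk_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single string", call. = FALSE)
  x
}

# longest common substring length between two strings (small inputs only);
# used for the scramble complementarity constraint
longest_common_substring <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  if (n == 0L || m == 0L) return(0L)
  best <- 0L
  prev <- integer(m)
  for (i in seq_len(n)) {
    cur <- integer(m)
    hit <- av[i] == bv
    cur[hit] <- 1L
    if (m > 1L) {
      idx <- which(hit & seq_len(m) > 1L)
      cur[idx] <- prev[idx - 1L] + 1L
    }
    best <- max(best, cur)
    prev <- cur
  }
  as.integer(best)
}
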