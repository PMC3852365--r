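## Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate code with a temporarily fixed RNG seed
#'
#' Saves and restores `.Random.seed` so that package functions taking a
#' `seed` argument do not disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

## Derive a distinct sub-seed from a master seed, kept below 2^31.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 1103515245 + 12345 * k) %% 2147483647
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Translate an in-frame nucleotide string (length multiple of 3 not
## required; trailing partial codon ignored). Stops rendered as "*".
translate_nt <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3
  if (n < 3) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(nt, 1, n)),
                                     if.fuzzy.codon = "X"))
}

str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a
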