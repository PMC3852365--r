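## IUPAC nucleotide ambiguity handling and degenerate primer sets.

#' IUPAC ambiguity code table
#'
#' Named list mapping each IUPAC nucleotide code to the set of concrete
#' bases it represents.
#' @export
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
                H = "D", V = "B", N = "N")

## Reverse complement preserving ambiguity codes.
revcomp_iupac <- function(x) {
  paste(rev(unname(IUPAC_COMP[str_chars(toupper(x))])), collapse = "")
}

assert_iupac <- function(x, what = "sequence") {
  ch <- str_chars(toupper(x))
  bad <- which(!ch %in% names(IUPAC_CODES))
  if (length(bad))
    stop(sprintf("invalid IUPAC character '%s' at position %d of %s",
                 ch[bad[1]], bad[1], what), call. = FALSE)
  invisible(x)
}

#' Expand a degenerate IUPAC primer
#'
#' Enumerates the concrete sequences represented by an IUPAC string, or just
#' counts them when the pool is large.
#'
#' @param primer IUPAC nucleotide string.
#' @param max_enumerate Pools larger than this are not enumerated; only the
#'   cardinality is returned.
#' @return List with `count` (numeric) and `sequences` (character vector, or
#'   `NULL` when the pool exceeds `max_enumerate`).
#' @examples
#' expand_degenerate("ACGT")$count  # 1
#' expand_degenerate("N")$count     # 4
#' @export
expand_degenerate <- function(primer, max_enumerate = 65536) {
  assert_iupac(primer, "primer")
  sets <- IUPAC_CODES[str_chars(toupper(primer))]
  count <- prod(vapply(sets, length, 1L))
  seqs <- NULL
  if (count <= max_enumerate) {
    grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
    seqs <- apply(grid[, rev(seq_along(sets)), drop = FALSE], 1, paste,
                  collapse = "")
  }
  list(count = count, sequences = seqs)
}

#' Degenerate primer sets targeting the copia RT domain
#'
#' The three published degenerate primer pairs (F, V and H) directed at
#' highly conserved peptide motifs of the copia-type reverse transcriptase.
#' Each is returned as a `primer_set` with a permissive product-length range:
#' the canonical RT product is about 300 bp, but diverged family members may
#' shift it.
#'
#' @param name One of "F", "V", "H".
#' @param max_mismatch Substitutions tolerated per primer (degenerate
#'   positions match their code set at zero cost).
#' @param product_range Allowed amplicon length range in bp.
#' @return A `primer_set` object.
#' @export
rt_primer_set <- function(name = c("F", "V", "H"), max_mismatch = 1,
                          product_range = c(100, 1500)) {
  name <- match.arg(name)
  p <- switch(name,
    F = c("ACNGCNTTYYTNCAYGG", "ARCATRTCRTCNACRTA"),
    V = c("CARATGGAYGTNAARAC", "CATRTCRTCNACRTA"),
    H = c("GAYGTNAARACNGNTTYYT", "AYRTRTCNACRTANARNA"))
  primer_set(name, p[1], p[2], max_mismatch = max_mismatch,
             product_range = product_range)
}

#' Construct a primer set
#'
#' @param name Label for the set.
#' @param forward,reverse IUPAC primer sequences, written 5'-3'.
#' @param max_mismatch Mismatches tolerated per primer.
#' @param product_range Numeric length-2, allowed product size in bp; must be
#'   at least the summed primer lengths.
#' @export
primer_set <- function(name, forward, reverse, max_mismatch = 1,
                       product_range = c(100, 1500)) {
  assert_iupac(forward, "forward primer")
  assert_iupac(reverse, "reverse primer")
  stopifnot(length(product_range) == 2, product_range[1] <= product_range[2])
  if (product_range[1] < nchar(forward) + nchar(reverse))
    stop("product_range minimum is shorter than the two primers combined",
         call. = FALSE)
  structure(list(name = name, forward = toupper(forward),
                 reverse = toupper(reverse),
                 max_mismatch = as.integer(max_mismatch),
                 product_range = as.integer(product_range)),
            class = "primer_set")
}

#' @export
print.primer_set <- function(x, ...) {
  cat(sprintf("primer_set %s: fwd %s rev %s (<=%d mismatches, product %d-%d bp)\n",
              x$name, x$forward, x$reverse, x$max_mismatch,
              x$product_range[1], x$product_range[2]))
  invisible(x)
}
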