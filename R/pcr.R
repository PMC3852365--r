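## In-silico PCR: degenerate primer site finding and amplification.

## Substitution count of a concrete sequence against an IUPAC pattern
## (degenerate positions match their code set at zero cost).
iupac_mismatches <- function(site, pattern) {
  p <- str_chars(toupper(pattern)); s <- str_chars(toupper(site))
  sum(!mapply(function(a, b) b %in% IUPAC_CODES[[a]], p, s))
}

genome_contigs <- function(genome) {
  if (inherits(genome, "annotated_genome")) genome$contigs
  else if (is.character(genome)) {
    if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
    genome
  } else stop("genome must be an annotated_genome or named character vector")
}

#' Find binding sites of a degenerate primer
#'
#' Reports every position on both strands where the IUPAC primer matches the
#' genome with at most `max_mismatch` substitutions; degenerate positions
#' match their code set at zero cost.  Matching is delegated to
#' `Biostrings::matchPattern` with `fixed = "subject"` (ambiguities in the
#' primer interpreted, genome letters literal).
#'
#' @param genome An `annotated_genome` or named character vector of contigs.
#' @param primer IUPAC primer string (5'-3').
#' @param max_mismatch Substitutions tolerated (<= 3).
#' @return Data frame `contig, start, end, strand, mismatches`; for a "-"
#'   strand site the span still refers to + strand coordinates and the
#'   primer anneals to the + strand (i.e. primes leftward synthesis).
#' @export
find_primer_sites <- function(genome, primer, max_mismatch = 1L) {
  stopifnot(max_mismatch <= 3L)
  assert_iupac(primer, "primer")
  contigs <- genome_contigs(genome)
  out <- list()
  for (cn in names(contigs)) {
    subj <- Biostrings::DNAString(contigs[[cn]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") primer else revcomp_iupac(primer)
      mm <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch,
                                     fixed = "subject")
      if (!length(mm)) next
      nmm <- vapply(as.character(mm), iupac_mismatches, 1L, pattern = pat,
                    USE.NAMES = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        contig = cn, start = BiocGenerics::start(mm),
        end = BiocGenerics::end(mm), strand = strand,
        mismatches = nmm, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$contig, res$start, res$strand), , drop = FALSE]
}

#' Amplify a genome with a primer set
#'
#' One amplicon per inward-facing pair of a + strand site (of either primer)
#' and a downstream - strand site (of either primer) whose product length
#' falls within the set's `product_range`.  Identical intervals are
#' collapsed and amplicons are sorted by coordinate.  The amplicon sequence
#' is reported 5'-3' from the set's forward primer: when the forward primer
#' matched the minus strand the genomic slice is reverse-complemented and
#' the strand is reported as "-", so amplifying a reverse-complemented
#' genome yields the same sequence multiset.
#'
#' @param genome An `annotated_genome` or named character vector.
#' @param primer_set A [primer_set()].
#' @return Data frame `contig, start, end, strand, length, fwd_primer,
#'   rev_primer, mismatches, sequence` (class `amplicon_table`).
#' @export
amplify <- function(genome, primer_set) {
  stopifnot(inherits(primer_set, "primer_set"))
  contigs <- genome_contigs(genome)
  prim <- c(forward = primer_set$forward, reverse = primer_set$reverse)
  sites <- do.call(rbind, lapply(names(prim), function(which) {
    s <- find_primer_sites(contigs, prim[[which]], primer_set$max_mismatch)
    if (nrow(s)) s$primer <- which
    s
  }))
  out <- list()
  if (!is.null(sites) && nrow(sites)) {
    plus <- sites[sites$strand == "+", , drop = FALSE]
    minus <- sites[sites$strand == "-", , drop = FALSE]
    rng <- primer_set$product_range
    for (i in seq_len(nrow(plus))) {
      p <- plus[i, ]
      cand <- minus[minus$contig == p$contig &
                    minus$end >= p$start + rng[1] - 1L &
                    minus$end <= p$start + rng[2] - 1L &
                    minus$start > p$end, , drop = FALSE]
      for (j in seq_len(nrow(cand))) {
        q <- cand[j, ]
        seqi <- substr(contigs[[p$contig]], p$start, q$end)
        strand <- "+"
        if (identical(p$primer, "reverse")) {
          seqi <- revcomp(seqi)
          strand <- "-"
        }
        out[[length(out) + 1L]] <- data.frame(
          contig = p$contig, start = p$start, end = q$end, strand = strand,
          length = q$end - p$start + 1L,
          fwd_primer = p$primer, rev_primer = q$primer,
          mismatches = p$mismatches + q$mismatches,
          sequence = seqi, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    res <- data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      length = integer(), fwd_primer = character(),
                      rev_primer = character(), mismatches = integer(),
                      sequence = character(), stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    res <- res[!duplicated(res[, c("contig", "start", "end")]), , drop = FALSE]
    res <- res[order(res$contig, res$start, res$end), , drop = FALSE]
  }
  res$primer_set <- rep(primer_set$name, nrow(res))
  rownames(res) <- NULL
  class(res) <- c("amplicon_table", "data.frame")
  res
}

#' Write amplicons as FASTA and TSV
#'
#' @param amplicons An `amplicon_table` from [amplify()].
#' @param dir Output directory.
#' @param prefix File prefix.
#' @export
write_amplicons <- function(amplicons, dir, prefix = "amplicons") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("%s_%s_%d_%d", amplicons$primer_set, amplicons$contig,
                 amplicons$start, amplicons$end)
  fa <- file.path(dir, paste0(prefix, ".fa"))
  tsv <- file.path(dir, paste0(prefix, ".tsv"))
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(amplicons$sequence), ids), fa)
  write.table(amplicons[, c("contig", "start", "end", "strand", "length",
                            "mismatches", "primer_set")],
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fa = fa, tsv = tsv))
}
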