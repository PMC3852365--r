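## Seeded local-alignment homology search (BLAST stand-in).

#' Search parameters
#'
#' Scoring and thresholding for the seeded local-alignment engine.  Defaults
#' give megablast-like behaviour: word size 11, +1/-2 match/mismatch, affine
#' gaps -5/-2, significance at E < 1e-20.  `karlin_lambda` is solved from
#' the score-generating equality at uniform base composition; `karlin_k` is
#' a calibration constant for the uniform background.
#'
#' @param word_size Exact-seed length in bp (>= 7).
#' @param match,mismatch,gap_open,gap_extend Alignment scores.
#' @param max_evalue Significance threshold.
#' @param karlin_k,karlin_lambda Karlin-Altschul constants; `NULL` lambda is
#'   solved numerically.
#' @param xdrop_ungapped,xdrop_gapped X-drop cutoffs.
#' @param band Half-width of the banded gapped extension.
#' @export
search_params <- function(word_size = 11L, match = 1L, mismatch = -2L,
                          gap_open = -5L, gap_extend = -2L,
                          max_evalue = 1e-20, karlin_k = 0.35,
                          karlin_lambda = NULL, xdrop_ungapped = 20L,
                          xdrop_gapped = 30L, band = 16L) {
  stopifnot(word_size >= 7L, match > 0, mismatch < 0)
  if (is.null(karlin_lambda))
    karlin_lambda <- solve_karlin_lambda(match, mismatch)
  structure(list(word_size = as.integer(word_size), match = as.integer(match),
                 mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 max_evalue = max_evalue, karlin_k = karlin_k,
                 karlin_lambda = karlin_lambda,
                 xdrop_ungapped = as.integer(xdrop_ungapped),
                 xdrop_gapped = as.integer(xdrop_gapped),
                 band = as.integer(band)),
            class = "search_params")
}

## Unique positive root of sum_ij p_i p_j exp(lambda * s_ij) = 1 at uniform
## base frequencies.
solve_karlin_lambda <- function(match, mismatch) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  uniroot(f, c(1e-6, 10))$root
}

evalue_of <- function(score, m, n, params) {
  params$karlin_k * m * n * exp(-params$karlin_lambda * score)
}

## Minimum score achieving max_evalue for query length m vs database n.
min_significant_score <- function(m, n, params) {
  ceiling(log(params$karlin_k * m * n / params$max_evalue) /
            params$karlin_lambda)
}

#' Seeded local-alignment search of a query against a genome
#'
#' Exact word seeding, ungapped X-drop extension, then banded gapped
#' extension; every local alignment with identity >= 90% and length >= 100
#' containing at least one exact word is guaranteed to be reported.  Both
#' strands are searched.  E-values follow Karlin-Altschul with the
#' parameters' constants; hits are sorted by score descending.
#'
#' @param query Query sequence (character).
#' @param genome An `annotated_genome` or named character vector.
#' @param params [search_params()].
#' @return Data frame `contig, qstart, qend, sstart, send, strand, length,
#'   identity, score, evalue` (1-based closed spans; `sstart < send` on the
#'   + strand coordinate system for both strands).
#' @export
search_genome <- function(query, genome, params = search_params()) {
  contigs <- genome_contigs(genome)
  query <- toupper(query)
  if (nchar(query) < params$word_size)
    stop("query shorter than word_size", call. = FALSE)
  dbn <- sum(nchar(contigs))
  min_score <- min_significant_score(nchar(query), dbn, params)
  out <- list()
  for (cn in names(contigs)) {
    subj <- toupper(contigs[[cn]])
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query else revcomp(query)
      h <- cpp_search(q, subj, params$word_size, params$match,
                      params$mismatch, params$gap_open, params$gap_extend,
                      params$xdrop_ungapped, params$xdrop_gapped,
                      params$band, min_score)
      if (!nrow(h)) next
      if (strand == "-") {
        ql <- nchar(query)
        tmp <- h$qstart
        h$qstart <- ql - h$qend + 1L
        h$qend <- ql - tmp + 1L
      }
      h$contig <- cn
      h$strand <- strand
      out[[length(out) + 1L]] <- h
    }
  }
  if (!length(out))
    return(data.frame(contig = character(), qstart = integer(),
                      qend = integer(), sstart = integer(), send = integer(),
                      strand = character(), length = integer(),
                      identity = numeric(), score = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$identity <- res$matches / res$length
  res$evalue <- evalue_of(res$score, nchar(query), dbn, params)
  res <- res[res$evalue <= params$max_evalue, , drop = FALSE]
  res <- res[order(-res$score, res$contig, res$sstart), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("contig", "qstart", "qend", "sstart", "send", "strand", "length",
          "identity", "score", "evalue")]
}

## Collapse hits to non-overlapping subject loci, keeping the best hit per
## locus (overlap on the subject defined as any shared base).
collapse_loci <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits <- hits[order(-hits$score), , drop = FALSE]
  keep <- logical(nrow(hits))
  occ <- list()
  for (i in seq_len(nrow(hits))) {
    cn <- hits$contig[i]
    iv <- occ[[cn]]
    s <- hits$sstart[i]; e <- hits$send[i]
    if (is.null(iv) || !any(s <= iv[, 2] & e >= iv[, 1])) {
      keep[i] <- TRUE
      occ[[cn]] <- rbind(iv, c(s, e))
    }
  }
  hits[keep, , drop = FALSE]
}

#' Count qualifying hit loci of a query (copy-number proxy)
#'
#' Number of non-overlapping subject loci with a significant hit;
#' overlapping hits on one locus are collapsed to the best.
#'
#' @inheritParams search_genome
#' @return Integer count.
#' @export
count_hits <- function(query, genome, params = search_params()) {
  nrow(collapse_loci(search_genome(query, genome, params)))
}

#' Write hits in 12-column tabular search format
#'
#' Columns mirror the standard tabular output: query, subject, percent
#' identity, alignment length, mismatches, gap openings (reported 0; the
#' engine does not count them separately), query/subject spans, E-value and
#' score.
#'
#' @param hits Data frame from [search_genome()].
#' @param query_id Query label.
#' @param path Output TSV path.
#' @export
write_hits <- function(hits, query_id, path) {
  df <- data.frame(
    query = query_id, subject = hits$contig,
    pident = round(100 * hits$identity, 2), length = hits$length,
    mismatch = round(hits$length * (1 - hits$identity)), gapopen = 0L,
    qstart = hits$qstart, qend = hits$qend,
    sstart = ifelse(hits$strand == "+", hits$sstart, hits$send),
    send = ifelse(hits$strand == "+", hits$send, hits$sstart),
    evalue = format(hits$evalue, digits = 3), bitscore = hits$score)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Enumerate non-overlapping Smith-Waterman local alignments (oracle)
#'
#' Full quadratic Smith-Waterman with affine gaps, repeatedly extracting the
#' best alignment and masking its subject span.  Exact but slow; intended as
#' an independent check of [search_genome()] on small instances.
#'
#' @param query,subject Sequences (character; single subject).
#' @param params [search_params()].
#' @param min_score Report alignments scoring at least this.
#' @param max_hits Safety cap.
#' @return Data frame `qstart, qend, sstart, send, score`.
#' @export
sw_enumerate <- function(query, subject, params = search_params(),
                         min_score, max_hits = 200L) {
  cpp_sw_all(toupper(query), toupper(subject), params$match, params$mismatch,
             params$gap_open, params$gap_extend, as.integer(min_score),
             as.integer(max_hits))
}
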