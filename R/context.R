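## Genomic context of element copies: flank copy-number class and gene
## proximity.

#' Context-profiling parameters
#'
#' @param flank_len Flank length used as the search query (bp).
#' @param gene_window Gene search window around the element (bp).
#' @param bins Copy-number class boundaries: low `[1,10]`, moderate
#'   `[11,100]`, high `[101,Inf)`.
#' @param min_flanks_per_family Minimum flank observations for a family to
#'   be reported.
#' @export
context_params <- function(flank_len = 500L, gene_window = 5000L,
                           bins = c(low = 10L, moderate = 100L),
                           min_flanks_per_family = 20L) {
  structure(list(flank_len = as.integer(flank_len),
                 gene_window = as.integer(gene_window), bins = bins,
                 min_flanks_per_family = as.integer(min_flanks_per_family)),
            class = "context_params")
}

bin_copy_number <- function(count, params = context_params()) {
  ifelse(count <= params$bins[["low"]], "low",
         ifelse(count <= params$bins[["moderate"]], "moderate", "high"))
}

#' Copy-number class of an element flank
#'
#' Searches the `flank_len` bp flank on one side of a copy against the whole
#' genome and counts qualifying hit loci (the flank's own locus included, so
#' the count is always >= 1 for an intact flank), then bins the count into
#' low/moderate/high.
#'
#' @param genome An `annotated_genome`.
#' @param copy One row of the element table (or a list with `contig`,
#'   `start`, `end`).
#' @param side `"left"` or `"right"`.
#' @param params [context_params()].
#' @param search_params [search_params()] passed to the engine.
#' @return List with `count` and `bin`, or `NULL` (with a warning) when the
#'   flank is truncated by the contig edge.
#' @export
classify_flank_copy_number <- function(genome, copy, side = "left",
                                       params = context_params(),
                                       search_params = copiascan::search_params()) {
  contig <- genome$contigs[[copy$contig]]
  if (side == "left") {
    s <- copy$start - params$flank_len; e <- copy$start - 1L
  } else {
    s <- copy$end + 1L; e <- copy$end + params$flank_len
  }
  if (s < 1L || e > nchar(contig)) {
    warning(sprintf("flank (%s) truncated by contig edge; side skipped", side))
    return(NULL)
  }
  flank <- substr(contig, s, e)
  count <- count_hits(flank, genome, search_params)
  list(count = count, bin = bin_copy_number(count, params))
}

#' Gene presence within the flank window of a copy
#'
#' @param copy Element copy (needs `contig`, `start`, `end`).
#' @param genes Gene table of the genome.
#' @param params [context_params()].
#' @return List with `gene_within_window` (any gene edge closer than
#'   `gene_window` bp on either side; overlap counts as distance 0) and
#'   `nearest_gene_distance` (`Inf` when the contig has no genes).
#' @export
gene_in_flank <- function(copy, genes, params = context_params()) {
  g <- genes[genes$contig == copy$contig, , drop = FALSE]
  if (!nrow(g))
    return(list(gene_within_window = FALSE, nearest_gene_distance = Inf))
  d <- pmax(0L, pmax(g$start - copy$end, copy$start - g$end) - 1L)
  list(gene_within_window = min(d) < params$gene_window,
       nearest_gene_distance = min(d))
}

#' Context profiles for every element copy
#'
#' Both flanks of each copy are profiled as separate flank observations.
#'
#' @param genome An `annotated_genome`.
#' @param params [context_params()].
#' @param search_params [search_params()].
#' @return Data frame, one row per (copy, side): `id, family, side,
#'   flank_hit_count, bin, gene_within_window, nearest_gene_distance`.
#' @export
context_profiles <- function(genome, params = context_params(),
                             search_params = copiascan::search_params()) {
  rows <- list()
  for (i in seq_len(nrow(genome$elements))) {
    el <- genome$elements[i, ]
    gene <- gene_in_flank(el, genome$genes, params)
    for (side in c("left", "right")) {
      cn <- classify_flank_copy_number(genome, el, side, params, search_params)
      if (is.null(cn)) next
      rows[[length(rows) + 1L]] <- data.frame(
        id = el$id, family = el$family, side = side,
        flank_hit_count = cn$count, bin = cn$bin,
        gene_within_window = gene$gene_within_window,
        nearest_gene_distance = gene$nearest_gene_distance,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-family genomic-context report
#'
#' Fractions of flank observations per copy-number bin and the fraction of
#' copies with a gene within the window; families with a gene fraction above
#' 0.6 are flagged as marker candidates.  Families with fewer than
#' `min_flanks_per_family` flank observations are excluded with a warning.
#'
#' @param profiles Data frame from [context_profiles()].
#' @param params [context_params()].
#' @return Data frame `family, n_flanks, frac_low, frac_moderate, frac_high,
#'   frac_gene_5kb, marker_candidate`.
#' @export
family_context_report <- function(profiles, params = context_params()) {
  out <- list()
  for (fam in unique(profiles$family)) {
    p <- profiles[profiles$family == fam, , drop = FALSE]
    if (nrow(p) < params$min_flanks_per_family) {
      warning(sprintf("family %s: only %d flank observation(s) (< %d); excluded from report",
                      fam, nrow(p), params$min_flanks_per_family))
      next
    }
    ## gene presence is a per-copy property; one observation per copy
    percopy <- p[!duplicated(p$id), , drop = FALSE]
    frac_gene <- mean(percopy$gene_within_window)
    out[[length(out) + 1L]] <- data.frame(
      family = fam, n_flanks = nrow(p),
      frac_low = mean(p$bin == "low"),
      frac_moderate = mean(p$bin == "moderate"),
      frac_high = mean(p$bin == "high"),
      frac_gene_5kb = frac_gene,
      marker_candidate = frac_gene > 0.6,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
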