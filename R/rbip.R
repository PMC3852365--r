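## RBIP marker design and in-silico genotyping: three primer sets per locus
## (flank x LTR junctions for the occupied allele, flank x flank for the
## empty allele).

#' Select recently retrotransposed copies suitable as RBIP loci
#'
#' Returns full-length copies with byte-identical LTR pairs and a detected
#' target site duplication — the hallmarks of recent insertion.
#'
#' @param genome An `annotated_genome`.
#' @param params [annot_params()].
#' @return Element table subset (possibly empty).
#' @export
find_recent_insertions <- function(genome, params = annot_params()) {
  el <- genome$elements
  if (!nrow(el)) return(el)
  keep <- logical(nrow(el))
  for (i in seq_len(nrow(el))) {
    e <- el[i, ]
    if (e$truncated_5p > 0 || e$truncated_3p > 0) next
    seqi <- substr(genome$contigs[[e$contig]], e$start, e$end)
    lt <- tryCatch(detect_ltr_pair(seqi, params), error = function(err) NULL)
    if (is.null(lt) || lt$identity < 1) next
    tsd <- detect_tsd(genome$contigs[[e$contig]], c(e$start, e$end), params)
    keep[i] <- !is.na(tsd)
  }
  el[keep, , drop = FALSE]
}

## Exact genomic occurrence count of a short oligo (both strands).
oligo_site_count <- function(genome, oligo) {
  nrow(find_primer_sites(genome, oligo, max_mismatch = 0L))
}

#' Design an RBIP marker for an insertion locus
#'
#' Four primers are placed around the insertion: `flkl` (forward, left
#' flank) with `ltrl` (reverse, inside the 5' LTR) amplify the left
#' junction; `ltrr` (forward, inside the 3' LTR) with `flkr` (reverse,
#' right flank) amplify the right junction; `flkl` with `flkr` amplify the
#' empty (pre-insertion) allele only.  Both junction products span their
#' LTR/flank boundary and the TSD.  Flank primers are pushed as far from
#' the TSD as the junction product bound allows and must each have a unique
#' exact genomic site (they are stepped inward until unique); the LTR
#' primers necessarily bind every LTR of the family — assay specificity
#' comes from the unique flank primers and the expected product sizes.
#' Repetitive flanks (not in the "low" copy-number bin) are rejected.
#'
#' @param genome An `annotated_genome`.
#' @param copy One row of the element table (a recent insertion).
#' @param primer_len Primer length in nt.
#' @param junction_range Allowed junction product lengths (bp).
#' @param params [annot_params()].
#' @param context_params [context_params()] for the flank uniqueness check.
#' @param search_params [search_params()] for the flank uniqueness check.
#' @param check_flank_bin Set `FALSE` to skip the (expensive) flank
#'   copy-number pre-check.
#' @return An `rbip_marker`: primers, their genomic spans, and expected
#'   `occupied_left`, `occupied_right`, `empty` product sizes.
#' @export
design_marker <- function(genome, copy, primer_len = 20L,
                          junction_range = c(100L, 400L),
                          params = annot_params(),
                          context_params = copiascan::context_params(),
                          search_params = copiascan::search_params(),
                          check_flank_bin = TRUE) {
  contig <- genome$contigs[[copy$contig]]
  tsd <- detect_tsd(contig, c(copy$start, copy$end), params)
  if (is.na(tsd))
    stop("no TSD at this locus; not a suitable RBIP site", call. = FALSE)
  tl <- nchar(tsd)
  if (copy$start - junction_range[2] < 1 ||
      copy$end + junction_range[2] > nchar(contig))
    stop("insufficient flanking sequence for marker design", call. = FALSE)
  if (check_flank_bin) {
    for (side in c("left", "right")) {
      cn <- classify_flank_copy_number(genome, copy, side, context_params,
                                       search_params)
      if (is.null(cn) || cn$bin != "low")
        stop(sprintf("repetitive %s flank (bin %s): no marker designed",
                     side, if (is.null(cn)) "edge" else cn$bin), call. = FALSE)
    }
  }
  uniquify <- function(make_primer, offsets) {
    for (off in offsets) {
      p <- make_primer(off)
      if (is.null(p)) next
      if (oligo_site_count(genome, p$seq) == 1) return(p)
    }
    stop("no unique primer placement found", call. = FALSE)
  }
  ## left flank forward primer: as far left as the junction bound allows;
  ## product = flkl start .. ltrl site end
  ltr_in <- 60L  # junction products reach this far into the LTR
  flkl <- uniquify(function(off) {
    s <- copy$start - junction_range[2] + ltr_in + off
    if (s < 1) return(NULL)
    list(seq = substr(contig, s, s + primer_len - 1L), start = s,
         end = s + primer_len - 1L)
  }, seq(0L, 200L, by = 10L))
  ltrl_end <- copy$start + ltr_in - 1L
  ltrl <- list(seq = revcomp(substr(contig, ltrl_end - primer_len + 1L,
                                    ltrl_end)),
               start = ltrl_end - primer_len + 1L, end = ltrl_end)
  ltrr <- list(seq = substr(contig, copy$end - ltr_in + 1L,
                            copy$end - ltr_in + primer_len),
               start = copy$end - ltr_in + 1L,
               end = copy$end - ltr_in + primer_len)
  flkr <- uniquify(function(off) {
    e <- copy$end + junction_range[2] - ltr_in - off
    if (e > nchar(contig)) return(NULL)
    list(seq = revcomp(substr(contig, e - primer_len + 1L, e)),
         start = e - primer_len + 1L, end = e)
  }, seq(0L, 200L, by = 10L))
  occupied_left <- ltrl$end - flkl$start + 1L
  occupied_right <- flkr$end - ltrr$start + 1L
  element_len <- copy$end - copy$start + 1L
  empty <- flkr$end - flkl$start + 1L - element_len - tl
  structure(list(
    locus = copy$id, family = copy$family, contig = copy$contig,
    element = c(copy$start, copy$end), tsd = tsd,
    primers = list(flkl = flkl, ltrl = ltrl, ltrr = ltrr, flkr = flkr),
    expected = c(occupied_left = occupied_left,
                 occupied_right = occupied_right, empty = empty)),
    class = "rbip_marker")
}

#' @export
print.rbip_marker <- function(x, ...) {
  cat(sprintf("rbip_marker %s (%s): occupied %d+%d bp, empty %d bp, TSD %s\n",
              x$locus, x$family, x$expected["occupied_left"],
              x$expected["occupied_right"], x$expected["empty"], x$tsd))
  invisible(x)
}

## Run one primer pair on one genome; returns product lengths.
pair_products <- function(genome, fwd, rev, product_range = c(50L, 2000L)) {
  ps <- primer_set("rbip", fwd, rev, max_mismatch = 0L,
                   product_range = product_range)
  amplify(genome, ps)$length
}

#' Genotype an accession panel at an RBIP marker
#'
#' Runs in-silico PCR with the three primer sets on every accession genome.
#' Call rules (haploid accessions): "occupied" requires both junction
#' products and no empty product; "empty" requires the flank-flank product
#' only; the co-occurrence of occupied and empty products is flagged
#' "mixed"; anything else is "ambiguous".
#'
#' @param panel An `accession_panel` (or named list of genomes).
#' @param marker An `rbip_marker`.
#' @param size_tol Tolerated deviation from expected product size (bp).
#' @return Data frame `accession, call, left_product, right_product,
#'   empty_product`.
#' @export
genotype_panel <- function(panel, marker, size_tol = 10L) {
  genomes <- if (inherits(panel, "accession_panel")) panel$accessions else panel
  pr <- marker$primers
  near <- function(lens, expect)
    any(abs(lens - expect) <= size_tol)
  rows <- lapply(names(genomes), function(acc) {
    g <- genomes[[acc]]
    left <- pair_products(g, pr$flkl$seq, pr$ltrl$seq)
    right <- pair_products(g, pr$ltrr$seq, pr$flkr$seq)
    empty <- pair_products(g, pr$flkl$seq, pr$flkr$seq)
    has_left <- near(left, marker$expected["occupied_left"])
    has_right <- near(right, marker$expected["occupied_right"])
    has_empty <- near(empty, marker$expected["empty"])
    call <- if (has_left && has_right && !has_empty) "occupied"
      else if (has_empty && !has_left && !has_right) "empty"
      else if (has_empty && (has_left || has_right)) "mixed"
      else "ambiguous"
    data.frame(accession = acc, call = call,
               left_product = if (length(left)) left[1] else NA_integer_,
               right_product = if (length(right)) right[1] else NA_integer_,
               empty_product = if (length(empty)) empty[1] else NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Text rendering of expected gel lanes for a genotyped panel
#'
#' @param calls Data frame from [genotype_panel()].
#' @param marker The `rbip_marker`.
#' @return Character vector, one line per accession.
#' @export
gel_schematic <- function(calls, marker) {
  vapply(seq_len(nrow(calls)), function(i) {
    r <- calls[i, ]
    bands <- c(
      if (!is.na(r$left_product)) sprintf("FLKLxLTRL:%dbp", r$left_product),
      if (!is.na(r$right_product)) sprintf("LTRRxFLKR:%dbp", r$right_product),
      if (!is.na(r$empty_product)) sprintf("FLKLxFLKR:%dbp", r$empty_product))
    sprintf("%-12s [%s] %s", r$accession, r$call,
            if (length(bands)) paste(bands, collapse = " ") else "-")
  }, "")
}

#' Bundled JC7-1 RBIP primer fixture
#'
#' The four published JC7-1 assay primers (FLKL, FLKR, LTRL, LTRR), shipped
#' as a plain-text fixture for format tests.  The original flanking
#' sequences are not public, so the printed product sizes cannot be
#' reconstructed from these primers alone.
#'
#' @return Named character vector of primer sequences.
#' @export
jc7_rbip_primers <- function() {
  path <- system.file("extdata", "jc7_rbip_primers.tsv",
                      package = "copiascan")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  setNames(df$sequence, df$name)
}
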