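## AnnotatedGenome: contigs with ground-truth element copies and gene track.

#' Create an annotated genome with a random background
#'
#' The background is i.i.d. uniform ACGT (GC 0.5), a neutral substrate that
#' keeps implanted homology unambiguous.
#'
#' @param size Background length in bp (single contig).
#' @param seed Integer seed.
#' @param contig Contig name.
#' @return An `annotated_genome` with empty element and gene tracks.
#' @export
new_genome <- function(size = 2e6, seed = 1L, contig = "chr1") {
  contigs <- with_seed(seed, setNames(random_dna(size), contig))
  structure(list(
    contigs = contigs,
    elements = empty_elements(),
    genes = data.frame(id = character(), contig = character(),
                       start = integer(), end = integer(),
                       strand = character(), stringsAsFactors = FALSE),
    provenance = list(size = size, seed = seed)),
    class = "annotated_genome")
}

empty_elements <- function() {
  data.frame(id = character(), family = character(), contig = character(),
             start = integer(), end = integer(), strand = character(),
             tsd = character(), pct_divergence = numeric(),
             truncated_5p = integer(), truncated_3p = integer(),
             ltr_identical = logical(), stringsAsFactors = FALSE)
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("annotated_genome: %d contig(s), %s bp, %d element copies, %d genes\n",
              length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ","),
              nrow(x$elements), nrow(x$genes)))
  invisible(x)
}

## Substitute bases i.i.d. at the given rate; returns the mutated string.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- str_chars(seq)
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(DNA_BASES, b), 1), "")
  }
  paste(ch, collapse = "")
}

## Shift stored feature coordinates >= at by delta on one contig.
shift_features <- function(genome, contig, at, delta) {
  for (tab in c("elements", "genes")) {
    df <- genome[[tab]]
    if (!nrow(df)) next
    sel <- df$contig == contig & df$start >= at
    df$start[sel] <- df$start[sel] + delta
    df$end[sel] <- df$end[sel] + delta
    genome[[tab]] <- df
  }
  genome
}

feature_intervals <- function(genome, contig) {
  rbind(
    if (nrow(genome$elements))
      genome$elements[genome$elements$contig == contig, c("start", "end")]
    else NULL,
    if (nrow(genome$genes))
      genome$genes[genome$genes$contig == contig, c("start", "end")]
    else NULL)
}

#' Implant copies of a family template into a genome
#'
#' Each copy is placed at a position at least `min_gap` bp away from every
#' existing feature, flanked by a target site duplication of uniform length
#' in `tsd_len_range` (the TSD is the host sequence at the insertion point,
#' duplicated), and mutated by i.i.d. substitutions at rate `divergence`
#' (both LTRs of a copy mutate independently).  With probability
#' `truncation_prob` a copy is 5'- or 3'-truncated by 10-40% of its length.
#' Ground truth is appended to the element track and coordinates of existing
#' features are shifted to stay exact.
#'
#' @param genome An `annotated_genome`.
#' @param template A `family_template` from [build_family_template()].
#' @param n Copies to implant.
#' @param divergence Per-site substitution rate in `[0, 0.3]`.
#' @param tsd_len_range TSD length range in bp (default 5 bp fixed).
#' @param truncation_prob Probability a copy is truncated.
#' @param min_gap Minimum distance to existing features in bp.  The default
#'   leaves room for the 5-kb gene window plus a 1-kb guard on each side, so
#'   a gene planted for one copy can never fall within 6 kb of another.
#' @param seed Integer seed.
#' @param max_tries Placement retries per copy before failing.
#' @return The genome with `n` new copies.
#' @export
implant_copies <- function(genome, template, n, divergence = 0,
                           tsd_len_range = c(5L, 5L), truncation_prob = 0,
                           min_gap = 14000L, seed = 1L, max_tries = 400L) {
  stopifnot(inherits(genome, "annotated_genome"),
            inherits(template, "family_template"),
            divergence >= 0, divergence <= 0.3)
  fam <- template$spec$name
  P <- template$spec$ltr_len
  with_seed(seed, {
    for (i in seq_len(n)) {
      contig <- sample(names(genome$contigs), 1)
      bg <- genome$contigs[[contig]]
      tl <- if (tsd_len_range[1] == tsd_len_range[2]) tsd_len_range[1] else
        sample(tsd_len_range[1]:tsd_len_range[2], 1)
      pos <- NA
      occ <- feature_intervals(genome, contig)
      for (try in seq_len(max_tries)) {
        p <- sample.int(nchar(bg) - 2L * min_gap, 1) + min_gap
        if (is.null(occ) || !nrow(occ) ||
            all(p + min_gap < occ$start | p - min_gap > occ$end)) {
          pos <- p; break
        }
      }
      if (is.na(pos))
        stop(sprintf("placement error: could not place copy %d of %s after %d tries",
                     i, fam, max_tries), call. = FALSE)

      copy_seq <- mutate_seq(template$seq, divergence)
      t5 <- 0L; t3 <- 0L
      if (truncation_prob > 0 && runif(1) < truncation_prob) {
        cut <- as.integer(runif(1, 0.1, 0.4) * nchar(copy_seq))
        if (runif(1) < 0.5) {
          t5 <- cut; copy_seq <- substr(copy_seq, cut + 1L, nchar(copy_seq))
        } else {
          t3 <- cut; copy_seq <- substr(copy_seq, 1L, nchar(copy_seq) - cut)
        }
      }
      strand <- "+"
      L <- nchar(copy_seq)
      ltr_identical <- t5 == 0L && t3 == 0L &&
        identical(substr(copy_seq, 1L, P),
                  substr(copy_seq, L - P + 1L, L))

      tsd <- substr(bg, pos, pos + tl - 1L)
      genome$contigs[[contig]] <- paste0(
        substr(bg, 1L, pos + tl - 1L), copy_seq, substr(bg, pos, nchar(bg)))
      ## features at/after the original TSD start move right
      genome <- shift_features(genome, contig, pos, L + tl)
      start <- pos + tl
      genome$elements <- rbind(genome$elements, data.frame(
        id = sprintf("%s_%d", fam, nrow(genome$elements) + 1L),
        family = fam, contig = contig, start = start,
        end = start + L - 1L, strand = strand, tsd = tsd,
        pct_divergence = divergence, truncated_5p = t5, truncated_3p = t3,
        ltr_identical = ltr_identical, stringsAsFactors = FALSE))
    }
    genome$provenance$implants <- c(genome$provenance$implants,
                                    setNames(n, fam))
    genome
  })
}

#' Plant genes around implanted element copies
#'
#' For each element copy of a family, with probability `flank_gene_prob` a
#' gene interval (0.5-2 kb) is placed with its nearest edge uniform in
#' `[0, 5000)` bp from the element on a random side; otherwise no gene is
#' planted near that copy, so its nearest gene is at least 6 kb away
#' (guaranteed by the implantation gap).
#'
#' @param genome An `annotated_genome` with implanted elements.
#' @param specs Named list of [family_spec()] (for `flank_gene_prob`); a
#'   single numeric probability may be given instead to apply to all copies.
#' @param seed Integer seed.
#' @param max_tries Placement retries per gene.
#' @return The genome with genes added.
#' @export
plant_genes <- function(genome, specs, seed = 1L, max_tries = 50L) {
  stopifnot(nrow(genome$elements) > 0)
  prob_for <- function(fam) {
    if (is.numeric(specs)) specs
    else specs[[fam]]$flank_gene_prob
  }
  with_seed(seed, {
    for (i in seq_len(nrow(genome$elements))) {
      el <- genome$elements[i, ]
      if (runif(1) >= prob_for(el$family)) next
      contig_len <- nchar(genome$contigs[[el$contig]])
      others <- genome$elements[-i, , drop = FALSE]
      others <- others[others$contig == el$contig, , drop = FALSE]
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        d <- sample.int(5000L, 1) - 1L          # nearest-edge distance
        glen <- sample(500:2000, 1)
        if (runif(1) < 0.5) {
          gs <- el$start - d - glen; ge <- el$start - d - 1L
        } else {
          gs <- el$end + d + 1L; ge <- el$end + d + glen
        }
        if (gs < 1L || ge > contig_len) next
        ## keep >= 6 kb from every other element and off other genes
        if (nrow(others) &&
            any(pmax(others$start - ge, gs - others$end) - 1L < 6000L)) next
        if (nrow(genome$genes) &&
            any(genome$genes$contig == el$contig &
                genome$genes$start <= ge + 100L &
                genome$genes$end >= gs - 100L)) next
        genome$genes <- rbind(genome$genes, data.frame(
          id = sprintf("gene_%d", nrow(genome$genes) + 1L),
          contig = el$contig, start = gs, end = ge,
          strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
      if (!placed)
        warning(sprintf("could not place a flank gene for %s", el$id))
    }
    genome
  })
}

#' Simulate an accession panel from a reference genome
#'
#' Builds one genome per accession.  For a locus marked "absent" the
#' accession carries the pre-insertion (empty) allele: the element plus one
#' TSD copy are excised, leaving exactly one copy of the TSD motif.  All
#' other sequence is shared, apart from an optional background SNP rate.
#'
#' @param reference An `annotated_genome` with implanted elements.
#' @param presence Logical matrix, accessions x locus ids (element ids);
#'   `TRUE` = insertion present.
#' @param snp_rate Background substitution rate applied per accession.
#' @param seed Integer seed.
#' @return An `accession_panel`: list with `accessions` (named list of
#'   genomes) and the `presence` matrix.
#' @export
simulate_accessions <- function(reference, presence, snp_rate = 0,
                                seed = 1L) {
  stopifnot(is.matrix(presence), !is.null(rownames(presence)),
            !is.null(colnames(presence)))
  missing_loci <- setdiff(colnames(presence), reference$elements$id)
  if (length(missing_loci))
    stop("lookup error: locus id(s) not in truth: ",
         paste(missing_loci, collapse = ", "), call. = FALSE)
  accs <- lapply(rownames(presence), function(acc) {
    g <- reference
    g$provenance$accession <- acc
    absent <- colnames(presence)[!presence[acc, ]]
    ## excise right-to-left so earlier coordinates stay valid
    if (length(absent)) {
      idx <- match(absent, g$elements$id)
      ord <- idx[order(g$elements$start[idx], decreasing = TRUE)]
      for (i in ord) {
        el <- g$elements[i, ]
        tl <- nchar(el$tsd)
        s <- g$contigs[[el$contig]]
        g$contigs[[el$contig]] <- paste0(
          substr(s, 1L, el$start - 1L), substr(s, el$end + tl + 1L, nchar(s)))
        g <- shift_features(g, el$contig, el$end + 1L, -(el$end - el$start + 1L + tl))
        g$elements <- g$elements[g$elements$id != el$id, ]
      }
    }
    g
  })
  names(accs) <- rownames(presence)
  if (snp_rate > 0) {
    accs <- with_seed(seed, lapply(accs, function(g) {
      g$contigs[] <- vapply(g$contigs, mutate_seq, "", rate = snp_rate)
      g
    }))
  }
  structure(list(accessions = accs, presence = presence),
            class = "accession_panel")
}

#' Write a genome as FASTA + GFF3 + provenance JSON
#'
#' Feature types used in the GFF3 (1-based inclusive):
#' `LTR_retrotransposon`, `target_site_duplication` and `gene`.
#'
#' @param genome An `annotated_genome`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the paths written.
#' @export
write_genome <- function(genome, dir, prefix = "genome") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fa"))
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  js <- file.path(dir, paste0(prefix, ".provenance.json"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(genome$contigs)), fa)
  rows <- character()
  gffrow <- function(contig, type, start, end, strand, attrs)
    sprintf("%s\tcopiascan\t%s\t%d\t%d\t.\t%s\t.\t%s",
            contig, type, start, end, strand, attrs)
  if (nrow(genome$elements)) {
    el <- genome$elements
    rows <- c(rows,
      gffrow(el$contig, "LTR_retrotransposon", el$start, el$end, el$strand,
             sprintf("ID=%s;family=%s;tsd=%s;ltr_identical=%s",
                     el$id, el$family, el$tsd, el$ltr_identical)),
      gffrow(el$contig, "target_site_duplication",
             el$start - nchar(el$tsd), el$start - 1L, "+",
             sprintf("ID=%s_tsd5;Parent=%s", el$id, el$id)),
      gffrow(el$contig, "target_site_duplication",
             el$end + 1L, el$end + nchar(el$tsd), "+",
             sprintf("ID=%s_tsd3;Parent=%s", el$id, el$id)))
  }
  if (nrow(genome$genes)) {
    gn <- genome$genes
    rows <- c(rows, gffrow(gn$contig, "gene", gn$start, gn$end, gn$strand,
                           sprintf("ID=%s", gn$id)))
  }
  writeLines(c("##gff-version 3", rows), gff)
  jsonlite::write_json(genome$provenance, js, auto_unbox = TRUE, digits = NA)
  invisible(c(fa = fa, gff = gff, json = js))
}
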