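## Structural annotation of full-length elements: LTR pair, PBS, PPT,
## GAG-POL ORF with domain order, TSD, restriction map, lineage assignment.

#' Annotation parameters
#'
#' Thresholds used by the structural annotator.  Defaults: tRNA-Met core
#' `TGGTATCAGAGC` searched within 30 bp after the 5' LTR with at most one
#' mismatch; PPT as the best purine window (>= 9 bp, purine fraction >= 0.8)
#' ending within 50 bp of the 3' LTR; LTRs at least 100 bp long and >= 85%
#' identical, anchored within 25 bp of the sequence ends; TSDs 4-6 bp.
#'
#' @param trna_core tRNA 3'-end complement used as the PBS core.
#' @param pbs_window bp after the 5' LTR searched for the PBS core.
#' @param pbs_max_mismatch Substitutions tolerated in the PBS core.
#' @param ppt_window bp before the 3' LTR searched for the PPT.
#' @param ppt_min_len Minimum PPT length in bp.
#' @param ppt_purine_frac Minimum purine fraction of a PPT.
#' @param min_ltr Minimum LTR length in bp.
#' @param min_ltr_identity Minimum identity between the two LTRs.
#' @param ltr_anchor bp of slack allowed between a sequence end and its LTR.
#' @param tsd_range Allowed TSD length range in bp.
#' @param rt_core_len Expected RT core length in amino acids.
#' @export
annot_params <- function(trna_core = TRNA_MET_CORE, pbs_window = 30L,
                         pbs_max_mismatch = 1L, ppt_window = 50L,
                         ppt_min_len = 9L, ppt_purine_frac = 0.8,
                         min_ltr = 100L, min_ltr_identity = 0.85,
                         ltr_anchor = 25L, tsd_range = c(4L, 6L),
                         rt_core_len = 220L) {
  structure(list(trna_core = toupper(trna_core),
                 pbs_window = as.integer(pbs_window),
                 pbs_max_mismatch = as.integer(pbs_max_mismatch),
                 ppt_window = as.integer(ppt_window),
                 ppt_min_len = as.integer(ppt_min_len),
                 ppt_purine_frac = ppt_purine_frac,
                 min_ltr = as.integer(min_ltr),
                 min_ltr_identity = min_ltr_identity,
                 ltr_anchor = as.integer(ltr_anchor),
                 tsd_range = as.integer(tsd_range),
                 rt_core_len = as.integer(rt_core_len)),
            class = "annot_params")
}

#' Detect the LTR pair of an element sequence
#'
#' Finds the highest-scoring pair of equal-length direct repeats with the 5'
#' member anchored within `ltr_anchor` bp of the sequence start and the 3'
#' member within `ltr_anchor` bp of the end (score = matches − 2·mismatches
#' along the repeat diagonal).
#'
#' @param seq Element sequence (character).
#' @param params [annot_params()].
#' @return List with `ltr5`, `ltr3` (1-based closed spans), `length` and
#'   `identity`.
#' @export
detect_ltr_pair <- function(seq, params = annot_params()) {
  if (nchar(seq) < 2 * params$min_ltr + 100)
    stop("sequence too short to contain an LTR pair", call. = FALSE)
  res <- cpp_ltr_scan(toupper(seq), params$min_ltr, params$ltr_anchor, 2L,
                      params$min_ltr_identity)
  if (!isTRUE(res$found))
    stop("not an LTR element: no qualifying direct-repeat pair found",
         call. = FALSE)
  list(ltr5 = c(res$ltr5_start, res$ltr5_end),
       ltr3 = c(res$ltr3_start, res$ltr3_end),
       length = res$length, identity = res$identity)
}

#' Detect the primer binding site (PBS)
#'
#' Locates the tRNA core complement within `pbs_window` bp downstream of the
#' 5' LTR, tolerating `pbs_max_mismatch` substitutions.  The spacer length is
#' the offset between the LTR end and the core start.
#'
#' @param seq Element sequence.
#' @param ltr5_end 1-based end position of the 5' LTR.
#' @param params [annot_params()].
#' @return List with `present`, `span` and `spacer_len` (`NA` when absent).
#' @export
detect_pbs <- function(seq, ltr5_end, params = annot_params()) {
  core <- str_chars(params$trna_core)
  k <- length(core)
  region_end <- min(nchar(seq), ltr5_end + params$pbs_window + k)
  s <- str_chars(toupper(substr(seq, ltr5_end + 1, region_end)))
  max_off <- min(length(s) - k, params$pbs_window)
  if (max_off >= 0) {
    for (off in 0:max_off) {
      if (sum(s[off + seq_len(k)] != core) <= params$pbs_max_mismatch)
        return(list(present = TRUE,
                    span = c(ltr5_end + off + 1, ltr5_end + off + k),
                    spacer_len = off))
    }
  }
  list(present = FALSE, span = c(NA_integer_, NA_integer_),
       spacer_len = NA_integer_)
}

#' Detect the polypurine tract (PPT)
#'
#' Scans the `ppt_window` bp immediately upstream of the 3' LTR for the
#' window (length >= `ppt_min_len`) with the highest purine fraction, at
#' least `ppt_purine_frac`; ties are broken towards the leftmost start and
#' then the longer window.
#'
#' @param seq Element sequence.
#' @param ltr3_start 1-based start position of the 3' LTR.
#' @param params [annot_params()].
#' @return List with `present`, `span` and `purine_frac`.
#' @export
detect_ppt <- function(seq, ltr3_start, params = annot_params()) {
  lo <- max(1L, ltr3_start - params$ppt_window)
  region <- str_chars(toupper(substr(seq, lo, ltr3_start - 1L)))
  n <- length(region)
  best <- NULL
  if (n >= params$ppt_min_len) {
    pur <- cumsum(c(0L, as.integer(region %in% c("A", "G"))))
    for (start in seq_len(n - params$ppt_min_len + 1L)) {
      for (len in params$ppt_min_len:(n - start + 1L)) {
        frac <- (pur[start + len] - pur[start]) / len
        if (frac < params$ppt_purine_frac) next
        if (is.null(best) || frac > best$frac ||
            (frac == best$frac && (start < best$start ||
             (start == best$start && len > best$len))))
          best <- list(start = start, len = len, frac = frac)
      }
    }
  }
  if (is.null(best))
    return(list(present = FALSE, span = c(NA_integer_, NA_integer_),
                purine_frac = NA_real_))
  list(present = TRUE,
       span = c(lo + best$start - 1L, lo + best$start + best$len - 2L),
       purine_frac = best$frac)
}

## All ATG..stop open reading frames on the + strand within a region.
find_orfs <- function(seq, region = c(1L, nchar(seq))) {
  sub <- toupper(substr(seq, region[1], region[2]))
  n <- nchar(sub)
  out <- list()
  for (frame in 0:2) {
    starts <- seq(1L + frame, n - 2L, by = 3L)
    if (!length(starts)) next
    codons <- substring(sub, starts, starts + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    ## segment between consecutive stops; ORF = first ATG .. stop
    seg <- cumsum(c(TRUE, head(is_stop, -1)))
    for (s in split(seq_along(codons), seg)) {
      stops <- s[is_stop[s]]
      if (!length(stops)) next
      stop_i <- stops[1]
      atgs <- s[is_atg[s] & s < stop_i]
      if (!length(atgs)) next
      a <- atgs[1]
      out[[length(out) + 1L]] <- data.frame(
        start = region[1] + starts[a] - 1L,
        end = region[1] + starts[stop_i] - 2L,  # excludes the stop codon
        aa_len = stop_i - a)
    }
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer(),
                                      aa_len = integer()))
  do.call(rbind, out)
}

## Approximate peptide motif search (<= max_mismatch substitutions);
## returns the first position or NA.
find_peptide_motif <- function(pep, motif, max_mismatch = 1L) {
  p <- str_chars(pep); m <- str_chars(motif)
  k <- length(m)
  if (length(p) < k) return(NA_integer_)
  for (i in 1:(length(p) - k + 1L)) {
    if (sum(p[i:(i + k - 1L)] != m) <= max_mismatch) return(i)
  }
  NA_integer_
}

#' Locate the GAG-POL open reading frame and its domain order
#'
#' Finds the longest + strand ORF in the element interior, translates it and
#' locates the sentinel domain motifs (GAG, protease, integrase, RT entry and
#' YVDD core, RNase H).  The copia-characteristic order (integrase before RT)
#' is verified and flagged.
#'
#' @param seq Element sequence.
#' @param region Region to scan (default: downstream of position 1; pass the
#'   interior from the 5' LTR end to catch ORFs running into the 3' LTR).
#' @param min_aa ORFs shorter than this are flagged degenerate.
#' @return List with `orf` span, `aa_len`, `peptide`, `domains` (data frame
#'   name/aa_pos), `copia_order` and `degenerate` flags.
#' @export
find_gag_pol <- function(seq, region = c(1L, nchar(seq)), min_aa = 900L) {
  orfs <- find_orfs(seq, region)
  if (!nrow(orfs))
    return(list(orf = c(NA, NA), aa_len = 0L, peptide = "",
                domains = data.frame(), copia_order = FALSE,
                degenerate = TRUE))
  best <- orfs[which.max(orfs$aa_len), ]
  pep <- translate_nt(substr(seq, best$start, best$end))
  motifs <- c(GAG = unname(DOMAIN_ANCHORS["GAG"]),
              PR = unname(DOMAIN_ANCHORS["PR"]),
              INT = unname(DOMAIN_ANCHORS["INT"]),
              RT = RT_MOTIF_ENTRY, RT_YVDD = RT_MOTIF_CORE,
              RH = unname(DOMAIN_ANCHORS["RH"]))
  pos <- vapply(motifs, function(m) find_peptide_motif(pep, m), 1L)
  dom <- data.frame(name = names(motifs), aa_pos = unname(pos),
                    stringsAsFactors = FALSE)
  found <- dom[!is.na(dom$aa_pos), ]
  copia_order <- !is.na(pos["INT"]) && !is.na(pos["RT_YVDD"]) &&
    pos["INT"] < pos["RT_YVDD"] &&
    all(diff(found$aa_pos) > 0)
  list(orf = c(best$start, best$end), aa_len = best$aa_len, peptide = pep,
       domains = dom, copia_order = copia_order,
       degenerate = best$aa_len < min_aa)
}

#' Detect a target site duplication around a genomic element copy
#'
#' Longest exact match (length within `tsd_range`) between the sequence
#' immediately left of the copy and immediately right of it.
#'
#' @param genome_seq Contig sequence (character).
#' @param span 1-based closed element span within the contig.
#' @param params [annot_params()].
#' @return TSD string, or `NA` when no match of at least the minimum length.
#' @export
detect_tsd <- function(genome_seq, span, params = annot_params()) {
  for (l in rev(seq(params$tsd_range[1], params$tsd_range[2]))) {
    if (span[1] - l < 1 || span[2] + l > nchar(genome_seq)) next
    left <- substr(genome_seq, span[1] - l, span[1] - 1L)
    right <- substr(genome_seq, span[2] + 1L, span[2] + l)
    if (identical(toupper(left), toupper(right))) return(toupper(left))
  }
  NA_character_
}

#' Restriction map of a sequence
#'
#' All exact recognition-site occurrences and the resulting fragment
#' lengths (cuts taken at site starts; fragments always partition the
#' sequence length).
#'
#' @param seq Sequence (character).
#' @param enzymes Named character vector of recognition sites.
#' @return Named list per enzyme: `sites` (1-based site starts) and
#'   `fragments` (lengths, summing to `nchar(seq)`).
#' @export
restriction_map <- function(seq,
                            enzymes = c(EcoRI = "GAATTC", BamHI = "GGATCC")) {
  s <- toupper(seq)
  L <- nchar(s)
  lapply(enzymes, function(site) {
    hits <- gregexpr(site, s, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    cuts <- sort(unique(hits - 1L))  # cut offset before each site start
    cuts <- cuts[cuts > 0 & cuts < L]
    list(sites = as.integer(hits), fragments = diff(c(0L, cuts, L)))
  })
}

#' Full structural annotation of an element sequence
#'
#' Runs LTR-pair, PBS, PPT and GAG-POL detection on a full-length element
#' (consensus or genomic copy normalised to + orientation) and returns an
#' `element_annotation` mirroring the structural summary table: total
#' length, LTR length, GAG-POL aa length, PBS spacer, PPT.
#'
#' @param seq Element sequence.
#' @param params [annot_params()].
#' @return An `element_annotation` list.
#' @export
annotate_element <- function(seq, params = annot_params()) {
  ltr <- detect_ltr_pair(seq, params)
  pbs <- detect_pbs(seq, ltr$ltr5[2], params)
  ppt <- detect_ppt(seq, ltr$ltr3[1], params)
  orf <- find_gag_pol(seq, region = c(ltr$ltr5[2] + 1L, nchar(seq)))
  structure(list(
    ltr5 = ltr$ltr5, ltr3 = ltr$ltr3, ltr_len = ltr$length,
    ltr_identity = ltr$identity,
    pbs = pbs, ppt = ppt, orf = orf,
    total_len = ltr$ltr3[2] - ltr$ltr5[1] + 1L), class = "element_annotation")
}

#' @export
print.element_annotation <- function(x, ...) {
  cat(sprintf("element_annotation: total %d bp, LTR %d bp (identity %.3f), GAG-POL %d aa, PBS spacer %s, PPT %s\n",
              x$total_len, x$ltr_len, x$ltr_identity, x$orf$aa_len,
              ifelse(x$pbs$present, x$pbs$spacer_len, "absent"),
              ifelse(x$ppt$present,
                     sprintf("purine %.2f", x$ppt$purine_frac), "absent")))
  invisible(x)
}

#' Structural summary table for a set of annotated families
#'
#' @param annotations Named list of `element_annotation` objects (one per
#'   family).
#' @param seqs Named character vector of the annotated sequences (used to
#'   print the PBS/PPT strings).
#' @param lineages Optional named lineage labels.
#' @return Data frame with columns lineage, family, total_len, ltr_len,
#'   gagpol_aa, pbs, ppt.
#' @export
structural_table <- function(annotations, seqs, lineages = NULL) {
  fam <- names(annotations)
  do.call(rbind, lapply(fam, function(f) {
    a <- annotations[[f]]; s <- seqs[[f]]
    data.frame(
      lineage = if (is.null(lineages)) NA_character_ else lineages[[f]],
      family = f,
      total_len = a$total_len, ltr_len = a$ltr_len,
      gagpol_aa = a$orf$aa_len,
      pbs = if (a$pbs$present) substr(s, a$ltr5[2] + 1L, a$pbs$span[2]) else NA,
      ppt = if (a$ppt$present) substr(s, a$ppt$span[1], a$ppt$span[2]) else NA,
      stringsAsFactors = FALSE)
  }))
}

#' Reference RT-core peptides for lineage assignment
#'
#' Synthetic reference peptides derived from the three lineage-ancestral RT
#' cores (two per lineage) plus a random outgroup peptide.  These stand in
#' for published plant copia reference RT sequences; they are generated, not
#' curated data.
#'
#' @param n_per References per lineage.
#' @param seed Seed for the reference draw.
#' @return Named character vector of peptides; names are
#'   `<lineage>_ref<i>` plus `outgroup`.
#' @export
lineage_references <- function(n_per = 2L, seed = 4242L) {
  with_seed(seed, {
    refs <- list()
    for (lin in c("I", "II", "III")) {
      for (i in seq_len(n_per)) {
        core <- family_rt_core(lin, ancestor_keep = 0.45)
        refs[[sprintf("%s_ref%d", lin, i)]] <-
          translate_nt(paste(core, collapse = ""))
      }
    }
    refs[["outgroup"]] <- paste(
      sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
             RT_CORE_LEN_AA, replace = TRUE), collapse = "")
    unlist(refs)
  })
}

#' Assign an RT-core peptide to a lineage
#'
#' Builds a neighbor-joining tree of the query, the labelled reference
#' peptides and the designated outgroup, roots at the outgroup, and votes the
#' lineage of the smallest clade containing the query and only references of
#' one lineage.  Bootstrap resampling of alignment columns gives the support;
#' below `min_support` of `bootstrap_n` replicates the query is left
#' "unassigned".
#'
#' @param rt_pep Query RT-core peptide.
#' @param references Named peptide vector as from [lineage_references()];
#'   must include an entry named "outgroup".
#' @param bootstrap_n Bootstrap replicates.
#' @param min_support Minimum winning-vote fraction.
#' @return List with `lineage` and `support` (votes for the winner).
#' @export
assign_lineage <- function(rt_pep, references = lineage_references(),
                           bootstrap_n = 100L, min_support = 0.5) {
  stopifnot("outgroup" %in% names(references))
  peps <- c(query = rt_pep, references)
  len <- min(nchar(peps))
  mat <- do.call(rbind, lapply(peps, function(p) str_chars(substr(p, 1, len))))
  vote_once <- function(cols) {
    m <- mat[, cols, drop = FALSE]
    d <- outer(seq_len(nrow(m)), seq_len(nrow(m)),
               Vectorize(function(i, j) mean(m[i, ] != m[j, ])))
    dimnames(d) <- list(rownames(mat), rownames(mat))
    tr <- neighbor_joining(d)
    tr <- ape::root(tr, outgroup = "outgroup", resolve.root = TRUE)
    ## walk from the query tip towards the root; first clade with references
    path <- ape::nodepath(tr, from = which(tr$tip.label == "query"),
                          to = ape::Ntip(tr) + 1L)
    for (node in path[-1]) {
      if (node <= ape::Ntip(tr)) next
      tips <- ape::extract.clade(tr, node)$tip.label
      refs <- setdiff(tips, c("query", "outgroup"))
      if (!length(refs)) next
      lins <- unique(sub("_ref[0-9]+$", "", refs))
      return(if (length(lins) == 1) lins else NA_character_)
    }
    NA_character_
  }
  votes <- vapply(seq_len(bootstrap_n), function(i)
    vote_once(sample.int(len, len, replace = TRUE)), "")
  tab <- table(votes[!is.na(votes)])
  if (!length(tab)) return(list(lineage = "unassigned", support = 0L))
  win <- names(tab)[which.max(tab)]
  support <- as.integer(max(tab))
  if (support < min_support * bootstrap_n)
    return(list(lineage = "unassigned", support = support))
  list(lineage = win, support = support)
}
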