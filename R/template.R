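## Family template construction: a full-length element sequence with exact
## ground-truth structural annotation.

.cache <- new.env(parent = emptyenv())

## Sentinel peptide anchors marking the GAG-POL domains.  These are fixed,
## published-style anchors of the package's own design (not copied from any
## element); the two RT anchors (TAFLHG, YVDDM) are forced by the degenerate
## primer sites themselves.
DOMAIN_ANCHORS <- c(GAG = "RQGSKGGRGGK", PR = "TLIDSGASHS",
                    INT = "KGYHPQTNGV", RH = "VSTDSRSLAQ")
RT_MOTIF_ENTRY <- "TAFLHG"   # encoded by the F forward primer site
RT_MOTIF_CORE  <- "YVDD"     # encoded by the shared reverse primer site

RT_CORE_LEN_AA <- 220L

## Layout of the degenerate primer binding sites inside the 660-nt RT core
## (1-based offsets; the core itself is codon-aligned within the ORF).
## The V and H forward sites overlap IUPAC-compatibly; the H reverse site is
## placed just downstream of the shared F/V reverse site.  Resulting product
## sizes: F 302 bp, V 225 bp, H 239 bp; three-set overlap 73 aa.
rt_core_sites <- function() {
  f <- rt_primer_set("F"); v <- rt_primer_set("V"); h <- rt_primer_set("H")
  list(
    list(seq = f$forward, at = 1L),
    list(seq = v$forward, at = 76L),
    list(seq = h$forward, at = 82L),
    list(seq = revcomp_iupac(f$reverse), at = 286L),
    list(seq = revcomp_iupac(v$reverse), at = 286L),
    list(seq = revcomp_iupac(h$reverse), at = 303L))
}

## Per-position IUPAC constraints over the RT core (N where unconstrained).
rt_core_constraints <- function() {
  if (!is.null(.cache$core_constraints)) return(.cache$core_constraints)
  cons <- rep("N", 3L * RT_CORE_LEN_AA)
  for (s in rt_core_sites()) {
    ch <- str_chars(s$seq)
    for (j in seq_along(ch)) {
      p <- s$at + j - 1L
      keep <- intersect(IUPAC_CODES[[cons[p]]], IUPAC_CODES[[ch[j]]])
      if (!length(keep))
        stop("internal error: incompatible primer-site constraints")
      code <- names(IUPAC_CODES)[vapply(IUPAC_CODES, setequal, TRUE, y = keep)]
      cons[p] <- code[1]
    }
  }
  .cache$core_constraints <- cons
  cons
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

sense_codons <- function() {
  if (is.null(.cache$sense)) {
    gc <- Biostrings::GENETIC_CODE
    .cache$sense <- names(gc)[gc != "*"]
  }
  .cache$sense
}

codons_for_aa <- function() {
  if (is.null(.cache$by_aa)) {
    gc <- Biostrings::GENETIC_CODE
    .cache$by_aa <- split(names(gc), unname(gc))
  }
  .cache$by_aa
}

## Conserved 4-aa scaffold anchors spaced through the RT core (aa offsets).
## Real RT domains carry short conserved blocks between the classic motifs;
## these give the multiple alignment reliable guide posts even between
## highly diverged families.
RT_SCAFFOLD_AA <- c(50L, 72L, 120L, 145L, 170L, 195L)
RT_SCAFFOLD_LEN <- 4L

## Deterministic resolution of the constrained core positions: first
## stop-free base combination per codon for the primer sites, plus fixed
## random sense codons for the conserved scaffold anchors.  Identical for
## every family, so all primers bind every family's RT core with zero
## mismatches and the scaffold is pan-family conserved.
resolved_core_motifs <- function() {
  if (!is.null(.cache$core_motifs)) return(.cache$core_motifs)
  cons <- rt_core_constraints()
  out <- rep(NA_character_, length(cons))
  for (c0 in seq(1, length(cons), 3)) {
    idx <- c0:(c0 + 2)
    if (all(cons[idx] == "N")) next  # free codon, family-specific
    found <- FALSE
    for (b1 in IUPAC_CODES[[cons[c0]]]) {
      for (b2 in IUPAC_CODES[[cons[c0 + 1]]]) {
        for (b3 in IUPAC_CODES[[cons[c0 + 2]]]) {
          if (!found && !(paste0(b1, b2, b3) %in% STOP_CODONS)) {
            out[idx] <- c(b1, b2, b3); found <- TRUE
          }
        }
      }
    }
    if (!found) stop("internal error: constrained codon admits only stops")
  }
  out <- with_seed(9001, {
    for (a in RT_SCAFFOLD_AA) {
      for (k in seq_len(RT_SCAFFOLD_LEN) - 1L) {
        c0 <- 3L * (a + k - 1L) + 1L
        if (all(is.na(out[c0:(c0 + 2)])))
          out[c0:(c0 + 2)] <- str_chars(sample(sense_codons(), 1))
      }
    }
    out
  })
  .cache$core_motifs <- out
  out
}

## A lineage-ancestral RT core: shared motif resolution plus random sense
## codons at free positions, fixed per lineage.
lineage_ancestor_core <- function(lineage) {
  key <- paste0("ancestor_", lineage)
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  seed <- c(I = 7101, II = 7202, III = 7303)[[lineage]]
  motifs <- resolved_core_motifs()
  core <- with_seed(seed, {
    out <- motifs
    for (c0 in seq(1, length(out), 3)) {
      if (is.na(out[c0]))
        out[c0:(c0 + 2)] <- str_chars(sample(sense_codons(), 1))
    }
    out
  })
  .cache[[key]] <- core
  core
}

## Family RT core: resample free codons of the lineage ancestor so that
## families of one lineage stay recognisably related while their pairwise
## peptide distance exceeds the family cut.
family_rt_core <- function(lineage, ancestor_keep = 0.45) {
  anc <- lineage_ancestor_core(lineage)
  out <- anc
  for (c0 in seq(1, length(out), 3)) {
    if (is.na(resolved_core_motifs()[c0]) && runif(1) > ancestor_keep)
      out[c0:(c0 + 2)] <- str_chars(sample(sense_codons(), 1))
  }
  out
}

## aa positions (within the ORF) of the RT core and sentinel anchors.
orf_layout <- function(aa_len) {
  rt_start <- aa_len - 299L
  list(
    gag = 25L, pr = as.integer(floor(0.30 * aa_len)), int = aa_len - 340L,
    rt_start = rt_start, rt_end = aa_len - 80L, rh = aa_len - 40L)
}

#' Build a full-length family template with ground-truth annotation
#'
#' Constructs the canonical element sequence of a family: identical 5'/3'
#' LTRs, the PBS immediately after the 5' LTR, a stop-free GAG-POL open
#' reading frame of exactly `spec$gagpol_len` codons carrying sentinel
#' peptide anchors for GAG, protease, integrase, RT and RNase H (the 220-aa
#' RT core embeds exact binding sites for all three degenerate RT primer
#' sets), and the PPT immediately before the 3' LTR.  When the ORF is too
#' long for the internal region (as for Jc8) it is allowed to run over the
#' PPT and into the 3' LTR: the overlapped PPT codons are constrained to the
#' PPT string and the 5' LTR copy inherits the overlapping ORF bases so the
#' LTR pair stays identical.
#'
#' @param spec A [family_spec()].
#' @param seed Integer seed; the same spec and seed give a byte-identical
#'   template.
#' @param ancestor_keep Probability that a free RT-core codon retains the
#'   lineage-ancestral codon (controls within-lineage relatedness).
#' @return A `family_template`: list with `seq` (character), `spec`, and
#'   `annotation` (ground-truth spans, 1-based closed coordinates).
#' @export
build_family_template <- function(spec, seed = 1L, ancestor_keep = 0.45) {
  validate_family_spec(spec)
  L <- spec$total_len; P <- spec$ltr_len; A <- spec$gagpol_len
  pbs <- toupper(spec$pbs); ppt <- toupper(spec$ppt)
  lp <- nchar(pbs); lq <- nchar(ppt)
  orf_nt <- 3L * (A + 1L)  # including stop codon
  avail <- L - 2L * P - lp - lq
  if (orf_nt > avail && (P + lp + orf_nt) > L)
    stop(sprintf("infeasible geometry for %s: ORF of %d nt cannot fit: 2*ltr_len + pbs + orf = %d > total_len = %d",
                 spec$name, orf_nt, P + lp + orf_nt, L), call. = FALSE)

  for (try in 0:24) {
    tpl <- with_seed(derive_seed(seed, 1000 + try),
                     .assemble_template(spec, L, P, A, pbs, ppt, lp, lq,
                                        orf_nt, avail, ancestor_keep))
    ## the reported GAG-POL ORF must be exactly the implanted one: reject
    ## draws where a chance upstream in-frame ATG extends it
    orfs <- find_orfs(tpl$seq, region = c(P + 1L, L))
    best <- orfs[which.max(orfs$aa_len), , drop = FALSE]
    if (nrow(best) == 1 && best$start == tpl$annotation$orf[1] &&
        best$aa_len == A)
      return(tpl)
  }
  stop("failed to assemble a template with a clean longest ORF; ",
       "try another seed", call. = FALSE)
}

.assemble_template <- function(spec, L, P, A, pbs, ppt, lp, lq, orf_nt,
                               avail, ancestor_keep) {
  guard <- orf_nt <= avail - 3L
  if (guard) {
    slack <- avail - orf_nt - 3L
    trailer <- min(slack, 120L)
    leader <- slack - trailer
    orf_start <- P + lp + leader + 3L + 1L
  } else {
    orf_start <- P + lp + 1L
  }
  orf_end <- orf_start + orf_nt - 1L
  ppt_span <- c(L - P - lq + 1L, L - P)
  ltr3_span <- c(L - P + 1L, L)

  ## forced bases inside the ORF from an overlapping PPT
  forced <- rep(NA_character_, L)
  forced[ppt_span[1]:ppt_span[2]] <- str_chars(ppt)

  lay <- orf_layout(A)
  core <- family_rt_core(spec$lineage, ancestor_keep)
  anchors <- list(
    list(aa = lay$gag, pep = DOMAIN_ANCHORS[["GAG"]]),
    list(aa = lay$pr,  pep = DOMAIN_ANCHORS[["PR"]]),
    list(aa = lay$int, pep = DOMAIN_ANCHORS[["INT"]]),
    list(aa = lay$rh,  pep = DOMAIN_ANCHORS[["RH"]]))
  aa_source <- rep("free", A)
  aa_source[lay$rt_start:lay$rt_end] <- "core"
  pep_at <- rep(NA_character_, A)
  for (a in anchors) {
    idx <- a$aa:(a$aa + nchar(a$pep) - 1L)
    if (any(aa_source[idx] == "core"))
      stop("internal error: anchor overlaps RT core")
    aa_source[idx] <- "anchor"
    pep_at[idx] <- str_chars(a$pep)
  }
  pep_at[1] <- "M"; aa_source[1] <- "anchor"

  by_aa <- codons_for_aa(); sense <- sense_codons()
  orf <- character(orf_nt)
  for (i in seq_len(A)) {
    p0 <- orf_start + 3L * (i - 1L)
    f <- forced[p0:(p0 + 2L)]
    if (aa_source[i] == "core") {
      j <- 3L * (i - lay$rt_start)
      codon <- core[(j + 1L):(j + 3L)]
      if (any(!is.na(f) & f != codon))
        stop(sprintf("infeasible geometry for %s: PPT overlaps the RT core",
                     spec$name), call. = FALSE)
    } else if (aa_source[i] == "anchor" && all(is.na(f))) {
      codon <- str_chars(sample(by_aa[[pep_at[i]]], 1))
    } else {
      ## free (or PPT-forced) codon: honour forced bases, avoid stops
      repeat {
        codon <- str_chars(sample(sense, 1))
        codon[!is.na(f)] <- f[!is.na(f)]
        if (!(paste(codon, collapse = "") %in% STOP_CODONS)) break
        if (all(!is.na(f)))
          stop(sprintf("infeasible geometry for %s: PPT forces a stop codon",
                       spec$name), call. = FALSE)
      }
    }
    orf[(3L * (i - 1L) + 1L):(3L * i)] <- codon
  }
  ## terminal stop codon
  fstop <- forced[(orf_end - 2L):orf_end]
  stop_codon <- str_chars("TAA")
  stop_codon[!is.na(fstop)] <- fstop[!is.na(fstop)]
  if (!(paste(stop_codon, collapse = "") %in% STOP_CODONS))
    stop(sprintf("infeasible geometry for %s: PPT overlaps the ORF stop codon",
                 spec$name), call. = FALSE)
  orf[(orf_nt - 2L):orf_nt] <- stop_codon

  ## LTR: random, then inherit any ORF bases that run into the 3' LTR
  ltr <- str_chars(random_dna(P))
  if (orf_end >= ltr3_span[1]) {
    x <- orf_end - ltr3_span[1] + 1L
    ltr[seq_len(x)] <- orf[(orf_nt - x + 1L):orf_nt]
  }

  seqv <- str_chars(random_dna(L))
  seqv[1:P] <- ltr
  seqv[(P + 1L):(P + lp)] <- str_chars(pbs)
  if (guard) seqv[(orf_start - 3L):(orf_start - 1L)] <- c("T", "A", "A")
  seqv[orf_start:orf_end] <- orf
  ## PPT bases win where not already forced through the ORF
  seqv[ppt_span[1]:ppt_span[2]] <- str_chars(ppt)
  seqv[ltr3_span[1]:ltr3_span[2]] <- ltr

  rt_nt0 <- orf_start + 3L * (lay$rt_start - 1L)
  ann <- list(
    ltr5 = c(1L, P), ltr3 = ltr3_span, ltr_identity = 1.0,
    pbs = c(P + 1L, P + lp), pbs_spacer = pbs_spacer_length(pbs),
    ppt = ppt_span, orf = c(orf_start, orf_start + 3L * A - 1L),
    aa_len = A, rt_core_nt = c(rt_nt0, rt_nt0 + 3L * RT_CORE_LEN_AA - 1L),
    domains = data.frame(
      name = c("GAG", "PR", "INT", "RT", "RH"),
      aa_start = c(lay$gag, lay$pr, lay$int, lay$rt_start, lay$rh),
      stringsAsFactors = FALSE),
    total_len = L)
  structure(list(seq = paste(seqv, collapse = ""), spec = spec,
                 annotation = ann),
            class = "family_template")
}

#' @export
print.family_template <- function(x, ...) {
  cat(sprintf("family_template %s (lineage %s): %d bp, LTR %d bp, GAG-POL %d aa\n",
              x$spec$name, x$spec$lineage, x$spec$total_len,
              x$spec$ltr_len, x$annotation$aa_len))
  invisible(x)
}
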