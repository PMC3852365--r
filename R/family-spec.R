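## Family structural parameter sets (FamilySpec).

#' Construct a family structural specification
#'
#' A `family_spec` bundles the per-family structural parameters used both to
#' simulate element copies and to validate their recovery: total element
#' length, LTR length, GAG-POL polyprotein length, primer-binding-site (PBS)
#' and polypurine-tract (PPT) strings, lineage membership, a target copy
#' number for simulation and the probability that an implanted copy carries a
#' gene within 5 kb of its flanks.
#'
#' Lowercase letters in `pbs`/`ppt` mark spacer or variable (non-core)
#' positions; the PBS must contain the tRNA-Met core complement
#' (`TGGTATCAGAGC`) with at most one mismatch.
#'
#' @param name Family label (e.g. "Jc1").
#' @param lineage Lineage label: "I", "II" or "III".
#' @param total_len Full element length in bp, LTR to LTR.
#' @param ltr_len Length of each long terminal repeat in bp.
#' @param gagpol_len GAG-POL open reading frame length in amino acids
#'   (excluding the stop codon).
#' @param pbs PBS string placed immediately after the 5' LTR.
#' @param ppt PPT string placed immediately before the 3' LTR.
#' @param target_copies Copies to implant when simulating.
#' @param flank_gene_prob Probability in `[0, 1]` that a copy has a gene
#'   within 5 kb.
#' @return A `family_spec` object.
#' @export
family_spec <- function(name, lineage, total_len, ltr_len, gagpol_len,
                        pbs, ppt, target_copies = 5, flank_gene_prob = 0.5) {
  spec <- structure(list(
    name = as.character(name), lineage = as.character(lineage),
    total_len = as.integer(total_len), ltr_len = as.integer(ltr_len),
    gagpol_len = as.integer(gagpol_len), pbs = as.character(pbs),
    ppt = as.character(ppt), target_copies = as.integer(target_copies),
    flank_gene_prob = as.numeric(flank_gene_prob)), class = "family_spec")
  validate_family_spec(spec)
  spec
}

TRNA_MET_CORE <- "TGGTATCAGAGC"

validate_family_spec <- function(spec) {
  with(spec, {
    if (total_len <= 2 * ltr_len)
      stop(sprintf("infeasible geometry for %s: total_len (%d) must exceed 2*ltr_len (%d)",
                   name, total_len, 2 * ltr_len), call. = FALSE)
    if (3 * (gagpol_len + 1) + 2 * ltr_len > total_len + 300)
      stop(sprintf(
        "infeasible geometry for %s: 3*(gagpol_len+1) + 2*ltr_len = %d exceeds total_len + 300 = %d",
        name, 3 * (gagpol_len + 1) + 2 * ltr_len, total_len + 300),
        call. = FALSE)
    if (flank_gene_prob < 0 || flank_gene_prob > 1)
      stop("flank_gene_prob must lie in [0, 1]", call. = FALSE)
    if (is.na(pbs_spacer_length(pbs)))
      stop(sprintf("PBS of %s does not contain the tRNA-Met core %s (<=1 mismatch)",
                   name, TRNA_MET_CORE), call. = FALSE)
  })
  invisible(spec)
}

#' Spacer length of a PBS string
#'
#' Locates the tRNA-Met core complement (`TGGTATCAGAGC`, up to one
#' substitution) within a PBS string and returns the offset between the LTR
#' end and the core start, i.e. the number of spacer nucleotides preceding
#' the core. Returns `NA` when the core is absent.
#'
#' @param pbs PBS string (case-insensitive; lowercase marks non-core
#'   positions).
#' @param max_mismatch Substitutions tolerated in the core.
#' @export
pbs_spacer_length <- function(pbs, max_mismatch = 1) {
  s <- str_chars(toupper(pbs))
  core <- str_chars(TRNA_MET_CORE)
  k <- length(core)
  if (length(s) < k) return(NA_integer_)
  for (off in 0:(length(s) - k)) {
    if (sum(s[off + seq_len(k)] != core) <= max_mismatch)
      return(off)
  }
  NA_integer_
}

#' Built-in nine-family copia parameter set
#'
#' Structural parameters of the nine full-length jatropha copia families
#' (Jc1-Jc9): lineage, total length, LTR length, GAG-POL length, PBS and PPT
#' strings. `target_copies` are desk-scale simulation defaults derived as
#' scaled-down proxies of per-family homology-search hit counts (true copy
#' numbers are unknown); `flank_gene_prob` defaults reflect the reported
#' gene-rich (more than 60% of flanks with a gene: Jc1, 2, 3, 7, 9) versus
#' gene-poor (under 40%: Jc5) flank classes.
#'
#' @return Named list of [family_spec()] objects.
#' @export
copia_families <- function() {
  rows <- list(
    list("Jc1", "I",   5398L, 510L, 1339L, "agTGGTATCAGAGCC", "AGGGGGAGAtt",   16L, 0.75),
    list("Jc2", "I",   5493L, 697L, 1326L, "acTGGTATCAGAGCC", "GGGAGGGGGAGAAt", 8L, 0.75),
    list("Jc3", "I",   5387L, 523L, 1314L, "agTGGTATCAGAGCC", "AGGGGGAGAtt",    6L, 0.75),
    list("Jc4", "I",   5254L, 440L, 1299L, "acTGGTATCAGAGCC", "AAGtGGGAGAt",    8L, 0.50),
    list("Jc5", "II",  6217L, 474L, 1370L, "tgTGGTATCAGAGCC", "AAGTGGGAGAt",   17L, 0.30),
    list("Jc6", "II",  7712L, 959L, 1428L, "atTGGTATCAGAGCC", "AAGtAGAGAAtGGA",10L, 0.50),
    list("Jc7", "II",  6652L, 447L, 1358L, "agTGGTATCAGAGCC", "AAGtGGGAGAt",    8L, 0.75),
    list("Jc8", "III", 4984L, 210L, 1528L, "TGGTATCAGAGCt",   "GAGGGGGAG",      3L, 0.50),
    list("Jc9", "III", 5018L, 161L, 1398L, "TGGTATCAGAGCC",   "GAGGGGGAG",     13L, 0.75))
  out <- lapply(rows, function(r) do.call(family_spec, r))
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Read a family parameter table
#'
#' Reads a TSV with columns `name`, `lineage`, `total_len`, `ltr_len`,
#' `gagpol_len`, `pbs`, `ppt` and optionally `target_copies`,
#' `flank_gene_prob`, returning a list of [family_spec()] objects.
#' @param path Path to the TSV file.
#' @export
read_family_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "lineage", "total_len", "ltr_len", "gagpol_len", "pbs", "ppt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("family table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(df$target_copies)) df$target_copies <- 5L
  if (is.null(df$flank_gene_prob)) df$flank_gene_prob <- 0.5
  out <- lapply(seq_len(nrow(df)), function(i)
    family_spec(df$name[i], df$lineage[i], df$total_len[i], df$ltr_len[i],
                df$gagpol_len[i], df$pbs[i], df$ppt[i],
                df$target_copies[i], df$flank_gene_prob[i]))
  names(out) <- df$name
  out
}
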