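## Shared fixtures, built once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

fix_template <- function(fam = "Jc1", seed = 1L) {
  cached(paste0("tpl_", fam, "_", seed),
         build_family_template(copia_families()[[fam]], seed = seed))
}

## Small genome with 5 zero-divergence Jc1 copies.
fix_genome_clean <- function() {
  cached("genome_clean", {
    g <- new_genome(5e5, seed = 2)
    implant_copies(g, fix_template("Jc1", 1), n = 5, divergence = 0, seed = 3)
  })
}

## Independent IUPAC table for oracle scans (kept separate from the
## package's own table on purpose).
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

## Brute-force primer-site oracle: direct set-membership scan at every
## offset on both strands (equivalent to expanding the primer and testing
## every expansion at every offset).
oracle_primer_scan <- function(genome_seq, primer, max_mismatch) {
  revcomp_chr <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
              W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
              N = "N")
    paste(rev(unname(comp[strsplit(x, "")[[1]]])), collapse = "")
  }
  s <- strsplit(genome_seq, "")[[1]]
  out <- NULL
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") primer else revcomp_chr(primer)
    p <- strsplit(pat, "")[[1]]
    k <- length(p)
    mism <- rep(0L, length(s) - k + 1L)
    for (j in seq_len(k)) {
      ok <- s[j:(length(s) - k + j)] %in% ORACLE_IUPAC[[p[j]]]
      mism <- mism + !ok
    }
    hit <- which(mism <= max_mismatch)
    if (length(hit))
      out <- rbind(out, data.frame(start = hit, strand = strand,
                                   mismatches = mism[hit]))
  }
  if (is.null(out)) data.frame(start = integer(), strand = character(),
                               mismatches = integer())
  else out[order(out$start, out$strand), , drop = FALSE]
}

random_dna_chr <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = "")

## A random in-frame coding sequence (no stops), n_codons long.
random_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
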