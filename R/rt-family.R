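## RT clone handling: frameshift-tolerant translation, core-block trimming,
## peptide distances, neighbor joining, family cutting, and the
## family-distribution homogeneity test.

#' Translate a nucleotide sequence with frameshift recovery
#'
#' Dynamic programming over reading positions: from any position the next
#' codon may consume 3 nt (normal), 2 nt (recover a deleted base) or 4 nt
#' (skip an inserted base); the last two count as one frameshift event and
#' cost `penalty` codons.  A stop codon may be read through as an ambiguous
#' residue at cost `stop_penalty` (a point-mutated, pseudogenised codon) —
#' this keeps the frame intact instead of detouring around the stop, which
#' would emit out-of-frame sequence, so `stop_penalty` must stay below
#' `penalty`.  Any of the three start offsets is
#' free.  The reported peptide is stop-free (read-through positions appear
#' as `X`).  Sequences needing more than `max_readthrough` read-throughs, or
#' whose best peptide is shorter than `min_aa`, are classified non-RT and
#' dropped (`NULL` return).
#'
#' @param nt Nucleotide sequence (>= 60 nt).
#' @param penalty Cost per frameshift, in codons.
#' @param stop_penalty Cost per stop-codon read-through, in codons.
#' @param min_aa Minimum acceptable peptide length.
#' @param max_readthrough Maximum tolerated stop read-throughs.
#' @return List with `aa`, `frameshift_events` and `readthroughs`, or
#'   `NULL` when no acceptable peptide exists.
#' @export
translate_with_frameshift_recovery <- function(nt, penalty = 4,
                                               stop_penalty = 2,
                                               min_aa = 20L,
                                               max_readthrough = 2L) {
  nt <- toupper(nt)
  n <- nchar(nt)
  if (n < 60) stop("sequence shorter than 60 nt", call. = FALSE)
  gc <- Biostrings::GENETIC_CODE
  ch <- str_chars(nt)
  ## best[i]: best score of a parse ending exactly at nt position i (0 = none
  ## consumed).  Track predecessor and move for traceback.
  NEG <- -1e9
  best <- rep(NEG, n + 1L)
  pred <- rep(NA_integer_, n + 1L)
  aa_at <- rep(NA_character_, n + 1L)
  ev <- rep(0L, n + 1L)
  rt <- rep(0L, n + 1L)
  best[1:3] <- 0  # free start offsets 0,1,2 (positions 0..2 consumed as slack)
  for (i in 0:(n - 1L)) {
    bi <- best[i + 1L]
    if (bi <= NEG / 2) next
    for (step in c(3L, 2L, 4L)) {
      j <- i + step
      if (j > n) next
      is_stop <- FALSE
      if (step == 2L) {
        aa <- "X"  # two-base consume: junction residue is ambiguous
      } else {
        aa <- unname(gc[paste(ch[(i + 1L):(i + 3L)], collapse = "")])
        if (is.na(aa)) next
        if (aa == "*") {
          if (step != 3L) next  # read-through only in-frame
          is_stop <- TRUE
          aa <- "X"
        }
      }
      cost <- if (is_stop) stop_penalty else if (step == 3L) 0 else penalty
      sc <- bi + 1 - cost
      if (sc > best[j + 1L]) {
        best[j + 1L] <- sc
        pred[j + 1L] <- i
        aa_at[j + 1L] <- aa
        ev[j + 1L] <- ev[i + 1L] + if (step == 3L) 0L else 1L
        rt[j + 1L] <- rt[i + 1L] + if (is_stop) 1L else 0L
      }
    }
  }
  endpos <- which.max(best) - 1L
  if (best[endpos + 1L] <= 0) return(NULL)
  ## traceback
  peptide <- character()
  i <- endpos
  while (!is.na(pred[i + 1L])) {
    peptide <- c(aa_at[i + 1L], peptide)
    i <- pred[i + 1L]
  }
  aa <- paste(peptide, collapse = "")
  if (nchar(aa) < min_aa || rt[endpos + 1L] > max_readthrough) return(NULL)
  list(aa = aa, frameshift_events = ev[endpos + 1L],
       readthroughs = rt[endpos + 1L])
}

#' Build RT clones from amplicons
#'
#' Translates each amplicon with frameshift recovery (amplicon sequences are
#' already oriented 5'-3' from the set's forward primer) and returns the
#' clone table; untranslatable products are dropped as non-RT.
#'
#' @param amplicons An `amplicon_table` from [amplify()].
#' @param accession Accession label recorded per clone.
#' @param require_rt_motif Keep only clones whose peptide carries the YVDD
#'   RT core motif (at most one substitution) — products not identifiable as
#'   the RT region (spurious primer pairings) are discarded.
#' @return Data frame `id, accession, primer_set, nt, aa, frameshift_events`.
#' @export
clones_from_amplicons <- function(amplicons, accession = "acc1",
                                  require_rt_motif = TRUE) {
  rows <- lapply(seq_len(nrow(amplicons)), function(i) {
    nt <- amplicons$sequence[i]
    tr <- translate_with_frameshift_recovery(nt)
    if (is.null(tr)) return(NULL)
    if (require_rt_motif &&
        is.na(find_peptide_motif(tr$aa, RT_MOTIF_CORE, 1L))) return(NULL)
    data.frame(id = sprintf("%s_%s_%d", accession, amplicons$primer_set[i], i),
               accession = accession, primer_set = amplicons$primer_set[i],
               nt = nt, aa = tr$aa, frameshift_events = tr$frameshift_events,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(id = character(), accession = character(),
                      primer_set = character(), nt = character(),
                      aa = character(), frameshift_events = integer(),
                      stringsAsFactors = FALSE)
  out
}

## Multiple peptide alignment via the mafft CLI.
align_peptides <- function(peps) {
  if (Sys.which("mafft") == "")
    stop("mafft not found on PATH; required for peptide alignment",
         call. = FALSE)
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)))
  writeLines(paste0(">", names(peps), "\n", unname(peps)), fin)
  status <- system2("mafft", c("--quiet", "--auto", "--amino", shQuote(fin)),
                    stdout = fout, stderr = FALSE)
  if (status != 0) stop("mafft failed", call. = FALSE)
  aln <- Biostrings::readAAStringSet(fout)
  setNames(as.character(aln), names(aln))
}

#' Trim aligned clones to their shared core block
#'
#' Aligns the clone peptides (mafft) and keeps the columns covered (non-gap)
#' by at least `min_coverage` of clones — the overlapped core region shared
#' by the different primer sets, about 75 aa for full RT amplicons.
#'
#' @param clones Clone table from [clones_from_amplicons()] (needs `id` and
#'   `aa`), or a named character vector of peptides.
#' @param min_coverage Column coverage threshold.
#' @return Character matrix (clones x core columns) with clone ids as
#'   rownames.
#' @export
trim_to_core <- function(clones, min_coverage = 0.95) {
  peps <- if (is.data.frame(clones)) setNames(clones$aa, clones$id) else clones
  if (length(peps) < 3)
    stop("need at least 3 clones to define a core block", call. = FALSE)
  aln <- align_peptides(peps)
  mat <- do.call(rbind, lapply(aln, str_chars))
  rownames(mat) <- names(aln)
  cov <- colMeans(mat != "-")
  block <- mat[, cov >= min_coverage, drop = FALSE]
  ## reorder to input order (mafft preserves it, but be safe)
  block[names(peps), , drop = FALSE]
}

#' Pairwise p-distance matrix of a peptide block
#'
#' `d = mismatches / compared columns`, comparing only columns where neither
#' sequence has a gap (pairwise deletion).
#'
#' @param block Character matrix from [trim_to_core()], or a character
#'   vector of equal-length peptides.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(block) {
  if (!is.matrix(block)) {
    stopifnot(length(unique(nchar(block))) == 1)
    nm <- names(block) %||% paste0("s", seq_along(block))
    block <- do.call(rbind, lapply(block, str_chars))
    rownames(block) <- nm
  }
  n <- nrow(block)
  d <- matrix(0, n, n, dimnames = list(rownames(block), rownames(block)))
  if (n < 2) return(d)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ok <- block[i, ] != "-" & block[j, ] != "-"
      d[i, j] <- d[j, i] <-
        if (!any(ok)) NA_real_ else mean(block[i, ok] != block[j, ok])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical agglomeration: iteratively join the pair minimising the
#' Q-criterion `(n-2)d(i,j) - r_i - r_j`, with branch lengths from the
#' rate-corrected formula.  Ties are broken towards the lowest index pair;
#' negative branch lengths are clamped to zero with the deficit moved to the
#' sister edge.  Returns an unrooted `phylo` tree.
#'
#' @param d Symmetric distance matrix (>= 3 taxa) or `dist` object.
#' @return An [ape::ape-package] `phylo` object.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa", call. = FALSE)
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  ## node bookkeeping for the phylo edge matrix
  ntip <- n
  next_internal <- ntip + 2L  # ntip+1 reserved for the final root join
  active <- seq_len(n)        # node id per active cluster
  edges <- matrix(integer(), 0, 2)
  lens <- numeric()
  D <- d
  while (nrow(D) > 2) {
    m <- nrow(D)
    r <- rowSums(D)
    q <- (m - 2) * D - outer(r, r, "+")
    diag(q) <- Inf
    ## lowest-index pair on ties (column-major order of which())
    idx <- which(q == min(q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    ## clamp negatives, transferring the deficit to the sister edge
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    node <- next_internal; next_internal <- next_internal + 1L
    edges <- rbind(edges, c(node, active[i]), c(node, active[j]))
    lens <- c(lens, li, lj)
    dn <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- D[keep, keep, drop = FALSE]
    D2 <- rbind(cbind(D2, dn[keep]), c(dn[keep], 0))
    D <- D2
    active <- c(active[keep], node)
  }
  ## final join of the last two clusters through the root node
  root <- ntip + 1L
  final_len <- max(D[1, 2], 0)
  edges <- rbind(edges, c(root, active[1]), c(root, active[2]))
  lens <- c(lens, final_len, 0)
  ## renumber internal nodes so the root is ntip+1 and children follow
  tr <- list(edge = edges, edge.length = lens, tip.label = labels,
             Nnode = max(edges) - ntip)
  class(tr) <- "phylo"
  tr <- ape::collapse.singles(tr)
  if (ape::Ntip(tr) > 2) tr <- ape::unroot(tr)
  stats::reorder(tr)
}

#' Cut clones into families by single-linkage clustering
#'
#' Single linkage at distance `family_cut` (default 0.40 peptide
#' p-distance); family labels `Jc1..Jck` are assigned by descending clone
#' count (ties by first occurrence).
#'
#' @param d Distance matrix from [p_distance_matrix()].
#' @param family_cut Distance threshold in `(0, 1]`.
#' @return List with `families` (named character vector clone -> family
#'   label) and `n_families`.
#' @export
cut_families <- function(d, family_cut = 0.40) {
  stopifnot(family_cut > 0, family_cut <= 1)
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) == 1) {
    fam <- setNames("Jc1", rownames(d))
    return(list(families = fam, n_families = 1L))
  }
  hc <- hclust(as.dist(d), method = "single")
  cl <- cutree(hc, h = family_cut)
  sizes <- sort(table(cl), decreasing = TRUE)
  relabel <- setNames(paste0("Jc", seq_along(sizes)), names(sizes))
  fam <- setNames(unname(relabel[as.character(cl)]), names(cl))
  list(families = fam, n_families = length(sizes))
}

#' Chi-square homogeneity test of family distributions across accessions
#'
#' Pearson chi-square (no continuity correction) on the accession x family
#' contingency table, df = (r-1)(c-1).
#'
#' @param counts Integer matrix or table, accessions x families.
#' @return List with `chi2`, `df` and `p`.
#' @export
family_distribution_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(dim(counts) < 2))
    stop("need at least 2 accessions and 2 families", call. = FALSE)
  n <- sum(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / n
  if (any(expected == 0))
    stop("expected cell count of zero; pool sparse rows/columns before testing",
         call. = FALSE)
  chi2 <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}
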