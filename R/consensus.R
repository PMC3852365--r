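## Iterative consensus building: from a family's RT consensus seed to the
## full-length element consensus, extending until the flanks diverge.

#' Majority-rule consensus of aligned clone sequences
#'
#' Column-wise majority over equal-length (gapless) clone sequences; ties
#' are broken towards the first base in alphabetical order and logged via a
#' message.
#'
#' @param seqs Character vector of equal-length nucleotide sequences.
#' @return Consensus string.
#' @export
seed_consensus <- function(seqs) {
  stopifnot(length(seqs) >= 1)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("clone sequences must be equal length; align or trim first",
         call. = FALSE)
  mat <- do.call(rbind, lapply(seqs, str_chars))
  ties <- 0L
  cons <- vapply(seq_len(ncol(mat)), function(j) {
    tab <- sort(table(mat[, j]), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) {
      ties <<- ties + 1L
      sort(names(tab)[tab == tab[1]])[1]
    } else names(tab)[1]
  }, "")
  if (ties > 0) message(sprintf("seed_consensus: %d tied column(s) broken alphabetically", ties))
  paste(cons, collapse = "")
}

## Column agreement profile of anchored member sequences against a
## reference coordinate system.  members: list of (seq, offset) where
## member position p corresponds to consensus column p + offset.
member_matrix <- function(members, ncol_total) {
  mat <- matrix(NA_character_, length(members), ncol_total)
  for (i in seq_along(members)) {
    m <- members[[i]]
    ch <- str_chars(m$seq)
    cols <- seq_along(ch) + m$offset
    ok <- cols >= 1 & cols <= ncol_total
    mat[i, cols[ok]] <- ch[ok]
  }
  mat
}

majority_profile <- function(mat) {
  counts <- vapply(DNA_BASES, function(b) colSums(mat == b, na.rm = TRUE),
                   numeric(ncol(mat)))
  if (!is.matrix(counts)) counts <- matrix(counts, nrow = 1)
  cov <- rowSums(counts)
  maxi <- max.col(counts, ties.method = "first")  # ties: alphabetical
  base <- DNA_BASES[maxi]
  agree <- counts[cbind(seq_along(maxi), maxi)] / cov
  base[cov == 0] <- NA
  agree[cov == 0] <- NA
  rbind(base = base, agree = agree)
}

## Change-point boundary: scanning outward over per-column agreement values,
## the boundary is the column maximising the cumulative sum of
## (agreement - 0.75), innermost on ties; 0 when the first window already
## disagrees.
boundary_changepoint <- function(agree) {
  if (!length(agree)) return(0L)
  cs <- cumsum(agree - 0.75)
  best <- max(cs)
  if (best <= 0) return(0L)
  which.max(cs >= best)  # innermost column attaining the maximum
}

#' Iteratively extend a family consensus to the element boundaries
#'
#' Each round collects member loci of the current consensus by seeded
#' search, extends every member span by `extend_step` bp on sides not yet
#' finished, re-anchors the members and recomputes the column-majority
#' consensus.  A side is finished at the first 20-column window in which
#' fewer than `boundary_agreement` of the covering members agree with the
#' majority (flank divergence marks the element edge); the final consensus
#' is trimmed at a change-point over the column agreement profile.
#' Members whose overall agreement with the consensus drops below 0.6 are
#' dropped (truncated copies).
#'
#' @param seed Seed consensus sequence (e.g. a family RT consensus).
#' @param genome An `annotated_genome` or named character vector.
#' @param params [search_params()] for member collection.
#' @param extend_step Extension per round per side in bp.
#' @param boundary_agreement Window agreement threshold declaring a side
#'   finished.
#' @param max_rounds Round cap.
#' @param min_members Minimum member loci required (mirrors the inability to
#'   build a consensus for very low-copy families).
#' @return A `consensus_state`: list with `consensus`, `members` (data frame
#'   of subject spans), `left_done`, `right_done`, `round`.
#' @export
iterative_extend <- function(seed, genome, params = search_params(),
                             extend_step = 500L, boundary_agreement = 0.6,
                             max_rounds = 40L, min_members = 3L) {
  contigs <- genome_contigs(genome)
  hits <- collapse_loci(search_genome(seed, genome, params))
  if (nrow(hits) < min_members)
    stop(sprintf("insufficient copies: %d member locus/loci found, need >= %d to deduce a consensus",
                 nrow(hits), min_members), call. = FALSE)
  ## anchor each member: consensus column 1 maps to subject position
  ## sstart - (qstart - 1) (minus-strand members are reverse-complemented).
  members <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    list(contig = h$contig, strand = h$strand,
         ## subject position of consensus column 1 on the member's own
         ## oriented axis
         anchor_start = if (h$strand == "+") h$sstart - (h$qstart - 1L)
                        else h$send + (h$qstart - 1L),
         left_ext = 0L, right_ext = 0L, dropped = FALSE)
  })
  cons <- toupper(seed)
  left_done <- FALSE; right_done <- FALSE
  round <- 0L
  left_off <- 0L   # columns added on the left so far
  repeat {
    round <- round + 1L
    if (!left_done) {
      members <- lapply(members, function(m) {
        m$left_ext <- m$left_ext + extend_step; m })
      left_off <- left_off + extend_step
    }
    if (!right_done) {
      members <- lapply(members, function(m) {
        m$right_ext <- m$right_ext + extend_step; m })
    }
    core_len <- nchar(seed)
    total_cols <- left_off + core_len + max(vapply(members, function(m)
      m$right_ext, 1L))
    ## materialise member sequences on the common column axis
    mseqs <- list()
    for (mi in seq_along(members)) {
      m <- members[[mi]]
      if (m$dropped) next
      clen <- nchar(contigs[[m$contig]])
      if (m$strand == "+") {
        s0 <- m$anchor_start - m$left_ext
        e0 <- m$anchor_start + core_len - 1L + m$right_ext
        s <- max(1L, s0); e <- min(clen, e0)
        if (s > e) next
        seqi <- substr(contigs[[m$contig]], s, e)
        offset <- left_off - (m$left_ext - (s - s0))
      } else {
        s0 <- m$anchor_start + m$left_ext
        e0 <- m$anchor_start - core_len + 1L - m$right_ext
        s <- min(clen, s0); e <- max(1L, e0)
        if (e > s) next
        seqi <- revcomp(substr(contigs[[m$contig]], e, s))
        offset <- left_off - (m$left_ext - (s0 - s))
      }
      mseqs[[length(mseqs) + 1L]] <- list(seq = toupper(seqi),
                                          offset = offset, mi = mi)
    }
    if (length(mseqs) < min_members)
      stop("insufficient copies: members lost during extension", call. = FALSE)
    mat <- member_matrix(mseqs, total_cols)
    prof <- majority_profile(mat)
    base <- prof["base", ]; agree <- as.numeric(prof["agree", ])
    core_cols <- (left_off + 1L):(left_off + core_len)
    ## drop members that no longer agree with the consensus overall
    consensus_row <- base
    magree <- apply(mat, 1, function(r) {
      ok <- !is.na(r) & !is.na(consensus_row)
      if (!any(ok)) return(0)
      mean(r[ok] == consensus_row[ok])
    })
    if (any(magree < 0.6) && sum(magree >= 0.6) >= min_members) {
      for (k in which(magree < 0.6)) members[[mseqs[[k]]$mi]]$dropped <- TRUE
      mat <- mat[magree >= 0.6, , drop = FALSE]
      prof <- majority_profile(mat)
      base <- prof["base", ]; agree <- as.numeric(prof["agree", ])
    }
    win <- 20L
    ## uncovered columns (beyond every member's reach) count as disagreement
    la <- rev(agree[seq_len(left_off)]); la[is.na(la)] <- 0
    ra <- agree[(left_off + core_len + 1L):total_cols]; ra[is.na(ra)] <- 0
    ## scan outward from the core on both sides
    if (!left_done)
      left_done <- any_window_below(la, win, boundary_agreement)
    if (!right_done)
      right_done <- any_window_below(ra, win, boundary_agreement)
    if ((left_done && right_done) || round >= max_rounds) {
      lb <- boundary_changepoint(la)
      rb <- boundary_changepoint(ra)
      cols <- (left_off + 1L - lb):(left_off + core_len + rb)
      consensus <- paste(base[cols], collapse = "")
      spans <- do.call(rbind, lapply(members, function(m) data.frame(
        contig = m$contig, strand = m$strand, anchor_start = m$anchor_start,
        dropped = m$dropped, stringsAsFactors = FALSE)))
      return(structure(list(consensus = consensus, members = spans,
                            left_done = left_done, right_done = right_done,
                            round = round), class = "consensus_state"))
    }
    ## grow the working consensus for the next round's coordinate frame
    cons <- paste(base[core_cols], collapse = "")
  }
}

## TRUE when some window of `win` consecutive values has mean < threshold.
any_window_below <- function(x, win, threshold) {
  x <- x[!is.na(x)]
  if (length(x) < win) return(FALSE)
  cs <- cumsum(x)
  means <- (cs[win:length(x)] - c(0, cs)[1:(length(x) - win + 1L)]) / win
  any(means < threshold)
}

#' @export
print.consensus_state <- function(x, ...) {
  cat(sprintf("consensus_state: %d bp, %d member(s) (%d dropped), %d round(s), left %s right %s\n",
              nchar(x$consensus), nrow(x$members), sum(x$members$dropped),
              x$round, ifelse(x$left_done, "done", "open"),
              ifelse(x$right_done, "done", "open")))
  invisible(x)
}
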