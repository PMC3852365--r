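test_that("the Jc1 template has the specified geometry and identical LTRs", {
  tpl <- fix_template("Jc1", 1L)
  spec <- copia_families()$Jc1
  expect_equal(nchar(tpl$seq), 5398)
  expect_identical(substr(tpl$seq, 1, 510),
                   substr(tpl$seq, 5398 - 509, 5398))
  expect_equal(substr(tpl$seq, 511, 525), toupper(spec$pbs))
  a <- tpl$annotation
  expect_equal(substr(tpl$seq, a$ppt[1], a$ppt[2]), toupper(spec$ppt))
  pep <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(tpl$seq, a$orf[1], a$orf[2])))))
  expect_equal(nchar(pep), 1339)
  expect_false(grepl("*", pep, fixed = TRUE))
})

test_that("infeasible family geometries raise parameter errors naming the inequality", {
  expect_error(family_spec("bad", "I", total_len = 2000, ltr_len = 1000,
                           gagpol_len = 100, pbs = "TGGTATCAGAGC",
                           ppt = "GAGGGGGAG"),
               "total_len")
  expect_error(family_spec("bad", "I", total_len = 3000, ltr_len = 400,
                           gagpol_len = 1200, pbs = "TGGTATCAGAGC",
                           ppt = "GAGGGGGAG"),
               "exceeds")
  expect_error(family_spec("bad", "I", total_len = 5398, ltr_len = 510,
                           gagpol_len = 1339, pbs = "AAAAAAAAAAAAAA",
                           ppt = "GAGGGGGAG"),
               "tRNA")
})

test_that("template construction is deterministic under a fixed seed", {
  spec <- copia_families()$Jc3
  t1 <- build_family_template(spec, seed = 9)
  t2 <- build_family_template(spec, seed = 9)
  t3 <- build_family_template(spec, seed = 10)
  expect_identical(t1$seq, t2$seq)
  expect_false(identical(t1$seq, t3$seq))
})

test_that("zero-divergence implants keep identical LTR pairs and exact truth", {
  g <- fix_genome_clean()
  el <- g$elements
  expect_equal(nrow(el), 5)
  expect_true(all(el$ltr_identical))
  expect_true(all(el$end - el$start + 1 == 5398))
  s <- g$contigs[[1]]
  for (i in seq_len(nrow(el))) {
    expect_identical(substr(s, el$start[i] - nchar(el$tsd[i]), el$start[i] - 1),
                     el$tsd[i])
    expect_identical(substr(s, el$end[i] + 1, el$end[i] + nchar(el$tsd[i])),
                     el$tsd[i])
  }
})

test_that("genome length is conserved: background + sum of copies + TSDs", {
  g <- fix_genome_clean()
  el <- g$elements
  expect_equal(sum(nchar(g$contigs)),
               5e5 + sum(el$end - el$start + 1) + sum(nchar(el$tsd)))
})

test_that("substitution counts at 5% divergence follow the binomial oracle", {
  tpl <- fix_template("Jc1", 1L)
  g <- new_genome(3e5, seed = 21)
  g <- implant_copies(g, tpl, n = 3, divergence = 0.05, min_gap = 2000,
                      seed = 22)
  n <- nchar(tpl$seq)
  sd3 <- 3 * sqrt(n * 0.05 * 0.95)
  for (i in 1:3) {
    copy <- substr(g$contigs[[1]], g$elements$start[i], g$elements$end[i])
    subs <- sum(strsplit(copy, "")[[1]] != strsplit(tpl$seq, "")[[1]])
    expect_gt(subs, n * 0.05 - sd3)
    expect_lt(subs, n * 0.05 + sd3)
    expect_false(g$elements$ltr_identical[i])
  }
})

test_that("TSD lengths honour the requested range", {
  tpl <- fix_template("Jc1", 1L)
  g <- new_genome(2e5, seed = 31)
  g <- implant_copies(g, tpl, n = 3, tsd_len_range = c(4L, 6L),
                      min_gap = 2000, seed = 32)
  expect_true(all(nchar(g$elements$tsd) >= 4 & nchar(g$elements$tsd) <= 6))
  g2 <- new_genome(2e5, seed = 33)
  g2 <- implant_copies(g2, tpl, n = 3, tsd_len_range = c(5L, 5L),
                       min_gap = 2000, seed = 34)
  expect_true(all(nchar(g2$elements$tsd) == 5))
})

test_that("structural annotation round-trips truth on a zero-divergence copy", {
  g <- fix_genome_clean()
  tpl <- fix_template("Jc1", 1L)
  el <- g$elements[1, ]
  copy <- substr(g$contigs[[el$contig]], el$start, el$end)
  ann <- annotate_element(copy)
  truth <- tpl$annotation
  expect_equal(ann$ltr5, truth$ltr5)
  expect_equal(ann$ltr3, truth$ltr3)
  ## detected PBS span covers the 12-nt tRNA core within the placed string
  expect_equal(ann$pbs$span,
               c(truth$pbs[1] + truth$pbs_spacer,
                 truth$pbs[1] + truth$pbs_spacer + 11L))
  expect_equal(ann$pbs$spacer_len, truth$pbs_spacer)
  expect_equal(ann$orf$orf, truth$orf)
  expect_equal(ann$orf$aa_len, truth$aa_len)
  expect_equal(ann$total_len, truth$total_len)
  ## PPT found within the truth tract
  expect_true(ann$ppt$span[1] >= truth$ppt[1] &&
              ann$ppt$span[2] <= truth$ppt[2] + 1)
  expect_identical(detect_tsd(g$contigs[[el$contig]], c(el$start, el$end)),
                   el$tsd)
})

test_that("placement fails loudly when the genome has no room", {
  tpl <- fix_template("Jc1", 1L)
  g <- new_genome(30000, seed = 41)
  expect_error(implant_copies(g, tpl, n = 10, min_gap = 8000, seed = 42,
                              max_tries = 20),
               "placement error")
})

test_that("gene planting matches the per-family probability (binomial oracle)", {
  ## synthetic element track on a flat contig; plant_genes only reads
  ## coordinates
  n <- 150
  starts <- seq(20000, by = 16000, length.out = n)
  g <- structure(list(
    contigs = setNames(strrep("A", max(starts) + 20000), "c"),
    elements = data.frame(
      id = paste0("e", 1:n), family = "F1", contig = "c", start = starts,
      end = starts + 4999, strand = "+", tsd = "AAAAA", pct_divergence = 0,
      truncated_5p = 0L, truncated_3p = 0L, ltr_identical = TRUE,
      stringsAsFactors = FALSE),
    genes = data.frame(id = character(), contig = character(),
                       start = integer(), end = integer(),
                       strand = character(), stringsAsFactors = FALSE),
    provenance = list()), class = "annotated_genome")

  p1 <- plant_genes(g, 1.0, seed = 51)
  near1 <- vapply(seq_len(n), function(i)
    gene_in_flank(p1$elements[i, ], p1$genes)$gene_within_window, TRUE)
  expect_true(all(near1))

  p0 <- plant_genes(g, 0.0, seed = 52)
  expect_equal(nrow(p0$genes), 0)
  dists <- vapply(seq_len(n), function(i)
    gene_in_flank(p0$elements[i, ], p0$genes)$nearest_gene_distance, 1)
  expect_true(all(dists >= 6000))

  p65 <- plant_genes(g, 0.65, seed = 53)
  frac <- mean(vapply(seq_len(n), function(i)
    gene_in_flank(p65$elements[i, ], p65$genes)$gene_within_window, TRUE))
  sd3 <- 3 * sqrt(0.65 * 0.35 / n)
  expect_gt(frac, 0.65 - sd3)
  expect_lt(frac, 0.65 + sd3)
})

test_that("accession panels carry the empty allele exactly where absent", {
  tpl <- fix_template("Jc7", 5L)
  g <- new_genome(2e5, seed = 61)
  g <- implant_copies(g, tpl, n = 1, divergence = 0, seed = 62)
  locus <- g$elements$id[1]
  accs <- paste0("acc", 1:12)
  presence <- matrix(TRUE, 12, 1, dimnames = list(accs, locus))
  presence[c(2, 9), 1] <- FALSE
  panel <- simulate_accessions(g, presence)
  lens <- vapply(panel$accessions, function(a) sum(nchar(a$contigs)), 1)
  expect_equal(sum(lens < max(lens)), 2)
  elem_len <- g$elements$end[1] - g$elements$start[1] + 1
  tsd_len <- nchar(g$elements$tsd[1])
  expect_equal(unname(max(lens) - min(lens)), elem_len + tsd_len)
  ## empty site retains exactly one TSD copy at the excision point
  a2 <- panel$accessions$acc2
  s <- a2$contigs[[1]]
  at <- g$elements$start[1]
  expect_identical(substr(s, at - tsd_len, at - 1), g$elements$tsd[1])
  expect_false(identical(substr(s, at, at + tsd_len - 1), g$elements$tsd[1]))

  ## all-present panels are equal-length
  all_p <- matrix(TRUE, 3, 1, dimnames = list(accs[1:3], locus))
  pan2 <- simulate_accessions(g, all_p)
  expect_equal(length(unique(vapply(pan2$accessions, function(a)
    sum(nchar(a$contigs)), 1))), 1L)

  bad <- matrix(TRUE, 2, 1, dimnames = list(accs[1:2], "nope"))
  expect_error(simulate_accessions(g, bad), "lookup error")
})

test_that("FASTA/GFF3 output is byte-identical under the same seed", {
  build <- function(dir) {
    tpl <- build_family_template(copia_families()$Jc9, seed = 3)
    g <- new_genome(1e5, seed = 71)
    g <- implant_copies(g, tpl, n = 2, divergence = 0.02, min_gap = 2000,
                        seed = 72)
    write_genome(g, dir, "g")
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- build(d1); p2 <- build(d2)
  expect_identical(readLines(p1["fa"]), readLines(p2["fa"]))
  expect_identical(readLines(p1["gff"]), readLines(p2["gff"]))
})
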