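## Shared RBIP fixture: one recent Jc7 insertion plus a marker and panel.
fix_rbip <- function() {
  cached("rbip", {
    g <- new_genome(3e5, seed = 701)
    g <- implant_copies(g, fix_template("Jc7", 5L), n = 1, divergence = 0,
                        seed = 702)
    rec <- find_recent_insertions(g)
    marker <- design_marker(g, rec[1, ])
    list(genome = g, recent = rec, marker = marker)
  })
}

test_that("only identical-LTR, full-length, TSD-flanked copies are recent", {
  tpl <- fix_template("Jc9", 1L)
  g <- new_genome(5e5, seed = 703)
  g <- implant_copies(g, tpl, n = 1, divergence = 0, min_gap = 2000,
                      seed = 704)
  g <- implant_copies(g, tpl, n = 3, divergence = 0.08, min_gap = 2000,
                      seed = 705)
  rec <- find_recent_insertions(g)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$pct_divergence, 0)

  empty <- new_genome(50000, seed = 706)
  expect_equal(nrow(find_recent_insertions(empty)), 0)
})

test_that("marker junction products span the TSD and respect size bounds", {
  fx <- fix_rbip()
  m <- fx$marker; el <- fx$recent[1, ]
  tl <- nchar(m$tsd)
  ## left junction product [flkl.start, ltrl.end] contains the left TSD copy
  expect_lte(m$primers$flkl$start, el$start - tl)
  expect_gte(m$primers$ltrl$end, el$start)
  ## right junction product contains the right TSD copy
  expect_lte(m$primers$ltrr$start, el$end)
  expect_gte(m$primers$flkr$end, el$end + tl)
  expect_lte(m$expected["occupied_left"], 400)
  expect_lte(m$expected["occupied_right"], 400)
  expect_gte(m$expected["occupied_left"], 100)
})

test_that("expected empty product length matches direct coordinate arithmetic", {
  fx <- fix_rbip()
  m <- fx$marker; el <- fx$recent[1, ]
  elem_len <- el$end - el$start + 1
  tl <- nchar(m$tsd)
  direct <- (m$primers$flkr$end - m$primers$flkl$start + 1) - elem_len - tl
  expect_equal(unname(m$expected["empty"]), direct)
  ## and equals the amplicon the empty allele actually produces
  presence <- matrix(FALSE, 1, 1, dimnames = list("a1", el$id))
  pan <- simulate_accessions(fx$genome, presence)
  amp <- amplify(pan$accessions$a1$contigs,
                 primer_set("e", m$primers$flkl$seq, m$primers$flkr$seq,
                            max_mismatch = 0, product_range = c(50, 2000)))
  expect_equal(amp$length, unname(m$expected["empty"]))
})

test_that("genotype calls reproduce the generating presence matrix", {
  fx <- fix_rbip()
  el <- fx$recent[1, ]
  accs <- paste0("acc", 1:12)
  presence <- matrix(TRUE, 12, 1, dimnames = list(accs, el$id))
  presence[c(3, 8), 1] <- FALSE
  panel <- simulate_accessions(fx$genome, presence)
  calls <- genotype_panel(panel, fx$marker)
  expect_equal(sum(calls$call == "occupied"), 10)
  expect_equal(sum(calls$call == "empty"), 2)
  expect_equal(calls$call == "occupied", unname(presence[, 1]))
  ## occupied and empty products never co-occur in a haploid genome
  expect_false(any(calls$call == "mixed"))
})

test_that("a SNP under a primer 3' end makes the call ambiguous", {
  fx <- fix_rbip()
  el <- fx$recent[1, ]
  g <- fx$genome
  s <- strsplit(g$contigs[[el$contig]], "")[[1]]
  at <- fx$marker$primers$flkl$end  # 3'-terminal base of the left primer
  s[at] <- setdiff(c("A", "C", "G", "T"), s[at])[1]
  g$contigs[[el$contig]] <- paste(s, collapse = "")
  calls <- genotype_panel(list(snp_acc = g), fx$marker)
  expect_equal(calls$call, "ambiguous")
})

test_that("repetitive flanks are rejected for marker design", {
  set.seed(707)
  tpl <- fix_template("Jc7", 5L)
  unit <- random_dna_chr(600)
  rep_block <- paste(rep(paste0(unit, random_dna_chr(50)), 25), collapse = "")
  g <- new_genome(2e5, seed = 708)
  ## element inserted immediately right of one repeat unit
  s <- g$contigs[[1]]
  tsd <- "ACGTG"
  ins <- paste0(substr(s, 1, 50000), rep_block, unit, tsd, tpl$seq, tsd,
                substr(s, 50001, nchar(s)))
  g$contigs[[1]] <- ins
  start <- 50000 + nchar(rep_block) + 600 + 5 + 1
  g$elements <- data.frame(
    id = "rep_copy", family = "Jc7", contig = names(g$contigs)[1],
    start = start, end = start + nchar(tpl$seq) - 1, strand = "+",
    tsd = tsd, pct_divergence = 0, truncated_5p = 0L, truncated_3p = 0L,
    ltr_identical = TRUE, stringsAsFactors = FALSE)
  expect_error(design_marker(g, g$elements[1, ]), "repetitive")
})

test_that("the bundled JC7-1 primer fixture is well-formed", {
  pr <- jc7_rbip_primers()
  expect_setequal(names(pr), c("FLKL", "FLKR", "LTRL", "LTRR"))
  expect_true(all(nchar(pr) == 20))
  expect_true(all(grepl("^[ACGT]+$", pr)))
  ## usable as primer sets for the occupied/empty assay layout
  ps <- primer_set("JC7-1_empty", pr[["FLKL"]], pr[["FLKR"]],
                   product_range = c(50, 2000))
  expect_s3_class(ps, "primer_set")
})
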