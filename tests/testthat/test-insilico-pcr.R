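test_that("degenerate expansion counts match exhaustive enumeration", {
  ## independent oracle: enumerate all concrete expansions via expand.grid
  oracle_expand <- function(primer) {
    sets <- ORACLE_IUPAC[strsplit(primer, "")[[1]]]
    grid <- do.call(expand.grid, c(sets, stringsAsFactors = FALSE))
    unique(apply(grid, 1, paste, collapse = ""))
  }
  f_fwd <- rt_primer_set("F")$forward
  exp_f <- expand_degenerate(f_fwd)
  expect_equal(exp_f$count, 512)
  expect_setequal(exp_f$sequences, oracle_expand(f_fwd))

  expect_equal(expand_degenerate("ACGT")$count, 1)
  expect_equal(expand_degenerate("ACGT")$sequences, "ACGT")
  expect_equal(expand_degenerate("N")$count, 4)
  for (p in c("CARATGGAYGTNAARAC", "AYRTRTCNACRTANARNA")) {
    e <- expand_degenerate(p)
    expect_equal(e$count, length(oracle_expand(p)))
  }
})

test_that("invalid IUPAC characters are rejected with their position", {
  expect_error(expand_degenerate("ACGUX"), "position 4")
  expect_error(primer_set("bad", "ACGTACGTACGTACGTACGT", "ACGTACGTACGJ",
                          product_range = c(40, 100)),
               "invalid IUPAC")
})

test_that("primer sites match a brute-force scan over a 10 kb genome", {
  set.seed(101)
  f <- rt_primer_set("F")
  g <- random_dna_chr(10000)
  ## plant one exact expansion of the forward primer
  site <- expand_degenerate(f$forward)$sequences[17]
  g <- paste0(substr(g, 1, 4999), site, substr(g, 5017, 10000))
  for (mm in 0:2) {
    got <- find_primer_sites(setNames(g, "c"), f$forward, max_mismatch = mm)
    want <- oracle_primer_scan(g, f$forward, mm)
    expect_equal(nrow(got), nrow(want), info = paste("mm =", mm))
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$mismatches, want$mismatches)
  }
  exact <- find_primer_sites(setNames(g, "c"), f$forward, max_mismatch = 0)
  expect_true(any(exact$start == 5000 & exact$strand == "+" &
                  exact$mismatches == 0))
})

test_that("site finding is monotone in max_mismatch and empty on empty input", {
  set.seed(7)
  g <- setNames(random_dna_chr(5000), "c")
  prev <- -1L
  for (mm in 0:3) {
    n <- nrow(find_primer_sites(g, "ACNGCNTTYYTNCAYGG", mm))
    expect_gte(n, prev)
    prev <- n
  }
  none <- find_primer_sites(setNames("ACGT", "c"), "ACNGCNTTYYTNCAYGG", 1)
  expect_equal(nrow(none), 0)
})

test_that("amplification produces one inward-facing product of the expected size", {
  set.seed(11)
  f <- rt_primer_set("F")
  fwd_site <- expand_degenerate(f$forward)$sequences[1]
  rev_site <- expand_degenerate(f$reverse)$sequences[1]
  rev_on_plus <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rev_site)))
  mid <- random_dna_chr(300 - nchar(fwd_site) - nchar(rev_on_plus))
  tmpl <- paste0(random_dna_chr(500), fwd_site, mid, rev_on_plus,
                 random_dna_chr(500))
  amp <- amplify(setNames(tmpl, "c"), f)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$length, 300)
  expect_equal(amp$sequence, substr(tmpl, amp$start, amp$end))

  ## outward-facing primers yield no product
  outward <- paste0(random_dna_chr(500), rev_on_plus, mid, fwd_site,
                    random_dna_chr(500))
  expect_equal(nrow(amplify(setNames(outward, "c"), f)), 0)
})

test_that("amplification is strand-symmetric", {
  g <- fix_genome_clean()
  f <- rt_primer_set("F")
  amp_fwd <- amplify(g, f)
  g_rc <- setNames(vapply(g$contigs, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    ""), names(g$contigs))
  amp_rev <- amplify(g_rc, f)
  expect_equal(sort(amp_fwd$sequence), sort(amp_rev$sequence))
})

test_that("every built-in family template yields an RT amplicon with each primer set", {
  for (fam in names(copia_families())) {
    tpl <- fix_template(fam, 2L)
    g <- setNames(tpl$seq, fam)
    for (s in c("F", "V", "H")) {
      amp <- amplify(g, rt_primer_set(s))
      expect_gte(nrow(amp), 1)
    }
    ampF <- amplify(g, rt_primer_set("F"))
    expect_true(any(abs(ampF$length - 300) <= 30),
                info = paste(fam, "F product near 300 bp"))
  }
})
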