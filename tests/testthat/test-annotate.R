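test_that("LTR pair detection recovers lengths and penalises substitutions", {
  tpl <- fix_template("Jc1", 1L)
  lt <- detect_ltr_pair(tpl$seq)
  expect_equal(lt$length, 510)
  expect_equal(lt$identity, 1.0)
  expect_equal(lt$ltr5, c(1L, 510L))
  expect_equal(lt$ltr3, c(5398L - 509L, 5398L))

  ## three substitutions placed in the 3' LTR reduce identity accordingly
  s <- strsplit(tpl$seq, "")[[1]]
  at <- 5398 - 509 + c(50, 200, 400)
  s[at] <- vapply(s[at], function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  lt3 <- detect_ltr_pair(paste(s, collapse = ""))
  expect_equal(lt3$length, 510)
  expect_equal(lt3$identity, (510 - 3) / 510)

  set.seed(501)
  expect_error(detect_ltr_pair(random_dna_chr(4000)), "not an LTR")
})

test_that("PBS detection reports the spacer between LTR and tRNA core", {
  tpl1 <- fix_template("Jc1", 1L)
  p1 <- detect_pbs(tpl1$seq, 510)
  expect_true(p1$present)
  expect_equal(p1$spacer_len, 2L)

  tpl8 <- fix_template("Jc8", 1L)
  p8 <- detect_pbs(tpl8$seq, 210)
  expect_true(p8$present)
  expect_equal(p8$spacer_len, 0L)

  ## two mismatches in the core exceed the tolerance
  seq2 <- paste0(strrep("G", 100), "agTGcTATCAcAGCC", strrep("G", 100))
  expect_false(detect_pbs(seq2, 100)$present)
})

test_that("PPT detection finds the best purine window", {
  seq1 <- paste0(strrep("C", 60), "AGGGGGAGA", strrep("C", 10),
                 strrep("G", 200))
  ppt <- detect_ppt(seq1, ltr3_start = 80L)
  expect_true(ppt$present)
  expect_equal(ppt$purine_frac, 1.0)
  expect_equal(ppt$span, c(61L, 69L))

  polyct <- paste0(strrep("CTTC", 40), strrep("G", 50))
  expect_false(detect_ppt(polyct, ltr3_start = 100L)$present)

  ## hand count inside "AAGTGGGAGAT": the best window is the 10-mer
  ## AAGTGGGAGA with 9/10 purines (no window of >= 9 nt does better)
  seq3 <- paste0(strrep("C", 50), "AAGTGGGAGAT", strrep("C", 20),
                 strrep("G", 100))
  p3 <- detect_ppt(seq3, ltr3_start = 82L)
  expect_equal(p3$purine_frac, 9 / 10)
})

test_that("GAG-POL detection reports length, domain order and degeneracy", {
  tpl <- fix_template("Jc1", 1L)
  orf <- find_gag_pol(tpl$seq, region = c(511L, nchar(tpl$seq)))
  expect_equal(orf$aa_len, 1339L)
  expect_true(orf$copia_order)
  expect_false(orf$degenerate)
  pos <- setNames(orf$domains$aa_pos, orf$domains$name)
  expect_true(all(diff(pos[c("GAG", "PR", "INT", "RT", "RT_YVDD", "RH")]) > 0))

  ## all nine consensus templates fall inside the published aa range
  for (fam in names(copia_families())) {
    t2 <- fix_template(fam, 2L)
    o <- find_gag_pol(t2$seq, region = c(t2$annotation$ltr5[2] + 1L,
                                         nchar(t2$seq)))
    expect_gte(o$aa_len, 1299L)
    expect_lte(o$aa_len, 1528L)
  }

  set.seed(502)
  short <- random_dna_chr(500)
  expect_true(find_gag_pol(short)$degenerate)
})

test_that("TSD detection returns the flanked duplication or nothing", {
  set.seed(503)
  elem <- random_dna_chr(300)
  g1 <- paste0(random_dna_chr(50), "GACGT", elem, "GACGT", random_dna_chr(50))
  expect_equal(detect_tsd(g1, c(56L, 355L)), "GACGT")
  g2 <- paste0(random_dna_chr(55), elem, random_dna_chr(55))
  expect_true(is.na(detect_tsd(g2, c(56L, 355L))))
})

test_that("restriction fragments partition the sequence", {
  set.seed(504)
  plain <- gsub("GAATTC|GGATCC", "ACACAC", random_dna_chr(3000))
  rm0 <- restriction_map(plain)
  expect_equal(rm0$EcoRI$fragments, nchar(plain))
  expect_equal(length(rm0$EcoRI$sites), 0)

  two <- paste0(substr(plain, 1, 999), "GAATTC", substr(plain, 1006, 1999),
                "GAATTC", substr(plain, 2006, 3000))
  rm2 <- restriction_map(two)
  expect_equal(rm2$EcoRI$sites, c(1000L, 2000L))
  expect_equal(rm2$EcoRI$fragments, c(999L, 1000L, nchar(two) - 1999L))
  expect_equal(sum(rm2$EcoRI$fragments), nchar(two))
})

test_that("lineage assignment is confident for references, agnostic for noise", {
  refs <- lineage_references()
  self <- assign_lineage(refs[["III_ref2"]], refs, bootstrap_n = 60)
  expect_equal(self$lineage, "III")
  expect_gte(self$support, 30)

  set.seed(505)
  noise <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                        220, replace = TRUE), collapse = "")
  expect_equal(assign_lineage(noise, refs, bootstrap_n = 60)$lineage,
               "unassigned")
})

test_that("queries drawn from the three ancestral cores recover their lineages", {
  refs <- lineage_references()
  got <- withr::with_seed(506, vapply(c("I", "II", "III"), function(lin) {
    core <- copiascan:::family_rt_core(lin, ancestor_keep = 0.6)
    q <- copiascan:::translate_nt(paste(core, collapse = ""))
    assign_lineage(q, refs, bootstrap_n = 60)$lineage
  }, ""))
  expect_equal(unname(got), c("I", "II", "III"))
})

test_that("lineage-specific structure holds: PBS spacer 2 for I/II, 0 for III", {
  fams <- copia_families()
  for (f in fams) {
    spacer <- pbs_spacer_length(f$pbs)
    if (f$lineage %in% c("I", "II")) expect_equal(spacer, 2L)
    else expect_equal(spacer, 0L)
  }
})

test_that("the structural table mirrors the family parameters on clean input", {
  anns <- list(); seqs <- character()
  for (fam in c("Jc1", "Jc6", "Jc8")) {
    tpl <- fix_template(fam, 1L)
    anns[[fam]] <- annotate_element(tpl$seq)
    seqs[[fam]] <- tpl$seq
  }
  tab <- structural_table(anns, seqs,
                          lineages = c(Jc1 = "I", Jc6 = "II", Jc8 = "III"))
  fams <- copia_families()
  for (i in seq_len(nrow(tab))) {
    f <- fams[[tab$family[i]]]
    expect_equal(tab$total_len[i], f$total_len)
    expect_equal(tab$ltr_len[i], f$ltr_len)
    expect_equal(tab$gagpol_aa[i], f$gagpol_len)
    ## reported PBS covers the spacer plus the 12-nt tRNA core
    expect_equal(tab$pbs[i],
                 substr(toupper(f$pbs), 1, pbs_spacer_length(f$pbs) + 12L))
  }
})
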