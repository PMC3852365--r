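test_that("clean single-frame ORFs translate without events", {
  set.seed(201)
  nt <- random_cds(100)
  tr <- translate_with_frameshift_recovery(nt)
  expect_equal(tr$aa, suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(nt)))))
  expect_equal(tr$frameshift_events, 0L)
  expect_equal(tr$readthroughs, 0L)
})

test_that("a single deleted base is recovered as one frameshift event", {
  ## "TTGAGTAAT" repeats carry stops in both shifted frames, so the
  ## recovery must place its single frame switch at the deletion site
  nt <- strrep("TTGAGTAAT", 33)
  del <- paste0(substr(nt, 1, 148), substr(nt, 150, nchar(nt)))
  tr <- translate_with_frameshift_recovery(del)
  expect_equal(tr$frameshift_events, 1L)
  ## peptide identical to the original except a short junction window
  pep <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(nt), no.init.codon = TRUE)))
  diff_at <- which(strsplit(tr$aa, "")[[1]] !=
                   strsplit(substr(pep, 1, nchar(tr$aa)), "")[[1]])
  expect_lte(length(diff_at), 5)
  expect_identical(substr(tr$aa, 1, 45), substr(pep, 1, 45))
  expect_gte(nchar(tr$aa), 96)

  ## generic random case: still exactly one event, full-length product
  set.seed(202)
  nt2 <- random_cds(100)
  del2 <- paste0(substr(nt2, 1, 149), substr(nt2, 151, 300))
  tr2 <- translate_with_frameshift_recovery(del2)
  expect_equal(tr2$frameshift_events, 1L)
  expect_gte(nchar(tr2$aa), 95)
})

test_that("a point-mutated stop codon is read through in frame", {
  set.seed(203)
  nt <- random_cds(100)
  mut <- paste0(substr(nt, 1, 150), "TGA", substr(nt, 154, 300))
  tr <- translate_with_frameshift_recovery(mut)
  expect_equal(tr$frameshift_events, 0L)
  expect_equal(tr$readthroughs, 1L)
  expect_equal(substr(tr$aa, 51, 51), "X")
  pep <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(nt))))
  expect_identical(substr(tr$aa, 1, 50), substr(pep, 1, 50))
  expect_identical(substr(tr$aa, 52, 100), substr(pep, 52, 100))
})

test_that("sequences with stops in every frame are classified non-RT", {
  ## "TAACTAACTAAC" repeats place a stop codon in all three frames every
  ## four codons; no path can assemble an acceptable peptide
  expect_null(translate_with_frameshift_recovery(strrep("TAACTAACTAAC", 10)))
})

test_that("core trimming keeps the shared block", {
  peps <- setNames(rep(strrep("ARNDCQEGHILKMFPSTWYVARNDCQEGHI", 3), 10),
                   paste0("c", 1:10))
  block <- trim_to_core(peps)
  expect_equal(ncol(block), 90)
  expect_equal(nrow(block), 10)

  ## staggered ends: block is the intersection of coverage (9/10 < 95%)
  base <- strrep("ARNDCQEGHILKMFPSTWYV", 5)  # 100 aa
  stag <- setNames(c(rep(base, 8),
                     substr(base, 11, 100), substr(base, 1, 90)),
                   paste0("s", 1:10))
  b2 <- trim_to_core(stag)
  expect_equal(ncol(b2), 80)

  expect_error(trim_to_core(stag[1:2]), "at least 3")
})

test_that("p-distances match hand-computed values", {
  expect_equal(p_distance_matrix(c(a = "MKVL", b = "MKVL"))["a", "b"], 0)
  expect_equal(p_distance_matrix(c(a = "MKVL", b = "MKVI"))["a", "b"], 0.25)
  ## hand oracle on three toy peptides:
  ## x vs y differ at 2/6, x vs z at 3/6, y vs z at 3/6 (positions 1,2,4)
  d <- p_distance_matrix(c(x = "AAAAAA", y = "AABBAA", z = "BBBAAA"))
  expect_equal(d["x", "y"], 2 / 6)
  expect_equal(d["x", "z"], 3 / 6)
  expect_equal(d["y", "z"], 3 / 6)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), c(x = 0, y = 0, z = 0))
  ## pairwise gap deletion
  dg <- p_distance_matrix(rbind(g1 = c("A", "-", "B", "B"),
                                g2 = c("A", "C", "B", "A")))
  expect_equal(dg["g1", "g2"], 1 / 3)
})

test_that("three-taxon NJ gives the analytic star branch lengths", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_equal(ape::Ntip(tr), 3)
  ## la = (dab+dac-dbc)/2 = 2, lb = 3, lc = 7
  pd <- ape::cophenetic.phylo(tr)
  expect_equal(pd["a", "b"], 5)
  expect_equal(pd["a", "c"], 9)
  expect_equal(pd["b", "c"], 10)
})

test_that("NJ exactly recovers additive four-taxon metrics", {
  ## ((a:2,b:3):1,(c:4,d:5)) -> additive matrix by path lengths
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 5
  d["a", "c"] <- d["c", "a"] <- 7
  d["a", "d"] <- d["d", "a"] <- 8
  d["b", "c"] <- d["c", "b"] <- 8
  d["b", "d"] <- d["d", "b"] <- 9
  d["c", "d"] <- d["d", "c"] <- 9
  tr <- neighbor_joining(d)
  expect_equal(ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]], d)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ agrees with an independent implementation on random metrics", {
  set.seed(204)
  for (i in 1:20) {
    n <- sample(5:8, 1)
    tr0 <- ape::rtree(n)
    D <- ape::cophenetic.phylo(tr0)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    mine <- neighbor_joining(D)
    expect_equal(phangorn::RF.dist(ape::unroot(tr0), mine), 0)
    expect_equal(phangorn::RF.dist(ape::nj(D), mine), 0)
  }
})

test_that("single-linkage family cutting separates clear clusters", {
  labs <- paste0("t", 1:6)
  d <- matrix(0.8, 6, 6, dimnames = list(labs, labs))
  d[1:3, 1:3] <- 0.05; d[4:6, 4:6] <- 0.05
  diag(d) <- 0
  f <- cut_families(d, 0.40)
  expect_equal(f$n_families, 2L)
  expect_equal(length(unique(f$families[1:3])), 1L)
  expect_equal(length(unique(f$families[4:6])), 1L)
  expect_equal(cut_families(d, 1.0)$n_families, 1L)
  ## labels ordered by descending clone count
  d2 <- matrix(0.8, 5, 5, dimnames = list(paste0("u", 1:5), paste0("u", 1:5)))
  d2[1:2, 1:2] <- 0.05; d2[3:5, 3:5] <- 0.05; diag(d2) <- 0
  f2 <- cut_families(d2, 0.4)
  expect_equal(unname(f2$families[3]), "Jc1")
  expect_equal(unname(f2$families[1]), "Jc2")
})

test_that("family count is non-increasing in the cut height", {
  set.seed(205)
  m <- matrix(runif(100, 0, 1), 10, 10,
              dimnames = list(paste0("x", 1:10), paste0("x", 1:10)))
  d <- (m + t(m)) / 2
  diag(d) <- 0
  counts <- vapply(seq(0.05, 1, by = 0.05), function(h)
    cut_families(d, h)$n_families, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("chi-square homogeneity matches the closed form and chisq.test", {
  h <- family_distribution_test(matrix(10, 2, 2))
  expect_equal(h$chi2, 0)
  expect_equal(h$p, 1)

  tab <- matrix(c(30, 10, 10, 30), 2, 2, byrow = TRUE)
  r <- family_distribution_test(tab)
  expect_equal(r$chi2, 20)      # closed form, no continuity correction
  expect_equal(r$df, 1)
  ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(r$chi2, unname(ref$statistic))
  expect_equal(r$p, ref$p.value)

  big <- matrix(5, 5, 10)
  expect_equal(family_distribution_test(big)$df, 36)
  expect_error(family_distribution_test(matrix(c(1, 0, 1, 0), 2, 2)),
               "pool")
})

test_that("the homogeneity test holds its type-I error on homogeneous draws", {
  set.seed(206)
  rejections <- vapply(1:200, function(i) {
    counts <- t(vapply(1:4, function(a)
      as.integer(stats::rmultinom(1, 40, prob = c(0.4, 0.35, 0.25))),
      integer(3)))
    family_distribution_test(counts)$p < 0.05
  }, TRUE)
  expect_lte(mean(rejections), 0.10)
})
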