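test_that("pairwise identity matches a brute-force column scan", {
  expect_identical(pairwiseIdentity("AHGKLMNPQR", "AHGKLMNPQR"), 1)
  expect_identical(pairwiseIdentity("AHGKLMNPQR", "AHGKLMNPQW"), 0.9)
  expect_identical(pairwiseIdentity("----", "AAAA"), 0)
  expect_error(pairwiseIdentity("AA", "AAA"), "length")
  set.seed(11)
  alpha <- c(strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]], "-")
  for (rep in 1:25) {
    a <- paste(sample(alpha, 30, TRUE), collapse = "")
    b <- paste(sample(alpha, 30, TRUE), collapse = "")
    expect_equal(pairwiseIdentity(a, b), bruteIdentity(a, b))
  }
  # matrix route agrees with the scalar route
  aln <- generateAlignment(c(G = 12, S = 3), gapRate = 0.15, seed = 2)$alignment
  im <- pairwiseIdentityMatrix(aln)
  rows <- unname(alignedRows(aln))
  for (i in c(1, 5, 9)) for (j in c(2, 7, 15))
    expect_equal(im[i, j], pairwiseIdentity(rows[i], rows[j]))
})

test_that("greedy redundancy removal collapses planted duplicates and matches the exhaustive oracle", {
  a <- hptAlignment(c("x", "y"), c("AHGKL", "AHGKL"))
  rr <- removeRedundancy(a)
  expect_identical(rr@keptIds, "x")
  expect_identical(rr@clusters$x, c("x", "y"))
  # threshold 1.0 on all-distinct rows keeps everything
  b <- hptAlignment(c("p", "q", "r"), c("AHGKL", "AHGKV", "AHGVV"))
  expect_identical(removeRedundancy(b, 1.0)@keptIds, c("p", "q", "r"))
  # planted duplicate groups, against the brute-force all-pairs oracle
  g <- generateAlignment(c(G = 16, S = 4), gapRate = 0.1, nDuplicates = 3,
                         nDuplicatedTemplates = 4, mutationRate = 0.015,
                         seed = 9)
  rr <- removeRedundancy(g$alignment, 0.98)
  oracle <- bruteGreedyClusters(unname(alignedRows(g$alignment)),
                                sequenceIds(g$alignment), 0.98)
  expect_identical(rr@keptIds, names(oracle))
  expect_identical(unname(as.list(rr@clusters)), unname(oracle))
  # every planted duplicate sits in its template's cluster
  for (tpl in names(g$truth$duplicateGroups))
    expect_true(all(g$truth$duplicateGroups[[tpl]] %in% rr@clusters[[tpl]]))
})

test_that("loosening the threshold never increases the number kept", {
  g <- generateAlignment(c(G = 20, S = 5), gapRate = 0.1, nDuplicates = 2,
                         nDuplicatedTemplates = 5, mutationRate = 0.02,
                         seed = 4)
  n98 <- length(removeRedundancy(g$alignment, 0.98)@keptIds)
  n90 <- length(removeRedundancy(g$alignment, 0.90)@keptIds)
  n100 <- length(removeRedundancy(g$alignment, 1.0)@keptIds)
  expect_lte(n90, n98)
  expect_lte(n98, n100)
})

test_that("anchor column detection maximizes anchor frequency", {
  a <- hptAlignment(paste0("s", 1:5),
                    c("AAHGK", "CAHGK", "DAHGK", "EAHGK", "FAHGK"))
  an <- findAnchorColumn(a)
  expect_identical(an@anchorCol, 3L)
  expect_identical(an@anchorFreq, 1)
  expect_identical(an@removedIds, character(0))
  # row lacking the anchor is flagged for removal
  b <- hptAlignment(paste0("s", 1:4),
                    c("AHGGK", "AHGGK", "AHGGK", "AQGGK"))
  expect_identical(findAnchorColumn(b)@removedIds, "s4")
  # competing columns: highest frequency wins (brute-force max check)
  set.seed(21)
  n <- 40
  rows <- replicate(n, paste(sample(c("A", "C", "D"), 10, TRUE),
                             collapse = ""))
  rows <- vapply(seq_len(n), function(i) {
    r <- strsplit(rows[i], "")[[1]]
    if (i <= 24) r[3] <- "H"          # 60% at column 3
    if (i <= 36) r[8] <- "H"          # 90% at column 8
    paste(r, collapse = "")
  }, "")
  aln <- hptAlignment(sprintf("r%02d", 1:n), rows)
  an <- findAnchorColumn(aln)
  freqs <- vapply(1:10, function(j)
    mean(substr(rows, j, j) == "H"), 0)
  expect_identical(an@anchorCol, which.max(freqs))
  expect_identical(an@anchorCol, 8L)
  # no conserved anchor below the floor
  c2 <- hptAlignment(c("a", "b"), c("AAGGK", "CAGGK"))
  expect_error(findAnchorColumn(c2), "no conserved anchor")
})

test_that("anchor-relative residues are read in ungapped coordinates", {
  # gapless: anchor at ungapped position 2, so H+4 is ungapped position 6
  expect_identical(residueAtOffset("AHGKLGS", 2, 4), "G")
  # same ungapped sequence interrupted by gaps: same residue, later column
  expect_identical(residueAtOffset("AHG--KLGS", 2, 4), "G")
  expect_identical(residueAtOffset("AH-GK", 2, 4), NA_character_)
  expect_error(residueAtOffset("A-GK", 2, 1), "gap at the anchor")
})

test_that("offset census recovers planted composition and partitions rows", {
  g <- generateAlignment(c(G = 87, S = 10, A = 3), gapRate = 0.1,
                         anchorDropout = 0.1, nShortRows = 2, seed = 7)
  aln <- g$alignment
  an <- findAnchorColumn(aln)
  pc <- countOffsetResidues(aln, an, 4)
  expect_identical(pc@counts[c("G", "S", "A")],
                   c(G = 87L, S = 10L, A = 3L))
  expect_identical(pc@total, 100L)
  expect_identical(pc@nShort, 2L)
  expect_identical(sort(an@removedIds), sort(g$truth$droppedIds))
  # row accounting: counted + too-short + removed = all rows
  expect_identical(pc@total + pc@nShort + length(an@removedIds),
                   nSequences(aln))
})

test_that("percent table reproduces printed-style census arithmetic", {
  pt <- percentTable(H4_COUNTS)
  expect_identical(attr(pt, "total"), 10073L)
  expect_identical(pt$residue[1:2], c("G", "S"))
  expect_identical(pt$percent[pt$residue == "G"], 86.94)
  expect_identical(pt$percent[pt$residue == "S"], 10.43)
  expect_identical(percentTable(c(G = 5))$percent, 100)
  expect_error(percentTable(c(G = 0)), "zero")
  # percents sum to 100 within rounding slack
  expect_lt(abs(sum(pt$percent) - 100), 0.05)
  # X handling: default counts in the denominator, excludable on request
  cx <- c(G = 90, X = 10)
  expect_identical(percentTable(cx)$percent, c(90, 10))
  ptx <- percentTable(cx, excludeX = TRUE)
  expect_identical(ptx$residue, "G")
  expect_identical(ptx$percent, 100)
})

test_that("logo information content behaves like a sequence logo", {
  pure <- hptAlignment(sprintf("s%03d", 1:1000),
                       rep("G", 1000))
  lm <- logoMatrix(pure)
  expect_equal(lm$info_bits, log2(20), tolerance = 1e-12)
  # uniform column has zero information
  unif <- hptAlignment(sprintf("s%02d", 1:20),
                       strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_equal(unique(logoMatrix(unif)$info_bits), 0)
  # 50/50 column: 1 bit of entropy
  half <- hptAlignment(c("a", "b"), c("G", "S"))
  lh <- logoMatrix(half)
  expect_equal(unique(lh$info_bits), log2(20) - 1, tolerance = 1e-12)
  expect_equal(sum(lh$height), log2(20) - 1, tolerance = 1e-12)
  # small-sample correction reduces information, never below zero
  lc <- logoMatrix(half, smallSampleCorrection = TRUE)
  expect_lt(unique(lc$info_bits), unique(lh$info_bits))
  expect_gte(min(lc$info_bits), 0)
  # gap-only columns are reported as missing
  gappy <- hptAlignment(c("a", "b"), c("-G", "-S"))
  lg <- logoMatrix(gappy)
  expect_true(is.na(lg$info_bits[lg$col == 1]))
  # bounds and per-column height sums on generated data
  g <- generateAlignment(c(G = 30, S = 10), gapRate = 0.2, seed = 3)$alignment
  lgm <- logoMatrix(g)
  expect_true(all(lgm$info_bits >= 0 & lgm$info_bits <= log2(20)))
  hsum <- tapply(lgm$height, lgm$col, sum)
  isum <- tapply(lgm$info_bits, lgm$col, function(x) x[1])
  expect_equal(unname(hsum), unname(isum), tolerance = 1e-10)
  fsum <- tapply(lgm$freq, lgm$col, sum)
  expect_true(all(abs(fsum - 1) < 1e-12))
})
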