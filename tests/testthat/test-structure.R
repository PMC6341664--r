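test_that("PDB reading: fields, altloc policy, first model only", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 20.00           N",
    "ATOM      2  CA  ALA A   1      11.804   7.000  -5.504  1.00 20.00           C",
    "ATOM      3  CA AGLY A   2      12.000   8.000  -4.000  0.40 20.00           C",
    "ATOM      4  CA BGLY A   2      12.100   8.100  -4.100  0.60 20.00           C",
    "HETATM    5  O   HOH A 101       1.000   2.000   3.000  1.00 30.00           O",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ALA A   1      99.000   6.134  -6.504  1.00 20.00           N",
    "ENDMDL", "END"), tf)
  m <- readPDB(tf)
  at <- atomTable(m)
  expect_identical(nrow(at), 4L)                      # altloc collapsed, model 1
  ca2 <- at[at$resseq == 2 & at$name == "CA", ]
  expect_identical(ca2$altloc, "B")                   # higher occupancy wins
  expect_identical(at$hetero, c(FALSE, FALSE, FALSE, TRUE))
  expect_false(any(at$x > 90))                        # model 2 ignored
  expect_identical(at$element[at$name == "N"], "N")
  expect_error(readPDB(tempfile()), "no such file")
})

test_that("structures round-trip through PDB files at format precision", {
  g <- generateStructurePair(nResidues = 30, regions = list(), seed = 3)
  tf <- withr::local_tempfile(fileext = ".pdb")
  writePDB(g$ref, tf)
  back <- readPDB(tf)
  expect_identical(nrow(atomTable(back)), 30L)
  expect_equal(as.matrix(atomTable(back)[, c("x", "y", "z")]),
               as.matrix(atomTable(g$ref)[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("atom matching pairs the intersection deterministically", {
  g <- generateStructurePair(nResidues = 20, regions = list(), seed = 1)
  m <- matchAtoms(g$ref, g$ref, "CA")
  expect_identical(nrow(m$P), 20L)
  expect_identical(m$P, m$Q)
  # intersection only
  sub <- structureModel(atomTable(g$ref)[3:20, ])
  m2 <- matchAtoms(sub, g$ref, "CA")
  expect_identical(sort(m2$keys$resseq), 3:20)
  # chain renaming with a chain map reproduces the same pairing
  ren <- atomTable(g$ref); ren$chain <- "Z"
  m3 <- matchAtoms(structureModel(ren), g$ref, "CA", chainMap = c(Z = "A"))
  expect_identical(m3$Q, m$Q)
  expect_error(matchAtoms(structureModel(ren), g$ref, "CA"), "no atoms")
})

test_that("Kabsch superposition is exact on rigid transforms and beats a rotation grid", {
  set.seed(42)
  P <- matrix(rnorm(30), 10, 3)
  R <- randomRotation()
  Q <- P %*% t(R) + matrix(rep(c(1, -2, 3), each = 10), 10)
  sp <- kabschSuperpose(P, Q)
  expect_lt(sp@rmsd, 1e-8)
  expect_equal(det(sp@rotation), 1, tolerance = 1e-9)
  expect_equal(applySuperposition(sp, P), Q, tolerance = 1e-8,
               ignore_attr = TRUE)
  # identity case
  sp0 <- kabschSuperpose(P, P)
  expect_lt(sp0@rmsd, 1e-10)
  expect_equal(sp0@rotation, diag(3), tolerance = 1e-8)
  # independent oracle: bio3d least-squares fit gives the same rmsd
  set.seed(7)
  Q2 <- Q + matrix(rnorm(30, 0, 0.3), 10, 3)
  sp2 <- kabschSuperpose(P, Q2)
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(Q2)),
                           mobile = as.vector(t(P)),
                           fixed.inds = bio3d::atom2xyz(1:10),
                           mobile.inds = bio3d::atom2xyz(1:10))
  expect_equal(sp2@rmsd, bio3d::rmsd(as.vector(t(Q2)), fitted),
               tolerance = 1e-3)   # bio3d::rmsd reports 3 decimals
  # planar 4-point toy set vs an exhaustive in-plane rotation grid (1 deg)
  P4 <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 2), 0)
  th <- 33 * pi / 180
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
               byrow = TRUE)
  Q4 <- P4 %*% t(Rz)
  Q4 <- Q4 + matrix(rnorm(12, 0, 0.05), 4, 3)
  grid <- vapply(seq(0, 359, by = 1) * pi / 180, function(a) {
    Ra <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
                 byrow = TRUE)
    Pa <- P4 %*% t(Ra)
    Pa <- sweep(Pa, 2, colMeans(Pa) - colMeans(Q4))
    sqrt(mean(rowSums((Pa - Q4)^2)))
  }, 0)
  expect_lte(kabschSuperpose(P4, Q4)@rmsd, min(grid) + 1e-12)
  # errors: mismatched sizes, too few points, collinear input
  expect_error(kabschSuperpose(P[1:4, ], Q), "size")
  expect_error(kabschSuperpose(P[1:2, ], Q[1:2, ]), "at least 3")
  L <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabschSuperpose(L, L + 1), "degenerate")
})

test_that("superposition rmsd is invariant under common rigid transforms", {
  set.seed(9)
  P <- matrix(rnorm(45), 15, 3)
  Q <- P + matrix(rnorm(45, 0, 0.5), 15, 3)
  base <- kabschSuperpose(P, Q)@rmsd
  for (k in 1:5) {
    R <- randomRotation(); tr <- rnorm(3, 0, 10)
    P2 <- sweep(P %*% t(R), 2, -tr)
    Q2 <- sweep(Q %*% t(R), 2, -tr)
    expect_equal(kabschSuperpose(P2, Q2)@rmsd, base, tolerance = 1e-8)
  }
})

test_that("regional RMSD separates planted displacement from the scaffold", {
  g <- generateStructurePair(
    nResidues = 167,
    regions = list(alphaA = list(start = 11, end = 21, offset = 1.7),
                   activeSite = list(start = 60, end = 90, offset = 0.2)),
    noiseSd = 0, seed = 5)
  alphaA <- regionSpec("A", 11, 21)
  # identical structures: zero in both modes
  expect_equal(regionRmsd(g$ref, g$ref, alphaA), 0, tolerance = 1e-10)
  expect_equal(regionRmsd(g$ref, g$ref, alphaA, mode = "local_fit"), 0,
               tolerance = 1e-10)
  # frame fitted on the unperturbed scaffold recovers the offsets exactly
  scaffold <- regionSpec("A", c(1, 22, 91), c(10, 59, 167))
  expect_equal(regionRmsd(g$mob, g$ref, alphaA, fitRegion = scaffold), 1.7,
               tolerance = 1e-8)
  act <- regionSpec("A", 60, 90)
  expect_equal(regionRmsd(g$mob, g$ref, act, fitRegion = scaffold), 0.2,
               tolerance = 1e-8)
  # a rigidly displaced region is internally undeformed
  expect_lt(regionRmsd(g$mob, g$ref, alphaA, mode = "local_fit"), 1e-8)
  # local fit never exceeds the global frame
  gn <- generateStructurePair(nResidues = 167,
                              regions = list(a = list(start = 11, end = 21,
                                                      offset = 1.7)),
                              noiseSd = 0.1, seed = 6)
  for (reg in list(alphaA, act, regionSpec("A", 1, 167))) {
    lf <- regionRmsd(gn$mob, gn$ref, reg, mode = "local_fit")
    gf <- regionRmsd(gn$mob, gn$ref, reg, mode = "global_frame")
    expect_lte(lf, gf + 1e-12)
  }
  # full-set region in the global frame equals the Kabsch rmsd
  m <- matchAtoms(gn$mob, gn$ref, "CA")
  expect_equal(regionRmsd(gn$mob, gn$ref, regionSpec("A", 1, 167)),
               kabschSuperpose(m$P, m$Q)@rmsd, tolerance = 1e-10)
})

test_that("clash scan matches a brute-force all-pairs oracle", {
  # worked two-carbon example: d = 2.0 A, overlap 1.70 + 1.70 - 2.0 = 1.4 A
  a <- structureModel(data.frame(name = "CB", resname = "GLN", chain = "A",
                                 resseq = 68, x = 0, y = 0, z = 0))
  b <- structureModel(data.frame(name = "CB", resname = "LYS", chain = "B",
                                 resseq = 1195, x = 2, y = 0, z = 0))
  hit <- clashScan(a, regionSpec("A", 68, 68, "heavy"),
                   b, regionSpec("B", 1195, 1195, "heavy"))
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$overlap, 1.4, tolerance = 1e-12)
  expect_equal(hit$distance, 2.0, tolerance = 1e-12)
  # far apart: no clash
  bfar <- structureModel(data.frame(name = "CB", resname = "LYS",
                                    chain = "B", resseq = 1195,
                                    x = 10, y = 0, z = 0))
  expect_identical(nrow(clashScan(a, regionSpec("A", 68, 68, "heavy"),
                                  bfar, regionSpec("B", 1195, 1195,
                                                   "heavy"))), 0L)
  # random 50-atom selections vs the brute-force oracle
  set.seed(23)
  mk <- function(chain) {
    n <- 50
    structureModel(data.frame(
      name = sample(c("CA", "CB", "N", "O", "SD"), n, TRUE),
      resname = "ALA", chain = chain, resseq = seq_len(n),
      x = runif(n, 0, 12), y = runif(n, 0, 12), z = runif(n, 0, 12),
      element = sample(c("C", "N", "O", "S"), n, TRUE)))
  }
  A <- mk("A"); B <- mk("B")
  got <- clashScan(A, regionSpec("A", 1, 50, "heavy"),
                   B, regionSpec("B", 1, 50, "heavy"), 0.4)
  radii <- list(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  want <- bruteClashPairs(atomTable(A), atomTable(B), radii, 0.4)
  expect_identical(nrow(got), if (is.null(want)) 0L else nrow(want))
  if (!is.null(want)) {
    gotKeys <- sort(paste(got$resseq_a, got$name_a, got$resseq_b,
                          got$name_b))
    at <- atomTable(A); bt <- atomTable(B)
    wantKeys <- sort(paste(at$resseq[want$i], at$name[want$i],
                           bt$resseq[want$j], bt$name[want$j]))
    expect_identical(gotKeys, wantKeys)
    expect_equal(sort(got$overlap), sort(want$overlap), tolerance = 1e-12)
  }
  # symmetry: swapping the selections yields the same pairs
  rev <- clashScan(B, regionSpec("B", 1, 50, "heavy"),
                   A, regionSpec("A", 1, 50, "heavy"), 0.4)
  expect_identical(nrow(rev), nrow(got))
  expect_equal(sort(rev$overlap), sort(got$overlap), tolerance = 1e-12)
  # output sorted by overlap descending
  expect_true(all(diff(got$overlap) <= 0))
})
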