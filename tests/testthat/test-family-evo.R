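test_that("identity matrix is 100 on the diagonal and symmetric", {
  set.seed(8)
  prots <- setNames(vapply(1:6, function(i) randProt(200), ""),
                    paste0("p", 1:6))
  m <- identityMatrix(prots)
  expect_equal(unname(diag(m)), rep(100, 6))
  expect_equal(m, t(m))
})

test_that("identity of a 10 percent mutated copy lands in the expected band", {
  set.seed(19)
  ok <- 0L
  for (k in 1:10) {
    p <- randProt(300)
    q <- haloriscan:::mutateProtein(p, 0.10)
    id <- identityMatrix(setNames(c(p, q), c("a", "b")))["a", "b"]
    if (id >= 85 && id <= 95) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("short perfect local matches do not count as family identity", {
  set.seed(3)
  shared <- randProt(30)
  a <- paste0(randProt(150), shared, randProt(150))
  b <- paste0(randProt(140), shared, randProt(160))
  m <- identityMatrix(setNames(c(a, b), c("a", "b")), min_aligned = 100L)
  expect_lt(m["a", "b"], 80)
})

test_that("single-linkage families follow the identity threshold", {
  m <- matrix(c(100, 85, 60, 85, 100, 82, 60, 82, 100), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(clusterFamilies(m, 80), list(c("a", "b", "c")))
  expect_length(clusterFamilies(m, 90), 3L)
  expect_length(clusterFamilies(m, 100.0001), 3L)
})

test_that("clusterFamilies equals a union-find oracle on random matrices", {
  set.seed(61)
  for (k in 1:20) {
    n <- sample(3:12, 1)
    m <- matrix(runif(n * n, 40, 100), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 100
    dimnames(m) <- list(paste0("x", 1:n), paste0("x", 1:n))
    got <- clusterFamilies(m, 80)
    want <- oracleComponents(m, 80)
    norm <- function(fams) unname(sort(vapply(fams, function(f)
      paste(sort(f), collapse = ","), "")))
    expect_equal(norm(got), norm(want))
  }
})

test_that("family naming assigns oriC1 to the genome-universal family", {
  fams <- list(c("g1_a", "g2_a", "g3_a"),       # universal
               c("g1_b", "g2_b"),               # largest partial
               c("g1_c"), c("g3_d"))
  gof <- c(g1_a = "g1", g2_a = "g2", g3_a = "g3", g1_b = "g1", g2_b = "g2",
           g1_c = "g1", g3_d = "g3")
  named <- nameFamilies(fams, gof)
  nm <- vapply(named, familyName, "")
  expect_equal(nm[1], "oriC1")
  expect_equal(familyCoverage(named[[1]]), 1)
  expect_setequal(nm, c("oriC1", "oriCa", "oriCb", "F3"))
  # the two largest non-universal families take oriCa/oriCb
  expect_equal(nrow(familyMembers(named[[which(nm == "oriCa")]])), 2L)
})

test_that("equal-size families break ties lexicographically and no universal warns", {
  fams <- list(c("g1_x", "g2_x"), c("g1_m", "g2_m"))
  gof <- c(g1_x = "g1", g2_x = "g2", g1_m = "g1", g2_m = "g2", g3_z = "g3")
  expect_warning(named <- nameFamilies(fams, gof), "no family covers")
  nm <- vapply(named, familyName, "")
  # lexicographically smaller first member wins oriCa
  expect_equal(familyMembers(named[[which(nm == "oriCa")]])$locus_tag[1],
               "g1_m")
})

test_that("single-genome input flags the degenerate oriC1 edge case", {
  fams <- list(c("g1_a", "g1_b"))
  gof <- c(g1_a = "g1", g1_b = "g1")
  expect_warning(named <- nameFamilies(fams, gof), "degenerate")
  expect_equal(familyName(named[[1]]), "oriC1")
})

test_that("ORB linkage scores consensus similarity within a family", {
  expect_equal(orbLinkageCheck(c(strrep("ACGT", 8), strrep("ACGT", 8)))$score, 1)
  a <- strrep("ACGTA", 6)
  b <- a
  substr(b, 1, 3) <- "TTT"
  expect_equal(orbLinkageCheck(c(a, b))$score, 0.9)
  expect_error(orbLinkageCheck("ACGT"), "at least 2")
})

test_that("same-family ORBs score above cross-family ORBs", {
  set.seed(33)
  ok <- 0L
  for (k in 1:20) {
    fam <- randDna(30, 0.5)
    other <- randDna(30, 0.5)
    a <- mutateSequence(fam, 0.05)
    b <- mutateSequence(fam, 0.05)
    same <- orbLinkageCheck(c(a, b))$score
    cross <- orbLinkageCheck(c(a, mutateSequence(other, 0.05)))$score
    if (same > cross) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})

mobCall <- function(lo, hi) {
  new("OriginCall", geneRef = "g", repliconId = "chr", status = "candidate",
      orbs = data.frame(start = lo, end = hi, orientation = "forward",
                        score = 20, side = "upstream"),
      atRich = data.frame(), layout = "upstream",
      originStart = as.integer(lo), originEnd = as.integer(hi), notes = "")
}

test_that("mobility annotation flags nearby transposases within the window", {
  ft <- makeFeatureTable(c("t1", "h1"), "CDS", c(13000L, 40000L),
                        c(14000L, 41000L), "+",
                        product = c("ISH3 family transposase",
                                    "hypothetical protein"))
  cl <- mobCall(9000L, 10000L)
  ann <- annotateMobility(cl, ft, window_bp = 10000L)
  expect_true(ann$later_acquired)
  expect_equal(ann$mobile_genes$locus_tag, "t1")
  expect_equal(ann$mobile_genes$distance_bp, 3000L)
  # nearest mobile gene outside the window
  ft2 <- ft; ft2$start[1] <- 35000L; ft2$end[1] <- 36000L
  expect_false(annotateMobility(cl, ft2, window_bp = 10000L)$later_acquired)
  # enlarging the window never flips a flag off
  expect_true(annotateMobility(cl, ft2, window_bp = 30000L)$later_acquired)
})

test_that("neighbor joining matches the three-taxon closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)$tree
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 1, 3))
  expect_error(njTree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers additive trees exactly and ignores taxon order", {
  set.seed(17)
  for (k in 1:5) {
    n <- sample(5:10, 1)
    true <- ape::rtree(n, br = function(m) runif(m, 0.1, 1))
    true <- ape::unroot(true)
    d <- ape::cophenetic.phylo(true)
    got <- njTree(d)$tree
    expect_equal(unname(c(ape::dist.topo(ape::unroot(got), true))), 0)
    expect_equal(ape::cophenetic.phylo(got)[rownames(d), colnames(d)], d,
                 tolerance = 1e-6)
    # label permutation gives an isomorphic tree
    perm <- sample(n)
    got2 <- njTree(d[perm, perm])$tree
    expect_equal(unname(c(ape::dist.topo(ape::unroot(got2),
                                         ape::unroot(got)))), 0)
  }
})

test_that("Poisson distances follow the closed form and mutation monotonicity", {
  p <- randProt(200)
  expect_equal(proteinDistance(p, p), 0)
  # exactly 10 percent differing ungapped columns
  a <- strrep("A", 100)
  b <- paste0(strrep("C", 10), strrep("A", 90))
  expect_equal(proteinDistance(a, b), -log(0.9), tolerance = 1e-9)
  set.seed(23)
  base <- randProt(300)
  d <- vapply(c(0.05, 0.15, 0.3, 0.5), function(r) {
    q <- haloriscan:::mutateProtein(base, r)
    al <- globalAlign(base, q)
    proteinDistance(al$aligned_a, al$aligned_b)
  }, 1)
  expect_true(all(diff(d) > 0))
  expect_warning(proteinDistance("AAAA", "CCCC"), "saturation")
})
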