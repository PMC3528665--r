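test_that("sequence mutation respects rate 0 and rate 1", {
  s <- randDna(500, 0.5)
  expect_equal(mutateSequence(s, 0, seed = 1L), s)
  m <- mutateSequence(s, 1, seed = 2L)
  expect_true(all(strsplit(m, "")[[1]] != strsplit(s, "")[[1]]))
})

test_that("observed substitution fraction tracks the binomial expectation", {
  rate <- 0.1
  n <- 2000L
  hits <- 0L
  trials <- 20L
  set.seed(71)
  for (k in seq_len(trials)) {
    s <- randDna(n, 0.5)
    m <- mutateSequence(s, rate)
    hits <- hits + sum(strsplit(m, "")[[1]] != strsplit(s, "")[[1]])
  }
  tot <- n * trials
  sdev <- sqrt(tot * rate * (1 - rate))
  expect_lt(abs(hits - tot * rate), 3 * sdev)
})

test_that("protected positions never mutate", {
  s <- strrep("ACGT", 25)
  m <- mutateSequence(s, 1, seed = 3L, protect = 1:10)
  expect_equal(substr(m, 1, 10), substr(s, 1, 10))
})

test_that("the generated genome matches its plan and architecture", {
  spec <- smallSpec(3L)
  g <- generateGenome(spec, 1L)
  expect_length(g$replicons, 3L)
  expect_equal(vapply(g$replicons, repliconLength, 1L),
               c(60000L, 40000L, 20000L))
  tr <- g$truth
  expect_equal(nrow(tr), 11L)  # the 6/4/1 initiator split
  expect_equal(as.integer(table(tr$replicon_id)[paste0("genome1_",
                                                       c("chr", "chrII",
                                                         "meg"))]),
               c(6L, 4L, 1L))
  n <- 11L
  expect_equal(sum(tr$origin_status == "dual"), round(spec$dual_fraction * n))
  expect_equal(sum(tr$origin_status == "deficient"),
               round(spec$deficient_fraction * n))
  expect_equal(sum(tr$origin_status == "none"), round(spec$none_fraction * n))
  # planted coordinates are consistent with the emitted annotation
  for (i in which(!is.na(tr$orb_start))) {
    r <- repliconById(g$replicons, tr$replicon_id[i])
    expect_lte(tr$orb_end[i], repliconLength(r))
    orb <- repliconSubseq(r, tr$orb_start[i], tr$orb_start[i] + 5L)
    expect_equal(nchar(orb), 6L)
  }
})

test_that("a degenerate plan makes every planted origin deficient", {
  spec <- syntheticSpec(
    n_genomes = 1L,
    replicons = list(list(class = "chromosome", length = 30000L,
                          topology = "circular", n_cdc6 = 4L)),
    deficient_fraction = 1, dual_fraction = 0, none_fraction = 0,
    seed = 4L)
  g <- generateGenome(spec, 1L)
  expect_true(all(g$truth$origin_status == "deficient"))
})

test_that("generation is byte-identical for a fixed seed", {
  spec <- syntheticSpec(
    n_genomes = 1L,
    replicons = list(list(class = "chromosome", length = 25000L,
                          topology = "circular", n_cdc6 = 2L)),
    seed = 11L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generateGenomeSet(spec, out_dir = d1)
  generateGenomeSet(spec, out_dir = d2)
  f1 <- file.path(d1, "genome1.gbk")
  f2 <- file.path(d2, "genome1.gbk")
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_equal(readLines(file.path(d1, "truth.tsv")),
               readLines(file.path(d2, "truth.tsv")))
})

test_that("emitted files are consumable without warnings", {
  spec <- syntheticSpec(
    n_genomes = 1L,
    replicons = list(list(class = "chromosome", length = 25000L,
                          topology = "circular", n_cdc6 = 2L)),
    seed = 12L)
  d <- withr::local_tempdir()
  generateGenomeSet(spec, out_dir = d)
  expect_no_warning(reps <- readReplicons(file.path(d, "genome1.gbk"),
                                          "genbank"))
  expect_no_warning(readAnnotations(file.path(d, "genome1.gff3"), reps))
})

test_that("intergenic background GC matches the spec away from planted elements", {
  spec <- syntheticSpec(
    n_genomes = 1L,
    replicons = list(list(class = "chromosome", length = 120000L,
                          topology = "circular", n_cdc6 = 6L)),
    seed = 21L)
  g <- generateGenome(spec, 1L)
  r <- g$replicons[[1]]
  covered <- rep(FALSE, repliconLength(r))
  ft <- features(r)
  for (i in seq_len(nrow(ft))) covered[ft$start[i]:min(ft$end[i], length(covered))] <- TRUE
  tr <- g$truth
  for (i in which(!is.na(tr$orb_start)))
    covered[max(1, tr$orb_start[i] - 50L):min(tr$orb_end[i] + 50L,
                                              length(covered))] <- TRUE
  v <- strsplit(as.character(repliconSequence(r)), "")[[1]][!covered]
  expect_lt(abs(mean(v %in% c("G", "C")) - spec$background_gc), 0.01)
})

test_that("truth comparison recounts a small fixed case correctly", {
  truth <- data.frame(
    genome_id = "g1", replicon_id = "chr",
    locus_tag = paste0("t", 1:6), is_cdc6 = TRUE,
    family_id = c("famA", "famA", NA, NA, NA, NA),
    origin_status = c("candidate", "candidate", "deficient", "dual",
                      "none", "none"),
    orb_start = NA_integer_, orb_end = NA_integer_,
    at_start = NA_integer_, at_end = NA_integer_, mobile_nearby = FALSE,
    stringsAsFactors = FALSE)
  calls <- data.frame(
    locus_tag = paste0("t", 1:6),
    status = c("candidate", "none", "deficient", "dual", "none", "deficient"),
    stringsAsFactors = FALSE)
  tc <- truthCompare(calls, truth)
  expect_equal(unname(tc$confusion["candidate", "candidate"]), 1L)
  expect_equal(unname(tc$confusion["candidate", "none"]), 1L)
  expect_equal(unname(tc$confusion["none", "deficient"]), 1L)
  ps <- tc$per_status
  expect_equal(ps$recall[ps$status == "candidate"], 0.5)
  expect_equal(ps$precision[ps$status == "deficient"], 0.5)
  expect_equal(ps$recall[ps$status == "dual"], 1)
  # perfect calls give unit precision/recall everywhere observed
  tc2 <- truthCompare(data.frame(locus_tag = truth$locus_tag,
                                 status = truth$origin_status), truth)
  expect_true(all(tc2$per_status$precision == 1, na.rm = TRUE))
  expect_true(all(tc2$per_status$recall == 1, na.rm = TRUE))
  # all-none calls: zero candidate recall
  tc3 <- truthCompare(data.frame(locus_tag = truth$locus_tag,
                                 status = "none"), truth)
  expect_equal(tc3$per_status$recall[tc3$per_status$status == "candidate"], 0)
})

test_that("the family Rand index rewards matching partitions", {
  truth <- data.frame(
    genome_id = "g1", replicon_id = "chr", locus_tag = paste0("t", 1:4),
    is_cdc6 = TRUE, family_id = c("A", "A", "B", "B"),
    origin_status = "candidate", orb_start = NA_integer_,
    orb_end = NA_integer_, at_start = NA_integer_, at_end = NA_integer_,
    mobile_nearby = FALSE, stringsAsFactors = FALSE)
  calls <- data.frame(locus_tag = truth$locus_tag, status = "candidate")
  fam <- function(name, members)
    new("OriginFamily", name = name,
        members = data.frame(genome_id = "g1", locus_tag = members,
                             stringsAsFactors = FALSE),
        orbConsensus = "", genomeCoverage = 1)
  good <- list(fam("oriC1", c("t1", "t2")), fam("oriCa", c("t3", "t4")))
  bad <- list(fam("oriC1", c("t1", "t3")), fam("oriCa", c("t2", "t4")))
  expect_equal(truthCompare(calls, truth, good)$rand_index, 1)
  expect_lt(truthCompare(calls, truth, bad)$rand_index, 1)
})
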