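test_that("FASTA records load as linear replicons", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">r1 some description", "ACGT"), f)
  reps <- readReplicons(f, "fasta")
  expect_length(reps, 1L)
  expect_equal(repliconId(reps[[1]]), "r1")
  expect_equal(repliconLength(reps[[1]]), 4L)
  expect_equal(topology(reps[[1]]), "linear")
  expect_equal(nrow(features(reps[[1]])), 0L)
})

test_that("ambiguity codes other than N are coerced to N with a warning", {
  expect_warning(r <- Replicon("r1", "ACGRTN", topology = "linear"),
                 "coerced to N")
  expect_equal(as.character(repliconSequence(r)), "ACGNTN")
})

test_that("GenBank write-then-read round-trips coordinates and sequence", {
  ft <- makeFeatureTable(
    locus_tag = c("g1", "g2", "g3"), kind = "CDS",
    start = c(1L, 120L, 290L), end = c(6L, 240L, 310L),
    strand = c("+", "-", "+"),
    product = c("orc/cdc6 replication initiator", "hypothetical protein",
                "ISH3 family transposase"))
  r <- Replicon("repA", randDna(400, 0.62), topology = "circular",
                repliconClass = "minichromosome", features = ft)
  f <- withr::local_tempfile(fileext = ".gbk")
  writeGenBank(list(r), f)
  back <- readReplicons(f, "genbank")[[1]]
  expect_equal(repliconId(back), "repA")
  expect_equal(topology(back), "circular")
  expect_equal(repliconClass(back), "minichromosome")
  expect_equal(as.character(repliconSequence(back)),
               as.character(repliconSequence(r)))
  expect_equal(features(back)[, c("locus_tag", "kind", "start", "end",
                                  "strand", "product", "wraps_origin")],
               ft[, c("locus_tag", "kind", "start", "end", "strand",
                      "product", "wraps_origin")])
})

test_that("synthetic multi-replicon GenBank round-trips exactly", {
  spec <- syntheticSpec(
    n_genomes = 1L,
    replicons = list(
      list(class = "chromosome", length = 25000L, topology = "circular",
           n_cdc6 = 2L),
      list(class = "minichromosome", length = 20000L, topology = "circular",
           n_cdc6 = 1L)),
    seed = 5L)
  g <- generateGenome(spec, 1L)
  f <- withr::local_tempfile(fileext = ".gbk")
  writeGenBank(g$replicons, f)
  expect_no_warning(back <- readReplicons(f, "genbank"))
  expect_length(back, 2L)
  for (k in 1:2) {
    expect_equal(as.character(repliconSequence(back[[k]])),
                 as.character(repliconSequence(g$replicons[[k]])))
    expect_equal(features(back[[k]])$start, features(g$replicons[[k]])$start)
    expect_equal(features(back[[k]])$end, features(g$replicons[[k]])$end)
    expect_equal(features(back[[k]])$strand, features(g$replicons[[k]])$strand)
  }
})

test_that("GFF3 annotations group by replicon and keep 1-based coordinates", {
  r1 <- Replicon("chr", randDna(500), topology = "circular")
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tCDS\t101\t200\t.\t+\t0\tID=gA;locus_tag=gA;product=thing",
               "chr\tsrc\tCDS\t490\t520\t.\t-\t0\tID=gB;locus_tag=gB"), f)
  ann <- readAnnotations(f, list(r1))
  ft <- ann[["chr"]]
  expect_equal(ft$start, c(101L, 490L))
  expect_equal(ft$end, c(200L, 520L))
  expect_equal(ft$strand, c("+", "-"))
  expect_equal(ft$locus_tag, c("gA", "gB"))
  # end beyond a circular replicon's length marks a wrap
  expect_true(ft$wraps_origin[2])
  expect_false(ft$wraps_origin[1])
})

test_that("GFF3 seqids must match a loaded replicon", {
  r1 <- Replicon("chr", randDna(100), topology = "linear")
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "nope\tsrc\tCDS\t1\t30\t.\t+\t0\tID=x"), f)
  expect_error(readAnnotations(f, list(r1)), "nope")
})

test_that("empty GFF3 yields empty feature sets without error", {
  r1 <- Replicon("chr", randDna(100), topology = "linear")
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", f)
  ann <- readAnnotations(f, list(r1))
  expect_equal(nrow(ann[["chr"]]), 0L)
})

test_that("CDS translation uses the bacterial/archaeal code on both strands", {
  r <- Replicon("r", "ATGGCTTAA", topology = "linear")
  ftp <- makeFeatureTable("g1", "CDS", 1L, 9L, "+")
  expect_equal(translateCds(r, ftp[1, ])$aa_sequence, "MA")
  rm_ <- Replicon("r", revcomp("ATGGCTTAA"), topology = "linear")
  ftm <- makeFeatureTable("g1", "CDS", 1L, 9L, "-")
  expect_equal(translateCds(rm_, ftm[1, ])$aa_sequence, "MA")
})

test_that("translation agrees with an independent codon-table oracle", {
  set.seed(42)
  code <- Biostrings::getGeneticCode("11")
  sense <- names(code)[code != "*"]
  nt <- paste0("ATG", paste(sample(sense, 298, replace = TRUE),
                            collapse = ""), "TAA")
  r <- Replicon("r", nt, topology = "linear")
  ft <- makeFeatureTable("g1", "CDS", 1L, nchar(nt), "+")
  got <- translateCds(r, ft[1, ])
  want <- paste(seqinr::translate(strsplit(tolower(nt), "")[[1]],
                                  numcode = 11), collapse = "")
  want <- sub("\\*$", "", want)
  expect_equal(got$aa_sequence, want)
  expect_equal(got$length_aa, nchar(want))
})

test_that("internal stop codons flag a pseudogene and return NULL", {
  r <- Replicon("r", "ATGTAATAA", topology = "linear")
  ft <- makeFeatureTable("g1", "CDS", 1L, 9L, "+")
  expect_warning(out <- translateCds(r, ft[1, ]), "pseudogene")
  expect_null(out)
})

test_that("gcProfile handles degenerate compositions", {
  rg <- Replicon("g", strrep("G", 2000), topology = "linear")
  expect_true(all(gcProfile(rg, window = 500, step = 100)$gc == 1))
  ra <- Replicon("a", strrep("ATGC", 500), topology = "linear")
  expect_true(all(gcProfile(ra, window = 4, step = 4)$gc == 0.5))
  expect_error(gcProfile(Replicon("s", "ACGT", topology = "linear"),
                         window = 10), "window")
})

test_that("gcProfile minimum falls inside a planted low-GC island", {
  set.seed(9)
  left <- randDna(12000, 0.62)
  island <- randDna(5000, 0.30)
  right <- randDna(13000, 0.62)
  r <- Replicon("chr", paste0(left, island, right), topology = "linear")
  prof <- gcProfile(r, window = 3000, step = 300)
  # exhaustive naive oracle over the same windows
  seqchr <- paste0(left, island, right)
  naive <- vapply(seq(1, nchar(seqchr) - 3000 + 1, by = 300), function(s) {
    v <- strsplit(substr(seqchr, s, s + 2999), "")[[1]]
    mean(v %in% c("G", "C"))
  }, 1)
  expect_equal(prof$gc, naive)
  m <- prof$midpoint[which.min(prof$gc)]
  expect_gt(m, 12000)
  expect_lt(m, 17000)
})

test_that("gcProfile is rotation-invariant on circular replicons", {
  set.seed(11)
  s <- randDna(6000, 0.62)
  r1 <- Replicon("c", s, topology = "circular")
  rot <- paste0(substr(s, 501, 6000), substr(s, 1, 500))
  r2 <- Replicon("c", rot, topology = "circular")
  g1 <- gcProfile(r1, window = 1000, step = 500)$gc
  g2 <- gcProfile(r2, window = 1000, step = 500)$gc
  expect_equal(sort(g1), sort(g2))
})

test_that("origin reports round-trip and recount correctly", {
  d <- withr::local_tempdir()
  # zero calls: header-only outputs
  paths <- writeOriginReport(list(), list(), file.path(d, "empty"))
  expect_equal(length(readLines(paths[["bed"]])), 0L)
  expect_equal(readLines(paths[["gff"]]), "##gff-version 3")

  orbs <- data.frame(start = c(150L, 260L), end = c(179L, 289L),
                     orientation = c("forward", "reverse"),
                     score = c(30, 28), side = "upstream")
  cl <- new("OriginCall", geneRef = "gene1", repliconId = "chr",
            status = "candidate", orbs = orbs, atRich = data.frame(),
            layout = "upstream", originStart = 150L, originEnd = 289L,
            notes = "")
  none <- new("OriginCall", geneRef = "gene2", repliconId = "chr",
              status = "none", orbs = data.frame(), atRich = data.frame(),
              layout = NA_character_, originStart = NA_integer_,
              originEnd = NA_integer_, notes = "")
  paths <- writeOriginReport(list(cl, none), list(), file.path(d, "one"))
  bed <- readLines(paths[["bed"]])
  expect_length(bed, 1L)
  # BED is 0-based half-open at the boundary
  expect_equal(strsplit(bed, "\t")[[1]][2:3], c("149", "289"))
  gff <- rtracklayer::import.gff3(paths[["gff"]])
  expect_length(gff, 3L)  # origin + 2 ORB children
  expect_equal(GenomicRanges::start(gff)[1], 150L)
  expect_equal(GenomicRanges::end(gff)[1], 289L)
  rsum <- read.delim(paths[["replicon"]])
  expect_equal(rsum$n_cdc6, 2L)
  expect_equal(rsum$n_ori_associated, 1L)
  expect_equal(rsum$percentage, "50%")
})
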