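# Independent oracles and small fixture builders shared across the suite.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Full Gotoh local-alignment DP (affine gaps: a gap of length k costs
# open + k * ext). Written independently of the package's alignment path.
oracleLocalScore <- function(a, b, mat = blosum62, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
    F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + mat[av[i - 1], bv[j - 1]],
                   E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# Union-find connected components over identity >= threshold.
oracleComponents <- function(mat, threshold) {
  n <- nrow(mat)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && mat[i, j] >= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  unname(split(rownames(mat), roots))
}

# Longest maximal G run by naive linear scan.
oracleLongestGRun <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  best <- 0L; cur <- 0L
  for (ch in v) {
    cur <- if (ch == "G") cur + 1L else 0L
    best <- max(best, cur)
  }
  best
}

randDna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

randProt <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

# Hamming distance allowing either orientation and small shifts between
# a discovered consensus and the planted one (equal widths).
motifRecoveryDistance <- function(found, planted) {
  if (nchar(found) != nchar(planted)) return(Inf)
  min(hamming(found, planted), hamming(found, revcomp(planted)))
}

# A small single-genome three-replicon spec mirroring the 6/4/1 initiator
# architecture at reduced replicon sizes, used where full-size runs would
# dominate the suite's runtime.
smallSpec <- function(seed) {
  syntheticSpec(
    n_genomes = 1L,
    replicons = list(
      list(class = "chromosome", length = 60000L, topology = "circular",
           n_cdc6 = 6L),
      list(class = "minichromosome", length = 40000L, topology = "circular",
           n_cdc6 = 4L),
      list(class = "megaplasmid", length = 20000L, topology = "circular",
           n_cdc6 = 1L)),
    seed = seed)
}

fastConfig <- function(seed) {
  runConfig(widths = c(25L, 30L, 35L), n_restarts = 10L, n_motifs = 6L,
            seed = seed)
}

repliconById <- function(replicons, id) {
  Filter(function(r) repliconId(r) == id, replicons)[[1]]
}

# IR sets with a planted motif instance in a subset of sequences.
plantedIrSet <- function(seed, consensus, n_ir = 20L, n_with = 16L,
                         rate = 0.05, len = 300L, reverse = FALSE) {
  set.seed(seed)
  w <- nchar(consensus)
  seqs <- character(n_ir)
  for (i in seq_len(n_ir)) {
    s <- randDna(len, 0.5)
    if (i <= n_with) {
      inst <- mutateSequence(consensus, rate)
      if (reverse) inst <- revcomp(inst)
      pos <- sample(1:(len - w + 1L), 1L)
      substr(s, pos, pos + w - 1L) <- inst
    }
    seqs[i] <- s
  }
  seqs
}

PLANTED30 <- "TGACCATGTCGAAGCTTACGGATCCAGTCA"
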