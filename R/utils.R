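#' @importFrom methods new validObject is slot
#' @importFrom stats runif setNames
#' @importFrom utils head read.delim write.table
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

# Coerce IUPAC ambiguity codes other than N to N; warn once per call.
normalizeDnaString <- function(x) {
  x <- toupper(x)
  bad <- gsub("[ACGTN]", "", x)
  if (nzchar(bad)) {
    warning("ambiguous residues other than N coerced to N: ",
            paste(unique(strsplit(bad, "")[[1]]), collapse = ","))
    x <- gsub("[^ACGTN]", "N", x)
  }
  x
}

revcompChr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Integer encoding A=1 C=2 G=3 T=4 N=5 (N scores as background everywhere)
encodeDna <- function(x) {
  m <- match(strsplit(x, "")[[1]], c(DNA_BASES4, "N"))
  m[is.na(m)] <- 5L
  m
}

decodeDna <- function(codes) {
  paste(c(DNA_BASES4, "N")[codes], collapse = "")
}

#' Derive a deterministic per-stage seed from a run seed
#'
#' Stages of the pipeline draw from independent deterministic streams so that
#' editing one stage never perturbs the randomness of another. The stage seed
#' is a 31-bit hash of the run seed and a fixed stage label.
#'
#' @param seed integer run seed.
#' @param label character stage label.
#' @return an integer seed below 2^31.
#' @export
stageSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 131) %% 2147483587)
}

withStageSeed <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stageSeed(seed, label))
  force(expr)
}

# Conventional half-up rounding (R's round() is banker's).
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

hammingDistance <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Best ungapped-offset similarity between two strings of possibly different
# width: slide one along the other (overlap at least half the shorter
# string), similarity = max matches / shorter length, so shifted copies of
# the same motif score high while a short accidental overlap cannot.
offsetSimilarity <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  w <- length(av)
  maxshift <- w - ceiling(w / 2)
  best <- 0L
  for (off in (-maxshift):(length(bv) - w + maxshift)) {
    ia <- seq_len(w)
    ib <- ia + off
    ok <- ib >= 1L & ib <= length(bv)
    if (!any(ok)) next
    best <- max(best, sum(av[ok] == bv[ib[ok]]))
  }
  best / w
}

emptyFeatureTable <- function() {
  data.frame(locus_tag = character(), kind = character(),
             start = integer(), end = integer(), strand = character(),
             product = character(), wraps_origin = logical(),
             stringsAsFactors = FALSE)
}

makeFeatureTable <- function(locus_tag, kind, start, end, strand,
                             product = "", wraps_origin = FALSE) {
  n <- length(locus_tag)
  data.frame(locus_tag = as.character(locus_tag),
             kind = rep_len(as.character(kind), n),
             start = as.integer(start), end = as.integer(end),
             strand = rep_len(as.character(strand), n),
             product = rep_len(as.character(product), n),
             wraps_origin = rep_len(as.logical(wraps_origin), n),
             stringsAsFactors = FALSE)
}
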