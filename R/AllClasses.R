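#' Replicon: one DNA molecule with its gene features
#'
#' A `Replicon` holds a single chromosome, minichromosome, megaplasmid or
#' plasmid: its sequence (a [Biostrings::DNAString] over A/C/G/T/N), its
#' topology, its replicon class and a gene-feature table. Coordinates are
#' 1-based closed throughout (the GenBank/Biostrings convention); a feature on
#' a circular replicon that crosses the coordinate origin is stored with
#' `end > length(sequence)` (virtual extension) and `wraps_origin = TRUE`.
#'
#' @slot id character replicon identifier (unique within a genome).
#' @slot sequence a [Biostrings::DNAString].
#' @slot topology `"circular"` or `"linear"`.
#' @slot repliconClass one of `"chromosome"`, `"minichromosome"`,
#'   `"megaplasmid"`, `"plasmid"`, `"unknown"`.
#' @slot features data.frame with columns `locus_tag`, `kind` (CDS/rRNA/
#'   tRNA/other), `start`, `end`, `strand` (+/-), `product`, `wraps_origin`.
#'
#' @export
setClass("Replicon",
  representation(id = "character", sequence = "ANY", topology = "character",
                 repliconClass = "character", features = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (length(object@id) != 1L || !nzchar(object@id))
      msg <- c(msg, "id must be a single non-empty string")
    if (!is(object@sequence, "DNAString"))
      msg <- c(msg, "sequence must be a DNAString")
    if (length(object@sequence) < 1L)
      msg <- c(msg, "sequence must be non-empty")
    freq <- Biostrings::alphabetFrequency(object@sequence)
    if (sum(freq[c("A", "C", "G", "T", "N")]) != length(object@sequence))
      msg <- c(msg, "sequence alphabet restricted to {A,C,G,T,N}")
    if (!object@topology %in% c("circular", "linear"))
      msg <- c(msg, "topology must be 'circular' or 'linear'")
    if (!object@repliconClass %in%
          c("chromosome", "minichromosome", "megaplasmid", "plasmid", "unknown"))
      msg <- c(msg, "invalid repliconClass")
    ft <- object@features
    need <- c("locus_tag", "kind", "start", "end", "strand", "product",
              "wraps_origin")
    if (!all(need %in% names(ft))) {
      msg <- c(msg, "features table missing required columns")
    } else if (nrow(ft) > 0) {
      L <- length(object@sequence)
      if (anyDuplicated(ft$locus_tag))
        msg <- c(msg, "locus_tag must be unique within a replicon")
      if (any(ft$start < 1L | ft$start > L))
        msg <- c(msg, "feature start outside replicon")
      if (any(ft$end < ft$start))
        msg <- c(msg, "feature end before start")
      if (any(!ft$wraps_origin & ft$end > L))
        msg <- c(msg, "non-wrapping feature extends past replicon end")
      if (any(ft$wraps_origin) && object@topology != "circular")
        msg <- c(msg, "wrapping feature on a linear replicon")
      if (!all(ft$strand %in% c("+", "-")))
        msg <- c(msg, "strand must be + or -")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a Replicon
#'
#' @param id replicon identifier.
#' @param sequence DNA sequence as a character string or
#'   [Biostrings::DNAString]; ambiguity codes other than N are coerced to N
#'   with a warning.
#' @param topology `"circular"` (default) or `"linear"`.
#' @param repliconClass replicon class label; default `"unknown"`.
#' @param features gene-feature data.frame (see [Replicon-class]); default
#'   empty.
#' @return a `Replicon` object.
#' @examples
#' r <- Replicon("r1", "ACGTACGT", topology = "linear")
#' repliconLength(r)
#' @export
Replicon <- function(id, sequence, topology = "circular",
                     repliconClass = "unknown", features = emptyFeatureTable()) {
  if (is.character(sequence)) {
    sequence <- Biostrings::DNAString(normalizeDnaString(sequence))
  }
  new("Replicon", id = id, sequence = sequence, topology = topology,
      repliconClass = repliconClass, features = features)
}

#' @describeIn Replicon replicon identifier.
#' @param x a `Replicon`.
#' @export
repliconId <- function(x) x@id

#' @describeIn Replicon sequence length in bp.
#' @export
repliconLength <- function(x) length(x@sequence)

#' @describeIn Replicon the sequence as a [Biostrings::DNAString].
#' @export
repliconSequence <- function(x) x@sequence

#' @describeIn Replicon the gene-feature table.
#' @export
features <- function(x) x@features

#' @describeIn Replicon the topology string.
#' @export
topology <- function(x) x@topology

#' @describeIn Replicon the replicon class label.
#' @export
repliconClass <- function(x) x@repliconClass

setMethod("show", "Replicon", function(object) {
  cat(sprintf("Replicon '%s': %d bp %s %s, %d features\n", object@id,
              length(object@sequence), object@topology, object@repliconClass,
              nrow(object@features)))
})

# Extract subsequence honoring circular wrap: 1-based closed; end may exceed
# the replicon length on circular replicons.
repliconSubseq <- function(replicon, start, end) {
  L <- repliconLength(replicon)
  stopifnot(start >= 1L, end >= start)
  if (end <= L) {
    return(as.character(Biostrings::subseq(replicon@sequence, start, end)))
  }
  if (replicon@topology != "circular")
    stop("interval extends past the end of linear replicon ", replicon@id)
  paste0(as.character(Biostrings::subseq(replicon@sequence, start, L)),
         as.character(Biostrings::subseq(replicon@sequence, 1L, end - L)))
}

#' ORB motif model (ZOOPS position frequency matrix)
#'
#' The probabilistic model of an ORB (origin recognition box) repeat fitted by
#' [discoverMotifs()]: a position frequency matrix over A/C/G/T, the
#' background composition it was fitted against, the log2-odds scoring matrix
#' used by [scanMotif()], the consensus string and the model's
#' likelihood-ratio support.
#'
#' @slot width motif width in bp (20-40).
#' @slot pfm 4 x width matrix, rows A,C,G,T; columns sum to 1.
#' @slot background length-4 background base frequencies.
#' @slot pseudoCount pseudo-count used in the M-step.
#' @slot logOdds 4 x width log2(pfm/background) matrix.
#' @slot consensus consensus DNA string.
#' @slot score likelihood-ratio support (log-likelihood gain over the
#'   background-only model).
#' @slot gamma fitted ZOOPS occurrence probability per sequence.
#' @export
setClass("MotifModel",
  representation(width = "integer", pfm = "matrix", background = "numeric",
                 pseudoCount = "numeric", logOdds = "matrix",
                 consensus = "character", score = "numeric",
                 gamma = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@width < 20L || object@width > 40L)
      msg <- c(msg, "width must lie in [20, 40]")
    if (!all(dim(object@pfm) == c(4L, object@width)))
      msg <- c(msg, "pfm must be 4 x width")
    if (any(abs(colSums(object@pfm) - 1) > 1e-9))
      msg <- c(msg, "pfm columns must sum to 1")
    if (length(object@background) != 4L ||
        abs(sum(object@background) - 1) > 1e-9)
      msg <- c(msg, "background must be 4 frequencies summing to 1")
    if (nchar(object@consensus) != object@width)
      msg <- c(msg, "consensus length must equal width")
    if (length(msg)) msg else TRUE
  })

#' @describeIn MotifModel consensus string of the model.
#' @param x a `MotifModel`.
#' @export
motifConsensus <- function(x) x@consensus

#' @describeIn MotifModel motif width in bp.
#' @export
motifWidth <- function(x) x@width

#' @describeIn MotifModel position frequency matrix (4 x width).
#' @export
motifPFM <- function(x) x@pfm

#' @describeIn MotifModel likelihood-ratio support of the model.
#' @export
motifScore <- function(x) x@score

setMethod("show", "MotifModel", function(object) {
  cat(sprintf("MotifModel: width %d, consensus %s, LLR %.2f, gamma %.2f\n",
              object@width, object@consensus, object@score, object@gamma))
})

#' Per-gene origin verdict
#'
#' The classification of the intergenic evidence flanking one orc/cdc6 gene:
#' `candidate` (at least two G-string-bearing ORBs forming an inverted pair or
#' occupying both flanking intergenic regions), `deficient` (qualifying ORBs
#' present but the candidate rule unmet, the oriC3-cdc6D*-like case), `dual`
#' (two independent candidate ORB sets from distinct motif families) or
#' `none`.
#'
#' @slot geneRef locus_tag of the orc/cdc6 gene.
#' @slot repliconId replicon the gene lives on.
#' @slot status one of `"candidate"`, `"deficient"`, `"dual"`, `"none"`.
#' @slot orbs data.frame of qualifying ORB elements (replicon coordinates).
#' @slot atRich data.frame (0 or 1 row) describing the AT-rich segment.
#' @slot layout `"upstream"`, `"downstream"`, `"both"` or `NA` for status
#'   `none`.
#' @slot originStart,originEnd minimal replicon interval covering the
#'   qualifying ORBs and AT-rich segment (NA for status `none`).
#' @slot notes free-text notes.
#' @export
setClass("OriginCall",
  representation(geneRef = "character", repliconId = "character",
                 status = "character", orbs = "data.frame",
                 atRich = "data.frame", layout = "character",
                 originStart = "integer", originEnd = "integer",
                 notes = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@status %in% c("candidate", "deficient", "dual", "none"))
      msg <- c(msg, "invalid status")
    if (!object@layout %in% c("upstream", "downstream", "both", NA_character_))
      msg <- c(msg, "invalid layout")
    if (object@status == "none" && nrow(object@orbs) > 0)
      msg <- c(msg, "status 'none' requires zero qualifying ORBs")
    if (length(msg)) msg else TRUE
  })

#' @describeIn OriginCall the call status string.
#' @param x an `OriginCall`.
#' @export
callStatus <- function(x) x@status

#' @describeIn OriginCall locus_tag of the associated orc/cdc6 gene.
#' @export
callGene <- function(x) x@geneRef

#' @describeIn OriginCall qualifying ORB table.
#' @export
callOrbs <- function(x) x@orbs

#' @describeIn OriginCall layout relative to the gene's coding orientation.
#' @export
callLayout <- function(x) x@layout

#' @describeIn OriginCall origin interval as c(start, end), NA for none.
#' @export
callInterval <- function(x) c(x@originStart, x@originEnd)

setMethod("show", "OriginCall", function(object) {
  cat(sprintf("OriginCall %s [%s]: %s, %d ORB(s), layout %s\n",
              object@geneRef, object@repliconId, object@status,
              nrow(object@orbs), object@layout))
})

#' Origin family: origins linked by initiator identity
#'
#' A cluster of origin-associated Orc/Cdc6 initiators (single-linkage
#' components at >= 80 percent pairwise identity) together with the ORB
#' consensus shared by its member origins. Families are named `oriC1` (the
#' family present in every input genome), `oriCa`/`oriCb` (the two largest
#' remaining families) and `F3`, `F4`, ... for the rest.
#'
#' @slot name family name.
#' @slot members data.frame with columns `genome_id`, `locus_tag`,
#'   `replicon_id`, `status`.
#' @slot orbConsensus consensus DNA string of member ORBs ("" if unknown).
#' @slot genomeCoverage fraction of input genomes represented.
#' @export
setClass("OriginFamily",
  representation(name = "character", members = "data.frame",
                 orbConsensus = "character", genomeCoverage = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@genomeCoverage < 0 || object@genomeCoverage > 1)
      msg <- c(msg, "genomeCoverage must lie in [0,1]")
    if (!all(c("genome_id", "locus_tag") %in% names(object@members)))
      msg <- c(msg, "members must have genome_id and locus_tag columns")
    if (length(msg)) msg else TRUE
  })

#' @describeIn OriginFamily family name.
#' @param x an `OriginFamily`.
#' @export
familyName <- function(x) x@name

#' @describeIn OriginFamily member table.
#' @export
familyMembers <- function(x) x@members

#' @describeIn OriginFamily fraction of input genomes with a member.
#' @export
familyCoverage <- function(x) x@genomeCoverage

setMethod("show", "OriginFamily", function(object) {
  cat(sprintf("OriginFamily %s: %d member(s), coverage %.2f\n",
              object@name, nrow(object@members), object@genomeCoverage))
})
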