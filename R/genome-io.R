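#' Read replicons from FASTA or GenBank
#'
#' One [Replicon-class] per record. GenBank features (CDS/rRNA/tRNA) are
#' captured with `/locus_tag` and `/product`; topology is taken from the
#' LOCUS line when present, else linear (FASTA records are always linear
#' unless retopologized by the caller). Residues other than A/C/G/T/N are
#' coerced to N with a warning.
#'
#' @param path input file path.
#' @param format `"fasta"` or `"genbank"`.
#' @return list of [Replicon-class] objects.
#' @export
readReplicons <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    lapply(seq_along(ss), function(i) {
      Replicon(id = sub("\\s.*$", "", names(ss)[i]),
               sequence = as.character(ss[[i]]), topology = "linear")
    })
  } else {
    readGenBank(path)
  }
}

#' Read gene annotations from GFF3
#'
#' Parses a GFF3 file (via rtracklayer) and returns feature tables grouped by
#' replicon id. Coordinates stay 1-based closed. A feature whose end exceeds
#' the length of a circular replicon is stored virtually extended with
#' `wraps_origin = TRUE`.
#'
#' @param path GFF3 file path.
#' @param replicons list of [Replicon-class] the seqids must match.
#' @return named list (by replicon id) of feature data.frames.
#' @export
readAnnotations <- function(path, replicons) {
  gr <- rtracklayer::import.gff3(path)
  ids <- vapply(replicons, repliconId, "")
  seqids <- as.character(GenomicRanges::seqnames(gr))
  unmatched <- setdiff(unique(seqids), ids)
  if (length(unmatched))
    stop("GFF3 seqids match no loaded replicon: ",
         paste(unmatched, collapse = ", "))
  lens <- setNames(vapply(replicons, repliconLength, 1L), ids)
  topo <- setNames(vapply(replicons, topology, ""), ids)
  if (!length(gr)) {
    empty <- emptyFeatureTable()
    return(setNames(rep(list(empty), length(ids)), ids))
  }
  md <- S4Vectors::mcols(gr)
  getcol <- function(name, default = "") {
    if (name %in% names(md)) {
      v <- as.character(md[[name]])
      v[is.na(v)] <- default
      v
    } else rep(default, length(gr))
  }
  type <- getcol("type", "other")
  kind <- ifelse(type %in% c("CDS", "rRNA", "tRNA"), type, "other")
  lt <- getcol("locus_tag")
  idc <- getcol("ID")
  lt <- ifelse(nzchar(lt), lt, idc)
  lt[!nzchar(lt)] <- paste0("feat", seq_len(length(gr)))[!nzchar(lt)]
  ft <- makeFeatureTable(
    locus_tag = lt, kind = kind,
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    product = getcol("product"),
    wraps_origin = FALSE)
  over <- ft$end > lens[seqids]
  if (any(over)) {
    if (any(over & topo[seqids] != "circular"))
      stop("feature extends past the end of a linear replicon")
    ft$wraps_origin[over] <- TRUE
  }
  split(ft, factor(seqids, levels = ids))
}

#' Translate a CDS feature with the bacterial/archaeal genetic code
#'
#' Extracts the feature's nucleotide span (wrap-aware on circular replicons),
#' reverse-complements minus-strand features, and translates with genetic
#' code table 11. The terminal stop is removed. A CDS containing an internal
#' stop codon is flagged as a pseudogene: a warning is raised and `NULL`
#' returned so screening skips it.
#'
#' @param replicon a [Replicon-class].
#' @param feature one row of the replicon's feature table (`kind == "CDS"`).
#' @return list with `id`, `aa_sequence`, `length_aa`, or `NULL` for a
#'   pseudogene.
#' @export
translateCds <- function(replicon, feature) {
  stopifnot(feature$kind == "CDS")
  nt <- repliconSubseq(replicon, feature$start, feature$end)
  if (feature$strand == "-") nt <- revcompChr(nt)
  if (nchar(nt) %% 3 != 0)
    stop("CDS length not divisible by 3 for ", feature$locus_tag)
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X")))
  if (endsWith(aa, "*")) aa <- substr(aa, 1, nchar(aa) - 1L)
  if (grepl("\\*", aa)) {
    warning("internal stop codon in ", feature$locus_tag,
            "; flagged pseudogene and excluded")
    return(NULL)
  }
  list(id = feature$locus_tag, aa_sequence = aa, length_aa = nchar(aa))
}

#' Sliding-window GC profile of a replicon
#'
#' GC fraction in windows of `window` bp every `step` bp (the conventional
#' whole-genome GC plot; defaults 50 kb / 1 kb). N bases are excluded from
#' both numerator and denominator. On circular replicons windows wrap across
#' the coordinate origin so every start position gets a full window; on
#' linear replicons only complete windows are reported and
#' `window > length` is an error.
#'
#' @param replicon a [Replicon-class].
#' @param window window size in bp.
#' @param step step size in bp.
#' @return data.frame with columns `midpoint` and `gc`.
#' @export
gcProfile <- function(replicon, window = 50000L, step = 1000L) {
  L <- repliconLength(replicon)
  circular <- topology(replicon) == "circular"
  if (window > L) {
    if (!circular) stop("window exceeds length of linear replicon")
    window <- L
  }
  codes <- encodeDna(as.character(repliconSequence(replicon)))
  if (circular) codes <- c(codes, codes[seq_len(window - 1L)])
  isGC <- cumsum(c(0L, codes %in% c(2L, 3L)))
  isN <- cumsum(c(0L, codes == 5L))
  starts <- if (circular) seq(1L, L, by = step)
            else seq(1L, L - window + 1L, by = step)
  gc <- isGC[starts + window] - isGC[starts]
  nn <- isN[starts + window] - isN[starts]
  denom <- window - nn
  data.frame(midpoint = ((starts + (window - 1) / 2 - 1) %% L) + 1,
             gc = ifelse(denom > 0, gc / denom, NA_real_))
}

#' Write origin prediction reports
#'
#' Writes (a) `origins.bed`: BED6 of predicted origin intervals (0-based
#' half-open, converted at this boundary), (b) `origins.gff3`: origin
#' features with their ORB elements as child features, (c)
#' `replicon_summary.tsv`: per-replicon `n_cdc6`, `n_ori_associated` (status
#' candidate or dual) and rounded percentage, (d) `genome_summary.tsv`:
#' per-genome predicted-origin and later-acquired counts, and (e)
#' `families.tsv`.
#'
#' @param calls list of [OriginCall-class] objects.
#' @param families list of [OriginFamily-class] objects (may be empty).
#' @param dir output directory (created if needed).
#' @param mobility optional data.frame from [annotateMobility()] rows with
#'   columns `gene_ref` and `later_acquired`.
#' @param genomeOf optional named character vector mapping replicon id to
#'   genome id (defaults to one genome, "genome1").
#' @return named character vector of the written file paths, invisibly.
#' @export
writeOriginReport <- function(calls, families, dir, mobility = NULL,
                              genomeOf = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(bed = file.path(dir, "origins.bed"),
             gff = file.path(dir, "origins.gff3"),
             replicon = file.path(dir, "replicon_summary.tsv"),
             genome = file.path(dir, "genome_summary.tsv"),
             families = file.path(dir, "families.tsv"))

  pred <- Filter(function(cl) callStatus(cl) %in% c("candidate", "dual"), calls)
  bed <- character()
  gff <- c("##gff-version 3")
  for (cl in pred) {
    iv <- callInterval(cl)
    name <- paste0("origin_", callGene(cl))
    bed <- c(bed, sprintf("%s\t%d\t%d\t%s\t%d\t.", cl@repliconId,
                          iv[1] - 1L, iv[2], name, 0L))
    gff <- c(gff, sprintf(
      "%s\treplicon_origin\torigin_of_replication\t%d\t%d\t.\t.\t.\tID=%s;status=%s",
      cl@repliconId, iv[1], iv[2], name, callStatus(cl)))
    orbs <- callOrbs(cl)
    if (nrow(orbs)) {
      for (i in seq_len(nrow(orbs))) {
        gff <- c(gff, sprintf(
          "%s\treplicon_origin\tsequence_motif\t%d\t%d\t%.2f\t%s\t.\tID=%s_orb%d;Parent=%s;Name=ORB",
          cl@repliconId, orbs$start[i], orbs$end[i], orbs$score[i],
          ifelse(orbs$orientation[i] == "reverse", "-", "+"), name, i, name))
      }
    }
  }
  writeLines(bed, paths[["bed"]])
  writeLines(gff, paths[["gff"]])

  repl <- vapply(calls, function(cl) cl@repliconId, "")
  stat <- vapply(calls, callStatus, "")
  reps <- unique(repl)
  rsum <- do.call(rbind, lapply(reps, function(r) {
    s <- summarizeReplicon(calls[repl == r])
    data.frame(replicon = r, n_cdc6 = s$n_cdc6,
               n_ori_associated = s$n_ori_associated,
               percentage = ifelse(is.na(s$percentage), "",
                                   paste0(s$percentage, "%")),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rsum)) rsum <- data.frame(replicon = character(),
                                        n_cdc6 = integer(),
                                        n_ori_associated = integer(),
                                        percentage = character())
  write.table(rsum, paths[["replicon"]], sep = "\t", quote = FALSE,
              row.names = FALSE)

  if (is.null(genomeOf)) genomeOf <- setNames(rep("genome1", length(reps)), reps)
  la <- setNames(rep(FALSE, length(calls)), vapply(calls, callGene, ""))
  if (!is.null(mobility) && nrow(mobility))
    la[mobility$gene_ref] <- mobility$later_acquired
  gid <- genomeOf[repl]
  gsum <- do.call(rbind, lapply(unique(gid), function(g) {
    sel <- gid == g & stat %in% c("candidate", "dual")
    data.frame(genome = g, n_predicted = sum(sel),
               n_later_acquired = sum(la[vapply(calls, callGene, "")[sel]]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(gsum)) gsum <- data.frame(genome = character(),
                                        n_predicted = integer(),
                                        n_later_acquired = integer())
  write.table(gsum, paths[["genome"]], sep = "\t", quote = FALSE,
              row.names = FALSE)

  fam <- do.call(rbind, lapply(families, function(f) {
    m <- familyMembers(f)
    if (!nrow(m)) return(NULL)
    data.frame(family = familyName(f), genome = m$genome_id,
               locus_tag = m$locus_tag,
               consensus = f@orbConsensus, coverage = familyCoverage(f),
               stringsAsFactors = FALSE)
  }))
  if (is.null(fam)) fam <- data.frame(family = character(), genome = character(),
                                      locus_tag = character(),
                                      consensus = character(),
                                      coverage = numeric())
  write.table(fam, paths[["families"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
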