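# Minimal GenBank flat-file reader/writer for the LOCUS/FEATURES/ORIGIN
# subset this pipeline produces and consumes. Locations supported: n..m,
# complement(n..m) and the circular-wrap form join(n..L,1..m) (and its
# complement). Qualifiers captured: /locus_tag, /product.

gbKinds <- c(CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA")

parseGbLocation <- function(loc) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  wraps <- FALSE
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1]]
    if (length(parts) != 2L)
      stop("unsupported join() location: ", loc)
    a <- as.integer(strsplit(parts[1], "\\.\\.")[[1]])
    b <- as.integer(strsplit(parts[2], "\\.\\.")[[1]])
    # wrap: a = start..L, b = 1..end ; stored with virtual extension
    return(list(start = a[1], end = a[2] + b[2], strand = strand,
                wraps = TRUE, span_a = a, span_b = b))
  }
  se <- as.integer(strsplit(loc, "\\.\\.")[[1]])
  if (length(se) == 1L) se <- c(se, se)
  list(start = se[1], end = se[2], strand = strand, wraps = wraps)
}

parseGenBankRecord <- function(lines) {
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) != 1L) stop("malformed GenBank record: missing LOCUS line")
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  id <- toks[2]
  topo <- if (any(tolower(toks) == "circular")) "circular" else "linear"
  rclass <- "unknown"
  defn <- grep("^DEFINITION", lines, value = TRUE)
  if (length(defn)) {
    d <- tolower(defn[1])
    rclass <- if (grepl("minichromosome", d)) "minichromosome"
      else if (grepl("megaplasmid", d)) "megaplasmid"
      else if (grepl("chromosome", d)) "chromosome"
      else if (grepl("plasmid", d)) "plasmid"
      else "unknown"
  }

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) != 1L)
    stop("malformed GenBank record '", id, "': missing ORIGIN")
  seqlines <- lines[(ostart + 1):length(lines)]
  seqlines <- seqlines[!grepl("^//", seqlines)]
  seqchr <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))

  feats <- emptyFeatureTable()
  if (length(fstart) == 1L && ostart > fstart + 1L) {
    flines <- lines[(fstart + 1):(ostart - 1)]
    # a new feature starts at column 6 with a key; qualifiers start with /
    keyline <- grepl("^\\s{5}\\S", flines)
    idx <- cumsum(keyline)
    recs <- split(flines, idx)
    rows <- list()
    for (rec in recs) {
      if (!length(rec) || !grepl("^\\s{5}\\S", rec[1])) next
      toks <- strsplit(trimws(rec[1]), "\\s+")[[1]]
      key <- toks[1]
      if (!key %in% names(gbKinds)) next
      loc <- parseGbLocation(paste(toks[-1], collapse = ""))
      quals <- trimws(rec[-1])
      getq <- function(name) {
        hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
        if (!length(hit)) return("")
        gsub("^\"|\"$", "", sub(paste0("^/", name, "="), "", hit[1]))
      }
      rows[[length(rows) + 1L]] <- makeFeatureTable(
        locus_tag = getq("locus_tag"), kind = gbKinds[[key]],
        start = loc$start, end = loc$end, strand = loc$strand,
        product = getq("product"), wraps_origin = loc$wraps)
    }
    if (length(rows)) feats <- do.call(rbind, rows)
  }
  if (any(!nzchar(feats$locus_tag)))
    feats$locus_tag[!nzchar(feats$locus_tag)] <-
      paste0(id, "_f", which(!nzchar(feats$locus_tag)))
  Replicon(id, seqchr, topology = topo, repliconClass = rclass,
           features = feats)
}

readGenBank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recend <- grep("^//", lines)
  if (!length(recend)) stop("malformed GenBank file: no record terminator")
  starts <- c(1L, head(recend, -1) + 1L)
  lapply(seq_along(recend), function(i) {
    chunk <- lines[starts[i]:recend[i]]
    chunk <- chunk[nzchar(trimws(chunk)) | grepl("^//", chunk)]
    parseGenBankRecord(chunk)
  })
}

formatGbLocation <- function(start, end, strand, wraps, L) {
  loc <- if (wraps) sprintf("join(%d..%d,1..%d)", start, L, end - L)
         else sprintf("%d..%d", start, end)
  if (strand == "-") loc <- sprintf("complement(%s)", loc)
  loc
}

#' Write replicons as a GenBank flat file
#'
#' Emits one record per replicon with LOCUS topology, a DEFINITION carrying
#' the replicon class, CDS/rRNA/tRNA features with `/locus_tag` and
#' `/product` qualifiers, and the full ORIGIN sequence. The subset emitted is
#' exactly what [readReplicons()] parses back, so write-then-read round-trips.
#'
#' @param replicons list of [Replicon-class] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenBank <- function(replicons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in replicons) {
    L <- repliconLength(r)
    cat(sprintf("LOCUS       %s %d bp    DNA     %s ARC 01-JAN-2000\n",
                repliconId(r), L, topology(r)), file = con)
    cat(sprintf("DEFINITION  synthetic %s %s.\n", repliconClass(r),
                repliconId(r)), file = con)
    cat("FEATURES             Location/Qualifiers\n", file = con)
    cat(sprintf("     source          1..%d\n", L), file = con)
    ft <- features(r)
    if (nrow(ft)) {
      for (i in seq_len(nrow(ft))) {
        key <- if (ft$kind[i] %in% names(gbKinds)) ft$kind[i] else "misc_feature"
        loc <- formatGbLocation(ft$start[i], ft$end[i], ft$strand[i],
                                ft$wraps_origin[i], L)
        cat(sprintf("     %-15s %s\n", key, loc), file = con)
        cat(sprintf("                     /locus_tag=\"%s\"\n",
                    ft$locus_tag[i]), file = con)
        if (nzchar(ft$product[i]))
          cat(sprintf("                     /product=\"%s\"\n",
                      ft$product[i]), file = con)
      }
    }
    cat("ORIGIN\n", file = con)
    s <- tolower(as.character(repliconSequence(r)))
    pos <- seq(1, nchar(s), by = 60)
    for (p in pos) {
      chunk <- substr(s, p, min(p + 59, nchar(s)))
      blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      cat(sprintf("%9d %s\n", p, paste(blocks, collapse = " ")), file = con)
    }
    cat("//\n", file = con)
  }
  invisible(path)
}
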