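#' Load a panel of Orc/Cdc6 seed proteins
#'
#' Reads a protein FASTA seed panel. With no `path`, the packaged synthetic
#' panel (`inst/extdata/synthetic_orc_cdc6_seeds.faa`) is used: eight
#' synthetic Orc/Cdc6-like proteins (>300 aa, N-terminal Walker-A motif)
#' constructed from a fixed seed; they are a stand-in for a curated panel of
#' real origin-associated initiators and are labelled synthetic throughout.
#'
#' @param path optional FASTA path.
#' @return named character vector of amino-acid sequences.
#' @export
readSeedPanel <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "synthetic_orc_cdc6_seeds.faa",
                        package = "haloriscan", mustWork = TRUE)
  ss <- Biostrings::readAAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Detect a Walker-A (P-loop) motif in the N-terminal region
#'
#' The AAA+ module of origin-associated Orc/Cdc6 initiators is operationalized
#' as the Walker-A pattern `[AG]-x(4)-G-K-[ST]` occurring entirely within the
#' N-terminal fraction of the protein (default 60 percent).
#'
#' @param protein character amino-acid string, or a list with `aa_sequence`.
#' @param n_terminal_frac fraction of the sequence searched from the N
#'   terminus.
#' @return list with `found` (logical) and `offset` (1-based start of the
#'   first match, NA if absent).
#' @export
detectAAAWalker <- function(protein, n_terminal_frac = 0.6) {
  aa <- if (is.list(protein)) protein$aa_sequence else protein
  n <- nchar(aa)
  if (n < 8L) return(list(found = FALSE, offset = NA_integer_))
  lim <- ceiling(n * n_terminal_frac)
  m <- regexpr("[AG].{4}GK[ST]", aa, perl = TRUE)
  if (m[1] > 0 && (m[1] + attr(m, "match.length") - 1L) <= lim) {
    list(found = TRUE, offset = as.integer(m[1]))
  } else {
    list(found = FALSE, offset = NA_integer_)
  }
}

# Soft winged-helix evidence for the C-terminal domain: helix-former
# enrichment in the C-terminal 100 residues mapped through a logistic. The
# score is reported but never gates a hit (the domain call in the underlying
# screen rests on homology, not an explicit structural test).
whScore <- function(protein) {
  aa <- if (is.list(protein)) protein$aa_sequence else protein
  n <- nchar(aa)
  tail <- substr(aa, max(1L, n - 99L), n)
  v <- strsplit(tail, "")[[1]]
  helix <- mean(v %in% c("A", "E", "L", "M", "Q", "K", "R", "H"))
  1 / (1 + exp(-12 * (helix - 0.40)))
}

#' Screen a genome's proteome for origin-associated Orc/Cdc6 homologs
#'
#' Translates every CDS and keeps proteins that (a) exceed the length
#' criterion, (b) align to at least one seed at or above the identity
#' threshold over a minimum aligned span (a deterministic stand-in for a
#' database-dependent e-value cutoff), and (c) carry an N-terminal Walker-A
#' motif. A soft winged-helix score is reported but not gating.
#'
#' @param replicons list of [Replicon-class] objects (one genome).
#' @param seeds named character vector of seed proteins (see
#'   [readSeedPanel()]).
#' @param min_len minimum protein length in aa (default 300).
#' @param min_identity_pct minimum percent identity to the best seed.
#' @param min_aligned minimum aligned residues to the best seed.
#' @return data.frame of per-CDS hits sorted by replicon then coordinate,
#'   with columns `locus_tag`, `replicon_id`, `start`, `end`, `strand`,
#'   `length_aa`, `best_seed_identity_pct`, `best_seed_id`,
#'   `best_aligned_length`, `aaa_motif_found`, `aaa_offset`, `wh_score`,
#'   `passes`, `aa_sequence`.
#' @export
screenProteome <- function(replicons, seeds, min_len = 300L,
                           min_identity_pct = 30, min_aligned = 150L) {
  if (length(seeds) == 0L) stop("empty seed panel")
  rows <- list()
  for (r in replicons) {
    ft <- features(r)
    cds <- ft[ft$kind == "CDS", , drop = FALSE]
    if (!nrow(cds)) next
    for (i in seq_len(nrow(cds))) {
      pr <- withCallingHandlers(
        translateCds(r, cds[i, ]),
        warning = function(w) invokeRestart("muffleWarning"))
      if (is.null(pr)) next
      rows[[length(rows) + 1L]] <- data.frame(
        locus_tag = pr$id, replicon_id = repliconId(r),
        start = cds$start[i], end = cds$end[i], strand = cds$strand[i],
        length_aa = pr$length_aa, aa_sequence = pr$aa_sequence,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(locus_tag = character(), replicon_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      length_aa = integer(),
                      best_seed_identity_pct = numeric(),
                      best_seed_id = character(),
                      best_aligned_length = integer(),
                      aaa_motif_found = logical(), aaa_offset = integer(),
                      wh_score = numeric(), passes = logical(),
                      aa_sequence = character(), stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, rows)

  best_pct <- rep(0, nrow(hits))
  best_len <- rep(0L, nrow(hits))
  best_id <- rep(NA_character_, nrow(hits))
  best_score <- rep(-Inf, nrow(hits))
  # proteins below the length criterion can never pass: skip their alignments
  idx <- which(hits$length_aa >= min_len)
  if (length(idx)) {
    for (s in names(seeds)) {
      al <- localAlignMany(hits$aa_sequence[idx], seeds[[s]])
      better <- al$score > best_score[idx]
      ib <- idx[better]
      best_score[ib] <- al$score[better]
      best_pct[ib] <- al$identity_pct[better]
      best_len[ib] <- al$aligned_length[better]
      best_id[ib] <- s
    }
  }
  hits$best_seed_identity_pct <- best_pct
  hits$best_seed_id <- best_id
  hits$best_aligned_length <- best_len

  walker <- lapply(hits$aa_sequence, detectAAAWalker)
  hits$aaa_motif_found <- vapply(walker, `[[`, TRUE, "found")
  hits$aaa_offset <- vapply(walker, `[[`, 1L, "offset")
  hits$wh_score <- vapply(hits$aa_sequence, whScore, 1)
  hits$passes <- hits$length_aa >= min_len &
    hits$best_seed_identity_pct >= min_identity_pct &
    hits$best_aligned_length >= min_aligned &
    hits$aaa_motif_found
  hits <- hits[order(hits$replicon_id, hits$start), ]
  rownames(hits) <- NULL
  hits[, c("locus_tag", "replicon_id", "start", "end", "strand", "length_aa",
           "best_seed_identity_pct", "best_seed_id", "best_aligned_length",
           "aaa_motif_found", "aaa_offset", "wh_score", "passes",
           "aa_sequence")]
}

# Position-specific profile over the anchor seed's coordinates, built from
# the global alignments of passing hits to that seed.
buildProfile <- function(passing_seqs, anchor, pseudo = 1) {
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  L <- nchar(anchor)
  counts <- matrix(0, nrow = 20L, ncol = L, dimnames = list(aa20, NULL))
  for (s in passing_seqs) {
    al <- globalAlign(s, anchor)
    sa <- strsplit(al$aligned_a, "")[[1]]
    sb <- strsplit(al$aligned_b, "")[[1]]
    pos <- cumsum(sb != "-")
    keep <- sb != "-" & sa %in% aa20
    idx <- cbind(match(sa[keep], aa20), pos[keep])
    counts[idx] <- counts[idx] + 1
  }
  bg <- rep(1 / 20, 20)
  freqs <- sweep(counts + pseudo * bg, 2, colSums(counts) + pseudo, "/")
  log2(sweep(freqs, 1, bg, "/"))
}

scoreAgainstProfile <- function(candidate, anchor, profile) {
  al <- globalAlign(candidate, anchor)
  sa <- strsplit(al$aligned_a, "")[[1]]
  sb <- strsplit(al$aligned_b, "")[[1]]
  pos <- cumsum(sb != "-")
  keep <- sb != "-" & sa %in% rownames(profile)
  if (!any(keep)) return(c(score = -Inf, columns = 0))
  sc <- profile[cbind(match(sa[keep], rownames(profile)), pos[keep])]
  c(score = mean(sc), columns = sum(keep))
}

#' Profile-based rescreen of borderline Orc/Cdc6 homologs
#'
#' Builds a position-specific frequency profile from the passing hits (each
#' globally aligned to the anchor seed, the seed most often chosen as best
#' hit), rescans every non-passing CDS against the profile log-odds, and
#' admits members whose mean per-column profile score and aligned coverage
#' exceed the thresholds. Divergent family members below the pairwise
#' identity cutoff but matching the family profile are thereby recovered.
#' The procedure is iterated until a fixed point or `iterations` rounds.
#'
#' Admitted members still satisfy the length and Walker-A criteria; `passes`
#' is updated and `profile_pass`/`profile_score` record the evidence.
#'
#' @param hits data.frame from [screenProteome()] (all CDS rows).
#' @param seeds the seed panel used for screening.
#' @param iterations maximum profile rounds (default 2).
#' @param min_profile_score minimum mean log2-odds per aligned profile
#'   column (default 1).
#' @param min_columns minimum aligned profile columns (default 150).
#' @param min_len length criterion retained from the screen.
#' @return the hit table with `profile_score`, `profile_pass` and updated
#'   `passes` columns.
#' @export
profileRescreen <- function(hits, seeds, iterations = 2L,
                            min_profile_score = 1.0, min_columns = 150L,
                            min_len = 300L) {
  if (!any(hits$passes)) stop("profile rescreen needs at least one passing hit")
  hits$profile_score <- NA_real_
  hits$profile_pass <- FALSE
  for (it in seq_len(iterations)) {
    pass <- hits$passes | hits$profile_pass
    anchor_id <- names(sort(table(hits$best_seed_id[pass]), decreasing = TRUE))[1]
    anchor <- seeds[[anchor_id]]
    prof <- buildProfile(hits$aa_sequence[pass], anchor)
    cand <- which(!pass & hits$length_aa >= min_len & hits$aaa_motif_found)
    added <- FALSE
    for (i in cand) {
      sc <- scoreAgainstProfile(hits$aa_sequence[i], anchor, prof)
      hits$profile_score[i] <- sc[["score"]]
      if (sc[["score"]] >= min_profile_score && sc[["columns"]] >= min_columns) {
        hits$profile_pass[i] <- TRUE
        added <- TRUE
      }
    }
    if (!added) break
  }
  hits$passes <- hits$passes | hits$profile_pass
  hits
}
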