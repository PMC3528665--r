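#' Pairwise identity matrix of initiator proteins
#'
#' Percent identity over the locally aligned span ([localAlign()]) for every
#' pair; diagonal 100, symmetric. Pairs whose local alignment covers fewer
#' than `min_aligned` residues score 0: a short perfectly matching block
#' (a shared catalytic motif, say) is not homology-wide identity and must
#' not link two initiators into one family.
#'
#' @param proteins named character vector of amino-acid sequences (>= 2).
#' @param min_aligned minimum aligned residues for an identity to count
#'   (default 100).
#' @return numeric matrix of identity percentages with dimnames.
#' @export
identityMatrix <- function(proteins, min_aligned = 100L) {
  n <- length(proteins)
  if (n < 2L) stop("identityMatrix needs at least 2 proteins")
  ids <- names(proteins)
  if (is.null(ids)) ids <- paste0("p", seq_len(n))
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (j in 2:n) {
    al <- localAlignMany(proteins[seq_len(j - 1L)], proteins[[j]])
    idpct <- ifelse(al$aligned_length >= min_aligned, al$identity_pct, 0)
    m[seq_len(j - 1L), j] <- idpct
    m[j, seq_len(j - 1L)] <- idpct
  }
  m
}

#' Cluster initiators into families by single linkage
#'
#' Connected components of the graph whose edges join proteins with
#' pairwise identity at or above `threshold_pct` (default 80, the family
#' rule). Member ordering within a family and family ordering are
#' deterministic (lexicographic by first member).
#'
#' @param matrix identity matrix from [identityMatrix()].
#' @param threshold_pct identity threshold in percent.
#' @return list of character vectors of member ids.
#' @export
clusterFamilies <- function(matrix, threshold_pct = 80) {
  adj <- matrix >= threshold_pct
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  fams <- unname(split(names(memb), memb))
  fams <- lapply(fams, sort)
  fams[order(vapply(fams, `[`, "", 1L))]
}

#' Name origin families oriC1 / oriCa / oriCb / F<k>
#'
#' The family present in every input genome is `oriC1` (largest such family
#' if several); among the rest the two largest by member count are `oriCa`
#' and `oriCb` (ties broken by lexicographically smallest member id); the
#' remainder are `F3`, `F4`, ... in decreasing size. With no
#' genome-universal family, no `oriC1` is assigned and a warning is raised.
#'
#' @param families list of member-id vectors from [clusterFamilies()].
#' @param genome_of named character vector mapping member id to genome id.
#' @param calls optional named list of [OriginCall-class] by locus_tag used
#'   to annotate member status.
#' @param orb_consensus optional named character vector of per-family ORB
#'   consensi (names matching family index).
#' @return list of [OriginFamily-class] objects.
#' @export
nameFamilies <- function(families, genome_of, calls = NULL,
                         orb_consensus = NULL) {
  n_genomes <- length(unique(genome_of))
  cov <- vapply(families, function(m)
    length(unique(genome_of[m])) / n_genomes, 1)
  size <- vapply(families, length, 1L)
  firstMember <- vapply(families, function(m) sort(m)[1], "")

  names_out <- rep(NA_character_, length(families))
  universal <- which(cov == 1)
  if (length(universal)) {
    u <- universal[order(-size[universal], firstMember[universal])][1]
    names_out[u] <- "oriC1"
    if (n_genomes == 1L)
      warning("single-genome input: any family trivially covers all genomes;",
              " oriC1 assignment is degenerate")
  } else {
    warning("no family covers all input genomes; no oriC1 assigned")
  }
  rest <- which(is.na(names_out))
  rest <- rest[order(-size[rest], firstMember[rest])]
  lab <- c("oriCa", "oriCb", paste0("F", seq_len(max(0L, length(rest) - 2L)) + 2L))
  names_out[rest] <- lab[seq_along(rest)]

  out <- vector("list", length(families))
  for (k in seq_along(families)) {
    mem <- families[[k]]
    status <- if (!is.null(calls)) {
      vapply(mem, function(m)
        if (m %in% names(calls)) callStatus(calls[[m]]) else NA_character_, "")
    } else rep(NA_character_, length(mem))
    out[[k]] <- new("OriginFamily", name = names_out[k],
                    members = data.frame(genome_id = unname(genome_of[mem]),
                                         locus_tag = mem,
                                         replicon_id = NA_character_,
                                         status = status,
                                         stringsAsFactors = FALSE),
                    orbConsensus = if (!is.null(orb_consensus) &&
                                       as.character(k) %in% names(orb_consensus))
                      orb_consensus[[as.character(k)]] else "",
                    genomeCoverage = cov[k])
  }
  out[order(match(names_out, c("oriC1", "oriCa", "oriCb",
                               sort(setdiff(names_out,
                                            c("oriC1", "oriCa", "oriCb"))))))]
}

#' ORB-initiator linkage consistency of a family
#'
#' Mean pairwise similarity of the member origins' ORB consensus sequences:
#' for equal widths 1 minus the normalized Hamming distance, otherwise the
#' best ungapped-offset similarity. Members lacking an ORB consensus are
#' skipped with a note.
#'
#' @param consensi character vector of member ORB consensi (length >= 2
#'   after dropping empties).
#' @return list with `score` (mean similarity in `[0,1]`) and `detail`
#'   (data.frame of per-pair similarities).
#' @export
orbLinkageCheck <- function(consensi) {
  keep <- nzchar(consensi) & !is.na(consensi)
  if (sum(!keep))
    message(sum(!keep), " member(s) lacking ORBs skipped")
  consensi <- consensi[keep]
  if (length(consensi) < 2L)
    stop("linkage check needs at least 2 members with ORBs")
  pairs <- utils::combn(length(consensi), 2)
  det <- data.frame(a = pairs[1, ], b = pairs[2, ], similarity = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    a <- consensi[pairs[1, k]]; b <- consensi[pairs[2, k]]
    det$similarity[k] <- if (nchar(a) == nchar(b))
      1 - hammingDistance(a, b) / nchar(a)
    else offsetSimilarity(a, b)
  }
  list(score = mean(det$similarity), detail = det)
}

#' Flag origins with nearby mobile elements
#'
#' Mobile genes are features whose product matches transposase, integrase,
#' insertion sequence or ISH (case-insensitive). An origin with a mobile
#' gene within `window_bp` of its interval is flagged later-acquired, the
#' signature of an origin translocated rather than vertically inherited.
#'
#' @param call an [OriginCall-class] with a defined origin interval.
#' @param features feature data.frame of the replicon (with `product`).
#' @param window_bp proximity window in bp (default 10000).
#' @return list with `gene_ref`, `mobile_genes` (data.frame `locus_tag`,
#'   `class`, `distance_bp`) and `later_acquired`.
#' @export
annotateMobility <- function(call, features, window_bp = 10000L) {
  iv <- callInterval(call)
  pat <- "(?i)transposase|integrase|insertion sequence|\\bISH"
  mob <- features[grepl(pat, features$product, perl = TRUE), , drop = FALSE]
  if (!nrow(mob) || any(is.na(iv))) {
    return(list(gene_ref = callGene(call),
                mobile_genes = data.frame(locus_tag = character(),
                                          class = character(),
                                          distance_bp = integer()),
                later_acquired = FALSE, window_bp = window_bp))
  }
  dist <- pmax(0L, pmax(mob$start - iv[2], iv[1] - mob$end))
  cls <- ifelse(grepl("(?i)integrase", mob$product, perl = TRUE),
                "integrase", "transposase")
  keep <- dist <= window_bp
  list(gene_ref = callGene(call),
       mobile_genes = data.frame(locus_tag = mob$locus_tag[keep],
                                 class = cls[keep],
                                 distance_bp = as.integer(dist[keep]),
                                 stringsAsFactors = FALSE),
       later_acquired = any(keep), window_bp = window_bp)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via ape) on a symmetric non-negative
#' distance matrix; negative branch lengths are clamped to zero with a
#' note. Optionally bootstraps by resampling the columns of a supplied
#' character alignment matrix feeding the distances.
#'
#' @param d symmetric distance matrix with dimnames, n >= 3.
#' @return list with `tree` (an [ape::phylo]) and `newick` string.
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  tr <- ape::nj(d)
  if (any(tr$edge.length < 0)) {
    message("negative NJ branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  list(tree = tr, newick = ape::write.tree(tr))
}

#' Poisson-corrected protein distance from a pairwise alignment
#'
#' The p-distance over ungapped columns, Poisson-corrected as
#' `-ln(1 - p)`. Columns in which either sequence is gapped (more than 50
#' percent gaps for a pair) are removed first, making the usual manual
#' removal of gappy alignment columns explicit. `p` is capped at 0.999 with
#' a warning to keep the distance finite.
#'
#' @param aligned_a,aligned_b equal-length gapped amino-acid strings.
#' @return numeric distance.
#' @export
proteinDistance <- function(aligned_a, aligned_b) {
  stopifnot(nchar(aligned_a) == nchar(aligned_b))
  a <- strsplit(aligned_a, "")[[1]]
  b <- strsplit(aligned_b, "")[[1]]
  keep <- a != "-" & b != "-"
  if (!sum(keep)) stop("no ungapped columns")
  p <- mean(a[keep] != b[keep])
  if (p >= 1) {
    warning("p-distance at saturation; capped")
    p <- 0.999
  }
  -log(1 - p)
}

#' Poisson distance matrix over a set of proteins
#'
#' Pairwise global alignments ([globalAlign()]) feeding
#' [proteinDistance()].
#'
#' @param proteins named character vector of amino-acid sequences.
#' @return symmetric distance matrix.
#' @export
proteinDistanceMatrix <- function(proteins) {
  n <- length(proteins)
  ids <- names(proteins)
  if (is.null(ids)) ids <- paste0("p", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    al <- globalAlign(proteins[[i]], proteins[[j]])
    d[i, j] <- d[j, i] <- proteinDistance(al$aligned_a, al$aligned_b)
  }
  d
}
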