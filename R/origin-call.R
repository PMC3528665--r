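# Group motif models into families: models whose consensi differ by more
# than width/4 (best ungapped offset) are distinct; similar models are merged
# by single linkage. Returns an integer family id per model.
motifFamilyIds <- function(models, distinct_frac = 0.25) {
  n <- length(models)
  if (n == 0L) return(integer())
  sim <- diag(n) * 0 + 1
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      s <- offsetSimilarity(motifConsensus(models[[i]]),
                            motifConsensus(models[[j]]))
      sim[i, j] <- s; sim[j, i] <- s
    }
  }
  adj <- sim >= (1 - distinct_frac)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  as.integer(igraph::components(g)$membership)
}

#' Classify the origin evidence flanking one orc/cdc6 gene
#'
#' Applies the origin decision rules to the qualifying (G-string-bearing)
#' ORB elements found in the gene's flanking intergenic regions, evaluated
#' in order dual, candidate, deficient, none:
#'
#' * `candidate`: at least two qualifying ORBs from one motif family,
#'   forming an inverted pair within one IR or occupying both flanking IRs.
#' * `dual`: two motif families, with consensus differing by more than a
#'   quarter of the motif width, each independently satisfying the
#'   candidate rule.
#' * `deficient`: qualifying ORBs present but no family satisfies the
#'   candidate rule (the single-ORB-per-IR case).
#' * `none`: no qualifying ORB.
#'
#' The origin interval is the minimal replicon span covering the qualifying
#' ORBs and the AT-rich segment of the occupied IRs.
#'
#' @param gene_ref locus_tag of the orc/cdc6 gene.
#' @param replicon_id id of the replicon carrying it.
#' @param elements data.frame of ORB elements: the [scanMotif()] columns
#'   plus `motif_family` (integer family id of the scoring motif) and
#'   `repl_start`/`repl_end` (element interval in replicon coordinates).
#'   Only rows with `has_g_string` qualify.
#' @param at_segments optional data.frame of AT-rich segments per IR with
#'   columns `side`, `repl_start`, `repl_end`, `at_fraction`.
#' @param gene_strand strand of the gene (`"+"`/`"-"`), used by
#'   [layoutClassify()].
#' @param max_gap maximum inverted-pair gap in bp.
#' @return an [OriginCall-class].
#' @export
callOrigin <- function(gene_ref, replicon_id, elements,
                       at_segments = NULL, gene_strand = "+",
                       max_gap = 400L) {
  if (is.null(elements) || !nrow(elements)) {
    return(new("OriginCall", geneRef = gene_ref, repliconId = replicon_id,
               status = "none", orbs = data.frame(), atRich = data.frame(),
               layout = NA_character_, originStart = NA_integer_,
               originEnd = NA_integer_, notes = "no ORB elements"))
  }
  qual <- elements[elements$has_g_string, , drop = FALSE]
  if (!nrow(qual)) {
    return(new("OriginCall", geneRef = gene_ref, repliconId = replicon_id,
               status = "none", orbs = data.frame(), atRich = data.frame(),
               layout = NA_character_, originStart = NA_integer_,
               originEnd = NA_integer_,
               notes = "ORB-like elements without G-string"))
  }
  if (!"motif_family" %in% names(qual)) qual$motif_family <- 1L

  famSatisfies <- function(df) {
    if (nrow(df) < 2L) return(FALSE)
    # an inverted pair within one IR
    for (s in unique(df$side)) {
      sub <- df[df$side == s, , drop = FALSE]
      pr <- pairInverted(sub, max_gap = max_gap)
      if (nrow(pr$pairs)) return(TRUE)
    }
    # or an inverted configuration flanking the gene: both IRs occupied and
    # the two sides contribute opposite orientations (one same-orientation
    # ORB per IR stays deficient, the single-ORB-per-IR exemplar)
    sides <- unique(df$side)
    if (length(sides) >= 2L) {
      o1 <- df$orientation[df$side == sides[1]]
      o2 <- df$orientation[df$side == sides[2]]
      if (any(outer(o1, o2, "!="))) return(TRUE)
      if (length(o1) >= 2L || length(o2) >= 2L) return(TRUE)
    }
    FALSE
  }
  fams <- split(qual, qual$motif_family)
  sat <- vapply(fams, famSatisfies, TRUE)

  status <- if (sum(sat) >= 2L) "dual" else if (sum(sat) == 1L) "candidate"
            else "deficient"
  usable <- if (any(sat)) do.call(rbind, fams[sat]) else qual
  sides <- unique(usable$side)
  at <- data.frame()
  if (!is.null(at_segments) && nrow(at_segments)) {
    at <- at_segments[at_segments$side %in% sides, , drop = FALSE]
  }
  lo <- min(c(usable$repl_start, if (nrow(at)) at$repl_start))
  hi <- max(c(usable$repl_end, if (nrow(at)) at$repl_end))
  call <- new("OriginCall", geneRef = gene_ref, repliconId = replicon_id,
              status = status, orbs = {
                u <- usable
                u$start <- u$repl_start; u$end <- u$repl_end
                rownames(u) <- NULL
                u
              },
              atRich = at, layout = NA_character_,
              originStart = as.integer(lo), originEnd = as.integer(hi),
              notes = "")
  call@layout <- layoutClassify(call, gene_strand)
  call
}

#' Classify an origin's layout relative to its gene
#'
#' `upstream`/`downstream` is decided from the IR side labels of the
#' qualifying ORBs, which are already expressed relative to the gene's
#' coding orientation; `both` when qualifying ORBs occur on both sides.
#'
#' @param call an [OriginCall-class] with status other than `none`.
#' @param gene_strand unused for side-labelled ORBs; kept for symmetry.
#' @return `"upstream"`, `"downstream"` or `"both"`.
#' @export
layoutClassify <- function(call, gene_strand = "+") {
  orbs <- callOrbs(call)
  if (!nrow(orbs)) return(NA_character_)
  sides <- unique(orbs$side)
  if (length(sides) > 1L) "both" else sides
}

#' Per-replicon origin summary
#'
#' Counts initiator genes and origin-associated ones (status `candidate` or
#' `dual`), with the percentage rounded half-up to the nearest integer (the
#' printed-table style); the percentage is `NA` when there are no initiator
#' genes.
#'
#' @param calls list of [OriginCall-class] for one replicon.
#' @return list with `n_cdc6`, `n_ori_associated`, `percentage`.
#' @examples
#' # 3 of 4 initiators origin-associated -> 75 percent
#' @export
summarizeReplicon <- function(calls) {
  n <- length(calls)
  stat <- vapply(calls, callStatus, "")
  nori <- sum(stat %in% c("candidate", "dual"))
  list(n_cdc6 = n, n_ori_associated = nori,
       percentage = if (n == 0L) NA_real_ else roundHalfUp(100 * nori / n))
}
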