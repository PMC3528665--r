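blosum62Matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Optimal local protein alignment (Smith-Waterman, affine gaps)
#'
#' Aligns two protein sequences with the BLOSUM62 matrix and BLAST-style
#' affine gap costs (a gap of length k costs `gap_open + k * gap_extend`,
#' defaults 11/1). The score is the DP-optimal local score; identity is
#' computed over the aligned span.
#'
#' @param a,b protein sequences as character strings, or lists with an
#'   `aa_sequence` field (as returned by [translateCds()]).
#' @param gap_open,gap_extend affine gap penalties.
#' @return list with `query_id`, `subject_id`, `score`, `aligned_length`,
#'   `identities`, `identity_pct`, `query_span`, `subject_span`.
#' @examples
#' localAlign("MKLVINGKT", "MKLVINGKT")$identity_pct
#' @export
localAlign <- function(a, b, gap_open = 11, gap_extend = 1) {
  qa <- if (is.list(a)) a$aa_sequence else a
  qb <- if (is.list(b)) b$aa_sequence else b
  stopifnot(nzchar(qa), nzchar(qb))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(qa), Biostrings::AAString(qb), type = "local",
    substitutionMatrix = blosum62Matrix(),
    gapOpening = gap_open, gapExtension = gap_extend)
  al <- Biostrings::nchar(pa)
  idn <- Biostrings::nmatch(pa)
  list(query_id = if (is.list(a)) a$id else NA_character_,
       subject_id = if (is.list(b)) b$id else NA_character_,
       score = Biostrings::score(pa),
       aligned_length = al,
       identities = idn,
       identity_pct = if (al > 0) 100 * idn / al else 0,
       query_span = c(Biostrings::start(Biostrings::pattern(pa)),
                      Biostrings::end(Biostrings::pattern(pa))),
       subject_span = c(Biostrings::start(Biostrings::subject(pa)),
                        Biostrings::end(Biostrings::subject(pa))))
}

# Vectorized screen helper: align many query proteins against one subject.
# Returns data.frame(score, aligned_length, identities, identity_pct).
localAlignMany <- function(queries, subject, gap_open = 11, gap_extend = 1) {
  qset <- Biostrings::AAStringSet(queries)
  pa <- Biostrings::pairwiseAlignment(
    qset, Biostrings::AAString(subject), type = "local",
    substitutionMatrix = blosum62Matrix(),
    gapOpening = gap_open, gapExtension = gap_extend)
  al <- Biostrings::nchar(pa)
  idn <- Biostrings::nmatch(pa)
  data.frame(score = Biostrings::score(pa), aligned_length = al,
             identities = idn,
             identity_pct = ifelse(al > 0, 100 * idn / al, 0))
}

#' Global pairwise alignment returning the two gapped strings
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine 11/1) used to obtain
#' homologous columns for evolutionary distances.
#'
#' @param a,b protein sequences as character strings.
#' @return list with `aligned_a`, `aligned_b` gapped strings.
#' @export
globalAlign <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = blosum62Matrix(), gapOpening = 11, gapExtension = 1)
  list(aligned_a = as.character(Biostrings::alignedPattern(pa)),
       aligned_b = as.character(Biostrings::alignedSubject(pa)))
}
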