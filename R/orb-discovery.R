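#' Extract intergenic regions flanking a gene
#'
#' For each side of the gene, the interval from the gene boundary to the
#' nearest annotated feature boundary, capped at `max_span` bp adjacent to
#' the gene. Sides are labelled `upstream`/`downstream` relative to the
#' gene's coding orientation. Circular replicons wrap across the coordinate
#' origin (wrapped IRs are stored with virtual extension, `end` beyond the
#' replicon length). Empty or negative gaps (overlapping annotations) are
#' omitted.
#'
#' @param replicon a [Replicon-class].
#' @param gene one row of the feature table (or a locus_tag present in it).
#' @param max_span maximum IR span in bp (default 5000).
#' @return data.frame with columns `replicon_id`, `gene_ref`, `side`,
#'   `start`, `end`, `sequence` (0-2 rows).
#' @export
extractFlankingIRs <- function(replicon, gene, max_span = 5000L) {
  ft <- features(replicon)
  if (is.character(gene)) {
    idx <- match(gene, ft$locus_tag)
    if (is.na(idx)) stop("gene ", gene, " not found on replicon ",
                         repliconId(replicon))
    gene <- ft[idx, ]
  }
  L <- repliconLength(replicon)
  circular <- topology(replicon) == "circular"
  gs <- gene$start
  ge <- gene$end

  others <- ft[ft$locus_tag != gene$locus_tag, , drop = FALSE]
  starts <- others$start
  ends <- others$end
  if (circular) {
    starts <- c(starts - L, starts, starts + L, gs - L, gs + L)
    ends <- c(ends - L, ends, ends + L, ge - L, ge + L)
  }

  out <- list()
  addIR <- function(a, b, physical_side) {
    len <- b - a + 1L
    if (len < 1L) return(invisible(NULL))
    if (len > max_span) {
      if (physical_side == "left") a <- b - max_span + 1L else b <- a + max_span - 1L
    }
    a0 <- if (circular) ((a - 1L) %% L) + 1L else a
    b0 <- a0 + (b - a)
    side <- if (gene$strand == "+") {
      if (physical_side == "left") "upstream" else "downstream"
    } else {
      if (physical_side == "left") "downstream" else "upstream"
    }
    out[[length(out) + 1L]] <<- data.frame(
      replicon_id = repliconId(replicon), gene_ref = gene$locus_tag,
      side = side, start = a0, end = b0,
      sequence = repliconSubseq(replicon, a0, b0), stringsAsFactors = FALSE)
  }

  # a feature overlapping the gene boundary leaves no IR on that side
  overlapsLeft <- any(starts < gs & ends >= gs)
  overlapsRight <- any(starts <= ge & ends > ge)
  leftEnds <- ends[ends < gs]
  if (!overlapsLeft) {
    if (length(leftEnds)) {
      addIR(max(leftEnds) + 1L, gs - 1L, "left")
    } else if (!circular && gs > 1L) {
      addIR(1L, gs - 1L, "left")
    }
  }
  rightStarts <- starts[starts > ge]
  if (!overlapsRight) {
    if (length(rightStarts)) {
      addIR(ge + 1L, min(rightStarts) - 1L, "right")
    } else if (!circular && ge < L) {
      addIR(ge + 1L, L, "right")
    }
  }
  if (!length(out)) {
    return(data.frame(replicon_id = character(), gene_ref = character(),
                      side = character(), start = integer(), end = integer(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Strand-symmetrized base composition of a set of sequences.
baseComposition <- function(seqs) {
  codes <- unlist(lapply(seqs, encodeDna))
  f <- tabulate(codes, 5L)[1:4]
  f <- f + rev(f)  # A<->T, C<->G symmetry
  f / sum(f)
}

# One ZOOPS EM fit at fixed width from a given pfm start. W: window matrix
# (rows = candidate sites over all sequences and strands, columns = motif
# positions, entries = base codes 1..4, N = 5). seqIdx groups rows by source
# sequence; Mi = sites per sequence.
zoopsEMFit <- function(W, seqIdx, Mi, bg, f0, gamma0 = 0.5, pseudo = 0.5,
                       tol = 1e-6, max_iter = 60L) {
  w <- ncol(W)
  nseq <- length(Mi)
  f <- f0
  gamma <- gamma0
  lbg <- log(bg)
  ll_old <- -Inf
  Z <- NULL
  for (iter in seq_len(max_iter)) {
    logR <- rbind(log(f) - lbg, 0)  # 5th row: N contributes background odds 1
    sc <- numeric(nrow(W))
    for (k in seq_len(w)) sc <- sc + logR[W[, k] + (k - 1L) * 5L]
    LR <- exp(pmin(sc, 700))
    S <- rowsum(LR, seqIdx)[, 1]
    denom <- (1 - gamma) + gamma * S / Mi
    Z <- (gamma / Mi[seqIdx]) * LR / denom[seqIdx]
    ll <- sum(log(denom))
    # M-step
    counts <- matrix(0, 4L, w)
    for (k in seq_len(w)) {
      ck <- W[, k]
      for (b in 1:4) counts[b, k] <- sum(Z[ck == b])
    }
    f <- sweep(counts + pseudo * bg, 2, colSums(counts) + pseudo, "/")
    Q <- rowsum(Z, seqIdx)[, 1]
    gamma <- min(max(mean(Q), 1e-3), 1 - 1e-3)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(pfm = f, gamma = gamma, loglik = ll_old, Z = Z)
}

# Multiplicity of the 8-mer starting at each position (0 where the 8-mer
# runs off the end or contains N), pooled over a list of code vectors.
# Repeated words mark recurring motif instances and guide EM seeding.
kmerPositionCounts <- function(codes_list, k = 8L) {
  ids <- lapply(codes_list, function(x) {
    n <- length(x)
    if (n < k) return(integer(0))
    m <- n - k + 1L
    id <- integer(m)
    bad <- logical(m)
    for (j in seq_len(k)) {
      v <- x[j:(j + m - 1L)]
      bad <- bad | v > 4L
      id <- id * 4L + (pmin(v, 4L) - 1L)
    }
    id[bad] <- -1L
    id
  })
  all_ids <- unlist(ids)
  valid <- all_ids >= 0L
  tab <- table(all_ids[valid])
  counts <- lapply(ids, function(id) {
    cnt <- rep(0L, length(id))
    ok <- id >= 0L
    cnt[ok] <- as.integer(tab[as.character(id[ok])])
    cnt
  })
  counts
}

# Build the candidate-site matrix for one width across sequences/strands.
# Windows of width w (1-based start positions) that fully contain a G-run of
# at least min_run bases.
windowsWithGRun <- function(x, w, min_run) {
  m <- length(x) - w + 1L
  keep <- logical(m)
  r <- rle(x == 3L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values & r$lengths >= min_run)) {
    lo <- max(1L, ends[k] - w + 1L)
    hi <- min(m, starts[k])
    if (lo <= hi) keep[lo:hi] <- TRUE
  }
  keep
}

buildSiteMatrix <- function(codes_fwd, codes_rev, w, kmer_counts = NULL,
                            g_run_filter = 0L) {
  Ws <- list(); seqIdx <- integer(); strand <- character()
  offset <- integer(); weight <- numeric()
  ci <- 0L
  for (i in seq_along(codes_fwd)) {
    for (str in c("forward", "reverse")) {
      ci <- ci + 1L
      x <- if (str == "forward") codes_fwd[[i]] else codes_rev[[i]]
      m <- length(x) - w + 1L
      if (m < 1L) next
      keep <- if (g_run_filter > 0L) windowsWithGRun(x, w, g_run_filter)
              else rep(TRUE, m)
      if (!any(keep)) next
      pos <- which(keep)
      Wi <- matrix(x[outer(pos - 1L, seq_len(w), "+")], length(pos), w)
      Ws[[length(Ws) + 1L]] <- Wi
      seqIdx <- c(seqIdx, rep(i, length(pos)))
      strand <- c(strand, rep(str, length(pos)))
      offset <- c(offset, pos)
      if (!is.null(kmer_counts)) {
        cnt <- kmer_counts[[ci]]
        wv <- rep(0, m)
        for (d in 0:(w - 8L)) {
          idx <- seq_len(m) + d
          idx <- idx[idx <= length(cnt)]
          wv[seq_along(idx)] <- pmax(wv[seq_along(idx)], cnt[idx])
        }
        weight <- c(weight, wv[pos])
      }
    }
  }
  if (!length(Ws)) return(NULL)
  if (is.null(kmer_counts)) weight <- rep(1, length(seqIdx))
  list(W = do.call(rbind, Ws), seqIdx = seqIdx, strand = strand,
       offset = offset, weight = weight)
}

motifFromFit <- function(fit, w, bg, pseudo) {
  pfm <- fit$pfm
  dimnames(pfm) <- list(DNA_BASES4, NULL)
  consensus <- paste(DNA_BASES4[apply(pfm, 2, which.max)], collapse = "")
  new("MotifModel", width = as.integer(w), pfm = pfm, background = bg,
      pseudoCount = pseudo, logOdds = log2(sweep(pfm, 1, bg, "/")),
      consensus = consensus, score = fit$loglik, gamma = fit$gamma)
}

#' Discover ORB-like motifs by ZOOPS expectation-maximization
#'
#' A MEME-style ZOOPS ("zero or one occurrence per sequence") mixture model
#' fitted by EM over both strands of the supplied intergenic regions: each IR
#' contributes at most one motif occurrence, drawn uniformly over candidate
#' positions with sequence-level occurrence probability gamma. Each candidate
#' width on the grid is fitted from `n_restarts` seeded starts (position
#' frequency matrix initialized from a randomly sampled site); EM runs to
#' log-likelihood convergence. With `n_motifs = 1` the best model per width
#' is returned, ranked by likelihood-ratio support; with `n_motifs > 1`
#' occurrences of each reported motif are masked and discovery repeats, so
#' distinct co-occurring motif families are each recovered.
#'
#' @param irs data.frame from [extractFlankingIRs()] (needs a `sequence`
#'   column), or a character vector of sequences.
#' @param width_min,width_max motif width bounds (default 20-40).
#' @param n_restarts seeded random starts per width.
#' @param seed integer seed fixing all randomness.
#' @param widths optional explicit width grid; default
#'   `{20, 25, 30, 35, 40}` clipped to the bounds.
#' @param n_motifs number of successive (masked) motifs to report.
#' @param background optional length-4 background composition; default
#'   estimated from the IRs (strand-symmetrized).
#' @param min_occurrences in multi-motif mode, the minimum number of
#'   confident occurrences (score at or above 55 percent of the model
#'   maximum) a reported motif must leave across the IRs; models that
#'   merely memorized a couple of chance-similar background windows fall
#'   below it and are suppressed.
#' @param g_run_filter when positive, restrict the candidate-site space to
#'   windows containing a G-run of at least this many bases. Haloarchaeal
#'   ORBs are defined by their terminal G-string, so sites that could never
#'   yield a qualifying element are excluded; this also keeps the AT-rich
#'   unwinding elements from dominating the motif search. 0 (default)
#'   scans every window.
#' @param pseudo pseudo-count for the M-step.
#' @param tol EM log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @return list of [MotifModel-class] objects, ranked by score.
#' @export
discoverMotifs <- function(irs, width_min = 20L, width_max = 40L,
                           n_restarts = 20L, seed = 1L, widths = NULL,
                           n_motifs = 1L, background = NULL,
                           g_run_filter = 0L, min_occurrences = 4L,
                           pseudo = 0.5, tol = 1e-6, max_iter = 60L) {
  seqs <- if (is.data.frame(irs)) irs$sequence else as.character(irs)
  if (length(seqs) < 2L) stop("motif discovery needs at least 2 IRs")
  if (is.null(widths)) {
    widths <- c(20L, 25L, 30L, 35L, 40L)
    widths <- widths[widths >= width_min & widths <= width_max]
  }
  if (max(nchar(seqs)) < min(widths))
    stop("all IRs shorter than the minimum motif width")
  bg <- if (is.null(background)) baseComposition(seqs) else background / sum(background)
  bg <- pmax(bg, 1e-6); bg <- bg / sum(bg)

  codes_fwd <- lapply(seqs, encodeDna)
  codes_rev <- lapply(seqs, function(s) encodeDna(revcompChr(s)))

  # one round of per-width fitting over the current (possibly masked)
  # codes; with require_ic, restarts converging to diffuse background
  # G-run models (high likelihood but low column information) are ignored
  # so the best *informative* local optimum is reported per width
  fitRound <- function(codes_fwd, codes_rev, require_ic = FALSE) {
    round_models <- list()
    codes_all <- vector("list", 2L * length(seqs))
    codes_all[seq(1L, by = 2L, length.out = length(seqs))] <- codes_fwd
    codes_all[seq(2L, by = 2L, length.out = length(seqs))] <- codes_rev
    kc <- kmerPositionCounts(codes_all)
    for (w in widths) {
      sm <- buildSiteMatrix(codes_fwd, codes_rev, w, kmer_counts = kc,
                            g_run_filter = g_run_filter)
      if (is.null(sm)) next
      # remap sequence indices to contiguous 1..n' (some IRs may be too
      # short for this width or hold no candidate site)
      uidx <- sort(unique(sm$seqIdx))
      if (length(uidx) < 2L) next
      sidx <- match(sm$seqIdx, uidx)
      Mi <- tabulate(sidx, length(uidx))
      best <- NULL
      # seed EM from sites containing repeated 8-mers: recurring words mark
      # motif instances, which uniform random sites almost never hit
      # (linear weighting so rarer families still draw seeds)
      seed_prob <- sm$weight + 0.5
      for (r in seq_len(n_restarts)) {
        j0 <- sample.int(nrow(sm$W), 1L, prob = seed_prob)
        site <- sm$W[j0, ]
        f0 <- matrix(0.2 / 3, 4L, w)
        for (k in seq_len(w)) {
          if (site[k] <= 4L) f0[site[k], k] <- 0.8 else f0[, k] <- 0.25
        }
        fit <- zoopsEMFit(sm$W, sidx, Mi, bg, f0, gamma0 = 0.3,
                          pseudo = pseudo, tol = tol, max_iter = max_iter)
        if (require_ic &&
            !isInformativeMotif(motifFromFit(fit, w, bg, pseudo))) next
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
      }
      if (!is.null(best)) {
        # phase refinement: a model locked a few columns off the motif is a
        # local optimum (its shifted-in columns read background); hill-climb
        # over column shifts, refitting from each shifted start
        shiftPfm <- function(f, k) {
          out <- matrix(bg, 4L, w)
          if (k > 0L) out[, seq_len(w - k)] <- f[, (k + 1L):w]
          else out[, (1L - k):w] <- f[, seq_len(w + k)]
          out
        }
        repeat {
          improved <- FALSE
          for (k in c(-3L, -2L, -1L, 1L, 2L, 3L)) {
            fit <- zoopsEMFit(sm$W, sidx, Mi, bg, shiftPfm(best$pfm, k),
                              gamma0 = best$gamma, pseudo = pseudo,
                              tol = tol, max_iter = max_iter)
            if (require_ic &&
                !isInformativeMotif(motifFromFit(fit, w, bg, pseudo))) next
            if (fit$loglik > best$loglik + 1e-9) {
              best <- fit
              improved <- TRUE
            }
          }
          if (!improved) break
        }
        round_models[[as.character(w)]] <- motifFromFit(best, w, bg, pseudo)
      }
    }
    scores <- vapply(round_models, motifScore, 1)
    unname(round_models[order(-scores)])
  }

  models <- list()
  withStageSeed(seed, "zoops-em", {
    if (n_motifs == 1L) {
      # best model per width, ranked by likelihood-ratio support
      models <- fitRound(codes_fwd, codes_rev)
    } else {
      # successive discovery: report the dominant motif, mask its
      # occurrences (and thereby any shifted variants of it) with N, and
      # refit; each recurring family surfaces in its own round. Stop when
      # the best remaining model is no longer informative across its width
      # (only diffuse background G-run structure is left).
      empty_rounds <- 0L
      for (round in seq_len(n_motifs)) {
        rm_ <- fitRound(codes_fwd, codes_rev, require_ic = TRUE)
        # one empty round is not terminal (the next draws fresh restarts,
        # giving rare families further chances); two in a row are
        if (!length(rm_)) {
          empty_rounds <- empty_rounds + 1L
          if (empty_rounds >= 2L) break
          next
        }
        empty_rounds <- 0L
        top <- rm_[[1]]
        n_occ <- 0L
        for (i in seq_along(seqs)) {
          # mask only confident instances of the reported motif: a lax
          # threshold would also erase other families' G-rich elements
          hits <- scanCodes(codes_fwd[[i]], codes_rev[[i]], top,
                            min_bits = 0.55 * maxBits(top))
          n_occ <- n_occ + nrow(hits)
          for (h in seq_len(nrow(hits))) {
            span <- hits$start[h]:hits$end[h]
            codes_fwd[[i]][span] <- 5L
            codes_rev[[i]][length(codes_rev[[i]]) + 1L - span] <- 5L
          }
        }
        # a recurring ORB family leaves several confident occurrences; a
        # model that memorized a couple of chance-similar background
        # windows does not, and is masked away without being reported
        if (n_occ < min_occurrences) next
        models[[length(models) + 1L]] <- top
      }
    }
  })
  models
}

maxBits <- function(motif) sum(apply(motif@logOdds, 2, max))

# Per-column relative entropy (bits) of a motif against its background.
motifColumnIC <- function(motif) {
  f <- motif@pfm
  colSums(f * log2(sweep(f, 1, motif@background, "/")))
}

# A genuine ORB model is informative across most of its width; a model that
# merely recapitulates background G-runs concentrates its information in a
# handful of G columns. Require at least `frac` of columns above `min_bits`.
isInformativeMotif <- function(motif, min_bits = 1, frac = 0.5) {
  mean(motifColumnIC(motif) >= min_bits) >= frac
}

# Scan coded strands with a motif; returns all sites >= min_bits with
# coordinates on the forward sequence, greedily non-overlapping.
scanCodes <- function(cf, cr, motif, min_bits) {
  w <- motif@width
  L <- length(cf)
  lo <- rbind(motif@logOdds, 0)
  hits <- list()
  for (str in c("forward", "reverse")) {
    x <- if (str == "forward") cf else cr
    m <- length(x) - w + 1L
    if (m < 1L) next
    sc <- numeric(m)
    for (k in seq_len(w)) sc <- sc + lo[x[k:(k + m - 1L)] + (k - 1L) * 5L]
    sel <- which(sc >= min_bits)
    if (!length(sel)) next
    start <- if (str == "forward") sel else L - w - sel + 2L
    hits[[str]] <- data.frame(start = start, end = start + w - 1L,
                              orientation = str, score = sc[sel])
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), end = integer(),
                      orientation = character(), score = numeric()))
  }
  h <- do.call(rbind, hits)
  h <- h[order(-h$score, h$start), ]
  chosen <- logical(nrow(h))
  occupied <- logical(L)
  for (i in seq_len(nrow(h))) {
    span <- h$start[i]:h$end[i]
    if (!any(occupied[span])) {
      chosen[i] <- TRUE
      occupied[span] <- TRUE
    }
  }
  h <- h[chosen, , drop = FALSE]
  h[order(h$start), , drop = FALSE]
}

#' Scan an intergenic region with a motif model
#'
#' Scores every position on both strands with the motif's log2-odds matrix
#' and reports sites at or above `min_bits`, greedily non-overlapping
#' (highest score first, ties leftmost). Each reported element carries its
#' sequence in motif orientation and the result of [detectGString()] on it.
#'
#' @param ir one IR row from [extractFlankingIRs()], or a character sequence.
#' @param motif a [MotifModel-class].
#' @param min_bits score threshold in bits; default 30 percent of the
#'   maximum achievable score of the motif.
#' @param min_g_run,terminal_window G-string parameters (see
#'   [detectGString()]).
#' @return data.frame of ORB elements: `gene_ref`, `side`, `start`, `end`
#'   (1-based within the IR), `orientation`, `sequence`, `score`,
#'   `g_run_length`, `g_run_offset`, `has_g_string`.
#' @export
scanMotif <- function(ir, motif, min_bits = NULL, min_g_run = 5L,
                      terminal_window = 10L) {
  seq <- if (is.data.frame(ir)) ir$sequence else as.character(ir)
  gene_ref <- if (is.data.frame(ir) && "gene_ref" %in% names(ir)) ir$gene_ref else NA_character_
  side <- if (is.data.frame(ir) && "side" %in% names(ir)) ir$side else NA_character_
  if (motif@width > nchar(seq)) {
    return(data.frame(gene_ref = character(), side = character(),
                      start = integer(), end = integer(),
                      orientation = character(), sequence = character(),
                      score = numeric(), g_run_length = integer(),
                      g_run_offset = integer(), has_g_string = logical(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(min_bits)) min_bits <- 0.30 * maxBits(motif)
  cf <- encodeDna(seq)
  cr <- encodeDna(revcompChr(seq))
  h <- scanCodes(cf, cr, motif, min_bits)
  n <- nrow(h)
  elem_seq <- character(n)
  grl <- integer(n); gro <- integer(n); hgs <- logical(n)
  for (i in seq_len(n)) {
    s <- substr(seq, h$start[i], h$end[i])
    if (h$orientation[i] == "reverse") s <- revcompChr(s)
    elem_seq[i] <- s
    g <- detectGString(s, min_run = min_g_run,
                       terminal_window = terminal_window)
    if (!is.null(g)) {
      grl[i] <- g$run_length; gro[i] <- g$offset; hgs[i] <- TRUE
    } else {
      grl[i] <- 0L; gro[i] <- NA_integer_; hgs[i] <- FALSE
    }
  }
  data.frame(gene_ref = rep(gene_ref, n), side = rep(side, n),
             start = h$start, end = h$end, orientation = h$orientation,
             sequence = elem_seq, score = h$score, g_run_length = grl,
             g_run_offset = gro, has_g_string = hgs,
             stringsAsFactors = FALSE)
}

#' Detect a terminal G-string in an ORB element
#'
#' The halophile-specific G-string is a long run of G at the end of an ORB
#' element. The longest maximal G run whose end lies within
#' `terminal_window` bases of either element end is reported when its length
#' reaches `min_run`.
#'
#' @param element_seq DNA string (in motif orientation).
#' @param min_run minimum run length (default 5).
#' @param terminal_window distance in bases from an element end within which
#'   the run must terminate (default 10).
#' @return list with `run_length` and `offset` (1-based start of the run),
#'   or `NULL` when absent.
#' @examples
#' detectGString("TAACAGCGGAAACAGTGGGGTGGGGGGGT")$run_length
#' @export
detectGString <- function(element_seq, min_run = 5L, terminal_window = 10L) {
  v <- strsplit(toupper(element_seq), "")[[1]]
  n <- length(v)
  r <- rle(v == "G")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_run)
  if (!length(runs)) return(NULL)
  nearEnd <- (n - ends[runs]) <= terminal_window | ends[runs] <= terminal_window
  runs <- runs[nearEnd]
  if (!length(runs)) return(NULL)
  best <- runs[which.max(r$lengths[runs])]
  list(run_length = r$lengths[best], offset = starts[best])
}

#' Pair forward and reverse ORB occurrences into inverted repeats
#'
#' Greedy maximum-score matching of forward with reverse motif occurrences
#' separated by at most `max_gap` bp (inner gap between the elements):
#' feasible pairs are taken in order of decreasing total score (ties by
#' leftmost coordinate), never reusing an element. Unpaired elements are
#' retained as singletons.
#'
#' @param elements data.frame from [scanMotif()] (one IR or one gene's IRs,
#'   scored by the same motif).
#' @param max_gap maximum gap between the paired elements in bp.
#' @return list with `pairs` (data.frame `i`, `j`, `start`, `end`,
#'   `total_score`) and `singletons` (integer row indices).
#' @export
pairInverted <- function(elements, max_gap = 400L) {
  empty <- data.frame(i = integer(), j = integer(), start = integer(),
                      end = integer(), total_score = numeric())
  if (!nrow(elements))
    return(list(pairs = empty, singletons = integer()))
  fw <- which(elements$orientation == "forward")
  rv <- which(elements$orientation == "reverse")
  cand <- list()
  for (i in fw) for (j in rv) {
    gap <- max(elements$start[i], elements$start[j]) -
      min(elements$end[i], elements$end[j]) - 1L
    if (gap <= max_gap) {
      cand[[length(cand) + 1L]] <- data.frame(
        i = i, j = j, start = min(elements$start[i], elements$start[j]),
        end = max(elements$end[i], elements$end[j]),
        total_score = elements$score[i] + elements$score[j])
    }
  }
  if (!length(cand))
    return(list(pairs = empty, singletons = seq_len(nrow(elements))))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$total_score, cand$start), , drop = FALSE]
  used <- logical(nrow(elements))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used[cand$i[k]] && !used[cand$j[k]]) {
      keep[k] <- TRUE
      used[cand$i[k]] <- TRUE
      used[cand$j[k]] <- TRUE
    }
  }
  list(pairs = cand[keep, , drop = FALSE],
       singletons = which(!used))
}

#' Find an AT-rich segment in an intergenic region
#'
#' Scores every position by the AT fraction of the `window`-bp window
#' centered on it (windows shrink at the IR edges); a position qualifies
#' when that fraction reaches background AT plus `margin`. Runs of at
#' least `window/2` qualifying positions are segments, trimmed at both
#' ends to A/T bases so boundaries do not spill into the GC flanks; the
#' segment with the highest AT fraction is reported. Against the ~62
#' percent GC haloarchaeal background this picks out the AT-rich duplex
#' unwinding element between ORB repeats.
#'
#' @param ir IR row or character sequence (length >= `window`).
#' @param background_gc background GC fraction of the replicon.
#' @param window smoothing window size in bp (default 50).
#' @param margin required AT excess over background AT (default 0.15).
#' @return list with `start`, `end` (1-based within the IR), `at_fraction`,
#'   `background_gc`, or `NULL` when no segment qualifies.
#' @export
atRichSegment <- function(ir, background_gc, window = 50L, margin = 0.15) {
  seq <- if (is.data.frame(ir)) ir$sequence else as.character(ir)
  n <- nchar(seq)
  if (n < window) stop("IR shorter than the AT window")
  codes <- encodeDna(seq)
  at <- as.integer(codes %in% c(1L, 4L))
  nn <- as.integer(codes == 5L)
  cat_ <- cumsum(c(0L, at))
  cnn <- cumsum(c(0L, nn))
  h <- window %/% 2L
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  wat <- cat_[hi + 1L] - cat_[lo]
  wnn <- cnn[hi + 1L] - cnn[lo]
  denom <- (hi - lo + 1L) - wnn
  frac <- ifelse(denom > 0, wat / denom, 0)
  thr <- (1 - background_gc) + margin
  qual <- frac >= thr
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= h)
  if (!length(runs)) return(NULL)
  best <- NULL
  for (k in runs) {
    a <- starts[k]; b <- ends[k]
    while (a < b && at[a] == 0L) a <- a + 1L
    while (b > a && at[b] == 0L) b <- b - 1L
    d <- (b - a + 1L) - (cnn[b + 1L] - cnn[a])
    atf <- if (d > 0) (cat_[b + 1L] - cat_[a]) / d else 0
    if (is.null(best) || atf > best$at_fraction)
      best <- list(start = a, end = b, at_fraction = atf,
                   background_gc = background_gc)
  }
  best
}
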