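#' Pipeline run configuration
#'
#' Centralizes every tunable threshold of the origin-prediction pipeline
#' with its documented range; serializes losslessly to YAML.
#'
#' @param min_len minimum initiator length in aa (default 300).
#' @param min_identity_pct,min_aligned screening thresholds (defaults
#'   30 / 150).
#' @param widths motif width grid within 20-40.
#' @param n_restarts EM restarts per width.
#' @param n_motifs successive masked motifs to discover.
#' @param min_g_run,terminal_window G-string rule (defaults 5 / 10).
#' @param at_window,at_margin AT-rich segment rule (defaults 50 / 0.15).
#' @param max_pair_gap inverted-pair gap cap in bp.
#' @param min_bits_frac scan threshold as a fraction of each motif's
#'   maximum achievable score.
#' @param min_motif_rel_support discard discovered motifs whose
#'   likelihood-ratio support falls below this fraction of the best
#'   model's.
#' @param max_ir_span IR extraction cap in bp.
#' @param family_threshold_pct family identity threshold (default 80).
#' @param mobility_window_bp mobile-element proximity window (default
#'   10000).
#' @param profile_rescreen run the profile rescreen after the pairwise
#'   screen.
#' @param seed integer run seed.
#' @return a validated list of class `RunConfig`.
#' @export
runConfig <- function(min_len = 300L, min_identity_pct = 30,
                      min_aligned = 150L, widths = c(25L, 30L, 35L),
                      n_restarts = 12L, n_motifs = 8L, min_g_run = 5L,
                      terminal_window = 10L, at_window = 50L,
                      at_margin = 0.15, max_pair_gap = 400L,
                      min_bits_frac = 0.30, min_motif_rel_support = 0.08,
                      max_ir_span = 5000L,
                      family_threshold_pct = 80,
                      mobility_window_bp = 10000L,
                      profile_rescreen = FALSE, seed = 1L) {
  cfg <- list(min_len = as.integer(min_len),
              min_identity_pct = min_identity_pct,
              min_aligned = as.integer(min_aligned),
              widths = as.integer(widths), n_restarts = as.integer(n_restarts),
              n_motifs = as.integer(n_motifs), min_g_run = as.integer(min_g_run),
              terminal_window = as.integer(terminal_window),
              at_window = as.integer(at_window), at_margin = at_margin,
              max_pair_gap = as.integer(max_pair_gap),
              min_bits_frac = min_bits_frac,
              min_motif_rel_support = min_motif_rel_support,
              max_ir_span = as.integer(max_ir_span),
              family_threshold_pct = family_threshold_pct,
              mobility_window_bp = as.integer(mobility_window_bp),
              profile_rescreen = isTRUE(profile_rescreen),
              seed = as.integer(seed))
  stopifnot(all(cfg$widths >= 20L), all(cfg$widths <= 40L),
            cfg$min_identity_pct >= 0, cfg$min_identity_pct <= 100,
            cfg$family_threshold_pct >= 0, cfg$family_threshold_pct <= 100,
            cfg$at_margin >= 0, cfg$at_margin <= 1,
            cfg$min_bits_frac > 0, cfg$min_bits_frac < 1,
            cfg$n_restarts >= 1L, cfg$n_motifs >= 1L)
  class(cfg) <- "RunConfig"
  cfg
}

#' Serialize / restore a run configuration
#'
#' @param config a [runConfig()].
#' @param path YAML file path.
#' @return `readRunConfig` returns the restored `RunConfig`.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  do.call(runConfig, yaml::read_yaml(path))
}

repliconGC <- function(replicon) {
  f <- Biostrings::alphabetFrequency(repliconSequence(replicon))
  gc <- f[["G"]] + f[["C"]]
  tot <- gc + f[["A"]] + f[["T"]]
  if (tot > 0) gc / tot else 0.5
}

#' Run the full origin-prediction pipeline
#'
#' Orchestrates screen -> intergenic regions -> ORB motif discovery ->
#' per-gene origin calls -> family clustering and naming -> mobility
#' annotation -> initiator NJ tree -> reports, deterministically for a
#' given config seed. Motif discovery pools the IRs of all genomes so that
#' origin families shared between genomes are learned once.
#'
#' @param genomes named list: genome id -> list of [Replicon-class].
#' @param config a [runConfig()].
#' @param seeds seed protein panel (default packaged synthetic panel).
#' @param out_dir optional report directory (see [writeOriginReport()]).
#' @return list with `hits`, `irs`, `motifs`, `calls` (named list of
#'   [OriginCall-class]), `families`, `mobility`, `tree`, `manifest`.
#' @export
runPipeline <- function(genomes, config = runConfig(),
                        seeds = readSeedPanel(), out_dir = NULL) {
  if (!length(genomes) || !length(unlist(genomes, recursive = FALSE)))
    stop("no input replicons")
  if (is.null(names(genomes)))
    names(genomes) <- paste0("genome", seq_along(genomes))

  # stage 1: initiator screen
  hits <- list()
  for (g in names(genomes)) {
    h <- screenProteome(genomes[[g]], seeds, min_len = config$min_len,
                        min_identity_pct = config$min_identity_pct,
                        min_aligned = config$min_aligned)
    if (config$profile_rescreen && any(h$passes))
      h <- profileRescreen(h, seeds, min_len = config$min_len)
    if (nrow(h)) h$genome_id <- g
    hits[[g]] <- h
  }
  allhits <- do.call(rbind, hits)
  pass <- allhits[allhits$passes, , drop = FALSE]

  repliconOf <- list()
  for (g in names(genomes)) for (r in genomes[[g]])
    repliconOf[[repliconId(r)]] <- r

  # stage 2: flanking intergenic regions
  irs <- list()
  for (i in seq_len(nrow(pass))) {
    r <- repliconOf[[pass$replicon_id[i]]]
    ir <- extractFlankingIRs(r, pass$locus_tag[i],
                             max_span = config$max_ir_span)
    if (nrow(ir)) irs[[length(irs) + 1L]] <- ir
  }
  irs <- if (length(irs)) do.call(rbind, irs) else
    data.frame(replicon_id = character(), gene_ref = character(),
               side = character(), start = integer(), end = integer(),
               sequence = character())

  # stage 3: pooled ZOOPS motif discovery, restricted to G-run-bearing
  # sites (the qualifying criterion for haloarchaeal ORBs); discovered
  # models whose consensus lacks a terminal G-string are discarded, the
  # explicit counterpart of keeping only G-string-harboring motifs
  motifs <- list()
  if (nrow(irs) >= 2L) {
    motifs <- discoverMotifs(irs, n_restarts = config$n_restarts,
                             seed = stageSeed(config$seed, "motifs"),
                             widths = config$widths,
                             n_motifs = config$n_motifs,
                             g_run_filter = config$min_g_run)
    motifs <- Filter(function(m) !is.null(detectGString(
      motifConsensus(m), min_run = config$min_g_run,
      terminal_window = config$terminal_window)), motifs)
    # drop marginal models: overfit background patterns carry far less
    # support than any recurring ORB family
    if (length(motifs)) {
      topscore <- max(vapply(motifs, motifScore, 1))
      motifs <- Filter(function(m)
        motifScore(m) >= config$min_motif_rel_support * topscore, motifs)
    }
  }
  famIds <- motifFamilyIds(motifs)

  # stage 4: scan IRs, call per-gene origins
  calls <- list()
  for (lt in unique(pass$locus_tag)) {
    gi <- which(pass$locus_tag == lt)[1]
    gene_irs <- irs[irs$gene_ref == lt, , drop = FALSE]
    elements <- list()
    ats <- list()
    if (nrow(gene_irs)) {
      bggc <- repliconGC(repliconOf[[pass$replicon_id[gi]]])
      for (k in seq_len(nrow(gene_irs))) {
        irrow <- gene_irs[k, , drop = FALSE]
        for (m in seq_along(motifs)) {
          el <- scanMotif(irrow, motifs[[m]],
                          min_bits = config$min_bits_frac * maxBits(motifs[[m]]),
                          min_g_run = config$min_g_run,
                          terminal_window = config$terminal_window)
          if (nrow(el)) {
            el$motif_id <- m
            el$motif_family <- famIds[m]
            el$repl_start <- irrow$start + el$start - 1L
            el$repl_end <- irrow$start + el$end - 1L
            elements[[length(elements) + 1L]] <- el
          }
        }
        if (nchar(irrow$sequence) >= config$at_window) {
          at <- atRichSegment(irrow, background_gc = bggc,
                              window = config$at_window,
                              margin = config$at_margin)
          if (!is.null(at)) {
            ats[[length(ats) + 1L]] <- data.frame(
              side = irrow$side,
              repl_start = irrow$start + at$start - 1L,
              repl_end = irrow$start + at$end - 1L,
              at_fraction = at$at_fraction, stringsAsFactors = FALSE)
          }
        }
      }
    }
    el <- if (length(elements)) do.call(rbind, elements) else NULL
    if (!is.null(el) && nrow(el) > 1L) {
      # overlapping elements from different models are the same physical
      # ORB (models of one family, or a model shifted into the flank):
      # keep only the best-scoring element at each locus, across families
      el <- el[order(-el$score, el$repl_start), , drop = FALSE]
      sel <- logical(nrow(el))
      for (k in seq_len(nrow(el))) {
        if (!any(sel & !(el$repl_end < el$repl_start[k] |
                           el$repl_start > el$repl_end[k]) &
                   el$side == el$side[k])) sel[k] <- TRUE
      }
      el <- el[sel, , drop = FALSE]
    }
    at <- if (length(ats)) do.call(rbind, ats) else NULL
    calls[[lt]] <- callOrigin(lt, pass$replicon_id[gi], el, at,
                              gene_strand = pass$strand[gi],
                              max_gap = config$max_pair_gap)
  }

  # stage 5: origin families from initiator identity
  ori <- names(calls)[vapply(calls, callStatus, "") %in% c("candidate", "dual")]
  families <- list()
  if (length(ori) >= 2L) {
    prot <- setNames(pass$aa_sequence[match(ori, pass$locus_tag)], ori)
    genome_of <- setNames(pass$genome_id[match(ori, pass$locus_tag)], ori)
    im <- identityMatrix(prot)
    fams <- clusterFamilies(im, threshold_pct = config$family_threshold_pct)
    families <- withCallingHandlers(
      nameFamilies(fams, genome_of, calls = calls),
      warning = function(w) invokeRestart("muffleWarning"))
    # attach the modal ORB consensus of each family's members
    for (k in seq_along(families)) {
      mem <- familyMembers(families[[k]])$locus_tag
      cons <- unlist(lapply(mem, function(m) {
        o <- callOrbs(calls[[m]])
        if (nrow(o) && "motif_id" %in% names(o))
          motifConsensus(motifs[[o$motif_id[which.max(o$score)]]])
      }))
      if (length(cons))
        families[[k]]@orbConsensus <- names(sort(table(cons),
                                                 decreasing = TRUE))[1]
    }
  }

  # stage 6: mobile-element proximity
  mobility <- do.call(rbind, lapply(calls, function(cl) {
    if (callStatus(cl) == "none") return(NULL)
    r <- repliconOf[[cl@repliconId]]
    ann <- annotateMobility(cl, features(r),
                            window_bp = config$mobility_window_bp)
    data.frame(gene_ref = ann$gene_ref, later_acquired = ann$later_acquired,
               n_mobile = nrow(ann$mobile_genes), stringsAsFactors = FALSE)
  }))

  # stage 7: initiator NJ tree
  tree <- NULL
  if (length(ori) >= 3L) {
    prot <- setNames(pass$aa_sequence[match(ori, pass$locus_tag)], ori)
    tree <- njTree(proteinDistanceMatrix(prot))
  }

  cfgfile <- tempfile(fileext = ".yaml")
  writeRunConfig(config, cfgfile)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfgfile)),
    n_genomes = length(genomes),
    n_replicons = length(repliconOf),
    n_cds = sum(vapply(unlist(genomes, recursive = FALSE),
                       function(r) sum(features(r)$kind == "CDS"), 1L)),
    n_cdc6_pass = nrow(pass),
    n_ori_associated = length(ori),
    n_later_acquired = if (!is.null(mobility)) sum(mobility$later_acquired)
                       else 0L,
    seed = config$seed)
  unlink(cfgfile)

  if (!is.null(out_dir)) {
    genomeOf <- setNames(
      rep(names(genomes), vapply(genomes, length, 1L)),
      unlist(lapply(genomes, function(g) vapply(g, repliconId, ""))))
    writeOriginReport(unname(calls), families, out_dir, mobility = mobility,
                      genomeOf = genomeOf)
  }
  list(hits = allhits, irs = irs, motifs = motifs, calls = calls,
       families = families, mobility = mobility, tree = tree,
       manifest = manifest)
}
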