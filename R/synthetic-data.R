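# Synthetic multi-replicon haloarchaeal genomes with planted ground truth.
# The generator emulates the architecture the pipeline targets: high-GC
# (~62%) circular replicons (chromosome / minichromosome / megaplasmid),
# multiple planted orc/cdc6 genes derived from the seed panel, inverted
# ORB repeat pairs with terminal G-strings flanking AT-rich spacers,
# transposase/integrase genes near a subset of origins, and decoy genes and
# shuffled-ORB intergenic regions without true origins.

DEFAULT_ORB_CONSENSI <- c(
  # the shared halophilic ORB printed for the dual-origin loci
  oriC1 = "TAACAGCGGAAACAGTGGGGTGGGGGGGT",
  oriCa = "ACTCCACAGTGGATCACGAAACTGGGGGGG",
  oriCb = "TTGCAACGTAGATAACCAGTACGGGGGGCT",
  orbX  = "CGAGTAATCGACATTACAGTCAGGGGGGAC")

#' Specification of a synthetic haloarchaeal genome set
#'
#' Bundles every knob of the generator. The defaults define the study
#' conditions used throughout the test-suite: five genomes of three circular
#' replicons each (chromosome 120 kb with 6 initiator genes, minichromosome
#' 60 kb with 4, megaplasmid 25 kb with 1 -- the 6/4/1 split of the
#' best-characterized haloarchaeon), 62 percent GC background, ORB
#' consensi for one universal family (`oriC1`), two partial families
#' (`oriCa`, `oriCb`, each planted in 60 percent of genomes) and a generic
#' family, 5 percent per-base ORB mutation, and roughly a tenth each of
#' deficient and dual loci with a quarter of initiators lacking any origin.
#'
#' @param n_genomes number of genomes.
#' @param replicons list of per-replicon specs: `class`, `length`,
#'   `topology`, `n_cdc6`.
#' @param background_gc background GC fraction.
#' @param orb_consensus named character vector of family ORB consensi; each
#'   must carry a terminal G-string.
#' @param orb_mutation_rate per-base substitution rate applied to planted
#'   ORBs (the terminal G-string positions are left intact: the G-string is
#'   the conserved, diagnostic part of a halophilic ORB).
#' @param family_presence fraction of genomes carrying each non-universal
#'   named family.
#' @param deficient_fraction,dual_fraction,none_fraction fractions of
#'   initiator genes planted as deficient / dual / origin-less; the rest
#'   are candidates.
#' @param mobile_fraction fraction of origin-bearing loci given a
#'   transposase or integrase within the mobility window.
#' @param mobility_window_bp window used when planting mobile genes.
#' @param decoy_gene_density decoy genes per bp (default 1/1500).
#' @param seed integer seed fixing all randomness.
#' @return object of class `SyntheticSpec` (a validated list).
#' @export
syntheticSpec <- function(n_genomes = 5L,
                          replicons = list(
                            list(class = "chromosome", length = 120000L,
                                 topology = "circular", n_cdc6 = 6L),
                            list(class = "minichromosome", length = 60000L,
                                 topology = "circular", n_cdc6 = 4L),
                            list(class = "megaplasmid", length = 25000L,
                                 topology = "circular", n_cdc6 = 1L)),
                          background_gc = 0.62,
                          orb_consensus = DEFAULT_ORB_CONSENSI,
                          orb_mutation_rate = 0.05,
                          family_presence = c(oriCa = 0.6, oriCb = 0.6),
                          deficient_fraction = 0.1,
                          dual_fraction = 0.1,
                          none_fraction = 0.27,
                          mobile_fraction = 0.4,
                          mobility_window_bp = 10000L,
                          decoy_gene_density = 1 / 1500,
                          seed = 1L) {
  spec <- list(n_genomes = as.integer(n_genomes), replicons = replicons,
               background_gc = background_gc, orb_consensus = orb_consensus,
               orb_mutation_rate = orb_mutation_rate,
               family_presence = family_presence,
               deficient_fraction = deficient_fraction,
               dual_fraction = dual_fraction, none_fraction = none_fraction,
               mobile_fraction = mobile_fraction,
               mobility_window_bp = as.integer(mobility_window_bp),
               decoy_gene_density = decoy_gene_density,
               seed = as.integer(seed))
  probs <- c(orb_mutation_rate, deficient_fraction, dual_fraction,
             none_fraction, mobile_fraction, family_presence)
  stopifnot(all(probs >= 0), all(probs <= 1),
            background_gc > 0, background_gc < 1,
            all(vapply(replicons, `[[`, 1L, "length") >= 20000L))
  for (cons in orb_consensus) {
    if (is.null(detectGString(cons)))
      stop("every planted ORB consensus must carry a terminal G-string")
  }
  class(spec) <- "SyntheticSpec"
  spec
}

randomDnaGC <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES4, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

randomDnaAT <- function(n, at = 0.8) randomDnaGC(n, 1 - at)

#' Mutate a DNA sequence by i.i.d. substitution
#'
#' Each position independently substitutes to a uniformly chosen different
#' base with probability `rate`. Deterministic given `seed`; positions in
#' `protect` are never touched.
#'
#' @param seq DNA string.
#' @param rate per-base substitution probability in `[0, 1]`.
#' @param seed optional integer seed (uses the current RNG stream if NULL).
#' @param protect integer positions exempt from mutation.
#' @return mutated DNA string.
#' @export
mutateSequence <- function(seq, rate, seed = NULL, protect = integer()) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  v <- strsplit(seq, "")[[1]]
  hit <- runif(length(v)) < rate
  hit[protect] <- FALSE
  for (i in which(hit & v %in% DNA_BASES4)) {
    v[i] <- sample(setdiff(DNA_BASES4, v[i]), 1L)
  }
  paste(v, collapse = "")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

mutateProtein <- function(aa, rate, protect = integer()) {
  v <- strsplit(aa, "")[[1]]
  hit <- runif(length(v)) < rate
  hit[protect] <- FALSE
  for (i in which(hit)) v[i] <- sample(setdiff(AA20, v[i]), 1L)
  paste(v, collapse = "")
}

walkerSpan <- function(aa) {
  m <- regexpr("[AG].{4}GK[ST]", aa, perl = TRUE)
  if (m[1] > 0) m[1]:(m[1] + attr(m, "match.length") - 1L) else integer()
}

# Inverse genetic-code map (table 11) with GC-biased codon weights so planted
# CDSs match the background composition instead of forming GC islands.
codonTables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc11 <- Biostrings::getGeneticCode("11")
      cache <<- split(names(gc11), gc11)
    }
    cache
  }
})

reverseTranslate <- function(aa, gc = 0.62) {
  tab <- codonTables()
  v <- strsplit(aa, "")[[1]]
  out <- character(length(v))
  for (i in seq_along(v)) {
    codons <- tab[[v[i]]]
    ngc <- vapply(strsplit(codons, ""), function(x) sum(x %in% c("G", "C")), 1L)
    wt <- gc^ngc * (1 - gc)^(3L - ngc)
    out[i] <- sample(codons, 1L, prob = wt)
  }
  stopcodons <- tab[["*"]]
  paste0(paste(out, collapse = ""), sample(stopcodons, 1L))
}

randomProtein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Plant an ORB: mutate the family consensus everywhere except the terminal
# G-string positions.
plantOrb <- function(consensus, rate) {
  g <- detectGString(consensus)
  protect <- if (!is.null(g)) g$offset:(g$offset + g$run_length - 1L) else integer()
  mutateSequence(consensus, rate, protect = protect)
}

shuffleSeq <- function(seq) {
  paste(sample(strsplit(seq, "")[[1]]), collapse = "")
}

# Build the per-genome gene plan: status + family of each initiator gene.
planGenome <- function(spec, genome_index) {
  n <- sum(vapply(spec$replicons, `[[`, 1L, "n_cdc6"))
  n_dual <- round(spec$dual_fraction * n)
  n_def <- round(spec$deficient_fraction * n)
  n_none <- round(spec$none_fraction * n)
  n_cand <- n - n_dual - n_def - n_none
  if (n_cand < 0) { n_none <- n_none + n_cand; n_cand <- 0L }
  status <- c(rep("dual", n_dual), rep("deficient", n_def),
              rep("none", n_none), rep("candidate", n_cand))[seq_len(n)]

  named <- names(spec$family_presence)
  here <- named[vapply(named, function(f) {
    carriers <- ceiling(spec$family_presence[[f]] * spec$n_genomes)
    # deterministic rotation so subsets differ between the named families
    shift <- match(f, named)
    genome_index %in% (((seq_len(carriers) - 1L + shift) %% spec$n_genomes) + 1L)
  }, TRUE)]
  fam <- rep("orbX", n)
  fam[status %in% c("none", "deficient")] <- "orbX"
  cand_idx <- which(status == "candidate")
  want <- c(if ("oriC1" %in% names(spec$orb_consensus)) "oriC1", here)
  for (k in seq_along(want)) {
    if (k <= length(cand_idx)) fam[cand_idx[k]] <- want[k]
  }
  data.frame(status = status, family = fam, stringsAsFactors = FALSE)
}

#' Generate one synthetic genome with ground truth
#'
#' Assembles each replicon left to right: background sequence at the target
#' GC, decoy CDSs, planted orc/cdc6 CDSs (seed-panel proteins mutated at
#' 10-45 percent of residues, Walker-A intact, reverse-translated with
#' GC-matched codons) and, for origin-bearing loci, intergenic regions
#' carrying the planted evidence (candidate: inverted mutated-consensus ORB
#' pair around a 60-120 bp AT-rich spacer; deficient: one same-orientation
#' ORB in each flanking IR; dual: independent pairs of two distinct
#' families on the two sides). Decoy IRs occasionally receive shuffled-ORB
#' sequences (same composition, destroyed order). A transposase or
#' integrase decoy is re-annotated near the planted fraction of origins.
#'
#' @param spec a [syntheticSpec()].
#' @param genome_index 1-based genome number (determines family presence).
#' @param seeds seed protein panel (default the packaged synthetic panel).
#' @return list with `genome_id`, `replicons` (list of [Replicon-class]),
#'   and `truth` (data.frame: one row per planted initiator gene with
#'   status, family, ORB/AT coordinates and mobile-element flag).
#' @export
generateGenome <- function(spec, genome_index, seeds = readSeedPanel()) {
  genome_id <- paste0("genome", genome_index)
  plan <- withStageSeed(spec$seed, paste0("plan-", genome_index),
                        planGenome(spec, genome_index))
  # persistent family ancestor proteins shared across genomes
  fam_names <- names(spec$orb_consensus)
  ancestors <- withStageSeed(spec$seed, "family-ancestors", {
    setNames(lapply(seq_along(fam_names), function(k) {
      seeds[[((k - 1L) %% length(seeds)) + 1L]]
    }), fam_names)
  })

  withStageSeed(spec$seed, paste0("generate-", genome_index), {
    gi <- 0L  # running gene index within the plan
    replicons <- list()
    truth <- list()
    rep_short <- c(chromosome = "chr", minichromosome = "chrII",
                   megaplasmid = "meg", plasmid = "pls", unknown = "rep")
    for (ri in seq_along(spec$replicons)) {
      rspec <- spec$replicons[[ri]]
      rid <- paste0(genome_id, "_", rep_short[[rspec$class]])
      L <- rspec$length
      genes <- plan[gi + seq_len(rspec$n_cdc6), , drop = FALSE]
      gi <- gi + rspec$n_cdc6

      reserved <- rspec$n_cdc6 * 2500L + 2000L
      nd <- min(round(L * spec$decoy_gene_density),
                floor((L - reserved) / 1700))
      slots <- rep("decoy", nd)
      # initiators spaced with at least one decoy between them so every
      # planted IR is private to its gene
      if (rspec$n_cdc6 > 0L) {
        anchor <- floor(seq(1L, nd, length.out = rspec$n_cdc6 + 1L))
        cpos <- vapply(seq_len(rspec$n_cdc6), function(k) {
          lo <- anchor[k] + 1L; hi <- max(lo, anchor[k + 1L] - 1L)
          sample(lo:hi, 1L)
        }, 1L)
        ord <- character(nd + rspec$n_cdc6)
        ord[cpos + seq_len(rspec$n_cdc6) - 1L] <- paste0("cdc6_", seq_len(rspec$n_cdc6))
        ord[ord == ""] <- "decoy"
        slots <- ord
      }

      chunks <- character()
      cursor <- 0L
      feats <- list()
      addChunk <- function(s) {
        chunks[[length(chunks) + 1L]] <<- s
        cursor <<- cursor + nchar(s)
      }
      addFeature <- function(locus_tag, kind, len, strand, product) {
        feats[[length(feats) + 1L]] <<- makeFeatureTable(
          locus_tag, kind, cursor + 1L, cursor + len, strand, product)
      }
      bg <- function(n) randomDnaGC(n, spec$background_gc)

      ndec <- 0L
      for (sl in slots) {
        if (sl == "decoy") {
          gap <- sample(150:450, 1L)
          if (runif(1) < 0.15) {
            # shuffled-ORB decoy IR: same composition, destroyed order
            cons <- spec$orb_consensus[[sample(length(spec$orb_consensus), 1L)]]
            addChunk(paste0(bg(gap %/% 2), shuffleSeq(cons), bg(gap %/% 2)))
          } else addChunk(bg(gap))
          ndec <- ndec + 1L
          aa <- randomProtein(sample(150:400, 1L))
          dna <- reverseTranslate(aa, spec$background_gc)
          strand <- sample(c("+", "-"), 1L)
          if (strand == "-") dna <- revcompChr(dna)
          addFeature(sprintf("%s_d%03d", rid, ndec), "CDS", nchar(dna),
                     strand, "hypothetical protein")
          addChunk(dna)
        } else {
          k <- as.integer(sub("cdc6_", "", sl))
          g <- genes[k, ]
          tag <- sprintf("%s_cdc6_%02d", rid, k)
          strand <- sample(c("+", "-"), 1L)
          # protein for this initiator
          aa <- if (g$status == "candidate" && g$family %in% fam_names &&
                    g$family != "orbX") {
            mutateProtein(ancestors[[g$family]], 0.08,
                          protect = walkerSpan(ancestors[[g$family]]))
          } else {
            # outside the named families: diverged well below the 80
            # percent family threshold but still within seed-panel reach
            sd <- seeds[[sample(length(seeds), 1L)]]
            mutateProtein(sd, runif(1, 0.28, 0.45), protect = walkerSpan(sd))
          }
          dna <- reverseTranslate(aa, spec$background_gc)
          if (strand == "-") dna <- revcompChr(dna)

          cons_main <- spec$orb_consensus[[if (g$family %in% fam_names)
            g$family else "orbX"]]
          other <- setdiff(fam_names, g$family)
          cons_alt <- spec$orb_consensus[[other[sample(length(other), 1L)]]]

          orb_lo <- NA_integer_; orb_hi <- NA_integer_
          at_lo <- NA_integer_; at_hi <- NA_integer_
          plantPair <- function(cons) {
            # returns chunk; records coordinates via closure
            p1 <- bg(sample(60:100, 1L))
            o1 <- plantOrb(cons, spec$orb_mutation_rate)
            atl <- sample(60:120, 1L)
            at <- randomDnaAT(atl)
            o2 <- revcompChr(plantOrb(cons, spec$orb_mutation_rate))
            p2 <- bg(sample(60:100, 1L))
            s1 <- cursor + nchar(p1) + 1L
            orb_lo <<- min(orb_lo, s1, na.rm = TRUE)
            orb_hi <<- max(orb_hi, s1 + nchar(o1) + atl + nchar(o2) - 1L,
                           na.rm = TRUE)
            at_lo <<- min(at_lo, s1 + nchar(o1), na.rm = TRUE)
            at_hi <<- max(at_hi, s1 + nchar(o1) + atl - 1L, na.rm = TRUE)
            paste0(p1, o1, at, o2, p2)
          }
          plantSingle <- function(cons) {
            p1 <- bg(sample(80:140, 1L))
            o1 <- plantOrb(cons, spec$orb_mutation_rate)
            p2 <- bg(sample(80:140, 1L))
            s1 <- cursor + nchar(p1) + 1L
            orb_lo <<- min(orb_lo, s1, na.rm = TRUE)
            orb_hi <<- max(orb_hi, s1 + nchar(o1) - 1L, na.rm = TRUE)
            paste0(p1, o1, p2)
          }

          if (g$status == "candidate") {
            addChunk(plantPair(cons_main))
            addFeature(tag, "CDS", nchar(dna), strand,
                       "orc/cdc6 replication initiator protein")
            addChunk(dna)
          } else if (g$status == "dual") {
            addChunk(plantPair(cons_main))
            addFeature(tag, "CDS", nchar(dna), strand,
                       "orc/cdc6 replication initiator protein")
            addChunk(dna)
            addChunk(plantPair(cons_alt))
            addChunk(bg(sample(120:240, 1L)))
          } else if (g$status == "deficient") {
            addChunk(plantSingle(cons_main))
            addFeature(tag, "CDS", nchar(dna), strand,
                       "orc/cdc6 replication initiator protein")
            addChunk(dna)
            addChunk(plantSingle(cons_main))
            addChunk(bg(sample(120:240, 1L)))
          } else {
            addChunk(bg(sample(200:450, 1L)))
            addFeature(tag, "CDS", nchar(dna), strand,
                       "orc/cdc6 replication initiator protein")
            addChunk(dna)
          }
          # initiator-identity family of this gene: named-family members
          # share a mutated ancestor; all other initiators are planted as
          # unrelated proteins, so each is its own singleton family
          fam_id <- if (g$status != "candidate") NA_character_
            else if (g$family == "orbX") paste0("solo_", tag)
            else g$family
          truth[[length(truth) + 1L]] <- data.frame(
            genome_id = genome_id, replicon_id = rid, locus_tag = tag,
            is_cdc6 = TRUE, family_id = fam_id,
            origin_status = g$status,
            orb_start = orb_lo, orb_end = orb_hi,
            at_start = at_lo, at_end = at_hi,
            mobile_nearby = FALSE, stringsAsFactors = FALSE)
        }
      }
      if (cursor < L) addChunk(bg(L - cursor))
      ft <- do.call(rbind, feats)
      seqchr <- paste(chunks, collapse = "")

      # plant mobile elements near the planned fraction of origins
      tr <- do.call(rbind, truth)
      mine <- which(tr$replicon_id == rid &
                      tr$origin_status %in% c("candidate", "dual", "deficient"))
      n_mob <- round(spec$mobile_fraction * length(mine))
      if (n_mob > 0L) {
        sel <- sample(mine, n_mob)
        for (t in sel) {
          lo <- tr$orb_start[t]; hi <- tr$orb_end[t]
          dec <- which(ft$product == "hypothetical protein")
          dist <- pmax(0L, pmax(ft$start[dec] - hi, lo - ft$end[dec]))
          ok <- dec[dist <= spec$mobility_window_bp * 0.8]
          if (length(ok)) {
            pick <- ok[sample(length(ok), 1L)]
            ft$product[pick] <- sample(c("ISH3 family transposase",
                                         "site-specific integrase"), 1L)
          }
        }
      }
      # record actual mobile proximity for every planted origin
      mobpat <- "(?i)transposase|integrase"
      mob <- ft[grepl(mobpat, ft$product, perl = TRUE), , drop = FALSE]
      for (t in seq_along(truth)) {
        if (truth[[t]]$replicon_id != rid ||
            is.na(truth[[t]]$orb_start)) next
        if (nrow(mob)) {
          dist <- pmax(0L, pmax(mob$start - truth[[t]]$orb_end,
                                truth[[t]]$orb_start - mob$end))
          truth[[t]]$mobile_nearby <- any(dist <= spec$mobility_window_bp)
        }
      }

      replicons[[length(replicons) + 1L]] <- Replicon(
        rid, seqchr, topology = rspec$topology,
        repliconClass = rspec$class, features = ft)
    }
    list(genome_id = genome_id, replicons = replicons,
         truth = do.call(rbind, truth))
  })
}

#' Generate the full synthetic genome set
#'
#' Runs [generateGenome()] for every genome of the spec and optionally
#' writes GenBank, GFF3 and ground-truth TSV files.
#'
#' @param spec a [syntheticSpec()].
#' @param out_dir optional output directory.
#' @param seeds seed protein panel.
#' @return list with `genomes` (list of per-genome results) and `truth`
#'   (combined data.frame).
#' @export
generateGenomeSet <- function(spec, out_dir = NULL, seeds = readSeedPanel()) {
  genomes <- lapply(seq_len(spec$n_genomes), function(i)
    generateGenome(spec, i, seeds = seeds))
  truth <- do.call(rbind, lapply(genomes, `[[`, "truth"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (g in genomes) {
      writeGenBank(g$replicons, file.path(out_dir, paste0(g$genome_id, ".gbk")))
      writeGFF3(g$replicons, file.path(out_dir, paste0(g$genome_id, ".gff3")))
    }
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(genomes = genomes, truth = truth)
}

#' Write replicon annotations as GFF3
#'
#' @param replicons list of [Replicon-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGFF3 <- function(replicons, path) {
  lines <- "##gff-version 3"
  for (r in replicons) {
    ft <- features(r)
    if (!nrow(ft)) next
    lines <- c(lines, sprintf(
      "%s\thaloriscan\t%s\t%d\t%d\t.\t%s\t%s\tID=%s;locus_tag=%s;product=%s",
      repliconId(r), ft$kind, ft$start, ft$end, ft$strand,
      ifelse(ft$kind == "CDS", "0", "."), ft$locus_tag, ft$locus_tag,
      gsub("[;=]", " ", ft$product)))
  }
  writeLines(lines, path)
  invisible(path)
}

randIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2L) return(1)
  agree <- 0L
  tot <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    tot <- tot + 1L
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  }
  unname(agree / tot)
}

#' Compare pipeline calls against planted ground truth
#'
#' Per-status confusion matrix and precision/recall, plus the Rand index of
#' the predicted family partition against the planted one (over genes with
#' a planted family that were called origin-associated).
#'
#' @param calls list of [OriginCall-class] (or data.frame with `locus_tag`
#'   and `status` columns).
#' @param truth ground-truth data.frame from [generateGenome()].
#' @param families optional list of [OriginFamily-class] for the Rand
#'   index.
#' @return list with `confusion` (truth x called matrix), `per_status`
#'   (data.frame of precision/recall per status), and `rand_index` (NA
#'   without `families`).
#' @export
truthCompare <- function(calls, truth, families = NULL) {
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- data.frame(locus_tag = vapply(calls, callGene, ""),
                        status = vapply(calls, callStatus, ""),
                        stringsAsFactors = FALSE)
  }
  lv <- c("candidate", "deficient", "dual", "none")
  called <- setNames(rep("none", nrow(truth)), truth$locus_tag)
  shared <- intersect(calls$locus_tag, truth$locus_tag)
  called[shared] <- calls$status[match(shared, calls$locus_tag)]
  confusion <- table(truth = factor(truth$origin_status, lv),
                     called = factor(called, lv))
  per_status <- do.call(rbind, lapply(lv, function(s) {
    tp <- confusion[s, s]
    prec <- if (sum(confusion[, s]) > 0) tp / sum(confusion[, s]) else NA_real_
    rec <- if (sum(confusion[s, ]) > 0) tp / sum(confusion[s, ]) else NA_real_
    data.frame(status = s, precision = prec, recall = rec)
  }))
  rand <- NA_real_
  if (!is.null(families)) {
    memb <- unlist(lapply(families, function(f) {
      setNames(rep(familyName(f), nrow(familyMembers(f))),
               familyMembers(f)$locus_tag)
    }))
    tg <- truth[!is.na(truth$family_id) & truth$locus_tag %in% names(memb), ]
    if (nrow(tg) >= 2L)
      rand <- randIndex(tg$family_id, memb[tg$locus_tag])
  }
  list(confusion = confusion, per_status = per_status, rand_index = rand)
}
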