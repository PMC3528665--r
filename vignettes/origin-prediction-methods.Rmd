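---
title: "Predicting orc/cdc6-associated replication origins in haloarchaea: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting orc/cdc6-associated replication origins in haloarchaea: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological problem

Haloarchaeal genomes are multi-replicon: a main chromosome plus
minichromosomes and megaplasmids, together carrying ten or more copies of
the replication-initiator gene *orc/cdc6*. Archaeal replication origins
are marked by a conserved architecture: inverted ORB repeats (origin
recognition boxes, roughly 20-40 bp, bound by the Orc/Cdc6 protein)
flanking an AT-rich duplex unwinding element, located in an intergenic
region directly adjacent to an *orc/cdc6* gene. In halophilic archaea the
ORB additionally carries a "G-string", a long run of G at one end of the
element, which stands out sharply against the ~62 % GC background of these
genomes. `haloriscan` turns that architecture into an explicit, tested
prediction pipeline: screen the proteome for origin-associated Orc/Cdc6
homologs, examine the flanking intergenic regions (IRs) for ORB-like
motifs, classify each initiator locus, group origins into families by
initiator identity, and flag likely later-acquired origins by
mobile-element proximity.

## Pipeline stages and their models

### Initiator screen (`screenProteome`)

Every CDS is translated with the bacterial/archaeal genetic code (table
11) and kept when it (a) exceeds 300 aa, (b) aligns locally
(Smith-Waterman, BLOSUM62, affine gaps 11/1) to at least one seed
initiator at >= 30 % identity over >= 150 aligned residues, and (c)
carries a Walker-A P-loop (`[AG]-x(4)-G-K-[ST]`) entirely within its
N-terminal 60 %, the operational signature of the AAA+ module. A soft
winged-helix score (helix-former enrichment of the C-terminal 100
residues through a logistic) is reported but never gates a hit, because
winged-helix evidence in this setting rests on homology rather than an
explicit structural test. The identity/coverage thresholds are a
deterministic replacement for a database-size-dependent e-value cutoff:
they are reproducible offline and exposed in the configuration.
`profileRescreen` optionally builds a position-specific profile from the
passing set (each member globally aligned to the anchor seed) and admits
divergent members that fall below the pairwise cutoff but match the
family profile (mean log2-odds >= 1 per aligned column over >= 150
columns), iterated to a fixed point.

### ORB discovery (`discoverMotifs`): ZOOPS EM

Motif discovery is a ZOOPS ("zero or one occurrence per sequence")
finite-mixture model fitted by EM over both strands, the classic
formulation: each IR either contains no occurrence (probability
`1 - gamma`) or exactly one, uniform over candidate sites; site
likelihoods are products of position-specific base frequencies against a
0-order background estimated from the IRs (strand-symmetrized). The
E-step computes posterior site responsibilities, the M-step re-estimates
the frequency matrix with a pseudo-count of 0.5 and updates `gamma`;
iteration stops when the relative change of the log-likelihood falls
below 1e-6 or after 60 iterations. Widths are searched on a grid
(20-40 bp bounds; the pipeline default is {25, 30, 35}).

Three design choices matter in practice and were settled during
development on synthetic data:

* **Seeding.** Uniform random restarts almost never initialize on a true
  motif instance, because instances are a vanishing fraction of candidate
  sites. Restarts are therefore seeded from sites containing repeated
  8-mers (multiplicity-weighted sampling), the cheap analogue of a full
  starting-point search; initial frequency matrices put 0.8 on the seed
  base per column. The best model per width is then phase-refined: a
  model locked a few columns off the motif is a local optimum whose
  shifted-in columns read background, so EM is re-run from
  column-shifted starts (up to +/- 3) until no shift improves the
  likelihood.
* **Candidate-site restriction.** Within the pipeline the site space is
  restricted to windows containing a G-run of at least `min_g_run` (5)
  bases. A window without a G-run can never yield a qualifying
  haloarchaeal ORB, and the restriction prevents the AT-rich unwinding
  elements -- which are themselves strong recurring "motifs" -- from
  dominating the search. `discoverMotifs` itself defaults to the
  unrestricted space.
* **Multiple motifs.** Distinct ORB families are recovered sequentially:
  the dominant model is reported, its confident occurrences (score >=
  0.55 of the model maximum; a laxer threshold would erase other
  families' G-rich elements) are masked with N, and discovery repeats.
  Models whose information content is concentrated in a handful of G
  columns (fewer than half the columns reaching 1 bit of relative
  entropy) are rejected per restart: after real families are exhausted,
  the highest-likelihood "motif" is a diffuse background-G-run model,
  and likelihood alone cannot distinguish it from a rare true family.
  A reported model must additionally leave at least four confident
  occurrences (>= 55 % of its maximum score) across the IRs: a model
  that memorized two or three chance-similar background windows has
  high per-column information but no recurrence, and is masked without
  being reported. An empty round is retried once with fresh restarts
  before discovery stops.

### Scanning, G-strings, pairing, AT-rich elements

IRs are scanned on both strands with each model's log2-odds matrix;
sites at or above 30 % of the model's maximum achievable score are kept,
greedily non-overlapping, and overlapping elements from different models
are collapsed to the best-scoring one (they are the same physical ORB).
An element qualifies only if it carries a G-string: a G-run of >= 5
bases ending within 10 bp of either element end, defaults motivated by
the 7-G terminal run of the ORB element shared between the two known
dual-origin loci; both ends are accepted because the literature does not
fix the end. Inverted pairs are formed by greedy maximum-score matching
of forward with reverse occurrences separated by at most 400 bp. The
AT-rich element is the best merged run of 50-bp windows whose AT
fraction exceeds background AT by 0.15 (an invented, reported margin),
with background composition estimated per replicon -- IRs are too short
to be their own null.

### Origin calls (`callOrigin`)

Statuses are evaluated dual -> candidate -> deficient -> none over the
qualifying (G-string-bearing) elements grouped by motif family (families
being models whose consensi differ by more than a quarter of the width):

* *candidate*: an inverted pair within one IR, or both flanking IRs
  occupied with opposite orientations between the sides (an inverted
  configuration around the gene), or both IRs occupied with at least two
  elements on one side.
* *dual*: two motif families independently satisfying the candidate
  rule -- the two-different-ORB-sets configuration seen at single loci
  on a megaplasmid and a chromosome in published genomes.
* *deficient*: qualifying ORBs present but no family satisfies the rule.
  This generalizes the published exemplar -- exactly one ORB-like
  element in each flanking IR, same orientation, no pair -- which this
  rule set classifies as deficient while still accepting genuine
  both-sided origins.
* *none*: no qualifying ORB.

The single-ORB-per-IR ambiguity deserves a note: a literal "ORBs in both
IRs" candidate rule would also accept the published deficient exemplar.
The resolution here -- requiring an inverted relationship or a
multi-element side for the both-IR layout -- keeps both published
configurations on their printed sides of the line.

### Families, naming, trees, mobility

Origin-associated initiators (status candidate or dual) are clustered by
single linkage at >= 80 % pairwise local-alignment identity. Identities
are only counted over alignments covering >= 100 residues: a short
perfect match to a shared catalytic motif is not family-wide homology,
and without the coverage floor single-linkage chains every family
together. Single linkage is the honest reading of grouping by pairwise
"high identities"; chaining remains its known caveat. The family present
in every input genome is named `oriC1` (ancestral); the two largest
remaining families become `oriCa` and `oriCb`; the rest are `F3, F4, ...`.
Trees are Saitou-Nei neighbor joining (via `ape::nj`, negative branch
lengths clamped to zero) on Poisson-corrected distances
(`-ln(1 - p)` over ungapped columns of pairwise global alignments),
the distance-based substitute for a likelihood phylogeny; topology-level
statements are the only ones the package makes. An origin is flagged
later-acquired when a feature annotated as transposase, integrase,
insertion sequence or ISH lies within 10 kb of the origin interval;
"nearby" is undefined in the source literature, so the window is a
configurable, reported default.

## The synthetic genome generator

`generateGenome` builds the study conditions every stage is tested
against: circular replicons at 62 % GC (chromosome / minichromosome /
megaplasmid with a 6/4/1 initiator split, mirroring the
best-characterized haloarchaeon), planted initiator CDSs
(seed-panel proteins mutated at 8 % within named families and 28-45 %
outside them, Walker-A intact, reverse-translated with GC-matched
codons so coding regions do not form composition islands), candidate
origins as inverted mutated-consensus ORB pairs around 60-120 bp AT-rich
spacers, deficient loci as one same-orientation ORB per flanking IR,
dual loci as two distinct-family pairs on the two sides, shuffled-ORB
decoy IRs, and transposase/integrase genes re-annotated near 40 % of
origins. The packaged seed panel is synthetic (eight Orc/Cdc6-like
proteins, >300 aa, N-terminal Walker-A), constructed from a fixed seed
because a curated panel of real initiator sequences cannot ship with the
package; it is labelled synthetic everywhere it appears.

Two generator choices are deliberate model simplifications. The terminal
G-string positions are exempt from ORB mutation: the G-string is the
conserved diagnostic feature of halophilic ORBs, and mutating it at the
background rate would make the planted truth itself ambiguous. And
planted families are defined by fixed consensus strings with i.i.d.
substitution -- real ORB families drift with position-dependent
constraint, and real IRs contain structure (promoters, terminators) that
i.i.d. background lacks. Passing tests on these genomes therefore
demonstrates that the machinery recovers the planted architecture under
calibrated noise, not that real-genome accuracy equals the measured
numbers.

## Problem sizes and determinism

All randomness flows from one run seed, forked per stage by fixed labels
(`stageSeed`), so a stage keeps its stream when other stages change and
identical configurations reproduce byte-identical outputs. The test
suite and the acceptance script run the full pipeline on single-genome
instances of the default architecture (60/40/20 kb replicons, 11
initiators) and multi-genome runs at five genomes of ~205 kb total; the
family-naming property is exercised at fifteen genomes on
initiator sets directly. These sizes were chosen so the whole suite runs
on a laptop in minutes while every planted family still has enough
instances (>= 6 pooled occurrences) for the motif stage to see.

## Known limitations

* Origins without ORB-like elements, or not adjacent to an *orc/cdc6*
  gene, are invisible to this design -- as they are to the architecture
  rule it implements.
* ARS activity (which predicted origins actually fire, versus remain
  dormant) is not computable from sequence here and is out of scope.
* Single-linkage families can chain; the coverage floor removes the
  short-alignment route, but genuinely intermediate initiators will
  still merge families.
* The ZOOPS stage assumes at most one occurrence per IR per family;
  tandem ORB arrays contribute only their best instance to model
  fitting (scanning still reports all of them).
* Counts on real genomes shift with annotation vintage: the gene calls
  define the IRs, and the published tallies depended on manual curation
  this package replaces with explicit thresholds.
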