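---
title: "Methods: detecting and curating CRISPR-Cas loci on plasmid communities"
author: "crisprmob"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and curating CRISPR-Cas loci on plasmid communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprmob)
```

## The problem

Plasmids are not just cargo for CRISPR-Cas immune systems — a measurable
fraction of natural plasmids carry complete CRISPR-Cas loci, orphan
arrays, or solo *cas* operons, and the spacer content of those arrays is
strongly biased towards *other plasmids* rather than viruses. Surveying
this mobilome-encoded immunity requires three things that generic CRISPR
finders do not provide: aggressive curation of false-positive tandem
repeats (plasmids are rich in iterons and transposon-associated
repeats), assembly of arrays and *cas* operons into loci across the
often-fragmented plasmid gene landscape, and targeting statistics that
respect the replicon (plasmid vs chromosome) and host-taxonomy structure
of the community.

`crisprmob` implements this survey as a reusable, fully tested pipeline
on arbitrary replicon FASTA + annotation input, and ships a synthetic
community generator with planted ground truth so that every stage can be
validated end to end.

## Array detection

`find_candidate_arrays()` is a CRT-style detector. An exact *k*-mer
(default *k* = 11) that recurs at a distance compatible with one
repeat-plus-spacer period (unit length 18-55 bp, spacer 15-80 bp) seeds
a repeat unit. The seed pair is extended by an X-drop rule (match +1,
mismatch -2, drop 4) so isolated substitutions between repeat copies do
not truncate the unit, capped so the remaining gap stays a legal spacer.
The unit is then chained greedily in both directions: the next
occurrence within spacer distance needs >= 80% Hamming identity, and the
*closest* qualifying occurrence wins, which keeps tandem decoys with
conserved linkers from skipping periods. Finally the unit register is
widened column-wise while at least two thirds of units agree with the
column majority (with a one-column look-ahead across isolated mutated
columns), and terminal columns with < 50% consensus agreement are
trimmed. Overlapping candidates are resolved by more repeats, then
longer span, then leftmost. Two-repeat candidates are kept at this
stage: they are excluded from every analysis, but their genomic
footprint must still be masked before spacer matching.

The 80% chaining threshold sits deliberately *below* the 70%
repeat-conservation curation threshold so that curation, not detection,
arbitrates borderline arrays. Detection runs on the forward strand only;
repeat periodicity is strand-symmetric, so reverse-orientation arrays
are found identically and all reported sequences are forward-strand.

## Curation: quarantine, rescue, secondary search

Candidates that are not high-confidence are quarantined only if they
clear four conservative filters, evaluated in a fixed order and with
strict boundary semantics:

1. average repeat conservation across the array > 70% — mean fraction
   of consensus positions matched per repeat, positions beyond a
   shorter repeat counting as mismatches;
2. spacer conservation < 50% — mean pairwise global-alignment identity
   over all spacer pairs;
3. standard error of the mean of spacer lengths < 3 (sample SD over
   the square root of n);
4. no overlap with an ORF of prediction confidence >= 90 (inclusive).

A failing array is *rejected*, with the first failing filter as the
recorded reason. Quarantined arrays are *rescued* when a *cas* gene on
the same replicon lies within 1 kb (edge-to-edge; overlap counts as
zero distance) or when the consensus repeat matches a trusted
high-confidence repeat at >= 95% identity over >= 95% of the trusted
repeat's length on either strand. Arrays that stay quarantined are
dropped. A secondary search then looks for arrays the detector missed:
every trusted repeat is searched (both strands, edit distance at most
5% of its length) against the community sequences with all previously
detected arrays masked; hits within 100 bp are clustered by single
linkage, clusters with fewer than three hits are discarded, and the
survivors become arrays whose inter-hit segments are the spacers.
Arrays with fewer than three repeats are excluded from all analyses.

### Two identity conventions

The survey needs two different notions of sequence identity, and the
package keeps them explicit rather than hiding one behind the other:

* **Spacer conservation** (a *diversity* metric) uses match-only global
  alignment: match scores 1, mismatch and gap score 0, gap open equals
  gap extend, and residues are paired only when they match, so identity
  equals `matches / alignment columns = L / (na + nb - L)` with `L` the
  longest-common-subsequence length. Unrelated random spacers score
  roughly 40-45% under this convention — safely below the 50% filter —
  while near-identical iteron linkers score near 100%. A convention that
  paired mismatching residues would let spurious gapped matching push
  random spacers above 50%.
* **Repeat-vs-repeat similarity** (the 85% association rule, the 95/95
  trusted-repeat rules) uses edit-distance-based alignment identity
  (`matches / alignment columns` of a unit-cost global alignment, via
  `adist`), so a repeat differing by substitutions at 4% of sites scores
  96%. For the 95/95 trusted-repeat rule the comparison is local
  (Smith-Waterman, +1/-1/-1) so a consensus whose detector boundary
  over-runs the repeat by a column or two is not penalised; coverage is
  measured on the trusted repeat.

A consequence worth stating: under the match-only convention, the
high-confidence evidence tier below is intentionally conservative.

### Evidence levels

External detectors report opaque confidence tiers; the package defines
an explicit surrogate so the keep/quarantine split is testable. Level 4
(kept automatically) requires >= 4 spacers, repeat conservation > 90,
spacer conservation < 20, spacer-length SEM < 3 and no high-confidence
ORF overlap. The last two conditions were added so that the
high-confidence tier is a strict subset of filter-passing arrays —
without them, a transposon-tandem false positive (conserved units,
diverse variable-length linkers) could reach level 4 and bypass curation
entirely. Because random spacers score ~40% under the match-only
identity, the < 20% condition makes level 4 rare on synthetic data; the
rescue rules, not the auto-keep path, carry true-array retention, which
is the conservative behaviour we want from a false-positive filter.
Level 3 means all four filters pass; level 2 at least two; level 1
otherwise.

## Locus assembly

Arrays closer than 10 kb (strict, edge-to-edge) to the nearest *cas*
operon on the same replicon are linked to it; ties go to the leftmost
operon. Unlinked arrays are associated with (typed by, but not merged
into) an operon's locus when their consensus repeat is at least 85%
identical, either strand, to the repeat of an operon-adjacent array;
the best identity wins, preferring a same-replicon operon, then the
leftmost. Everything else becomes an orphan array or orphan *cas*
locus. Loci are summarised per replicon with completeness counts, a
multi-system flag (two or more operon-bearing loci, labelled with the
type combination, e.g. "I+IV") and the adaptation-module flag (both
*cas1* and *cas2* in the operon gene list). The 10 kb and 85% cutoffs
are taken as given survey parameters; their upstream derivation is out
of scope here.

## Prevalence and enrichment statistics

`prevalence()` reports, per locus category and replicon class, the
fraction of replicons carrying at least one locus and the mean per-Mbp
count (count x 1e6 / replicon length, averaged over replicons) — the
length correction matters because chromosomes are 1-2 orders of
magnitude longer than plasmids.

`indval()` implements a binary indicator-value analysis: for subtype
*j* and group *k* with `a_k` presences among `n_k` replicons, fidelity
`B = a_k/n_k`, specificity `A = a_k / sum(a)` (standard) or
`A = (a_k/n_k) / sum_g(a_g/n_g)` (group-equalized, correcting for
unequal group sizes, the IndVal.g analogue), and the statistic is
`sqrt(A*B)` for the best group. The binary variant is chosen because
the unit of observation is subtype presence per replicon; counts above
one are collapsed. Significance comes from permuting row group labels,
`p = (1 + #[permuted >= observed]) / (n_perm + 1)` (the +1/+1 keeps p
positive and valid), with 9999 permutations by default and Bonferroni
correction across subtypes. An exhaustive mode enumerates all distinct
two-group assignments for small designs, with `p = #[stat >= observed] /
n_assignments`. On binary data the permutation distribution is discrete,
so the test is mildly conservative; the type-I error stays within two
standard errors of the nominal 0.05 in the package's null simulations
(1000 matrices of 300 replicons).

`enrichment_2x2()` reports the sample (cross-product) odds ratio with
the two-sided exact p-value of the hypergeometric table — e.g.
conjugative-transfer capability versus CRISPR-Cas carriage.

## Spacer-protospacer matching

All detected array footprints — including two-repeat candidates — are
masked with N before any matching, which makes self-matches and matches
to undetected array copies impossible by construction. Spacers are
collected from cas-linked and repeat-associated arrays always, and from
orphan arrays only when the consensus repeat can be typed against a
subtyped entry of the trusted-repeat lookup (>= 85% identity, either
strand); untypeable orphan spacers are excluded to avoid contamination
from residual false-positive arrays. Plasmid targets are restricted to
high-confidence ORFs (confidence >= 90) in the masked sequence; virus
genomes are searched whole.

Matching is a seeded local alignment: exact 8-mer seeds group by
diagonal and are verified with full Smith-Waterman under the unit
scheme score = matches - 2 x mismatches - 3 x gaps (linear gaps).
Significance uses the Karlin-Altschul expectation
`e = K * m * n * exp(-lambda * S)` with `m` the spacer length and `n`
the total database length. For this scheme and uniform base
composition, lambda solves `(1/4)e^lambda + (3/4)e^(-2 lambda) = 1`,
i.e. `lambda = log((3 + sqrt(21))/2) ~ 1.333`; `K = 0.7` was frozen
once from a null simulation (random 35-mers against a 200 kb shuffled
database, counting distinct hits of the exact search as implemented at
scores 13-14), slightly above the classic ungapped value for +1/-2 and
therefore the stricter choice. Matches with `e <= 0.05` are retained.

Two caveats are documented rather than hidden. First, expectation
values describe the expected number of chance alignments, so
thresholding at 0.05 admits chance hits at about that rate per
spacer-database search; with the desk-scale databases of the synthetic
community (1e5-1e6 bp) the e = 0.05 bar sits at alignment scores of
13-15 where short chance alignments live, whereas survey-scale
databases (1e9-1e10 bp) push the bar to scores above 21, where chance
hits effectively vanish. Validation against planted truth therefore
asserts recall and masking safety exactly, but a small rate of weak
chance hits in random background is the statistically expected
behaviour, not a defect. Second, the downstream statistics are designed
to be robust to exactly this: every spacer is counted at most once per
target category no matter its number of matches, and duplicating a
database entry changes nothing.

Target-class proportions (plasmid-only / virus-only / both) are
reported over matched spacers and over all spacers, since dual-target
spacers make the two denominators genuinely different. Conjugative
targeting bias gives each spacer with at least one plasmid match a
total weight of 1, split proportionally between its distinct
conjugative and non-conjugative plasmid targets (4 conjugative + 1
non-conjugative = 0.8/0.2); mobilizable plasmids count as
non-conjugative under the default dichotomy, and the label mapping is
configurable.

## The targeting network and taxonomic confinement

Every ordered (source plasmid, target plasmid) connected by at least
one spacer-protospacer match is one directed pair; cross-targeting
plasmids contribute two pairs; self-targeting is excluded from pairs
but reported. Each pair is assigned to the most specific host-taxonomy
rank at which both hosts agree (agreeing at a rank but not at any more
specific one), each pair counted once; hierarchically inconsistent
taxonomies are an error, and pairs with unknown hosts are dropped from
confinement but kept in the network. The null model permutes the
plasmid-to-taxonomy assignment among the plasmids participating in
pairs — so a plasmid in many pairs keeps one coherent permuted
taxonomy — 100 times, and reports per-rank medians. The permutation
unit is a genuine modelling choice; a per-endpoint mode (labels
shuffled over pair slots) is available behind `unit = "endpoint"`
without any claim of equivalence. The network is exported as GraphML
and an edge-list TSV (igraph), with host order and CRISPR-carriage as
node attributes and distinct-spacer counts as edge weights.

## The synthetic community generator

`generate_community()` emulates the statistical structure the pipeline
assumes, with known ground truth; identical configuration and seed
reproduce the output byte for byte. Its defaults are the package's
study conditions, chosen once:

* 40 plasmids of 8-25 kb and 10 chromosomes of 50-100 kb, i.i.d.
  uniform ACGT background — at these lengths and detector defaults the
  expected number of spurious candidate arrays in pure background is
  far below one;
* 60 true arrays of 4-8 repeats; repeats 23-47 bp with 2% per-copy
  substitution; spacers 25-45 bp sliced from a shared random pool
  without replacement (keeping inter-spacer identity low by
  construction) with per-array lengths jittered +/- 2 bp around a
  centre, mirroring the narrow within-array spacer-length spread of
  real arrays; every planted array is verified against the four
  curation filters and redrawn until it passes;
* 30 decoys alternating between iterons (4-6 near-identical ~20 bp
  units with near-identical equal-length linkers, violating spacer
  conservation) and transposon tandems (conserved units, random
  linkers of strongly variable 15-80 bp length, violating the length
  SEM), each verified to violate exactly its tagged filter;
* half of the true arrays get a *cas* operon planted 100-900 bp away
  with a subtype label and gene list (adaptation module with
  probability 0.5), plus 5 stand-alone orphan operons;
* ORFs are emitted directly as GFF features with a numeric confidence
  in [0, 100] (60% high-confidence), placed only in feature-free
  sequence, because ORF confidence comes from an external predictor in
  a real survey; true arrays therefore never overlap high-confidence
  ORFs by construction;
* 60 protospacers, each an exact copy of a planted spacer with exactly
  1 substitution, planted 70% into high-confidence ORFs of *other*
  plasmids and 30% into 15 virus genomes of 5-30 kb, on either strand.
  Source spacers are drawn from cas-linked arrays so the typed-spacer
  inclusion rule cannot silently remove planted targets;
* host taxonomy is a balanced binary tree (2 domains deep to 64
  species) sampled i.i.d. per replicon; mobility labels are drawn
  i.i.d. with proportions 0.4/0.3/0.3
  (conjugative/mobilizable/non-mobilizable);
* the trusted-repeat database contains every planted master repeat
  (subtyped when the array is cas-linked, untyped otherwise) plus a few
  unrelated subtyped repeats.

What the generator does *not* emulate — realistic codon usage and GC
structure, repeat degeneracy with indels, leader sequences and PAMs,
shared repeat families across unrelated arrays, database redundancy —
bounds what green tests mean: they demonstrate that the algorithms
implement their stated rules exactly and recover planted structure
under calibrated noise, not that the detector matches any external
tool on natural sequence.

## Numerical and interface choices

* Internal coordinates are 1-based inclusive throughout (the
  R/Bioconductor and GFF3 convention); `to_zero_based()` /
  `to_one_based()` convert to and from half-open coordinates for
  interoperability and are round-trip tested.
* All thresholds keep their printed boundary semantics: strictly
  greater than 70, strictly below 50 and 3, ORF confidence >= 90
  inclusive, linkage strictly below 10 kb, association >= 85%
  inclusive, rescue distance <= 1 kb inclusive.
* Arrays with a single spacer cannot fail the spacer-based filters
  (the metrics are undefined) and are flagged instead.
* Every stochastic stage (generator, IndVal permutations, confinement
  permutations) takes an explicit seed, and the pipeline reuses its
  master seed everywhere, so a rerun with the same configuration is
  byte-identical.
* Validation sizes: the bundled checks run the community at 70
  plasmids / 110 arrays / 110 decoys / 210 protospacers, the metric
  oracles at 1000 random arrays, the IndVal null at 1000 matrices of
  300 replicons, and the confinement null at 100 runs of 100
  permutations — sizes chosen so the full suite completes in a few
  minutes on one core while keeping binomial error bands tight enough
  to be meaningful.

## A worked example

```{r example, eval = FALSE}
library(crisprmob)
cfg <- pipeline_config(out_dir = "crisprmob_out", seed = 5,
                       synth = synthetic_config(n_plasmids = 15,
                                                n_chromosomes = 4,
                                                n_true_arrays = 20,
                                                n_decoys = 10,
                                                n_protospacers = 25),
                       n_perm_indval = 999)
res <- run_pipeline(cfg)
res$prevalence
res$proportions
res$weights$totals
res$confinement
```

The result bundle contains every stage product (curated arrays, loci,
prevalence and IndVal tables, spacer matches, conjugative weights, the
targeting network and its confinement null), and the same tables are
persisted as TSV/GFF3/GraphML under `out_dir` together with a manifest
recording the seed, configuration hash and per-stage record counts.

## Known limitations

Repeat chaining is substitution-aware but not indel-aware, matching the
generator's mutation model; heavily indel-degenerate natural arrays
would need an alignment-based chainer. The detector does not call array
orientation (leader end) or PAMs. Subtype labels pass through from the
input annotation — there is no HMM-based *cas* typing. The
Karlin-Altschul parameters assume uniform base composition; strongly
skewed genomes would need refitting. IndVal here is the binary variant;
abundance-weighted IndVal.g as implemented in community-ecology
packages would require per-replicon locus counts to be meaningful.
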