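---
title: "Methods: population-level viromics with viropop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-level viromics with viropop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viropop)
```

# Scope and model

`viropop` implements the inference chain used to characterize viral
communities in depth-stratified, oxygen-deficient water columns from
assembled virome contigs: evidence-integrated viral identification,
clustering of contigs into species-level *viral populations*,
read-recruitment abundance estimation, community ecology with
habitat-exclusivity (endemism) classification, gene-sharing genus
networks, and genomic-context adjudication of putative auxiliary
metabolic genes (AMGs). The package consumes the *outputs* of
virus-detection and annotation tools (VirSorter categories, VirFinder
scores, CAT and PHASTER calls, gene tables, read-to-contig alignments in
PAF); it never runs those tools itself.

All stages are exercised end-to-end against a ground-truthed synthetic
virome generator, so the package is testable without any external data.

# Evidence tiers

Four evidence sources per contig are integrated into confidence tiers:

* **high** — VirSorter category 1 or 2, *or* VirFinder score strictly
  greater than 0.9;
* **medium** — VirSorter prophage categories 4–6 validated by PHASTER;
  *or* VirSorter category 3 with a VirFinder score in \[0.7, 0.9\]
  (both ends inclusive) validated by CAT; *or* exactly one of the two
  detectors identifies the contig (VirSorter in 1–3, or VirFinder ≥ 0.7)
  when no high rule fired;
* **none** — otherwise.

Missing evidence is encoded as `NA` (`"."` on disk) and never satisfies
a rule; it is semantically distinct from a score of 0 or `FALSE`.
Rules are evaluated high → medium in a fixed order and `rule_fired`
records the first match, which makes the engine total and deterministic
over the whole evidence space — the test suite enumerates the full grid
against an independently written truth table.

One design point deserves a note: the "only identified by one detector"
medium rule is intrinsically non-monotone in the VirFinder score when
VirSorter reports category 3 without CAT validation (raising the score
from 0.65 to 0.75 makes *both* detectors fire, and the pair then needs
CAT to stay medium). We keep the rule as stated — it reflects the
published decision logic — and test monotonicity on the sub-space where
it genuinely holds.

Contigs shorter than 1.5 kbp are excluded before classification
(`classifyContigs(minLength = 1500)`, boundary inclusive). Whether the
length filter preceded or followed tool execution in the original
workflow is unknowable from the outputs; filtering first is the
conservative choice because it only removes rows.

# Average nucleotide identity and population clustering

Viral populations are species-level clusters: contigs larger than 5 kbp
(strict) clustered at **ANI ≥ 95% over ≥ 80% of the shorter sequence**,
with the longest member as representative.

`pairwiseANI()` offers two routes:

* **seeded-diagonal** (`method = "seed"`, the default above 2 kb):
  exact-match 15-mer anchors index candidate diagonals; each candidate
  is scored by gap-free extension over the full overlap span of that
  diagonal, on both strands, and the diagonal with the most matching
  columns wins. ANI = 100 × matches / aligned columns;
  the aligned fraction is the span divided by the shorter contig's
  length. On substitution-divergent sequences (the regime that matters
  near a 95% threshold) this reproduces a nucmer-style single best
  chain. K-mers containing N are never seeded and N matches nothing, so
  ambiguous bases count against identity through the denominator.
* **dynamic programming** (`method = "dp"`, default at ≤ 2 kb,
  refused above): full Needleman–Wunsch global alignment
  (via `Biostrings::pairwiseAlignment`, match +1, mismatch −2, gap open
  10 / extend 4, so gaps are never preferred over mismatch runs) with an
  ACGTN substitution matrix in which N mismatches everything including
  itself. This quadratic route doubles as the independent oracle: the
  suite checks agreement with the seeded route within 0.5 percentage
  points on 200 random pairs.

Sequences with no shared anchor on either strand (effectively unrelated)
report ANI 0 with aligned fraction 0 rather than an error, so greedy
clustering can simply reject them.

`clusterPopulations()` is greedy longest-first dereplication: retained
contigs are sorted by length descending with ties broken by contig id
ascending, and each contig joins the first existing population whose
*representative* it matches at both thresholds (inclusive), else founds
a new population. Member-to-representative (not member-to-member)
identity is enforced, matching standard greedy dereplication practice;
the explicit sort makes the partition invariant to input order, and the
scan order guarantees representatives are the longest members. The suite
verifies the partition against a brute-force reference and against
planted truth (20 populations at 2% within- / ≥15% between-population
divergence recovered exactly).

# Read recruitment and abundance

Alignment records (PAF, 0-based half-open, both strands counted) pass a
read-level retention rule — identity 100 × matches / aligned bases
≥ 95% **and** aligned fraction of the read ≥ 0.90, both inclusive — and
contigs pass a breadth rule: abundance is only retained when reads cover
**more than 75%** of the contig's positions (interval union; strict,
because the rule is phrased as "over 75%"). Boundary cases
(94.9/95.0, 0.89/0.90, 0.74/0.76) are pinned in the tests.

The retained signal is normalized as

$$\mathrm{abundance} = \frac{\text{mean depth}}
{\text{metagenome size in Gbp}},\qquad
\text{mean depth} = \frac{\text{aligned bases}}{\text{contig length}}.$$

Mean depth already normalizes by contig length; dividing by library size
(Gbp) makes values comparable across samples. The constant (per-Gbp) is
a presentation choice — every downstream use is comparative, so any
fixed monotone variant gives identical ecology. Per-sample *relative*
abundances divide each column by its sum (all-zero columns stay zero).
A population's "detected" state means exactly: normalized abundance
> 0, i.e. it passed the breadth rule.

Reads hitting several contigs are counted once per alignment record; no
primary-alignment deduplication is attempted (the generator emits one
record per read, and recruitment in practice is run against the
dereplicated representatives).

# Ecology and endemism

* **Pielou's evenness** J = H′/ln S with Shannon entropy in natural log
  over positive entries; undefined (NA, never 0) below two detected
  populations.
* **Jackknife-2 richness** (Burnham–Overton):
  S + Q1(2n−3)/n − Q2(n−2)²/(n(n−1)); cross-checked against
  `vegan::specpool`.
* **Accumulation curves** use `vegan::specaccum(method = "random")`
  (default 100 permutations) under a caller-supplied seed; the
  final-step new-population detection rate is the mean fraction of
  populations first observed when the last sample is added.
* **Bray–Curtis** via `vegan::vegdist`; a pair of all-zero samples is
  undefined and returned as NA with a warning.
* **Sample dendrograms**: Manhattan distance with average linkage by
  default (the defaults of the pvclust-style analysis this mirrors);
  ties are resolved by `stats::hclust`'s deterministic merge order, and
  the tree is exported as Newick. Bootstrap/approximately-unbiased
  support values and NMDS ordination are out of scope.

**Endemism and exclusivity.** A population is *endemic* when absent
from a caller-supplied reference (global) detection set. Its
exclusivity label derives from the set of redox zones where abundance
exceeds `epsilon`: any oxic detection gives `cosmopolitan` (if in the
reference set) or `oxygenated_only`; `{euxinic}`, `{redoxcline}` and
`{redoxcline, euxinic}` map to the corresponding anoxic-exclusive
classes; an empty set is `indeterminate` (near-undetectable, no
inference). `epsilon` defaults to 0 — i.e. detection is exactly
"passed the breadth rule" — because no explicit trace-abundance cutoff
is published; it is exposed as a parameter.

# Gene-sharing genus networks

Populations are nodes; the edge weight between two populations with
`nA` and `nB` protein clusters (PCs), sharing `shared` of `nTotal`, is
the −log10 hypergeometric upper-tail probability of sharing at least
that many, computed in log space (`stats::phyper(log.p = TRUE)`), so
large PC universes cannot overflow. Edges below `threshold`
(default 1.0, P ≤ 0.1) are dropped.

Genus calling is deliberately simpler than vConTACT2's
ClusterONE/MCL machinery: connected components of size ≥ 2 with
internal edge density ≥ 0.5 become genera; members need at least one
internal edge (configurable) to be `clustered`, otherwise they are
`outliers`; nodes without retained edges are `singletons`. Outputs are
comparable in *kind* (genera / outliers / singletons), not in exact
membership, to vConTACT2. Protein clusters are consumed as a
membership table; no protein alignment is performed here.

# AMG genomic context

The qualitative published reasoning — "interior of the viral genome"
versus "at the edge of the viral contig, drawing into question…" — is
formalized with two defaults: `edgeMargin = 3` genes (an AMG is
*interior* when at least that many genes separate it from both contig
ends, and when a PHASTER prophage span is available, the AMG must lie
inside it) and `window = 5` genes of flanking context on each side in
which viral genes (`viral_hallmark`/`viral_like`) are counted. Boundary
evidence combines att sites and predicted termini: both att sites or
termini ⇒ `genome_bounded`; one att ⇒ `partial`; else `unbounded`.

Confidence: **high** = interior with viral support on both flanks;
**medium** = interior with one supported flank, or edge placement on a
genome-bounded contig; **low** otherwise. An edge AMG is never high.
The three anchoring patterns — interior/unbounded with viral flanks
(the PAPS reductase situation), edge/unbounded (the Mu-like diguanylate
cyclase), and att-bounded interior (the Ack/Pta prophage) — reproduce
exactly in the tests. The published coverage-consistency argument is
represented only descriptively (`geneRegionMeanDepth()`), with no
automated verdict.

# The synthetic virome generator

`simulateVirome()` plants a fully known community so downstream
inference can be scored:

* **Samples**: six viromes spanning two oxic (148, 200 m), three
  redoxcline (237, 247, 267 m) and one euxinic (900 m) depth, 100 Mbp
  library size each — a miniature of a stratified-basin sampling design.
* **Genomes**: 20 populations × 3 members of 20 kb by default.
  Representatives are independent uniform random sequences (planted
  between-population divergence is therefore effectively maximal and
  unalignable, trivially exceeding the `inter_divergence` floor of
  0.15); members carry i.i.d. substitutions at `intra_divergence`
  (default 0.02), so planted within-population ANI ≈ 100 × (1 − rate)
  is analytically predictable. Substitution-only mutation (no indels)
  is deliberate: it keeps the ANI oracle exact. The first member *is*
  the representative genome, which pins the longest/lexicographic
  representative recovery at equal lengths.
* **Abundances**: log-normal(0, 1) weights per population and sample,
  masked by a planted exclusivity class and rescaled so detectable
  populations average `target_depth` fold-coverage per sample. The
  default class mix (per 20 populations: 6 cosmopolitan, 7
  basin-endemic-but-oxygenated, 4 euxinic-only, 1 redoxcline-only,
  1 redoxcline+euxinic, 1 undetectable) mirrors the reported proportions
  of such classes in a stratified euxinic basin. `undetectable`
  populations get a fixed 0.05 × `target_depth` coverage: at the study
  depths used here (≤ 20×) that is ≈ 1× coverage, whose expected breadth
  1 − e^(−1) ≈ 63% sits safely below the 75% retention rule, emulating
  "near undetectable" populations that defeat distribution inference.
* **Reads**: emitted directly as full-length alignment summaries (PAF)
  against each population's representative — Poisson read counts,
  uniform placement, binomial match counts at 1 − `read_error`
  (default 0.01). Bypassing a real mapper isolates the retention and
  normalization logic from mapping-software behavior.
* **Evidence**: per contig, drawn from configurations consistent with
  its planted tier under the rule engine, or (with probability
  `evidence_confusion[tier]`) with a uniformly chosen wrong tier.
  Planted tier proportions default to 60/30/10% high/medium/none.
* **Determinism**: every output is a pure function of the plan; each
  stage draws from its own seed offset so module-level reruns reproduce.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: indels and rearrangements (real ANI estimation
must chain across gaps), chimeric or fragmented assemblies, platform
error profiles and variable read lengths, multi-mapping ambiguity
between similar members, uneven within-contig coverage (GC bias,
origin peaks), and any real taxonomy behind the protein-cluster
profiles. Results on synthetic data bound the *logic*, not the
upstream tools.

# Numerical choices and problem sizes

Thresholds are compared inclusively (≥ 95 ANI, ≥ 0.80 AF, ≥ 95%
identity, ≥ 0.90 read fraction) except the two "larger/over than"
rules, which are strict (> 5000 bp, breadth > 0.75). Degenerate inputs
resolve explicitly: empty alignment sets give breadth 0; all-zero
abundance columns stay zero through relative normalization; evenness
below two populations is NA; all-zero sample pairs give NA
dissimilarity with a warning; all-N sequences are rejected as
unalignable.

The shipped tests run the study at desk scale by design: 20 planted
populations of 3 × 20 kb members for clustering recovery, 50× target
depth for abundance recovery (Spearman ≥ 0.95 per sample), 20× for
endemism recovery (≥ 95% of populations), 200 random pairs ≤ 2 kb for
the ANI oracle, 1 000 contigs for tier-confusion accuracy, and
hypergeometric enumeration up to a 30-PC universe. These sizes were
chosen once as the smallest community at which every planted effect is
comfortably detectable, and the acceptance script
(`scripts/acceptance.R`) re-runs the same study from scratch at a
caller-supplied seed.

# Known limitations

* The seeded ANI route evaluates single gap-free diagonals; it is exact
  for substitution-divergent contigs but will underestimate identity
  across indels or rearrangements (use the DP route, or an external
  aligner, below 2 kb).
* Genus membership is a thresholded-component approximation, not a
  vConTACT2 re-implementation; counts of outliers/singletons are not
  expected to match that tool's internals.
* The AMG adjudicator encodes placement and boundary logic only; it
  cannot weigh sequence-level homology or coverage consistency, which
  remain manual steps.
* Recruitment consumes alignment summaries; mapping decisions (primary
  vs secondary hits, pairing) are upstream of the package.
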