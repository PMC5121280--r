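---
title: "Methods: gene-family identification, microsynteny, selection and divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family identification, microsynteny, selection and divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

famsynt is a pipeline for comparative evolutionary analysis of a plant
transcription-factor family defined by two diagnostic protein domains: the
N-terminal QLQ (Gln-Leu-Gln) protein-interaction domain and the WRC
(Trp-Arg-Cys) zinc-finger DNA-binding domain. Starting from per-species
genome annotation (GFF3) and sequences (FASTA), it identifies family
members, builds a distance phylogeny with subfamily assignment, compares
exon-intron structures, detects microsynteny around each member to classify
duplication modes, estimates Ka/Ks with a sliding-window scan, and measures
type-I/II functional divergence between subfamilies. A genome simulator
with planted history provides ground truth for every stage; this vignette
records the models, the parameters that matter, and the design choices made
where the design was genuinely open.

## Family identification: PSSM domain scanning

Membership requires at least one QLQ hit and at least one WRC hit in the
protein (two WRC copies are allowed and counted). Domains are found with a
position-specific scoring matrix built from a packaged seed alignment:
log-odds in bits against a uniform 1/20 background with an additive
pseudocount (default 0.5 spread over the alphabet). The scan threshold
defaults to 60% of the maximum attainable bit score; overlapping windows
are resolved greedily by score (ties leftmost). E-values attach a
Gumbel-tail estimate fitted by moments to 10,000 random windows at build
time, multiplied by the number of windows scanned.

The packaged QLQ and WRC seed alignments are **synthetic**: motif-plausible
twelve-sequence alignments written for this package (Pfam seed files are
not redistributed here). The simulator plants domains from the same seed
columns, so the scanner and the generator share one definition of the
domain signal — the benchmark therefore demonstrates pipeline correctness,
not the detection power of any particular Pfam profile on real proteomes.

## Phylogeny, bootstrap, subfamilies

Distances are protein p-distances under pairwise deletion with the Poisson
correction `d = -ln(1 - p)`; saturated pairs (`p >= 1`) are flagged rather
than silently truncated. Trees are Saitou-Nei neighbor joining with the
Studier-Keppler Q criterion; negative branch lengths are clamped to zero
and Q ties break on the lexicographically smallest pair of cluster
representatives, so results are deterministic. Bootstrapping resamples
alignment columns (default 1000 replicates) and counts, for each internal
bipartition of the original tree, the replicates that contain it;
internally a replicate's distance matrix is a weighted column sum, which
keeps 1000 replicates fast.

Subfamilies are obtained by cutting the `k - 1` longest internal branches
among those whose support reaches `min_support` (default half the
replicates); cutting `k - 1` edges of a tree always yields `k` groups,
labelled I, II, ... by decreasing size. `k = 5` is the default, with both
`k` and `min_support` exposed because the clade count is a judgement call
on real data.

Multiple alignment is a means here, not a result: equal-length inputs (the
simulator never inserts indels, a deliberate non-goal) are treated as
aligned, and anything else is passed to MAFFT (`--auto`, single-threaded),
the aligner a practitioner would use.

## Microsynteny and duplication classification

Each family member is an anchor; its flank set is every gene whose span
intersects a 100 kb window either side of the anchor (windows clipped at
chromosome ends, partial overlaps included). Flank proteins are compared
with BLASTP — one search over the union of flank proteins per genome pair,
memoised across anchors — and a flanking pair is *conserved* when it is the
best non-self hit in both directions (reciprocal best hit) with
`E <= 1e-10`, where E is recomputed from the bit score as
`E = m * n * 2^(-bit)` with `n` the opposing flank set's residue count, so
the search space matches the anchor-pair comparison actually performed.
Reciprocity plus greedy one-to-one resolution (ties to the smaller gene id)
guarantees no flanking gene supports two pairs of one block.

Classification per anchor pair: **tandem** if the anchors share a
chromosome with at most one intervening gene (tandem takes precedence);
otherwise **large_scale** with four or more conserved pairs; **relaxed**
with two or three; **none** below that. Inter-species anchors follow the
same flank/match rules, with blocks of at least two conserved pairs
reported and members absent from every block listed as non-syntenic.

## Ka/Ks: NG86 with sliding windows

Protein alignments guide codon back-translation: every protein gap becomes
a `---` codon gap, stop codons are trimmed, and ungapping either sequence
recovers its CDS exactly. The estimator is Nei-Gojobori (1986): per-codon
synonymous site counts are the fraction of synonymous single-nucleotide
changes at each position, with mutations to stop codons excluded from both
numerator and denominator (so S + N = 3 per codon); multi-nucleotide codon
differences are averaged over all minimal substitution pathways with equal
weights, dropping pathways through stop codons and renormalising (if every
pathway is blocked, stop-crossing paths are re-admitted — a guard that
essentially never fires). Proportions are Jukes-Cantor corrected,
`d = -(3/4) ln(1 - (4/3) p)`, with `p >= 3/4` flagged undefined; the ratio
is undefined when `Ks = 0`, never fabricated. Windows are 150 bp moved in
9 bp steps, fully contained only, so
`n_windows = floor((L - 150)/9) + 1`; window coordinates are 1-based
alignment bp. Gapped codon columns are excluded from sites and differences
alike (complete deletion within a window).

## Functional divergence

**Type I** (rate shift) is the Poisson-gamma two-state mixture: per
alignment column, substitution counts within each subfamily cluster come
from Fitch parsimony on the cluster's own NJ subtree (gap-majority columns
excluded). With probability `1 - theta` a site's rate is shared between
clusters, with probability `theta` the rates are independent; rates are
gamma with mean one, counts Poisson given rate times a per-cluster
tree-length scalar. `theta`, the gamma shape and the two scalars are
estimated by L-BFGS-B from five starts over `theta` in {0.05, ..., 0.85}
(log-likelihood tolerance 1e-8); the SE comes from the observed Fisher
information, the LRT compares against `theta = 0` with chi-squared(1), and
per-site posteriors `Q_k` flag critical sites above 0.9. Because
`theta = 0` sits on the boundary, the chi-squared(1) reference is
conservative (the true null is a half-half mixture), so the test rejects
slightly below the nominal level — visible in the calibration benchmark.
A `theta` estimated at the boundary is reported as 0 with an explicit
`at_boundary` flag rather than a dash.

**Type II** (property shift) is a moments estimator: a site is a fixed
difference when both clusters are monomorphic with different residues,
radical when the residues fall in different property classes (basic
K/R/H, acidic D/E, polar S/T/N/Q/C/Y/W/G, nonpolar A/V/L/I/M/F/P). With
`rF` the radical fraction among fixed differences and `rW` the radical
fraction among within-cluster changes (the two most frequent residues of
each polymorphic column), `theta2 = (rF - rW)/(1 - rW)` with a
delta-method SE; negative estimates are reported as-is. Posteriors follow
Bayes' rule for radical fixed sites against the baseline radical rate.
Clusters need at least four sequences; smaller subfamilies are skipped with
a reason. Site indices in all reports are 1-based alignment columns.

## The simulator: what it emulates and what it does not

`simulate_genomes()` plants a full family history so that every inference
stage can be scored against truth: multi-chromosome gene orders with ~10 kb
mean spacing; family genes carrying both domains (seed consensus with
per-column substitution probability 0.1, substitutes drawn from the
residues observed in the seed column); a star radiation of five subfamilies
(deep branches 0.5 substitutions/codon, within-subfamily 0.08, species
terminal branches 0.05); tandem copies inserted adjacent to their source
and segmental blocks of eight genes centered on the family anchor copied to
another chromosome with per-gene retention 0.9; coding sequences evolved
under a Goldman-Yang-style codon process (uniform codon frequencies,
`kappa = 2`, background `omega = 0.2`, `omega = 0.02` inside domains —
domains are under strong purifying selection, as the sliding-window valleys
over QLQ/WRC regions in real data suggest). Family members are placed with
a minimum same-chromosome separation (18 gene slots) and copy blocks land
away from existing family windows (14 slots), reflecting the dispersed
chromosomal distribution of real family members; without this, planted
blocks create genuine — but unintended — microsynteny between unrelated
anchors. Everything runs off a single RNG stream per `simulate()` call, so
equal seeds give byte-identical outputs.

Deliberately not modelled: indels in coding sequence (pairs are
alignment-free), recombination, UTRs (exon features equal CDS segments),
polyploidy beyond block copies, and base-composition or codon-usage bias.
Passing benchmarks therefore demonstrate that the estimators and rules
recover a known history under their own model assumptions at realistic
sizes — not that they are robust to alignment error or compositional
artefacts in real genomes.

Two estimator benchmarks deserve their rationale spelled out. The
omega-recovery check runs the codon evolver with `kappa = 1` because NG86's
site counting assumes no transition/transversion bias; benchmarking the
estimator under its own generating model isolates estimator correctness,
while the monotonicity check (estimates increasing in simulated omega over
{0.1, 0.2, 0.5, 1, 2}) runs at the realistic `kappa = 2`. The theta-I
calibration/recovery benchmark draws site counts directly from the
Poisson-gamma model (`simulate_site_counts()`, `alpha = 1`,
`d1 = d2 = 1.5`, 500 sites) — the cleanest test of the ML machinery — while
the sequence-level generator (`plant_rate_shift()`) is exercised separately
through the parsimony-correlation property test.

## Numerical and procedural choices

- Coordinates are GFF3-native 1-based inclusive everywhere; one transcript
  per gene (the longest CDS when several are annotated); stop codons are
  trimmed before translation checks; CDS whose length is not divisible by
  three are flagged and excluded from codon analyses.
- All tie-breaks are deterministic: NJ pair selection and one-to-one match
  resolution are lexicographic, subfamily labels order by size then
  smallest member, overlapping domain hits resolve best-score-then-leftmost.
- Report files contain no timestamps, and every stage's seed derives from
  the run seed, so pipeline runs with equal seeds are byte-identical (the
  determinism benchmark checks exactly this).
- Problem sizes used by the test-suite benchmarks are the package's own
  choice of "desk scale": 20 simulation seeds for classification and
  domain-calling recovery, 10 for subfamily recovery (1000 bootstrap
  replicates each), 20 replicates for the theta-I checks, 200 pairs for
  omega recovery, 25 small random configurations for truth-integrity
  properties, with compact genomes (two species, four chromosomes, ~240
  genes per species) throughout.

## Known limitations

- The NG86 endpoint counting can register a few nonsynonymous differences
  between codons connected purely by synonymous events (the serine codon
  islands) at high divergence; the omega = 0 check is therefore a bound on
  the nonsynonymous fraction, not exactly zero.
- The Gumbel E-value for domain hits is a moments fit to a uniform-window
  null, adequate for ranking and thresholding here but not calibrated
  against real proteome composition.
- Type-II theta is a moments estimator on consensus-level fixed
  differences; its contract is parameter recovery on simulations, not
  numeric equality with any external implementation.
- With fewer than four qualifying internal branches at the requested
  support, subfamily assignment refuses rather than guessing; lower
  `min_support` or `k` explicitly.
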