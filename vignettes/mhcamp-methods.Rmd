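---
title: "Methods: genotyping and evolutionary analysis of duplicated MHC amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotyping and evolutionary analysis of duplicated MHC amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mhcamp)
```

This vignette documents the models and procedures the package implements,
the parameters that matter, and the design choices made where the design was
genuinely open. The system it targets is an extremely duplicated MHC class I
gene family: a single individual carries tens of distinct exon-3 sequence
variants ("alleles", not assignable to loci), in three in-frame length
classes — 241 bp with no deletion, 238 bp with a one-codon deletion, and
235 bp with a two-codon deletion. Exon 3 encodes part of the α2 domain, so
the evolutionary contrasts between these classes (diversity, positive
selection, network structure) speak to whether a class encodes classical
antigen-presenting molecules.

## The genotyping model

Each amplicon is one PCR of one individual and template (genomic DNA or
cDNA), identified by a unique pair of 6 bp barcodes. Reads are assigned only
on an exact match of both tags and a within-budget match of both primers
(default 0 mismatches; degenerate primer positions match any of their IUPAC
expansions). Exact tag matching is deliberate: 6-mers are short, plates use
unique tag pairs, and error-correcting tags risks cross-talk between
amplicons, which is worse than losing a read.

Assigned, trimmed reads form a variant table — sequences with read counts,
ordered by count descending with lexicographic tie-break (a total order, so
tables are reproducible). Reads containing ambiguous bases are dropped; when
an amplicon exceeds the read cap (default 20,000) a seeded uniform subsample
is used.

Three artifact filters act on each table, in a fixed order:

1. **Copy threshold** — variants with fewer than `min_copies` (default 10)
   reads are removed.
2. **Chimera flagging** — a variant is removed (and reported) when two
   strictly more abundant, equal-length variants exist such that the variant
   agrees with one parent at every parent-differing site up to a single
   breakpoint and with the other beyond it, with at least one differing site
   per side. This is the signature of a template-switching PCR artifact.
3. **Error collapse** — processing by descending abundance, a variant within
   `max_edit` (default 2) edits of an already-retained, strictly more
   abundant variant is removed. Levenshtein distance is used rather than
   Hamming so 1-base indel artifacts are caught too. Equal counts never
   collapse (the strictly-more-abundant rule), so genuine co-abundant
   near-neighbours survive.

The order — noise floor first, then parent-dependent tests — removes
low-copy junk before it can serve as spurious chimera parents; all removals
are logged so alternative orders can be audited, and the composed filter is
idempotent.

Finally, **replicate verification**: an allele is accepted for an individual
and template only when present in the retained set of both (configurably,
r of n) independent PCRs. Alleles verified in both gDNA and cDNA are
transcribed; gDNA-only alleles are putatively non-expressed; cDNA-only
alleles are reported but never added to genotypes, because gDNA is the
genotype source and a cDNA-only call more likely reflects gDNA dropout than
a real allele. ORF status is computed in frame 1 (the exon fragment carries
one dangling base, so valid lengths are ≡ 1 mod 3); frame-incompatible
lengths are `frameshift`, in-frame stops are `stop_codon`.

## Length classes

Classification is by codon-aware comparison to a configured 241 bp
no-deletion reference, scored with match +1, mismatch −1, gap open −4, gap
extend −1 per base, and a +2 bonus for a gap that starts on a codon boundary
and has length divisible by 3. Because the only admissible geometries are
deletion-only (one 3-base gap, one 6-base gap, or two one-codon gaps), the
optimum under this scoring is found by exhaustive gap placement, which is
exact here and avoids a subtlety of affine dynamic programming: the
codon-boundary bonus is a property of a completed gap and cannot be applied
Markovianly at gap opening. Ties break leftmost. Anything else — insertions,
frame-breaking gaps such as an 11 bp deletion — is `other`. Two non-adjacent
one-codon deletions are accepted as `del6` (the generator permits them, and
classification must recover whatever the generator can emit); the default
two-codon deletion is adjacent. All coordinates are exon-local 0-based codon
indices; a display mapping to any external residue numbering is the user's
concern, since published numbering schemes for this gene family are
reference-dependent.

## Diversity statistics

π is the unweighted mean pairwise nucleotide p-distance over **unique**
alleles — allele-set diversity, not sample diversity — because the objects
of interest are allele collections; a frequency-weighted variant is
available. Pairwise deletion removes gapped or ambiguous columns per pair.
Aggregate per-individual summaries use the sample (n−1) SD. Display rounding
is 3 decimals for distances, 2 for ratios, whole percent for fractions. The
minimum-locus bound is ⌈max alleles per individual / 2⌉, the weakest bound
consistent with heterozygosity.

## Site-wise selection

Both site tests consume the same sufficient statistics, computed once per
alignment: a neighbor-joining tree (p-distance, negative branches clamped to
0), Fitch parsimony ancestral codon states per site (ties resolved to the
lexicographically smallest codon, so results are deterministic), and per
site the nonsynonymous/synonymous change counts n and s summed over edges,
with multi-step codon changes averaged over orderings excluding stop-codon
intermediates. The expected nonsynonymous fraction f of a site is the
Nei–Gojobori potential-site fraction of its observed codons (stop-excluded
neighbourhoods).

* The **counting test** compares n against Binomial(n+s, f): the p-value is
  the tail probability in the observed direction, and a site is positive
  when n/(n+s) > f with p < α (default 0.05). This is the directional-tail
  convention of counting-style selection tests; each direction is assessed
  by its own tail. Sites with no inferred changes get p = 1.
* The **likelihood-ratio test** fits a two-rate model (synonymous rate
  α_s with exposure 1−f, nonsynonymous rate β_s with exposure f) to the
  same counts by maximum likelihood and compares β_s = α_s against the free
  model with a χ²(1) likelihood-ratio (G) statistic, requiring β_s > α_s
  for a positive call. This collapses the MG94-style per-branch codon
  likelihood onto the inferred substitution counts with mutational-
  opportunity offsets — a deliberate approximation: a full 61-state pruning
  optimisation per site is orders of magnitude more expensive and adds
  nothing at the alignment depths the suite exercises, while the collapsed
  test keeps the model structure (two rates, LRT, direction) exact.

A site is a **consensus PSS** when positive in at least k of the m enabled
tests (default: all enabled). The consensus set is monotone non-increasing
in k. The subsampling driver draws `n_reps` (default 100) subsets of
`subset_size` (default 47 — the size of the smallest length class) without
replacement, runs one designated test per draw (default: counting), and
returns the PSS-count distribution, which is how classes of very different
size are compared fairly. Stop-containing alleles are excluded from
selection input with a warning. Recombination is checked before selection;
the pipeline warns but does not mask sites.

## Recombination

Three tests, combined by the same k-of-m consensus (default 2 of 3):

* **MaxChi** (pairwise): the site-difference indicator of an aligned pair is
  split at every candidate breakpoint and scored by the 2×2 χ²; the maximum
  is compared against permutations of site order. The reported breakpoint is
  the midpoint of the inter-difference gap containing the maximising column,
  since the data cannot localise further. Pairs with fewer than 4 differing
  sites are untestable.
* **Chimaera** (triplet): restricted to parent-informative sites, the
  recombinant is encoded as a binary match-to-parent-A vector and scanned
  the same way; permutation shuffles the binary vector.
* **PHI**: mean refined incompatibility over pairs of nearby (within
  `window`, default 100 columns) parsimony-informative sites, with site-order
  permutation; recombination makes nearby sites *more* compatible than
  distant ones, so small statistics are significant (one-sided).

All permutation p-values equal (1 + #{perm ≥ obs}) / (n_perm + 1), hence lie
in [1/(n_perm+1), 1] and can never be zero. Permutation null distributions
depend only on the (length, difference-count) pattern, so they are cached
and shared across pairs within a scan. Triplet enumeration is cubic, so
driver scans default to the most frequent alleles (`top`, default 50).

## Split networks

Distances are Kimura two-parameter with gamma rate correction (default shape
0.29); `gamma_shape = Inf` gives classical K2P. Columns with gaps or
ambiguity are deleted pairwise; saturated pairs (non-positive log/power
arguments) are flagged and set to a configurable ceiling rather than
propagating NaN. Alleles of different length classes are first gap-aligned
to the reference by the classifier, so deletions become gap columns.

The circular taxon ordering comes from NeighborNet agglomeration and is
canonicalised — smallest label first, direction toward its smaller
neighbour — so output is deterministic; for star-like metrics with no
non-trivial splits every ordering is valid and the sorted order is used.
Split weights are fitted by non-negative least squares of split-path
distances to the observed distances over all circular splits of the
ordering; negative split weights are meaningless, so ordinary least squares
with a non-negativity clamp is the right reading of OLS edge estimation
here. Splits below `threshold` (default 1e-6) are dropped; zero-distance
duplicate taxa are merged first and reported. On additive (tree) metrics
this reproduces every tree split with its branch length and the induced
distances match the input; the two edges incident to a rooted tree's root
merge into a single split, as they must in an unrooted representation.
Bootstrap resamples alignment columns, rebuilds the full network per
replicate, and scores each original split by bipartition identity; the
display threshold (default 70%) is presentation-only. Output is a
SplitsTree-readable NEXUS file with Taxa, optional Distances, and Splits
blocks including the cycle and confidences.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, at
desk scale:

* An exon-3 allele pool per class, derived from a common random (or
  supplied) reference: the class founder loses the configured codons
  (del3: codon 42; del6: codons 48–49 by default, exon-local), receives
  `class_stem_subs` shared stem substitutions (defaults 0/25/8), and each
  allele then mutates independently — per codon, a single-nucleotide change
  to a weighted neighbour, nonsynonymous neighbours weighted by ω
  (background 1, planted sites 5). ω scales both the probability and the
  type of change, so planted sites are faster-evolving and
  nonsynonymous-biased, as positive selection makes them; the per-codon rate
  is calibrated (with an analytic correction for the ω inflation) so the
  realized pool π tracks `class_target_pi` (defaults 0.128 / 0.016 / 0.111,
  the magnitudes of the three classes in the motivating system). The stem
  substitutions give a deletion lineage its own divergent branch, which is
  what makes the low-diversity class a supported cluster in the split
  network rather than a knot at the centre.
* Planted positively selected sites per class: 18 for no_del, 8 for del6
  (6 shared), none for del3 — the qualitative selection contrast between
  classes.
* Genotypes: per individual and class, a carrier draw (defaults 1 / 0.99 /
  0.93) and a copy number uniform in `copy_number_range`. The defaults
  (no_del 5–10, del3 1–2, del6 1–4) are a deliberately scaled-down regime
  coupled to the default coverage of 1000 reads per amplicon: they keep
  per-allele depth near 60–100×, where a fixed 10-copy floor plays the same
  role it plays at the real scale (tens of alleles at 20,000–100,000 reads
  per amplicon, which is reachable by config but wasteful for testing).
  Alleles closer than `min_pool_edit` (default 3) edits are never
  co-assigned to one individual: such pairs are indistinguishable from
  PCR-error variants under the 1–2 bp collapse rule, so no replicate-
  verified pipeline could recover both, and any real post-filter allele set
  has the same granularity. A class with diversity target 0 skips the
  constraint and yields identical alleles by design.
* Reads: fwd_tag + fwd_primer + insert + revcomp(rev_primer + rev_tag),
  with degenerate primer positions realized per read; i.i.d. substitution
  errors over the whole read (default 0.5%/base); with probability
  `chimera_rate` (default 2%) the insert is a two-parent join at a uniform
  internal breakpoint — uniform because nothing constrains real breakpoint
  placement and uniformity is the testable default; half the reads are
  emitted on the reverse strand; negative controls (default 6) receive zero
  reads. Every read is logged with template, chimera parents, breakpoint and
  error counts, so downstream truth comparisons never guess.

What the generator does **not** emulate: quality-score-dependent errors,
indel sequencing errors, plate-geometry effects, tag jumping, template
abundance bias, or contamination of negative controls. Passing tests
therefore demonstrate correctness of the pipeline's logic under its stated
assumptions, not robustness to every failure mode of a real sequencing run.

## Numerical and testing choices

Determinism: one global seed fans out to stage seeds through an integer
hash (`derive_seed`), so stages can be rerun independently; identical seeds
give byte-identical FASTQ output. Variant-table order, Fitch tie-breaks,
leftmost gap ties and the canonical cycle make every downstream result
deterministic too.

The test suite runs at fixed problem sizes chosen to finish in minutes while
keeping the statistics meaningful: genotyping recovery uses 20 individuals
at 1000× coverage (noisy) and 8 at 800× (zero-noise identity); selection
calibration uses seven 50-allele neutral pools (560 sites); recovery uses
100 alleles with 10 planted sites; subsampling uses the full 100×47 design;
network bootstraps use 60–200 replicates. Zero-noise identity checks use
coverage where the multinomial floor of the 10-copy filter is negligible —
at very low coverage the filter itself removes real alleles, which is a
property of the method, not a bug of the test.

## Known limitations

* Alleles cannot be assigned to loci; all statistics are over allele sets.
* The likelihood site test shares its substitution counts with the counting
  test, so the two tests are correlated; the consensus rule is a guard
  against single-test artifacts, not an ensemble of independent methods.
  External site-test results can be combined through the same consensus
  machinery if run separately.
* Peptide-binding-region overlap reports require a user-supplied residue
  mask; none is invented.
* The breakpoint of a pairwise MaxChi scan is only localised to the gap
  between flanking informative sites; triplet scans localise exactly on the
  informative-site grid.
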