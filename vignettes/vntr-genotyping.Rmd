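---
title: "Minisatellite VNTR genotyping and cohort analysis with vntrscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minisatellite VNTR genotyping and cohort analysis with vntrscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vntrscope)
```

## The problem

A tandem repeat (TR) is a nucleotide pattern repeated two or more times in
succession. Minisatellites — TRs with repeat units of roughly 7 to 126 bp —
are among the most mutable loci in the human genome, and a substantial
fraction of them vary in copy number between individuals. Such loci are
called VNTRs (variable number tandem repeats). Copy-number changes in and
around genes can alter transcription factor binding, splicing and
expression, and several minisatellite VNTRs are established disease loci.

Genotyping minisatellites from short reads is hard for one structural
reason: a read can only witness an allele whose entire tandem array, plus
enough flanking sequence to anchor the read to a unique locus, fits inside
the read. `vntrscope` implements the complete desk-scale analysis chain
around this constraint:

1. a **wraparound dynamic-programming aligner** that counts pattern copies
   in a sequence,
2. a **genotyper** that turns per-read copy observations into per-sample
   allele calls, encoded as integer copies gained or lost (CGL) relative
   to the reference, with read support (SP), written to VCF,
3. **cohort statistics** (common/private VNTR classification,
   heterozygosity, the gain/loss spectrum, tumor/normal comparisons),
4. **validation procedures** (Mendelian trio consistency, cross-platform
   allele agreement, long-read confirmation),
5. **population analysis** (presence/absence allele matrix, PCA, decision
   tree ancestry classification, one-sided Fisher exact marker scan), and
6. a **VNTR–expression association scan** (gene pairing within 10 kb,
   genotype classes, covariate residualization with surrogate hidden
   factors, one-way ANOVA with FDR control).

A synthetic-data generator produces every input the pipeline consumes, so
each stage is testable end to end without any external download.

## The alignment core

The copy number of a repeat in a sequence is measured by a *local
wraparound alignment*: the sequence is aligned against the infinite cyclic
extension of the pattern, so the alignment may begin at any pattern phase
and wrap around the unit as many times as the sequence supports. Scoring
is match +2, mismatch −5, gap −7 per gapped base (linear gap penalty; the
single published penalty value is interpreted as per-base, and affine gaps
are deliberately out of scope). `N` always scores as a mismatch.

Implementation: the pattern is unrolled into a finite text long enough
that the finite optimum equals the cyclic optimum, and a standard
Smith–Waterman recursion (implemented in C++ for speed) with full
traceback is run. The sufficiency argument for the unroll length: in a
positive-scoring local alignment every skipped text base costs 7 while a
match gains only 2, so an optimal alignment consumes fewer than
`9/7 × |seq|` text bases; the package unrolls to at least
`1.5 × |seq| + 2 × |pattern|` bases. The test suite verifies optimality
against two independent oracles — `Biostrings::pairwiseAlignment` on the
unrolled text and a brute-force enumeration of all local alignments on
tiny instances.

**Copy counting convention.** Copies are the number of *pattern positions
consumed* along the optimal path (match, mismatch, or pattern-side gap
columns) divided by the pattern length, reported to 0.01. A perfect
`k`-fold repeat yields exactly `k`. This convention makes the quarter-copy
long-read validation rule and the integer CGL encoding mutually
consistent. Ties in the DP are broken deterministically (diagonal over
gap, earliest end cell), so paths are reproducible.

**Rounding convention.** Fractional reference copy numbers are legitimate
(a 3.5-copy reference is an array of 3½ units). All conversions between
fractional copies and integers — building a synthetic array, rounding a
read observation, encoding CGL — round halves *away from zero*. Using R's
default round-half-to-even here would make a 3.5-copy reference encode to
4 while its own array measures back as 3, a subtle self-inconsistency
that the test suite guards against.

## Detectability calculus

Two rules decide whether an allele *could* be seen:

* **Read-length rule**: the tandem array plus a minimum 10 bp flank on
  each side must fit within the read
  (`array_length + 2 × 10 ≤ read_length`).
* **Copy floor**: the repeat finder requires a minimum number of pattern
  copies in the array. The floor is 1.8–1.9 copies depending on pattern
  length; the exact dependence is not published, so the package exposes
  `min_copies` with default **1.9** (the conservative end) in
  `detectable_cgl_range()`, and default **1.8** in
  `detectable_fractions()`, where it reproduces the published convention
  that a reference locus needs at least 2.8 copies for a loss of one copy
  to be observable. Both defaults are configurable and the choice is a
  documented open point rather than a derived fact.

`detectable_cgl_range()` combines both rules into the integer CGL interval
of observable alleles at a locus; the cross-platform consistency
procedure, the end-to-end recovery tests, and the gain/loss spectrum
interpretation all restrict themselves to this interval.

## The genotyper

Reads are matched to loci by their flanking sequence: the last bases of
the left flank and the first bases of the right flank act as anchor
probes (12 bp by default), verified outward up to 50 bp at a 90% identity
threshold. The sequence between the anchors is the observed array; its
copy number is measured with the wraparound aligner. Reads claimed by
more than one locus — which happens for dispersed, near-identical
("indistinguishable") repeat families — are discarded rather than risked
as wrong-locus evidence, mirroring the singleton/indistinguishable
curation of reference TR sets.

Allele calling requires **at least two reads** supporting the same
integer copy number; a locus with no supported allele is *not genotyped*,
which is deliberately distinct from a reference-allele genotype (the
distinction becomes the "other" class in the expression analysis).
Per-sample calls with more alleles than the expected chromosome count
(2 on autosomes; 2/1 on X for females/males; 0/1 on Y) are *multis* —
likely artifacts or segmental duplications — and are removed per sample
before any cohort statistic. A locus is a **VNTR** when any remaining
non-reference allele is observed in any sample.

Genotypes are written as VCF 4.2 with two FORMAT fields: `SP` (reads
supporting each allele) and `CGL` (signed copies gained/lost, e.g.
`0,+2` for a heterozygous reference/gain-of-two locus). Two files are
emitted: all genotyped loci, and the VNTR-flagged subset. Positions are
1-based in VCF; all internal intervals are 0-based half-open.

## Cohort statistics

* **Common/private**: a VNTR is *common* when at least `ceil(0.05 × n)`
  samples carry a non-reference allele and *private* when at most
  `floor(0.01 × n)` (but at least one) do. The ceiling/floor conventions
  are the only pair consistent with the published thresholds of 126 and
  25 samples for n = 2504.
* **Heterozygosity**: reported per sample as the percentage of loci with
  two distinct called alleles. The default denominator is the sample's
  own VNTR loci (loci where that sample carries a non-reference allele);
  the package also offers all genotyped loci. The carrier-restricted
  denominator is the appropriate proxy when allele discovery is
  read-length-limited, and the choice is explicit and configurable
  because the quantity is a convention, not a measurement.
* **Gain/loss spectrum**: every non-reference allele occurrence is
  binned by CGL; losses and gains are totaled and their ratio reported
  to one decimal.
* **Tumor/normal**: heterozygous fractions per tissue, somatic alleles
  (present in tumor only), loss-of-heterozygosity loci (heterozygous in
  normal, single-allele in tumor), and loci losing both alleles.
* **Annotation overlap**: interval overlap flags (any shared base) via
  `GenomicRanges`; enrichment statistics over those flags are out of
  scope.

## Validation procedures

* **Mendelian consistency**: an autosomal locus is consistent when the
  child's genotype splits into one allele present in the mother and one
  present in the father; a son's X allele must occur in the mother, his
  Y allele in the father. Loci lacking calls in a required member are
  excluded from the denominator. Increasingly stringent tiers (both
  parents heterozygous; whole trio heterozygous; whole trio heterozygous
  with pairwise-distinct genotypes) guard against configurations that
  are trivially consistent. A child locus with a single called allele is
  scored leniently (consistent if the allele occurs in either parent);
  the stringent tiers exist precisely to exclude such ambiguity, and the
  lenient rule is a documented choice.
* **Cross-platform consistency**: for one individual sequenced twice,
  the non-reference alleles at loci genotyped in both call sets (VNTR in
  at least one) are compared as `|intersection| / |union|`, after
  removing alleles outside the detectable range of the *shorter* read
  length. The restriction is applied to both sets — on clean data it
  only affects the longer-read set, and the symmetric form guarantees
  the statistic is order-invariant on noisy data.
* **Long-read confirmation**: a predicted allele is validated when at
  least one long read spanning the locus measures a wraparound copy
  number within ±0.25 copies of the prediction. Loci without covering
  reads are unevaluated.

## Population analysis

Samples become binary vectors of allele presence (carrier coding — one
copy or two both count as presence, matching the presence/absence
construction; dosage coding is a possible variant but not what the
procedure describes). Alleles present in fewer than 5% of samples are
uninformative and dropped. PCA uses mean-centering without unit-variance
scaling — the columns are already on a common 0/1 scale, and scaling
rare-allele columns would amplify noise; this is configurable in
principle and logged as a choice.

Ancestry classification: a stratified 70/30 train/test split, then an
`rpart` decision tree on the top 10 PCs. The only published tuning detail
is 10-fold cross-validation, so the package cross-validates the maximum
tree depth over {3, 5, 8, unbounded} and reports per-population recall
on the held-out split. All randomness (split, folds, tree) is
seed-driven.

Marker scan: for each (allele, super-population) pair, a one-sided
Fisher exact test (exact hypergeometric tail, over-representation only)
on the 2×2 carrier table of in-population versus all other samples.
Odds ratios are the sample estimate, with a Haldane–Anscombe 0.5
correction on zero cells for the reported `log2` value only — the
p-value stays exact. Benjamini–Hochberg adjustment runs across all
tests; a marker requires `q < 0.05` and `log2(OR) > 1`. Whether the
published construction counted carriers or allele copies is not stated;
carrier counting matches the presence/absence vectors used everywhere
else and is what the package implements.

## Expression association

Genes are paired with VNTR loci whose intervals lie within 10 kb
(distance between interval hulls, not TSS-anchored — the pairing is
stated in terms of genes, not transcription starts; a TSS-anchored
variant would only need a different gene table). Each sample's genotype
class is its sorted allele multiset (`"0/+1"`); samples without a call
form the pooled `"other"` class, on the assumption their alleles fell
outside the detection range. A locus enters the scan only with at least
two classes (three when `"other"` is present) and at least 20 samples
per class; genes with median TPM of zero are dropped.

Expression values are `log2(TPM + 1)` (the pseudocount convention is a
package choice; the exact published normalization is unstated) and are
residualized by per-gene OLS on sex, population covariates, and hidden
factors. Hidden factors come from a simplified iterative surrogate
procedure: repeatedly residualize on the known covariates plus accepted
factors, take the leading principal component of the residual, and
accept it unless it correlates above 0.85 with anything already in the
design (stop at the first rejection, cap at 15). This reproduces the
published stopping logic — hidden covariates beyond the useful set were
over 85% correlated with existing ones — without re-implementing the
full IA-SVA algorithm, which is out of scope. The aggressive variant can
absorb genuine genotype signal when very few genes are scanned; at
realistic scan sizes (hundreds of genes) the effect is negligible, and
the test suite demonstrates planted-effect recovery at the full scan
scale rather than on toy matrices.

Per pair, a one-way fixed-effects ANOVA (`residuals ~ genotype class`)
yields F and p; BH adjustment runs across all tested pairs and
significant records carry the maximum pairwise difference of class
residual means.

## The synthetic-data generator

The generator emulates, with full determinism given `(config, seed)`:

* a reference TR set with pattern sizes 7–126 bp, reference copies
  2–10, unique flank contexts, and a configurable fraction of
  indistinguishable loci built as families sharing a pattern and
  near-identical flanks;
* diploid multi-population cohorts: haplotypes drawn independently per
  locus (no linkage — sufficient for every analysis here and an explicit
  non-goal otherwise), with planted population-specific marker alleles
  at chosen in/out frequencies, sex assigned alternately within each
  population, and haploid X/Y handling;
* mother–father–child trios with a per-locus de novo ±1-copy mutation
  rate;
* error-bearing short reads (uniform sampling from both haplotypes,
  both strands, substitution errors only — indel read errors are a
  non-goal) and per-locus long reads;
* expression matrices with sex, population, hidden-factor and planted
  carrier-shift effects on the `log2(TPM+1)` scale.

Default study conditions — five populations of 200 samples, 400 loci,
and a marker panel of 50 alleles per population at in/out haplotype
frequencies 0.4/0.05 — were fixed once, up front, as the conditions for
the ancestry-classification experiment. The background allele-frequency
law (per-locus non-reference frequency `Beta(0.4, 3)` with 36% of loci
monomorphic; losses 64% of non-reference draws; truncated-geometric
magnitudes) is a configurable stand-in: the real allele-frequency law of
human minisatellites is unknown, and no conclusion in the package
depends on its exact shape.

Two generator details matter for correctness rather than realism.
First, arrays are *maximal*: the two flank bases adjacent to each array
boundary are forced to differ from the cyclic continuation of the
pattern, as in curated reference sets. Without this, flanks occasionally
continue the repeat and copy measurements drift past the quarter-copy
validation tolerance. Second, allele arrays change length by whole
copies, so boundary phases are allele-independent.

**What passing tests do and do not show.** The generator's reads have
uniform coverage, substitution-only errors, and no mapping ambiguity
beyond the planted indistinguishable families. Passing the end-to-end
recovery test therefore demonstrates the correctness of the
pipeline's logic — matching, measurement, support counting, encoding,
filtering — not robustness to real-world coverage bias, indel errors, or
reference mismapping.

## Numerical and experimental design choices

* **Spanning-read support.** At coverage c and read length `rl`, an
  allele occupying `L = array + 20` bp is fully spanned by
  `Poisson(c/2 × (rl − L + 1)/rl)` reads per haplotype. Near `L ≈ rl`
  this expectation approaches zero, so the two-read support rule cannot
  recover borderline alleles at 30×. The recovery experiments therefore
  use loci with arrays at most about a third of the read length, where
  the support-failure probability per allele is below 1%. This is a
  Lander–Waterman design constraint decided before any test was run,
  not a tuned threshold.
* **Problem sizes.** The test suite runs cohorts up to 1000 samples ×
  400 loci (ancestry), a 1071-pair expression scan with 193 planted
  effects, 4000–5000-locus trios, and read-level recovery over
  20–30 loci × 2–3 samples at 30×; the whole suite completes in a few
  minutes on one CPU. These sizes were chosen as the smallest at which
  the binomial/FDR assertions have sensible power.
* **Ties and degenerate inputs.** DP tie-breaks are fixed (see above);
  empty FASTQ at zero coverage, empty reference sets, single-sample
  cohorts, zero-variance expression and rank-deficient covariate
  designs all have defined behavior (empty outputs or errors naming the
  offending columns/samples).

## Limitations

* Arrays longer than the read length are invisible by construction;
  every cohort quantity is conditional on detectability.
* The multi filter implements exactly the sex-aware
  "more alleles than expected chromosomes" rule; any finer published
  filtering criteria beyond that rule are not reproduced.
* The hidden-factor estimator is a simplified surrogate-variable
  procedure, not IA-SVA.
* Macrosatellites (patterns of hundreds to thousands of bp), SNP
  linkage, PCR bias and quality-score modeling are out of scope.
* The decision tree classifies super-population-scale structure; no
  admixture estimation or sub-population classification is attempted.

## A minimal session

```{r example, eval = FALSE}
cfg <- sim_config(n_populations = 2, samples_per_population = 30,
                  n_loci = 40, pattern_length_range = c(7, 15),
                  ref_copies_range = c(2, 4),
                  allele_cgl_range = c(-1, 1))
ref <- generate_reference(cfg, seed = 11)
truth <- sample_cohort(ref, cfg, seed = 12)

reads <- synthesize_reads(truth, ref, "S0001", read_length = 150,
                          coverage = 30, seed = 13)
calls <- genotype_sample(reads, ref, "S0001")

cohort <- vntr_cohort(truth_as_calls(truth), truth$samples, ref$loci)
copy_spectrum(cohort)$ratio
classify_common_private(cohort)
```
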