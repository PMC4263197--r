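---
title: "Combining multi-platform genotype data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining multi-platform genotype data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imputeqc)
```

## The problem

Biobank consortia genotype their cohorts on whatever SNP array each site
had at the time. The raw platforms overlap on far too few markers to pool
directly, so the standard remedy is to impute every per-site, per-platform
dataset up to a common dense reference panel and merge the *imputed*
probabilistic genotypes instead. Getting from a pile of heterogeneous
PLINK files to one analysis-ready dataset involves a long chain of
unglamorous but failure-prone steps — genome-build conversion, strand
harmonization, chromosome segmentation for parallel imputation,
post-imputation quality metrics, cross-dataset merging rules, duplicate
handling, and post-merge QC. `imputeqc` implements that chain as testable,
composable functions, together with a seeded simulator so the entire
pipeline can be exercised and verified on synthetic data.

The package deliberately does **not** reimplement production imputation
HMMs. A deterministic nearest-haplotype imputer stands in for them (see
below), behind the same file contracts (Oxford GEN + info metrics), so
real imputer output can be dropped in without code changes.

## Pipeline stages

### Build conversion

Marker coordinates are converted between genome builds through a
precomputed conversion table (one row per marker, old coordinates to new),
the artifact a batch coordinate-conversion run produces. Four steps run in
order: markers with indeterminate mappings (unknown chromosome and/or
position) are dropped; names, chromosomes and base-pair positions are
updated; output is re-sorted. Two surviving markers landing on the same
(chrom, pos) with the same allele pair is treated as a fatal collision
because downstream matching keys on exactly that triple. Coordinates are
1-based and fully closed throughout, as in GEN/haps/PLINK conventions.

### Strand harmonization

Array platforms report alleles on inconsistent strands, so every study
dataset must be rotated onto the reference panel's strand before
imputation. `classify_strand()` applies three criteria in order:

1. **Observed alleles.** A non-palindromic allele set equal to the
   reference set is kept; equal to the complemented set (A↔T, C↔G) is
   flipped; incompatible either way is discarded. Markers monomorphic in
   the study sample expose only one allele; they are oriented by whether
   that allele (or only its complement) belongs to the reference set, and
   discarded as unresolvable when both readings fit.
2. **Minor allele frequency.** Palindromic (A/T, C/G) markers carry no
   strand information in their labels. When both study and reference MAF
   are at or below `maf_ambiguity_bound` (default 0.4), the study minor
   allele is compared with the reference minor allele: agreement keeps,
   complement flips. The 0.4 default reflects that near 0.5 the identity
   of the minor allele is itself a coin flip.
3. **LD pattern.** When MAF is uninformative, the signs of dosage
   correlations with up to `window` (default 100) flanking non-palindromic
   markers are compared between study and reference. Neighbors count as
   informative when the reference correlation magnitude is at least 0.2;
   markers with fewer than 3 informative neighbors, or a tied vote, are
   discarded. A strict majority of inverted signs flips; of consistent
   signs keeps.

The thresholds in step 3 (|r| ≥ 0.2, ≥ 3 neighbors, strict majority) are
this package's concrete realization of "LD pattern within 100-SNP
windows"; they are exposed as arguments. Correlations are computed on
genotype dosages, not haplotypes, so the check is usable before phasing.
A flip never rewrites genotype data — it complements the allele *labels*
while 0/1 and dosage encodings keep their meaning under the relabeled
alleles.

Optional pre-filters (`filter_study_qc()`) mirror common input hygiene:
sample call rate ≥ 0.95, marker call rate ≥ 0.95, MAF ≥ 5%, and an
optional blanket removal of palindromic markers (off by default; strand
repair on non-palindromic markers is exact, and palindromic markers are
individually arbitrated).

### Segmentation

Two partitioning schemes are provided, matching the two ways production
imputers are parallelized:

* `plan_snplets()` — blocks of `core_size` consecutive study markers
  (default 30,000) with `buffer_size` flanking markers (default 700) on
  each side, truncated at chromosome ends.
* `plan_genomic_windows()` — consecutive base-pair windows (default 6 Mb)
  starting at the first imputation target, each flanked by a base-pair
  buffer (default 250 kb). Windows that overlap the centromere, terminal
  remnants shorter than a window, and windows containing no genotyped
  (type-2) marker are merged into the segment immediately upstream. When
  the offending window is the *first* one there is no upstream segment,
  so it merges into the following segment instead — the one boundary case
  the upstream rule cannot cover.

Internally window arithmetic is half-open so disjointness is checkable;
emitted bounds are inclusive. For SNPlet plans the base-pair core bounds
tile the chromosome (each internal boundary sits just before the next
core's first study marker) so that *imputed* reference markers falling
between two cores' study markers still have exactly one owning segment.
`stitch_segments()` removes buffer rows, concatenates cores in position
order, records the owning segment per marker, errors on markers claimed
by two cores, and warns (listing positions) on gaps.

### The stand-in imputer

`impute_segment()` is a deliberately simple, fully deterministic
imputation rule used to exercise the pipeline end to end: for each
pre-phased study haplotype, the `k` (default 5) reference haplotypes with
the highest Hamming agreement over the nearest `flank` (default 50)
genotyped markers are selected; each untyped allele probability is their
agreement-weighted vote, and genotype triplets are products over the two
haplotypes. Ties rank by reference haplotype index. Genotyped (type-2)
markers pass through as probability-1 triplets; a segment with zero
genotyped markers is refused, since there is no imputation basis.
Imputing a sample whose haplotypes are present in the panel with `k = 1`
reproduces its genotypes exactly — a property the tests assert. It makes
no claim to production accuracy: there is no recombination map, no
mutation model, and no proper hidden-state averaging.

Per-marker quality uses the standard variance-ratio *info* score: with
expected allele-A dosage $e_i = 2p_{AA,i} + p_{AB,i}$ and
$\theta = \bar e/2$,
$$\mathrm{info} = 1 - \frac{\overline{\mathrm{Var}}(d_i)}{2\theta(1-\theta)},$$
clipped to $[0,1]$, with $-1$ as the "undefined" sentinel (monomorphic
$\theta$ or all triplets missing). The score is invariant under AA↔BB
relabeling.

### Masked evaluation

`run_masked_eval()` hides a seeded fraction of genotyped markers,
re-imputes them, and scores each against the hidden truth: hard-call
concordance (argmax triplet if its probability reaches `call_threshold`,
default 0.9 — the threshold is a package choice, exposed on the CLI),
squared dosage correlation (allelic R², with the signed correlation also
reported for diagnostics), and the info score, summarized overall and by
MAF bin (widths 0.1 and 0.01 both supported). A dataset whose mean masked
concordance reaches 0.80 is flagged mergeable.

Two cautions the masked analysis itself demonstrates: concordance at
low-MAF markers is inflated (predicting the major homozygote everywhere
already exceeds 90% at MAF < 5%), so imputation *quality* monotonicity
with MAF should be read off the info score or allelic R², which rise
steeply from rare to common markers; concordance stays near 1 across the
range on a faithful panel.

### Merging

`merge_datasets()` implements the cross-dataset rules. Datasets are gated
first: fewer than 100 samples, a non-genome-wide platform, or masked
concordance below 0.80 excludes a dataset (boundaries inclusive on the
passing side). Markers are cross-matched by chromosome, position and
unordered allele pair — never by label — and only keys with info score
strictly above 0.7 in *every* eligible dataset survive. Output labels are
the plurality input label; plurality ties go to the rs-style label with
the larger numeric suffix (lexicographically larger when none is
rs-style — a deterministic extension of the larger-rs rule); any label
attached to more than one distinct position drops all its positions.
Datasets whose ordered alleles are reversed relative to the first
eligible dataset have P(AA)/P(BB) swapped per sample (an involution), and
their `exp_freq_a1` enters the average as `1 − value`. Merged info
metrics are equally weighted means with `-1` sentinels ignored (all-`-1`
stays `-1`); `type` is the numeric minimum; `snp_id` is always `"---"`.
Duplicate samples keep the copy from the dataset with the higher call
rate, ties and missing call rates falling back to dataset order (logged).

One ambiguity deserves note: whether the merged `exp_freq_a1` is only
anchor-relative or additionally forced to minor-allele orientation. Both
readings are implemented behind `minor_allele` (default `TRUE`, flipping
the averaged frequency once more when it exceeds 0.5, so the merged file
always reports minor-allele frequencies). The probability-file alignment
under reversed alleles is taken to be the symmetric P(AA)↔P(BB) swap.

### Post-merge QC

`qc_report()` reproduces the standard best-practices summaries on the
merged set: the strict info > 0.7 filter (0.3 and 0.9 supported as
liberal/conservative alternatives), marker call-rate tables at
{0.95, 0.98, 0.99}, sample call-rate tables computed *after* the 99%
marker filter (samples are reported, never removed), and MAF tables at
{0.05, 0.01, 0.005, 0.001, 0.0005, 0.0001} computed after the info and
99% call-rate filters with monomorphic markers excluded (a marker must
carry at least one copy of a minor allele). Call rates on probabilistic
genotypes require hard calls; the 0.9 hard-call threshold is a package
choice, exposed everywhere. MAF is computed from hard calls by default
(consistent with the call-rate framing), from dosages behind a flag.
Every table satisfies dropped + remaining = total and proportions summing
to exactly 1 — recomputation is exact even where printed tables round.

### Population structure

`king_kinship()` implements the KING-robust between-family estimator
$$\hat\phi_{ij} = \frac{N^{Aa,Aa}_{ij} - 2N^{AA,aa}_{ij}}
{N^{Aa}_i + N^{Aa}_j}$$
over markers non-missing in both samples (≈0.5 duplicates, ≈0.25
parent-offspring, ≈0 unrelated; robust to stratification).
`select_unrelated()` links pairs with $\hat\phi > 0.125$ (second-degree
relatives), and keeps one representative per connected component — the
highest call rate, ties to the smallest id. Relatives are removed before
pruning and PCA, matching the order of the protocol this package follows.

`ld_prune()` keeps common markers (MAF > 10%) and repeatedly slides a
100-marker window (step 5 — a package default; the protocol leaves the
step unstated) removing one of any pair with dosage r² at or above the
threshold (0.1 for the conservative setting, 0.4 as the lenient one)
until all surviving within-window pairs comply; the lower-MAF member of a
pair is removed, ties dropping the later marker. An optional cap thins
the survivors evenly toward a target count (off by default at desk
scale). `pca_genotypes()` standardizes each marker by its allele
frequency (center $2\hat p$, scale $\sqrt{2\hat p(1-\hat p)}$),
mean-imputes missing cells, and eigendecomposes the sample covariance
exactly — appropriate at desk scale; a randomized solver is a deliberate
non-feature until matrix sizes demand it. Up to 32 components are
returned; scree plots show the first 10 by default.

## The synthetic-data generator

`simulate_reference()` and `simulate_study()` generate every fixture the
tests use. Ancestral allele frequencies are uniform on (0.05, 0.95);
subpopulation frequencies follow a Balding–Nichols Beta around the
ancestral value with divergence `F`. Each subpopulation carries a small
founder pool (default 8), and every panel haplotype is a mosaic copy of
its subpopulation's founders with a per-marker switch probability
(default 0.02), which induces block LD that decays with marker distance
— mosaic copying was chosen over coalescent simulation for speed and
dependency-freedom; it is sufficient to create the LD the stand-in
imputer and the strand LD-check rely on. Study individuals pair randomly
drawn panel haplotypes; platforms observe overlapping marker subsets;
complement flips are injected on a recorded subset of non-palindromic
markers; coordinates are shifted to a stale build with a matching
conversion table (a fraction marked unmapped); duplicates are copied
across platforms with independent missingness. The seed fully determines
all output, and every injection is recorded in a truth store so each
pipeline stage can be checked against it.

Defaults describe a desk-scale study: one 5 Mb chromosome with 500
markers, 200 reference haplotypes, 100 study individuals on 3 platforms
(each genotyping 60% of markers, 60% of those shared), 2% injected
flips, 5 duplicate samples, 1% missingness. What the generator does
*not* emulate: realistic human demography and recombination maps, rare
variants below the ancestral-frequency floor except through drift,
genotyping error correlated with probe chemistry, indels, and the X
chromosome. Passing tests therefore demonstrate that the *bookkeeping
and rules* are correct, not that imputation accuracy transfers to real
cohorts.

## Numerical and degenerate-case choices

* Probabilities are written with 3 decimals (configurable); the `-1`
  sentinel is always written bare; triplets are never silently
  renormalized on I/O, and the all-zero triplet encodes missing.
* Hard-call argmax ties resolve to the first class (AA before AB before
  BB), deterministically.
* Monomorphic markers: excluded from MAF tables, undefined (`-1`) info,
  undefined allelic R²; PCA drops them before standardizing.
* Fewer samples than requested components truncates the PCA with a
  warning; an all-zero covariance yields zero variance-explained rather
  than NaN.
* PLINK text files do not record allele roles; on reading, `allele_a` is
  the lexicographically smaller observed allele, and markers monomorphic
  in the file keep `NA` for the unobserved allele (handled by the strand
  stage as described above).

## Problem sizes

The test-suite and verification runs use the generator defaults above
(hundreds of markers, tens to hundreds of samples), segment plans with
100-marker cores and 40-marker buffers, and the production parameters
(30,000/700, 6 Mb/250 kb) on synthetic marker grids of 65,000 markers for
the planning invariants. These sizes were chosen so every property is
exercised on multiple segments and platforms while any single check stays
in the seconds range.

## Known limitations

The stand-in imputer's accuracy degrades quickly when study haplotypes
are absent from the reference panel. LD-based strand arbitration of
palindromic markers is only as good as the local LD, and discards markers
honestly when fewer than three informative neighbors exist. Sample
identity across datasets is by exact `sample_id` match; genotype-based
duplicate detection is out of scope, as are chain-file parsing, indels,
X-chromosome handling, BGEN/binary-PLINK I/O, HWE testing and association
analysis.
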