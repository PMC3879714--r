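---
title: "Methods: panel-based microbiota quantification and amplicon taxonomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel-based microbiota quantification and amplicon taxonomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micropanel)
library(dplyr)
```

`micropanel` implements the analysis chain for a gut-microbiota profiling
assay built from 24 rRNA-gene primer sets (49 oligos) run on a 48 x 48
microfluidic singleplex qPCR chip, optionally followed by tagged-amplicon
sequencing of the harvested products. This vignette explains the models and
procedures, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was open.

## The primer panel

The panel targets the dominant intestinal phyla and nested subgroups at
domain, phylum, class, family, genus and species level. Each assay is a
forward primer plus one or more reverse primers (the *Enterococcus* assay
has two reverses and hence two expected products). Sequences may contain
IUPAC degenerate codes; matching honours degeneracy in the primer only, and
an `N` in a reference never matches — primers are the only degenerate
sequences in scope.

Binding-site coordinates use the conventional *E. coli* rRNA-gene numbering:
1-based, the forward position is the 5'-most base of the forward site, the
reverse position the 3'-most base of the reverse site, so that

```
amplicon length = reverse position − forward position + 1.
```

This convention is not arbitrary: it reproduces every printed expected size
in the shipped panel table, which `validate_panel()` checks row by row. The
table gives a single position per oligo, so the per-primer footprint
(which bases the primer itself covers) is deliberately left out of the size
check.

All primers except the species-specific ones carry a 22-nt universal tail
at the 5' end (forward and reverse tails differ), which lets a barcode
library be incorporated during amplification; `tagged_primer()` reconstructs
the synthesized oligo. The two assays that target the 23S gene (genus
*Lactobacillus*; class beta/gamma-proteobacteria) carry a gene flag so the
sequence-side taxonomy, which relies on a 16S reference collection, can
exclude them.

`predict_amplicons()` performs in-silico PCR: the forward primer is matched
on the given strand, each reverse primer as its reverse complement
downstream, on both orientations of the reference. A `max_mismatch`
parameter (default 0, i.e. exact degenerate matching) supports
mismatch-tolerant site search; the assay's specificity was established
empirically, not computationally, so exactness is the right default.

## From raw Cq to relative abundances

The chip crosses 48 detector inlets (24 assays in technical duplicate) with
48 sample inlets into 2304 singleplex chambers. `load_cq()` parses the
vendor-style grid export, accepting both point- and comma-decimal dialects
(the vendor software emits commas; detection is per file and can be forced)
and mapping configurable no-call tokens (default: empty cell and `999`) to
missing.

Processing order follows the text of the underlying protocol:

1. **Calibration** (`ipc_calibrate()`). Each run carries an interplate
   calibrator (IPC). The exact correction arithmetic is not fixed by the
   protocol, so the simplest scheme that makes runs comparable is used: per
   run and primer set, subtract the offset of the run's IPC Cq from the
   cross-run mean IPC Cq. It reduces to the identity for a single run; a
   per-run global offset is obtainable by collapsing the per-set offsets.
   IPC no-calls flag the affected run/set as uncorrectable rather than
   silently passing through.
2. **Cut-offs** (`apply_cutoffs()`). Cq values *exceeding* (strictly) a
   primer-specific cut-off are unspecific and become no-calls; a value at
   the boundary is retained. Cut-offs are a user-supplied table; absent
   entries default to the total cycle count. Filtering precedes replicate
   averaging, matching the order in which the steps are described.
3. **Replicate collapse** (`collapse_replicates()`). Technical duplicates
   are averaged; one called replicate is used as-is (discarding half-called
   pairs would inflate missingness), none gives a missing value.
4. **Quantification.** Relative quantities assume perfect per-cycle
   doubling: for every set X, `R_X = 2^(Cq_N − Cq_X)` against the
   general-bacteria normalizer N, which is taken to represent the whole
   community; for N itself the quantity is referred to the number of
   amplification cycles actually run, `R_N = 2^(35 − Cq_N)`. The constant
   35 is the sum of the PCR and C0t stages of the standard thermal protocol
   (`total_cycles()`); hot start and final extension do not amplify. An
   alternative normalization to each sample's mean Cq over all sets
   (`total_mean_normalize()`) is provided for sensitivity checks.

Under the same doubling model a 9-cycle separation between the highest
specific and lowest unspecific Cq bounds cross reaction at
`2^-9 = 0.195% < 1%` (`cross_reaction_fraction()`).

## The statistical pipeline

All abundances are analysed on the natural-log scale
(`abundance_matrix()`). Variable selection (`select_variables()`) applies,
in order:

1. drop variables with more than half the data missing;
2. among surviving ancestor/descendant pairs of the panel lineage with
   Pearson correlation above 0.99 (on pairwise-complete observations,
   computed *before* imputation), keep only the highest-level assay —
   conclusions drawn for it cover the collapsed sub-level assays. The rule
   applies to lineage pairs only; unrelated assays are never collapsed, and
   ties cannot occur because each lineage is a chain;
3. among the general-bacteria assays keep only the normalizer.

Remaining missingness (bounded at 0.35 per variable) is handled by EM
imputation under a multivariate Gaussian (`em_impute()`): each variable
depends freely on the others through an unstructured covariance, and on gut
section, diarrhoeic status and their interaction through cell means over
the 2 x 2 design. The E-step fills missing coordinates with their
conditional expectations (accumulating conditional covariances), the
M-step updates cell means and the pooled maximum-likelihood covariance
(denominator `n`, so nested likelihood ratios are internally consistent).
Defaults: relative log-likelihood tolerance 1e-8, at most 500 iterations,
initialization from per-cell observed means and the complete-case
covariance (diagonal fallback). The observed-data log-likelihood is checked
to be non-decreasing on every run; non-convergence raises a diagnostic
carrying the trajectory rather than returning a half-converged fit.

With as many variables as the study retains (15) and few samples (23) the
unstructured covariance is near-singular. An optional ridge
(`sigma + ridge * tr(sigma)/p * I`) stabilizes the EM and the downstream
inversions; with a ridge the likelihood can drift very slightly
non-monotonically, so the check downgrades to a single warning. The
simulation-based guarantees (type-I error, parameter recovery) are
established in the `p << n` regime where no ridge is needed.

Model control uses standardized residuals (`standardized_residuals()`):
residuals from the fitted cell means multiplied by the symmetric inverse
square root of the estimated covariance, which at the fitted model are
white up to sampling error.

Group effects are tested with Wilks likelihood-ratio tests (`wilks_lrt()`):

* `"S/L"` equates the section means within each status (status effects
  remain free to differ with gut section), two constrained mean vectors;
* `"S+/S-"` and `"L+/L-"` equate the status means within one section, one
  constrained vector.

The statistic is `-2 log Lambda` from the ratio of maximized likelihoods,
Bartlett-corrected as `(n − g − (p − m + 1)/2) · log(|Σ_r|/|Σ_f|)` and
referred to a chi-square with `p` degrees of freedom per constrained mean
vector (`m`). The exact reference distribution used historically for this
kind of test is not fixed; the Bartlett-corrected chi-square was chosen
over exact F transformations for transparency, and its calibration is
verified by simulation (type-I error within [0.03, 0.08] at the nominal
0.05, with p = 4 variables and n = 40). Significance is declared at
p < 0.05; no multiplicity correction is applied, matching the original
analysis design.

`primer_summaries()` back-transforms fitted cell means to estimated mean
percentages relative to total bacteria, `100·exp(mean)`, with Wald
intervals computed on the log scale and exponentiated — hence asymmetric
about the estimate, which is why this interval form was inferred. Standard
errors use the unbiased residual variance (`n − g` denominator).
Read-density comparisons between status groups use the two-sided Wilcoxon
rank-sum test (`wilcoxon_by_status()`), exact for up to 10 tie-free
observations per group, normal approximation with continuity correction
otherwise.

## The sequence-side pipeline

Reads have the 5' structure `barcode + forward tag + forward primer +
insert`. `demultiplex()` recognizes all three components in one pass
(degeneracy-aware for the primer), trims them, and reports rejects with
reason codes; only tagged assays participate, so the untagged
species-specific assays can never receive reads. When two assays' forward
primers can bind the same conserved position (the archaeal and
general-bacteria assays differ only at degenerate positions), candidates
are tried longest-first, then least-degenerate-first, so the exact assay
wins over a degenerate superset. Barcodes must be unique with pairwise
Hamming distance greater than twice the mismatch tolerance (default
tolerance 0); the built-in barcode generator emits 10-mers at pairwise
distance at least 5, synthetic stand-ins for a commercial barcode library
whose sequences are proprietary.

Cleaning (`quality_filter()`) keeps records whose mean per-base accuracy
(mean of `1 − 10^(−Q/10)`) is at least 0.96 and whose insert is at least
200 bp — the two published thresholds. "Minimum quality of 96%" is
interpreted as this read-level mean accuracy; a separate per-base gate
(Phred >= 15 by default) governs which windows may produce k-mers below.

Clustering (`greedy_cluster()`) is incremental greedy centroid formation at
99.5% identity: sequences are processed in a deterministic order
(descending length, then lexicographic — making the outcome independent of
input order), each joining the first centroid whose pairwise identity
(matches / alignment columns, global end-free alignment, fixed +1/−1
scoring) reaches the threshold, else founding a new cluster. The word-index
acceleration of production clustering tools is deliberately not reproduced;
correctness and auditability win at desk scale. Exact duplicates are
dereplicated first, and member counts always sum to the input count.

Taxonomy assignment uses quality-aware 8-mer set-overlap similarity
(`kmer_similarity()`): the percentage of the query's unique 8-mers found in
the reference's, with the query's count as denominator (the original
convention of this family of k-mer matchers; the published description
leaves the denominator open). Only windows whose every base reaches the
per-base Phred gate yield k-mers, and queries with fewer than 20 usable
8-mers are skipped to "unclassified" rather than scored. `kmer_search()`
returns hits within 1% of the best similarity ("return the best 1%
similarities" read as a relative band, not a count) that also reach the 50%
absolute cut-off. `assign_weighted_taxonomy()` then distributes each
cluster's reads over its hits proportionally to similarity, so scores sum
exactly to the read count and densities to 1 — the conservation constraint
the published description states; the precise score-to-density transform is
otherwise an interpretation and is flagged as such. Phylotypes below 1%
density are removed (`filter_density()`), their mass retained under a
`filtered` remainder so totals stay auditable. `specificity_matrix()`
partitions each 16S assay's densities into its target clade versus
off-target, the tabular form of the assay-specificity figure.

## The synthetic-data generator

The generator makes every pipeline stage testable without external data,
with full determinism under a fixed seed (`withr::with_seed`; no global
state, no time-based entropy).

**Reference collection** (`make_reference()`): one pseudo-rRNA sequence per
representative community member (one per assay, plus a named
*S. alactolyticus*-like species under *Streptococcus*), generated by seeded
mutation along the panel lineage so related taxa share recent backbone, on
a common ~1.3 kb coordinate frame mirroring the *E. coli* numbering. Real
rRNA genes are ~1.5 kb and the panel's printed coordinates span positions
7–1241, so full-length frames are the only way to plant every site at its
printed offset. Sites are planted broadest-assay-first; where two binding
sites physically overlap (several assays target the same conserved
regions) the more specific assay wins and the broader one simply fails to
amplify that member — exactly as competitive template mismatches behave.
Every planted product is verified by in-silico PCR into an `amplicons`
truth table, and forward sites are instantiated to remain
assay-distinguishable where degenerate primers of different assays bind the
same position.

**Chip runs** (`simulate_chip()`): the quantification formulas inverted.
Per sample the total-bacteria Cq follows the gut section's typical load
(the large intestine carries more bacteria), each assay's Cq is offset by
−log2 of its true clade fraction (a primer detects its whole target clade,
consistent with the panel's nested design), and noise enters at three
levels: per-sample load (default SD 1 cycle), per-sample-and-assay
biological variation (default SD 2 cycles — gut taxon abundances genuinely
vary by several log units between animals), and technical duplicates
(default SD 0.15 cycles). Missingness is injected completely at random per
sample and assay (scalar default 0.1, bounded at 0.35 — the regime the
imputation model is trusted in; named per-assay rates may exceed it to
emulate the assay dropout that removes variables from analysis, which is a
different mechanism from the MCAR noise the bound protects). An IPC sample
with a fixed community and no dropout is appended to every run. Group
sizes default to the study design: 5, 7, 4 and 7 samples for S−, S+, L−
and L+. The planted effects default to a 5-fold *Streptococcus* depletion
under diarrhoea with a compensating enterobacterial increase, and a
section effect enriching *Bacteroidetes*/clostridia in the large
intestine.

The `scenario_paper_missingness()` preset plants the observed selection
structure: five rare-clade assays miss >50% of their data (dropout rate
0.8 so the >1/2 criterion is met with margin at n = 23), and the two
lineage chains (beta/gamma-proteobacteria ~ Enterobacteriaceae ~ *E. coli*;
*Bacteroidetes* ~ *Bacteroides*) share their biological noise draw so their
log-abundances correlate above 0.99 — the mechanism by which nested assays
measuring the same organisms correlate in real data. Selection then
retains 15 of 24 assays.

**Reads** (`simulate_reads()`): per sample and tagged 16S assay, taxa are
drawn multinomially by abundance among the assay's amplifiable clade
members, and each read is assembled as barcode + forward tag + planted
forward site + amplicon interior, truncated to the configured read length,
with substitution errors at the configured per-base rate and qualities set
consistently with that rate. 23S assays are not simulated: the taxonomy
stage is 16S-only, and the *Lactobacillus* product (216 bp) minus its
primer cannot pass the 200 bp length filter anyway. Homopolymer indels,
the dominant error mode of the original sequencing chemistry, are out of
scope by default so alignment identities remain interpretable in tests.
The headline power scenario (5-fold *Streptococcus* depletion, 7 vs 5
samples, 1000 reads per sample) uses error-free reads, so that detection
power reflects community composition and multinomial sampling rather than
sequencing noise — error handling is exercised separately — and stays at
desk scale.

**What passing tests do and do not show.** The generator emulates the
study's design, noise magnitudes, missingness and effect structure, but
not PCR efficiency differences between assays (the assay is explicitly not
absolutely quantitative across primer sets), chimeras, homopolymer errors,
or a realistic reference database the size of a public 16S collection.
Green tests therefore certify the correctness and calibration of the
computations, not field performance on real sequencing runs.

## Problem sizes and interfaces

The simulation suites use deliberately modest sizes chosen to give the
statistical checks adequate Monte-Carlo resolution: 50 replicates at
n = 200 for EM parameter recovery, 1000 null replicates (p = 4, n = 40)
for type-I error, 20 seeds for the detection-power check, and 1000 random
pairs for the k-mer oracle. These are the package's own choices of
simulation size; the tested tolerances are stated next to each check.

The package's functions, the testthat suite and `scripts/acceptance.R` are
the interface: this is an analysis library, not a shell tool, so the
per-stage command-line wrappers a sequencing facility might want are left
to callers (every stage is a plain function over data frames and returns a
tibble, so wrapping is one `Rscript` line). Known limitations: the IPC
correction arithmetic and the k-mer score-to-density transform are
interpretations constrained by the published text rather than verbatim
re-implementations, and the Wilks reference distribution is the
Bartlett-corrected chi-square, not an exact F.
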