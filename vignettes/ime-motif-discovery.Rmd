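---
title: "Discovering intron-mediated enhancement motifs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering intron-mediated enhancement motifs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Intron-mediated enhancement (IME) is the elevation of a gene's expression by
sequences inside a transcribed intron, almost always the first one. Classical
screens for IME signals (the IMEter family) rank k-mers purely by their
enrichment in promoter-proximal versus distal introns. `imescan` implements a
screen that layers three further, independent lines of evidence on top of the
frequency criterion, all computable from population resequencing data and a
gene annotation:

1. **conservation** — functional motifs should be depleted of segregating
   SNPs, so a hexamer's masked-count conservation rate should be higher in
   first introns (where IME acts) than in other introns;
2. **relative frequency** — the IMEter rationale: normalised occurrence in
   first introns over normalised occurrence in other introns, `F > 1`;
3. **positional preference** — cis-regulatory elements tend to sit at
   characteristic positions; the binned distribution of a hexamer's relative
   start positions within first introns should be significantly non-uniform;
4. **positional contrast** — the positional distribution in first introns
   should differ from the one in other introns, excluding preferences that
   are generic properties of introns rather than of IME.

A hexamer passing all four criteria is a *candidate*; candidates are then
validated downstream by co-expression, expression level, allele-specific
expression over natural variants, and a feature-based expression classifier.

## The statistics

**Counting.** All k-mers are counted canonically (a k-mer and its reverse
complement are one class; for k = 6 there are `(4^6 + 4^3)/2 = 2080`
classes), with a step-1 window over each intron sequence in transcript
orientation. The first and last 3 bp of each intron are excluded so the
invariant splice-site dinucleotides do not dominate; windows containing `N`
or a masked position are skipped. Introns shorter than 10 bp are discarded
at extraction time.

**Conservation.** SNPs are taken from a population VCF, filtered to
positions with a haploid minor-allele count of at least 50 and at least 500
called alleles (thresholds are arguments; the synthetic pipeline scales the
called-allele requirement to its 200-accession panel, using 150). Each SNP
position is replaced by `*` and the counting repeated; the conservation rate
of a hexamer is the ratio masked count / unmasked count, computed separately
for first and other introns. The random expectation at SNP density `d` is
`(1 - d)^k`, the probability that a window contains no SNP.

**Relative frequency.** `F = (C_f / sum C_f) / (C_o / sum C_o)` over the
2080 classes. Ties (`F = 1`) fail the strict criterion.

**Positional entropy.** Each occurrence's relative position is its 1-based
start divided by the intron length; occurrences come only from the trimmed
interior, so positions never reach 0 or 1. Positions are binned into 10
equal bins and summarised as Shannon entropy with natural logarithm (the
base is a monotone rescaling and cannot affect p-values; the maximum is
`ln 10`). The null is simulated: multinomial draws of the same number of
occurrences over 10 uniform bins, with the add-one empirical p-value
`p = (1 + #{S_sim <= S_obs}) / (1 + n_sim)`.

**Positional contrast.** The 2 x 10 table of binned counts (first vs other
introns) is tested for homogeneity by a Monte-Carlo exact conditional test:
tables are drawn from the multivariate hypergeometric distribution given the
observed margins, and the add-one fraction of tables no more probable than
the observed one is reported. `stats::fisher.test`'s network algorithm is
available as `method = "exact"` for small tables and serves as the
cross-check in the test suite; full enumeration at genome-scale counts is
infeasible.

**Multiplicity.** Both positional p-value families are adjusted by
Benjamini-Hochberg across all observed hexamers; criteria 3 and 4 are
`q < alpha` with `alpha = 0.05` by default (exposed as a parameter, since
the per-criterion significance level interacts with the corpus size).

### Simulation resolution

An add-one empirical p-value can never fall below `1/(n_sim + 1)`. For BH
control across M ≈ 2080 hexamers to be *attainable* for a k-mer of rank r,
the floor must lie below `alpha * r / M`; at the conventional
`n_sim = 10^4` the floor is ~1e-4, which can never reach `0.05/2080` when
only a few k-mers carry true signal. The genome-wide scan therefore defaults
to `n_sim = 10^5` for both families (the single-k-mer function keeps 10^4 as
its default for interactive use). To keep the scan tractable the p-values
are computed in two stages: a 2000-draw first pass for every k-mer, then a
full-resolution second pass only where the coarse p-value is at most 0.1.
Both stages yield valid add-one p-values; k-mers left with the coarse
estimate have p-values far too large to influence any BH decision at
conventional alpha. Entropy nulls are cached per occurrence count and seeded
from that count, so results do not depend on the order in which k-mers are
processed.

## Validation machinery

**Co-expression.** Genes whose first intron contains a candidate (or its
reverse complement) should be co-regulated beyond what sharing any equally
frequent hexamer produces. For each candidate, control hexamers are matched
on first-intron occurrence count within ±10% (inclusive integer bounds);
the candidate's vector of all pairwise Pearson correlations (natural-log
expression across conditions) is compared to each control set's vector by
Cohen's d (pooled-SD form), and the mean d over controls is the candidate's
co-expression effect. Candidates with mean d > +0.05 are *refined*
candidates. Pair vectors above 200,000 pairs are subsampled with a fixed
seed; the elements of a pair-correlation vector are not independent, and the
effect size is used descriptively, exactly as in the screening procedure it
implements. Matching on occurrence (not gene-set size) controls for the
frequency-homology confound: homologous genes share both expression profile
and sequence, so an unmatched comparison would reward common hexamers.

**Expression level.** Per-gene median expression of a motif's gene set
versus a background set, Cohen's d plus Welch's t.

**IMEter-style scorer.** A pentamer log-odds scorer is trained on the corpus
at hand: canonical pentamer relative frequencies in TSS-proximal (first)
introns over distal (other) introns, `log2` ratio, with smoothing applied in
relative-frequency space (`+ pseudocount/4^5` to both rates — smoothing raw
counts would make the weights depend on corpus duplication). A sequence's
score is the sum of weights over its pentamer windows. This scorer stands in
for the published IMEter as a feature and comparator; it is trained on the
current corpus, not on an external training set, which every report states.

**Allelic effects.** For each motif, genes harbouring it in the reference
first intron are found (IUPAC-aware, both strands); accessions are split
into a canonical set (no alternate allele at any covered position, at least
one called genotype) and a variant set (at least one alternate allele
anywhere in the motif footprint). Genes with fewer than 2 accessions per
side are skipped. Per gene, Cohen's d (canonical − variant; positive means
the intact motif is expressed higher) with Welch's t-test — Welch because
the two accession groups have no reason to share a variance. Per motif, the
d values are summarised (mean, median, one-sample t), re-summarised over the
genes with uncorrected per-gene p < 0.05, and a Wilcoxon signed-rank test is
added for the significant subset; BH-FDR is applied across motifs within
each test family. Across motifs, enrichment of positive medians among
candidates versus non-candidate controls uses a one-sided (greater) Fisher
exact test, and the candidate positive count is tested against p0 = 0.5
with a two-sided exact binomial. The sidedness was fixed by matching the
tests' printed reference values and is stated in all reports. A gene whose
intron carries additional intact copies of the motif is still classified
"variant" if any copy is mutated; buffering by intact copies therefore
biases effects toward zero, which makes positive findings conservative.

**Consensus motifs.** Candidate hexamers are collapsed by average-linkage
hierarchical clustering of a gapless alignment distance: minimum over both
orientations and offsets −2..+2 of mismatches in the overlap plus 0.25 per
overhanging base, normalised by k. The default cut height of 0.22 merges
k-mers differing by one substitution (distance 1/6) or a one-base shift
(0.5/6) and their combinations, while keeping unrelated k-mers (≥ 2
substitutions, distance ≥ 1/3) apart. Per cluster, members are aligned to
the medoid, each column emits the IUPAC code covering all observed bases,
and columns supported by fewer than 2 member bases are trimmed from the
ends. Consensus orientation follows the medoid, so a family may be reported
as the reverse complement of its conventional spelling; the two are the same
double-stranded motif. A gapless metric cannot represent single-indel
relationships between hexamers — allowing internal gaps would merge families
that differ by an indel, which is precisely the distinction a 6-mer screen
means to keep — so families whose published grouping rests on gapped
alignments or on visual tree inspection may come out as separate clusters
here; the linkage heights are reported so a user can reproduce any manual
grouping.

## The expression classifier

25 first-intron features per gene: length; distance to the translation
start and to the TSS; the pentamer log-odds score; SNPs per bp;
differentially methylated positions in all-C and CG context (consumed as BED
intervals; both position counts and region counts are available, positions
by default — the two definitions coexist in the literature describing such
features); transposable-element count normalised by length; an intron
retention flag (1 iff the intron overlaps an exon of an alternative
transcript of the same gene); conserved non-coding positions normalised by
length; minimum folding energy consumed from a per-intron table and divided
by length + 40 (20 bp exon overhang at each side); base composition on the
splice-site-trimmed sequence; and the 10 reverse-complement-collapsed dimer
frequencies normalised by intron length. Computing folding thermodynamics
is out of scope — the energy table is a pluggable input, and the synthetic
generator fabricates plausibly scaled values (about −0.3 kcal/mol per bp
with Gaussian spread).

Labels are high/low expression split at the median of per-gene median
expression (ties to the low class), or, in quartile mode, only the top and
bottom quartiles (sharper contrast, middle half unlabeled). The classifier
is a random forest — 6000 trees, maximum depth 10, minimum 2 samples per
leaf, sqrt(25) features per split, 80/20 train/test split, 10-fold
cross-validated ROC on the whole labeled set — trained through xgboost's
parallel-tree (bagging) mode with a squared-error objective on 0/1 labels,
so trees are probability estimators and `min_child_weight` equals the
minimum leaf size exactly. This implementation was chosen because its tree
structure supports exact Shapley attributions natively; the one
hyperparameter without an exact analogue is the minimum-samples-per-split
of 5, which is dominated by the depth and leaf constraints at these data
sizes. Bagging uses subsample fraction 0.632, the expected unique fraction
of a bootstrap sample. Importances are (i) permutation MDA — held-out
accuracy drop averaged over 5 seeded permutations per feature — and (ii)
per-sample Shapley attributions, which sum with the base value to the model
output exactly up to the library's single-precision accumulation (observed
~1e-6 per 100 trees, ~2e-5 at 6000 trees).

## The synthetic corpus

The generator emits a complete, self-consistent study input set with known
truth: genome FASTA, GFF3 annotation, haploid VCF, condition- and
accession-wise expression TSVs, auxiliary BEDs and a folding-energy table.
Default study conditions: 500 genes on 2 chromosomes, both strands, 2-6
exons; first-intron lengths lognormal around ~260 bp and other introns
~160 bp (matching the first/other length asymmetry of plant genomes); GC
fraction 0.32 (AT-rich, typical of plant introns); 30% of genes carry their
first intron in the 5'UTR; introns carry GT..AG boundaries; 200 accessions;
SNP density 0.016/bp, suppressed by a factor 0.2 inside planted motif
copies; a two-point allele-frequency mixture (70% of sites with minor
counts 55-100, which pass the minor-allele-50 filter; the rest 2-40, which
mostly fail it) with 2% missing calls; 300 expression conditions.

The planted motif (default TTTCGA, 2 copies in the first introns of 33% of
genes, relative positions Beta(2,5), i.e. 5'-biased) defines the ground
truth. The planting intensity is chosen so the planted hexamer's total
first-intron count (~330 planted + ~95 background) lands inside the densest
stratum of background hexamer counts — the all-A/T hexamers, whose expected
count at GC 0.32 is ~430. Without this, a 500-gene corpus would contain no
occurrence-matched control hexamers within ±10% and the co-expression
validation could not run at all. Expression follows a single-factor model:
`value = baseline + 0.4 * motif + 0.6 * motif * f_c + N(0, 1)` per
condition (so motif genes are shifted and mutually correlated with expected
pairwise r of `0.36/1.36 ≈ 0.26`), and per accession
`value = baseline + 0.4 * motif − 0.5 * mutated + N(0, 1)`, making the
theoretical per-gene allele effect d = 0.5 exactly. An optional
`g_loading` couples the baseline to the first intron's standardised
G content (default 0, i.e. off), for classifier studies in which base
composition is a true expression determinant rather than a null feature.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: linkage disequilibrium and population structure
(variant accessions are independent across sites), homology (the
frequency-matched control design exists to absorb a confound the generator
does not create), realistic splicing signals beyond GT..AG, overlapping
genes, expression count noise (matrices are Gaussian on the log scale), and
any biological relationship between the auxiliary tracks (DMRs, CNS, TEs
are uniform random intervals; their classifier features are true negatives
by construction).

Problem sizes in the shipped checks were chosen to make every stage's
signal analysable in closed form at desk scale: the full pipeline runs on
the 500-gene corpus; allele-effect recovery uses 50 genes with 100
accessions per allele group; unit tests use 15-80-gene corpora. With the
default conditions the strict conservation inequality (criterion 1) for the
planted hexamer holds with roughly a two-sigma margin — the binding noise
source is the binomial variation of the masked-count ratio over the ~100
background occurrences in other introns — so on rare seeds the
planted-truth integration check can fail on that criterion; this is a
property of the study conditions, not of the estimator. Likewise, the
quartile-vs-median class-contrast comparison of the classifier is only
marginally positive in expectation here: at 500 genes, quartile labelling
halves the training set while the ideal-feature AUC gain from the sharper
contrast is only a few hundredths, so the sign of the comparison is close
to a coin flip on any single corpus — the contrast reliably helps only when
features predict expression broadly and the gene count is in the thousands.
One further artefact of planting exact motif copies is worth knowing:
frame-shifted relatives of the planted hexamer (for TTTCGA, the hexamer
TTCGAA spelled by every copy's trailing base) inherit its enrichment,
positional bias and gene set, and can legitimately pass all criteria
alongside it.

## Degenerate inputs and tie rules

Zero-occurrence k-mers have undefined entropy and conservation and are
excluded from candidacy with a warning. A k-mer absent from other introns
has `F = Inf` and passes criterion 2 only through the explicit finiteness
check. Equal conservation rates or `F = 1` fail their strict criteria.
Genes exactly at the label median go to the low class. Multi-allelic VCF
records count as one polymorphic position; indels are ignored; missing
genotype calls leave the called-allele denominator. An intron too short for
its trimmed window (`length < 2*trim + k`) contributes no windows. The
first intron of a gene with several transcripts is the rank-1 intron whose
5' end is closest to the gene's TSS, ties broken by longest transcript and
then transcript id.
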