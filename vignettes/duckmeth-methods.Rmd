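---
title: "Methods: context-resolved methylome, chromatin and small RNA analysis"
author: "duckmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: context-resolved methylome, chromatin and small RNA analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and motivation

`duckmeth` implements the statistics used to characterize a plant methylome
in which the RNA-directed DNA methylation (RdDM) and CMT2 pathways have
collapsed — the situation found in duckweed (*Spirodela polyrhiza*), a
rapidly clonally propagating aquatic monocot. In such a genome the
informative quantities are not differential-methylation calls but the
architecture of what remains: how much CG and CHG methylation is present
and whether it is symmetrically maintained across strands, whether CHH
methylation (and its CWA subcontext, the CMT2 signature) exists at all,
whether transposons retain CHH enrichment, how H3K9me2 heterochromatin is
distributed, which small RNA size classes are produced, and whether
apparent gene-body methylation (gbM) survives a blind statistical test.
The package covers that full path from a per-cytosine methylation table to
summary statistics, together with a seeded synthetic-data generator that
provides ground truth for every stage.

# Coordinate conventions

All internal containers are `GRanges` and follow the Bioconductor 1-based
closed convention. Converters live at the file boundaries: allc positions
are 1-based and map directly; GFF3 is native; BED (0-based half-open) is
converted by `rtracklayer` on import/export. Overlap semantics are
half-open in effect — an interval ending where another begins does not
overlap it — which `findOverlaps` on closed intervals yields naturally.
Each cytosine site is a width-1 range at the coordinate of the base on the
reference (Watson) strand; a minus-strand cytosine sits at the coordinate
of its complementary guanine, matching the allc convention.

# Context classification

The two bases 3' of a cytosine on its own strand define the plant
methylation contexts: CG, CHG and CHH (H = A, C or T). `duckmeth`
additionally records the subcontext splits that carry mechanistic
information:

* **CWG vs CCG** within CHG (W = A or T). CAG/CTG is palindromic at the
  cytosine and maintained as a strand-symmetric dyad by CMT3; CCG is not
  palindromic (the base opposite its G is itself a CG-context cytosine).
* **CWA vs non-CWA** within CHH. CWA enrichment diagnoses CMT2 activity;
  its absence alongside missing 24-nt siRNAs indicates both asymmetric
  pathways are gone.

Sites whose trinucleotide contains N, or that lie within 2 bp of their
strand's 3' sequence end, are emitted with context "undefined" and
excluded from every statistic; classification is still made when the
context is decidable (CGN is CG, since only the second base matters).
These exclusions avoid biased denominators at contig edges. Soft-masked
(lowercase) bases are folded to uppercase and recorded but not treated
specially.

Symmetric dyads are paired explicitly: each Watson CG with the Crick CG
one base downstream, each Watson CAG/CTG with the Crick CWG two bases
downstream. CCG sites are unpaired by default; `includeCCG = TRUE` exposes
the alternative pairing for sensitivity analysis, since published
strand-symmetry figures sometimes show "CHG" without stating whether CCG
was included.

# Weighted methylation

All levels are *weighted*: the sum of methylated read counts divided by
the sum of total read counts over qualifying sites — a coverage-weighted
pooled ratio, not a mean of per-site ratios. Two coverage floors are used,
both configurable:

* `minCov = 5` for aggregate levels (genome, windows, features,
  metaplots), the convention for weighted-level reporting;
* `minCov = 3` for per-site levels, site calls and dyad strand levels.

The aggregate floor is read as a per-site filter applied before summation
(the methylpy/Schultz convention); a per-region reading of the same
threshold would conflate coverage with region size. Sites on the
designated organelle control contig are excluded from nuclear statistics.

# Nonconversion and site calls

Sodium bisulfite fails to convert a small fraction of unmethylated
cytosines. The chloroplast genome is unmethylated, so the pooled level of
the control contig estimates the nonconversion rate
epsilon = sum(mc) / sum(cov) over all contexts there.

A site is *methylated* when its methylated read count is inconsistent
with nonconversion alone: one-sided binomial p = P(X >= mc | n = cov,
p = epsilon), followed by Benjamini–Hochberg correction and a q < 0.05
call. Correction is applied within each context class separately: CG, CHG
and CHH site counts and effect sizes differ by orders of magnitude, and a
joint correction would let the CG signal distort the CHH threshold. The
0.05 default is conventional, not derived.

# Metaplots

Locus bodies (start-to-stop for genes, first-to-last bp for transposons)
are divided into 20 proportional windows — window w of a length-L body
spans [floor(wL/20), floor((w+1)L/20)) in locus coordinates. The 1,000-bp
flanks are divided into 20 fixed 50-bp windows; constant-length flanks
make "proportional" and "fixed" coincide, and fixed width is the only
self-consistent reading. Minus-strand loci are mirrored so window 1 is
always the distal 5' flank window. One pooled weighted level is computed
per window across all loci (ratio of sums). For genes, body windows count
only positions inside the coding-exonic mask; flanks are unrestricted.
Windows running off a chromosome end contribute whatever sites exist.
Loci shorter than the window count are skipped with a warning.

# Feature enrichment and gbM

Per-feature methylation enrichment is a one-sided binomial test per
context against a background rate taken from the pooled counted positions
of all features of that type — coding-exonic positions for genes, the
full span for transposons — followed by BH correction across tested
features within each context. Two counting bases are implemented because
the published descriptions support both:

* **reads** (default): successes = methylated reads, trials = total
  reads;
* **sites**: successes = methylated sites (from the site calls),
  trials = sites with coverage >= 3.

A gene is classified **gbM** when CG-enriched without CHG or CHH
enrichment; any CHG/CHH enrichment takes precedence; features never
tested are insufficient-data. Note that the reads-basis binomial treats
reads as independent; with bimodal per-site levels real genes are
overdispersed relative to that null, so a genome-wide scan yields a tail
of nominally CG-enriched genes even when no biologically coherent gbM
class exists — the known false-positive behavior of blind gbM scans in
species that have lost gbM, visible on the synthetic fixture as well.

# Chromatin overlap

Peak occupancy is merged-peak coverage divided by genome length. Element
overlap counts an element once if it intersects >= 1 bp of any peak
(strand-ignorant). The Fisher exact test is computed from the
hypergeometric distribution in log space, with the two-sided p-value
summing all tables whose probability does not exceed the observed one
(with the standard 1e-7 relative tie slack). Because the "neither" cell
of an interval 2x2 table is not observable, it is estimated as
round(G / mean interval length) minus the other cells — a genome-slots
estimate in the bedtools-fisher style, floored at zero with a warning.
The estimator is isolated in `buildContingency()` so alternative
constructions can be swapped; enrichment conclusions should name the
construction used, as different tools' n22 estimates differ.

# Small RNA profile

The size profile is a pure length histogram of adapter-trimmed reads
(duplicates counted per occurrence — the plotted quantity is read
abundance), over a configurable 20–25-nt range, with reads shorter than
15 nt dropped. Alignment is out of scope; an id-filter hook lets an
external aligner's read list restrict the pool, covering both the
"all trimmed reads" and "genome-matched reads" readings of published
size-class figures.

# The synthetic generator

The generator emits a miniature genome whose *structure* mirrors the
study system while staying small enough (~212 kb) that the full pipeline
runs in seconds: 4 chromosomes of 50 kb stand in for 20 chromosomes of
~8 Mb, plus a 12-kb unmethylated chloroplast contig. Defaults encode the
study conditions:

* CG dyads methylated with probability 0.10 ("roughly 10% of CG sites"),
  CWG dyads with probability 0.03, CHH probability 0 (absent), CCG
  unmethylated when symmetric maintenance is on;
* methylated background dyads are **all-or-nothing**: both strands share
  true level 1, the fully maintained epiallele state. This bimodality is
  the realistic regime for maintained CG methylation and makes residual
  strand asymmetry attributable to nonconversion noise alone;
* gbM genes (2.5% of 96 genes) draw exonic CG levels from
  Beta(mean 0.85, concentration 20), shared across each dyad;
* coverage is Poisson with mean 20 (negative binomial behind a
  dispersion knob); observed counts are
  mc ~ Binomial(cov, level + (1 - level) * 0.005): nonconversion
  (epsilon = 0.005) contributes false-methylated signal on unmethylated
  molecules only, with sequencing error on methylated molecules folded
  into the level distribution;
* one 4-kb pericentromeric H3K9me2 domain per chromosome (scaled from
  ~400–600-kb domains) plus scattered 200–600-bp peaks until 15% genome
  occupancy; half the 40 LTR annotations sit inside the domains;
* small RNAs are 21-nt dominant (70%) with 24-nt nearly absent (5%),
  10,000 reads;
* genome GC is 0.43, gene segments (3 exons, 2 introns, >= 80 bp each)
  have Dirichlet-distributed proportions so exon/intron boundaries vary
  between genes as in real annotations; gene and LTR intervals may
  overlap each other, as real TE annotations do.

Everything is driven by a single seed (stage generators use seed, seed+1,
seed+2, seed+3) and a fixed seed reproduces every output byte-identically.
The truth table records each site's true level, region label and
simulated coverage, and `truthExpectedLevels()` gives the
law-of-large-numbers target — the coverage-weighted mean of
level + (1 - level) * epsilon — that pipeline estimates are compared to.

What the generator does **not** emulate: realistic transposon sequence,
read-level bisulfite simulation (counts are drawn directly), mapping
artifacts, batch effects, or biological overdispersion beyond the Beta
site-level model. Passing recovery tests therefore demonstrate
correctness of the statistics under the stated model, not robustness to
alignment or library artifacts.

# Problem sizes and numerical choices

The validation suite runs the classifier against an independent
regex-scan oracle on one hundred random 1-kb sequences; binomial tails
against direct summation up to n = 500 at 1e-12 relative error (tails
below double underflow are checked to underflow together); the Fisher
test against exhaustive enumeration for tables with totals up to 40 at
1e-10 absolute. Error control is checked on twenty replicate null
simulations of 1,000 genes (50 sites at 20x each) and power on genes at
three times the background CG level, under both counting bases. Recovery
runs use the default ~212-kb fixture at 20x (weighted-level and epsilon
recovery), 30x for dyad symmetry (>= 10,000 dyads), and a uniform-level
(0.3) run for metaplot flatness; these sizes make the whole suite run in
under a minute while leaving Monte-Carlo noise an order of magnitude
below each tolerance.

Ties in BH correction are handled by `stats::p.adjust` (stable step-up).
`enrichedFraction()` rounds half-away-from-zero, matching how published
per-mille fractions are printed. Degenerate inputs (empty methylomes,
all-zero tables, features without counted positions, windows without
sites) return NA or named errors rather than silent zeros.

# Known limitations

* The reads-basis feature test ignores site-level overdispersion (see
  above); the sites basis is less powerful but better calibrated when
  levels are bimodal. Both are reported; neither is "the" answer.
* The n22 genome-slots estimate makes the Fisher p-value construction-
  dependent; use it for ranking and order-of-magnitude statements.
* The dyad symmetry summary conditions on both strands reaching the
  coverage floor, which slightly favors well-covered regions.
* IUPAC ambiguity codes other than N are rejected rather than resolved.
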