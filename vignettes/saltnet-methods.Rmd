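---
title: "saltnet: models and methods behind the ceRNA pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{saltnet: models and methods behind the ceRNA pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltnet)
```

# Overview

`saltnet` reconstructs a miRNA-centric competing endogenous RNA (ceRNA)
network from whole-transcriptome RNA-seq of a two-condition plant stress
experiment (a salt-stressed vs control design with three biological
replicates per condition). The pipeline runs six stages:

1. **quantify** — normalization (FPKM, CPM, SRPBM) and per-class
   differential expression by a negative-binomial exact test;
2. **lncrna** — filtering of lncRNA candidates, positional classification
   against the coding annotation, and cis-target pairing;
3. **circrna** — back-splice junction calling from chimeric-segment
   alignments, circRNA typing and SRPBM quantification;
4. **duplex** — plant-style miRNA target prediction (Allen
   complementarity score plus a nearest-neighbor duplex energy model);
5. **mimic** — endogenous target mimic (miRNA sponge) detection;
6. **network** — assembly of the differential ceRNA network with hub and
   sponge annotation, exported as SIF/GraphML/TSV.

Because raw sequencing data for this kind of study are rarely deposited,
the package ships a first-class synthetic-data generator
(`synth_scenario()`, `synth_fixture()`) that emits a genome, annotation,
sequences, counts, and chimeric reads with known ground truth for every
stage. All validation in the test suite and the acceptance script runs
against these fixtures.

# Differential expression

## Model

Counts for feature $i$ in sample $j$ are modelled as negative binomial
with mean $\mu_{ij}$ and dispersion $\phi$:
$\mathrm{Var} = \mu + \phi\,\mu^2$. One **common dispersion** is estimated
by the method of moments, pooled over features and groups on
library-size-scaled counts:

$$\hat\phi = \frac{\sum_i (s_i^2 - \bar x_i)}{\sum_i \bar x_i^2},$$

floored at $10^{-8}$. Per-feature dispersion shrinkage (as in edgeR or
DESeq2) is deliberately out of scope; with three replicates per group a
single moment estimate over thousands of features is stable and keeps the
test exactly enumerable.

The two-sided p-value is an **exact conditional test**: after scaling all
samples to the mean library size, the group sums $S_1, S_2$ of $n_1, n_2$
replicates are NB with size $n_g/\phi$. Conditioning on the total
$s = S_1 + S_2$ under the null of equal means, the distribution over
$S_1 = 0,\dots,s$ is enumerated directly and the p-value is the total
probability of outcomes no more likely than the observed split. In the
$\phi \to 0$ limit this reduces to the conditional binomial test, which
the unit tests exploit as a degenerate oracle; the general case is checked
against direct convolution of `dnbinom` terms.

## Calling rules

Fold changes are computed on CPM with a pseudocount of 0.5 CPM on both
group means — the pseudocount prevents infinite fold changes for features
observed in only one condition. A feature is called:

* **mRNA / circRNA / miRNA**: `|log2FC| >= 1` and raw `p < 0.05`;
* **lncRNA**: `|log2FC| >= 1` and Benjamini–Hochberg `FDR < 0.05`.

This asymmetry between classes is reproduced deliberately from the
upstream analysis convention this pipeline mirrors, and is exposed as
configuration (`sig_on` in `de_test()`, `lncrna_sig_on` in the pipeline
config). Features with a total count below 10 across all samples are not
tested and are reported `ns` with `p = 1`.

Library-size (CPM) normalization assumes approximately balanced
up/down-regulation. Strongly asymmetric differential signal inflates one
group's library sizes and shrinks estimated fold changes toward zero
(composition bias); TMM-style robust normalization is a known remedy and
is out of scope here. The synthetic generator plants balanced signs for
this reason.

# lncRNA identification

Candidates are retained when **all** of the following hold, and removals
are annotated with the first failing rule (in this order):

| rule | threshold | removal reason |
|---|---|---|
| no same-strand exonic overlap with a known mRNA | — | `overlap` |
| spliced length | >= 200 nt | `length` |
| mean supporting read depth | >= 3 | `coverage` |
| CPC score | < 0.5 | `cpc` |
| CNCI score | < 0 | `cnci` |

One wording caveat is worth recording: read literally, the upstream
convention eliminates transcripts with CPC < 0.5 **and** CNCI < 0, which
would delete precisely the noncoding transcripts it is trying to keep.
`saltnet` resolves the contradiction in favour of standard usage of these
tools: low coding potential on both scores *retains* a candidate, and
transcripts at or above either threshold are treated as coding and
removed.

## Positional classes

Retained lncRNAs get one class code with precedence `x > o > i > j > u`:

* `x` — antisense: exonic overlap with a coding exon on the opposite strand;
* `o` — sense-overlapping: same-strand exonic overlap with a coding exon;
* `i` — intronic: contained entirely within an intron of a same-strand
  coding transcript;
* `j` — bidirectional: no exonic overlap, but the lncRNA 5' end lies
  within 1000 nt of a coding 5' end on the opposite strand (divergent,
  head-to-head orientation). The 1 kb window is configurable; no standard
  definition of "bidirectional" exists, so the choice is documented here
  and pinned by tests;
* `u` — intergenic otherwise.

The precedence order resolves multi-rule hits deterministically. An
opposite-strand intronic lncRNA falls through to `u`: only exon-exon
overlap counts for `x`/`o`, and `i` requires the same strand. Note that a
genuinely sense-overlapping transcript is removed by the `overlap` filter
before classification; class `o` therefore appears only when
classification is run on candidates that bypassed that filter, and the
synthetic generator uses such candidates to exercise the filter rule.

Cis targets pair each differential lncRNA with every gene whose genomic
span lies within 100 kb (boundary-inclusive; overlap counts as distance
0, spans measured from first exon start to last exon end). Pairs are
annotated with the Pearson correlation of `log2(FPKM + 1)` across samples;
a constant expression vector yields `NA` rather than an error.

# circRNA detection

A back-splice read is a two-segment chimeric alignment whose 3' segment
maps upstream of its 5' segment; the junction acceptor is the 3' segment
start, the donor the 5' segment end. Junctions grouped by
(chromosome, acceptor, donor, strand) are accepted when:

* at least one supporting read carries **<= 2 mismatches** (reads above
  the cap do not count as support — per-read evidence counting, as in
  CIRI-style callers);
* the span (donor − acceptor) is **strictly below 100 kb**.

Rejection reasons follow the precedence `mismatches → support → span` and
are mutually exclusive; a junction with zero emitted reads can never form
a candidate group and is "undetectable" by construction.

Typing against the annotation uses a ±2 nt boundary tolerance (alignment
jitter allowance): `exonic` when acceptor and donor both coincide with
exon boundaries of one same-strand transcript (with `n_exons` the number
of that transcript's exons enclosed by the junction), `ciRNA` when the
junction lies wholly within one intron of a same-strand transcript, and
`intergenic` otherwise — including junctions that overlap annotation
without a consistent spliced or intronic origin, since the type vocabulary
is fixed to these three. Abundance is quantified as SRPBM
(split reads per billion mapped reads): $\mathrm{reads} \times 10^9 /
\mathrm{mapped}$.

# miRNA target prediction

## Allen complementarity score

The duplex aligner minimises an additive penalty over the
miRNA–site duplex (miRNA positions numbered 1-based from the 5' end):

| state | penalty |
|---|---|
| Watson–Crick pair | 0 |
| G:U wobble | 0.5 |
| mismatch | 1 |
| bulged nucleotide (either side) | 1 |

Penalties are **doubled** when the miRNA position involved lies in
positions 2–13; a site-side bulge is doubled when *both* flanking miRNA
positions are in that region. Alignment is semi-global: the whole miRNA is
consumed and unaligned site overhangs are free. Ties are broken toward
fewer bulged nucleotides, then the 5'-most site placement, then a fixed
transition preference (pair > miRNA-gap > site-gap), making the reported
alignment canonical and byte-reproducible. The dynamic program is
implemented in C++ and checked against an independently coded recursion
in the test suite, with a true exhaustive path enumerator validating the
recursion on tiny duplexes.

## Duplex energy model and MFE ratio

Duplex free energy is a deliberately simple, fully documented
nearest-neighbor model — a package contract, not a reproduction of any
external folding engine:

* stack free energies for adjacent paired positions from a fixed 16-entry
  Watson–Crick table (kcal/mol, keyed by the miRNA-strand dinucleotide;
  see `saltnet:::STACK_WC`);
* +1.0 kcal/mol per G:U pair participating in a stack, capped so a stack
  is never destabilising (at −0.1 kcal/mol);
* +3.0 kcal/mol per internal loop/bulge event (a maximal run of unpaired
  columns between paired columns); terminal unpaired columns cost nothing;
* the total is clamped at 0.

The **MFE ratio** divides the site's energy by the energy of the fully
Watson–Crick-paired miRNA under the same model, clamped to [0, 1]; a
perfect complement scores exactly 1. One consequence of the loop term is
worth knowing: the ratio is *not* globally monotone in the number of
mismatches — mutating an isolated pair between two internal loops merges
them into a single loop and can lower the total energy. It is monotone for
terminal mismatch runs and always drops strictly below 1 for the first
mismatch, which is what the property tests assert.

`predict_targets()` scans every window of length miRNA + 3 (step 1),
keeps the best site per (miRNA, transcript) pair (lowest Allen score,
ties by lowest energy then 5'-most), and reports the pair when that site
has **Allen score <= 7** and **MFE ratio > 0.65**.

# Endogenous target mimics

`etm_check()` decides mimicry of an aligned ncRNA site by rule order,
recording the first violation:

1. exactly one bulge, on the **ncRNA side**, 1–5 nt long, located between
   two miRNA positions that both lie in the "middle" region
   (positions 9–12 by default; configurable) —
   violations: `bulge_side` (miRNA-side bulge, or no bulge at all),
   `bulge_position` (wrong place, wrong size, or multiple bulges);
2. no mismatch at any middle position (`middle_mismatch`);
3. at most 4 mismatches outside the middle (`mismatch_count`);
4. no run of 3 or more consecutive mismatches
   (`consecutive_mismatches`); runs are counted over miRNA positions and
   bulges do not interrupt a run.

G:U wobbles count as pairs throughout. A perfect complement *fails* —
it is a cleavage target, not a mimic — and no passing site can have an
Allen score of 0, since the mandatory bulge carries a positive penalty.
`scan_mimics()` slides a window of miRNA length + 5 so the largest
allowed bulge fits, and circRNA sequences are supplied back-splice-joined
(the circle's sequence with its first 25 nt appended) so
junction-crossing sites are discoverable. These rules are permissive
enough that occasional background sites in random sequence pass them;
this is expected behaviour, and planted-truth checks therefore compare
labels at the planted interval.

# Network assembly

Nodes are differential entities participating in at least one qualifying
edge; target edges require both the miRNA and the mRNA to be
differential, mimic edges the miRNA and the ncRNA. Multiple sites between
one pair collapse to a single edge carrying best-site evidence and a site
count. Triples enumerate (miRNA, mRNA, ncRNA) combinations sharing the
miRNA through one edge of each kind.

* A miRNA is flagged a **hub** when its degree strictly exceeds 6
  ("more than six" — degree 7 qualifies, 6 does not).
* A lncRNA/circRNA is flagged a **sponge** when it has mimic edges to at
  least 2 distinct miRNAs.

Exports: SIF (`mirna TAB targets|sponged_by TAB partner`), GraphML with
all node/edge attributes (losslessly re-importable via
`import_network_graphml()`), node/edge TSVs, and a JSON summary.

# The synthetic-data generator

`synth_scenario()` fixes the study conditions; every stage derives its
random stream deterministically from the scenario seed, and the same seed
reproduces every emitted file byte for byte.

What it emulates:

* one chromosome (2 Mb by default), features placed left-to-right with
  random gaps — the simplest layout that still exercises the 100 kb
  window rules;
* multi-exon mRNAs, mostly > 1000 nt with ~7 exons, vs short lncRNA
  candidates (35% under 300 nt, most under 600 nt, 1–2 exons) — the
  structural contrast between the two classes in real plant
  transcriptomes;
* lncRNA candidates of every positional class, plus filter decoys that
  each violate exactly one retention rule;
* 18–25 nt miRNAs; planted target sites (near-perfect complements) and
  target decoys (mismatches across the 5'-proximal doubled region);
  planted mimic sites satisfying all eTM rules and mimic decoys violating
  exactly one named rule each, so failure causes are attributable;
* back-splice junctions of all three types plus rejection decoys for each
  acceptance criterion (excess mismatches, zero support, excess span);
* NB counts (dispersion 0.1, a common bulk RNA-seq regime) over a
  3 vs 3 design with planted |log2FC| = 2 at balanced signs, and
  lncRNA–gene cis pairs sharing a per-sample lognormal latent factor
  (sd 1.0 on the log scale — a strong shared regulatory signal, so the
  planted positive correlation separates clearly from NB noise at three
  replicates).

Site constructions are verified against the package's own aligner at
generation time and redrawn when the dynamic program finds a different
optimal geometry (up to 60 draws): a planted site is only ground truth if
the aligner realises the intended label, which is exactly the contract
the downstream checks rely on. Planted interaction partners are given
priority when the DE subset is drawn, so the demo network is non-trivial;
the per-class DE fraction is unchanged.

What it does **not** emulate: read-level FASTQ simulation, sequencing
error, fragment/GC bias, isoform complexity, multi-chromosome genomes,
genuinely coding ORFs in mRNAs, and real coding-potential scores (CPC and
CNCI scores are drawn from simple uniform ranges on either side of the
thresholds). Passing tests therefore demonstrate the correctness of the
pipeline's logic under its stated model, not robustness to aligner
artefacts or biological confounders in real data.

# Numerical and validation choices

* Coordinates are 0-based half-open internally; GTF output is 1-based
  closed; site intervals in result tables are 1-based inclusive.
* Allen scores are half-integers; the C++ core works in doubled integer
  units so all comparisons are exact.
* BH adjustment is step-up `p.adjust(..., "BH")` over tested features
  only; ties in p are processed in stable feature-id order.
* Validation problem sizes: the duplex dynamic program is compared with
  an independent recursion on 10,000 random short duplexes (length 5-10,
  where the recursion is itself validated by exhaustive path enumeration);
  interval logic on 1000 random lncRNA configurations and 500 random
  junctions against per-base oracles; planted-site labelling on 50 true +
  50 decoy sites for both targets and mimics; DE calibration on a
  2000-feature null simulation (observed false-positive rate ~0.05) and
  power on 100 planted 4-fold features at mean >= 500 (observed ~0.99).
  The one-command demo (`saltnet_demo(seed = 42)`) runs the full pipeline
  on a 40-gene scenario and is asserted byte-reproducible.

# Known limitations

* No TMM/median-ratio normalization: strongly asymmetric DE biases CPM
  fold changes (see above).
* One common NB dispersion; no tagwise shrinkage, no GLM designs beyond
  two groups.
* The duplex energy model is a documented simplification; its constants
  are a package contract and are not calibrated to any external folding
  engine.
* The back-splice caller consumes simplified chimeric-segment tables; it
  does not re-align raw reads or reconstruct full-length circRNA isoforms.
* Expression-correlation filtering of ceRNA triples (and hypergeometric
  shared-miRNA scoring) is not applied; triples are purely structural.
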