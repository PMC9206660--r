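---
title: "Models and methods behind pepseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pepseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The assay and the analysis problem

pepseq analyzes pooled *self-editing* screens of peptide-prime-editor
fusions. Each cell carries a single library member: an 85-residue peptide
fused N-terminally to a PE2 prime editor (SpCas9 nickase plus reverse
transcriptase). All cells are treated with one pegRNA that writes a fixed
6-nt substitution (CCTCTG -> GAATTC) into a linker site directly adjacent
to the peptide's own coding sequence. Because the edited site and the
peptide barcode sit on the same amplicon, paired-end sequencing links
genotype to peptide: read 1 covers the peptide coding sequence, read 2 the
target site. The analysis question is which peptides raise (or lower) the
efficiency of the editor they are fused to.

The pipeline has five parts, mirroring the package's modules: library
design, a ground-truthed simulator, read processing, beta-binomial effect
inference, and an additive model for dual-peptide fusions.

# Library design

Proteins are tiled into 85-residue peptides starting every 45 residues.
The final tile is anchored at `length - 85` whenever the regular grid
stops short of the C-terminus, so every residue is covered and all
peptides have identical length; consecutive regular tiles overlap by 40
residues, giving near-2x coverage away from the ends. Proteins shorter
than one tile are rejected rather than padded. For every serine and
threonine in a wild-type tile, a phosphomimetic variant substitutes that
single residue with glutamate; combinatorial multi-site substitutions are
deliberately out of scope, consistent with a library whose mutant count
equals the number of S/T sites.

Encoding samples one codon per residue from a user-supplied codon-usage
table (uniform over sense codons by default) with two library-wide
contracts:

* the **first eight nucleotides** of each coding sequence are unique
  across the library — this is the demultiplexing key, matched exactly
  with no error tolerance;
* each phosphomimetic record carries a unique **9-nt tag**. Its genomic
  position is not pinned down by the assay description, so the package
  places it immediately 3' of the open reading frame, outside the
  translated frame; `aa_seq` and the translation round-trip are therefore
  unaffected, and the tag travels with the coding sequence in FASTA
  output.

Prefix collisions are resolved by resampling synonymous codons for the
first three residues. A hard limit is worth knowing about: the prefix
space equals the codon-degeneracy product of those residues, and a family
of peptides sharing a low-degeneracy start can exceed it (a Met-Trp-Met
start admits exactly one prefix). The encoder then reports the colliding
records instead of silently relaxing the contract. Coordinates are 0-based
half-open throughout.

# The synthetic screen generator

The simulator exists so that every downstream stage can be tested against
a known truth without any sequencing download, and its generative model is
exactly the model the inference assumes. Peptide $i$ has a Beta law for
its editing rate with parameters $(\alpha_i, \beta_i)$; replicate $j$
realizes $p_{ij} \sim \mathrm{Beta}(\alpha_i, \beta_i)$; read outcomes are
multinomial at the configured depth with prime-edited probability
$(1-\text{indel rate}) \cdot p_{ij} \cdot (1-\text{partial fraction})$,
which reduces to $y_{ij} \sim \mathrm{Bin}(n_j, p_{ij})$ when the nuisance
rates are zero. Replicates can share a batch label to share their Beta
draw, emulating replicates with a common library integration, which in
real screens correlate much more strongly than independent integrations.

Default study conditions were fixed once, from what the assay typically
shows, and are not tuned per analysis: baseline mean editing 0.2 (the
middle of the 16–28% edited-allele range the assay produces), indel rate
0.005 (the 0.3–0.7% range), partial-edit fraction 0.01 ("nearly all
remaining reads are unedited"), concentration $\alpha + \beta = 50$
(visible but not overwhelming replicate overdispersion), enhancer fold
1.5x over baseline, depth 1000 reads per peptide per replicate, and three
replicates with independent integrations.

Reads are built concretely: read 1 is a prefix of the peptide coding
sequence (plus tag), read 2 the amplicon carrying the planted allele.
Indel alleles are 1–3 nt insertions or deletions placed uniformly within
6 nt of the edited region, mimicking nick-proximal indels; the real indel
spectrum of prime editing is not modelled and this spectrum is a
stand-in. Partial edits carry a proper prefix of the alternative allele.
Substitution errors are applied per base at a configurable rate with a
two-level quality model: high (Q37) everywhere except error positions and
an optional random fraction, which get low (Q15). That is deliberately
minimal — the downstream filters are threshold tests at Q30, so two
levels on either side of the threshold exercise every branch; realistic
sequencer error profiles, quality curves and PCR duplicates are
non-goals. Everything is deterministic given the seed, to the byte, in
the written FASTQ.

What passing tests on these simulations do **not** show: robustness to
real error profiles (context-dependent, quality-correlated), to chimeric
or duplicated reads, or to library synthesis artifacts. They do show that
the counting and inference machinery is internally correct under the
model the method itself assumes.

# Read processing

Read 1 is used only for demultiplexing: exact match of its first eight
nucleotides against the library prefixes, unassigned otherwise. Read 2 is
aligned globally (Needleman–Wunsch) to the reference amplicon under match
+1, mismatch −1, gap open −5, gap extend 0 — read literally, any gap
costs 5 regardless of length, and end gaps are penalized like internal
ones. The optimum is computed by `Biostrings::pairwiseAlignment`, which
reproduces this scheme exactly (the suite checks it against exhaustive
enumeration of all global alignments on a thousand random pairs);
per-position events with reference and query coordinates are extracted
in-package. Because reads arriving from an amplicon concentrate on few
distinct sequences, `count_outcomes()` aligns each distinct read-2
sequence once and reuses the cached events, applying only the per-read
quality logic individually — the suite verifies this grouped path against
the single-read reference path read for read.

Three quality rules are applied to each aligned read, in order:

1. reads with mean PHRED quality below 30 are dropped (target read only;
   read 1 contributes nothing beyond its prefix);
2. mismatches at bases with quality below 30 are masked, i.e. treated as
   reference;
3. indels without at least three matching nucleotides of quality ≥ 30 on
   **both** sides are masked and removed before classification.

Classification precedence: any surviving indel makes the read `indel`;
else, if the edited region reads exactly as the alternative allele and no
unmasked mismatch lies elsewhere, `prime_edited`; else a read with zero
unmasked differences is `unedited`; everything else — including partial
installations of the edit — is `other`. Edit calling is all-or-nothing: a
read whose differences are a proper subset of the programmed edit
positions is `other`, not edited. Masking interacts with the edit region
in one direction only: masking a low-quality base reverts it to
reference, so it can never *create* an edit call, but it can rescue an
edited read whose only blemish is a low-quality error at a position where
reference and alternative allele agree.

Numerical conventions worth stating: traceback ties in the alignment are
resolved deterministically (by the aligner's fixed priority); the
counting table always contains every library peptide in every replicate,
with zeros; unassigned and quality-dropped reads are tallied separately
and conservation (kept + dropped + unassigned = total) is asserted in the
tests.

# Beta-binomial effect inference

Peptides with fewer than 100 kept reads in **any** replicate are removed
entirely (strictly-less-than: totals of exactly 100 survive). For each
remaining peptide the edited counts over $k$ replicates are modelled as
beta-binomial, and $(\alpha_i, \beta_i)$ is estimated by maximum
likelihood. The stationarity conditions of the log-likelihood
$\sum_j \ln B(y_j+\alpha,\, n_j-y_j+\beta) - k \ln B(\alpha,\beta)$
are the digamma score equations

$$\textstyle\sum_j [\psi(y_j+\alpha) - \psi(n_j+\alpha+\beta)]
  = k\,[\psi(\alpha) - \psi(\alpha+\beta)],$$

and analogously for $\beta$; the package solves them by gradient-based
optimization on the log scale, started from the moment estimate, and
verifies the result against direct likelihood-grid maximization in the
tests. When no interior stationary point is reached — a single replicate,
all counts at a boundary, or non-overdispersed data whose likelihood
supremum sits at infinite concentration — the estimator falls back to
moment matching and says so in its `method` field.

The moment-matching route views the beta-binomial as an overdispersed
binomial. With $m = \mathrm{mean}_j(y_j/n_j)$:

$$\mathrm{obsvar} = \mathrm{var}_j(y_j/n_j), \qquad
  \mathrm{expvar} = \frac{m(1-m)}{\mathrm{mean}_j(n_j)},$$
$$\alpha+\beta = \frac{\mathrm{mean}_j(n_j)-1}
  {\mathrm{obsvar}/\mathrm{expvar}-1} - 1, \qquad
  \alpha = m\,(\alpha+\beta).$$

The observed variance uses the $k-1$ denominator (small-$k$
unbiasedness). The concentration formula is genuinely depth-dependent —
scaling all counts tenfold changes it — and is undefined for
underdispersed data; in that branch the concentration is clamped to a cap
(default $10 \cdot \mathrm{mean}(n_j)$, i.e. "at most mildly
overdispersed at this depth") while preserving the mean. Means of exactly
0 or 1 get half a pseudocount so both parameters stay finite. Fitted laws
are summarized by the Beta mean $\alpha/(\alpha+\beta)$ and variance
$\alpha\beta/[(\alpha+\beta)^2(\alpha+\beta+1)]$.

Control peptides are pooled into a single fitted law — the screen's
comparison distribution. Each peptide's **exceedance probability** is
$P(Y_\text{pep} > Y_\text{ctrl}) + \tfrac12 P(Y_\text{pep} =
Y_\text{ctrl})$ with both counts beta-binomial at a common reference
depth, taken as the median kept depth across the screen (the assay
description never fixes this depth; the median is a neutral choice). The
tie-splitting term makes identical laws score exactly 0.5. The sum is
computed by exact pmf-product enumeration up to depth 5000 and Monte
Carlo beyond, seeded.

Hit tables combine three views. Per-replicate edited fractions are
divided by the mean control fraction of the same replicate (so control
fold change is 1 by construction, and replicates with zero control
editing are excluded with a warning); a two-sided paired t-test compares
each peptide's fractions with the per-replicate control means, with
Benjamini–Hochberg adjustment at the requested FDR; and peptides are
ranked by a composite priority — exceedance probability first, then
higher fitted mean, then lower fitted variance. The composite is a
documented design choice, not a claimed reproduction of any particular
published weighting. At three replicates the paired t-test is
deliberately weak (two degrees of freedom against integration-level
overdispersion), so small screens can produce strong rankings and zero
FDR-significant calls at once; the beta-binomial ranking is the primary
readout and the t-test columns are a complementary, conservative view.

# The additive dual-peptide model

For screens that fuse two peptides (one N-terminal, one C-terminal) in
all combinations, the package fits

$$\text{observed}(i, j) \approx \text{baseline} + a_i + b_j$$

by least squares on the per-pair **median** control-normalized edited
fraction across replicates. Effects are identifiable only up to a shift,
fixed by anchoring the control peptide at 0 in each position, so the
baseline is the predicted control-control level and predictions are
invariant to the anchoring choice. Separate N- and C-position effect
vectors are fitted rather than one shared effect per peptide, because the
assay distinguishes orientation; this is an interpretation of an
under-specified model and is stated as such. Additivity is quantified by
the Pearson correlation between predicted and observed per-pair medians
(over pairs, not replicates), reported as undefined when either vector
has zero variance, and disconnected pair designs are rejected rather than
silently fitted.

# Problem sizes and verification

The suite verifies, among others: alignment optimality against exhaustive
enumeration (1000 random pairs of length ≤ 6); each quality-filter clause
on constructed reads; exact identity between planted truth and counted
categories for an error-free 50-peptide, depth-500, 3-replicate screen;
the MLE against a likelihood-grid oracle on 200 random small instances
(mean agreement within 1e-3); recovery of known Beta laws at $k=8$,
$n=2000$ (≥ 95% of fitted means within 3 sampling SDs); a full
200-peptide screen with ten planted 1.5x enhancers ranked at AUROC >
0.95 with control fold change 1 ± 0.05; and exact recovery of planted
additive effects on a noiseless 10x10 dual grid (1e-8 against the
normal-equations oracle), with $r > 0.9$ at noise SD 0.05. The same
200-peptide screen is what `scripts/acceptance.R` re-runs end to end.

These sizes were chosen as the smallest at which the statistical claims
are meaningful; all scale linearly in depth and library size if larger
checks are wanted.

# Known limitations

* The aligner's gap model is the literal reading of "open −5, extend 0";
  if a screen's true pipeline charged extension, long indels would score
  differently.
* The indel spectrum, partial-edit structure and quality model of the
  simulator are stylized stand-ins, adequate for exercising filters and
  counters but not for benchmarking against real sequencer output.
* Inference is per-peptide maximum likelihood: no shrinkage across
  peptides, no batch-effect regression, no Bayesian posteriors.
* Prefix uniqueness can be unattainable for phosphomimetic families with
  low-degeneracy N-terminal codons; the encoder reports rather than
  repairs this.
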