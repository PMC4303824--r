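---
title: "Three-clade conservation and selection analysis with ReGenEvo"
author: "ReGenEvo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-clade conservation and selection analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ReGenEvo)
```

## The question and the model

Genes retained in metazoan genomes after the loss of their
essential-amino-acid pathway partners pose a simple dichotomy. If the
enzyme still performs a constrained function, its metazoan orthologs
should evolve like any conserved gene: tracking the species tree
`((metazoa, fungi), plant)` and showing the strongest similarity inside
Opisthokonta (metazoa + fungi). If the constraint was lost only in
metazoans, the fungal and plant copies — both still doing the ancestral
job — should resemble each other more than either resembles the metazoan
copies, and the metazoan lineage should accumulate non-synonymous
changes faster.

ReGenEvo operationalises this with three signals per gene family and a
conjunctive verdict. Each signal is deliberately simple, deterministic
and inspectable; the package's claim is not that any one of them is the
best available estimator, but that the three together discriminate the
two regimes cleanly, which the simulator lets us verify end to end.

### Signal 1: smoothed inter-clade conservation profiles

For one alignment column and one clade pair (A, B), every residue of A
is scored against every residue of B with BLOSUM62 and the |A|·|B|
values are averaged; their population standard deviation is kept as a
per-column dispersion. Columns containing a gap, `X` or any nonstandard
residue in *any* sequence are removed first, so the three clade-pair
profiles share a single x-axis. The per-column means `x` are then passed
through the first-order low-pass filter

y[n] = alpha * x[n] + (1 - alpha) * y[n - 1]

which exposes regional conservation tendencies rather than single-column
noise. The filter is directional, so it is applied to `x` as read and to
`rev(x)`, and the two outputs are averaged. Three numerical choices are
ours:

* **alpha = 0.05** by default. Smaller alpha smooths harder at the cost
  of positional resolution (time constant ≈ 1/alpha ≈ 20 columns). Note
  that it is *low* alpha that smooths: descriptions that attach "less
  noise" to *higher* alpha invert the recurrence as written above, and we
  implement the recurrence literally.
* **y[1] is initialised to x[1]** (the filter's steady state for a
  constant signal), avoiding a startup transient that would otherwise
  bias the first ~1/alpha columns toward an arbitrary origin.
* **Column indices are 1-based** throughout, the R convention.

The profile contrast compares mean smoothed *fp* against mean smoothed
*mf*: a difference above `delta` (default 0) in favour of *fp* is a
non-ToL call, the mirror case ToL-like, anything else indeterminate.
The original visual approach judged these diagrams by eye; `delta` makes
the rule explicit and tunable, and the margin (mean *fp* − mean *mf*, in
BLOSUM score units) is always reported so a user can apply their own
threshold.

### Signal 2: Nei–Gojobori Ka/Ks with clade-pair averaging

Protein alignments are back-translated against the source CDS (each
residue replaced by its own codon, gaps by `---`; a terminal stop codon
is tolerated and stripped; internal stops are an error; `X` residues
keep their source codon verbatim but never enter scoring). On the codon
alignment, each inter-clade pair is scored by NG86 counting:

* *Sites*: each codon position contributes a synonymous fraction equal
  to the number of synonymous single-nucleotide mutants over the number
  of non-stop mutants at that position. Synonymous plus non-synonymous
  sites sum to exactly 3 per codon — a conservation law the tests check
  for all 61 sense codons.
* *Differences*: for codons differing at k positions, the k! mutational
  orderings are enumerated; orderings passing through a stop codon are
  excluded and the remainder renormalised (if every ordering is blocked,
  all are used with stop-crossing steps counted as non-synonymous — a
  fallback that never occurs for sense-codon pairs under the standard
  code but keeps the function total).
* *Correction*: proportions pN, pS are Jukes–Cantor corrected,
  d = −(3/4)·ln(1 − (4/3)p). A proportion at or beyond 3/4 is flagged
  **saturated**; the estimate is `NA`, excluded from clade means, and
  counted per clade pair rather than capped — deep three-clade
  divergence saturates Ks routinely, and an arbitrary cap would leak
  into the averages.

Ka denotes the non-synonymous and Ks the synonymous rate, the standard
convention. The clade contrast calls a gene metazoan-elevated when mean
Ka(mf) > Ka(fp) *and* Ka(mp) > Ka(fp), strictly. As a stand-in for a
likelihood-ratio branch test, `kaksBootstrap()` resamples codon columns
(default 200 replicates) and reports a percentile CI for
Ka(mf) − Ka(fp); the pipeline verdict itself uses only the point
contrast, keeping it deterministic.

The implementation is table-driven (61 site counts, 61×61
pathway-averaged difference tables built once per session); the test
suite contains an independent brute-force enumeration oracle and checks
agreement to 1e−12 on random codon pairs.

### Signal 3: tree topology and the mf/fp ratio

Trees are built by neighbor joining (`ape::nj`) on Kimura-corrected
protein distances d = −ln(1 − p − 0.2p²), with p the mismatch
proportion over pairwise gap-free columns. Distances beyond the
formula's domain (p ≳ 0.854) are capped at 10 and flagged. Negative NJ
branch estimates are clamped to zero with the deficit moved to the
sibling edge. This replaces a full maximum-likelihood search: NJ on
corrected distances is deterministic, fast, exact on additive inputs
(tested on 50 random additive matrices per run), and sufficient for
*topology-class* recovery, which is all the verdict consumes. Users with
ML trees pass them straight to `classifyTopology()`/`runGene(tree=)`.

Unrooted trees are midpoint-rooted (`phangorn::midpoint`). Rooting
matters: with a strongly accelerated metazoan subtree the longest
leaf-to-leaf path runs from a metazoan to a plant leaf and its midpoint
falls on the metazoan stem, which is exactly what turns the (always
ToL-shaped) species topology into an *observed* autotrophic paraphyly —
the same long-branch geometry that produces this call on real
accelerated genes. Classification is by union monophyly on the rooted
tree: M∪F monophyletic → `tol_like`; F∪P → `autotrophic_paraphyly`;
M∪P → `fungi_outgroup`; none → `unresolved`. Union monophyly handles
paraphyletic constituent clades gracefully (fungi may be paraphyletic
while F∪P is still a clade).

The **mf/fp ratio** is our operationalisation of "relative branch
length": mean patristic distance over all metazoa×fungi leaf pairs
divided by the mean over all fungi×plant pairs. It is exposed as its own
function so alternative definitions (e.g. stem-branch ratios) can be
added without touching the classifier. Bootstrap support
(`bootstrapSupport()`, default 100 column-resampling replicates, seeded)
annotates the NJ tree but does not enter the verdict.

### The verdict

`finalClass(topology, conservation, kaksElevated)` is a pure function:
non-ToL requires `autotrophic_paraphyly` ∧ non-ToL conservation ∧
metazoan-elevated Ka; ToL requires `tol_like` ∧ ToL-like conservation ∧
no elevation; everything else — including `fungi_outgroup` trees, which
arise from lineage-specific duplication histories rather than functional
drift — is `mixed`. The conjunctive rule is our formalisation of the
qualitative practice of requiring phylogenetic, conservation and rate
evidence to agree before calling a gene non-ToL; `mixed` makes
disagreement explicit instead of forcing a binary call.

## The simulator: what it emulates and what it does not

`simulateFamily()` draws a random stop-free coding sequence and evolves
it by accept/reject point mutation down a species tree with the fixed
`((metazoa, fungi), plant)` topology: candidate mutations arrive as a
Poisson process (rate × branch length × sequence length), synonymous
candidates are always accepted, non-synonymous ones with probability
omega, stop-creating ones never. Acceleration multiplies the rate on the
metazoan stem and subtree; since a rate multiplier and a branch-length
multiplier are equivalent for this process, the multiplier is folded
into the branch lengths of the recorded `trueTree`.

Default conditions (chosen once, as the study design the package
emulates): **10 sequences per clade** (typical of curated three-clade
ortholog panels), **300 codons** (a mid-sized enzyme domain after gap
filtering), **omega = 0.2** (moderate purifying selection), branch
layout cladeDepth 0.15, metazoan/fungal stems 0.15, opisthokont stem
0.10, plant stem 0.30 (candidate substitutions per site). This puts
fungi–plant leaf divergence at 0.85 and metazoa–fungi at 0.60 — deep, as
befits >1 Gya splits, but below synonymous saturation so both Ka and Ks
remain estimable at the default length. The **non-ToL scenario** uses
metazoanMultiplier 3; an optional omegaMultiplier lets users separate a
faster clock from relaxed selection, two mechanisms the biological
hypothesis does not distinguish. Within-clade subtree shapes are random
coalescent draws rescaled to the fixed depth, so clades are ultrametric
and exchangeable.

On the true trees these choices make the diagnostics exact constants:
mf/fp = 0.6/0.85 ≈ 0.706 without acceleration and 1.2/0.85 ≈ 1.412 with
it, straddling 1 as the ratio interpretation requires.

The **"deep" preset** scales all branches six-fold and (unless the user
sets omega explicitly) tightens omega to 0.05. This is the regime of a
deeply diverged but strongly conserved protein, and it is the regime
that actually saturates NG86 Ks: working the site/pathway tables through
their limits shows synonymous-only drift saturates at pS ≈ 0.88 (well
past the 3/4 boundary, because two-fold degenerate sites contribute 1/3
of a synonymous site but up to half a synonymous difference), whereas
full codon randomisation under neutrality plateaus at pS ≈ 0.744 — just
*under* the boundary, so a neutral deep preset would flag saturation
only by sampling noise. Under the deep preset essentially all
fungi–plant pairs are flagged saturated while Ka stays near 0.26,
mirroring the real pattern of saturated Ks with estimable, sub-unity Ka.

What the simulator does **not** emulate — and hence what passing tests
do and do not show: no indels (families are born aligned, so the gap
filter and back-translation gap handling are exercised by constructed
fixtures, not by the simulator); no codon-frequency or
transition/transversion bias (NG86's equal-weighting assumptions are
exactly met, which is why the neutral calibration recovers Ka/Ks ≈ 1 —
on real data NG86 carries known biases); no rate heterogeneity among
sites or domains; no gene duplication/loss (the fungi-outgroup category
is reachable only via user-supplied trees); clean, complete, correctly
assigned orthologs. Recovery accuracy on the benchmark therefore
measures the pipeline's correctness and discriminative power under its
own model, not robustness to alignment error or model misspecification.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle or a
closed form: filter properties on 1,000 fuzzed signals; hand-checked
BLOSUM62 column scores; NG86 against brute-force enumeration (100 random
10-codon pairs, 1e−12); the 3-sites-per-codon conservation law over all
61 sense codons; NJ exactness on 50 random additive matrices (6–12
leaves); topology and ratio checks on noise-free generating trees;
back-translation round trips on fuzzed gapped families; and the
benchmark of 20 families per scenario at the default conditions with
recovery required in ≥90% of families, run twice to confirm
byte-identical outputs under one master seed. These sizes keep the full
suite under a couple of minutes on one CPU while leaving each stochastic
check comfortable margins; they are the package's chosen validation
conditions, stated here so users can scale them up.

## Known limitations

* NG86 with Jukes–Cantor correction underestimates divergence when
  substitution is biased; clade means additionally mix pair depths. The
  clade *contrast* (a within-gene comparison) is robust to much of this,
  but absolute Ka/Ks values should not be over-interpreted.
* Midpoint rooting assumes a roughly clock-like background; a gene with
  strong rate acceleration in a *non*-metazoan lineage could be
  mis-rooted and mis-classified. Supplying an outgroup-rooted tree
  sidesteps this.
* The conservation contrast reduces a whole profile to its mean; genes
  with regionally opposed signals (one domain non-ToL, another ToL)
  average toward indeterminate. The per-column TSV output and the
  profile plot are provided for exactly this inspection.
* The conjunctive verdict is conservative by construction: single-signal
  evidence yields `mixed`, never `non-ToL`.
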