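---
title: "Classifying genome-wide co-expression distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying genome-wide co-expression distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexshape)
```

## The model

A co-expression network built from a genes-by-samples matrix usually keeps
only the extreme pairwise correlations. coexshape works from the opposite
premise: the *whole* distribution of one gene's Pearson correlations to
every other expressed gene is a biological signal in itself. A gene
uncoupled from the transcriptome shows correlations piled up around zero
(a "null" distribution); a gene embedded in one large coordinated program
shows an excess of positive correlations (a negatively skewed
distribution); a gene positively tied to one program and negatively to
another shows strong correlations of both signs at once (a bimodal
distribution).

Each gene *i* is summarized by twelve numbers: the proportions
$OBP_{i,1..8}$ of its $G-1$ correlations falling into eight 0.25-wide bins
spanning $[-1, +1]$, plus the mean, SD, skewness and excess kurtosis
($OMN_i, OSD_i, OSK_i, OKU_i$) of those correlations. The same twelve
quantities are fixed in advance for eight template shapes $j$ (expected
values $EBP_{j,k}, EMN_j, ESD_j, ESK_j, EKU_j$), and the gene is compared
to every template by Euclidean distance

$$D_{i,j} = \Big[\textstyle\sum_{k=1}^{8}(OBP_{i,k}-EBP_{j,k})^2 +
(OMN_i-EMN_j)^2 + (OSD_i-ESD_j)^2 + (OSK_i-ESK_j)^2 +
(OKU_i-EKU_j)^2\Big]^{1/2},$$

rescaled per gene to similarities
$S_{i,j} = 1 - (D_{i,j}-\min_j D)/(\max_j D - \min_j D)$ and normalized to
probabilities $P_{i,j} = S_{i,j}/\sum_j S_{i,j}$. The gene is assigned to
the shape with the largest $P_{i,j}$.

The eight shapes partition three contrasts, fixed once and used by every
downstream test:

* null (1, 2) versus non-null (3-8),
* unimodal (1-4) versus bimodal (5-8),
* symmetric (1, 2, 5, 6) versus skewed (3, 4, 7, 8), with positive skew
  (excess negative correlations) for 3 and 7 and negative skew (excess
  positive correlations) for 4 and 8.

```{r templates}
default_templates()
```

## Template numerics and their provenance

The nominal bin proportions shipped with the package are ad-hoc constants
that realize each shape's qualitative definition: a narrow and a wide
central peak for the two null shapes, a mirrored pair of one-sided
unimodal profiles, an inner-mode and an outer-mode symmetric bimodal
profile, and a mirrored pair of end-heavy bimodal profiles. Their expected
moments are always *derived from the bin midpoints* by
`template_moments()`, with the same population-moment convention used for
the observed correlations, so the twelve distance components stay
commensurate. Any replacement table -- for instance one calibrated on a
specific compendium -- can be dropped in through `load_templates()`, which
accepts percent- or fraction-scaled rows and optional explicit moment
columns, and re-validates every structural predicate.

Validation is deliberately strict and machine-checkable:

* a null shape must hold at least 80% of its mass at $|r| < 0.5$ (the
  central four bins) and a non-null shape must not. We use the
  four-central-bin window because the wide null template spreads half its
  mass beyond $|r| = 0.25$ by design; a two-bin window cannot separate
  "wide null" from "non-null" at any single threshold.
* modality is counted on the bin profile (runs of equal bins collapse;
  profile ends count as one-sided maxima): unimodal shapes must have
  exactly one mode, bimodal shapes at least two separated by a strict
  local minimum.
* skewed shapes must have derived (or supplied) skewness of the flagged
  sign; symmetric shapes must have $|ESK| \le 0.05$.
* the shipped registry must additionally satisfy exact mirror closure:
  shape 4 is the bin-reverse of 3, and 8 of 7, which makes mirror
  equivariance of the classifier (reversing a gene's histogram and
  negating its mean and skewness swaps 3 with 4 and 7 with 8) an exact,
  testable property.

Bin terms enter the distance on the fraction scale (summing to 1), not the
percent scale (summing to 100). On the percent scale the squared bin terms
would outweigh the moment terms by roughly $10^4$ and the moments would be
decorative; `percent_scale = TRUE` reproduces that literal alternative for
comparison.

Two silent corners of the formulas are resolved explicitly: when all eight
distances are equal, the similarity rescaling is 0/0 and we define all
$S_{i,j} = 1$ (hence uniform $P$) with a tie flag; exact ties on the
maximum probability resolve to the lowest shape ID, also flagged. Genes
whose correlations are numerically constant get skewness and kurtosis
reported as 0 with a `degenerate` flag rather than NaN, keeping the
distance computable and the gene visible in the output.

## Binning and moment conventions

Bins are left-closed and right-open except the last, which is closed so
$r = 1$ is countable; values a few ulp outside $[-1, 1]$ from floating
point are clamped. Moments default to population (method-of-moments)
definitions with *excess* kurtosis, because the template moments are
moments of a discrete probability distribution, for which the n-corrected
sample estimators are not meaningful; a `"sample"` estimator variant is
available for the observed side. Correlations are Pearson throughout (a
Spearman switch exists as a documented extension and simply
rank-transforms the rows first).

Correlation summaries are computed in row blocks of the standardized
matrix, so memory stays $O(G \times \text{block})$; results are invariant
to block size, gene order and sample permutation, and are checked in the
tests against a per-pair `cor()` loop.

## Condition comparison

For two-condition designs the pipeline is rerun independently within each
condition on the shared gene set and per-gene shape pairs are classified
by which of the three dichotomies they cross. Correlations are recomputed
from scratch per condition -- nothing is residualized -- because a change
in a gene's genome-wide correlation pattern between phenotypic states is
exactly the signal of interest. Each condition must keep at least three
samples (fewer makes Pearson correlation degenerate), and genes constant
within either condition are excluded and reported.

## Enrichment and connectivity statistics

Category-within-shape enrichment uses both hypergeometric tails:
$p_\text{enrich} = P(X \ge k)$ (evaluated at $k-1$ with the upper tail,
avoiding the classic off-by-one) and $p_\text{deplete} = P(X \le k)$,
which satisfy $p_\text{enrich} + p_\text{deplete} = 1 + P(X = k)$ -- an
identity the tests assert exactly. Raw p-values at $\alpha = 0.05$ drive
the significance flag, mirroring the decision rule the method was
published with; Benjamini-Hochberg adjusted values over the whole
category-by-shape family are reported alongside for transparency, not for
gating. Dichotomy association uses Pearson's chi-square on the 2x2 table
without Yates correction by default (the corrected variant is a flag).
Connectivity analyses take per-gene degree from the PCIT-filtered network,
test degree across shapes by one-way fixed-effects ANOVA, and test the
top/bottom degree fractions (default 5%, boundary ties included) for shape
enrichment.

## PCIT

The network filter evaluates, for every gene trio $(x, y, z)$, the three
first-order partial correlations and a local tolerance
$\epsilon = \frac{1}{3}(|r_{xy.z}/r_{xy}| + |r_{xz.y}/r_{xz}| +
|r_{yz.x}/r_{yz}|)$; the edge $(x, y)$ is eliminated by the trio if
$|r_{xy}| \le \epsilon|r_{xz}|$ and $|r_{xy}| \le \epsilon|r_{yz}|$, and
an edge is significant only if no trio eliminates it. The absolute-ratio
tolerance keeps $\epsilon$ non-negative when partial and direct
correlations disagree in sign. The scan is vectorized over the
conditioning gene ($O(G^3)$ time, $O(G^2)$ memory) and is pinned in the
tests both to hand-computed three-gene cases and to a naive triple-loop
transcription of the rule on random matrices. Inputs with off-diagonal
correlations of exactly $\pm 1$ are rejected (the partials are undefined;
in practice this means duplicated genes should be removed upstream).

## What the simulator emulates -- and what it does not

`simulate_expression()` draws gene $g$ in module $m$ as
$x_g = w_g f_m + \sqrt{1-w_g^2}\,\varepsilon_g$ with a shared latent
factor per module, so within-module correlations concentrate at
$w_a w_b$ and anti-correlated blocks arise from opposite-signed weights
on one factor. This latent-factor Gaussian model was chosen over copula
constructions for transparency: the implied correlation structure is
closed-form, ground truth is exact, and a heavy-tailed noise switch
(unit-variance $t_3$) probes Pearson robustness. Ground truth is recorded
at the dichotomy level (null / one-sided / bimodal) rather than as exact
shape IDs, because exact IDs depend on the template numerics in use.

The simulator does *not* model counts, library sizes, dispersion, or
normalization artifacts -- it produces the post-normalization Gaussian-like
matrices the classifier consumes. Passing the synthetic recovery tests
therefore demonstrates that the pipeline identifies the correlation
structures it claims to identify; it does not certify behavior under
normalization pathologies, which the user owns upstream.

A composition effect is worth spelling out because it guided the standard
validation fixtures. A module's members show *negatively* skewed
correlation distributions only when the module spans at least about half
of the analyzed genes: with a minority module the positive-correlation
block is the minority mass of the histogram and the sample skewness of a
member's correlations is *positive*, landing the gene in the bimodal or
positive-skew shapes instead. Both regimes are real signal -- both are
non-null -- but the skew-direction label flips with module share. The
single-module validation fixture therefore uses a module of 150 genes out
of 300, where members' mean correlation is positive, their skewness
negative, and assignment lands in shape 8.

## Standard validation conditions

The test suite and `scripts/acceptance.R` regenerate everything from code
at fixed problem sizes, chosen so the whole suite runs in well under a
minute while keeping every effect unambiguous:

* noise-only: 300 genes, 50 samples -- at least 95% of genes must land in
  the null shapes, and the pooled correlation histogram must be centered
  (|mean| < 0.02) and symmetric.
* single positive module: 150 module genes (weight 0.9) + 150 noise
  genes, 50 samples -- module members in the negative-skew shapes and
  hypergeometrically enriched there at $p \le 0.05$.
* anti-correlated pair: 75 + 75 genes with weights $\pm 0.9$ on one
  factor + 150 noise genes -- members in bimodal shapes.
* condition rewiring: 300 genes, 100 samples per condition; 30 genes are
  noise in A and a weight-0.9 module in B. At least 80% of detected
  null/non-null transitions must be truly rewired genes, and a
  structure-free control must show at most 5% spurious transitions. The
  per-condition sample size of 100 keeps chance correlations between
  noise genes and the module factor (of order $1/\sqrt{n}$) from leaking
  noise genes into non-null shapes.
* connectivity: 100 module + 100 noise genes, 50 samples, full PCIT --
  degree-by-shape ANOVA at $p < 0.05$, bottom-5%-degree genes enriched in
  null shapes and top-5% in non-null shapes at $p \le 0.05$.

## Known limitations

* The skew-direction of a module's members is a function of module share
  (above), so shape IDs should be read jointly with the dichotomy flags.
* Template numerics are nominal defaults; results at the level of
  individual shape IDs (notably the sparsely-populated inner-mode bimodal
  shape 5) are sensitive to them, while the dichotomy-level conclusions
  are robust in our fixtures.
* The equal weighting of the twelve distance components means the four
  moments jointly carry about a third of the squared distance for typical
  profiles; distributions far from every template are resolved mostly by
  their moments.
* PCIT is $O(G^3)$: ~1 s at $G = 200$, minutes at $G \approx 2000$, and
  guarded by `max_genes = 5000` by default.
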