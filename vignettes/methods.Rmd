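---
title: "Genome scans from genomic evaluations: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome scans from genomic evaluations: models, tests and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`blupscan` turns a routine genomic evaluation into a genome-wide
association scan. This vignette is the package's own account of the
statistics it implements, the parameters that matter, what the built-in
simulator does and does not emulate, and the numerical and design choices
that were genuinely open.

## The model and the back-transformation

The centred animal model is

$$ y = X\beta + a + e, \qquad a \sim N(0, G\sigma_a^2), \quad
   e \sim N(0, I\sigma_e^2), $$

where $G = ZZ'$ and column $j$ of $Z$ standardizes the allele dosages by
the founder-generation reference-allele frequency $p_j$:
$z_{ij} = (m_{ij} - 2p_j) / \sqrt{m \, 2p_j(1-p_j)}$. Dividing by the
marker count $m$ inside the square root puts the average diagonal of $G$
near 1 when the dosages segregate at the frequencies used for scaling.
Frequencies come from the founders because they are the least related
animals in a cross; if no founders are flagged the whole sample is used,
with a warning.

This animal model is equivalent to the marker-effects (ridge) model
$y = X\beta + (NZ)g + e$ with $g \sim N(0, I\sigma_g^2)$ and
$\sigma_g^2 = \sigma_a^2$: identical fitted values, identical restricted
likelihood, and $a = Zg$. The equivalence is what makes the scan cheap —
after fitting the $n$-dimensional animal model once, every marker effect
follows from the linear map

$$ \hat g = Z' G^{-1} \hat a , $$

and because $ZZ'G^{-1} = I$ on the range of $G$, the reconstruction
$Z\hat g = \hat a$ holds to machine precision; the package asserts it on
every scan.

## The exact variance of a marker effect and the two tests

Writing $\mathrm{Var}(\hat a) = G\sigma_a^2 - \mathrm{PEV}(\hat a)$, with
$\mathrm{PEV}(\hat a) = C^{aa}\sigma_e^2$ the random-effect block of the
inverted mixed-model-equations coefficient matrix
$\begin{bmatrix} X'X & X'N \\ N'X & N'N + G^{-1}\lambda \end{bmatrix}$,
$\lambda = \sigma_e^2/\sigma_a^2$, the covariance of the back-transformed
effects is $Z'G^{-1}\mathrm{Var}(\hat a)G^{-1}Z$. Only its diagonal is
needed; `var_ghat_diag()` accumulates it column-by-column so the $m \times
m$ matrix is never formed, and the factor $G^{-1}Z$ is cached (it is
trait-independent and reusable). The PEV has a second, algebraically
equivalent route through the REML projection matrix,
$G\sigma_a^2 - \sigma_a^4\, G N' P N G$; the package computes both and the
test suite requires them to agree, which protects the reconstruction of
$C^{aa}$ from silent algebra errors.

Two standardizations are offered:

* **SNP_ej** $= \hat g_j / \sqrt{\mathrm{Var}(\hat g_j)}$ — each marker is
  scaled by its own estimation variance. This is the recommended test.
* **SNP_epj** $= \hat g_j / \sqrt{\sigma_g^2 - \mathrm{Var}(\hat g_j)}$ —
  scaling by the prediction error variance. Because
  $\mathrm{Var}(\hat g_j) \ll \sigma_g^2$ for any single marker on a dense
  panel, the denominator is nearly the same constant $\sqrt{\sigma_g^2}$
  for every marker, and the test is severely conservative. It is kept for
  comparison; the plasmode study quantifies the gap.

P-values are two-sided normal, $p_j = 2(1-\Phi(|t_j|))$, with no
degrees-of-freedom correction — the statistic is treated as exactly
standard normal. Markers whose estimation variance is numerically
degenerate are flagged with a reason code rather than given `NaN`
p-values, so multiple-testing counts stay explicit.

### When is SNP_ej calibrated?

$\mathrm{Var}(\hat g_j)$ is the *marginal* variance of the BLUP predictor
under the model's own prior, i.e. over draws of $g \sim N(0,
\sigma_g^2I)$. Under that regime the statistic is exactly standard normal
— the suite verifies a pooled SD of 1.00 at $n/m = 0.5$ with known
variance components. Against a *point null* ($g_j$ exactly 0, as in a
permutation), the conditional variance of $\hat g_j$ is smaller than the
marginal one by the leverage the marker's own prior effect contributes,
a deficit that scales with $n/m$. At panel scale ($m$ in the tens of
thousands, $n$ in the hundreds, $n/m \approx 0.02$) the deficit is
negligible and the test is uniform under the null; at the package's
desk-scale plasmode design ($n = 300$, $m = 800$, $n/m = 0.375$) the
measured null SD of SNP_ej is about 0.93 and the empirical size at 5% is
about 0.035 — mildly conservative. Users running plasmode checks on small
simulated panels should expect this; it is a property of testing a point
null with a prior-based variance, not an implementation artifact.

## Segment tests

Per chromosome, the marker with the largest $-\log_{10}p$ is selected
(ties: smaller position, then marker id) and expanded 1 Mb each way —
closed interval, positions compared in Mb at full precision. The segment
model partitions the additive variance,

$$ y = X\beta + a_1 + a_2 + e, \qquad a_1 \sim N(0, G_1\sigma_{a1}^2),
   \quad a_2 \sim N(0, G_2\sigma_{a2}^2), $$

where $G_1$ is built from the segment's markers *with its own
segment-size divisor* (a full-strength relationship matrix), while
$G_2 = G - Z_sZ_s'$ subtracts the genome-scaled segment columns from $G$.
These two scalings are intentionally different: the subtraction trick
keeps $G$ fixed across segments (compute once, reuse), and the identity
$Z_sZ_s' = (m_s/m)\,G_1$ — exposed as
`segment_crossprod_from_g1()` and tested — bridges them.

The reduced model is the single-GRM animal model; it is fitted once per
dataset and reused for every segment (its likelihood does not depend on
the segment). The LRT $2(\ell_2 - \ell_1)$ is referred to a chi-square
with **0.5** degrees of freedom, implemented literally as the upper tail
of a gamma with shape 0.25 and scale 2. This fractional-df reference is
unusual — the conventional null for a variance component on its boundary
is the mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ — but it reproduces
published segment-test p-values of this form exactly, so it is the
default; the mixture is available via `lrt_pvalue(..., mixture = TRUE)`
for sensitivity analysis. In practice the segment component sits on its
zero boundary well over half the time under the null (the segment and
complement matrices both carry the pedigree relatedness), so the
0.5-df reference is conservative there: measured null-segment size at 5%
was 0 over 20 simulated studies.

Bonferroni correction defaults to `genome_length_mb / (2 * half_width_mb)`
segments — 1400 for a 2800-Mb genome in 2-Mb windows, hence the threshold
0.05/1400 = 3.571429e-05 — with both the genome length and $\alpha$
configurable.

## REML: optimizers, constants, boundaries

* **Single GRM.** The eigendecomposition of $NGN'$ rotates the model to
  independent observations, reducing REML to a one-dimensional profile
  likelihood in the variance ratio $\gamma = \sigma_a^2/\sigma_e^2$,
  optimized by golden-section search on $\log\gamma \in [-18.4, 18.4]$
  with an explicit check of the $\gamma = 0$ boundary.
* **Two GRMs.** Bounded quasi-Newton (L-BFGS-B) on log variance
  components with the analytic gradient
  $-\tfrac12[\mathrm{tr}(PK_k) - y'PK_kPy]$, initialized from the
  single-GRM fit as $(0.1\hat\sigma_a^2,\, 0.9\hat\sigma_a^2,\,
  \hat\sigma_e^2)$. Components are floored at $10^{-10}\mathrm{var}(y)$
  and reported as 0 when they end on the floor.

Both paths evaluate the same exact restricted log-likelihood *including*
the $-(n-p)/2\log 2\pi$ constant, so likelihoods are comparable across
nested fits within a run (the LRT needs this); the test suite pins the two
routes to each other at $10^{-6}$. Printed log-likelihoods are comparable
only within a run — whether any published value includes the constant is
generally unknowable, so only likelihood *differences* are ever compared
to published numbers.

Rank-deficient $G$ (routine in a cross, where all genotypes are mosaics of
a few founder haplotypes) is handled once, up front:
`ensure_invertible_grm()` adds a ridge of $10^{-8}\overline{\mathrm{diag}(G)}$
only when the Cholesky factorization fails or is numerically singular, and
the same regularized matrix is then used everywhere ($G^{-1}$ in the MME,
the back-transformation, the complement subtraction), keeping all routes
mutually consistent. The ridge perturbs reported effects at the
$10^{-8}$ relative level.

## The plasmode harness

`run_plasmode()` repeats, per replicate: shuffle the target chromosome's
genotype block — jointly across rows (`LD_rows`, preserving within-block
LD exactly) or independently per column (`LE_columns`, forcing linkage
equilibrium) — recompute founder frequencies and the whole $G$ from the
permuted matrix, refit the animal model by REML, back-transform, and
collect the block markers' p-values, which are now known nulls. The
phenotype vector is never permuted. Markers that a shuffle leaves
monomorphic among the founder rows are dropped from that replicate (as QC
would drop them in a fresh analysis) and reported as `NA`. Replicate
sub-seeds are drawn once from the run seed, so runs are bit-reproducible
and single replicates can be replayed. $G$ is recomputed from scratch
every replicate — correctness over speed; at the default reduced scale
(100 replicates, $n = 300$, $m = 800$, 150-SNP block) a scenario takes
under ten seconds.

The QQ table uses order statistics of $-\log_{10}p$ (via quantiles, so
replicates with dropped markers keep a fixed length) averaged over
replicates, with a pointwise 95% envelope from the same number of
uniform-reference replicates of the same shape — the observed curves and
the reference band go through identical machinery.

## The F2 simulator: what it emulates, what it does not

`simulate_f2()` emulates a two-line resource cross: divergent founder
lines (4 + 15 founders by default), F1 from line-A sire × line-B dam
matings, F2 from F1 × F1 matings avoiding full sibs, meiosis with Haldane
crossovers (Poisson, 1 per 100 Mb by default). Founder haplotypes come
from a first-order Markov chain whose stationary frequencies follow a Beta
distribution and whose adjacent-marker correlation is `ld_rho` (default
0.8, chosen once as a realistic within-line association for a dense
livestock panel). Phenotypes are additive: true breeding value = centred
QTL dosages × effects, residual SD set so the F2 heritability equals
`h2_target` (default 0.42), plus a sex effect.

Known gaps between the simulator and real data:

* **Mid-range LD is too weak.** The Markov chain's correlation decays
  geometrically per marker, so at the default 0.2-Mb spacing the simulated
  F2 shows $r^2 \approx 0.05$–0.07 at 1 Mb, whereas real pig populations
  of this design show $r^2 \approx 0.2$ at 1 Mb. Short-range LD (needed
  for the plasmode LD/LE contrast) is strong ($r^2 \approx 0.4$ at
  0.2 Mb), but segment tests on simulated data lean more heavily on the
  causal marker itself than they would in real data. Neither `ld_rho` nor
  the line-divergence parameter can close this gap at this spacing.
* No genotyping error, no imputation error, no missing-position markers
  unless injected; `missing_rate` masks cells completely at random.
* QTL effects are purely additive; no dominance, no epistasis.

Consequently, green calibration and power results at desk scale show the
machinery is correct under its own assumptions; they do not certify
behaviour on real data with long-range LD.

## Study presets and problem sizes

Two presets fix the designs used by the tests, the acceptance script and
the documentation. `config_reduced_gwas()` (300 F2, 800 markers on three
chromosomes, the 150-marker chromosome being the plasmode shuffle target)
drives the equivalence, cross-method and type-I-error studies.
`config_segment_power()` (500 F2, 1000 markers on two chromosomes) places
one major QTL mid chromosome 1 with effect 0.506, sized so the QTL
explains about 12% of the phenotypic variance — the scale of segment the
method is meant to flag, matching the magnitude of the one significant
segment in the motivating application — plus four ±0.4 background QTL on
the same chromosome; chromosome 2 is QTL-free and supplies null segments.
At these sizes the full test suite runs in a few minutes. At the 12%
design the segment test's power against the 1400-segment Bonferroni
threshold is right around 50% — the LRT's critical value (14.73) sits in
the middle of the realized LRT distribution — so power tallies over 20
replicates land on either side of 10/20 depending on the seed; this is a
property of the design, reported as measured, not adjusted for.

## Other editing and interface choices

* QC order is fixed: unmapped markers → sample missingness → marker
  missingness → MAF, with MAF computed after sample removal; comparisons
  are strict (`> 0.10`, `< 0.01`). QC is idempotent.
* Missing dosage codes `NA`, `-9` and blank all map to missing; mean
  imputation by $2p_j$ makes imputed cells exactly neutral in the centred
  matrix. A post-imputation MAF re-filter would be a no-op under mean
  imputation and is not emulated.
* Positions are stored 1-based in bp as in PLINK maps; Mb is derived,
  never stored rounded.
* The counted allele of the input file is the reference allele; no MAF
  folding outside QC.
* The single-marker scan defaults to the P3D shortcut (null-model variance
  components reused across markers); `mode = "exact"` re-optimizes the
  variance ratio per marker. The tested SNP stays in $G$.
* GRMs round-trip through TSV at 17 significant digits with a metadata
  sidecar (frequencies, divisor, ridge epsilon).
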