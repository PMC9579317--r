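---
title: "Models and methods behind immqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind immqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immqtl)
```

# The populations

All four populations descend from one cross between homozygous parents
P1 (marker code 2, genotype *AA*) and P2 (code 0, *BB*).  The base
population PIL consists of pure-inbred lines — doubled haploids (one
meiosis, chromosome doubling) or recombinant inbred lines (repeated
selfing).  Because each line can be maintained by selfing, three
heterozygous populations can be reconstituted at will: IB1 (each line ×
P1), IB2 (each line × P2) and IF2 (crosses between pairs of distinct
lines).  The IF2 mimics F2 genotype frequencies — with balanced pair
sampling the single-locus distribution converges to 1:2:1 — while IB1
and IB2 contain only two genotype classes each (`{AA, AB}` and
`{AB, BB}`), a structural fact that drives everything below about what
is estimable where.

Only the PIL is genotyped.  Hybrid genotypes are deduced:
IB1 maps parental codes 2→2, 0→1; IB2 maps 0→0, 2→1; IF2 combines the
two parents' alleles ((2,2)→2, (0,0)→0, mixed→1).  Heterozygous calls in
the PIL are genotyping artefacts (pure lines are homozygous) and are
converted to missing; markers monomorphic among the observed lines
cannot separate the genotype classes and are dropped before mapping,
with the dropped list retained in the analysis context.

# Genotype priors

At a scan position flanked by informative markers at recombination
fractions $r_1$ and $r_2$, the probability that a homozygous line
carries the P1 allele follows from the no-interference two-interval
gamete classes.  Writing $t_1, t_2$ for the per-side transmission
probabilities ($t = 1-r$ if the flank shows the P1 allele, $r$
otherwise, and $\tfrac12$ when the side is missing or absent),

$$P(\text{P1 allele} \mid \text{flanks}) =
  \frac{t_1 t_2}{t_1 t_2 + (1-t_1)(1-t_2)}.$$

The unit tests verify this against a brute-force enumeration of the four
crossover configurations.  For RILs every pairwise fraction is first
expanded by the Haldane–Waddington map expansion $R = 2r/(1+2r)$ for
selfed RILs — the package assumes selfed rather than sib-mated RILs, a
choice flagged here because input files only distinguish "DH" from
"RIL".  Hybrid priors factorize over parental gametes: an IF2 individual
with parental P1-allele probabilities $p, q$ has class probabilities
$(pq,\; p(1-q)+q(1-p),\; (1-p)(1-q))$ over codes (2, 1, 0); IB1/IB2
inherit one fixed allele from the recurrent parent.

Missing marker calls are imputed (for the stepwise regression and
marker-correlation outputs) by the same engine: each missing cell takes
the more probable homozygote given its nearest non-missing flanks, exact
ties and fully uninformative cells falling back to the marker's more
frequent class and finally to code 2.  The mapping likelihood itself
never uses imputed calls — it marginalizes missing flanks through the
priors.

# Interval mapping and ICIM

At each scan position the phenotype is a three-component normal mixture

$$y_i \sim \sum_{g \in \{2,1,0\}} \pi_{ig}\,
  N\!\left(\mu_{pop(i)} + a x_g + d z_g,\; \sigma^2\right),
  \qquad x = (1, 0, -1),\; z = (0, 1, 0),$$

with $\pi_{ig}$ the marker-conditional priors above.  The F2-metric
parameterization makes $a$ and $d$ the usual additive and dominance
effects.  Combined designs share $(a, d)$ across member populations with
population-specific intercepts $\mu_{pop}$ and a **pooled** residual
variance; per-population variances were rejected because at desk-scale
sizes they destabilize the EM when one population carries little
information at a position.  The EM starts from the Haley–Knott
regression on prior-expected codings and iterates expectation /
weighted-least-squares steps until the relative log-likelihood change
falls below $10^{-6}$ (at most 200 iterations); at fully informative
positions the priors are degenerate, the EM converges in one step, and
the LOD equals the least-squares likelihood-ratio LOD
$\tfrac n2 \log_{10}(RSS_0/RSS_1)$ exactly — an identity the acceptance
suite asserts to $10^{-6}$.

LOD partitions are drop-one likelihood-ratio tests: the additive
(dominance) LOD refits the mixture with $a = 0$ ($d = 0$) rather than
using Wald approximations.  Dominance is structurally estimable only
when the group contains IF2 or both backcross populations; PIL-, IB1- or
IB2-alone fits report a single composite effect in the additive column
($a$, $a-d$, $a+d$ respectively) with the dominance column flagged not
estimable.

ICIM prepends stepwise regression of the phenotype on all marker
codings (additive for every marker, dominance where heterozygotes
exist; population intercepts forced).  Entry requires a partial-F
p-value at most PIN, removal requires p above POUT; the partial-F
machinery is implemented directly on QR decompositions.  The scan then
runs on phenotypes adjusted by all selected effects *except* those of
the two markers flanking the current interval, which are added back so
the local signal survives.  With nothing selected, ICIM reduces exactly
to IM (a unit-tested identity).  Permutation thresholds re-run the full
two-step scan on each within-population permutation, so the stepwise
selection is itself part of the null distribution, and take the
empirical $(1-\alpha)$ quantile of the genome-wide maximum LOD.

Peaks are maximal runs of positions at or above the threshold, one QTL
per run at the maximum (ties leftmost); the one-LOD support interval
extends from the peak while the LOD stays within 1 of the peak value,
clipped at chromosome ends.  PVE partitions at the peak use the
within-population-centred prior-expected codings,
$PVE_{add} = 100\, a^2 \mathrm{Var}(\bar x)/V_p$, with $V_p$ the pooled
within-population phenotypic variance — between-population mean
differences are absorbed by the intercepts and should not count as
explainable variance.  Posterior codings were the considered
alternative; prior codings keep the partition independent of the fitted
effects' magnitudes.

# Variance decomposition across populations

Per population, a one-way ANOVA with entries as the genetic factor
gives $V_{error} = MS_e$, $V_{geno} = \max(0, (MS_g - MS_e)/\bar r)$
with $\bar r$ the harmonic-mean replication number (the standard
approximation under unbalanced missingness), and entry-mean broad-sense
heritability $H^2 = V_{geno}/(V_{geno} + V_{error}/\bar r)$; a
plot-basis value is reported alongside since the basis convention is
not universal.  Raw (untruncated) components stay visible in the ANOVA
table.

Under single-locus theory with allele frequency ½, linkage equilibrium
and no epistasis, the genotypic variances have expectations

$$E[V_g(\mathrm{PIL})] = 2V_A,\qquad
  E[V_g(\mathrm{IF2})] = V_A + V_D,\qquad
  E[V_g(\mathrm{IB1}) + V_g(\mathrm{IB2})] = V_A + 2V_D,$$

where $V_A = \tfrac12\sum a_i^2$ and $V_D = \tfrac14\sum d_i^2$ are the
F2-reference additive and dominance variances.  The backcross
populations individually contain a $\pm\sum a_i d_i$ cross term; only
their sum cancels it, so IB1 and IB2 enter the estimator **only as a
sum** (using them individually would require estimating that covariance
term as a third parameter from the same two observations).  The
available equations are solved by non-negative least squares; when the
system is rank-deficient (e.g. only IB1+IB2 present) the identified
composite $V_A + 2V_D$ is reported with the components flagged, never
fabricated.  The error variance on the F2 scale is the DF-weighted pool
of the per-population error variances, and
$h^2 = V_A/(V_A + V_D + V_{error})$.

# The simulation engine

Meiosis is simulated as independent per-interval Bernoulli
recombination with probabilities from the chosen map function — no
interference beyond what the map function encodes, consistent with
interval-based map input and standard for QTL power simulators.  QTL
loci are inserted into the marker grid so marker and QTL genotypes are
drawn jointly with full linkage.  DH lines double one F1 gamete.  RILs
are ten selfing generations from the F1 followed by a forced-fixation
pass (residual heterozygous loci — below 0.2% at F10 — resolved to
either allele with probability ½), since downstream code treats pure
lines as fully homozygous.  IF2 pairing is either uniform random
(repeated pairs allowed, self-pairs never: a selfed line is not a
hybrid) or balanced, where each line appears exactly $2n_{IF2}/n_{PIL}$
times via random permutation blocks.

Genotypic values sum per-locus values $(v_2, v_1, v_0)$ plus optional
3×3 digenic deviation tables — the most general digenic form, since the
input format only needs to declare pairs and their tables.  Epistasis
enters only the generator, not the mapping models.  When noise is given
as a heritability, the error variance is
$V_e = V_G(F2)\,(1-h^2)/h^2$ with $V_G(F2)$ estimated from a simulated
reference F2 of 20,000 individuals rather than a closed form, so
linkage between QTLs and epistasis are automatically included; at that
size the conversion is accurate to about 2% and the acceptance checks
use the closed forms $a^2/2 + d^2/4$ for unlinked loci as the oracle.

The fixture generator's defaults are the package's reference study
conditions: seven chromosomes with eleven markers at 10 cM, Kosambi
function, DH lines, sizes 200/200/200/300 with balanced IF2 sampling,
three replications for ANOVA inputs, and a five-QTL trait (additive
effects 1…0.6, dominance 0.8…0.4, $h^2 = 0.6$).  What the generator
does **not** emulate — segregation distortion, genotyping error,
injected missingness, crossover interference, multi-environment
structure — bounds what passing tests say about real data: they
validate the estimators under their own assumptions, not robustness to
violations of them.

# Power analysis

Each run simulates fresh populations, maps every group with every
requested method, extracts QTL and matches them to the truth by a
greedy nearest-first rule on the same chromosome within the support
interval (default 10 cM), each detection and each true QTL used at most
once; the matching is therefore monotone in the support interval by
construction.  Power is the per-QTL fraction of matched runs; FDR pools
counts over runs, $\sum FP / (\sum TP + \sum FP)$, avoiding undefined
per-run ratios; per-interval detection frequencies assign each
detection to the marker interval containing its peak.  The default
per-run threshold is a fixed LOD 3 (flagged in the outputs); per-run
permutation thresholds are available but cost a full re-scan per
permutation.

# Numerical choices and tunable parameters

| parameter | default | meaning |
|---|---|---|
| `step` | 1 cM | scan grid spacing (markers always included) |
| `pin` / `pout` | 0.001 / 2·pin | stepwise entry/removal p-values |
| `threshold` | LOD 3.0 | fixed significance threshold |
| `n_perm`, `alpha` | 0 (off), 0.05 | permutation threshold settings |
| `si` | 10 cM | support interval for truth matching |
| EM | tol 1e-6, 200 iter | relative log-likelihood convergence |

Degenerate situations are resolved deterministically: residual-variance
estimates are floored at $10^{-10}\,\mathrm{Var}(y)$ so near-perfect
fits cannot produce non-positive variances; LOD values are clamped at 0
(the alternative nests the null, so negative values can only arise from
numerical noise); imputation and classification ties break towards code
2; peak ties break leftmost; constant traits report zero skewness and
kurtosis with a degeneracy flag.

The test suite runs the full machinery at reduced problem sizes chosen
to keep each property statistically decisive — e.g. recombination laws
at $n = 2000$ within 3σ binomial bands, variance recovery as the median
of 20 replicates of the reference conditions, permutation calibration
with 300 permutations against 400 fresh null scans, and the ICIM-vs-IM
comparison over 50 replicates of two coupling-phase QTLs 30 cM apart.
These sizes are the package's own choices for decisive yet quick
checks; all thresholds derive from the sampling distributions involved,
not from observed outcomes.

# Known limitations

One-dimensional scans only: epistatic QTL mapping and QTL-by-environment
interaction are out of scope (epistasis exists only in the generator),
and phenotypes must come from single-environment trials.  Linkage maps
are consumed, never constructed or re-estimated.  The combined-ANOVA
decomposition assumes linkage equilibrium and no epistasis; with linked
QTLs its components absorb covariance terms.  RILs are assumed selfed.
Input files are plain text; spreadsheet input is not supported.
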