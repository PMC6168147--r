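---
title: "Methods: diet, isotopic niche, and source-mixing analyses in isoforage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet, isotopic niche, and source-mixing analyses in isoforage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoforage)
```

`isoforage` implements the quantitative workflow of a combined gut-content and
natural stable-isotope study of two co-occurring reef predators — gray
triggerfish (*Balistes capriscus*) and red snapper (*Lutjanus campechanus*) —
sampled at artificial reefs across three coastal regions (east, central,
west) and three ontogenetic size classes (juvenile, sub-adult, adult). This
vignette describes each model, its assumptions, the tunable parameters, and
the design decisions taken where the methodology was genuinely open.

## The synthetic study design

The raw per-fish field data behind studies of this kind are rarely deposited,
so the package ships a generator whose defaults encode the study conditions:
unbalanced per-cell sample sizes for gut-content and isotope analyses (from 2
adult red snapper guts in the west up to 99 sub-adult guts in the east),
per-cell muscle means and standard errors for δ13C, δ15N, δ34S, pooled
primary-producer summaries (particulate organic matter, POM: δ13C −22.50 ‰,
δ15N 6.03 ‰, n = 12; benthic microalgae, BMA: δ13C −18.80 ‰, δ15N 5.27 ‰,
n = 9), and species-specific fork-length breakpoints between size classes
(gray triggerfish 111–183 / 184–283 / 284–382 mm FL; red snapper 145–222 /
223–356 / 357–570 mm FL). Published standard errors are converted to standard
deviations as SD = SE·√n using each cell's isotope sample size.

Within a cell, isotope triples are trivariate normal with diagonal covariance
by default: the group tables report only per-axis SEs, and we do not invent
correlations that were never stated. A full covariance override exists for
tests that need correlated axes.

Per-gut prey-group composition is generated from the same zero/one-inflated
Beta family the estimator assumes (below): each of the seven quantitative
prey groups (barnacles, bivalves, cnidarians, crabs, fish, gastropods,
stomatopods) is drawn independently, draws are renormalized to sum to one
when any group is non-zero, and all-zero guts are redrawn. The per-species
(π0, π1, α, β) defaults were chosen once to give zero-heavy guts with mean
contributions in the ballpark of the published patterns — crabs dominant in
both diets, barnacles exclusive to gray triggerfish, stomatopods rare in
gray triggerfish — and are constant across regions; regional structure can
be injected through the `prey_params` table when needed. Dry weights are
proportions times a lognormal total gut weight (median 1 g, σ_log = 0.5);
all %W analyses are scale-free, so any positive total works. Counts are one
plus a weight-scaled Poisson draw, which treats an occurrence of a colonial
or fragmentary taxon as at least one individual.

In cells where the gut and isotope sample sizes differ, the generator emits
`max(n_gut, n_iso)` fish; isotope-only fish carry excluded-type gut content
(bait, chyme, or empty guts), so that the exclusion filter recovers the
designed gut counts exactly, mirroring how field exclusions produced the
published totals (21% of red snapper guts excluded). What the generator does
*not* emulate: within-gut prey-size structure, taxon-level composition
beyond a representative family per group, seasonal or regional producer
variation, and any isotope–diet coupling within individuals — passing tests
therefore demonstrate correctness of the estimators under the stated
distributional assumptions, not robustness to the full messiness of field
data.

## Diet composition and the index of relative importance

Guts are excluded when empty or containing only unidentifiable content,
chyme, bait, parasites, or inorganic material; one identifiable item retains
the gut. Prey groups below 1% of total identifiable dry weight (threshold
configurable, ≥ rule at the boundary) are dropped once per species over all
its guts, matching how 16 field categories were reduced to 7 quantitative
groups globally rather than per cell.

For each reporting cell, %FO is the percentage of guts containing the group,
%N the percentage of all counted individuals, and %W the percentage of total
dry weight; %N and %W each sum to 100. The index of relative importance
follows Pinkas: IRI_g = (%N_g + %W_g)·%FO_g, normalized to %IRI summing
to 100. %IRI is computed within each reporting cell (species × size class or
species × region), matching how such results are presented per panel.

## Diet-mixture contribution estimation

Per-gut %W proportions for one prey group are zero-heavy with occasional
exact ones. The estimator models a proportion w as

* w = 0 with probability π0 (prey absent from the gut),
* w = 1 with probability π1 (gut filled by the prey),
* w ~ Beta(α, β) on (0, 1) otherwise,

with mean contribution p = π1 + (1 − π0 − π1)·α/(α + β). The point masses
have closed-form MLEs (observed fractions); the Beta shapes are fitted by
Nelder–Mead on (log α, log β) from a method-of-moments start, using
sufficient statistics so cost is independent of n. The cited mixture-model
literature does not print its interior density; the zero/one-inflated Beta
is the smallest standard family consistent with every stated property
(point masses at 0 and 1, a full/reduced distinction, ML estimation), and
the generator mirrors it exactly so consistency is testable.

Variant selection is deterministic from the data: `absent` when no gut
contains the group (reported `NA`), `inapplicable` when fewer than
`min_nonzero = 3` guts contain it (reported `X`; the source description says
only "insufficient number", so the cutoff is configurable), `full` when at
least one gut is 100% this prey, otherwise `reduced` with π1 ≡ 0 (reported
`*`). Requesting the reduced model on data containing an exact 1 is refused.
Degenerate interiors (a single value, or all values numerically equal) fall
back to a point mass at the observed mean and are flagged. Standard errors
are nonparametric bootstrap over guts (default 1000 resamples); the original
SE method is unstated, and the bootstrap tracks the Monte-Carlo sampling SD
within a factor of 1.3 at n = 100 in our tests.

Marginal fits are intentional: the per-group means are not constrained to
sum to 1 across prey groups, which matches how such tables are reported.

## PERMANOVA, pairwise tests, and SIMPER

%W is square-root transformed to damp dominant prey groups and converted to
Bray–Curtis dissimilarities (via `vegan::vegdist`). The one-way pseudo-F
comes from the squared-dissimilarity partition SS_total = Σ_{i<j} d²_ij/N
and SS_within = Σ_g Σ_{i<j∈g} d²_ij/n_g, F = (SS_B/(k−1))/(SS_W/(N−k)).
p-values use random relabeling with the (1 + count)/(1 + B) estimator, so p
is never zero; when the label multiset admits at most 10,000 distinct
arrangements the full enumeration is used and p is exact. The number of
distinct relabelings realized is reported alongside (the "unique perms"
convention). Pairwise tests report t = √F on the two-group restriction; the
p-value is identical under the monotone transform. Only one-way and pairwise
tests are implemented: the original three-factor crossed design ran in
proprietary software whose multi-factor permutation scheme is not described,
and the inferential content of the published table is pairwise.

SIMPER uses the additive decomposition of Bray–Curtis over variables,
δ_g(i,j) = 100·|x_ig − x_jg|/Σ_h(x_ih + x_jh), averaged over cross-group
pairs; contributions sum exactly to the overall average between-group
dissimilarity.

## Isotope comparisons, trophic level, and length adjustment

Delta notation is δ = (R_sample/R_standard − 1)·10³ (‰). Group contrasts use
one-way Pillai-trace MANOVA over the crossed cells (numerically equal to
Hotelling's T² for two groups) and per-axis Welch t tests under Shaffer's
modified-Bonferroni step-down: sorted p-values are tested against α/t_i,
where t_i is the largest number of pairwise nulls that can simultaneously be
true after i − 1 rejections (3, 1, 1 for three groups; computed by the
standard recursion for any k). Welch tests were chosen because the group
sizes are strongly unbalanced — the same motivation given for Shaffer's
procedure. Testing stops at the first non-rejection, so decisions are
monotone, and they always sit between Bonferroni's and unadjusted testing's.

Trophic level is Post's TL = 1 + (δ15N_fish − δ15N_prod)/Δn with Δn = 3.4 ‰
per step and δ15N_prod the sample-size-weighted POM/BMA pooled mean
(5.704 ‰ under the default design). Regional niche analyses pool size
classes, so isotope values are first length-adjusted, δX′ = δX − a·FL, with
a the OLS slope of δX on fork length; adjusted values have exactly zero OLS
slope and the operation is idempotent.

## Isotopic niches: standard ellipses and Layman metrics

The standard ellipse of a (δ13C, δ15N) scatter is the 1-SD Mahalanobis
contour of the sample covariance (denominator n − 1): SEA = π·√det(Σ̂),
containing 1 − e^(−1/2) ≈ 39.35% of its own bivariate normal distribution —
the conventional "40% of the data". The small-sample correction is
SEA_c = SEA·(n−1)/(n−2), requiring n ≥ 3.

Posterior uncertainty for the area uses the conjugate inverse-Wishart
posterior for Σ. The default prior is the vague (Jeffreys) limit, so
Σ | data ~ IW(n − 1, S) with S the centered sum of squares. This choice has
a useful exactness property: the credible interval for det Σ is a
probability pivot, so 95% intervals cover the true SEA at exactly 95% for
normal data (verified by simulation at n = 30 over 1000 datasets). A proper
normal-inverse-Wishart prior is available through `prior_df` and
`prior_scale` for sensitivity analysis; increasing the prior scale inflates
small-sample areas. Posterior mean areas exceed the ML SEA at small n,
converging as n grows.

Ellipse overlap is computed on the SEA_c contours by polygonal approximation
(512 vertices, relative area error ≈ 2.5·10⁻⁵) with exact convex-polygon
(Sutherland–Hodgman) clipping. The 0.60 significance rule is stated in the
source literature without a denominator; we therefore report all three
conventions — intersection over union, over the mean area, and over each
ellipse — with the union (the only symmetric, ≤ 1-bounded choice) driving
the significance flag by default.

Layman-style metrics are the mean distance to centroid (CD) and per-axis
ranges (CR, NR, SR for δ13C, δ15N, δ34S). CD defaults to the δ13C–δ15N
plane, consistent with the 2-D ellipse analyses it accompanies; a 3-axis
variant is available because the published table does not state
dimensionality. With unbalanced groups, bootstrap intervals resample exactly
m points per group per replicate, m being the smallest group size (default
10,000 replicates), so interval widths are comparable across groups.

## Two-source Bayesian mixing model

Contributions of pelagic (POM) and benthic (BMA) carbon are estimated from
consumer (δ13C, δ15N) with trophic discrimination factors 1.3 ± 0.30 ‰
(δ13C) and 3.4 ± 0.60 ‰ (δ15N) per step. δ34S is excluded: producer δ34S
was not obtainable on filters. The likelihood for consumer j and isotope iso
is

y_j,iso ~ Normal( Σ_k p_k(μ_k,iso + m·Δ_iso),
                  Σ_k p_k²(σ_k,iso² + m²·SD_Δ,iso²) + σ_res,iso² )

— "process" error (source spread and TDF uncertainty, mixture-weighted) plus
a free residual SD per isotope, the published two-error formulation closest
to "residual and process error". The prior is Dirichlet(1, 1) on
(p_POM, p_BMA) and half-normal (scale 3 ‰) on residual SDs; the model is not
concentration dependent. The trophic-step multiplier m is exposed rather
than fixed: consumers near trophic level 4 mixing directly against producers
need multi-step discrimination for mass balance, so the report pipeline uses
m = TL − 1 with TL from Post's equation, while m = 1 reproduces the
single-step convention. Both choices are legitimate; the difference is a
translation of the corrected consumer toward or away from the source
polygon, and with the printed group means no single m reproduces the
published posterior contributions exactly — the published headline
percentages are taken as not reproducible without the raw data.

Sampling is random-walk Metropolis on (logit p_POM, log σ_res) with proposal
scales adapted toward ~30% acceptance during burn-in only (adaptation then
freezes, preserving detailed balance in the retained draws); post-burn-in
draws are thinned to at most 10,000 per chain. The study-scale schedule is
100,000 iterations with 50,000 burn-in (escalating to 300,000/200,000 on
convergence failure); simulation tests use 10,000/5,000, which recovers true
contributions in {0.3, 0.5, 0.7} within ±0.05 at n = 60. Convergence is
monitored by split-chain Gelman–Rubin R-hat with a 1.05 threshold (the
diagnostic is standard; the original cutoff is unstated). The two-source
simplex makes the (p_POM, p_BMA) draw correlation exactly −1 — the negative
posterior correlation observed in such models is a structural property, not
evidence by itself of a missing source.

## Numerical choices and problem sizes

Boundary %W values within 10⁻⁹ of 0 or 100 are snapped before proportion
conversion; Beta optimization rejects shapes above 10⁸; ellipse fits refuse
singular covariances; permutation p-values compare with a 10⁻¹² slack so
ties count as exceedances. Simulation-based tests use: 10⁶ points for
ellipse coverage, 1000 datasets of n = 30 for credible-interval calibration,
2000 null datasets (n = 20, B = 199) for PERMANOVA type-I error, 20 seeds at
n = 10,000 for diet-mixture bias, and 20 seeds × 3 truth values at n = 60
(10,000 iterations, 3 chains) for mixing recovery — sizes at which the
Monte-Carlo error of each check is several times smaller than its tolerance.

## Known limitations

Multi-factor (crossed, interaction) PERMANOVA, dispersion tests (PERMDISP),
concentration-dependent or >2-source mixing, kernel-density niche
estimation, and joint compositional diet models are out of scope. The
diet-mixture interior family and the bootstrap SE are documented choices
where the original methodology is silent; conclusions that depend on them
should be checked against the reduced-information metrics (%FO, %N, %W)
that need no distributional assumptions.
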