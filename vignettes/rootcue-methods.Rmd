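---
title: "Methods and design choices in rootcue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in rootcue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootcue)
```

`rootcue` implements a screening workflow for identifying root metabolites
that guide the foraging of root-feeding insect larvae: curation of
untargeted LC-MS feature tables, differential-abundance screening between
root tissue types, targeted quantification of a benzoxazinoid panel,
behavioral choice and damage statistics, and a cross-reference of enriched
metabolites against compounds with known behavioral activity. This
vignette explains the statistical model behind each stage, the parameters
that matter, and the design decisions taken where the procedure was
genuinely open.

## Feature curation

An untargeted feature table holds one row per mass feature (an m/z ×
retention-time signal) and one intensity column per sample. Curation
reduces it to "informative features" in three stages.

**Retention-time exclusion** (`min_rt`, minutes; default 0.3). Features in
the void volume lack retention and co-elute excessively, so identification
is unreliable. The boundary is inclusive on the retained side: a feature
at exactly `rt = 0.3` is kept. The wording "eluting between 0 and 0.3
minutes" is ambiguous at the endpoint, so the curation report exposes the
boundary count (`n_at_rt_boundary`) to make the convention auditable.

**Mass-decimal exclusion** (`max_frac`; default 0.8). In the 100–1200 Da
range, masses with a fractional part above ~0.8 do not correspond to
feasible biological elemental compositions and are treated as instrument
artifacts. The boundary is strict (`> 0.8` removed); a tolerance of 1e-9
absorbs binary floating-point representation error, so a nominal mass of
250.80 is retained.

**Fragment grouping** (`rt_window` = 0.04 min, `r_min` = 0.8). In-source
fragments and adducts of one compound co-elute and share the compound's
abundance profile. Two features are linked when they elute within
`rt_window` of each other *and* their raw intensities have Pearson
*r* > `r_min` across all samples. Grouping precedes normalization in the
workflow, so the correlation is computed on raw intensities. Two open
choices were settled as follows:

* *Chain-wise vs pairwise.* The linkage condition can be required of every
  pair in a group (clique) or transitively (connected components). The
  default is connected components — the common behavior of co-elution
  grouping tools, and the only mode in which grouping is order-independent
  without further tie-breaking. `group_mode = "clique"` provides the
  stricter reading via a greedy clique partition (features assigned in
  decreasing mean-abundance order to the first clique they are fully
  linked to).
* *Zero variance.* A feature with constant intensity has undefined
  correlation; it receives no edges and becomes a singleton group, rather
  than being linked by convention.

Raising `r_min` or shrinking `rt_window` removes edges and can only split
groups, so the group count is monotone in both thresholds — a property the
test suite checks, along with exact equivalence of the partition to a
brute-force union–find over the explicitly enumerated edge set on hundreds
of random small tables.

**Representative selection.** If a group contains an identified compound,
its deprotonated molecular ion ([M−H]⁻, the quantifiable species in
negative-mode electrospray) is retained; otherwise the member with the
highest mean raw intensity across all samples. "Most abundant" uses the
mean rather than the single-sample maximum to be robust to one-sample
spikes. Two degenerate cases are handled with warnings: an identified
compound without an [M−H]⁻ member falls back to the most abundant member,
and a group containing two identified compounds is represented by the
lowest-m/z [M−H]⁻ feature.

## Differential screening

Peak areas are positive and strongly right-skewed, so intensities are
normalized with the inverse hyperbolic sine, ArcSinH(x) = ln(x + √(x²+1)),
which behaves like ln(2x) for large x but is defined and zero at zero. Note
the consequence: the classification is *not* invariant to rescaling all
intensities by a common constant near zero, only in the large-intensity
regime where ArcSinH is effectively a shifted logarithm.

Per feature, the two root types are compared with a two-sided
pooled-variance Student *t* test ("Student" is read literally;
`welch = TRUE` gives the unequal-variance alternative). Zero pooled
variance is resolved explicitly: equal means give t = 0, p = 1; unequal
means give p = 0 with a warning. P-values are Benjamini–Hochberg adjusted
across features (`stats::p.adjust` behind the exported `bh_fdr()`
surface), and a feature is called enriched when q < `alpha` (default 0.05)
*and* its fold change exceeds `fc_cut` (default 2). The fold change is
computed on raw (untransformed) group means, as peak-area ratios are
conventionally reported on the raw scale, while the test runs on the
transformed scale; both are returned. An infinite fold change (one group
mean zero) passes the fold-change criterion when the test is significant.
Because it is ambiguous whether published screens of this kind threshold
the adjusted or the raw p-value at 0.05, `use = "q"` (default) and
`use = "p"` are both supported.

For the 2 × 2 root-type × genotype design, every feature gets a
fixed-effects two-way ANOVA with interaction on the ArcSinH scale. For
unbalanced designs Type II sums of squares are used (via `car::Anova`) —
the standard choice in the absence of pre-specified contrasts; on balanced
data this reduces to the classical decomposition, which the tests verify
against an explicit sums-of-squares oracle. The interaction screen then
reports features with interaction q < 0.05 (excluding identified
compounds, whose behavior is assessed individually) and, separately,
additional features with a genotype main effect.

## Targeted quantification

Calibration curves are least-squares fits of UV area on standard
concentration *through the origin*: a blank has zero signal, and a ratio
(area per concentration) is what the downstream conversion uses.
Concentrations are scaled by extraction volume over tissue fresh weight to
µg g⁻¹ FW. For compounds too dilute to give reliable UV signals, a
compound-specific MS-to-UV conversion factor — the through-origin slope
Σ(uv·ms)/Σ(ms²) over samples where both channels are reliable — predicts
the UV signal from the more sensitive MS channel; every quantified value
carries a `measured`/`predicted` provenance flag. The reliability floor is
a parameter (`uv_floor`) because no universal threshold exists; the
synthetic generator suggests 3× the expected blank amplitude.

Knockout efficiency is reported as 100 × (1 − Σmutant/ΣWT) on *total*
summed concentrations (the headline number), with per-root-type and
per-compound reductions alongside, since a statement like "reduced by more
than 97%" can be read either way. The quantity is bounded above by 100,
attained only when the mutant total is exactly zero.

Relative gene expression uses 2^−ΔΔCt: ΔCt = Ct(target) − Ct(reference)
per sample, ΔΔCt relative to the mean control ΔCt. The estimator is
invariant to adding a constant to all Ct values, and reproduces powers of
two exactly for integer ΔΔCt — both properties are tested.

## Behavioral statistics

**Choice assays.** Each treatment × timepoint cell is tested on the dish
counts of larvae on option A out of the deciding larvae. Undecided larvae
(on neither option) are excluded from the denominator — the alternative
"off-option as failure" reading would conflate indecision with avoidance.
The cell test is an intercept-only binomial GLM with a Wald test of
logit = 0, with the standard error inflated by √φ when the Pearson
dispersion φ exceeds 1 (quasi-binomial correction); p-values are BH
adjusted across cells. This per-cell Wald realization stands in for
least-squares-means post hoc contrasts, which coincide with the cell
estimate in an intercept-only cell. When all deciding larvae sit on one
option the Wald statistic degenerates (complete separation), and the cell
falls back to the exact binomial test. Under the null generator the
procedure's type-I error sits at the nominal 5% level within binomial
simulation error, and it agrees closely with the exact mid-p binomial test
at moderate counts — both checked in the acceptance suite.

**Damage scores.** Ordinal 0–5 per-root scores are averaged per plant
within root type and the paired per-plant means are compared with the
Wilcoxon signed-rank test. Zero differences are dropped (the convention of
common desktop statistics software). Because ties are ubiquitous on an
ordinal scale, the exact null distribution is enumerated over all 2ⁿ sign
assignments of the mid-ranked absolute differences for n ≤ 15 pairs —
`stats::wilcox.test` would silently fall back to a normal approximation
under ties — and a normal approximation with continuity and tie correction
is used beyond that. The two-sided p-value is twice the smaller tail,
capped at 1, matching the exact convention of `wilcox.test` on tie-free
data (verified in the tests).

Treatment comparisons use the tie-corrected Kruskal–Wallis statistic
followed by Tukey HSD on the rank-transformed plant means — an explicit
rank approximation of "Tukey post hoc tests" on ordinal data — with a
compact letter display derived from the maximal cliques of the
non-significance graph. Preference–performance relationships use Spearman
rank correlations with mid-ranks for ties; for n ≤ 9 the two-sided p-value
is exact by full enumeration of all n! permutations, otherwise the t
approximation on n − 2 degrees of freedom is used.

## Cue cross-referencing

Candidate foraging cues are the intersection of identified metabolites
classified as enriched in the preferred tissue with a literature-derived
table of behaviorally active compounds. Names are normalized
(case-folding, whitespace, unicode dashes) and mapped through an explicit
synonym table; there is deliberately *no* fuzzy matching — unmatched names
within edit distance 2 of a table entry are reported as warnings for human
review, never auto-matched. The packaged activity table carries a
`source_tag` per row: the behaviorally decisive entries are transcribed
from the primary literature, while rows completing the table to its
documented length of 13 compounds are marked `placeholder` because the
original supplementary listing is not redistributable; the decisive
property for the cross-reference — which enriched metabolites are active —
is carried entirely by the transcribed rows.

## The synthetic-data generator

The generator exists so that every stage is testable against known truth.
Its defaults encode the study conditions the pipeline targets: 4,956 mass
features over RT 0–8.5 min and m/z 100–1200, of which 444 elute before 0.3
min; 2 root types × 2 genotypes × 10 replicates; a six-compound
benzoxazinoid-like knockout class at 3% residual abundance; choice assays
with 15 dishes of 6 larvae; damage scoring of 2 embryonic and 6
postembryonic roots on 20 plants; qPCR with 11 samples per group and a 75%
planted knockdown (encoding "more than 70%"); a targeted-panel knockout of
97.5% (encoding "more than 97%").

Intensities are generated hierarchically: each compound has a latent
per-sample abundance — a log-normal base level (sdlog 1.5 across
compounds, giving a realistic dynamic range) times planted design effects
times biological noise (`noise_sigma` = 0.3 on the natural-log scale,
i.e. ~30% CV) — and each fragment observes that latent abundance times a
fragment-specific yield times small analytical noise (`fragment_sigma` =
0.05). This construction makes co-elution grouping meaningful:
within-compound fragment correlations are ~0.95+ on the raw scale, while
the 0.04-min RT window keeps unrelated compounds apart. The distributional
form is a modeling decision — positive, right-skewed peak areas with
multiplicative noise are what the ArcSinH transform is designed for — not
something the emulated data format prescribes.

Differential effects are planted at the *compound* level (all fragments
shift together, as real fragments of one metabolite must), with
`n_diff_features` read as the number of differential compounds; the
emitted ground truth lists both compound and member-feature ids, plus the
junk (unretained and bad-decimal) feature ids. One caveat is intrinsic to
the design: two differential compounds shifted in the same direction are
correlated through the shared design indicator, so if they also co-elute
within the RT window they can merge into one group. At the default effect
size this affects a small percentage of compounds (the grouping-recovery
test requires ≥ 95% of compounds back as exactly one pure group).

What the generator does *not* emulate: chromatographic peak shapes,
isotope patterns and adduct mass relationships, missing values,
between-batch drift, or heteroscedastic detector saturation. Passing tests
therefore demonstrate the correctness of the statistical machinery under
the stated model, not robustness to every artifact of real LC-MS data.

All generators are driven by one integer seed; inside `run_pipeline()`
each stage k receives the sub-seed `(seed + 7919·k) mod (2³¹ − 1)`
(`split_seed()`), so adding or removing a stage never perturbs the draws
of the others, and identical configurations give identical reports up to
the single timestamp field.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at deliberately chosen sizes:
the full 4,956-feature design for the curation bookkeeping and the default
screen; 500-feature tables over 20 seeds for planted-effect recovery
(8-fold effects; sensitivity and observed FDR measured against ground
truth); 2,000 independent null features for type-I calibration of the
per-feature t tests; 1,000 replicate null experiments for the preference
test's rejection rate; 200 random ≤ 50-feature tables for the
grouping-oracle equivalence. These sizes give the property checks
binomial error bars tight enough to be informative while keeping the whole
suite fast.

Numerical conventions collected in one place: the RT filter keeps the
boundary value; the decimal filter removes strictly above 0.8 with a 1e-9
representation tolerance; correlation edges require strictly r > 0.8;
zero-variance vectors never form edges; fold changes are max/min with
direction labels, 0/0 flagged `undefined`; BH q-values are clipped at 1
and returned in input order; Wilcoxon zeros are dropped and two-sided
p-values are twice the smaller tail, capped at 1; Spearman uses mid-ranks;
the compact letter display letters maximal cliques in decreasing size
order.

## Known limitations

* The curation thresholds (0.3 min, 0.8 decimal, 0.04 min, r = 0.8) are
  instrument- and method-specific; they are exposed as parameters, and no
  attempt is made to learn them from data.
* The per-feature ANOVA assumes homoscedastic Gaussian errors on the
  ArcSinH scale; heavily zero-inflated features violate this.
* The Tukey-on-ranks post hoc procedure is an approximation of the named
  procedure, not an exact distributional match.
* Two acceptance checks (the published enrichment and interaction-screen
  counts) are bound to the deposited curated feature table those counts
  were derived from and remain red unless a transcription of that table is
  supplied; see `tests/testthat/test-acceptance.R` for the drop-in path
  and format.
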