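---
title: "Adaptive evolution in cytoplasmic genomes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive evolution in cytoplasmic genomes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cytosim` is an individual-based forward simulator for asexual cytoplasmic
genomes — mitochondria, plastids, and obligate endosymbionts — that live in
multiple copies inside diploid host cells. Its purpose is to quantify how
two features peculiar to this system, uniparental inheritance and the
germline transmission bottleneck, shape the accumulation of beneficial and
deleterious substitutions relative to a free-living asexual population that
is exposed to selection directly.

## The model

The population holds `N` diploid hosts. Each host carries `n` cytoplasmic
genome copies, and each genome is summarised by the pair (α, κ): the number
of beneficial and deleterious substitutions it has fixed. Sites are not
tracked individually — with `l = 20000` bp and per-site rates of
10⁻⁹–10⁻⁷, the expected per-genome load stays far below `l` over any
simulated horizon, so mutation saturation is negligible and a genome class
is fully described by its counts. Counts never decrease: there is no back
mutation, recombination, or paternal leakage.

A generation is one pass through four stages:

1. **Mutation.** Every genome copy independently gains
   `Binomial(l, mu_b)` beneficial and `Binomial(l, mu_d)` deleterious
   substitutions. A copy hit by both kinds in one generation keeps both
   increments.
2. **Selection.** Each host's relative fitness is computed from its *total*
   substitution loads (summed over its `n` copies), and `N` hosts are
   resampled with replacement in proportion to fitness. Selection acts only
   on hosts; there is no replicative advantage within cells.
3. **Gametogenesis.** Every surviving host produces two gametes, one of
   each self-incompatible mating type (`A` and `a`). Each gamete receives
   `b` genome copies sampled with replacement from the parent's `n`
   (`b ≤ n/2`) — the transmission bottleneck.
4. **Mating and repopulation.** `A`-gametes are paired uniformly at random
   with `a`-gametes (a host's own two gametes may pair, with probability
   `1/N`; forbidding this would impose an arbitrary derangement for a
   vanishing effect). Under *uniparental* inheritance only the `A` gamete's
   `b` copies enter the zygote; under *biparental* inheritance the pooled
   `2b` copies do. Each zygote is then restored to `n` copies by sampling
   with replacement from its pool.

Generation records are taken immediately after repopulation. Beneficial-only
runs stop once every genome in the population carries at least `gamma`
beneficial substitutions (with a safety cap that flags truncation rather
than erroring); all other runs use a fixed horizon of 10⁴ generations.

The free-living null model strips away the host level: `N_FL` cells carry
one genome each, and the life cycle is mutation followed by
fitness-proportional resampling. Matched comparisons use `N_FL = N` (one
cell per host) or `N_FL = N × n` (one cell per cytoplasmic genome).

## Fitness maps

A cell's fitness depends only on its total beneficial load `x` and total
deleterious load `y`, each saturating at `X = n_ref × gamma_ref`
substitutions (250 at the defaults). With `u = min(x, X)/X`:

* beneficial component: `w_b = (1 − s_b) + s_b · u^θ`, with θ = 2
  (concave up), 1 (linear), or 1/2 (concave down);
* deleterious component: `w_d = 1 − s_d · u^θ`, with θ = 2 (concave down)
  or 1 (linear);
* combined: `w = max(0, w_b + w_d − 1)` — deviations from one add, and the
  floor keeps sampling weights valid when `s_b + s_d > 1`.

So a cell with no beneficial substitutions has fitness `1 − s_b` on the
beneficial axis, a fully adapted cell (`x ≥ X`) has 1, a mutation-free cell
has 1 on the deleterious axis and a fully loaded one `1 − s_d`. These
endpoint anchors are exact by construction and asserted to machine
precision in the tests; the power-law interiors are one natural family with
the right endpoints and curvatures, and the exponents are exposed in
`fitness_spec()` so other forms can be swapped in. The default deleterious
shape is concave down because cells tolerate a low proportion of mutant
genomes and are strongly affected only at high load.

Free-living fitness uses the linear forms only (so that selection per
substitution is independent of the existing load) and multiplies the
per-substitution increment by `s_FL`, clamping each component at its
endpoint before the additive combination. At `s_FL = 1` a substitution on a
free-living genome changes its cell's fitness exactly as much as a
substitution on one cytoplasmic genome changes its host's.

## Default parameters

| parameter | default | meaning |
|---|---|---|
| `N` | 1000 | diploid hosts |
| `n` | 50 | genome copies per host |
| `b` | 25 or 5 | bottleneck (relaxed `n/2`, tight `n/10`) |
| `l` | 20000 bp | genome length (animal mtDNA scale) |
| `mu_d` | 10⁻⁷ /site/gen | deleterious rate (mtDNA estimates) |
| `mu_b` | 10⁻⁹–10⁻⁸ | beneficial rate (1–10% of `mu_d`) |
| `s_b`, `s_d` | 0.01–0.1 | per-axis selection coefficients |
| `gamma` | 5 | per-genome target ending beneficial-only runs |
| `s_FL` | 1–50 | free-living fitness scaling |

These are the conditions under which all headline statistics are computed;
`preset()` materialises the standard grids.

## Engines and randomness

Long runs use a compiled engine (Rcpp) that stores the population as a
K × N class-count matrix. Its stages are exact, not approximate: mutation
draws the number of hit genomes from `Binomial(N·n, 1−(1−μ)^l)`, picks a
uniform random distinct subset of genome slots, and gives each hit a
zero-truncated `Binomial(l, μ)` count — equivalent to per-copy binomials
but costing only as much as there are mutation events. Gamete and zygote
sampling draw multinomial class counts through the conditional-binomial
chain. The same life cycle is implemented a second time in plain R
(`mutate_cell()`, `select_hosts()`, `gametogenesis()`,
`mate_and_repopulate()`, `advance_generation()`): these functions are the
readable specification of each stage, and the test suite checks both
implementations against an exhaustive enumeration of all outcomes of one
generation on a tiny instance (N = 2, n = 2, b = 1, l = 1), as well as
against neutral molecular-clock expectations.

All randomness flows through R's RNG, so a run is a pure function of
`(config, seed)` and trajectories are bit-for-bit reproducible. Replicate
`r` of a set uses the `r`-th element of a seed stream derived from the base
seed (`derive_seeds()`), keeping replicates independent but reproducible.

## Analysis statistics

**Drift and selection phases.** The drift phase of beneficial class α runs
from the first generation a genome with α substitutions is observed to the
start of its final uninterrupted presence interval before a genome with
α+1 appears; the selection phase runs from there to the first appearance of
α+1. Presence is evaluated as "any genome with ≥ α substitutions", so a
class consumed by onward mutation is not spuriously counted as lost.
Aggregates exclude α = 1, whose dynamics are set by the all-wild-type
starting conditions. Loss and regain probabilities are per-generation event
rates inside the drift window (losses over present generations, regains
over absent generations).

**Sweep slope `m_g` and coexistence `c_g`.** `c_g` is the mean number of
classes present per generation — beneficial classes in beneficial-only
runs, full (α, κ) classes otherwise. `m_g` approximates the decline slope
of near-fixed wild types: every class that reaches ≥ 99.5% frequency
contributes the time from its *first* generation at ≥ 99.5% to its first
generation below 0.5%, and `m_g = −99.5 / mean(duration)` %/generation.
Timing the drop from first (rather than last) attainment deliberately
includes the plateau at near-fixation, during which the successor class
establishes: the plateau is part of the wild type's residence at the top
and, at the strong-selection end where sweeps are fast, omitting it
overstates the slope by the full establishment time. Classes still common
at the end of a run are censored and excluded; if no class ever reaches
99.5%, `m_g` is undefined while `c_g` is still reported.

**Ratchets and the hitchhiking index φ.** A deleterious ratchet is a click
of Muller's ratchet: the generation in which the genome class with the
fewest deleterious substitutions is lost (the population minimum of κ
rises); a beneficial ratchet is the same event for α. A jump of the minimum
by more than one counts as one event with a recorded jump size. For each
beneficial ratchet at generation g, the observed gap is the distance to the
first deleterious ratchet at or after g. The null expectation places the
observed D deleterious ratchets uniformly at random over the T generations
and uses the forward waiting time T/D; φ is the mean observed gap divided
by T/D. Beneficial ratchets with no later deleterious ratchet are censored;
they contribute their censored gap T − g to the primary index, and the
index with censored pairs excluded is reported alongside, since reasonable
conventions differ here. Two numerical caveats are documented rather than
hidden: (1) the exact mean forward wait into D uniform points is T/(D+2),
not T/D, so on independent streams φ is biased low by D/(D+2) — negligible
for dense streams (the calibration tests use D = 100 over T = 10⁴, where
the bias is 2%) but conservative when only a handful of ratchets occur;
(2) φ = 0 arises when every beneficial ratchet coincides with a deleterious
one (maximal hitchhiking), φ ≈ 1 under independence, φ > 1 when beneficial
substitutions inhibit deleterious fixation.

**Adaptive-evolution ratio.** At the 10⁴-generation horizon, each
replicate's population-mean α per genome is divided by its mean κ, and the
per-replicate ratios are averaged (a mean of ratios — deliberately not the
ratio of means, which weights replicates unequally). Replicates with zero
deleterious load are excluded and counted.

**Variance panels.** The within-cell variance is the variance, across a
cell's `n` copies, of the per-copy beneficial substitution count
(population-variance convention, divisor `n`), averaged over cells; the
between-cell panel is the population variance of cell fitness. "Variation
in the genomes carried by cells" can also be read as class diversity, so
the mean number of distinct classes per cell is emitted alongside.

## What the simulations do and do not emulate

The simulator *is* the data source: there is no external input, and all
reported quantities are Monte-Carlo summaries over seeded replicates of the
model above. The model captures multilevel sampling (within-cell
segregation through gametogenesis and repopulation, between-host
selection), recurrent mutation, drift at both levels, and the contrast
between inheritance modes. It deliberately omits: within-cell selection
(selfish replication), recombination and paternal leakage, site-level
identity (hence no site-frequency or dN/dS statistics), distributions of
fitness effects (every substitution on an axis has the same effect),
overlapping generations, and multicellular germline structure. Conclusions
drawn from it therefore concern the population-genetic consequences of
inheritance mode and bottleneck size under these idealisations, not
organism-specific predictions.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full study conditions
(N = 1000, n = 50, l = 20000) but with 8–20 replicates per condition rather
than hundreds, which keeps the whole suite within desk-scale runtimes while
leaving standard errors small relative to the acceptance tolerances; the
replicate counts are fixed in the code and seeded, so results are exactly
reproducible. Small-instance distributional checks (χ² against exhaustive
enumeration) use 4000–10000 draws. Degenerate inputs are handled
explicitly: a population whose every cell has zero fitness raises an
extinction error carrying the generation index; `mu_b + mu_d > 1` is
rejected at configuration time; a beneficial-only run that cannot reach its
target (e.g. `mu_b = 0`) terminates at the safety cap with a truncation
flag instead of an error; and the `b ≤ n/2` constraint admits the single
`n = 1, b = 1` case so the cytoplasmic engine can emulate a single-genome
Wright-Fisher population, which the tests exploit to cross-check the two
engines distributionally.

## Known limitations

φ is reported per replicate and averaged; no analytic confidence intervals
are attempted (bootstrap over replicates is the supported route). The
uniform-placement null for φ is approximate at very low ratchet counts, as
noted above. The m_g statistic depends on near-fixation actually occurring;
under weak selection or very high mutation supply no class may reach 99.5%
and the statistic is reported as missing. Runtime is dominated by
biparental-inheritance configurations, whose cells stay highly
heteroplasmic; the compiled engine handles the default conditions in
seconds per thousand generations, but much larger `N × n` would call for a
sparser population representation.
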