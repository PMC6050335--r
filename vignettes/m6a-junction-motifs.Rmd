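---
title: "Methods: junctional m6A motifs, melting thermodynamics and binding fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junctional m6A motifs, melting thermodynamics and binding fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6Ajunction)
```

This vignette documents the models behind `m6Ajunction`, the assumptions
they make, the parameters that matter, and the design decisions taken where
more than one reasonable convention exists. Everything quantitative shown
here is computed by the code as it runs.

## The scientific setting

N6-methyladenosine perturbs RNA secondary structure in a context-dependent
way. Buried in a duplex, the methyl group clashes with Watson-Crick A-U
geometry and destabilises the pair. At a helix junction with a bulged
nucleotide immediately 5' of the adenosine, the bulge gives the methyl
group room to stack on the 3' neighbour while A-U pairing is maintained,
and methylation then *stabilises* the fold, more so in the presence of
Mg2+. The package quantifies this contrast in three measurement domains
(UV melting, fluorescence polarization binding, secondary-structure
surveys) and provides the folding machinery needed to ask how often the
stabilised junctional motif can occur across a set of sites.

## Two-state melting thermodynamics

A melt is modelled as a two-state folded/unfolded equilibrium with van't
Hoff constant $K = \exp[(1/T_m - 1/T)\,\Delta H/R]$, $R = 0.0019872$
kcal/(mol K). The folded fraction is the logistic $K/(1+K)$ for a
unimolecular hairpin; for a bimolecular duplex at total strand
concentration $C_T$ the fraction is the root of a quadratic in $K$,
implemented in the numerically safe closed form. Both curves pass through
one half exactly at $T_m$ — an identity the tests assert for arbitrary
$\Delta H$. Entropy and free energy follow as $\Delta S = \Delta H/T_m$
(hairpin) or $\Delta S = \Delta H/T_m - R\ln(C_T/2)$ (duplex) and
$\Delta G = \Delta H - T\Delta S$.

Assumptions: strictly two states (no intermediates), temperature-independent
$\Delta H$, and — for the duplex — equal strand concentrations. Non-two-state
melts are out of scope.

Key parameters:

| parameter | units | default | rationale |
|---|---|---|---|
| `t_eval` | K | 310.15 | contrasts are conventionally quoted at 37 °C |
| `ct` | mol/L | none (required for duplex) | melts are typically run near 3 µM strand |
| melt grid | °C | 81 points, 15–95 | the standard UV melt range |
| noise `sigma` | fraction units | 0.01 | realistic photometric scatter on a normalised melt |

Fitting uses `minpack.lm::nlsLM` with a deterministic multi-start: $T_m$
initialised where the signal crosses its midpoint, $\Delta H$ at −40
kcal/mol, perturbed over a 3×3 grid ($T_m \pm 5$ K, $\Delta H \times
\{0.5, 1, 2\}$); lowest residual sum of squares wins, ties broken by grid
order. Raw absorbance can be fitted with jointly estimated linear folded
and unfolded baselines (four extra parameters); the default pathway takes
pre-normalised folded fractions, and whether a given instrument's traces
need the baseline mode is left to the user — both are provided.
Folded-fraction inputs outside $[-0.05, 1.05]$ are rejected rather than
silently clipped.

Methylation differences are reported *signed*:
$\Delta\Delta G = \Delta G_{\mathrm{methylated}} - \Delta G_{\mathrm{unmodified}}$,
negative meaning methylation stabilises. Uncertainties come from the
standard deviation across replicate fits when at least three replicates
exist (`fit_melting_replicates()`), combined in quadrature for
differences; for a single curve a seeded parametric bootstrap is available
(`fit_melting(n_boot = 500)`), off by default so a single fit stays cheap.

## Fluorescence polarization binding

With trace labelled RNA ($R_t$ = 2 nM) titrated with protein, one-site
binding uses the exact bound fraction from the quadratic equilibrium
solution, and the observed anisotropy interpolates the free-RNA and
complex endpoints: $A_t = A + (B - A) f_b$. This form satisfies the
physical limits $A_t(0) = A$ and $A_t \to B$ at saturation; the tests pin
both, along with the non-negativity of the discriminant and $f_b \in
[0,1]$ over random parameter grids.

Two independent sites use
$$A_t = \frac{A + B L/K_{D1} + C L^2/(K_{D1} K_{D2})}{1 + L/K_{D1} + L^2/(K_{D1} K_{D2})},$$
a convex combination of the three endpoint anisotropies, under the
free-ligand approximation $L \approx L_t$ (valid when $R_t$ is far below
the $K_D$s; the fit raises a flag when $R_t > 0.01\,K_{D1}$). Model
comparison fits both models and prefers the smaller small-sample-corrected
information criterion (AICc), which penalises the two extra two-site
parameters; the models are not nested in their parameterisation, so a
likelihood-ratio test would be inappropriate. Dissociation constants are
fitted on a log10 scale from a log-spaced start grid spanning the titrated
range — deterministic, and immune to the scale problems of fitting
molar-range constants directly. Two safeguards: a fitted constant above
the largest titrated concentration is flagged as a lower bound rather than
a point estimate, and near-constant titrations return
`kd_identifiable = FALSE` instead of a spurious constant. The
total-intensity check `(I_max - I_min)/I_min` (threshold 0.10; ~0.05 in a
well-behaved assay) guards the anisotropy read-out itself.

## The folding engine

The energy model (`default_energy_model()`, version `simple-1.0`) is a
deliberately compact Turner-style table: sequence-dependent stacking for
the six allowed pairs (Watson-Crick plus G-U), length-tabulated hairpin,
bulge and internal-loop penalties with Jacobson-Stockmayer log
extrapolation, and an affine multiloop score. It reproduces the universal
qualitative behaviour — helices favourable, loops penalised, G-C > A-U >
G-U — without attempting any published program's exact energies, which
would add hundreds of parameters the motif analysis does not need. The
classifier is deliberately decoupled from it: `import_structures()`
accepts dot-bracket or CT output from any external predictor, so surveys
can be driven by production-grade energy models when available.

Decisions a nearest-neighbor implementation must make, and the choices
here: minimum hairpin loop 3 nt; interior loops capped at 30 unpaired
(standard); lonely pairs permitted (always — a no-lonely-pair mode would
require a parallel set of recurrences for a restriction nothing downstream
needs); no dangle or coaxial terms; exterior bases free; the open chain
defines energy zero. MFE ties are broken toward 5'-most pairing by
selecting the lexicographically smallest dot-bracket string, which makes
every downstream result deterministic.

Suboptimal enumeration follows the Wuchty strategy: partial structures are
expanded only while an exact lower bound (from the DP matrices, using an
unambiguous exterior/closed/multiloop grammar) stays within the window, so
the output is the *complete, duplicate-free* set of structures with energy
at most MFE + window. The window is either absolute (0–3 kcal/mol, the
survey's thresholds) or a percentage, interpreted as
$\mathrm{MFE} + |\mathrm{MFE}| \cdot p/100$ — percent-of-a-negative-energy
is ambiguous, and this reading makes the threshold grow with window size
like the absolute mode. A configurable structure-count guard (default
20000) turns combinatorial explosions into a clean truncation error.
Floating-point feasibility uses a 1e-6 kcal/mol slack; test assertions on
energies use 1e-9 tolerances.

Correctness is anchored by two independent oracles: an exhaustive
recursive enumerator (guarded to 22 nt) scoring with the same
decomposition-based `structure_energy()`, and a memoised pair-set counting
recurrence. The acceptance suite checks DP/brute-force energy equality on
100 random sequences up to 18 nt and exact subopt set equality at a
3 kcal/mol window up to 14 nt.

## Motif classification

Categories follow the junctional taxonomy: `duplex_AU`/`duplex_AY`
(helix-interior pair), `unpaired`, `fiveB_AU`/`fiveB_AY` (junctional pair,
bulge immediately 5' of A), `AU_threeB`/`AY_threeB` (bulge 3' of A) and
`partner_bulge` (bulge adjacent to the partner on the opposite strand).
The taxonomy names the categories but not a decision procedure, so the
package fixes one:

1. If the focal A is unpaired, mismatch imputation is attempted: an
   unpaired A immediately adjacent to a canonical pair, facing *exactly
   one* unpaired nucleotide across an internal loop, is treated as
   mismatch-paired with that nucleotide. This operationalises the
   convention used with predictors that only emit canonical pairs (count
   an A-Y site adjacent to a canonical pair as a mismatch); G-U wobbles
   count as canonical throughout. Otherwise the call is `unpaired` (which
   also covers bulged A, loop A, exterior A and multiloop A).
2. A (real or imputed) pair is junctional iff at least one of the four
   flanking positions $(i\pm1, j\pm1)$ is unpaired or out of helix;
   otherwise it is a duplex call.
3. Junctional pairs take a bulge side with precedence 5'-of-A > 3'-of-A >
   partner-side (the 5' bulge is the motif of interest, so it wins when a
   junction offers several unpaired neighbours). Any run of one or more
   consecutive unpaired nucleotides counts as a bulge; the run length is
   recorded so stricter definitions can filter downstream. A junctional
   pair with no unpaired neighbour at all (abutting helices, chain ends)
   falls back to the duplex call, keeping the eight categories exhaustive.

Exhaustiveness and single-firing are tested by classifying every structure
of random short sequences; fidelity by a 22-fixture hand-labelled suite
covering all eight categories, both strands, both bulge sides, G-U closing
pairs and multi-nucleotide bulges.

Surveys report, per energy threshold, the fraction of sites with any
structure within the threshold exhibiting `fiveB_AU`, and likewise for the
partner-generalised `fiveB_AX` = `fiveB_AU` or `fiveB_AY` ("any structure
within the window" matches counting a sequence as forming the motif if it
appears among the predictor's output structures). These fractions are
monotone in the threshold by construction, and `fiveB_AX` dominates
`fiveB_AU` — both invariants are asserted rather than assumed. MFE-mode
counts (category of the single lowest-energy structure) always sum to the
number of surveyed sites. Transcriptome-scale published percentages are
*not* a target here: they depend on a specific external site list and on
other programs' energy tables. The package reproduces the procedure and
its structural properties at desk scale, and ingests external predictions
for users who have them.

Re-ranking applies signed per-category ΔΔG offsets at the focal A and
re-sorts the ensemble, reporting whether the MFE identity changed. Default
offsets are the hairpin-construct melting contrasts (with Mg2+:
`fiveB_AU` −0.9, `duplex_AU` +0.6, `AU_threeB` +1.2, `unpaired` +0.7,
`partner_bulge` +0.4 kcal/mol; without Mg2+: −0.3, +0.8, +1.2, +0.7, +1.4).
No measurement exists for the A-Y mismatch categories, so their offsets
default to zero; and the without-Mg2+ values for `AU_threeB` and
`unpaired` reuse the with-Mg2+ numbers, since those contrasts were
reported as essentially Mg2+-insensitive. Applying hairpin-derived offsets
to arbitrary sequence contexts is an approximation, and the table carries
that caveat as an attribute.

## Synthetic data: what it emulates, what it does not

Generators are pure functions of their seed (the RNG state is saved and
restored, so callers' streams are untouched). Melting curves are drawn
from the exact two-state models on the standard 81-point 15–95 °C grid
with i.i.d. Gaussian noise, default sigma 0.01 folded-fraction units;
titrations from the exact isotherms with sigma 0.002 anisotropy units —
plausible instrument noise levels, since no noise model is prescribed by
the assays themselves. Transcripts use uniform base composition (GC
tunable) with DRACH 5-mers planted at recorded, non-overlapping positions;
control sites are drawn A-centred and rejected on any DRACH match.
Labelled motif windows come from designed hairpin templates whose drawn
structure realises each category; for the five canonical-pair categories
the template's drawn structure is also verified to be the engine's MFE, so
end-to-end planted-fraction recovery is exact by construction.

What passing these tests shows: the pipeline recovers known parameters and
planted structure under its own generative assumptions at realistic noise.
What it does not show: real transcripts are not uniform-composition, real
m6A maps carry detection biases, real melts can violate two-state
behaviour, and real predictors use richer energy models. The
import adapters and per-stage interfaces exist precisely so real data can
replace each synthetic input.

## Problem sizes and determinism

The shipped test and acceptance runs use: 100 random sequences ≤ 18 nt for
oracle equality and 40 sequences ≤ 14 nt for subopt completeness; 200
seeded replicates for melting recovery (thresholds ±0.5 K, ±5% ΔH at 95%);
50 replicate pairs per ΔΔG contrast (recovered within ±0.1 kcal/mol); 200
replicates per binding target (medians within ±10% one-site, ±20%
two-site); and 100 replicates for model-preference rates (≥ 90%). These
sizes give stable Monte-Carlo summaries in seconds to tens of seconds;
all seeds are fixed, and every reported number is recomputed at run time.

## Known limitations

- The energy table is intentionally minimal: no dangles, no coaxial
  stacking, no special hairpin sequences, no mismatch-specific interior
  terms. Absolute energies are not comparable to full nearest-neighbor
  implementations; motif classification of imported structures is.
- No pseudoknots, no partition-function probabilities.
- The m6A flag does not alter pairing legality or folding energetics;
  methylation enters only through the per-category re-ranking offsets,
  which are motif-level constants measured on specific hairpin constructs.
- Depletion-corrected or cooperative binding models and multi-state melts
  are out of scope; weak binders are reported as bounds, not estimates.
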