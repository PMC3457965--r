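---
title: "Predicting allele-specific extension probe specificity from match/mismatch duplex concentrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting allele-specific extension probe specificity from match/mismatch duplex concentrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hseprobe)
```

## The problem

Allele-specific extension reactions (ASER) — including haplotype-specific
extraction (HSE), which pulls one contributor's chromosome out of a DNA
mixture by extending an allele-specific probe with biotinylated
nucleotides — depend on the polymerase extending the probe only on the
allele where its 3' terminus is perfectly paired. In practice the
polymerase extends 3'-terminal mismatches at an appreciable rate, and
whether a given probe discriminates its SNP turns out to depend strongly
on probe length: within one design, trimming a handful of bases off the
5' end can move separation from ~60% to nearly 100%, and further trimming
destroys it again.

Classical design covariates — melting temperature, duplex free energy,
G/C content, even the match/mismatch free-energy difference
$\Delta\Delta G^\circ_{M\text{-}MM}$ — do not predict this. The quantity
that does is the *difference in equilibrium duplex concentration* between
the matched and the mismatched target at assay conditions:

$$\Delta con_{M\text{-}MM}(L) \;=\; con_M(L) - con_{MM}(L),$$

evaluated across the 5'-truncation series of one probe design. Short
probes bind neither allele ($\Delta con \to 0$); long probes saturate
*both* alleles — the single mismatch no longer suffices to keep the wrong
template free ($\Delta con \to 0$ again). In between, $\Delta con$ passes
through a maximum, and the length at that maximum is the recommended
design. $\Delta con$ values are meaningful only *relative to one probe
set*: their absolute magnitude differs between sets without a difference
in achievable specificity.

## The thermodynamic substrate

`hseprobe` computes duplex stability with the nearest-neighbor model:

$$\Delta H^\circ, \Delta S^\circ \;=\; \sum_{\text{doublets}} \Delta H^\circ_i, \Delta S^\circ_i \;+\; \text{initiation terms},$$

using the published unified Watson-Crick parameters (SantaLucia 1998;
Allawi & SantaLucia 1997), single-internal-mismatch doublets (Allawi &
SantaLucia 1997–1998; Peyret et al. 1999) and terminal-mismatch doublets
(SantaLucia & Peyret 2001), shipped as plain-text tables under
`inst/extdata/nn/` and swappable via `nn_params()`. Two mismatch
geometries are modelled — a 3'-terminal mismatch (one substituted
terminal stack) and a penultimate ("−1") mismatch (two substituted
flanking stacks) — because these are the only geometries that occur in
allele-specific extension designs; anything else is rejected rather than
silently mis-parameterized. Initiation terms are keyed by the probe's
terminal bases, the same accounting used by Biopython's `Tm_NN`
implementation of these tables, which the test suite uses as a frozen
cross-implementation reference.

Entropy is salt-corrected per SantaLucia (1998),
$\Delta S^\circ[\mathrm{Mon^+}] = \Delta S^\circ(1\,\mathrm{M}) +
0.368\,(N-1)\ln[\mathrm{Mon^+}]$, with magnesium folded into a sodium
equivalent ($[\mathrm{Mon^+}] + 120\sqrt{[\mathrm{Mg^{2+}}]\,
\mathrm{(mM)}}$ mM, von Ahsen 2001). The melting temperature uses the
hetero-duplex convention $T_m = 1000\,\Delta H^\circ / (\Delta S^\circ +
R\ln(C_T/4)) - 273.15$ — stated explicitly so results are reproducible
bit-for-bit; in the probe-excess regime the choice of $C_T/4$ versus
$C_T$ shifts $T_m$ by a constant ~1–2 °C and does not move the
$\Delta con$ optimum.

The equilibrium duplex concentration solves the two-state mass action
$P + T \rightleftharpoons PT$ with
$K = \exp(-1000\,\Delta G^\circ/(R\,T))$, as the smaller root of
$Kx^2 - (1 + K(P_0+T_0))x + KP_0T_0 = 0$ evaluated in the
cancellation-free form $x = 2c/(b + \sqrt{b^2 - 4Kc})$. The solver is
exercised against an independent iterative mass-action solver on 1000
random instances spanning $K = 10^{-6}$–$10^{30}\,\mathrm{M^{-1}}$ and is
accurate to 10+ significant digits; the result is clamped to
$[0, \min(P_0, T_0)]$ and the Boltzmann exponent capped at 345 (beyond
which the bound root is saturated to within double precision).

## Default assay conditions

All conditions are parameters of `duplex_params()`; the defaults describe
the HSE assay the model was built around:

| parameter | default | rationale |
|---|---|---|
| `temperature_c` | 64 °C | the protocol's hybridization/extension temperature; 58 °C is also quoted for the same protocol and is worth exploring via this flag (see below) |
| `probe_conc` | 5 µM | oligo probe concentration; the source protocol's "5 mM" is physically implausible for an oligo assay and is read as 5 µM |
| `target_conc` | 3 fM | per-allele genomic target: 300–500 ng human gDNA in 30 µl split between two contributors |
| `monovalent` | 50 mM | typical extension-buffer monovalent ionic strength (the actual buffer is proprietary) |
| `magnesium` | 1.5 mM | typical Taq buffer free Mg²⁺ |

Because the reference simulations were produced by a proprietary
multi-state engine under unpublished buffer conditions, per-length
$T_m$/$\Delta G$/$con$ values are treated as calibration references with
tolerance, never as exact oracles; the package's claims are structural
(curve shape, optimum location, trends). Notably, at 58 °C the simulated
optima of the worked-example sets land within 0–1 nt of the published
simulated optima (e.g. P38FC 10, P244RC 13, P30RC 24), while the 64 °C
default preserves all the structural results; the temperature is left at
the protocol's stated 64 °C rather than tuned.

## Probe sets and the optimum rule

A *probe set* is the 5'-truncation series of one design (locus ×
orientation × allele × discriminator position), built either from a locus
sequence (`enumerate_probes()`, 1-based coordinates on the forward
strand with an explicit strand field — the Bioconductor convention) or
directly from a catalogued full-length probe (`probe_series()`).
`delta_con_curve()` simulates $con_M$, $con_{MM}$ and $\Delta con$ per
length; `select_optimum()` implements the selection rule:

* **argmax** of $\Delta con$, ties broken toward the *shorter* probe
  (shorter probes are cheaper and less prone to accumulating mismatch
  tolerance; a deterministic rule is required);
* a **plateau** of near-ties within 10% of the maximum
  (`plateau_tol = 0.10`) — published best lengths are frequently reported
  as pairs like "20, 21", i.e. near-ties were treated as equivalent;
* a **no-discrimination floor** at 1% of the target concentration
  (`floor_frac = 0.01`): when even the best length separates less than
  that, the set is flagged rather than ranked — designs whose mismatch is
  as stable as the match (e.g. some A·C terminal pairs) produce exactly
  this signature.

```{r p224}
cv <- simulate_probe_set("P224FC", lengths = 9:25)
print(cv)
```

The curve rises with length, peaks, and declines as both alleles approach
target saturation — the "parabola-like" signature. Across probe sets the
optimum shifts with base composition: G/C-rich probes reach binding
saturation earlier, so their optimum sits at shorter lengths.

```{r shift}
gc_shift_table()
```

The six core sets used here (P38FC, P244RC, P224RG, P224FC, P30FG,
P30RC) are the package's own panel choice: terminal-discriminator sets
from the bundled catalogue spanning mean G/C ~24–84%.

This G/C dependence supports a shortcut regression: fitting optimal
length on probe G/C content over the experimentally best probes
(`best_probe_points()`, the asterisked rows of the bundled summary table,
with G/C computed from the actual best-length truncation) yields a
negative slope and predicts the experimental optima to within 2 nt:

```{r gcmodel}
pts <- best_probe_points()
m <- fit_gc_length_model(pts$gc_pct, pts$best_length, source = "experimental")
m
max(abs(predict(m, pts$gc_pct) - pts$best_length))
```

The regression coefficients are fitted by this package from the bundled
points; no published coefficient values are claimed or reproduced.

## Specificity screening

`scan_binding_sites()` replaces an alignment-tool screen: it slides the
probe over both strands of up to ±50 kb of flanking sequence (50 kb being
the practical limit between an extraction SNP and its reporter STR
marker) and classifies every site with ≤ `max_mismatches` (default 2)
by whether its 3'-terminal `anchor_len` bases (default 3) are all matched
— only such sites are extendable and therefore true specificity risks.
These thresholds are explicit configuration: the alignment tool used in
the original workflow does not document its internal criteria, so no
attempt is made to reproduce its hit counts numerically. Probes
containing `GGG` runs trigger a promiscuity warning (G-rich low-complexity
probes are known mishybridizers). Thermodynamic scoring of off-target
sites is deliberately out of scope — the screen is count-based.

## Bundled experimental tables

Three transcribed tables (`hse_probes()`, `hse_set_summary()`,
`hse_length_profiles()`) carry the probe catalogue (41 sets / 137
probes), the per-set summary (best tested lengths, enrichment, ddG,
simulated best lengths, concordance labels: 36 right / 5 wrong = 88%/12%)
and the per-length profiles of the two worked examples. Transcription is
verbatim including the source's internal inconsistencies, which are
flagged rather than corrected: independent per-column rounding (printed
$\Delta con$ can differ from $con_M - con_{MM}$ by one last-digit unit —
`check_profile_consistency()` asserts agreement to ±1), a G/C typo in the
P224FC 6-mer row (printed 43%, sequence gives 33%), a mismatch label
(P240FT "C-A") that contradicts its set name, and a locus-naming
disagreement between the catalogue and the summary for four FG/FG-1
designs.

Enrichment is computed as the dominant contributor's share of total STR
signal, $100\cdot\max(s_1,s_2)/(s_1+s_2)$ — a **surrogate** definition
(the source renders its efficiency equation only as a figure) chosen
because it is symmetric in contributor labelling and reproduces the
reported behaviour: 50% for an unseparated mixture, → 100% for complete
separation. Classification uses the published thresholds exactly:
complete > 89%, significant 61–89%, none ≤ 60% (values in the open
interval (60, 61) fall in "significant", making the three classes a
partition of $[0,100]$).

Two analyses run over the tables. `concordance_summary()` reports the
printed right/wrong labels *and*, separately, a rule-based recount
(best experimental and simulated lengths within $k$ nt, default 1) —
the two are never merged, because the printed labelling is broader than
any fixed-window rule. `mismatch_position_summary()` pairs each terminal
design with its "−1" variant; with a strict > +10-point rule exactly
three pairs improve at the penultimate position, and the two published
decreases (−22, −23 points) are reproduced. The strict rule reproduces
the published *count*, though one of the three improving pairs differs
from the published listing (which includes a +10-point pair and omits a
+22-point pair whose terminal design showed no separation at all).

## Numerical and design notes

* **Monotonicity caveat.** Within a truncation series, $T_m$ and
  $|\Delta G^\circ|$ rise with length *as a trend*, not strictly: adding
  an A/T-rich 5' base at low ionic strength can contribute a marginal
  stack whose free energy at assay temperature is slightly positive. The
  bundled P30RC profile itself shows such a reversal at the 23-mer, and
  the engine reproduces its direction; strict monotonicity holds (and is
  asserted) for the P224FC series, whose printed profile rises strictly.
* **Match/mismatch dominance.** $con_M \ge con_{MM}$ wherever duplex
  forms appreciably. The published terminal-mismatch dH/dS can cross over
  far above the melting transition (e.g. ~89 °C for the C·A example),
  where both concentrations are < 10⁻⁴ of target; tests verify any such
  violation is parameter-driven and negligible.
* **Degenerate inputs.** Probes shorter than 6 nt, ambiguity codes,
  multiple mismatches and unsupported mismatch positions are rejected
  with specific errors; equilibrium and Tm edge cases return defined
  values (`NA` + "no two-state Tm"; clamped concentrations) rather than
  NaN.
* **Synthetic loci.** `generate_locus()` emulates flanking sequence as an
  i.i.d. background at a target G/C with planted, ground-truth-recorded
  off-target copies; it is byte-reproducible from its seed and leaves the
  caller's RNG untouched. It does *not* emulate repeat structure,
  segmental duplications or conserved motifs — real genomic flanks will
  show more (and more clustered) off-target hits than the generator, so a
  clean screen on synthetic data is a correctness check of the scanner,
  not a safety claim about a real locus.
* **Problem sizes.** The bundled analyses simulate 17–21 lengths × 2
  duplexes per probe set (six core sets plus worked examples) and screen
  20 kb synthetic loci; the full test suite and the reproduction script
  each run in well under a minute on one CPU.

## Limitations

The engine is deliberately two-state per probe/target pair: no coupled
multi-state equilibria (hairpins, probe dimers, competition among all
genomic sites in one system), no RNA or modified bases, no polymerase
kinetics. The mismatch-discrimination step of the polymerase itself is
outside the model — $\Delta con$ predicts the *hybridization* side of
specificity, which is why sets with unusually favorable or unfavorable
enzymatic mismatch extension can deviate from the prediction.
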