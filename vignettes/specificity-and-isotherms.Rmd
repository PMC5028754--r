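---
title: "Methods: protease specificity profiling and ITC isotherm analysis"
author: "picsitc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protease specificity profiling and ITC isotherm analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picsitc)
```

This package implements two analysis tracks that are usually run together
when characterising a candidate protease and its ubiquitin-binding partner
domains: a PICS (Proteomic Identification of protease Cleavage Sites)
pipeline that turns MS peptide-identification lists into a substrate
specificity matrix, and an isothermal titration calorimetry (ITC) track that
forward-models and fits binding isotherms for one and two independent sites.
This vignette is the package's own account of the underlying models, the
parameters that matter, and the design choices taken where more than one
reasonable implementation exists.

## The PICS screen

A PICS experiment digests a whole proteome with a site-specific protease
(trypsin here), chemically protects all free amines, and offers the
resulting peptide library to a test protease. Wherever the test protease
cleaves a library peptide, the product acquires a fresh N-terminus, which is
biotinylated, enriched, and identified by MS. MS therefore observes the
*prime side* (P1′–P5′ in Schechter–Berger nomenclature) of each cleavage
event; the non-prime side (P5–P1) must be reconstructed computationally by
locating the peptide in the proteome.

Four identification lists enter the analysis: the test enzyme reaction, a
catalytically inactive point-mutant control, a mock (buffer) control, and
the unprocessed library. The filter cascade is:

1. keep peptides flagged as carrying an N-terminal biotin (all four lists);
2. keep test peptides identified with confidence **strictly over 80%** and
   control peptides over 10% — "over" is read literally as a strict
   inequality;
3. remove any test peptide whose sequence occurs in either control list
   (exact sequence identity);
4. remove peptides present in the unprocessed library run.

Two choices here deserve a note. Duplicate sequences within one run are
collapsed to their highest-confidence instance before filtering, because the
lists are per-sequence evidence, not spectral counts. And the unprocessed
library run is treated like a control (biotin filter plus the 10% control
threshold) — the more aggressive alternative of subtracting the whole raw
library list removes nothing extra in practice, because library peptides
that matter for subtraction are identified with usable confidence anyway.

### Back-mapping and the ambiguity rule

Each surviving prime-side peptide is located in the proteome by exact
substring search (no I/L equivalence, no tolerant matching). Each occurrence
contributes the five residues immediately N-terminal as a candidate P5–P1
window; positions beyond the protein N-terminus are padded with `-`, a gap
symbol that is excluded from all frequency counts rather than diluting them.
If all occurrences agree on one preceding 5-mer, the window is assigned. If
several *distinct* preceding sequences exist, the non-prime side is
unknowable and is discarded — but the peptide's prime side is retained,
since the MS evidence for it is not in doubt. This "prime kept, non-prime
excluded" reading is the default (`ambiguous_prime = TRUE` in
`build_matrix()`); the switch exists because the alternative reading
(discard the peptide entirely) is also defensible, and flipping it lets a
user measure how much the choice matters on their data.

The specificity matrix is the 20 × 10 table of per-subsite amino-acid
frequencies, each column normalised over its non-gap observations; columns
with zero observations are all-zero and flagged. Raw frequencies are the
primary output; an enrichment table (frequency over library background, via
`library_background()` and `enrichment()`) is provided because tryptic
libraries are compositionally biased, but it is an optional extra.

## The synthetic-data generator

No raw screen data ship with the package, so a generator produces every
input: a random i.i.d.-residue proteome, its digest, and the four
identification lists under a *planted* protease whose specificity is a
per-subsite position-weight table. The probability of cleaving a given bond
is `efficiency` times the product of the normalised subsite weights over the
window, the simplest generative model consistent with a position-weight
description. Identification noise consists of background peptides drawn from
the library (mostly uncleaved library members, as real contaminants are),
with a configurable shuffled-decoy fraction (default 5%) and a configurable
fraction spuriously biotin-flagged (default 10%); background draws are
shared across the three reaction runs so control subtraction is meaningful.
Confidence scores are percentages: genuine products draw from 85–100,
background from 5–95. The defaults (100-protein proteomes of 100–300
residues in the property suites, 400 background identifications in the
workflow scripts) keep every end-to-end run in seconds while leaving
hundreds of cleavage events to tally.

What the generator does **not** emulate: mass spectra, retention times,
search-engine score distributions, missed cleavages, modifications other
than the biotin flag, and homology structure in the proteome (real proteomes
contain repeated domains, which inflate the ambiguous-mapping rate well
beyond what i.i.d. sequences show). Passing the planted-motif and
null-protease suites therefore demonstrates that the *analysis* is sound,
not that real screens are this clean.

Two properties anchor the suites: a strict single-subsite motif with no
noise must come back with frequency 1.0 at the planted residue, and an
efficiency-0 protease must produce zero cleavage windows through the full
cascade — the null outcome that a catalytically inactive aspartyl protease
produces in the real assay.

## The ITC track

A titration injects ligand (syringe concentration $X_s$) in steps of volume
$\Delta V$ into a cell of volume $V_0$ containing macromolecule. The
perfusion cell displaces liquid: after each injection, everything already in
the cell is diluted by $(1 - f/2)/(1 + f/2)$ with $f = \Delta V / V_0$, and
the injection delivers $X_s f/(1 + f/2)$ of fresh ligand. The cumulative
binding heat after injection $i$ is

$$Q_i = V_0 \sum_s \Delta H_s\,[\mathrm{bound}_s]_i,$$

and the measured heat of injection $i$ includes the heat carried out with
the displaced volume:

$$q_i = Q_i - Q_{i-1} + \frac{\Delta V_i}{V_0}\,\frac{Q_i + Q_{i-1}}{2}.$$

Heats are normalised per mole of injectant and a constant dilution-heat
offset is added. With this correction a tight-binding isotherm is an exact
step: $\Delta H$ per mole before the equivalence point, zero after.

```{r step}
prot <- injection_protocol(1.43, 100, 1000, rep(9, 30))
round(simulate_isotherm(prot, one_site_params(N = 1, Kd = 1e-9, dH = -5))$normalized, 3)
```

**Equilibrium solvers.** For one class of `N` identical sites the bound
ligand solves a quadratic; the numerically stable root
$2 L_t N M_t / (b + \sqrt{b^2 - 4 L_t N M_t})$, $b = L_t + N M_t + K_d$,
avoids catastrophic cancellation at high Wiseman $c$. For two independent
sites the free ligand solves
$L_t = L + M_t L/(K_{d1}+L) + M_t L/(K_{d2}+L)$, strictly increasing in
$L$, by safeguarded Newton bracketed on $[0, L_t]$ to a residual below
$10^{-12}\max(1, L_t)$. Both are checked against plain bisection oracles on
1000 random states, and the two-site model with equal constants collapses
onto the one-site model with $N = 2$ to $10^{-10}$ in the heats.

**Fitting.** The objective is the unweighted residual sum of squares
$\chi^2 = \sum_i (q_i^{obs} - q_i^{model})^2$ in (kcal/mol)². The heats are
*linear* in the enthalpies and the offset once the dissociation constants
(and stoichiometry) are fixed, so those parameters are profiled out by
linear least squares at every step while Levenberg–Marquardt works on
$\log N$ and $\log K_d$ (logs enforce positivity and make the ×1.5
perturbations used in the recovery suites symmetric). When no start is
given, a coarse grid scan over $K_d$ (and $N$) seeds the optimiser. The
two-site fit fixes one ligand per site ($N_1 = N_2 = 1$) and resolves the
site-label exchange symmetry by reporting $K_{d1} \le K_{d2}$; a fit with
$K_{d1} \approx K_{d2}$ is flagged degenerate, not failed. Flat data are
flagged `kd_identifiable = FALSE` rather than returning an arbitrary
constant. First-injection exclusion is available (`exclude_first`) but off
by default.

**The χ² profile.** `chi2_profile_two_sites()` maps χ² over a
$(K_{d1}, K_{d2})$ lattice with the linear parameters re-optimised per node
and reports the acceptance region under a user-chosen threshold and the
range each constant spans over it. The threshold is deliberately a user
input: χ² levels quoted from instrument software depend on instrument
weighting and on the raw thermograms, which are not portable, so profiles
are validated structurally here — the minimum sits at the generating node on
noiseless data, superlevel sets are nested, and a threshold at the minimum
returns only the argmin.

**Thermodynamics.** $\Delta G = RT\ln(K_d/1\,\mathrm{M})$ and
$\Delta\Delta G = RT\ln(\text{ratio})$ with
$R = 1.987204 \times 10^{-3}$ kcal mol⁻¹ K⁻¹ at 298.15 K unless overridden;
a 3-fold affinity ratio is 0.65 kcal/mol, i.e. 0.7 at one decimal.

## Problem sizes and numerical defaults

Simulated titrations default to 30 injections of 9 μL, enough to pass molar
ratio 2 for every protocol in the workflow scripts; round-trip recovery is
exercised for Wiseman $c$ from 1 to 1000. The optimiser runs with
`ftol = 1e-14`, `ptol = 1e-12`, 500 iterations — tight because the recovery
suites assert 1% agreement on noiseless data. Property suites use
100-protein proteomes (≈1200 tryptic peptides), which tally a few hundred
cleavage windows per planted screen. Coordinates are 1-based inclusive
throughout, matching subsite conventions.

## Known limitations

* Exact string matching only; homologous or repeated sequence regions in
  real proteomes raise the ambiguous-mapping rate.
* No FDR re-estimation: confidence scores are taken as given.
* No ΔCp, competitive, or sequential-sites ITC models, and no peak
  integration from raw power traces — inputs are per-injection heats.
* A single-site fit applied to genuinely two-site data reports an *apparent*
  $(N, K_d)$ pair that depends on how far the weak site is driven toward
  saturation; such fits are summaries, not estimates of either site.
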