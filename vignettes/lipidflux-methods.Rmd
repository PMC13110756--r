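---
title: "Methods: quantifying newly synthesised lipids from heavy-water labeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying newly synthesised lipids from heavy-water labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Heavy water given in drinking water (nominally 25% enrichment) labels newly
synthesised lipids: deuterium enters fatty-acyl chains through deuterated
acetyl-CoA and NADPH during de novo synthesis, so molecules made during the
labeling window carry a roughly binomial number of deuteriums over their
accessible C–H positions, while pre-existing molecules carry none beyond
natural abundance. On a high-resolution LC-MS instrument this appears as a
ladder of isotopologue peaks M+1…M+20 spaced by the ²H–¹H mass difference
(1.0062767 u). The analysis problem is to (i) integrate that ladder
reliably, (ii) strip the contribution of naturally occurring heavy isotopes
(¹³C dominates), and (iii) summarise and compare the resulting labeling
distributions across experimental groups — here a cuprizone
demyelination/remyelination design with groups Ctrl, Cpz and Rem, plus a
light-water control arm.

`lipidflux` implements the full chain, each stage as a data-frame-first
function so stages pipe into one another, and ships a synthetic-data
generator whose ground truth makes every stage testable without any
instrument data.

## Lipid chemistry

Shorthand names (`PC 34:1`, `PE P-18:0/18:1`, `HexCer 18:1;O2/24:0;O`,
`cholesterol`, …) are parsed by a small grammar covering sixteen classes.
Only the class and the total composition (carbons, double-bond equivalents,
`;O` oxygens) determine the neutral formula, so sn-resolved and
sum-composition names of the same species agree by construction; the `P-`
(vinyl ether) and `O-` (alkyl ether) prefixes differ by one double-bond
equivalent (2 H). Atomic masses and isotopic abundances come from a single
packaged constants table (AME2020 masses, IUPAC-CIAAW 2021 abundances), so
all m/z values are reproducible bit for bit. Charges are restricted to
|z| = 1, matching the ions the workflow targets.

The accessible-hydrogen count `n_h` used by the generator and for matrix
sizing defaults to the non-exchangeable C–H hydrogen count of the neutral
species (O–H and N–H protons exchange with water and cannot record
synthesis). No claim is made about which sites truly incorporate label in
vivo — the number is an overridable default, and for the synthetic targets
it is deliberately set small (30–36) so that the M+20 grid truncation is
negligible.

## Extraction

Extracted-ion chromatograms sum centroid intensities within a symmetric
±10 ppm window per MS¹ scan. Peak integration anchors every isotopologue on
the M+0 apex retention time and accepts apices within ±0.1 min; bounds
descend from the apex to the nearest local minimum or below 1% of the apex,
and the area is a trapezoidal integral. These integration rules (descent
rule, 1% baseline stop, nearest-apex tie-break) are documented defaults,
not inferences about any particular vendor implementation. An isotopologue
is "detected" when its apex exceeds 3× the median non-zero intensity of the
XIC outside the retention window, falling back to an absolute floor of 1
when no outside baseline exists — the upstream acquisition literature does
not define its detection criterion, so ours is explicit and configurable.

## Natural-abundance correction

At Orbitrap resolving powers (FWHM 60,000 at MS¹) the heavy-isotope peaks
of C, N and O are *not* mass-resolved from the deuterium grid: a resolution
model `R(m) = R_ref (m/m_ref)^(-1/2)` decides, isotope by isotope, whether
the distance between its mass shift and the nearest grid multiple of
1.0062767 u is below one FWHM. Unresolved isotopes enter an exact
polynomial convolution over the formula's atoms; resolved isotopes are
assumed to fall outside the ±10 ppm windows and are excluded from both
measurement and correction (their per-atom probability is renormalised
away). Natural deuterium itself sits exactly on the grid and is therefore
always corrected — one consequence is that even an infinitely resolving
instrument leaves a small (≈10⁻⁴ per hydrogen) off-diagonal term, so the
"fully resolved ⇒ identity matrix" limit holds only to that term.

The correction matrix's column *j* is the natural-abundance pattern of the
molecule carrying *j* tracer deuteriums, shifted down *j* bins; a tracer
purity below 1 redistributes tracer atoms binomially (default purity 1;
heavy water sold for labeling is essentially pure, and the source study
reports no purity setting). The matrix is truncated at M+20 with leaked
tail mass reported rather than redistributed. Inversion uses Lawson–Hanson
non-negative least squares rather than a direct solve: under noise a
triangular solve produces negative fractions, violating the definition of
a distribution. The NNLS solver is implemented in-package (no solver
package is available in the supported dependency set) and is verified in
the tests against an exhaustive isotopomer-enumeration oracle and exact
forward-model round trips.

## Quantifiability, percent deuteration, statistics

A lipid shows quantifiable deuteration when

1. the corrected deuterated-to-M+0 ratio, averaged over the light-water
   control samples, is below 5% (per-sample application is a config
   option — the source wording does not disambiguate, and the mean is the
   default), and
2. at least four consecutive isotopologues among M+1…M+20 are detected in
   at least 3 of 4 samples of one heavy-water group (generalised to ≥75%
   of the group, rounded up).

Percent deuteration is defined as `100 × (1 − x₀)` — the molar percentage
of molecules carrying at least one deuterium. With tens of accessible
hydrogens at 25% body-water enrichment a newly made molecule almost surely
carries ≥1 ²H, so this equals the fraction newly synthesised to within
`(1−p·eff)^n_h` (< 0.4% for the defaults). An atom-weighted alternative
(`Σ i·xᵢ / (N·Σxᵢ)`) is reported as a secondary column. Pools are split as
`non-deuterated = total × x₀`, `deuterated = total × (1 − x₀)` on the
raw-signal scale (an optional scalar response factor per lipid converts to
amounts; full internal-standard quantification is out of scope).

Lipids quantifiable in all three heavy-water conditions are tested by
one-way ANOVA with Tukey HSD post tests; in exactly two, by a two-sample
t-test; otherwise they are untested. p-values are Benjamini–Hochberg
adjusted across all tested lipids of the run. A *myelination marker* is a
lipid with no deuteration during cuprizone intoxication (non-quantifiable
in Cpz, or mean Cpz deuteration below the 5% floor) **and** a significant
increase of Rem over Ctrl at q < 0.05; remaining lipids are classed
increased/decreased-under-Cpz by the significant Cpz-vs-Ctrl contrast, or
constitutive. For heat-map display, non-quantifiable conditions are shown
as zero but excluded from the tested means.

## Fragment-level label localisation

MS² product ions localise the label: for PE/PE-P in negative mode the
phosphoethanolamine (m/z 140.0118) and dehydroglycerol
phosphoethanolamine (m/z 196.0380) headgroup ions, per-chain carboxylates
and acyl neutral losses; for PC/SM the phosphocholine cation (184.0733);
for HexCer the hexose loss and dehydrated sphingoid base. Assignments
match centroids within ±20 ppm (looser than MS¹: the product-ion scans are
acquired at 15,000 FWHM) of `fragment + d × 1.0062767/|z|` for
`d = 0…min(d_max, k)` given a precursor fragmented at M+k. At 15,000 FWHM a
one-¹³C reading (shift 1.0033548) is not resolved from a one-²H reading;
matched peaks consistent with both within one MS² FWHM are flagged
`c13_ambiguous` rather than forced to one interpretation. Reported ppm
errors surface any systematic offset; no recalibration is attempted.

## Imaging

Ion images sum per-pixel centroid intensities within ±15 ppm. Pixels
without a spectrum are missing, not zero. Per-pixel division by a sprayed
internal-standard image cancels any multiplicative sensitivity field
exactly (pixels with zero/missing standard become missing). Region
statistics treat the per-sample region mean as the unit — pixels are only
replicates within a section, animals are the replicates across groups —
and run one-way ANOVA with Tukey HSD per region (and per isotopologue).
Region masks are an explicit input (label table); anatomical registration
is out of scope.

## The synthetic world

The generator states its world once:

* body-water enrichment p = 0.25 (the nominal drinking-water enrichment),
  incorporation efficiency 0.7 — a single multiplicative factor standing in
  for unknown per-site incorporation, configurable because the true value
  is unknown;
* labeling distribution `(1−f_new)·δ₀ + f_new·Binomial(n_h, p·eff)`;
* group profiles: constitutive `f_new = 0.4` everywhere; marker
  `Ctrl 0.1, Cpz 0, Rem 0.4`; cuprizone-induced `Ctrl 0.2, Cpz 0.5,
  Rem 0.3`; light-water controls 0. Between-animal SD 0.03 on `f_new`;
* four samples per group (the study design's n), 1% multiplicative area
  noise, 2 ppm centroid jitter, Gaussian chromatographic peaks with
  σ = 0.05 min on a 0.01-min scan grid, and a 10-count detector floor below
  which centroids are not written (vendor-like peak picking);
* the MSI phantom: a corpus-callosum band with group-dependent `f_new`
  (Rem 0.5 vs Cpz 0.1, a designed ≈5-fold M+6 contrast), a smooth 0.4–1.6
  left-right sensitivity gradient multiplying every peak, 10% lognormal
  pixel noise, and a sprayed-standard peak per pixel.

Every random draw flows from one recorded seed. What a green test
establishes is therefore recovery of *this* world — isolated Gaussian
peaks, no co-eluting isobars, no retention drift, no matrix clusters — and
not performance on real tissue data; co-elution screening and alignment
remain the user's responsibility via the target list.

Numerical notes: the correction forward model is also used by the
generator, so generator-vs-pipeline agreement tests are only meaningful
because the *inverse* path (integration + NNLS) is independently validated
against enumeration oracles and geometry fixtures. With 1% area noise the
per-sample percent-deuteration error is dominated by the M+0 draw
(≈1 percentage point for weakly labeled species); the zero-noise round
trip is accurate to < 0.5 percentage points, and labeled fractions on the
noisy cohort to < 0.02 absolute.

## File formats

mzML and imzML support is deliberately minimal — centroided spectra,
uncompressed 64-bit little-endian arrays — because no reader exists in the
supported dependency set; the package reads what it writes plus any file
restricted to those encodings. Pre-extracted long-format CSV peak tables
bypass raw extraction entirely, and all tabular outputs carry a commented
provenance header (package version, config hash, seed).
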