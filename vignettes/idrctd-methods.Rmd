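---
title: "Methods: quantifying forms of intrinsic disorder in receptor cytoplasmic tails"
author: "idrctd package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying forms of intrinsic disorder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrctd)
```

# Scope

`idrctd` implements the three computational layers used to compare forms of
intrinsic disorder in the NMDA-receptor GluN2A/GluN2B C-terminal subdomains
(and in disordered regions generally):

1. **sequence statistics** — charge composition, the kappa
   charge-segregation statistic, windowed hydropathy, residue-spacing
   patterning and the diagram-of-states classification;
2. **conformational-ensemble observables** — radius-of-gyration
   distributions, residue contact-frequency maps, geometric hydrogen-bond
   detection and per-residue secondary-structure occupancy, computed from
   multi-model PDB conformer sets (the molecular-dynamics engine that
   produces such ensembles is out of scope: only the analysis is
   implemented);
3. **single-molecule FRET population analysis** — trace selection under
   alternating-laser excitation, photobleach detection, proximity-ratio
   histograms, Gaussian-mixture fitting with BIC model selection, and
   inversion of state mean efficiencies to mean dye separations under a
   self-avoiding-walk (SAW) polymer model.

A synthetic-data module generates all three input classes with known ground
truth, so the full pipeline is testable offline.

# Sequence-level statistics

Charges are counted at pH 7.4: arginine and lysine positive, aspartate and
glutamate negative, histidine neutral, termini uncharged (regions are
internal fragments of a receptor subunit). FCR and NCPR are the sum and
difference of the charge fractions.

**Kappa.** Per-window charge asymmetry
$\sigma = (f_+ - f_-)^2 / (f_+ + f_-)$ is evaluated over sliding windows of
5 and 6 residues; $\delta$ is the mean squared deviation of window
$\sigma$ from the whole-sequence value; kappa is the mean over the two
window sizes of $\delta/\delta_{max}$. For $\delta_{max}$ we evaluate
$\delta$ over a deterministic reference set of maximally segregated
arrangements: every layout $[0^a][+^{n_+}][0^b][-^{n_-}][0^c]$ with the
neutral residues distributed over the three gaps (strided for very long
sequences), plus the observed arrangement itself, which bounds kappa at 1.
A genuinely exhaustive maximum over all permutations is exponential, and —
as our short-string enumeration tests show — is occasionally attained by
arrangements that split a charge block, so *no* block-layout convention can
equal it exactly; the constructed reference set is the convention used
here, as in the standard classification tools, and is what the reported
kappa values mean. Sequences with fewer than two charges return `NA`
(kappa undefined).

**Diagram of states.** Classification uses only $(f_+, f_-)$: weak
polyampholyte below FCR 0.25, intermediate in [0.25, 0.35), strong
polyampholyte at FCR ≥ 0.35, and a positive/negative polyelectrolyte when
one sign's fraction reaches 0.35 while the other stays below. Boundary
values are assigned deterministically to the more-charged region.

**Hydropathy.** Kyte–Doolittle values are rescaled linearly from
[−4.5, 4.5] to [0, 9] and averaged in 5-residue sliding windows; the 0–9
convention matches the magnitude of the tabulated reference values
(3.3–3.8), whose caption nominally describes a 0–1 rescale — an
inconsistency we resolve in favour of the printed magnitudes.

**Patterning.** `residue_spacing()` reports the separations between
consecutive occurrences of a pooled residue class (arginine, aromatics,
…). `unpaired_arginine_count()` implements a simple pairing heuristic —
acidic residues first neutralise lysines, the excess then pairs arginines
— reconstructing a verbal description; under the tabulated charge
composition of the GluN2A subdomain this arithmetic cannot reach the
narrative counts, so the function is documented as a replaceable
heuristic and is not used in any acceptance check.

**Alignment.** Pairwise identity/similarity use Needleman–Wunsch global
alignment (BLOSUM62, affine gaps open 10 / extend 0.5, via Biostrings),
with gap columns counted in the denominator.

# Ensemble observables

Trajectories are multi-model PDB files with an optional per-frame replica
temperature (REMARK 250 records or a sidecar CSV); frames in a temperature
window (default 300–310 K) can be selected by label — no replica-exchange
demultiplexing is attempted. Radius of gyration is uniform-weighted by
default (mass weighting available; the reference analyses do not state
their choice). Contacts: two residues at sequence separation ≥ 2 are in
contact when any heavy-atom pair is within 6.5 Å; the map entry is the
fraction of frames in contact, computed once per unordered pair and
mirrored, so symmetry is exact.

Hydrogen bonds use the geometric criterion N···O ≤ 3.5 Å and N–H···O
angle > 120°, with the amide hydrogen reconstructed on the N-terminal
bisector (1.01 Å) when absent; the chain's first residue has no donor.
Secondary structure follows Kabsch–Sander-style patterns built on those
bonds — consecutive n-turns make helix, inter-strand bridge patterns make
sheet, remaining turn spans make turn, everything else coil — and the
8-class repertoire is collapsed to {helix, sheet, turn, coil} with
{H, G, I} → helix and {E, B} → sheet. Residues without backbone atoms
(e.g. coarse-grained bead chains) are coil.

# smFRET analysis

The proximity ratio is the raw acceptor fraction
$E_t = I_{A,t}/(I_{A,t}+I_{D,t})$; no gamma, crosstalk or background
corrections are applied anywhere, matching the uncorrected convention of
the reference histograms.

**Change points.** Steps are found by recursive binary segmentation with
a CUSUM mean-shift statistic; a split must exceed 3 units of the
segment-local robust noise SD (MAD of first differences) both in the scan
statistic and in the step size. The size criterion suppresses the false
change points that scan statistics alone produce on long traces; the
segment-local noise scale matters because post-bleach background noise can
be far smaller than shot noise.

**Photobleaching.** A donor bleach is a downward step in the *total*
intensity. An acceptor bleach conserves the total (the donor rises in
compensation) and a conformational transition steps both channels while
conserving the total, so the acceptor bleach is detected instead on the
direct-excitation (ALEX) channel, which carries no conformational
dynamics. This separation is what lets dynamic molecules be histogrammed
to their true bleach point rather than their first transition.

**Selection.** A molecule is accepted when the direct-excitation channel
shows real acceptor signal, the total intensity and the direct channel
each bleach in at most one step (multi-step implies an aggregate), and a
donor rise accompanies an acceptor bleach that precedes donor bleaching.
`classify_dynamics()` calls a molecule dynamic only on an E change point
with anticorrelated donor/acceptor steps and conserved total intensity,
which excludes focus drift (correlated steps) and bleaching.

**Mixture fitting.** Histograms (default 50 bins on [0, 1]) are fit by
maximum multinomial likelihood with mixtures of k = 1…4 Gaussians
truncated to the unit interval; expectation–maximisation on the binned
counts locates each optimum from deterministic starts and quasi-Newton
iteration polishes it. k is selected by BIC on the binned likelihood,
taking the smallest k within 2 units of the minimum — a deterministic
reading of "increase the number of Gaussians until the fit statistic
stops improving". Widths are reported as full width at half maximum
($2\sqrt{2\ln 2}\,\sigma$), and component SDs are bounded in
[0.005, 0.5] to exclude degenerate spikes and unidentifiable plateaus.

**SAW inversion.** The end-to-end distance distribution
$P(x) \propto x^{2+g} e^{-\alpha x^{\delta}}$, $x = r/r_{rms}$, with
$g = (\gamma-1)/\nu$, $\delta = 1/(1-\nu)$, $\nu = 0.5876$,
$\gamma = 1.1615$; $\alpha$ and the normalisation follow analytically
from $\int P = 1$ and $\langle x^2 \rangle = 1$. Given a state's mean
proximity ratio, we solve (bracketed monotone root find) for the scale
whose distribution-averaged efficiency
$\int P(x)\,[1+(x\,r_{rms}/R_0)^6]^{-1}dx$ equals it. The **reported
distance defaults to the rms separation** of the solved distribution:
across the five tabulated reference states the rms convention matches the
printed values to 0.5–3%, whereas the distribution mean deviates by up to
5.6%, so the rms is what those numbers evidently are; the mean is also
returned. The Förster radius default, 5.1 nm for Alexa 555/647, is a
literature value — the source table does not print one — and results are
sensitive to it: the residual 2.6% discrepancy on the low-FRET reference
state (8.86 vs 8.6 ± 0.2 nm) would close at $R_0 \approx 5.0$ nm. We keep
5.1 nm and report the discrepancy rather than adjusting the constant.
A rigid-chain mode (zero-width distribution) inverts the plain Förster
relation and returns exactly $R_0$ at $E = 0.5$, a useful sanity check.

```{r saw-example}
m <- saw_model()
saw_mean_distance(0.85, m)   # high-FRET state
saw_mean_distance(0.20, m)   # low-FRET state
```

# Synthetic data

**Sequences.** `generate_sequence()` permutes a fixed composition and,
given a kappa target, anneals with swap-only moves (composition exactly
preserved, geometric cooling, cap 10⁵, tolerance 0.01). The packaged
FASTA fixture contains *synthetic surrogates* of the rat GluN2A/GluN2B
chains — not the natural sequences, which are not redistributed here —
constructed so that each tabulated region reproduces the reference charge
counts exactly, the kappa values within the annealing tolerance, the
arginine/aromatic consecutive-spacing means, and the windowed hydropathy
to one decimal. Arginine positions are laid out first (their spacing is a
hard constraint), the remaining charges are annealed around them, and
aromatics are placed on neutral positions afterwards
(`scripts/make_fixtures.R`, deterministic seeds). Tests against these
fixtures therefore verify the *pipeline's self-consistency* with the
printed statistics; they do not re-derive the statistics from database
records. One tabulated value (full-chain FCR 0.264 over 627 residues) is
not representable as any integer residue count and the surrogate realises
the closest value, 0.263; likewise the printed boundary "1243–1462" is
only consistent with the printed charge fractions when read to the chain
C-terminus (1243–1464), which is the packaged default.

**Ensembles.** The Gaussian model is a freely jointed CA-bead chain
(bond 3.8 Å) whose mean squared radius of gyration approaches $Nb^2/6$;
the excluded-volume model is a hard-sphere pivot Monte Carlo sampler
(bead radius 1.9 Å, i.e. spheres touching at the bond length; burn-in
5N attempted pivots, N attempts between recorded frames). Over chain
lengths 25–200 its fitted size exponent is ≈ 0.62, above the asymptotic
SAW value 0.588 as expected from corrections to scaling at strong
excluded volume; the scaling check uses 400 recorded frames per length so
the Monte Carlo error on the fitted exponent is small against the
acceptance band. Ideal-helix (φ = −57°, ψ = −47°) and extended
(φ = −139°, ψ = 135°) fixtures are built from standard backbone internal
coordinates by natural-extension-reference-frame placement; the
paired-strands fixture is an idealised *flat* antiparallel two-strand
template with exact 2.9 Å N···O register — real strands twist, which
frustrates a long perfect ladder, and the flat template is the cleanest
geometry that exercises the bridge-pattern rules.

**FRET traces.** A continuous-time Markov chain over conformational
states is discretised at 10 frames/s (state taken at the frame midpoint);
per-frame proximity ratios add truncated-Gaussian conformational jitter
whose width is set so the *observed* peak width (jitter plus shot noise,
by error propagation through the proximity ratio) matches the state's
nominal FWHM. Noise is Gaussian with variance proportional to intensity
plus a read-noise floor (camera-like; Poisson available), and each dye
bleaches at an exponential single-step time — several steps for synthetic
aggregates. What the simulator does *not* emulate: blinking, spectral
crosstalk, gamma imbalance, diffusing background — so passing tests show
correct recovery under idealised photophysics, not robustness to every
experimental artefact.

# Acceptance problem sizes

The bundled checks run at sizes chosen to keep the whole suite in a few
minutes while leaving statistical headroom: mixture-recovery uses 20
replicates of 20 000 frames (1 000 molecules × 20 frames) per
configuration; the freely jointed chain check uses 500 frames at N = 100;
the excluded-volume scaling fit uses 400 frames at each of
N ∈ {25, 50, 100, 200}; photobleach and dynamics detection use 200
simulated molecules each.

# Known limitations

- Kappa is convention-dependent through $\delta_{max}$; values are
  comparable within this package (and with tools using the same
  segregated-reference construction), not across arbitrary conventions.
- The SAW inversion assumes distance dynamics fast relative to the frame
  time, a single Förster radius, and isotropic dye orientation; reported
  separations inherit the $R_0$ uncertainty discussed above.
- Trace selection assumes an ALEX direct-excitation channel; without it,
  acceptor bleaches during a live donor cannot be separated from genuine
  low-FRET transitions, and `detect_photobleach(channel = "total")` is
  then the conservative choice.
- The secondary-structure assignment uses the package's geometric
  hydrogen-bond criterion, not the electrostatic energy of the original
  8-class algorithm; on idealised fixtures they agree by construction,
  on real ensembles small differences at element boundaries are expected.
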