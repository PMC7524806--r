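---
title: "Calcium-dependent co-regulation of ion channels under growth: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calcium-dependent co-regulation of ion channels under growth: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Excitable cells keep their electrical phenotype while their physical size
changes severalfold. Because voltage dynamics depend on conductance
*densities*, growth — which adds membrane faster than it adds channels —
dilutes every current and can silence a cell. `calreg` implements and
analyses a candidate solution: a *master regulation* scheme in which a
single sensed variable, the time-averaged intracellular calcium
concentration, jointly drives transcription of all channel types. The
package asks when this scheme compensates size changes, and when and why it
fails pathologically for channel-specific perturbations.

## The membrane model

The cell is a single compartment with eight stomatogastric-type
conductances (A, CaS, CaT, H, Kd, Leak, NaV, KCa):

$$C_m \dot V = -\sum_i \bar g_i\, m_i^{p_i} h_i^{q_i} (V - E_i),$$

with the published gating kinetics of this model family (sigmoidal steady
states, voltage-dependent time constants; KCa activation additionally
scales with $[\mathrm{Ca}]/([\mathrm{Ca}] + 3\,\mu M)$). Written in
densities ($\mu S/mm^2$), the equation is independent of absolute cell
size. The calcium reversal follows the Nernst potential of the
instantaneous calcium concentration with 3 mM external calcium.

Intracellular calcium obeys a thin-shell balance

$$\dot{[\mathrm{Ca}]} = -\frac{\phi\, i_{Ca} A}{2F\eta}
  - \frac{[\mathrm{Ca}] - [\mathrm{Ca}]_\infty}{\tau_{Ca}},$$

where $i_{Ca}$ is the calcium current density through CaS and CaT, $A$ the
membrane area and $\eta$ the effective shell volume. Under the thin-shell
assumption $\eta \propto A$, so the flux factor $A/\eta$ — and with it the
whole dynamical system — is invariant under size changes at fixed
densities. The package treats $\eta$ as an effective scaling constant;
only the ratio $A/\eta$ ever enters.

Integration is exponential Euler at $dt = 0.05$ ms (every state variable is
relaxed towards its instantaneous equilibrium with its instantaneous time
constant), gates clipped to $[0,1]$, with a 500 mV divergence guard. A
tenfold finer step changes the reference burst period by well under 2%
(tested).

### Calibration of the unprinted calcium parameters

$\tau_{Ca} = 200$ ms, $[\mathrm{Ca}]_\infty = 0.05\,\mu M$ and the
geometry ($A = 0.0628\ mm^2$, shell depth $\approx 1.1\,\mu m$) follow the
model lineage the kinetics come from. The dimensionless flux prefactor
$\phi$ is not printed anywhere in that lineage consistently; it rescales
the absolute calcium concentration and therefore the loop gain of the
regulation model. We calibrated it once, against an architectural
criterion: *the closed-loop regulator, with the stated timescales
($\tau_{\mu_i} = 5000/\bar g_i$ ms, $\tau_g = 5$ s), must hold the
reference burster at its own calcium target*. At $\phi = 1$ (the naive
per-cell transcription of the lineage's flux constant) the mRNA variables
swing by multiples of the conductances within a single burst cycle, the
zero floor rectifies those swings, and the loop walks off to a remote
attractor. At $\phi = 0.2$ the loop holds baseline to within 0.5% over
hundreds of seconds and recovers a fourfold scale-down to ~2%. All
calcium-dependent results in the package use $\phi = 0.2$; the parameter
is exposed in `default_ca_params()`.

With this calibration the reference model (printed conductances
$g_A = 379$, $g_{CaS} = 165$, $g_{CaT} = 2.35$, $g_H = 0.72$,
$g_{KCa} = 297$, $g_{Kd} = 1713$, $g_{Leak} = 0.46$, $g_{NaV} = 1370$
$\mu S/mm^2$) bursts with a period of about 810 ms, a duty cycle of about
0.49, and a mean calcium of about 58 µM — the calcium target used
throughout.

## The regulation and growth models

mRNA and conductance densities evolve as

$$\tau_{\mu_i} \dot\mu_i = \mathrm{Ca}_{target} - [\mathrm{Ca}], \qquad
  \tau_g \dot g_i = \mu_i - g_i,$$

with $\tau_{\mu_i} = 5000/\bar g_i$ ms so that the controller's motion
direction reproduces the model's conductance ratios
($g_j/g_i = \tau_{\mu_i}/\tau_{\mu_j}$), and $\tau_g = 5$ s (deliberately
fast, as in the source scheme, to keep simulations tractable). Both
variables are floored at zero: concentrations cannot be negative. All
eight channels are regulated by default (whether the leak is regulated is
not specified by the scheme; a config switch excludes it).

Because the error enters every $\dot\mu_i$ identically, over any interval
long compared with $\tau_g$ the conductance increments satisfy
$\Delta g_j/\Delta g_i \to \tau_{\mu_i}/\tau_{\mu_j}$ — the controller can
only move along one ray in conductance space. That reduces the
compensation question to a one-dimensional fixed-point problem along the
*growth ray* (uniform scaling of all densities), and justifies classifying
ray fixed-point stability by the slope of mean calcium against scale: the
feedback is restorative exactly where calcium rises with scale.

Growth is linear and relative: $\dot A = k A_0$, $\dot \eta = k \eta_0$,
which conserves $A/\eta$ exactly (a literal equal-absolute-rate reading
would break the thin-shell ratio on dimensional grounds). During growth,
conductance densities acquire a dilution term $-(\dot A/A) g_i$: new
membrane dilutes existing channels, and the calcium error drives
resynthesis. At fixed size the equations reduce exactly to the displayed
ones. The open-loop comparison integrates
$\dot G_i = r_i$, $\dot A = r_{growth}$ (constant effector drive, the
simplest reading of the scheme) in closed form.

## Population analyses and their scales

All population results are computed at desk scale, sized so the full test
suite and the acceptance script run on one CPU in minutes:

* **Model database**: rejection sampling from the hypercube
  $[0, 2\bar g_i^{ref}]^8$; a draw is kept if it bursts regularly
  (period CV ≤ 0.2, ≥ 2 spikes per burst) with period and duty cycle
  within ±20% of the reference targets. A 6 s prescreen (spiking with
  burst-like ISI structure) rejects most draws cheaply. Defaults: 30
  models (the source study used 635); acceptance is ~3%.
* **Ray scans**: 30 log-spaced scale factors in $[0.05, 3]$ (plus scale 1),
  15 s of model time per point with the first 5 s discarded. Target
  crossings are refined by four bisection simulations. Excursions within
  3% of the target are treated as averaging jitter (the window-to-window
  variability of mean calcium) and suppressed before crossing detection.
  A handful of models whose calcium curve peaks exactly at their own
  target (a tangency, not a transversal crossing) legitimately report
  zero stable fixed points.
* **Burst metrics**: spikes are upward 0 mV crossings; bursts are broken
  where an interspike interval exceeds 3× the median ISI; the duty cycle
  adds a nominal 5 ms spike width to the first-to-last-spike span. The
  source operationalisation is unstated; these defaults satisfy the
  constructed-train checks in the tests and all tolerance bands are
  carried in `classifier_config()`.

## Level sets, basins, silent states

The calcium level set of a 2-D projection (group-summed densities on each
axis) is sampled adaptively: random initial points, Delaunay
triangulation, then repeated subdivision (at the centroid) of the largest
triangle whose nodes straddle the target level, until the budget or a
minimum-edge criterion is reached; the set is extracted by linear
interpolation on straddling edges. Basins of attraction under regulation
use the same skeleton with a categorical field (terminal classification of
the closed loop) and refinement of label-mixed triangles. Centroid
placement was chosen over circumcentre for robustness to sliver triangles.

The analytical silent-state solver looks for simultaneous zeros of the
voltage and calcium equations under steady-state gating with calcium
frozen at the target: $V_{Ca}$ solves the window-current balance
$\phi i_{Ca}(V) A/(2F\eta) = -(\mathrm{Ca}_{target} -
\mathrm{Ca}_\infty)/\tau_{Ca}$ (roots bracketed on a 0.5 mV grid in
$[-80, 0]$ mV, refined by Brent to $10^{-6}$ mV), $V_V$ solves the total
steady-state current. The silent set is the plane locus where the closest
pair satisfies $|V_V - V_{Ca}| < 0.05$ mV. Gating and the calcium
reversal are evaluated at the target concentration (a switch allows
resting calcium instead). Marginal stability of the voltage equation is
reported as $\partial i_{tot}/\partial V$; actual branch stability is
assigned by 20 s direct simulation from the candidate state (±2 mV band,
no spikes), as in the source analysis.

One quantitative consequence of the calibration: the mean calcium influx
over a burst cycle is ~10× smaller than the peak steady window current, so
trapped silent states require roughly tenfold the reference CaS+CaT
density — this ratio is nearly independent of $\phi$. The silent-set
analyses therefore use a calcium-axis extent up to 20× the reference,
while level-set and basin projections keep the default
$[0.01, 2.5]\times$ extent.

## Perturbation experiments

Generic perturbations are summarised by the mean and the ($N-1$) standard
deviation of per-channel relative changes $(g - g_0)/g_0$. The sampler
draws normal relative changes and re-standardises them so every draw
realises the requested moments exactly (the base distribution is not
specified by the scheme; normal is the natural maximum-entropy choice, and
negative conductances are resampled). Zero-dispersion perturbations are
exactly size-change equivalents; recovery failure is expected — and
observed — to track dispersion, not mean.

## What the synthetic populations do and do not show

The database emulates "many different conductance mixes, same phenotype";
its hypercube bounds and tolerances are free parameters of the study
design, not measured biology. Passing tests show that the *mechanism* —
ray-confined integral control on a calcium readout — behaves as analysed
within this model family. They do not show anything about real
transcription dynamics (the timescales are artificially fast), about
spatially extended cells, channel noise, or calcium microdomain structure,
all of which are deliberately outside scope.

## Known limitations

* Stability along the ray is classified by the slope sign of the calcium
  curve (exact for ray-confined motion), not by a full 13-dimensional
  linearisation.
* Fixed-point tangencies (curves touching the target) are not resolved
  beyond the grid; they appear as zero-stable-point models.
* The classifier merges tonic spiking and one-spike bursting into one
  label; the four-way partition is preserved.
* Basin maps are 2-D sections of an 8-D basin geometry, as in the source
  analysis.
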