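---
title: "Capacitance-drive models of ultrasonic neuromodulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capacitance-drive models of ultrasonic neuromodulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicesim)
```

## The model

Low-intensity ultrasound can excite or suppress neural activity depending on
how it is pulsed. The intramembrane-cavitation account of this phenomenon
holds that ultrasound makes nanoscale regions of the lipid bilayer (the
"bilayer sonophores") oscillate at the carrier frequency, so the membrane
capacitance oscillates too. A time-varying capacitance injects a
displacement current `Vm dCm/dt` into the membrane equation: over each
carrier cycle the strongly asymmetric hyperpolarization rectifies the ionic
currents (the leak current above all) into a slow net influx of positive
charge, and over tens of milliseconds this accumulation brings the neuron to
its discharge threshold.

`nicesim` implements this mechanism at the level most useful for studying
*cell-type selectivity*: the capacitance waveform is not derived from the
full sonophore mechanics but represented by its validated sinusoidal
reduction

    Cm(t) = Cm0 + C_Amp * sin(2 pi f (t - t_pulse)),

gated by a pulse envelope (carrier frequency `f`, pulse repetition frequency,
duty cycle) and weighted by the sonicated membrane fraction `fs`:
`Cm = fs * Cm_s(t) + (1 - fs) * Cm0`. The phase restarts at zero at each
pulse onset, so the capacitance is continuous at pulse-on edges; at
pulse-off edges a discontinuity is allowed and harmless because the
integrator's state variable is charge (below). The drive is a contract —
`Cm` and `dCm/dt` as functions of time — and a mechanics backend could
replace the sinusoid without touching any neuron code.

The single anchoring calibration is the published operating point: at
0.69 MHz and 3.3 W/cm² (320 kPa) the full mechanics produces an ~80%
capacitance decline, i.e. `C_Amp = 0.8` µF/cm² for `Cm0 = 1` µF/cm².
Away from that point `amplitude_from_intensity()` scales `C_Amp` with the
pressure amplitude (∝ √I). This mapping is *declared configuration, not
physics*: the true amplitude–intensity relation is owned by the out-of-scope
sonophore mechanics, every intensity label produced by the package states
the mapping, and amplitudes are clipped below `Cm0` (the capacitance must
stay positive) with a warning.

## Neuron models

Five single-compartment Hodgkin–Huxley models are built from a published
parameter table (`param_registry()`):

* **RS, FS, LTS** — regular-spiking pyramidal, fast-spiking and
  low-threshold-spiking cortical neurons: Traub-type Na⁺/delayed-rectifier
  K⁺ kinetics with a per-cell spike-threshold shift `V_T`, the slow
  non-inactivating M current, and leak. The LTS model adds the low-threshold
  T-type calcium current `I_T = g_T s² u (Vm − V_Ca)` with a fixed 120 mV
  reversal and a −7 mV uniform gate shift.
* **TC** — thalamocortical relay cell: Na, Kd, T (gate shift 0), the
  hyperpolarization-activated mixed cationic current I_h with its
  calcium-regulation scheme, a potassium leak, and leak. The calcium
  reversal is computed by the Nernst relation from a submembrane calcium
  pool (shell depth 100 nm, decay 5 ms) fed by the inward T current.
* **RE** — thalamic reticular cell: Na, Kd, the reticular T-current variant
  and leak, with the same calcium pool.

The T-gate steady states and time constants are implemented exactly as
printed in the source table, including the piecewise U-gate time constant
with its branch at `Vm + V_x = −80` mV. Two typographic/constant decisions
deserve note:

* The τ prefactor is read as **1/3.7** (exposed as `T_TAU_SCALE`), i.e. the
  24 °C time constants divided by the Q10 = 3 factor `3^1.2 ≈ 3.7`. This
  reading reproduces the stated near-rest recovery times (S gate ~2 ms,
  U gate ~15 ms) and all resting potentials; the alternative literal reading
  (×13.7) does neither.
* The resting intracellular calcium is not tabulated; candidate literature
  values are 240 nM and 50 nM. The package uses **50 nM**, selected by the
  validation protocol used for all adopted constants — reproducing the
  tabulated resting potentials: with 50 nM the TC model rests at −62.8 mV
  (reference −63.4, tolerance 1 mV) and RE at −89.6 (reference −89.5);
  240 nM puts TC 1.9 mV too depolarized through the strongly nonlinear
  (∝ Ca⁴) I_h locking term. The residual 0.6 mV offset is attributed to
  using the ohmic driving force `(Vm − V_Ca)` with the tabulated
  conductance, where the original thalamic models used constant-field
  permeation with a permeability parameter.

The Na/Kd/M, I_h + calcium regulation, and reticular T rate functions are
not printed in the source table; they are adopted verbatim from the models
it cites and verified through the resting-potential targets
(`resting_state()` reproduces all five tabulated values, the cortical ones
to < 0.1 mV).

Chimeric manipulations (`add_channel()`) append the LTS-parameter T channel
to RS or FS models ("RS+", "FS+") to show the T channel alone confers
low-duty-cycle hypersensitivity.

## Integration

The membrane equation is integrated in **charge density** `Q = Cm Vm`:

    dQ/dt = −(sum of ionic currents) − (synaptic currents)/area + I_ext/area

with `Vm = Q / Cm(t)` inside every current term. This is algebraically
identical to the usual form `Cm dVm/dt + Vm dCm/dt = −ΣI`, but `Q` is
physically continuous across capacitance discontinuities at pulse edges,
which removes an integration pathology at pulse-off edges.

The integrator (compiled, Rcpp) uses fixed steps at the published carrier
resolution: **0.025/f µs during ultrasound-on** (40 steps per carrier cycle)
and 10 µs during off periods. Gates advance by Rush–Larsen exponential
relaxation (exact for frozen rates, unconditionally stable), the charge by a
midpoint (RK2) step, the calcium pool by the exact step of its linear ODE,
and the I_h regulation scheme by an explicit Euler step (its rates are slow
on the step scale). A fixed-step scheme was chosen over the adaptive
multistep family used historically because it is simpler, bit-for-bit
deterministic, and passes the refinement oracle: halving all steps changes a
subthreshold trace by < 0.1 mV in max-norm (asserted in the tests).

Two numerical guards: gate variables are clipped to [0, 1] after every step,
and the voltage used for *rate evaluation only* is clamped to
[−1500, 500] mV — all gates saturate far inside that range, while the deep
capacitance dips of near-ceiling drive amplitudes would otherwise overflow
the exponential rate functions. The true `Vm` always drives the currents.

Spike detection — an upward crossing of 0 mV with a 1 ms refractory floor —
is declared plumbing: the source phenomenology reports "volleys" without a
criterion. Detection runs inside the integration loop at full resolution;
`detect_spikes()` applies the same rule to stored traces. Because
`sign(Vm) = sign(Q)`, carrier-frequency oscillations of `Vm` do not create
spurious crossings. Initial conditions are always the computed resting
state; nothing in the simulator is random.

## Synapses and the cortical microcircuit

The three-population network is one RS, one FS and one LTS neuron (one
neuron per population, as in the source network diagram) with eight
synapses: AMPA (reversal 0 mV, rise 0.1 ms, decay 3 ms) from RS to all
three populations including itself, GABA_A (reversal −85 mV) from FS
(decay 8 ms) and LTS (decay 50 ms); there is no LTS→LTS connection.
Conductance follows

    I = g_bar * P(t) * s(t) * (Vm − V_rev),

where `s(t)` is the bi-exponential kernel normalized to unit peak and
superposed over presynaptic spikes, and `P(t) = F·D1·D2` is the short-term
plasticity state: on each presynaptic spike `F += f` and each `D *= d`,
between spikes all factors relax exponentially to 1. Only the excitatory
connections onto the interneurons are dynamic (RS→FS facilitating with two
depression processes, RS→LTS facilitating). `P(t)` multiplies the whole
conductance, as the printed synaptic equation states; with the alternative
per-event bookkeeping the baseline network runs ~2.5 Hz too fast. The
unit-peak normalization of `s(t)` is declared (the source does not state
one); total conductances are used as printed and converted to densities by
the postsynaptic membrane area, as is the thalamic DC input (0.17 nA to RS
and 1.4× that to FS; nothing to LTS). Synaptic delays are zero (none are
printed).

With only the thalamic input the network settles into asynchronous activity
with the RS cell near the published ~7 Hz anesthetized baseline (the package
computes 8.5 Hz over the final 2 s of a 2.5 s run).

## Protocols and their calibrations

* **Threshold search** (`find_threshold()`): geometric bisection on drive
  amplitude to 2% relative tolerance, criterion ≥ 1 spike, bracket
  auto-expanded up to the admissible ceiling (`C_Amp < Cm0`). Thresholds are
  reported natively in amplitude space. This bounded space compresses the
  published orders-of-magnitude *intensity* threshold separations into small
  amplitude ratios near the ceiling: orderings (LTS below the chimeras below
  the native RS/FS; RS censored at the ceiling at 5% duty) are exact model
  content, the magnitudes are not. At 50% duty, where all thresholds are
  comfortably inside the range, the RS/LTS ratio is ~2.4, matching the
  published ~2×.
* **Phase diagrams** (`phase_diagram()`): duty × amplitude grids labelled
  `none` / `LTS-only` (suppression zone) / `joint` (activation zone), with
  500 ms default waveforms.
* **Thalamic duty response** (`duty_response()`): 1.5 s stimulus, rate over
  the last 0.5 s, so transient-only responses count as zero. The default
  amplitude **0.84 µF/cm²** is a second qualitative calibration point: the
  thalamic protocol's published stimulus (5.2 W/cm²) maps above the
  sinusoidal reduction's admissible range under the √I rule, and 0.84 is the
  amplitude at which the model reproduces the full published thalamic
  phenomenology simultaneously — TC locking 1:1 to the 100 Hz pulse train at
  5% duty, RE firing one initial volley and stopping at 5%, and RE switching
  to sustained volleys at 7%. Below (≤ 0.82) TC locks 2:1; above (≥ 0.85)
  RE fires tonically at 5%.
* **Thalamic-input sweep** (`thalamic_sweep()`): per input level, the
  LTS-recruitment ("suppression") threshold is probed with the network
  protocol stimulus (1 s, 5% duty, PRF 100) on a settled baseline, and the
  RS-activation threshold with a 0.5 s, 50% duty, PRF 10 probe; recruitment
  means exceeding the population's own no-drive baseline by 5 Hz. With a
  shorter suppression probe the trend direction is not robust (the
  recruitment race between LTS and FS is ignition-dominated), which is why
  the probe length is part of the protocol definition.

## What the tests do and do not show

The suite asserts the quantitative operating points (acoustic conversions,
all five resting potentials, the ~7 Hz network baseline, TC 100 ± 5 Hz
phase-locking, LTS recruitment at 30–50 Hz with RS suppression) and the
qualitative structure (CW excites RS/FS/LTS while 5% duty excites only LTS;
chimeric threshold orderings; the RE 5→7% duty transition; both
thalamic-input trend directions; charge-balance, refinement, gate-bound and
determinism oracles). Problem sizes are the protocol sizes: single-neuron
runs of 0.3–1.5 s at 0.69 MHz carrier resolution, network runs of 1.6–2.5 s;
carrier-insensitive properties (thresholds vary < 1% between 0.2 and 1 MHz
here) are tested at a 0.2 MHz carrier.

Passing these tests shows the reduced model reproduces the published
selectivity phenomenology and its printed operating points. It does *not*
validate the amplitude–intensity mapping away from the calibration points,
absolute intensity thresholds, real membrane mechanics (the sinusoid lacks
the sharp non-sinusoidal excursions of the cavitation waveform), population
statistics (one neuron per population, no background noise, no conduction
delays, no NMDA/GABA_B), or any morphology-dependent effect.

## Known limitations

* Near-ceiling amplitudes (`C_Amp → Cm0`) produce physically implausible
  multi-thousand-mV capacitance-dip excursions; results there characterize
  the reduction, not the mechanics. The thalamic calibration deliberately
  stays at 0.84.
* The TC resting potential carries a ~0.6 mV structural offset (ohmic vs
  constant-field T-current driving force).
* The LTS network recruitment rate (30 Hz) sits at the low edge of the
  published ~40 Hz because the sinusoidal drive accumulates charge more
  slowly per cycle than the true cavitation waveform.
* Thresholds are exact in amplitude space only; intensity labels inherit the
  declared √I approximation.
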