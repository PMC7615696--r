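---
title: "An interneuron GABA/NPY model of neurovascular coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An interneuron GABA/NPY model of neurovascular coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvcgaba)
```

## The mechanism being modelled

Activated cortical neurons need their local blood supply adjusted within
seconds. For excitatory (somatosensory) activity the dominant fast pathway is
potassium: K⁺ released into the extracellular space is taken up by the
astrocyte and released at its endfeet into the perivascular space, where it
hyperpolarizes the vascular smooth muscle cell (SMC) through inwardly
rectifying K⁺ channels, closing voltage-operated Ca²⁺ channels (VOCC) and
dilating the arteriole.

GABAergic interneurons of the nNOS-expressing type engage a different, and
internally opposed, pair of pathways:

* **GABA** opens Cl⁻ channels (reversal −75 mV) on the astrocyte and the SMC,
  hyperpolarizing the SMC → VOCC closes → dilation;
* **NPY** increases the VOCC conductance (up to +5%) → more Ca²⁺ entry →
  constriction;
* **NO**, co-released by these interneurons, inhibits GABA transaminase
  (GABA-T), the enzyme degrading GABA to glutamate. NO therefore protects the
  GABA (dilatory) arm. Blocking NO synthesis (L-NAME) disinhibits GABA-T,
  GABA is degraded, and the NPY (constrictive) arm dominates.

The package integrates this mechanism as a deterministic ODE system and
reports what optical imaging spectroscopy measures: fractional changes of
oxy-, deoxy- and total hemoglobin (ΔHbO, ΔHbR, ΔHbT).

## State equations

Time is in milliseconds everywhere; the kinetic rates (~2×10⁻³ ms⁻¹) give
~450 ms time constants, commensurate with the 2-s stimulations. GABA, NPY and
glutamate are nondimensionalized so that the regular stimulated maximum is of
order 1 and the resting value is 0.

Signalling (per-species stimulus indicators $I$ are Heaviside windows with
strict boundaries):

$$\frac{dGABA}{dt} = -\beta_{GABA}\,G_{T,act}(NO)\,(GABA - GABA_{base})
  + \alpha_{GABA} I_{GABA}(t)$$

$$\frac{dNPY}{dt} = -\beta_{NPY}(NPY - NPY_{base}) + \alpha_{NPY} I_{NPY}(t)$$

$$\frac{dGlu}{dt} = f(K_e) + \beta_{GABA}G_{T,act}\,GABA - \beta_{Glu} Glu$$

$$G_{T,act}(NO) = \tfrac12\!\left[(G_{T,max}+G_{T,min})
  - (G_{T,max}-G_{T,min})\tanh\frac{NO - GT_{mid}}{GT_{slope}}\right]$$

$f(K_e)$ is a tanh switch centred at 5 mM: extracellular K⁺ above threshold
releases glutamate from the excitatory neuron. The GABA-degradation product
also feeds glutamate — that is the NO-gated arm.

With the default activity bounds ($G_{T,min}=1$, $G_{T,max}=2$) the steady
stimulated GABA elevation is $\alpha_{GABA}/(\beta_{GABA}G_{T,act})$, so
moving GABA-T from its minimum to its maximum activity halves the elevation
exactly — the analytic identity $100(1 - G_{T,min}/G_{T,max}) = 50\%$ that
the test suite and `scripts/acceptance.R` verify by direct ODE integration.

**NO dynamics.** The NO species is a first-order
production/decay surrogate:
$dNO/dt = -\beta_{NO}(NO - NO_{rest}(1-L)) + \alpha_{NO} I_{NO}(t)(1-L)$ with
blockade flag $L$. Defaults: $\beta_{NO} = 2.2\times10^{-3}$ ms⁻¹ (matching
the other decay scales) and $\alpha_{NO}$ set so the sustained-stimulus
elevation is 10× the resting 0.02047 µM — enough to saturate the GABA-T
sigmoid toward $G_{T,min}$ during stimulation. Blockade is modelled as
complete (NOS inhibition measured experimentally is >90%): both the resting
supply and stimulated production are zeroed, so NO decays to ~0 and GABA-T
settles near $G_{T,max}$.

One genuine inconsistency is worth recording: with the default midpoint
(0.06 µM) and slope (0.02128 µM), the activity at resting NO evaluates to
1.976, not the nominal minimum of 1. We keep the printed constants and
therefore verify the 50%/100% statements at the sigmoid's saturation limits
rather than at resting NO.

## Channel fluxes and the vascular surrogate

The two authored channel models are

$$J_{GABA} = g_{GABA}(GABA)\,(v - E_{GABA}), \qquad
  g_{GABA} = \frac{G_{GABA}}{2}\Big(1+\tanh\frac{GABA - g_{mid}}{g_{slope}}\Big)$$

applied identically on the astrocyte ($v_k$) and SMC ($v_i$), with
$G_{GABA} = 0.3\,G_{Cl,i} = 4.02\times10^{-7}$ µM mV⁻¹ ms⁻¹, and

$$J_{VOCC} = g_{VOCC}(NPY)\,
  \frac{v_i - v_{Ca1}}{1+\exp(-(v_i - v_{Ca2})/R_{Ca})}.$$

**Endpoint-renormalized VOCC sigmoid.** The raw tanh form
$G_{Ca,i}(1 + \tfrac{N_{inc}}{2}\tanh\frac{NPY-N_{mid}}{N_{slope}})$ cannot
satisfy both stated endpoints ($g_{VOCC}(0)=G_{Ca,i}$,
$g_{VOCC}(1)=1.05\,G_{Ca,i}$) for the default midpoint/width. We therefore
rescale the sigmoid affinely so both endpoints hold exactly, keeping
monotonicity and shape; `vocc_sigmoid = "literal"` switches back to the raw
form for sensitivity checks. Where the sources of record print conflicting
sigmoid constants, the registry keeps both (`*_text` variants) with the
tabulated value as default.

**The reduced electro-vascular surrogate.** A full neurovascular-unit model
of membrane electrophysiology has hundreds of parameters; the mechanisms
relevant here are sign-chains (K⁺ → hyperpolarize → dilate; GABA → Cl⁻ →
hyperpolarize → dilate; NPY → VOCC → Ca²⁺ → constrict), and the observable is
the hemoglobin trace, not membrane potential. We therefore collapse the
electrophysiology into six first-order states:

| state | dynamics | constants (defaults) |
|---|---|---|
| $K_e$ | relax to 3 mM + stimulus source | rate 2.2×10⁻³ ms⁻¹; source sized for +6 mM steady elevation (physiological 3–10 mM range) |
| $K_p$ | first-order lag behind $K_e$ | 2×10⁻³ ms⁻¹ (astrocytic relay) |
| $v_k$ | relax to −80 mV + K⁺ depolarization − Cl⁻ flux | 10 mV amplitude, tanh saturation |
| $v_i$ | relax to −45 mV − KIR-like shift(k_p) − Cl⁻ flux (− optional 20-HETE·BK leak) | KIR amplitude 8 mV; Cl⁻ flux-to-voltage weight 2500 mV/µM sized for ~10 mV hyperpolarization at saturating GABA |
| $Ca_i$ | relax to $J_{VOCC}(v_i,NPY)/J_{VOCC}(v_{i,rest},0)$ | baseline exactly 1 |
| $r$ | relax to $1 + 0.15\tanh((1-Ca_i)/0.5)$ | ±15% maximal radius excursion |

The 20-HETE (arachidonic-acid metabolite) branch appears only as an optional
scalar multiplier on a BK-like leak term and is off by default — forcing it
to zero has no significant effect on the hemoglobin profiles in this regime,
so the default model omits it. Membrane-level fidelity is explicitly not a
goal; the surrogate is judged on the hemoglobin-trace shape.

## Hemodynamics

Flow follows Poiseuille in baseline-normalized variables, $CBF = r^4$. The
venous compartment is the Buxton balloon in normalized volume $v$ and
deoxyhemoglobin $q$:

$$\dot v = (f_{in} - v^{1/\alpha})/\tau, \qquad
  \dot q = \frac1\tau\Big(f_{in}\frac{E(f_{in})}{E_0} - q\,v^{1/\alpha - 1}\Big),
  \qquad E(f) = 1-(1-E_0)^{1/f}$$

with τ = 2000 ms, Grubb exponent α = 0.38 and E₀ = 0.4 — standard
balloon-literature values, all config-exposed. Outputs are
$\Delta HbR = q - 1$; total hemoglobin from the flow closure
$\Delta HbT = CBF\cdot q/CMRO - 1$ (the multiplicative reading of
HbT ∝ CBF·HbR/CMRO in normalized variables, pinned to zero at baseline);
and $\Delta HbO = \Delta HbT - \Delta HbR$, which makes hemoglobin
conservation bit-exact at every sample. `hbt_mode = "volume"` provides the
standard balloon alternative $\Delta HbT = v - 1$ for sensitivity checks.
CMRO₂ is $1 + g\,a(t)$ with $a$ a first-order-lagged stimulus indicator; by
default $g = 0.2$ for whisker (excitatory, metabolically active) stimulation
and 0 for optogenetic stimulation, since direct interneuron photostimulation
carries no comparable metabolic load. Both gains are overridable.

## Protocols

* **whisker**: drives $K_e$ and NO (excitatory pathway). The 5-Hz carrier is
  not resolved; the stimulus is its 2-s envelope.
* **optogenetic**: drives GABA, NPY and NO (interneuron pathway; 99-Hz
  carrier likewise enveloped). The NPY pulse width is **half** the GABA
  pulse; this asymmetry, together with the GABA-conductance midpoint at 0.5,
  is what produces the early constriction (ΔHbR up, ΔHbO/ΔHbT down) before
  the dilation reversal.
* **L-NAME**: a pure switch — no other parameter changes between drug and
  no-drug conditions.

In this reduced model the whisker response is *exactly* LNAME-invariant: NO's
only downstream target is GABA-T, whisker stimulation recruits no GABA, and
the NO→20-HETE interaction is outside scope. The LNAME-insensitivity checks
therefore pass with zero difference rather than merely <10%.

Each run begins with a baseline equilibration: all inputs off, integrate
until the largest state derivative falls below 10⁻⁹ ms⁻¹ (warning if the
budget, default 60 s, is exhausted), then pin the balloon at its exact
(1, 1) fixed point and normalize flow by the equilibrated radius so the
pre-stimulus hemoglobin baseline is identically zero.

## Numerical choices

* Integrator: `deSolve::lsoda` (automatic stiff/non-stiff switching),
  `rtol = 1e-8`, `atol = 1e-10`, which keeps residual baseline drift below
  10⁻⁹ and makes repeated runs bitwise identical.
* Output grid 10 ms; simulation window onset 1 s + stimulus 2 s +
  post-window 18 s, matching typical ~20 s experimental epochs.
* Heaviside windows use strict inequalities at both boundaries; the solver
  never evaluates exactly at a discontinuity in a way that matters at these
  tolerances.
* Degenerate inputs fail fast with classed conditions
  (`nvc_invalid_protocol`, `nvc_invalid_parameter`,
  `nvc_integration_failure` with a state dump, `nvc_configuration_error`,
  `nvc_comparison_error`).
* Steady-state oracles in the tests integrate to 2×10⁴ ms (≈44 time
  constants) at tightened tolerance and compare against closed forms to
  <0.1%.

## The synthetic reference generator

Experimental trial-averaged traces are not published as data files, so the
reference module generates *synthetic* stand-ins: per-condition
gamma-kernel templates (onset lag 300 ms, peaks at ~0.7 s and ~2 s) with the
described morphology — whisker hyperemia; optogenetic early HbR-up/HbT-dip
then reversal; blockade constriction-dominated — plus seeded Gaussian noise
averaged over 12 pseudo-trials. HbT is built as HbO + HbR within each trial,
so conservation holds exactly. These references emulate *morphology and
trial-averaging statistics only*: amplitudes are plausible round numbers, not
measurements, and no post-stimulus oscillations are included. Consequently,
passing the comparison-based tests demonstrates that the tooling and the
qualitative dynamics are right; it says nothing quantitative about agreement
with real mouse data.

## Known limitations

* The surrogate's Hb amplitudes (tens of %) exceed typical experimental
  fractional changes (a few %); the acceptance surface here is shape and
  sign structure, not absolute amplitude. Scaling the radius excursion
  `r_amp` down rescales all three channels together.
* Post-stimulus oscillations seen experimentally are not modelled.
* Astrocytic Ca²⁺/IP₃ signalling, detailed channel gating, vesicle
  stochasticity and the full NO synthesis cascade are out of scope; NO is a
  lumped first-order species.
* The model is deterministic; inter-animal and inter-trial variability exist
  only in the synthetic reference generator.
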