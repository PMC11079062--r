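---
title: "Methods: coupled mean-field UDS networks, detection, and connectivity inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled mean-field UDS networks, detection, and connectivity inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`udsnet` implements a rate model of two coupled cortical networks. Each
network carries an excitatory activity $E(t)$, an inhibitory activity
$I(t)$ and a slow adaptation variable $A(t)$:

$$\tau_E \dot E = -E + \Omega_E\!\left(W_{EE}E - W_{EI}I - W_{EA}A + \xi + i_E\right)$$
$$\tau_I \dot I = -I + \Omega_I\!\left(W_{IE}E - W_{II}I + \xi\right)$$
$$\tau_A \dot A = -A + W_{AE}E$$

with the threshold-linear response
$\Omega(x)=\min(1,\max(0, g\,(x-\theta)))$. The default constants are
$\tau_E=10$ ms, $\tau_I=5$ ms, $\tau_A=300$ ms, $g_E=6$, $g_I=30$,
$\theta_E=0.0517$, $\theta_I=0.2778$, $W_{EE}=1$, $W_{II}=0.083$,
$W_{EI}=0.166$, $W_{IE}=1.66$, $W_{EA}=0.166$, $W_{AE}=1.1$, and a
zero-mean Gaussian noise current of SD $\sigma=0.03$. The Down state
$(E,I)=(0,0)$ is always a steady state; an Up state exists at the
positive intersection of the two nullclines, at
$(E,I)\approx(0.2006,0.4751)$ with adaptation slaved to activity
($A = W_{AE}E$). A third, unstable point lies on the separatrix between
the two basins. Slow adaptation shifts the excitatory nullcline up
during Up states and down during Down states, so each state erodes its
own stability; noise triggers the actual transitions, producing the
Up-Down-state (UDS) oscillation.

Two identical networks are coupled unidirectionally: the afferent
network's excitatory activity drives the efferent excitatory population
through $i_E(t) = W_{EXT} E_A(t)$, with no back-projection. The only
parameters that distinguish cells/regions are $W_{EXT}$ and the
efferent recurrent excitation $W_{INT}$ (its $W_{EE}$). Strong drive
phase-locks the efferent to the afferent; higher $W_{INT}$ stabilizes
the efferent Up state so that it can outlast an entire afferent Down
state (*spontaneous persistent activity*, SPA); weaker $W_{EXT}$ lets
the efferent Down state outlast an entire afferent Up state
(*spontaneous persistent inactivity*, SPI).

## The simulation operating point

Three numerical choices required judgment; all are exposed as arguments
and documented here because they shape every simulated number.

**Response ceiling.** `response()` and all fixed-point algebra use the
saturating form above. The integrator, however, runs the
threshold-linear response without the hard ceiling (argument
`response_cap`, default `Inf`). With the ceiling active, the state
$(E,I)=(1,1)$ is itself an attractor: once the excitatory activity
outruns inhibition during an upward transition (its linear-band growth
rate, $(g_EW_{EE}-1)/\tau_E = 0.5/\mathrm{ms}$, far exceeds what the
maximal inhibitory current $W_{EI}+W_{II}=0.25$ can cancel at a ceiling
of 1), the trajectory is absorbed there and the oscillation dies. In
the uncapped form the inhibitory response transiently exceeds 1 during
transitions — the fast loop gain
$g_Eg_IW_{EI}W_{IE}\approx 50$ then terminates every excursion — and
the excitatory activity never rises above $\approx 0.5$, so the ceiling
would not have been touched by $E$ anyway. This is the regime in which
the model's published behavior (bounded activity that "never reaches
saturation") is actually realizable.

**Inhibitory time constant.** `uds_params()` carries the textbook
$\tau_I = 5$ ms. At that value the determinant/trace stability
requirement of the linearized fast subsystem,
$\tau_I\,(g_EW_{EE}+1) < \tau_E\,(g_IW_{II}+1)$, already fails at
$W_{EE}=1$ (35 vs 34.9) and fails badly over the recurrent-excitation
range used for fitting; the Up point is then so weakly damped that it
collapses through fast E–I ringing whatever the recurrent strength, and
the central SPA–$W_{INT}$ relation vanishes. The simulation reference
set `sim_params()` therefore uses $\tau_I = 3.5$ ms — the largest round
value satisfying the stability requirement across the whole grid
($\tau_I < 4.5$ ms at $W_{EE} = 1.12$). Fixed points are unaffected
(time constants cancel at steady state); `regime_diagnostics()` reports
the printed inequalities verbatim at any parameter set and computes the
authoritative Jacobian eigenvalues.

**Noise process.** The noise current is an Ornstein-Uhlenbeck process
with stationary SD $\sigma = 0.03$ and correlation time
`tau_noise = 200` ms, updated once per integration step with the exact
discretization (so its statistics are independent of `dt`), held
constant across RK4 substeps, and fed to the excitatory population
only. Rationale: (i) state transitions are quasi-static barrier
escapes, so the noise must be slow relative to the fast subsystem —
white per-step noise at 0.2 ms averages to almost nothing over
$\tau_E$ and produces dwell times of minutes, not the ~1 s UDS the
model is meant to exhibit; 200 ms gives an isolated-network UDS cycle
rate of 0.3–0.6 Hz with duty cycle ~0.3–0.5. (ii) The inhibitory
response band is only $1/g_I \approx 0.033$ wide; injecting the same
noise directly into the inhibitory population knocks its argument out
of the band at sub-$\sigma$ excursions and destroys the Up state.
`sigma_i_frac` adds an independent inhibitory stream and
`shared_noise` routes the excitatory stream into both populations, for
sensitivity analyses.

The integrator is classical RK4 at `dt = 0.2` ms, started in the Down
state with a 5 s burn-in discarded; an Euler variant is available for
comparison (`method = "euler"`).

## Surrogate recordings

`make_cell_dataset()` emulates paired in vivo recordings: the efferent
excitatory activity is mapped affinely to membrane potential (defaults
anchored at Up $-52.4$ mV / Down $-74.2$ mV, the depolarized and
hyperpolarized levels of medial entorhinal layer-3 neurons under
urethane), with Gaussian observation noise (1 mV), 1 ms triangular
+40 mV action potentials at inhomogeneous Poisson times (rate
proportional to supra-threshold activity — chosen to trip the 10 SD
derivative detector), and a 50 Hz mains sinusoid. The Up anchor is the
realized mean Up-state activity of the trace (for a trace pinned at the
fixed point this is the fixed point), because adaptation drags activity
below the nominal Up point over a dwell. The afferent activity becomes
a z-scored LFP with configurable polarity (+1: Up = positive
deflection; real LFP polarity is depth-dependent and out of scope) and
1/f background. Desynchronized epochs are emulated by replacing both
channels with 1/f noise at 20% of the UDS amplitude, which suppresses
the 0.05–2 Hz band the detector relies on.

What the surrogates do *not* emulate: non-Gaussian V_m noise spectra,
electrode drift, true spike waveform diversity, depth-dependent LFP
inversion, and any physiological difference between regions beyond
$(W_{EXT}, W_{INT})$. Passing the pipeline's tests on surrogates shows
the machinery is faithful to the model, not that the model captures
every property of real recordings.

## Detection pipeline

Preprocessing follows standard practice for these recordings: spikes
are detected where the derivative of the 100 Hz–8 kHz band-passed V_m
exceeds 10 SD above its mean (SD of the derivative; the upper band edge
is capped at $0.45 f_s$ on lower-rate recordings) and 3 ms after each
onset is linearly interpolated; 8-pole zero-phase Butterworth band-stops
remove 50 Hz and harmonics; the UDS band filter (0.05–2 Hz) is a
zero-phase frequency-domain filter with raised-cosine edges, chosen
over an IIR realization because a relative band edge of $10^{-4}$ is
numerically fragile there.

Desynchronized epochs are found from a multitaper spectrogram (15 s
windows, 50% overlap, time-bandwidth 4, seven Slepian tapers computed
from the tridiagonal formulation) via two features per window: maximum
log power in 0.05–2 Hz and integrated log power in 4–40 Hz. The
decision rule is ours (the features alone do not fix one): a window is
desynchronized when the per-Hz mean log-power gap between the bands
falls below 20 dB (synchronized surrogate windows sit at 25–28 dB,
desynchronized 1/f windows at 10–14 dB) or when the robust z-score of
the low-band feature falls below $-6$ (clean recordings show |z| up to
~5 because the within-recording spread of this feature is tiny).

Segmentation uses a two-state explicit-duration HMM with Gaussian
emissions and inverse-Gaussian dwell distributions, decoded at 50 Hz
(the band limit makes higher rates redundant) with duration support
truncated at 30 s and renormalized. The state means vary slowly in time
(centered 50 s windows, edge-clamped). Fitting is segmental EM:
initialization by a two-component Gaussian mixture (a separation below
0.5 pooled SD raises "no UDS detected"), then alternation of
explicit-duration Viterbi decoding with closed-form re-estimation; the
tracked objective is the joint path+data log score and an iteration
that would decrease it is reverted, so the recorded history is monotone
by construction. With two states the transition matrix is forced, and
the first segment carries the full duration pmf while the last is
right-censored (survival). The Viterbi recursion is validated against
exhaustive enumeration of all duration-respecting segmentations on
small instances.

## Persistence statistics

Efferent state initiations are matched greedily to the nearest
same-type afferent initiation (ties toward the earlier one); matches
that would break temporal order — which happens around transient
desynchronizations — are dropped rather than forced onto distant
neighbours, so the trigger sets always partition the afferent sequence
in time order. A state whose trigger set spans $n$ afferent states has
quantized duration $n/2$ (each afferent Up or Down contributes half a
cycle), always a half-integer, and is SPA/SPI when $n \ge 3$; this
makes $\phi_{SPA}$ identically the fraction of quantized Up durations
$\ge 1.5$. The continuous companion rescales time so every afferent
state spans half a cycle, and the comb statistic (mass within $\pm$0.1
of half-integers) quantifies how tightly transitions lock. Recording
edge states are excluded from all rates and delays. History dependence
is summarized by $p_1 = 1 - m_1$ and $p_2 = 1 - m_2/p_1$ from the first
two half-integer mode masses; a memoryless (Bernoulli) chain has
$p_1 = p_2$, while adaptation predicts $p_1 > p_2$.

## Grid fitting

`build_grid_library()` simulates the coupled pair over a rectangular
$(W_{EXT}, W_{INT})$ grid — desk-scale default $12 \times 12$ points
$\times$ 3 seeds $\times$ 200 s, with the afferent trajectory shared
across grid points within a seed — and stores per-point SPA/SPI rates,
skipped-state fractions, delays and quantized-duration pools. The
default bounds, $W_{EXT} \in [0.18, 0.30]$ and
$W_{INT} \in [1.00, 1.12]$, were placed by a coarse regime map so that
all four qualitative regimes fall inside the grid; the locking boundary
sits where the drive swing $W_{EXT}\,\bar E_{up}$ matches the Up-state
escape threshold ($\approx 0.057$ in current units), i.e.
$W_{EXT} \approx 0.27$–$0.30$. A cell is fitted by exhaustive
minimization of
$d = \sqrt{(\phi_{SPA}-\xi_{SPA})^2 + (\phi_{SPI}-\xi_{SPI})^2}$
(ties toward smaller $W_{INT}$, then smaller $W_{EXT}$); an alternate
fit using afferent-side skipped-state proportions is computed
alongside. Delay predictions are read from the matched grid entry, and
group comparisons use two-sided Wilcoxon rank-sum tests and Spearman
correlations.

## Known limitations

* The locking corner retains an SPA floor of roughly 5–15%: with
  identical parameters in both networks the efferent's spontaneous
  transition hazard during an afferent dwell is of the same order as
  the afferent's own, and afferent sub-threshold noise leaks through
  strong coupling. Complete locking (rates below 2%) is not reachable
  at this operating point.
* The exponential sensitivities of the rates to the weights are
  correspondingly milder (e-folding scales of order 0.03–0.1 rather
  than 0.004–0.015): the steeper published scales require an effective
  noise temperature far below what the afferent's own UDS pacing
  demands under these barrier heights.
* Transition locking is loose enough that the continuous
  cycle-rescaled durations spread around the half-integer comb
  (comb fraction ~0.2–0.4 rather than ~0.8); the *quantized* rule is
  exact by construction.
* $W_{EXT}$ recovery is weak wherever SPI is identically zero (upper
  third of the grid): the likelihood is flat along that axis there.
  $W_{INT}$ recovery, driven by SPA, is robust across the grid.
* History dependence of persistence is absent at this operating point:
  with $\tau_A = 300$ ms adaptation saturates within the first spanned
  afferent state, and afferent cycle-length heterogeneity favors
  consecutive persistence, so the measured $p_2$ is at or slightly
  above $p_1$ rather than below it.

## Problem sizes

Defaults were chosen so a full run — unit tests, the acceptance checks,
and `scripts/acceptance.R` — completes on a single core in well under
an hour: grid library $12 \times 12 \times 3 \times 200$ s,
regime-corner checks $5 \times 300$ s, surrogate cohort of 20 cells
$\times$ 240 s analyzed by the full detector. The same functions scale
to the publication-grade setting
($100 \times 100 \times 5 \times 1000$ s) unchanged via their
arguments.
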