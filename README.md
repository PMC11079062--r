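# udsnet

Tools for studying how two cortical networks interact during slow
(Up-Down state, UDS) oscillations, and for inferring their functional
connectivity from paired electrophysiology.

During deep sleep and anesthesia, cortical networks alternate between
an active Up state and a quiescent Down state at ~0.5 Hz. A driven
("efferent") network — e.g. an entorhinal cell population receiving
neocortical input — usually follows the driving ("afferent") network,
but can transiently decouple: an Up state that outlasts an entire
afferent Down state is *spontaneous persistent activity* (SPA), and a
Down state that outlasts an entire afferent Up state is *spontaneous
persistent inactivity* (SPI). `udsnet` packages the full computational
loop around these phenomena:

* **Model** (`uds_params`, `fixed_points`, `regime_diagnostics`):
  a mean-field excitatory/inhibitory/adapting rate model,
  $\tau_E\dot E=-E+\Omega_E(W_{EE}E-W_{EI}I-W_{EA}A+\xi+i_E)$ (and
  its inhibitory and adaptation companions), with closed-form
  nullclines, fixed points and stability diagnostics.
* **Simulation** (`simulate_network`, `simulate_coupled`,
  `binarize_states`): RK4 integration with an Ornstein-Uhlenbeck noise
  current; unidirectional coupling $i_E = W_{EXT}E_A(t)$.
* **Surrogate recordings** (`make_cell_dataset`, `render_vm`,
  `render_lfp`): model activity rendered as realistic paired
  membrane-potential/LFP recordings with ground truth — bimodal mV
  distributions, spikes, 50 Hz mains, optional desynchronized epochs.
* **Detection** (`remove_spikes`, `notch_mains`, `uds_band_filter`,
  `find_desynchronized`, `fit_edhmm`, `viterbi_decode`): preprocessing
  and two-state explicit-duration HMM segmentation of recordings into
  Up/Down intervals.
* **Statistics** (`assign_transitions`, `spa_spi_rates`,
  `quantized_durations`, `transition_delays`,
  `history_probabilities`): greedy transition assignment, SPA/SPI
  rates, durations quantized in half afferent-cycle units, transition
  delays, and the history probabilities $p_1$, $p_2$.
* **Inference** (`build_grid_library`, `fit_cell`,
  `exponential_trend`, `predict_delays`, `group_compare`,
  `run_pipeline`): a simulated $(W_{EXT}, W_{INT})$ grid library and
  per-cell matching by the rate-space distance
  $d=\sqrt{(\phi_{SPA}-\xi_{SPA})^2+(\phi_{SPI}-\xi_{SPI})^2}$.

## Worked example

```r
library(udsnet)

# the model's fixed points at the reference constants
fixed_points(uds_params())
#> Fixed points (self_consistent adaptation)
#>   Down:   E = 0.000000, I = 0.000000
#>   Up:     E = 0.200644, I = 0.475096  (A = 0.220709)
#>   Saddle: E = 0.000000, I = 0.062040 (on separatrix)

# three surrogate cells with known connectivity, a small grid library,
# and the full detect -> assign -> fit loop
config <- list(
  cells = list(c(0.22, 1.02), c(0.26, 1.06), c(0.29, 1.10)),
  duration = 180, seed = 5, detect_desync = FALSE,
  grid = list(w_ext_values = seq(0.20, 0.30, length.out = 4),
              w_int_values = seq(1.00, 1.12, length.out = 4),
              n_seeds = 1, duration = 120))
res <- run_pipeline(config)
res$table[, c("truth_w_ext", "truth_w_int", "phi_spa", "phi_spi",
              "fit_w_ext", "fit_w_int")]
#>   truth_w_ext truth_w_int   phi_spa    phi_spi fit_w_ext fit_w_int
#> 1        0.22        1.02 0.1428571 0.02040816 0.3000000      1.00
#> 2        0.26        1.06 0.4444444 0.00000000 0.2666667      1.12
#> 3        0.29        1.10 0.3428571 0.00000000 0.2666667      1.12
```

Each row is one surrogate cell: its generating weights, the SPA/SPI
proportions measured after spike removal, filtering and EDHMM
segmentation, and the weights recovered by matching those proportions
against the simulated grid. At this demonstration scale (3 minutes per
cell, a 4 x 4 single-seed library) the recovered recurrent excitation
tracks the truth ordering only coarsely — rate estimates carry binomial
noise of a few percentage points — and the afferent weight is only
weakly identified where SPI is zero; the test suite quantifies recovery
on a 20-cell cohort against a 12 x 12 library (see the methods
vignette for what is and is not identifiable).

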