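---
title: "A minimal receptor–readout–storage model of habituation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A minimal receptor-readout-storage model of habituation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habinfo)
```

# The model

`habinfo` simulates and solves a minimal stochastic model of habituation:
the progressive decrease of a system's response to a repeated identical
stimulus. Three internal components interact with an external signal $H$:

* a **receptor** $R$, a two-state unit (passive/active) separated by a
  barrier $\Delta E$. It switches along two pathways with Arrhenius-type
  rates: a *sensing* pathway driven by the current signal value $h$
  (activation rate $\propto e^{\beta(h-\Delta E)}$) and an *internal*
  pathway whose deactivation rate grows with the storage level,
  $\propto e^{\beta\kappa\sigma s/N_S}$. The two pathways form a
  non-equilibrium cycle; without storage the receptor would satisfy
  detailed balance.
* a **readout** population $U$, a birth–death process whose birth rate is
  boosted when the receptor is active. Its mean $\langle U\rangle(t)$ is
  the observable response. Instead of specifying the production energies
  $V$ and $c$ directly, the package fixes the passive and active
  stationary means, $\langle U\rangle_P = e^{-\beta V}$ and
  $\langle U\rangle_A = e^{-\beta(V-c)}$, and inverts them
  (`derive_energies()`).
* a **storage** population $S$ with hard capacity $N_S$, produced
  catalytically by the readout at rate $u\,e^{-\beta\sigma}\Gamma_S^0$ and
  decaying at rate $s\,\Gamma_S^0$. It feeds back on the receptor and is
  the model's finite-time memory.

The signal is exponentially distributed with time-dependent mean
$\langle H\rangle(t)$ that switches between a background $H_{\min}$ and a
stimulus $H_{\max}$ on a square-wave schedule (`signal_protocol()`). The
inhibition strength defaults to $\kappa = H_{\mathrm{ref}}/(\alpha\sigma)$
so that a reference signal $H_{\mathrm{ref}}$ is balanced by the feedback
of a fraction $\alpha$ of the storage capacity; a protocol can instead
adapt $\kappa$ to its own stimulus strength (`adaptive_kappa`).

Free parameters of interest are the inverse temperature $\beta$ (1/energy)
and the storage cost $\sigma$ (energy). Defaults (energy in units of the
signal energy): $\Delta E = 1$, $N_S = 30$,
$\langle U\rangle_P = 30$, $\langle U\rangle_A = 150$, $g = 1$,
$\alpha = 2/3$, $H_{\mathrm{ref}} = 10$, $H_{\min} = 0.1$,
$H_{\max} = 10$, stimulus duration $T_s = 100$ and pause
$\Delta T = 100$ time units.

Note on the readout means: the active mean must exceed the passive one —
an active receptor pumps the readout up, and the response must grow under
stimulation — so the defaults are $\langle U\rangle_P = 30$,
$\langle U\rangle_A = 150$. Both orientations are accepted by the
constructor as long as the active mean is larger.

## Timescales

The solution method rests on the hierarchy
$\tau_U \ll \tau_R \ll \tau_S \approx \tau_H$: the readout equilibrates
instantly given the receptor, the receptor given storage and signal, and
only the storage (and the signal statistics) evolve on the slow scale.
The model fixes only this ordering, so the package must choose concrete
values; they are a modeling decision, not a fitted quantity. The
defaults are $\tau_U = 0.01$, $\tau_R = 1$, $\tau_S = \tau_H = 2000$ time
units with $\Gamma_S^0 = 1/\tau_S$, i.e. **one stimulus period
($T_s + \Delta T = 200$) is one tenth of the storage relaxation time**.
This placement is what produces the habituation phenomenology the model
is built for: the storage integrates over many presentations (gradual
decrement over $O(10)$ stimuli, $n^{(\mathrm{hab})} = 13$ at
$\beta = 3, \sigma = 0.6$), retains memory across pauses (potentiation),
and keeps accumulating after the response has plateaued (subliminal
accumulation of a few percent). If instead $\tau_S \ll T_s$ the storage
relaxes within every window, memory cannot span stimuli, and no
cross-stimulus habituation is possible at all; if $\tau_S \gg$ the whole
train, nothing relaxes during pauses and spontaneous recovery disappears
on any observable horizon.

# The timescale-separation (TSS) solver

Under the hierarchy above the joint law factorizes as
$p(u, r, s, h, t) = p^{\rm st}_{U|R}(u|r)\, p^{\rm st}_{R|S,H}(r|s,h)\,
p_S(s,t)\, p_H(h,t)$, and the slow marginal obeys a discrete
Chapman–Kolmogorov recursion: one step propagates the storage at frozen
readout and then redresses the fast variables under the signal law at the
new time (`step_joint()`).

Numerical choices:

* **Conditional laws.** $p^{\rm st}_{U|R}$ is Poisson with mean
  $e^{-\beta(V - cr)}$, renormalized on the truncated grid
  $[0, U_{\max}]$ with $U_{\max} = \lceil m + 8\sqrt{m}\rceil$ ($m$ the
  largest mean; truncated mass is monitored and must stay below
  $10^{-8}$). The receptor activation probability
  $p_A = k_{\rm on}/(k_{\rm on}+k_{\rm off})$ is evaluated in log space,
  so arbitrarily strong signal draws cannot overflow.
* **Signal integrals.** All expectations over the exponential signal law
  use Gauss–Laguerre quadrature under the substitution $x = \lambda h$,
  which absorbs the exponential weight exactly; the remaining integrands
  (activation probabilities, entropies of two-component Poisson
  mixtures) are smooth and bounded. They do, however, vary on the
  $1/\beta$ scale, far inside the signal mean, so convergence in the
  node count is slow at first: 64 nodes leave a relative error of a few
  $10^{-3}$ in the information observables. The default is 512 nodes,
  at which a node-doubling check (512 → 1024, exercised in the tests and
  against an independent dense trapezoid) moves the values by less than
  $10^{-6}$.
* **Storage propagator.** Over one step the storage generator at frozen
  readout is restricted to the $n$-nearest neighbors of the initial state
  (default $n = 2$), its diagonal set to minus the column sums so the
  restricted chain conserves probability, and the propagator obtained by
  eigendecomposition with coefficients matching the delta initial
  condition. Against the dense matrix exponential of the untruncated
  generator the truncation error is below $10^{-5}$ in total variation at
  the operating step sizes.
* **Step size.** The largest storage jump rate on the grid times the
  step must not exceed 0.2 (so at most a fraction of a jump occurs per
  step and the $n = 2$ truncation is accurate), and at least ten steps
  resolve every stimulus and pause (`max_step()`). A halving test keeps
  the mean readout stable to $10^{-4}$ relative at the reduced-model
  settings used in the tests. The leading error is a half-step lag of
  order $\mathrm{d}t/2 \cdot \partial_t\langle U \rangle$, which cancels
  in the paired comparisons (information gain, recovery-time ratios)
  the package reports.
* **Stationary states.** Within a constant-signal segment the storage
  marginal evolves linearly, $q \mapsto Aq$ with a column-stochastic
  kernel; `stationary_solve()` takes the Perron eigenvector of $A$,
  refines it by power iteration and certifies a one-step total-variation
  residual below $10^{-9}$. Trajectories start from the stationary state
  under $H_{\min}$, so the first stimulus defines the initial response.

# The exact stochastic oracle

`gillespie_simulate()` is an exact continuous-time simulation of the full
four-variable model. The signal is a jump process: redrawn from the
current epoch's exponential law at waiting times of mean $\tau_H$ and at
every protocol switch, making successive draws uncorrelated while
matching the prescribed marginals. Each trajectory owns a
counter-seeded xoshiro256++ stream, so ensembles are bit-reproducible.

Exactness imposes a well-posedness constraint the solver does not have:
the expected sensing rate $E[e^{\beta h}]$ diverges unless
$\beta \langle H\rangle < 1$. At the default study conditions
($\beta = 3$, $H_{\max} = 10$) the full model is therefore not
simulable by SSA — which is precisely why the TSS solution is the
production method. Cross-validation uses a **reduced model**
(`reduced_params()`: $N_S = 5$, readout means 5/20, $\beta = 0.5$,
$H_{\max} = 1.5$) where both engines are valid. Its signal redraw time is
set ten times shorter than the storage relaxation
($\tau_H = 2$, $\tau_S = 20$): the recursion treats the signal as
uncorrelated between steps (this is also what makes the storage
independent of the signal, $I_{S,H} = 0$), so the stochastic process must
decorrelate its signal faster than the storage moves for the two engines
to target the same law. With these settings the solver's mean readout
and storage agree with $10^4$-trajectory ensemble means to within Monte
Carlo error (no detectable bias at $4\times 10^4$ trajectories).

# Habituation metrics and hallmarks

The response to stimulus $k$ is $\langle U\rangle$ sampled at a fixed
phase of the window (default: the end; the metrics move by less than a
percent between phase 0.9 and 1). The system has habituated at the first
stimulus whose relative decrement falls to 0.5% or below — provided an
earlier decrement exceeded the threshold, so a response that never
changes (feedback disabled, $\kappa = 0$) does not count as instantly
habituated. Recovery is probed counterfactually: the background
relaxation is computed once and single probe stimuli are applied from
states along it, with the first passage below a 1% deficit resolved by
bisection; both thresholds are arguments.

`hallmark_suite()` runs the five paired experiments. Conventions chosen
where the phenomenology fixes only the direction:

* *Potentiation*: second train after a pause of $2\Delta T$.
* *Subliminal accumulation*: the extended train continues for as many
  extra stimuli as were needed to habituate
  ($n_{\rm extra} = n^{(\rm hab)}$). At $\beta = 3$, $\sigma = 0.6$ the
  recovery period lengthens by ≈ 6%.
* *Intensity sensitivity*: swept over $H_{\max} \in \{5, 10, 20, 40\}$, a
  factor-two ladder around the reference signal. Well below the
  reference signal the normalized decrement is non-monotone (a
  near-background stimulus produces little storage and little
  habituation), so the sweep covers the regime at and above
  $H_{\mathrm{ref}}$ where the effect is clean.
* *Frequency sensitivity*: swept over $\Delta T \in \{400, 200, 100,
  50\}$ at fixed $T_s$. More frequent stimulation habituates *deeper*
  and *earlier in time*; the stimulus count $n^{(\rm hab)}$ actually
  grows as $\Delta T$ shrinks, because each presentation then moves the
  slow storage less while presentations arrive more often.

# Information and thermodynamics

All information is reported in nats. Under the TSS factorization the
channel from signal to fast variables is
$p_{U,S|H}(u,s|h) = \phi_h(u|s)\, p_S(s)$ with
$\phi_h(u|s) = \sum_r p^{\rm st}_{U|R}(u|r)\, p^{\rm st}_{R|S,H}(r|s,h)$:

* $I_{U,H}$ (`mutual_information_UH()`): entropy of the signal-averaged
  readout law minus the average conditional entropy. Equivalently the
  negative entropy change of the readout under conditioning; the tests
  verify the identity against a direct Kullback–Leibler route to
  $10^{-10}$. Zero cells contribute $0\log 0 \equiv 0$; tiny negative
  round-off is clipped at zero.
* $I_{S,H}$ (`mutual_information_SH()`) is computed by the explicit
  $(u, r)$ marginalization rather than by shortcut, and vanishes to
  round-off: in this limit the storage sees the signal only through the
  *stationary* readout, so it carries no information on the current
  signal value.
* $\Delta I_f = I_{(U,S),H} - I_{U,H} \ge 0$
  (`feedback_information()`): the extra signal information carried by
  the storage jointly with the readout. With $\kappa = 0$ the storage
  drops out of the channel and $\Delta I_f = 0$.
* $J_{\rm int}$ (`internal_flux()`): $\sigma$ times the net storage
  probability current (positive while charging, negative while
  relaxing, zero at stationarity). The *in/hab* differences
  ($\Delta I_{U,H}$, $\Delta\Delta I_f$, $\Delta J_{\rm int}$) compare
  the first and the habituated stimulus at the same window phase.
* $\delta Q_R$ (`receptor_dissipation()`): the average log cycle
  affinity of the two-pathway receptor cycle,
  $\beta(H + \kappa\sigma \langle S\rangle/N_S)$ — the barrier cancels
  around the cycle.

# Pareto optimization

Under a constant signal the stationary objectives are the information
$I^{\rm st}_{U,H}$ and the total energy consumption
$E_{\rm tot} = \delta Q_R + E_{\rm int}$. Because the net storage flux
vanishes identically at any one-dimensional birth–death stationary
state, the storage term uses the one-way production flux,
$E_{\rm int} = \tau_S \sum \Gamma_{s\to s+1}(u)\, p(u,s)$ (a `net` mode
is available). Two deliberate choices:

* **Trade-off weights.** $E_{\rm tot}$ (30–200) is two orders of
  magnitude larger than $I^{\rm st}$ (≈ 0.5), so uniformly spaced
  weights $\gamma$ put nearly every maximizer of
  $\gamma I - (1-\gamma)E$ at one of the two extreme points. The default
  grid is uniform in $\log(\gamma/(1-\gamma))$ (`gamma_grid_logit()`).
* **The front proper.** A linear scalarization can only reach the convex
  hull of the objective scatter. `pareto_front()` therefore also
  reports the non-dominated set, found by an energy-sorted sweep and
  cross-checked in the tests against a brute-force pairwise dominance
  filter; `front_sigma_profile()` reads it as the optimal storage cost
  at fixed $\beta$ (the system cannot choose its temperature). At the
  reference signal the front passes through $(\beta, \sigma) \approx
  (3, 0.6{-}0.7)$ — the same region where the information gain
  $\Delta I_{U,H}$ under switching stimulation peaks.
* **Collapse statistic.** With the inhibition adapted to the stimulus,
  $\kappa = H_{\max}/(\alpha\sigma)$, the fronts for different stimulus
  strengths nearly coincide. The primary statistic compares them where
  they live, in the $(\beta, \sigma)$ plane (mean absolute difference of
  the per-$\beta$ optimal $\sigma$); an $(E, I)$-interpolated distance
  is reported as a secondary output but is dominated by curve endpoints
  on finite grids (a front reaching the $\sigma$ grid boundary plunges
  at the edge of the energy overlap).

# Neural mapping

For comparison with population recordings of repeated looming
stimulation, readout units are mapped to binary neurons: each unit is a
subpopulation of $N = 20$ neurons, each firing with probability
$p = 0.5$ whenever the unit is activated (once per activation run —
i.e. per presentation; $p$ only disperses the embedding). Units are
simulated at $(\beta, \sigma) = (4.5, 0.15)$, near the onset of
habituation, under a looming-like protocol (one presentation every 150
time units, 50-unit windows) with a receptor-equilibrated jump
simulator: the receptor is kept at its conditional stationary activation
probability while $(u, s, h)$ evolve exactly. This is the appropriate
stochastic engine here because the full SSA is ill-posed at
$\beta \langle H\rangle > 1$ (see above).

Two modeling choices matter and are exposed as arguments:

* **Excitability dispersion** (`DeltaE_spread`, default ±4 energy
  units of per-unit receptor-barrier jitter). Identical units habituate
  only as a population rate, participation is re-randomized at every
  presentation, and no principal component can encode a habituation
  axis. Dispersion makes dropout persistent and ordered — the least
  excitable units stop responding first — which is also the
  biologically expected picture.
* **Activation indicator**: window-averaged readout above one third of
  the way from the passive to the active mean, with the signal redrawn
  $T_s/32$ apart during a presentation so the window average is a graded
  function of the unit's storage.

With these settings the per-stimulus activation fraction declines
steadily (≈ 0.6 → 0.35 over 30 presentations) and the second principal
component of the neuron-by-time activity separates early from late
stimuli. At this population size (120–240 units) the *monotone rank
ordering* of PC2 stimulus means is not statistically stable — the
habituation variance is comparable to the next noise eigenvalue and the
component can mix — so the tests assert the robust early/late
separation for model-generated activity, and the strict rank-correlation
criterion ($|\rho| \ge 0.8$) on the deterministic synthetic fixture.

`generate_fixture()` builds that synthetic stand-in for a processed
recording: stimulus-locked transients (square pulse convolved with an
exponential kernel) whose amplitude decays across stimuli with a
per-neuron e-folding scale spread around 5 stimuli, plus optional noise.
It emulates only the stimulus-locked habituating structure of real
normalized-fluorescence matrices — no spontaneous activity, correlated
noise, motion artifacts or cell-type structure — so passing PCA tests on
it demonstrates the analysis pipeline, not biological fidelity.

# Problem sizes

The shipped tests and the acceptance script run, on one CPU in a few
minutes: full-grid solver runs (249 × 31 state space) over 25–40-stimulus
protocols; a 5 × 5 $(\beta,\sigma)$ information scan; Pareto grids of
9 × 15 points with three stimulus strengths, twice; a $10^4$-trajectory
reduced-model ensemble at 20 sample times; and 240 stochastic units
expanded to 4800 neurons. Denser grids (the defaults of
`pareto_front()` are 33 × 59) reproduce the same structure when more
time is available.

# Known limitations

* The solver is specific to this model's structure; it is not a general
  master-equation engine, and there is no continuous-state
  (Fokker–Planck) approximation.
* The TSS law discards signal–storage correlations by construction
  ($I_{S,H} = 0$); at $\tau_H \approx \tau_S$ the exact process carries
  a small correlation the solver cannot represent.
* Exact stochastic simulation requires $\beta\langle H\rangle < 1$.
* Hallmark sweeps assert monotonicity on the documented grids; far
  outside them (e.g. near-background stimuli) some trends invert, as
  discussed above.
* The neural stage models activation statistics only; evoked-response
  waveforms are beyond a switching input, and the zebrafish recording
  itself is not required or shipped — only its schema is supported.
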