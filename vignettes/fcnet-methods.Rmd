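---
title: "Functional connectivity methods in fcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional connectivity methods in fcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcnet)
```

`fcnet` estimates statistical dependence between multichannel
neurophysiological time series and characterizes the resulting weighted
functional networks.  This vignette documents the models behind each
estimator, the parameters that matter, the numerical choices made where
the definitions leave room, and what the synthetic test beds do and do
not establish.

## Zero-phase filtering

Phase-synchronization analysis requires narrow-band signals: an
instantaneous phase is only interpretable for an oscillation confined
to one band.  `filtfilt_fft()` applies an FIR filter twice, forwards
and backwards, so phase responses cancel and the effective transfer
function is $|H(f)|^2$ — filtering never shifts an oscillation in time
and therefore cannot create spurious phase coupling.

Numerical choices:

- **Padding.**  Each channel is mirror-reflected by the kernel length
  at both ends before filtering and cropped afterwards, which bounds
  border transients.  Reflection padding (not circular) is used: it
  avoids the jump discontinuity that circular wrap-around introduces
  when the two ends of a record differ.
- **Frequency-domain convolution.**  Each pass multiplies spectra at an
  FFT length equal to the next power of two at or above padded length
  plus kernel length, so the circular convolution equals plain causal
  convolution exactly; the result matches a direct two-pass time-domain
  convolution to round-off (the test suite verifies $10^{-6}$ relative
  agreement over randomized lengths 32–256 and kernels 3–31, and
  $10^{-9}$ on a fixed case).
- **Kernels.**  `design_windowed_sinc()` (windowed-sinc design via
  `signal::fir1`) produces symmetric, linear-phase kernels with unit
  mid-band gain.  User-supplied kernels may be asymmetric; the two-pass
  scheme still yields zero net phase, with the magnitude squared.
- Arithmetic is double precision throughout.

## Phase synchronization

The analytic signal is built per channel in the frequency domain
(negative-frequency coefficients zeroed, positive doubled); its angle
is the instantaneous phase in $(-\pi, \pi]$.  A four-quadrant angle is
used: a two-quadrant arctangent would alias antiphase to in-phase.
Only 1:1 phase locking is considered.

Because the Hilbert transform is non-local, phases near the record
edges are distorted; `instantaneous_phase(discard = d)` marks $d$
samples at each end to be excluded from all phase averages.  The
effective sample count for significance testing is then $N - 2d$.

- **PLV** $= |\langle e^{i\varphi_{kl}}\rangle|$ — the mean resultant
  length of the circular relative-phase distribution; 1 only for
  perfect locking.
- **PLI** $= |\langle \mathrm{sign}\,\varphi_{kl}\rangle|$ — discards
  zero-lag coupling; an exactly zero relative phase contributes 0 (a
  measure-zero event for real data, deterministic for duplicated
  channels).
- **ImC** and **wPLI** come from Welch cross-spectra.  "About five"
  50%-overlapping segments are realized as exactly
  $s = \lfloor 2N/(n_{\mathrm{seg}}+1)\rfloor$ samples per segment with
  hop $\lfloor s/2\rfloor$, Hann-tapered (the taper is otherwise
  unconstrained by the definitions).  The wPLI average
  $|\langle\mathrm{Im}X\rangle| / \langle|\mathrm{Im}X|\rangle$ is
  taken **over segments** at each frequency bin; averaging over bins
  instead would make a single-segment wPLI identically 1 and was
  rejected.  Band values are arithmetic means over the bins inside the
  band, and 0/0 bins are defined as 0.
- **Significance.**  Wilkie's approximation of the Rayleigh test,
  $p = \exp\{\sqrt{1+4N+4(N^2-NK)}-(1+2N)\}$, $K = N\,\mathrm{PLV}^2$,
  assumes approximately independent consecutive phases — optimistic for
  strongly autocorrelated narrow-band data, which is why the
  `discard`-corrected $N$ must be supplied explicitly.  The grouping of
  the formula is validated by its endpoints ($p = 1$ exactly at
  PLV $= 0$; strictly decreasing in PLV and in $N$).  FDR correction is
  Benjamini–Hochberg over the $n_{ch}(n_{ch}-1)/2$ pairwise tests.

## Mutual information

`kraskov_mi()` implements the Kraskov algorithm-1 estimator: for each
joint point, $\varepsilon_i$ is the max-norm distance to its $k$-th
neighbour, $n_x$ and $n_y$ count marginal points strictly within
$\varepsilon_i$, and
$\widehat{MI} = \psi(k) - \langle\psi(n_x+1)+\psi(n_y+1)\rangle + \psi(N)$
(nats).  Defaults: $k = 4$ (the customary bias/variance compromise for
$N$ in the hundreds to thousands), jitter $10^{-10}$ of the sample
standard deviation with a stored seed (neighbour counts are ill-defined
on repeated values, common in quantized EEG), minimum $N = 20$.

Two design choices deserve emphasis:

- **Copula transform.**  After jittering, each marginal is mapped to
  $(\mathrm{rank}-0.5)/N$ before the neighbour search.  Mutual
  information is invariant under strictly monotone marginal
  transformations, but the raw k-NN estimator is only approximately so
  (the max norm mixes the two scales); on the copula scale the
  invariance is exact, and the same shared jitter draw makes
  `kraskov_mi(x, y)` equal `kraskov_mi(y, x)` bit-for-bit.  Gaussian
  closed-form recovery ($-\tfrac12\ln(1-\rho^2)$) is unaffected within
  the tested $\pm 0.05$ nats at $N = 4000$.
- **Negative estimates.**  Small negative values are expected under
  independence and are reported as-is in `mi_matrix(...)$mi`; they are
  floored at 0 only before the symmetric-uncertainty or
  total-correlation normalization so normalized outputs stay in
  $[0, 1]$.  The diagonal is `NA`: self-MI of continuous data diverges.

`kl_entropy()` is the Kozachenko–Leonenko estimator
$\psi(N)-\psi(k)+\langle\log 2r_i\rangle$ on the raw (jittered) data —
no copula transform, since differential entropy is not
scale-invariant.

## Generalized synchronization

If $y$ is a function of $x$'s state, then states nearby in $x$'s
reconstructed space have images nearby in $y$'s.  After delay embedding
(`embed_delay()`, with required $m$ and $\tau$ — automatic selection by
false-nearest-neighbours or auto-MI is out of scope), for each state
$X_i$ the package compares the mean distance to its own $k$ nearest
neighbours ($R^{(k)}_i(X)$), to all admissible states ($R_i(X)$), and
to the $k$ states selected by the *other* channel's neighbour times
($R^{(k)}_i(X|Y)$), plus the analogous mean rank $G^{(k)}_i(X|Y)$:

$$S = \Big\langle \tfrac{R^{(k)}_i(X)}{R^{(k)}_i(X|Y)} \Big\rangle,\quad
  H = \Big\langle \log\tfrac{R_i(X)}{R^{(k)}_i(X|Y)} \Big\rangle,\quad
  M = \Big\langle \tfrac{R_i(X)-R^{(k)}_i(X|Y)}{R_i(X)-R^{(k)}_i(X)} \Big\rangle,\quad
  L = \Big\langle \tfrac{G_i(X)-G^{(k)}_i(X|Y)}{G_i(X)-G^{(k)}_i(X)} \Big\rangle.$$

Choices and conventions:

- **Orientation.**  `gs_matrix()[i, j]` is $\mathrm{Index}(X_i|X_j)$:
  channel $i$'s space conditioned on channel $j$'s neighbour times.
  For unidirectional coupling driver $\to$ response, the *driver
  conditioned on the response* is the larger entry — the response
  embeds the driver's dynamics, so its neighbourhoods locate the
  driver's.  The coupled Hénon benchmark in the test suite pins this
  direction down empirically (20/20 seeds at moderate coupling).
- **Theiler window.**  States within `theiler` samples of the reference
  time are excluded from all neighbour sets; temporally adjacent states
  are trivially close and would otherwise fake synchronization.  The
  default is $m\tau$; `theiler = 0` reproduces the plain formulas and
  is what the identical-signal and independence endpoint checks use.
- **Ranks.**  Own-neighbour mean rank is $(k+1)/2$ by construction;
  $G_i(X)$ is taken as half the per-state count of admissible states
  (the mean rank of a uniformly random admissible partner, up to $1/2$),
  so $L = 1$ exactly for identical signals and centres near 0 under
  independence.  Distance ties are broken stably by time index.
- **Degenerate input** (constant series: zero denominators) raises an
  error rather than returning NaN.
- All four indices are computed jointly from one set of neighbour
  statistics; channel pairs are processed one at a time so memory stays
  at one distance row, not an all-channel cache.

The fast path is verified against an explicit distance-matrix
evaluation to $10^{-10}$ over randomized instances ($N_v \le 60$, 50
cases, all four indices), and `stride > 1` subsampling equals the
computation on the explicitly subsampled state list.

## Network metrics

On a nonnegative weight matrix (zero diagonal; typically a
connectivity matrix): strength (row sums), weighted clustering
$C_i = 2 t_i / (k_i(k_i-1))$ with geometric-mean triangles
$t_i = \tfrac12\sum_{j,h}(w_{ij}w_{ih}w_{jh})^{1/3}$ (requires weights
$\le 1$; `rescale_weights()` is provided but never applied silently),
Dijkstra shortest paths with link length $f(w) = 1/w$, characteristic
path length, and Brandes betweenness.

- **Disconnected graphs.**  $L_i$ averages the *finite* distances and
  the number of unreachable ordered pairs is reported explicitly, so
  the global $L$ stays finite and the information loss is visible.
- **Betweenness.**  Dependencies are accumulated over ordered
  source–target pairs and normalized by $(N-1)(N-2)$, which maps a
  star's centre to exactly 1.  Equal-length path ties are recognized
  with an absolute tolerance of $10^{-12}$ so floating-point round-off
  cannot split a genuinely tied shortest-path count.
- Oracles: Floyd–Warshall for distances, exhaustive simple-path
  enumeration for betweenness ($n \le 8$), plus igraph cross-checks on
  larger random graphs.

## Synthetic test beds

- `gen_coupled_oscillators()` produces narrow-band tones whose phase
  performs a random walk (step 0.1 rad/sample) partially shared across
  channels in proportion to `coupling`, plus a constant lag and additive
  noise (s.d. 0.1 by default).  The walk keeps PLV away from 1 at
  intermediate coupling and gives the Rayleigh test a non-degenerate
  null.  Note the walk is strongly autocorrelated: at $N = 2000$ there
  are only $\sim 20$ effectively independent phase samples, so the
  uncoupled chance-level PLV is $\sim 0.3$, not the
  $1/\sqrt{N}$-scale value naive intuition suggests.
- `gen_unidir_henon()` iterates two identically parameterized Hénon
  maps ($a = 1.4$, $b = 0.3$) with the driver entering the response's
  quadratic term with weight `coupling`.  Near $C \approx 0.7$ the pair
  transitions to full synchronization, where the directional asymmetry
  necessarily vanishes; directionality tests therefore run at
  $C = 0.6$, below the transition.
- `gen_random_weighted_graph()` draws Erdős–Rényi topologies with
  uniform $(0, 1]$ weights.

All generators derive per-channel RNG streams from one integer seed, so
outputs are byte-identical across runs and channels are unaffected by
how many others are generated.  These fixtures emulate controllable
coupling, not real electrophysiology: no $1/f$ background, no volume
conduction or common reference, no nonstationarity, no artifacts.
Passing tests establish estimator correctness and sensitivity under
known ground truth — not robustness to the confounds of real
recordings, for which ImC/wPLI (reference/volume-conduction) and the
Theiler window (autocorrelation) are the built-in mitigations.

## Problem sizes and runtime

The test suite and endpoint scripts use deliberately modest sizes —
signals of $10^3$–$4\times10^3$ samples, up to 20 seeds per stochastic
claim, brute-force oracles at $N_v \le 60$ states or $n \le 8$ nodes —
chosen so the full suite runs in about two minutes on one CPU while
still pinning every fast path to an independent reference.  The
estimators themselves scale to realistic recordings (the O($N^2$) MI
and GS cores are compiled; graph metrics are $O(n^3)$ in plain R and
comfortable at the $\sim 10^2$ nodes typical of sensor-level networks).

## Known limitations

- Wilkie significance is only available for PLV, and its independence
  assumption makes it anti-conservative for heavily oversampled
  narrow-band data; surrogate-based testing is out of scope.
- No automatic selection of the embedding parameters $m$, $\tau$.
- MI is reported for pairs only (no conditional or multivariate
  variants); the k-NN estimator's small negative excursions under
  independence are inherent.
- Graph metrics assume nonnegative weights and (for clustering and
  betweenness) undirected networks; directed clustering/betweenness
  variants are not implemented.
- Text-matrix I/O only; neurophysiology container formats (EDF/FIF)
  are out of scope.
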