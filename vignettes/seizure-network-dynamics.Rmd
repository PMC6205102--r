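---
title: "Phase-synchronization network dynamics around seizures: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-synchronization network dynamics around seizures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasenet)
```

## The analysis in one paragraph

phasenet turns a multichannel peri-seizure recording (ECoG or similar) into a
sequence of weighted functional networks and summarizes how those networks
reorganize. For every pair of channels it computes the **mean phase
coherence** of the Hilbert-transform instantaneous phases in 1-s sliding
windows (50% overlap), giving one symmetric M×M connectivity matrix per
window. Each window's network is reduced to its vector of weighted node
degrees; the average degree is the network's **mean phase synchronization**.
Degree vectors are clustered with agglomerative **Ward** linkage into a small
set of recurring **network states**, and the **state-change rate** (label
changes per second) is tracked across the preseizure, seizure, and
postseizure periods. Across seizures, period differences are tested with the
**Friedman test** and **Dunn's post hoc** pairwise comparisons.

## Signal model and preprocessing

A recording is a channels × samples matrix with a sampling rate `fs`, channel
labels, and seizure onset/termination annotations in seconds. The analysis
span is `preseizure_full + seizure + postseizure_full`, where the pre- and
postseizure periods have the same duration `D` as the seizure. For stage-wise
statistics the seizure is split evenly into `S1..S4` and flanked by
quarter-length `preS` and `postS`. All period boundaries are snapped to the
sample grid; when `D` in samples is not divisible by four, stage boundaries
are placed by rounding cumulative quarter points, so stage lengths differ by
at most one sample and the stages exactly tile the seizure.

Preprocessing is deliberately minimal: caller-supplied bad channels are
removed (a variance z-score helper, `flag_bad_channels()`, can suggest
candidates, but it is a screen, not a substitute for review), and the
conventional bands are extracted with linear-phase Hamming-window FIR
bandpass filters — theta 4–8, alpha 8–13, beta 13–30, gamma 30–45 Hz —
while *broadband* means the unfiltered signal. Zero phase lag matters here
more than anywhere: a filter delay would appear downstream as spurious phase
differences. The default applies the filter once and shifts the output by the
integer group delay `L/2` (the filter order is even by construction);
forward–backward filtering (`method = "filtfilt"`) is available as an
alternative. The transition bandwidth defaults to
`min(max(0.25·low, 2 Hz), low)`, a compromise that keeps the theta filter
selective (2 Hz transition, order ≈ 3.3·fs/2) without making it impractically
long. Roughly one filter order at each end of a filtered segment is edge-
contaminated; for narrow low bands this exceeds the default 0.25-s phase
edge margin, so treat the first/last second of theta-band output with
suspicion or enlarge `edge_margin_s`.

## Phase and connectivity

The instantaneous phase is the four-quadrant angle of the analytic signal
(FFT half-spectrum construction), computed once over the **whole contiguous
segment** and then windowed — computing it per window would re-introduce the
edge artifacts windowing is meant to avoid. The discrete analytic signal is
circular, so a configurable margin (default 0.25 s) at each end is flagged
invalid, and any window touching it is dropped.

For phases $\phi_1, \phi_2$ over a window of $N$ samples,

$$\lambda = \left| \frac{1}{N} \sum_{t=1}^{N} e^{\,j(\phi_1(t) - \phi_2(t))} \right|,$$

the modulus of the circular mean of the phase differences: 1 for a constant
phase difference of any size, 0 for differences spread evenly around the
circle. Two identities anchor the implementation exactly: $\lambda = 1$ when
both arguments are equal, and $\lambda = 0$ when the difference advances by
$2\pi k/N$ per sample (the $N$-th roots of unity sum to zero). For
independent uniform phases the expected value is $\sqrt{\pi/4}/\sqrt{N}$
(about 0.04 at $N = 500$), which the property tests check by simulation.
$\lambda$ depends only on phases, so it is invariant to any per-channel
amplitude scaling; matrices are made exactly symmetric, carry a unit
diagonal by convention (ignored by all degree computations), and are clamped
to $[0,1]$ against floating-point overshoot.

Windows are aligned to the start of the analysis span; the number of
complete windows is $\lfloor (T - N)/\mathrm{step} \rfloor + 1$ and a final
partial window is never padded. At 500 Hz with 1-s windows, $N = 500$ and the
step is 250 samples.

## Degrees, states, and state-change rate

The degree of node $i$ in a window is $\sum_{j \ne i} \lambda_{ij}$, in
$[0, M-1]$; the mean over nodes is the mean phase synchronization (also
reported normalized by $M-1$ for cross-grid comparability — the rank-based
statistics use the raw values, which are monotone-equivalent). Period
summaries are arithmetic means over the windows whose centers fall in the
period; empty periods are reported missing, never zero.

Network states come from agglomerative hierarchical clustering of the
per-window degree vectors under Ward's criterion: repeatedly merge the two
clusters whose union minimally increases the total within-cluster sum of
squared Euclidean errors. The merge cost is computed exactly from cluster
centroids, $\Delta\mathrm{SSE} = \frac{n_a n_b}{n_a+n_b}\lVert c_a - c_b
\rVert^2$; ties are broken toward the pair with the lexicographically
smallest (older, younger) creation order, making the linkage deterministic
for any input order. A brute-force implementation that re-evaluates the SSE
increase of every candidate merge by explicit summation reproduces the
linkage exactly in the tests; `stats::hclust(method = "ward.D2")` agrees up
to its `sqrt(2 * SSE-increase)` height convention. Clustering is fit per
seizure per band on the windows of the full analysis span (broadband by
default).

**Choosing K.** With $d(k)$ the merge distance paid to go from $k+1$ to $k$
clusters, K is the argmax over $k \in [k_{\min}, k_{\max}]$ (defaults 2 and
$\min(20, W-2)$) of the discrete second derivative
$s(k) = d(k-1) - 2d(k) + d(k+1)$, ties broken toward smaller K. The curve is
evaluated on the conventional dendrogram scale $\sqrt{2\,\Delta\mathrm{SSE}}$
rather than on raw SSE increases. This was a genuinely open design point, and
the raw scale turns out to be unusable: because $\Delta\mathrm{SSE}$ grows
with cluster sizes, the last one or two merges dominate the curvature and
the knee collapses to $k = 2$ even for data built from five equally tight,
equally separated clusters — a configuration where the square-root scale
recovers $k = 5$ cleanly (and still recovers $k = 2$ for two-cluster data).
The square-root scale is also what the widely used Ward implementations
display as "distance". `scale = "sse"` remains available for comparison.
A limitation either way: knee detection on a merge-cost curve is fragile
when the data's hierarchy is strongly two-level; bounding $k_{\max}$ keeps
the search away from the degenerate top of the tree.

States are labelled 1..K by first window of occurrence. The state-change
rate of a period counts label changes between consecutive windows whose
centers both lie in the period — pairs straddling a period boundary are
attributed to neither side — divided by the period's annotated duration in
seconds (not by the window count; the two differ when edge windows were
dropped). Periods with fewer than two windows have an undefined rate,
reported missing.

## Group statistics

Per-seizure period summaries form an n-seizures × k-periods table. The
Friedman test ranks within rows (mid-ranks for ties) and refers the
tie-corrected statistic
$Q = (k-1)\sum_j (R_j - n(k+1)/2)^2 / (A - C)$, with $A$ the sum of squared
ranks and $C = nk(k+1)^2/4$, to $\chi^2(k-1)$. It is implemented from first
principles so a full within-row permutation enumeration can validate both
the statistic and an exact p-value on small tables (`exact = TRUE`,
feasible up to $(k!)^n \approx 5\times10^6$); on tied tables it matches
`stats::friedman.test`. Dunn's post hoc compares mean ranks,
$z = (\bar R_i - \bar R_j)/\sqrt{k(k+1)/(6n)}$, two-sided, with Bonferroni
multiplication by the number of compared pairs (all $k(k-1)/2$ by default;
Šidák available). The exact adjustment behind published "Dunn's multiple
comparison" results varies between toolboxes; on borderline pairs the choice
can flip significance, which is why both variants are exposed. Calibration
under the null (i.i.d. rows, n = 22, k = 6) is verified by simulation: the
empirical type-I error at α = 0.05 over 2000 tables falls in [0.03, 0.07].

## The synthetic generator

Real peri-seizure ECoG cannot ship with a package, so validation rests on a
coupled phase-oscillator simulator with planted structure. Channel phases
follow Kuramoto-type dynamics
$d\theta_i = 2\pi f_i\,dt + \sum_j K_{ij}\sin(\theta_j - \theta_i)\,dt +
\sigma\,dW_i$, integrated by Euler–Maruyama at the sampling rate (2-ms steps
at 500 Hz, adequate for ≤ 45 Hz oscillators), observed as
$x_i = \sin\theta_i$ plus white noise. Mean phase coherence responds
monotonically to coupling in this model, giving analytic anchors: uncoupled
identical oscillators give $\lambda = 1$ exactly; oscillators detuned by an
integer number of Hz give $\lambda \approx 0$ over 1-s windows; coupling
above the locking threshold drives $\lambda$ toward 1.

The canonical fixture (`make_seizure_fixture()`) emulates the qualitative
peri-seizure pattern reported for clinical grids: 48 channels (a 6 × 8
grid, the mid-range of clinical grid sizes) at 500 Hz, a 60-s seizure with
equal pre/post periods. Natural frequencies are spread over 8–16 Hz so
unlocked channels decohere within one window. Five states are planted as
coupling topologies (total locked pull 36 rad/s split over the subset's
pairs, above the widest subset's frequency half-spread of ~19 rad/s;
background total 1.4 rad/s, far below threshold): the two grid halves
alternate locking every 10 s before onset; S1–S3 carry background coupling
only (the early-seizure synchronization dip); in S4 the front three quarters
of the grid lock (the late-seizure rise), persisting into the postseizure
period where the back-three-quarters topology alternates in. The
hypersynchronized states deliberately recruit *three quarters* of the grid,
not all of it: with a full-grid lock the five state centroids split into one
low- and one high-synchronization super-group whose separation dwarfs
everything else, and no curvature rule can then see five states — a
geometry, not an algorithm, problem. Phase noise is 0.3 rad/√s and
observation noise 0.1 (signal amplitude 1). State switches are offset 0.25 s
from the window-center grid, because a boundary exactly at a window center
produces a half-and-half window with no meaningful planted label; windows
that straddle any boundary are flagged `ambiguous` in the ground truth and
excluded from recovery scoring.

What the fixture does **not** emulate: 1/f spectra, amplitude dynamics and
artifacts, volume conduction (which inflates zero-lag synchrony in real
grids), spatial electrode geometry, and biological variability between
seizures. Passing the recovery tests therefore demonstrates that the
pipeline's inference machinery is correct on data with known structure — not
that five states or any particular synchronization pattern will be found in
a given patient.

## Numerical and interface choices

* Phases wrapped to $(-\pi, \pi]$; all containers refuse non-finite values
  early, and constant channels are rejected by name before phase estimation.
* The connectivity stack is bit-reproducible for fixed inputs; the simulator
  is bit-reproducible for a fixed seed and restores the caller's RNG state.
* Ward heights are theoretically non-decreasing; the implementation asserts
  monotonicity up to float jitter and clamps to the running maximum.
* `run_pipeline()` validates the whole configuration (unknown keys rejected,
  band edges against Nyquist) before touching data; failures name the stage.
  With two or more input seizures it also runs the group statistics on the
  stage-wise summaries and on the state-change rates of the three
  equal-length periods.
* Problem sizes used in the shipped validation: the canonical 48-channel,
  180-s fixture for end-to-end recovery (20 seeds); brute-force linkage
  oracles at W ≤ 12; exact Friedman enumeration at n ≤ 6, k = 3; null
  calibration over 2000 tables of 22 × 6.

## Worked example

```{r example, eval = FALSE}
sim <- make_seizure_fixture(seed = 1)
rec <- sim$recording
seg <- segment_periods(rec)

phase <- analytic_phase(rec)
conn <- sliding_connectivity(phase)        # 1-s windows, 50% overlap
deg <- degree_vectors(conn)
mps <- mean_phase_synchronization(deg)
summarize_periods(mps, seg)

link <- ward_linkage(deg)
K <- select_k(link)                        # 5 on the canonical fixture
states <- assign_states(link, K)
state_change_rate(states, seg)
```
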