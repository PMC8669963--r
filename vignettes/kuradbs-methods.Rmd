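---
title: "Methods: a plasticity-endowed Kuramoto model of DBS insertion and withdrawal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a plasticity-endowed Kuramoto model of DBS insertion and withdrawal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`kuradbs` simulates a fully connected network of $N$ Kuramoto phase
oscillators as a stand-in for a population of neural ensembles whose
collective synchronization is the quantity of clinical interest. Each
oscillator $i$ carries an unwrapped phase $\varphi_i$ evolving as

$$
\frac{d\varphi_i}{dt} \;=\; \omega_i \;+\; \frac{1}{N}\sum_{j \ne i}
K_{ij}\,\sin(\varphi_j - \varphi_i) \;+\; I_i(t),
$$

integrated with explicit Euler at $dt = 1$ iteration. The natural
frequencies $\omega_i$ are i.i.d. $U(0,1)$ (radians per iteration). The
drive $I_i(t)$ is a rectangular pulse train — the deep-brain-stimulation
(DBS) input — with default rate 130 Hz and amplitude 3.0, gated ON or OFF
per schedule block.

Synaptic plasticity enters through the static coupling matrix. For each
unordered pair $(i,j)$ two variates $r_1, r_2 \sim U(0,1)$, $r_1 \ne r_2$,
are drawn once, and

$$
K_{ij} \;=\; \alpha_p\, e^{\,r_1 \tau_p} \;-\; \alpha_d\, e^{\,r_2 \tau_d},
$$

where $\alpha_p$ and $\alpha_d$ are potentiation (LTP-like) and
depotentiation (LTD-like) rates and $\tau_p = \tau_d = 0.5$ are damping
parameters. The matrix is symmetric with zero diagonal and **never changes
during a run**: a "virtual patient" is a fixed plasticity signature, not an
adaptive learner. Activity-dependent plasticity is explicitly out of scope.

Synchronization of a schedule block is quantified by the phase-locking
value of each pair over the block's $T$ recorded iterations,

$$
\mathrm{PLV}_{ij} = \Bigl|\tfrac{1}{T}\textstyle\sum_{t=1}^{T}
e^{-\mathrm{i}\,(\varphi_i(t)-\varphi_j(t))}\Bigr| \in [0,1],
$$

and the *grand-average PLV* is the mean over all $\binom{N}{2}$ unordered
pairs. Two block schedules are built in: the chronic
*withdrawal/renewal* protocol (DBS ON, OFF, ON2, OFF2, ON3; 2,000
iterations each; the first ON block is the 100% baseline for percentage
change) and the *de novo* protocol (OFF then ON, equal lengths of 500,
1,000 or 2,000 iterations; the naive OFF block is the baseline).

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `n` | oscillator count | 100 | the studied network size |
| `alpha_p`, `alpha_d` | potentiation / depotentiation rates (dimensionless) | per condition | the seven-condition bank spans 0.001–8.0 |
| `tau_p`, `tau_d` | damping parameters in the coupling exponents | 0.5 | the studied value |
| `frequency_hz` | DBS pulse rate | 130 | standard clinical high-frequency DBS |
| `amplitude` | phase-velocity increment during a pulse | 3.0 | the studied drive strength |
| `iteration_duration_ms` | simulated ms per iteration | 1.0 | a convention, not a given: it makes 130 Hz ≈ one pulse per 7.7 iterations |
| `pulse_width_iterations` | pulse duration | 1 | unstated in the source model; configurable |
| `n_replicates` | independent "patients" per condition | 10 (20 in the pattern suite) | the mean ± SD summaries require replication; the original count is unstated |
| `burn_in` | fraction of a block excluded from PLV | 0 | no transient exclusion is mentioned for the original analysis |

The seven built-in plasticity conditions (`condition_bank()`):
(1) $\alpha_p{=}8,\ \alpha_d{=}0.001$; (2) $0.001, 8$; (3) $8, 8$;
(4) $4, 4$; (5) $0.7, 0.7$; (6) $0.1, 0.1$; (7) $0.001, 0.001$.

## Design choices where the source was open

**Coupling sign.** The printed phase equation carries
$\sin(\varphi_i - \varphi_j)$, under which positive (potentiation-dominated)
coupling is *repulsive*. That contradicts the reported behaviour (high
potentiation giving stable, high phase locking), so the default is the
standard attractive convention $\sin(\varphi_j - \varphi_i)$; the literal
printed sign is available via `sign_convention = "repulsive"`.

**Sum index and $K$ placement.** The printed sum runs over the free index
and shows $K_{ij}/N$ outside the summation; the only reading that makes
per-pair plasticity draws meaningful is a per-pair $K_{ij}$ inside a sum
over $j \ne i$, normalized by $1/N$. That is what is implemented.

**Exponential form.** $e^{r\tau}$ is implemented literally as printed, not
as a damped $e^{-r/\tau}$. With $\tau = 0.5$ and $r \in (0,1)$ both
readings are bounded and order-preserving in $\alpha$, so the qualitative
condition ranking is unaffected.

**PLV averaging index.** The printed PLV formula sums over an oscillator
index inside a pairwise quantity, which is not computable as written; PLV
as established in the literature is a time (or trial) average, and one PLV
is evaluated per condition block, so the implementation averages over the
block's recorded iterations.

**Time base and integrator.** No $dt$, integrator or pulse width is stated.
One iteration = 1 ms, $dt = 1$, explicit Euler, pulse width 1 iteration;
all configurable. Note that with couplings up to $|K| \approx 13$ and
$dt = 1$ the update is a large-step discrete map, not a converged ODE
solution — this is deliberate: "iterations" are the stated time unit of the
original experiments, and halving $dt$ would change the attractor. The
integrator aborts with a diagnostic if any $|\varphi| > 10^9$ rad.

**State carry-over and seeding.** Within a replicate, frequencies, coupling
and initial phases (drawn $U(0, 2\pi)$; the source is silent) are drawn
once and phases persist across blocks — one patient is one continuous
system; the pulse clock runs on the global iteration counter, so chaining
blocks is bit-identical to one long block. Replicate $k$ uses the
deterministic child seed $(\text{master}\cdot 10007 + k\cdot 1000003)
\bmod (2^{31}{-}1)$, so adding replicates never perturbs existing ones. De
novo runs at different durations are independent draws.

**Replicates behind mean ± SD.** The original summaries do not state the
number of runs; the default is $R = 10$, with $R = 20$ in the acceptance
pattern suite, and the SD is across replicates (across-pair spread is
available via `plv_matrix()`).

## What the generator emulates — and a structural caveat

The synthetic world is exactly the stated one: no empirical recordings are
consumed, and every run is reproducible from a seed. A green pattern test
therefore establishes internal consistency of this model, not clinical
validity: real basal-ganglia signals have band-limited rhythms,
noise, delays, and activity-dependent plasticity, none of which are
modelled.

One property deserves emphasis. The DBS drive is applied **identically to
every oscillator** (the source gives no target subset). An identical
additive drive is a common mode: it shifts all phases equally, cancels in
every pairwise difference $\varphi_i - \varphi_j$, and therefore — exactly,
not approximately — cannot move any PLV. In this stated world, ON/OFF
block contrasts within a condition are replicate noise, while contrasts
*between* plasticity conditions are large and stable. The committed
calibration run (`scripts/calibration.R`, master seed 1, 20 replicates,
default parameters) prints: condition-1 block means ≈ 0.176 with a maximum
relative deviation of 0.7% from the ON baseline; condition-2 block means ≈
0.090; condition 1 above condition 2 in every block in 20/20 matched
pairs; condition-2 OFF-above-preceding-ON in 11/20 replicates (a noise
tally, as expected ≈ 50%); de novo condition-1 ON/OFF ratio 0.992. The
pattern-suite thresholds were frozen from this run *before* the acceptance
tests were executed: a 10% relative stability band for condition 1 and a
5% replicate-noise band for the de novo ON-vs-baseline comparison; the
matched-pair dominance check (≥ 18/20) and the OFF-increase majority check
are taken as stated. A systematic ON/OFF effect would require breaking the
drive symmetry (a target subset, per-oscillator amplitudes) — supported via
`stimulus_spec(targets = ...)` but intentionally not the default.

## Numerical choices

- PLV is computed for all pairs at once as $|\bar Z^\top Z|/T$ with
  $Z = e^{\mathrm{i}\varphi}$ (complex BLAS), which matches the scalar
  definition to ~1e-15 and keeps the full study (7 conditions × 5 blocks ×
  20 replicates at $N = 100$) around two minutes on one CPU.
- The Euler coupling term uses
  $\sin(\varphi_j-\varphi_i) = \sin\varphi_j\cos\varphi_i -
  \cos\varphi_j\sin\varphi_i$, i.e. two matrix–vector products per step.
- Percentage change sets the baseline entry to exactly 100 (not
  `100*x/x`), and errors on a non-positive baseline rather than emitting
  `NaN`.
- With $K \equiv 0$ and the drive off, the recorded trajectory equals
  $\varphi_i(0) + \omega_i t$ exactly (Euler is exact for a constant
  derivative; the test uses dyadic-rational parameters so even floating
  point accumulation is exact).
- CSV summaries are written with fixed 6-significant-digit formatting so
  identical results give byte-identical files; the JSON config echo keeps
  full precision.
- `r1 == r2` collisions (probability zero in continuous draws) trigger a
  redraw of `r2`, guarding degenerate test fixtures.

## Known limitations

- Static plasticity only: the coupling matrix cannot respond to the
  oscillatory state, which the source itself lists as its main limitation.
- The common-mode drive caveat above: default DBS ON/OFF contrasts are
  noise by construction.
- No biophysics: no conduction delays, no basal-ganglia anatomy, no
  band-specific filtering, no fitting to patient recordings.
- The 1 ms/iteration mapping is a convention; results are reported in
  iterations, and wall-clock claims about real stimulation durations should
  not be read off the time axis.
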