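---
title: "The radial-shell spheroid model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The radial-shell spheroid model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `rsspheroid`, the meaning
and defaults of its parameters, the numerical decisions behind the solvers,
what the synthetic-data generator does and does not emulate, and the known
limitations — in particular of the cellular-automaton parameter transfer.

## Model

A tumor spheroid is assumed rotationally symmetric. Its state is the vector
of cell concentrations $c_T(r_i, t) \in [0,1]$ on radial shells
$[i\,dr, (i{+}1)\,dr]$, normalized so that $\sum_T c_T = 1$ is maximal dense
packing. Three types are tracked: proliferation-competent cells $p$,
radiation-damaged cells $d$ (present only after irradiation; they still
metabolize and attempt division), and membrane-defect cells $n$ (secondary
necrotic material; no oxygen consumption, no proliferation).

**Quasi-steady oxygen.** Oxygen diffusion equilibrates within minutes while
cell dynamics unfold over hours, so the partial oxygen pressure
$\rho(r_i)$ is the steady solution of
$D_\rho \frac{1}{r^2}\partial_r (r^2 \partial_r \rho)
 = a\,(c_p + c_d)\,\mathbb{1}[\rho > \rho_{an}]$,
with a fixed pressure $\rho_0$ at the surface shell (the outermost shell
with total concentration above 0.1) and zero flux at the center. Cells
below the anoxic threshold $\rho_{an}$ stop consuming; the resulting anoxic
core is a free boundary. Sparse material outside the surface shell is
treated as fully oxygenated. Oxygen stands in for the full set of
metabolic gradients; no other nutrient is resolved.

**Rates.** Four processes act on the concentrations:

* *Proliferation.* A shell with $\rho > \rho_h$ produces new volume at rate
  $\gamma c_p V_i$, placed into the neighborhood $\{i-1, i, i+1\}$
  proportional to the local free volume $F_j = (1 - \sum_T c_T) V_j$ and
  normalized by the neighborhood volume $\sum_j V_j$. Total production is
  therefore damped by the neighborhood free-volume fraction — logistic
  saturation — and the shell width $dr$ is the effective range over which
  daughters are placed, not a mere discretization parameter.
* *Anoxic death.* Where $\rho \le \rho_{an}$, types $p$ and $d$ convert to
  $n$ at rate $\epsilon$ (volume conserving). Death of damaged cells under
  anoxia is assumed symmetric to $p$ (configurable via `eps_on_damaged`).
* *Necrotic decay.* Type-$n$ volume is removed at rate $\delta$ everywhere.
* *Inward transport.* Between shells $(i-1, i)$ a volume flux
  $\lambda\,(\sum_T c_T(r_i))\,F_{i-1}$ moves inward, split across types by
  the composition of shell $i$. The flux vanishes when the inner shell is
  full, so a packed core is stationary and the spheroid stays compact.

**Radiotherapy.** An irradiation event of dose $d$ instantaneously converts
the fraction $1 - S$ of $c_p$ to $c_d$ per shell, with the canonical
linear-quadratic survival $S = \exp(-(\alpha d_{eff} + \beta d_{eff}^2))$
evaluated at the oxygen-reduced effective dose
$d_{eff} = d\,(m\rho + K) / (m(\rho + K))$ (Alper–Howard–Flanders; the
enhancement ratio spans $m$ under anoxia down to 1 at full oxygenation).
Damaged cells divide at rate $\gamma(1 - P_{mc})$ and break up at rate
$\gamma P_{mc}$; $P_{mc}$ steps from $P_{mc,1} < 0.5$ to $P_{mc,2} > 0.5$
at a configurable delay $\tau_{mc}$ (default 120 h) after irradiation. With
multiple fractions the clock restarts at the most recent event — the
single-dose setting the model was built for makes no distinction. Breakup
is gated by the same oxygen condition as division (`mc_loss_gated`, with
the ungated variant available), survivors of a dose remain type $p$, and
damaged cells are not re-damaged with different sensitivity at later
fractions.

## Parameters

| name | unit | meaning | typical / default |
|---|---|---|---|
| `gamma` | 1/h | maximal proliferation rate | ln 2 / doubling time (20–40 h) |
| `a` | mmHg/s | oxygen consumption per packed cell volume | 10–28 |
| `epsilon` | 1/h | anoxic death rate | fitted over 1e-4–10 |
| `delta` | 1/h | necrotic volume reduction rate | fitted over 1e-4–10 |
| `lambda` | 1/h | inward transport rate | fitted via velocity `lambda*dr` in 1–100 µm/h |
| `kappa` | – | shell width in cell diameters, `dr = kappa * dr_star` | 1–10 |
| `dr_star` | µm | single-cell diameter | 16 (fixed) |
| `rho_h` | mmHg | hypoxic proliferation threshold | defaults to `rho_an` |
| `D_rho` | m²/s | oxygen diffusion constant | 2e-9 (fixed) |
| `rho0` | mmHg | surface oxygen pressure | 100 (fixed) |
| `rho_an` | mmHg | anoxic threshold | 0 (fixed) |
| `alpha`, `beta` | 1/Gy, 1/Gy² | LQ radiosensitivities | cell-line specific |
| `Pmc1`, `Pmc2` | – | mitotic-catastrophe probabilities | fitted, `< 0.5 <` |
| `tau_mc` | h | Pmc switch delay | 120 |
| `oer_m`, `oer_K` | –, mmHg | oxygen enhancement constants | 3, 3.28 |

Units are µm, hours and mmHg internally; `D_rho` and `a` are converted once
at construction (2e-9 m²/s = 7.2e6 µm²/h). The model dynamics are
independent of `dr_star` itself because consumption is defined per cell
volume, not per cell. `rho_h` defaults to `rho_an` because only the
ordering $\rho_h \gtrsim \rho_{an}$ is established; any separation can be
configured. File interfaces use days for time; conversion happens only at
the I/O boundary.

## Numerical choices

**Oxygen discretization.** Conservative finite volumes on the shell faces
give a tridiagonal system per solve; discrete consumption equals the
diffusive influx through the surface face to round-off, and the scheme is
exact for the quadratic profile of a uniformly consuming oxygenated sphere.

**Anoxic free boundary.** The consuming set starts with every shell and
shells are disabled where the solve leaves them at or below $\rho_{an}$ —
but only one per iteration, innermost first. Disabling the entire
sub-threshold region at once would overshoot the core by several shells,
because the over-consuming iterate lies everywhere below the free-boundary
solution. The one-at-a-time rule keeps the consuming set monotonically
shrinking (so at most one iteration per shell) and converges to the
smallest self-consistent core. The scalar anoxic radius is reported at the
*center* of the outermost anoxic shell: the zero-flux discrete boundary
lands on the first shell face above the true free boundary, so the face
position would carry a $+U(0, dr)$ bias while the center estimate stays
within $\pm dr/2$ of the closed-form free boundary (verified against the
analytic outer↔necrotic relation across 250–600 µm).

**Gate regularization.** The indicator gates ($\epsilon$-death where
$\rho \le \rho_{an}$, proliferation where $\rho > \rho_h$) make the
right-hand side discontinuous exactly on the moving free boundary, which
produces Filippov sliding: the adaptive integrator collapses to ~1e-3 h
steps and long runs take minutes. The default dynamics therefore replace
the indicators by exponential shoulders of width `gate_width` = 0.5 mmHg
(death weight $e^{-(\rho-\rho_{an})/\sigma}$, proliferation weight
$1 - e^{-(\rho-\rho_h)/\sigma}$). Near the core the profile is flat
(zero-flux), so 0.5 mmHg corresponds to a radial blur well under one shell;
measured trajectories change by < 0.5% while runtimes drop a
thousandfold. `gate_width = 0` restores the exact indicator forms and is
used in the unit tests of the rate formulas.

**Integrator.** Explicit embedded Dormand–Prince 5(4) with relative
tolerance 1e-6 and absolute 1e-9. Steps that would take any concentration
outside $[0, 1]$ (or a shell total above 1) by more than 1e-9 are rejected
and halved; accepted states are clipped at 0. Sample times, irradiation
events and the $P_{mc}$ switch are hard breakpoints; irradiation is applied
between integration segments on the freshly solved oxygen profile. The
grid auto-extends by 8 empty shells whenever the outermost shell exceeds
total concentration 1e-6, so the spheroid never reaches the boundary.

**Initial condition.** Experiments start from an already-formed spheroid,
so the state at $t = 0$ is built by seeding a sigmoid profile
$c_p = c_{max}/(1 + e^{(r - R_{seed})/w})$ (with $w = dr/2$,
$R_{seed} = 0.2^{1/3} R_{target}$), rescaling it to exactly 20% of the
target volume — on coarse grids the raw sigmoid can otherwise overshoot —
and integrating free growth until the volume-equivalent radius first
reaches $R_{target}$ (bisection of the final step to a relative stopping
tolerance of 1e-4). The seed is small enough to have no anoxic core, and
initialization is memoryless: states built for different targets produce
growth curves that overlay after a time shift.

## Calibration

The objective is the concatenated residual of outer and (when available or
inferable) necrotic radii at the data times, weighted 1:1 by default;
necrotic target radii can be inferred once from the outer radii through the
closed-form oxygen relation when histology is unavailable. Every
evaluation rebuilds the initial state for the curve's first radius and
simulates to its last time; simulation failures return a large finite
penalty. Goodness of fit is reported as $R^2$ on volumes (data-mean
convention), with the model interpolated linearly to the data times.

Optimization is bounded least squares by `stats::nlminb` (PORT) with a
seeded Latin-hypercube multi-start (default 8 starts). Free parameters are
mapped to the unit box — after a log10 transform for `epsilon` and `delta`,
which range over orders of magnitude — because PORT receives no scaling
information otherwise and stalls. Each start is additionally polished by
restarting from its endpoint while that still improves the objective.
Results are bit-reproducible for identical specification and seed.

Above $R \approx 3\,dr$ only the rim proliferates and the growth-curve
slope is set by the product $\gamma\,dr$; $\gamma$ and $\kappa$ are then
not individually identifiable, only their product. Curves that include
radii below $dr$ add the exponential phase, whose rate is $\gamma$ alone,
and make both identifiable. The test suite asserts both facets on fixed
synthetic benchmarks.

The radiation workflow is two-staged: $P_{mc,1}, P_{mc,2}$ (optionally
$\tau_{mc}$) are fitted to the outer-radius dynamics of the highest-dose
arm with all untreated-growth parameters frozen; optionally $\alpha, \beta$
are then fitted on one intermediate-dose arm. Arms not used by either
stage are pure predictions, and the result carries an audit of which doses
were touched.

## Synthetic data

`generate_fixture()` emulates the design of typical spheroid monitoring
experiments: daily sampling over about three weeks, radii from tens to
hundreds of µm, and multiplicative lognormal measurement noise of a few
percent (3% by default in the recovery tests, 2% for radiation arms) on
both outer and necrotic radii. Ground-truth parameters travel with the
curve. It does **not** emulate biological replicate variability, seeding
or spheroid-formation effects, plate-reader diameter conventions,
histology segmentation error, or model misspecification — a green recovery
test therefore establishes that the calibration machinery can invert the
model's own output under realistic sampling and noise, not that the model
is a correct description of any particular cell line.

## Cellular automaton and parameter transfer

The lattice model realizes the same mechanisms stochastically: one cell
per voxel (spacing `dr_star`), division attempts with probability
$\gamma\,dt$ gated by oxygen (solved with the same 1D solver on the
radialized occupancy, exploiting the same rotational symmetry), mitotic
catastrophe by $P_{mc}$ at the attempt, anoxic conversion with
$\epsilon\,dt$, removal with $\delta\,dt$, and a rate-independent greedy
inwards shuffle to a fixed point in place of the transport rate $\lambda$
(which therefore requires $dt \cdot \max(\gamma, \epsilon, \delta) \le
0.1$). The interaction neighborhood is one or more Moore/von-Neumann
components with alternation weights; a component is drawn per division
attempt. Runs with equal seeds are bit-reproducible; the RNG is a seeded
`mt19937_64` with package-internal uniform draws so results do not depend
on the C++ standard library's distribution implementations.

Two daughter-placement rules are provided. The default (`uniform_free`)
places the daughter uniformly on the free sites of the drawn component, so
division succeeds whenever any site is free; the alternative
(`draw_and_fail`) draws one site and fails if occupied, damping division by
the neighborhood's free fraction like the shell model's logistic factor.

**Known limitation.** The linear transfer relation
$\kappa \approx 1.19\,d_{neigh} - 0.29$ is used as given. Measured against
this package's shell dynamics it does not reproduce matched front speeds:
across Moore orders 1, 2 and the 3/4 mixture the asymptotic CA/RS speed
ratio is stable at ≈ 2.2 for `uniform_free` and ≈ 0.5 for `draw_and_fail`.
The relation evidently calibrates the pair of laws used in its derivation
(not reproduced in available sources), which differ from this package's
normative damped-logistic production law by an overall rate normalization.
Quantitative RS↔CA trajectory agreement at the 5% level should therefore
not be expected from this transfer, and the corresponding end-to-end check
in the test suite documents this honestly as a failing expectation. The
geometric side of the transfer (mean neighbor distances, the κ inversion
and its round-trip) is exact.

## Other resolved choices

* Damaged cells consume oxygen (they still attempt division); only
  membrane-defect cells do not.
* Configuration files are JSON (read back through the validating
  constructors, with a content hash for provenance); no YAML reader is
  assumed on the target systems.
* The command-line interface is a thin wrapper (`rs_cli()`) over the
  package functions; all outputs stay inside the chosen output directory
  and every run writes a `run_info.json` with version and configuration
  hash.

## Limitations

Beyond the transfer caveat above: no cell-cycle structure, no
oxygen-consuming proliferation-incompetent (senescent) compartment, no
additional metabolite or waste gradients, no mechanical pressure fields,
no sublethal damage repair or dose-rate effects, and no spheroid-control
statistics (relapse/control classification across ensembles) — the model
deliberately stays minimal so that every parameter remains biologically
interpretable and estimable from growth curves.
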