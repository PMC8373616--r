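---
title: "Markov blankets of neural systems: models, verification, scales"
author: "MarkovBlankets package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov blankets of neural systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MarkovBlankets)
```

# The statistical boundary of a neural unit

A Markov blanket separates a set of *internal* states $\mu$ from *external*
states $\eta$: conditioned on the blanket states $b$, the two are
independent,

$$\mu \perp \eta \mid b \iff p(\mu, \eta \mid b) = p(\mu \mid b)\, p(\eta \mid b).$$

On a directed dependency graph the blanket of a target set is the union of
its parents, its children, and the other parents of its children
(`pearlBlanket()`); on a directed acyclic graph this is exactly the minimal
conditioning set that d-separates the targets from everything else, which is
what the package's test suite verifies by brute-force subset search.

The blanket itself splits by *direction of influence*: sensory states $s$
are influenced by external but not internal states and mediate
outside-to-inside influence; active states $a$ are influenced by internal
but not external states and mediate inside-to-outside influence. In a
dynamical setting this becomes a sparsity constraint on the flow,

$$\dot\mu = f_\mu(\mu, s, a), \quad
  \dot a = f_a(\mu, s, a), \quad
  \dot s = f_s(\eta, s, a), \quad
  \dot\eta = f_\eta(\eta, s, a),$$

i.e. four influences are forbidden: $\mu \to s$, $\mu \to \eta$,
$\eta \to a$, $\eta \to \mu$. `validatePartition()` reports exactly the
edges violating these exclusions; it is monotone in the edge set, so losing
a dependency can never break a blanket while gaining one generally does —
the package's negative controls (`perturbAddEdge()`) exercise precisely
this asymmetry.

`classifyBlanket()` derives the sensory/active split from the graph: a
blanket node with an internal parent can only be active, one with an
external parent only sensory, one with parents in both cannot satisfy the
constraints at all (reported as a violation), and one with parents in
neither is *ambiguous*. Ambiguity is reported rather than silently
resolved, because either assignment is consistent; a `ambiguousTo` argument
folds such nodes into one side for pipelines that need a full partition
(`nestedBlankets()` defaults them to sensory). Reversing the internal and
external labels swaps sensory and active — the package tests this
reversibility on every fixture.

## Conditional independence for flows: the one-step reading

Flow graphs of dynamical systems are cyclic, so d-separation is applied to
the one-step unrolled graph (`unrollOneStep()`): each state gets a node
$x_t$ and $x_{t+\mathrm{d}t}$, with $x_{t+\mathrm{d}t}$'s parents being the
declared influences at $t$ plus $x_t$ itself. Self-dependence is implicit
throughout the package — every flow depends on its own state, visible as
the diagonal of any Jacobian — so self-loops are never stored as edges and
are reinstated only by the unrolling. The one-step (dynamic Bayesian
network) semantics is deliberate: flow sparsity does not in general imply
independence in the *stationary* density, which is why the stationary
partial correlation (`stationaryPartialCorrelation()`) is reported as a
diagnostic and never as a pass/fail criterion.

# The model zoo

All conductance-based models use mV, ms, mS/cm², µA/cm², µF/cm²;
neural-mass connection weights are unitless gains.

**Gated-leak Hodgkin–Huxley** (`hodgkinHuxley()`). The membrane potential
$a$ integrates an injected current $s$ against potassium, sodium and leak
currents gated by $\mu_K^4$, $\mu_{Na}^3$ and $\mu_l$, each gate relaxing
with voltage-dependent rates $\alpha_i(a), \beta_i(a)$. This variant uses a
single cubed sodium gate (no separate inactivation state) and a gated leak
current; the textbook 1952 formulation ($m^3h$ sodium, ungated leak) ships
alongside as `classicHodgkinHuxley()` for comparison. The gated-leak form
does not by itself fix the rate functions, so the K and
Na gates default to the classic voltage-dependent rates while the leak gate
uses voltage-independent equal rates ($\alpha_l = \beta_l = 0.1$/ms, so it
relaxes to $1/2$); all are overridable. One consequence is worth knowing:
because the leak-gate rates are flat in voltage, the declared dependency
$a \to \mu_l$ has zero derivative everywhere and finite-difference probing
cannot see it — the structural check therefore asserts the *subgraph*
relation, which is the direction that matters (probing must never invent an
edge).

**FitzHugh–Nagumo** (`fitzhughNagumo()`), dimensionless, with
$\dot a = a - a^3/3 - \mu + s$ and $\tau \dot\mu = a + \alpha - \beta\mu$
(defaults $\tau = 12.5, \alpha = 0.7, \beta = 0.8$). The recovery variable
is the internal state and its flow never sees the injected current.

**Morris–Lecar** (`morrisLecar()`). Constants follow the standard
barnacle-muscle set (Hopf regime: $C = 20$, $g_{Ca} = 4.4$, $g_K = 8$,
$g_L = 2$, $v_1 = -1.2$, $v_2 = 18$, $v_3 = 2$, $v_4 = 30$,
$\varphi = 0.04$). The single potassium gate has a tanh
steady state equal to $1/2$ at its midpoint voltage and a
cosh-shaped voltage-dependent time constant.

**Neural-mass units** (`neuralMassNetwork()`, `neuralMassPair()`). The
schematic being modelled fixes only the dependency structure — a unit's
potential depends on its own conductance alone, while its conductance
collects presynaptic potentials through connection gains and a sigmoid
firing-rate function — not closed-form dynamics. The package therefore uses
the simplest flows with that sparsity: first order in both variables with
linear decay ($\tau_v = 4$ ms, $\tau_g = 8$ ms defaults) and a logistic
rate function (slope 0.56/mV, threshold 0 mV defaults, the conventional
values for population models). The *dependency contract is the tested
surface*; the decay constants only ensure a stable operating point.

**Canonical microcircuit chains** (`cmcChain()`). Four populations per
column — spiny stellate (SS), superficial pyramidal (SP), inhibitory
interneurons (II), deep pyramidal (DP) — each a voltage/conductance unit.
Intrinsic wiring defaults to the canonical convention (SS→SP, SS→II,
SP→DP, SP→II, II⊣SS/SP/DP, DP→II) and is configurable; any intrinsic
matrix preserves blanket validity because intrinsic edges never cross
columns. Extrinsic wiring is the load-bearing structure: ascending
connections originate at SP and terminate on the next column's SS and II
(a `forwardToDeep` switch adds DP targets, an alternative laminar
convention); descending connections originate at DP and terminate on the
previous column's SP and II. Because SS and II never project outside their
column, taking them as internal (column 1) and external (column 2) makes
SP$_1$ classify active and DP$_2$ sensory — the pyramidal populations *are*
the blanket.

**Newtonian spring–mass chain** (`springChain()`). The same asymmetry in a
mechanical dress: a particle's momentum (internal) collects neighbouring
positions (sensory) and its own (active), while its position is moved only
by its own momentum. The role-collapsed dependency graph instantiates the
same blanket template as the neural-mass pair, which a test checks
explicitly. The free chain conserves momentum exactly and energy to
integrator tolerance, giving sharp closed-form checks on the integrator.

**Random blanket systems** (`randomBlanketSystem()`). Linear stochastic
systems whose drift is dense inside the allowed blocks and exactly zero in
the four forbidden blocks, shifted along the diagonal until every
eigenvalue has real part $\le -0.1$. The diagonal shift is the reason the
construction is sound: the diagonal is the implicit self-dependence, so
stabilization can never create a forbidden edge. These are the calibration
substrate for the statistical tests precisely because their regression null
is well understood. `perturbAddEdge()` re-applies the same shift if a
gained weight destabilizes the drift, for the same reason.

# Simulation

`integrateModel()` uses classical fixed-step RK4 for deterministic models
and Euler–Maruyama with additive diagonal Gaussian noise otherwise. The
choice of the simplest stochastic scheme is deliberate: the one-step map
$x_{t+\mathrm{d}t} = x_t + f(x_t)\mathrm{d}t + \sigma\sqrt{\mathrm{d}t}\,\varepsilon_t$
is itself the regression model the statistical verifier fits, so the
verifier's null model is the simulated process with no discretization gap.
Noise is drawn one state-ordered vector per step after seeding once at the
start, making trajectories bit-identical for identical (seed, dt, init) —
the reproducibility tests compare written CSV files byte for byte. The
integrator refuses non-finite states (naming the first bad time and state)
and warns when the step size puts a stable linearized system outside the
explicit stability region ($|1 + \mathrm{d}t\,\lambda| > 1$).

Default steps: 0.01 ms for conductance models, 0.001 time units for
FitzHugh–Nagumo. For the *linear calibration fixtures* the package's
analyses use $\mathrm{d}t = 0.1$: with the stability margin 0.1, a
2000-step run then spans roughly twenty relaxation times of the slowest
mode. Much smaller steps make the regression design nearly integrated
(per-step autocorrelation $\approx 1$), which visibly distorts
finite-sample test calibration long before it affects the dynamics
themselves.

`stationaryCovariance()` solves the continuous Lyapunov equation
$J\Sigma + \Sigma J^\top + Q = 0$ by the direct Kronecker-product method —
exact, and entirely adequate at the dimensions this package works at
(tens of states). It is the analytic oracle against which long simulations
are compared, and the source of `stationaryInitialState()` draws.

# Statistical verification

`dynamicCITest()` operationalizes the dynamic independence reading. Each of
the four forbidden influences has its own direction, named by the predicted
block: the *internal* direction asks whether $\eta_t$ adds predictive power
for $\Delta\mu_t$ beyond $(\mu, s, a)_t$ (detects gained $\eta \to \mu$);
the *active* direction does the same for $\Delta a_t$ (detects
$\eta \to a$); the *external* and *sensory* directions mirror them with
candidate $\mu_t$ (detecting $\mu \to \eta$ and $\mu \to s$). A gained
external-to-active influence is invisible to internal-increment prediction
— only the active direction can see it — which is why `blanketReport()`
runs every applicable direction (Bonferroni-corrected) and uses the active
direction for its negative control.

The comparison of nested regressions uses the ordinary F statistic for a
single predicted component. For several components it uses the
multivariate nested comparison, Wilks' $\Lambda$ in Rao's F form, rather
than combining per-component p-values: the components share one random
design, so independence-based combinations (Fisher's method) are
measurably anticonservative here.

**What "exact" means and what it does not.** Conditional on the design
matrix, the single-component F null is exact for a linear system driven by
Gaussian noise under the Euler–Maruyama map, because each row's error is
the innovation of that step. Unconditionally there is a small
finite-sample distortion: later design rows depend on earlier innovations
(the classic dynamic-regression effect). Two measures keep it negligible at
the package's calibration length ($T = 2000$ transitions, 11 states):
the step-size choice above, and starting calibration runs from the
stationary law (`stationaryInitialState()`) rather than from rest — the
from-rest transient systematically shrinks early design rows and was the
dominant residual distortion. With both, the measured size at
$\alpha = 0.05$ over seeded replicates sits within the exact binomial 99%
band and replicate p-values pass Kolmogorov–Smirnov uniformity at 1%; a
slight residual distortion of order $10^{-2}$ in size can still surface in
very large replicate sets, and is the reason the package reports
calibration empirically instead of claiming exactness outright.

Degenerate inputs are handled explicitly: an empty candidate block yields
an `"accept"` with $p = 1$; constant or collinear columns raise an error
naming the offending labels; trajectories shorter than ten samples per
state are refused.

# Scales: coarse-graining and blankets of blankets

`coarseGrain()` maps micro nodes to macro units and draws a macro edge
whenever *any* micro edge crosses between two groups — existential, not
weighted, because blanket structure needs only the presence of dependence.
Within-group edges vanish; roles and signs are inherited only when all
members agree. The operation is functorial over composition
(`composeGroupings()`), tested on random graphs.

`nestedBlankets()` climbs a ladder of groupings: at each scale it takes a
user-chosen internal set, computes its blanket on the macro graph,
classifies, and validates. The internal choice is user-specified at every
scale on purpose — the role assignment is equally valid reversed, so any
automatic "most internal" heuristic would be arbitrary. On a four-column
chain grouped by column, choosing column 1 internal yields the middle two
columns as the blanket insulating the ends; `networkBlanketGraph()` ships
the same structure one scale up, as a static schematic of six resting-state
networks (visual networks internal, attention networks active, default-mode
sensory, sensorimotor external) — synthetic by construction, since
network-level dynamics are out of scope.

`macroCICheck()` is the soundness bridge: a macro partition that validates
structurally must also satisfy the one-step d-separation on the *micro*
graph — the autonomous (internal and active) micro states at $t+\mathrm{d}t$
d-separated from external micro states at $t$ given the internal and
blanket states at $t$. The autonomous formulation matters: a gained micro
edge from an external group into an active group leaves the internal-only
statement intact but breaks the autonomous one. The suite verifies the
bridge exhaustively on chains of up to six columns. Whether macro-level
sparsity could be *derived* from micro dynamics rather than checked is left
open deliberately; the package only checks.

# Problem sizes and numerical choices

The shipped analyses use: exhaustive 5-node DAG enumeration (1024
order-respecting DAGs; relabelling equivariance covers the rest) plus 200
random 10-node DAGs for the blanket-vs-search equivalence; 200 + 300
replicates at $T = 2000$ for calibration; 100 replicates at $T = 5000$ for
power, with monotonicity probed on a weight grid $\{0.05, 0.2, 0.5\}$ and
length grid $\{500, 2000, 5000\}$ at 50 replicates each; a $10^6$-step run
at $\mathrm{d}t = 0.02$ for the Lyapunov-vs-simulation comparison (chosen
so discretization bias and Monte-Carlo error are both a few percent); a
$10^6$-step scalar Ornstein–Uhlenbeck run at $\mathrm{d}t = 0.01$ compared
to $\sigma^2/2\theta$ within three batch-means standard errors; and
$10^5$ RK4 steps at $\mathrm{d}t = 10^{-3}$ for the spring-chain energy
drift bound of $10^{-6}$ relative. Finite differences use central stencils
with steps scaled by coordinate magnitude ($10^{-6}$ for structural
probing, $10^{-5}$ for linearization); the structural edge threshold is
$10^{-6}$ in derivative magnitude.

# What the synthetic fixtures do and do not show

Every statistical claim is calibrated on linear Gaussian systems because
there the null is analytically understood; nonlinear models enter the
statistical machinery only in small-noise regimes around stable operating
points, where `blanketReport()` first relaxes the model deterministically
and flags an unstable spectral abscissa. Passing tests therefore
demonstrate that the *method* behaves as claimed under its stated regime —
they do not show that empirical neural recordings satisfy blanket sparsity,
that real cortical columns implement the canonical microcircuit's wiring,
or that the F-test retains its size under strong nonlinearity,
state-dependent noise, or measurement noise, none of which the generators
emulate. Edge gains are tested at generic random weights; parameter sets
where a gained edge cancels exactly form a measure-zero set the package
makes no attempt to characterize.

# Known limitations

- Noise is additive, diagonal and Gaussian; no state-dependent or
  correlated noise.
- No adaptive step size, delays, or event detection; no spiking models.
- Blanket *verification* only: the package never searches partitions or
  learns structure from data.
- The DOT reader accepts only the package's own DOT dialect (GraphML is
  the general-purpose interchange format).
- The conditional-independence machinery is linear; conditional mutual
  information or other nonparametric tests are out of scope.
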