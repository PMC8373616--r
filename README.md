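# MarkovBlankets

Markov blanket analysis of multiscale neural dynamical systems: dependency
graphs, blanket extraction and classification, structural and statistical
verification of the implied conditional independencies, and recursive
coarse-graining from neurons to cortical columns to networks.

## The problem

A Markov blanket is the statistical boundary of a system: the minimal set
of variables — parents, children, and parents of children — that renders a
set of *internal* states μ conditionally independent of everything
*external* η,

```
μ ⊥ η | b   ⟺   p(μ, η | b) = p(μ | b) p(η | b).
```

The blanket b splits into *sensory* states s (influenced by external but
not internal states) and *active* states a (influenced by internal but not
external states). For dynamical systems this is a sparsity constraint on
the flow — μ̇ = f<sub>μ</sub>(μ,s,a), ȧ = f<sub>a</sub>(μ,s,a),
η̇ = f<sub>η</sub>(η,s,a), ṡ = f<sub>s</sub>(η,s,a) — forbidding exactly
four influences: μ→s, μ→η, η→a, η→μ. The same template recurs across
scales of neural organisation: ion-channel gates blanketed by a neuron's
membrane potential and injected current, conductances of one neuron
coupled to another's only through pre- and postsynaptic potentials,
cortical columns whose superficial and deep pyramidal cells form the
blanket between the spiny-stellate/interneuron cores of neighbouring
columns, and whole brain networks blanketing one another.

This package is for researchers who want to make such claims *checkable*:
declare a model's dependency structure, extract and classify its blanket,
verify the four exclusions structurally (d-separation on the one-step
unrolled graph) and statistically (nested-regression tests on simulated
trajectories, with edge-gain negative controls), and repeat the analysis
after coarse-graining to any spatial scale.

## What is in the box

- **Graphs** — `DependencyGraph`, `pearlBlanket()`, `classifyBlanket()`,
  `validatePartition()`, `dSeparated()`, `unrollOneStep()`; DOT and
  GraphML round-tripping.
- **Model zoo** — gated-leak and classic Hodgkin–Huxley, FitzHugh–Nagumo,
  Morris–Lecar, voltage/conductance neural-mass units
  (`neuralMassPair()`), canonical-microcircuit column chains
  (`cmcChain()`), Newtonian spring–mass chains (`springChain()`), and
  seeded random linear blanket systems (`randomBlanketSystem()`);
  `structuralGraph()` cross-checks every declared edge by
  finite-difference probing of the flow.
- **Simulation** — seeded, reproducible RK4 / Euler–Maruyama integration
  (`integrateModel()`), linearization, Lyapunov stationary covariances.
- **Verification** — one-step conditional-independence tests in four
  directions (`dynamicCITest()`), stationary partial-correlation
  diagnostics, and `blanketReport()` bundling everything with a negative
  control.
- **Scales** — `coarseGrain()`, `nestedBlankets()`, `macroCICheck()`
  (macro-blanket soundness verified on the unrolled micro graph).
- **CLI** — a thin wrapper with `build`, `verify` and `ladder`
  subcommands at `system.file("cli", "mbtool.R", package = "MarkovBlankets")`.

## Worked example

Two coupled cortical columns, coarse-grained to their eight populations.
With the spiny stellate cells and interneurons of column 1 as internal
states and those of column 2 as external states, the pyramidal populations
classify exactly as the laminar wiring predicts:

```r
library(MarkovBlankets)

m <- cmcChain(2)
macro <- coarseGrain(modelGraph(m), populationGrouping(m))
classifyBlanket(macro, internal = c("SS1", "II1"), external = c("SS2", "II2"))
#> $sensory: "SP2" "DP2"
#> $active:  "SP1" "DP1"
```

Column 1's superficial pyramidal cells are active states (they carry the
ascending influence), column 2's deep pyramidal cells sensory (they carry
the descending influence back); no edge violates the blanket exclusions.

A full verification run on the two-neuron model — structural validation,
conditional-independence tests on a simulated trajectory, stationary
diagnostics, and a negative control that gains one forbidden
external-to-active edge:

```r
pair <- neuralMassPair(noise = 0.2)
part <- partitionFromRoles(modelGraph(pair))
#>   internal: g1 | sensory: v2 | active: v1 | external: g2

rep <- blanketReport(pair, part, tEnd = 400, dt = 0.05, seed = 1)
#> violations: 0
#> internal-direction p: 0.706  accept
#> active-direction p:   0.17   accept
#> negative control: 1 violation; active-direction p: 3.55e-32  reject
#> max |stationary partial correlation|: 7.4e-09
```

The intact pair passes every test; the single gained edge is both a
structural violation and statistically unmissable. The near-zero stationary
partial correlation between g1 and g2 given the blanket is the Gaussian
stationary reading of the same independence.

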