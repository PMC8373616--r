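#' @include depgraph.R
NULL

## x/(1 - exp(-x/y)) with the removable singularity at x = 0 handled
.vtrap <- function(x, y) {
    ## limit x/(1 - exp(-x/y)) -> y as x -> 0
    ifelse(abs(x / y) < 1e-7, y, x / (1 - exp(-x / y)))
}

#' Default parameters for the gated-leak Hodgkin-Huxley variant
#'
#' Membrane constants use the standard squid-axon values (mV, ms, mS/cm2,
#' uF/cm2). The potassium and sodium gate rate functions are the classic
#' voltage-dependent forms; the leak gate -- this variant gates the leak
#' current with its own first-order state -- uses voltage-independent equal
#' rates so the gate relaxes to 1/2.
#'
#' @return Named list of parameters accepted by [hodgkinHuxley()].
#' @export
hhParams <- function() {
    list(C = 1, gK = 36, gNa = 120, gl = 0.3,
         vK = -77, vNa = 50, vl = -54.4,
         alphaK  = function(a) 0.01 * .vtrap(a + 55, 10),
         betaK   = function(a) 0.125 * exp(-(a + 65) / 80),
         alphaNa = function(a) 0.1 * .vtrap(a + 40, 10),
         betaNa  = function(a) 4 * exp(-(a + 65) / 18),
         alphaL  = function(a) rep_len(0.1, length(a)),
         betaL   = function(a) rep_len(0.1, length(a)))
}

.checkHHParams <- function(p) {
    if (p$C <= 0) stop("parameter error: capacitance C must be positive")
    if (any(c(p$gK, p$gNa, p$gl) < 0))
        stop("parameter error: conductances must be non-negative")
    invisible(TRUE)
}

#' Single-neuron conductance model with a voltage blanket (gated-leak variant)
#'
#' Membrane potential `a` (the active state) integrates an injected current
#' `s` (the sensory state) and three ionic currents whose gates
#' `mu_K`, `mu_Na`, `mu_l` (the internal states) open and close as functions
#' of the potential:
#' \deqn{\dot a = (s - g_K \mu_K^4 (a - v_K) - g_{Na} \mu_{Na}^3 (a - v_{Na})
#'   - g_l \mu_l (a - v_l)) / C}
#' \deqn{\dot\mu_i = \alpha_i(a)(1 - \mu_i) - \beta_i(a)\mu_i}
#' In this variant a single (cubed) sodium gate stands in for activation and
#' inactivation together, and the leak current carries its own gate; see
#' [classicHodgkinHuxley()] for the textbook formulation with `m^3 h`
#' sodium kinetics and an ungated leak. The gate flows confine every gate to
#' `[0, 1]` whenever the rates are non-negative.
#'
#' Declared dependencies: the potential's parents are the injected current and
#' the three gates; each gate's only parent is the potential.
#'
#' @param params list as from [hhParams()]; rate functions overridable.
#' @param noise per-state diffusion amplitudes (recycled).
#' @return A [DynamicalModel-class] with states `a`, `mu_Na`, `mu_K`, `mu_l`
#'   and input `s`.
#' @export
hodgkinHuxley <- function(params = hhParams(), noise = 0) {
    params <- utils::modifyList(hhParams(), params)
    .checkHHParams(params)
    states <- c("a", "mu_Na", "mu_K", "mu_l")
    flow <- function(t, x, u, p) {
        a <- x[1]
        da <- (u[1] -
               p$gK  * x[3]^4 * (a - p$vK) -
               p$gNa * x[2]^3 * (a - p$vNa) -
               p$gl  * x[4]   * (a - p$vl)) / p$C
        c(da,
          p$alphaNa(a) * (1 - x[2]) - p$betaNa(a) * x[2],
          p$alphaK(a)  * (1 - x[3]) - p$betaK(a)  * x[3],
          p$alphaL(a)  * (1 - x[4]) - p$betaL(a)  * x[4])
    }
    edges <- rbind(c("s", "a"), c("mu_Na", "a"), c("mu_K", "a"),
                   c("mu_l", "a"),
                   c("a", "mu_Na"), c("a", "mu_K"), c("a", "mu_l"))
    newDynamicalModel("hodgkin_huxley", states, "s", flow, params, noise,
        edges,
        roles = c(a = "active", mu_Na = "internal", mu_K = "internal",
                  mu_l = "internal", s = "sensory"),
        stateRanges = matrix(c(-90, 40, 0.02, 0.98, 0.02, 0.98, 0.02, 0.98),
                             nrow = 2, dimnames = list(c("lo", "hi"), states)),
        inputRanges = matrix(c(-10, 20), nrow = 2,
                             dimnames = list(c("lo", "hi"), "s")))
}

#' Classic Hodgkin-Huxley (1952) formulation
#'
#' Textbook kinetics: sodium current `g_Na m^3 h (a - v_Na)`, potassium
#' `g_K n^4 (a - v_K)`, ungated leak `g_l (a - v_l)`. Provided for comparison
#' with [hodgkinHuxley()]; the same blanket role assignment applies (gates
#' internal, potential active, injected current sensory).
#'
#' @inheritParams hodgkinHuxley
#' @return A [DynamicalModel-class] with states `a`, `m`, `h`, `n`.
#' @export
classicHodgkinHuxley <- function(params = hhParams(), noise = 0) {
    params <- utils::modifyList(hhParams(), params)
    params$alphaH <- function(a) 0.07 * exp(-(a + 65) / 20)
    params$betaH <- function(a) 1 / (1 + exp(-(a + 35) / 10))
    .checkHHParams(params)
    states <- c("a", "m", "h", "n")
    flow <- function(t, x, u, p) {
        a <- x[1]
        da <- (u[1] -
               p$gK * x[4]^4 * (a - p$vK) -
               p$gNa * x[2]^3 * x[3] * (a - p$vNa) -
               p$gl * (a - p$vl)) / p$C
        c(da,
          p$alphaNa(a) * (1 - x[2]) - p$betaNa(a) * x[2],
          p$alphaH(a)  * (1 - x[3]) - p$betaH(a)  * x[3],
          p$alphaK(a)  * (1 - x[4]) - p$betaK(a)  * x[4])
    }
    edges <- rbind(c("s", "a"), c("m", "a"), c("h", "a"), c("n", "a"),
                   c("a", "m"), c("a", "h"), c("a", "n"))
    newDynamicalModel("classic_hodgkin_huxley", states, "s", flow, params,
        noise, edges,
        roles = c(a = "active", m = "internal", h = "internal",
                  n = "internal", s = "sensory"),
        stateRanges = matrix(c(-90, 40, 0.02, 0.98, 0.02, 0.98, 0.02, 0.98),
                             nrow = 2, dimnames = list(c("lo", "hi"), states)),
        inputRanges = matrix(c(-10, 20), nrow = 2,
                             dimnames = list(c("lo", "hi"), "s")))
}

#' FitzHugh-Nagumo oscillator
#'
#' Two-state reduction of excitable membrane dynamics, in dimensionless units:
#' \deqn{\dot a = a - a^3/3 - \mu + s, \qquad
#'       \dot\mu = (a + \alpha - \beta\mu)/\tau}
#' The membrane potential `a` is the active state, the recovery variable `mu`
#' the internal state, and the injected current `s` the sensory state. The
#' recovery flow does not depend on the current.
#'
#' @param params list with `tau` (> 0), `alpha`, `beta`. Defaults
#'   `tau = 12.5`, `alpha = 0.7`, `beta = 0.8`.
#' @param noise per-state diffusion amplitudes (recycled).
#' @return A [DynamicalModel-class] with states `a`, `mu` and input `s`.
#' @export
fitzhughNagumo <- function(params = list(), noise = 0) {
    params <- utils::modifyList(list(tau = 12.5, alpha = 0.7, beta = 0.8),
                                params)
    if (params$tau <= 0)
        stop("parameter error: recovery time constant tau must be positive")
    flow <- function(t, x, u, p)
        c(x[1] - x[1]^3 / 3 - x[2] + u[1],
          (x[1] + p$alpha - p$beta * x[2]) / p$tau)
    edges <- rbind(c("s", "a"), c("mu", "a"), c("a", "mu"))
    newDynamicalModel("fitzhugh_nagumo", c("a", "mu"), "s", flow, params,
        noise, edges,
        roles = c(a = "active", mu = "internal", s = "sensory"),
        stateRanges = matrix(c(-2.5, 2.5, -1, 2), nrow = 2,
                             dimnames = list(c("lo", "hi"), c("a", "mu"))),
        inputRanges = matrix(c(-1, 1.5), nrow = 2,
                             dimnames = list(c("lo", "hi"), "s")))
}

#' Default Morris-Lecar parameters
#'
#' Constants follow the standard published barnacle-muscle
#' set (Hopf regime): `C = 20` uF/cm2, conductances `gCa = 4.4`, `gK = 8`,
#' `gL = 2` mS/cm2, reversals `vCa = 120`, `vK = -84`, `vL = -60` mV, gating
#' constants `v1 = -1.2`, `v2 = 18`, `v3 = 2`, `v4 = 30` mV, rate scale
#' `phi = 0.04` /ms.
#'
#' @return Named list accepted by [morrisLecar()].
#' @export
mlParams <- function() {
    list(C = 20, gCa = 4.4, gK = 8, gL = 2,
         vCa = 120, vK = -84, vL = -60,
         v1 = -1.2, v2 = 18, v3 = 2, v4 = 30, phi = 0.04)
}

#' Morris-Lecar neuron
#'
#' Voltage `a` (active) with instantaneous calcium activation and a single
#' slow potassium gate `mu` (internal) driven by injected current `s`
#' (sensory):
#' \deqn{\dot a = (s - g_L(a - v_L) - g_{Ca} m_\infty(a)(a - v_{Ca})
#'                 - g_K \mu (a - v_K)) / C}
#' \deqn{\dot\mu = (w_\infty(a) - \mu)/\tau(a)}
#' with `m_inf(a) = (1 + tanh((a - v1)/v2))/2`,
#' `w_inf(a) = (1 + tanh((a - v3)/v4))/2` and voltage-dependent time constant
#' `tau(a) = 1/(phi cosh((a - v3)/(2 v4)))`. The gate's steady state equals
#' 1/2 at its midpoint voltage `v3`.
#'
#' @param params list as from [mlParams()].
#' @param noise per-state diffusion amplitudes (recycled).
#' @return A [DynamicalModel-class] with states `a`, `mu` and input `s`.
#' @export
morrisLecar <- function(params = mlParams(), noise = 0) {
    params <- utils::modifyList(mlParams(), params)
    if (params$C <= 0) stop("parameter error: capacitance C must be positive")
    if (any(c(params$gCa, params$gK, params$gL) < 0))
        stop("parameter error: conductances must be non-negative")
    if (params$phi <= 0)
        stop("parameter error: phi must be positive (tau(a) > 0)")
    flow <- function(t, x, u, p) {
        a <- x[1]
        minf <- 0.5 * (1 + tanh((a - p$v1) / p$v2))
        winf <- 0.5 * (1 + tanh((a - p$v3) / p$v4))
        da <- (u[1] - p$gL * (a - p$vL) - p$gCa * minf * (a - p$vCa) -
               p$gK * x[2] * (a - p$vK)) / p$C
        c(da, (winf - x[2]) * p$phi * cosh((a - p$v3) / (2 * p$v4)))
    }
    edges <- rbind(c("s", "a"), c("mu", "a"), c("a", "mu"))
    newDynamicalModel("morris_lecar", c("a", "mu"), "s", flow, params, noise,
        edges,
        roles = c(a = "active", mu = "internal", s = "sensory"),
        stateRanges = matrix(c(-80, 40, 0.02, 0.98), nrow = 2,
                             dimnames = list(c("lo", "hi"), c("a", "mu"))),
        inputRanges = matrix(c(0, 120), nrow = 2,
                             dimnames = list(c("lo", "hi"), "s")))
}

#' Gating steady state of the Morris-Lecar potassium channel
#'
#' @param a voltage (mV).
#' @param params list as from [mlParams()].
#' @return `w_inf(a)`.
#' @export
mlGatingSteadyState <- function(a, params = mlParams())
    0.5 * (1 + tanh((a - params$v3) / params$v4))

## ---- neural mass units ------------------------------------------------------

.sigmoid <- function(v, slope, threshold) 1 / (1 + exp(-slope * (v - threshold)))

#' Network of voltage/conductance neural-mass units
#'
#' Each unit `i` has a mean membrane potential `v_i` and a lumped synaptic
#' conductance `g_i`, first order in both with linear decay:
#' \deqn{\dot v_i = -v_i/\tau_v + g_i, \qquad
#'       \dot g_i = -g_i/\tau_g + \sum_j W_{ij}\, \sigma(v_j)}
#' where `sigma` is a logistic firing-rate function. The dependency sparsity
#' is the model's point: a unit's potential depends only on that unit's own
#' conductance (and itself), while its conductance collects the potentials of
#' presynaptic units through the connectivity weights `W` -- so the potential
#' acts as the unit's active state and the conductance as its internal state,
#' with presynaptic potentials playing sensory roles.
#'
#' @param W numeric `n x n` weight matrix; `W[i, j]` is the gain from unit
#'   `j`'s potential onto unit `i`'s conductance. The diagonal is ignored
#'   (a unit's own potential does not drive its own conductance).
#' @param slope,threshold logistic firing-rate parameters (defaults 0.56 /mV
#'   and 0 mV).
#' @param tauV,tauG decay time constants (ms) of potential and conductance.
#' @param noise per-state diffusion amplitudes (recycled).
#' @param labels optional unit labels (default `u1 ... un`).
#' @return A [DynamicalModel-class] with states `v<label>`, `g<label>`
#'   interleaved per unit, no exogenous inputs.
#' @export
neuralMassNetwork <- function(W, slope = 0.56, threshold = 0,
                              tauV = 4, tauG = 8, noise = 0, labels = NULL) {
    W <- as.matrix(W)
    n <- nrow(W)
    if (ncol(W) != n) stop("weight matrix W must be square")
    diag(W) <- 0
    if (is.null(labels)) labels <- as.character(seq_len(n))
    if (length(labels) != n) stop("shape mismatch: need one label per unit")
    vlab <- paste0("v", labels)
    glab <- paste0("g", labels)
    states <- as.vector(rbind(vlab, glab))
    params <- list(W = W, slope = slope, threshold = threshold,
                   tauV = tauV, tauG = tauG, labels = labels)
    flow <- function(t, x, u, p) {
        v <- x[seq(1, length(x), by = 2)]
        g <- x[seq(2, length(x), by = 2)]
        rate <- .sigmoid(v, p$slope, p$threshold)
        dv <- -v / p$tauV + g
        dg <- -g / p$tauG + as.vector(p$W %*% rate)
        as.vector(rbind(dv, dg))
    }
    edges <- cbind(glab, vlab)
    signs <- rep("unsigned", n)
    nz <- which(W != 0, arr.ind = TRUE)
    if (nrow(nz)) {
        edges <- rbind(edges, cbind(vlab[nz[, "col"]], glab[nz[, "row"]]))
        signs <- c(signs,
                   ifelse(W[nz] > 0, "excitatory", "inhibitory"))
    }
    m <- newDynamicalModel("neural_mass", states, character(), flow, params,
        noise, edges, roles = "unassigned",
        groups = as.vector(rbind(labels, labels)),
        stateRanges = matrix(rep(c(-5, 5), 2 * n), nrow = 2,
                             dimnames = list(c("lo", "hi"), states)))
    m@graph@edges$sign <- signs
    m
}

#' Two coupled neural-mass units with a documented blanket
#'
#' Builds a pair of units where unit 2's potential drives unit 1's
#' conductance with gain `Amu` (the sensory-to-internal weight) and unit 1's
#' potential drives unit 2's conductance with gain `Aeta` (the
#' active-to-external weight). From unit 1's perspective the documented
#' blanket roles are: `g1` internal, `v1` active, `v2` sensory, `g2`
#' external -- the potential of a unit can only be influenced by its own
#' conductance, while its conductance can collect many presynaptic
#' potentials.
#'
#' @param Amu gain from the sensory potential `v2` onto the internal
#'   conductance `g1`.
#' @param Aeta gain from the active potential `v1` onto the external
#'   conductance `g2`.
#' @param ... passed to [neuralMassNetwork()].
#' @return A [DynamicalModel-class] with states `v1`, `g1`, `v2`, `g2` and
#'   roles assigned as above.
#' @export
neuralMassPair <- function(Amu = 1, Aeta = 1, ...) {
    W <- matrix(c(0, Amu, Aeta, 0), nrow = 2, byrow = TRUE)
    m <- neuralMassNetwork(W, ...)
    m@name <- "neural_mass_pair"
    nodeRoles(m@graph) <- c(v1 = "active", g1 = "internal",
                            v2 = "sensory", g2 = "external")
    m
}

## ---- canonical microcircuit chains ------------------------------------------

.CMC_TYPES <- c("SS", "SP", "II", "DP")

#' Default intrinsic connectivity of a canonical-microcircuit column
#'
#' 4 x 4 matrix over populations (rows = target, columns = source) in the
#' order spiny stellate (SS), superficial pyramidal (SP), inhibitory
#' interneurons (II), deep pyramidal (DP). Nonzero entries: SS excites SP and
#' II; SP excites DP and II; II inhibits SS, SP and DP; DP excites II.
#' Intrinsic edges never cross columns.
#'
#' @return Numeric matrix with dimnames over population types.
#' @export
cmcIntrinsicWeights <- function() {
    W <- matrix(0, 4, 4, dimnames = list(.CMC_TYPES, .CMC_TYPES))
    W["SP", "SS"] <- 1;  W["II", "SS"] <- 1
    W["DP", "SP"] <- 1;  W["II", "SP"] <- 1
    W["SS", "II"] <- -1; W["SP", "II"] <- -1; W["DP", "II"] <- -1
    W["II", "DP"] <- 1
    W
}

#' Chain of canonical-microcircuit cortical columns
#'
#' Builds `L` four-population columns (spiny stellate SS, superficial
#' pyramidal SP, inhibitory interneurons II, deep pyramidal DP), each
#' population a voltage/conductance neural-mass unit, coupled by the
#' stereotyped laminar pattern: ascending (forward) connections originate at
#' the superficial pyramidal cells of column `i` and terminate on the spiny
#' stellate cells and interneurons of column `i + 1`; descending (backward)
#' connections originate at the deep pyramidal cells of column `i + 1` and
#' terminate on the superficial pyramidal cells and interneurons of column
#' `i`. Spiny stellate cells and interneurons never project outside their
#' column, which is what lets them play internal/external roles while the
#' pyramidal populations form the blanket: with the SS and II states of one
#' column as internal set and those of the next as external, the first
#' column's superficial pyramidal cells classify as active states and the
#' second column's deep pyramidal cells as sensory states.
#'
#' @param L number of columns (>= 1).
#' @param intrinsic 4 x 4 intrinsic weight matrix as in
#'   [cmcIntrinsicWeights()] (any such matrix keeps blanket validity, since
#'   intrinsic edges never cross columns).
#' @param forwardGain,backwardGain extrinsic gains.
#' @param forwardToDeep also send forward connections to the next column's
#'   deep pyramidal cells (an alternative laminar convention; default off).
#' @param ... firing-rate and decay parameters passed to the unit dynamics,
#'   as in [neuralMassNetwork()].
#' @return A [DynamicalModel-class] with states `<pop><col>_v`,
#'   `<pop><col>_g` (e.g. `SP1_v`), grouped by population.
#' @export
cmcChain <- function(L, intrinsic = cmcIntrinsicWeights(),
                     forwardGain = 1, backwardGain = 0.5,
                     forwardToDeep = FALSE, ...) {
    if (L < 1) stop("L must be >= 1")
    pops <- as.vector(t(outer(seq_len(L), .CMC_TYPES,
                              function(i, p) paste0(p, i))))
    nPop <- length(pops)
    Wpop <- matrix(0, nPop, nPop, dimnames = list(pops, pops))
    for (i in seq_len(L)) {
        blk <- paste0(.CMC_TYPES, i)
        Wpop[blk, blk] <- intrinsic
        if (i < L) {
            Wpop[paste0("SS", i + 1), paste0("SP", i)] <- forwardGain
            Wpop[paste0("II", i + 1), paste0("SP", i)] <- forwardGain
            if (forwardToDeep)
                Wpop[paste0("DP", i + 1), paste0("SP", i)] <- forwardGain
            Wpop[paste0("SP", i), paste0("DP", i + 1)] <- backwardGain
            Wpop[paste0("II", i), paste0("DP", i + 1)] <- backwardGain
        }
    }
    args <- list(...)
    m <- do.call(neuralMassNetwork, c(list(W = Wpop, labels = pops), args))
    m@name <- "cmc_chain"
    ## relabel states population-first: SP1_v instead of vSP1
    old <- m@stateLabels
    lab <- sub("^([vg])(.*)$", "\\2_\\1", old)
    m@stateLabels <- lab
    names(m@noise) <- lab
    colnames(m@stateRanges) <- lab
    ren <- structure(lab, names = old)
    m@graph@nodes$id <- unname(ren[m@graph@nodes$id])
    m@graph@edges$from <- unname(ren[m@graph@edges$from])
    m@graph@edges$to <- unname(ren[m@graph@edges$to])
    m@params[c("L", "forwardGain", "backwardGain", "forwardToDeep")] <-
        list(L, forwardGain, backwardGain, forwardToDeep)
    m@params$intrinsic <- intrinsic
    validObject(m)
    m
}

#' Select state ids of a canonical-microcircuit chain
#'
#' @param model a [cmcChain()] model.
#' @param population character vector of population types (`"SS"`, `"SP"`,
#'   `"II"`, `"DP"`); default all.
#' @param column integer vector of column indices; default all.
#' @return Character vector of matching state labels.
#' @export
cmcStates <- function(model, population = .CMC_TYPES,
                      column = seq_len(model@params$L)) {
    want <- outer(population, column, paste0)
    lab <- model@stateLabels
    lab[sub("_[vg]$", "", lab) %in% want]
}

#' Population- and column-level coarse grainings of a model
#'
#' `populationGrouping` maps every state to its population macro-unit (the
#' node `group` attribute, e.g. both `SP1_v` and `SP1_g` to `"SP1"`);
#' `columnGrouping` maps every state of a [cmcChain()] to its column.
#'
#' @param model a [DynamicalModel-class] with grouped states.
#' @return A [CoarseGraining-class].
#' @export
populationGrouping <- function(model) {
    g <- nodeGroups(model@graph)
    g <- g[model@stateLabels]
    if (any(is.na(g)))
        stop("model has ungrouped states: ",
             paste(names(g)[is.na(g)], collapse = ", "))
    CoarseGraining(g)
}

#' @rdname populationGrouping
#' @export
columnGrouping <- function(model) {
    lab <- model@stateLabels
    col <- sub("^[A-Z]+([0-9]+)_[vg]$", "column\\1", lab)
    if (any(col == lab)) stop("state labels are not in <pop><col>_<v|g> form")
    CoarseGraining(structure(col, names = lab))
}

## ---- structural verification ------------------------------------------------

#' Recover the dependency graph of a flow by finite-difference probing
#'
#' Numerically differentiates the model's flow at each probe point; an edge
#' `j -> i` is included iff `|df_i/dx_j| > tol` at any probe (diagonal terms
#' are the implicit self-dependence and are skipped). Inputs are probed the
#' same way as states. Probing can miss a declared dependency at degenerate
#' points (where a partial derivative happens to vanish) but never invents
#' one beyond `tol`, so for a correctly declared model the result is a
#' subgraph of the declared edges.
#'
#' @param model a [DynamicalModel-class].
#' @param probes matrix of probe points, one row per probe, columns named by
#'   states then inputs (as from [randomProbes()]); or a single named vector.
#' @param tol absolute derivative threshold.
#' @return A [DependencyGraph-class] over the model's states and inputs with
#'   the same roles as the declared graph.
#' @export
structuralGraph <- function(model, probes, tol = 1e-6) {
    if (is.null(dim(probes))) probes <- matrix(probes, nrow = 1,
        dimnames = list(NULL, names(probes)))
    if (nrow(probes) < 1L) stop("need at least one probe point")
    states <- model@stateLabels
    inputs <- model@inputLabels
    vars <- c(states, inputs)
    if (!all(vars %in% colnames(probes)))
        stop("probe columns must cover all states and inputs")
    nS <- length(states)
    present <- matrix(FALSE, nS, length(vars),
                      dimnames = list(states, vars))
    for (k in seq_len(nrow(probes))) {
        x0 <- probes[k, states]
        u0 <- if (length(inputs)) probes[k, inputs] else numeric()
        f0 <- model@flow(0, x0, u0, model@params)
        if (length(f0) != nS || !all(is.finite(f0)))
            stop("non-finite flow at probe point ", k, " (",
                 paste(sprintf("%s=%g", vars, probes[k, vars]),
                       collapse = ", "), ")")
        for (j in seq_along(vars)) {
            h <- 1e-6 * max(1, abs(probes[k, vars[j]]))
            xp <- x0; up <- u0; xm <- x0; um <- u0
            if (j <= nS) {
                xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
            } else {
                up[j - nS] <- up[j - nS] + h; um[j - nS] <- um[j - nS] - h
            }
            d <- (model@flow(0, xp, up, model@params) -
                  model@flow(0, xm, um, model@params)) / (2 * h)
            if (!all(is.finite(d)))
                stop("non-finite derivative at probe point ", k)
            present[, j] <- present[, j] | (abs(d) > tol)
        }
    }
    for (s in states) present[s, s] <- FALSE   # implicit self-dependence
    nz <- which(present, arr.ind = TRUE)
    edges <- if (nrow(nz)) cbind(vars[nz[, "col"]], states[nz[, "row"]])
             else NULL
    DependencyGraph(model@graph@nodes, edges)
}

#' Random probe points within a model's plausible ranges
#'
#' @param model a [DynamicalModel-class].
#' @param n number of probes.
#' @param seed RNG seed.
#' @return Matrix `n x (states + inputs)` with named columns, each value
#'   drawn uniformly within the model's declared range for that variable.
#' @export
randomProbes <- function(model, n, seed = 1L) {
    set.seed(seed)
    rng <- cbind(model@stateRanges, model@inputRanges)
    vars <- c(model@stateLabels, model@inputLabels)
    m <- matrix(stats::runif(n * length(vars)), nrow = n)
    m <- sweep(m, 2, rng["hi", ] - rng["lo", ], "*")
    m <- sweep(m, 2, rng["lo", ], "+")
    colnames(m) <- vars
    m
}
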