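#' @include simulate.R
NULL

#' Random directed acyclic graph
#'
#' Draws a uniformly random topological order of `n` labelled nodes and
#' includes each order-respecting edge independently with probability `p`.
#' Deterministic given `seed`.
#'
#' @param n number of nodes (>= 1); ids are `x1 ... xn`.
#' @param p edge probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return An acyclic [DependencyGraph-class].
#' @export
randomDAG <- function(n, p, seed = 1L) {
    if (n < 1) stop("n must be >= 1")
    if (p < 0 || p > 1) stop("p must lie in [0, 1]")
    set.seed(seed)
    ids <- paste0("x", seq_len(n))
    ord <- sample(n)
    edges <- NULL
    if (n >= 2) {
        pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
        keep <- stats::runif(nrow(pairs)) < p
        if (any(keep))
            edges <- cbind(ids[ord[pairs[keep, 1]]], ids[ord[pairs[keep, 2]]])
    }
    DependencyGraph(ids, edges)
}

#' Random stable linear system with a valid blanket partition by construction
#'
#' Builds a linear stochastic model `dx = J x dt + sigma dW` over internal
#' (`mu*`), sensory (`s*`), active (`a*`) and external (`eta*`) states whose
#' drift matrix is dense within the blocks the blanket flow constraints
#' allow -- internal flow depends on (internal, sensory, active), active flow
#' on (internal, sensory, active), external flow on (external, sensory,
#' active), sensory flow on (external, sensory, active) -- and exactly zero
#' in the four forbidden blocks (internal->sensory, internal->external,
#' external->active, external->internal). The drift is then shifted by a
#' multiple of the identity so that every eigenvalue has real part at most
#' `-margin`; the shift only touches the diagonal (the implicit
#' self-dependence), so the constructed sparsity is untouched and
#' [validatePartition()] returns no violations by construction.
#'
#' The external set may be larger than the internal set, echoing the fact
#' that a unit's sensory states can arise from many different external
#' states.
#'
#' @param nInternal,nSensory,nActive,nExternal block sizes (each >= 1).
#' @param margin stability margin: eigenvalues of `J` are pushed to real
#'   part `<= -margin` (default 0.1).
#' @param noise diffusion amplitude per state (recycled; default 1).
#' @param weightSd standard deviation of the nonzero drift entries before
#'   stabilization.
#' @param seed RNG seed.
#' @return A [DynamicalModel-class] with `params$J`, `params$linear = TRUE`
#'   and roles stored in its graph.
#' @export
randomBlanketSystem <- function(nInternal = 3, nSensory = 2, nActive = 2,
                                nExternal = 4, margin = 0.1, noise = 1,
                                weightSd = 0.5, seed = 1L) {
    if (min(nInternal, nSensory, nActive, nExternal) < 1)
        stop("all four block sizes must be >= 1")
    set.seed(seed)
    labels <- c(paste0("mu", seq_len(nInternal)),
                paste0("s", seq_len(nSensory)),
                paste0("a", seq_len(nActive)),
                paste0("eta", seq_len(nExternal)))
    roles <- rep(c("internal", "sensory", "active", "external"),
                 c(nInternal, nSensory, nActive, nExternal))
    names(roles) <- labels
    n <- length(labels)
    allowed <- outer(roles, roles, function(to, from)
        !(paste(from, to) %in% paste(.FORBIDDEN$fromRole, .FORBIDDEN$toRole)))
    J <- matrix(stats::rnorm(n * n, sd = weightSd), n, n,
                dimnames = list(labels, labels))
    J[!allowed] <- 0
    shift <- max(Re(eigen(J, only.values = TRUE)$values)) + margin
    J <- J - shift * diag(n)
    .linearModel("random_blanket_system", J, roles, noise)
}

#' Linear stochastic model around a drift matrix
#'
#' Wraps `dx = J x dt + sigma dW` as a [DynamicalModel-class] with the
#' dependency graph read off the nonzero off-diagonal entries of `J`
#' (rows are targets, columns sources; the diagonal is the implicit
#' self-dependence and stored as no edge).
#'
#' @param J square drift matrix; dimnames supply state labels (defaults
#'   `x1 ... xn`).
#' @param roles role vector passed to [DependencyGraph()].
#' @param noise per-state diffusion amplitudes (recycled; default 1).
#' @param name model name.
#' @return A [DynamicalModel-class] with `params$linear = TRUE`.
#' @export
linearModel <- function(J, roles = "unassigned", noise = 1, name = "linear") {
    J <- as.matrix(J)
    if (is.null(rownames(J)) && nrow(J))
        dimnames(J) <- list(paste0("x", seq_len(nrow(J))),
                            paste0("x", seq_len(nrow(J))))
    .linearModel(name, J, roles, noise)
}

## shared constructor (rows of J = targets)
.linearModel <- function(name, J, roles, noise) {
    labels <- if (is.null(rownames(J))) character() else rownames(J)
    off <- J
    diag(off) <- 0
    nz <- which(off != 0, arr.ind = TRUE)
    edges <- if (nrow(nz)) cbind(labels[nz[, "col"]], labels[nz[, "row"]])
             else NULL
    flow <- function(t, x, u, p) as.vector(p$J %*% x)
    newDynamicalModel(name, labels, character(), flow,
        list(J = J, linear = TRUE), noise, edges, roles = roles,
        stateRanges = matrix(rep(c(-3, 3), length(labels)), nrow = 2,
                             dimnames = list(c("lo", "hi"), labels)))
}

#' Add a single dependency between two role classes
#'
#' Picks one random node of `fromRole` and one of `toRole` (seeded) and adds
#' the directed influence, returning a perturbed copy; the original is left
#' untouched. For a linear model the drift entry is set to `weight`; for a
#' general model the flow is wrapped so the target's derivative gains
#' `weight * x[from]`. Adding an edge into a forbidden block is the canonical
#' negative control: blanket structure survives lost dependencies, not gained
#' ones.
#'
#' @param x a [DependencyGraph-class] or [DynamicalModel-class] with roles in
#'   its (declared) graph.
#' @param fromRole,toRole role names.
#' @param weight influence weight (models only; `0` gives a structurally
#'   present but statistically null edge).
#' @param seed RNG seed for the node choice.
#' @param margin for linear models: if the added weight makes the drift
#'   unstable, the diagonal is shifted so all eigenvalues have real part
#'   `<= -margin` again. The shift only touches the implicit
#'   self-dependence, so neither the added edge nor the blanket template is
#'   affected. Set to `NA` to disable.
#' @return Perturbed copy of `x`. The chosen edge is in
#'   `attr(result, "addedEdge")`.
#' @export
perturbAddEdge <- function(x, fromRole, toRole, weight = 0.5, seed = 1L,
                           margin = 0.1) {
    g <- if (is(x, "DynamicalModel")) x@graph else x
    if (!is(g, "DependencyGraph"))
        stop("x must be a DependencyGraph or DynamicalModel")
    roles <- nodeRoles(g)
    cand <- if (is(x, "DynamicalModel")) x@stateLabels else names(roles)
    fromSet <- intersect(cand, names(roles)[roles == fromRole])
    toSet <- intersect(cand, names(roles)[roles == toRole])
    if (!length(fromSet)) stop("no nodes with role ", fromRole)
    if (!length(toSet)) stop("no nodes with role ", toRole)
    ## prefer pairs whose dependency is absent (the point is to *gain* an
    ## edge); if the block is already fully connected, strengthen an
    ## existing dependency instead
    pairs <- expand.grid(from = fromSet, to = toSet,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
    if (!nrow(pairs))
        stop("no admissible ", fromRole, " -> ", toRole, " pair")
    present <- paste(pairs$from, pairs$to) %in%
        paste(g@edges$from, g@edges$to)
    gain <- any(!present)
    if (gain) pairs <- pairs[!present, , drop = FALSE]
    set.seed(seed)
    k <- sample.int(nrow(pairs), 1L)
    from <- pairs$from[k]
    to <- pairs$to[k]
    if (is(x, "DependencyGraph")) {
        out <- if (gain) .addGraphEdge(x, from, to) else x
    } else {
        out <- x
        if (gain) out@graph <- .addGraphEdge(x@graph, from, to)
        iTo <- match(to, x@stateLabels)
        iFrom <- match(from, x@stateLabels)
        if (isTRUE(x@params$linear)) {
            out@params$J[iTo, iFrom] <- out@params$J[iTo, iFrom] + weight
            if (!is.na(margin)) {
                top <- max(Re(eigen(out@params$J, only.values = TRUE)$values))
                if (top > -margin)
                    out@params$J <- out@params$J -
                        (top + margin) * diag(nrow(out@params$J))
            }
        } else {
            baseFlow <- x@flow
            out@flow <- function(t, x, u, p) {
                d <- baseFlow(t, x, u, p)
                d[iTo] <- d[iTo] + weight * x[iFrom]
                d
            }
        }
        out@name <- paste0(x@name, "_perturbed")
    }
    attr(out, "addedEdge") <- c(from = from, to = to)
    out
}

.addGraphEdge <- function(g, from, to) {
    if (any(g@edges$from == from & g@edges$to == to))
        stop("edge ", from, " -> ", to, " already present")
    g@edges <- rbind(g@edges,
        data.frame(from = from, to = to, sign = "unsigned",
                   stringsAsFactors = FALSE))
    validObject(g)
    g
}

#' Newtonian spring-mass chain
#'
#' `n` particles on a line, each with position `a_i` and momentum `mu_i`,
#' coupled by springs between neighbours (optionally anchored to walls at
#' the ends):
#' \deqn{\dot a_i = \mu_i / m_i, \qquad
#'       \dot\mu_i = k_{i-1}(a_{i-1} - a_i) + k_i (a_{i+1} - a_i)}
#' The dependency structure realizes the same blanket template as the
#' neural models: a particle's momentum (internal state) collects the
#' positions of many particles (its own, the active state, and its
#' neighbours', sensory states), while its position is influenced only by
#' its own momentum.
#'
#' @param n number of particles (>= 2).
#' @param masses positive masses (kg), recycled.
#' @param springK spring constants (N/m), recycled to `n - 1` (or `n + 1`
#'   when anchored).
#' @param anchored if `TRUE`, the end particles are also attached to fixed
#'   walls; if `FALSE` (default) the chain is free and total momentum is
#'   conserved.
#' @return A [DynamicalModel-class] with states `a1, mu1, ..., an, mun`.
#' @export
springChain <- function(n, masses = 1, springK = 1, anchored = FALSE) {
    if (n < 2) stop("n must be >= 2")
    masses <- rep_len(masses, n)
    if (any(masses <= 0)) stop("masses must be positive")
    nSpring <- if (anchored) n + 1L else n - 1L
    springK <- rep_len(springK, nSpring)
    if (any(springK < 0)) stop("spring constants must be non-negative")
    alab <- paste0("a", seq_len(n))
    mlab <- paste0("mu", seq_len(n))
    states <- as.vector(rbind(alab, mlab))
    params <- list(m = masses, k = springK, anchored = anchored, n = n)
    flow <- function(t, x, u, p) {
        a <- x[seq(1, 2 * p$n, by = 2)]
        mu <- x[seq(2, 2 * p$n, by = 2)]
        if (p$anchored) {
            ext <- c(0, a, 0)                 # wall - particles - wall
            tension <- p$k * diff(ext)        # n + 1 spring tensions
        } else {
            tension <- c(0, p$k * diff(a), 0) # virtual slack end springs
        }
        dmu <- utils::tail(tension, p$n) - utils::head(tension, p$n)
        da <- mu / p$m
        as.vector(rbind(da, dmu))
    }
    edges <- cbind(mlab, alab)                     # own momentum -> position
    edges <- rbind(edges, cbind(alab, mlab))       # own position -> momentum
    if (n >= 2) {
        left <- cbind(alab[-n], mlab[-1])          # left neighbour position
        right <- cbind(alab[-1], mlab[-n])         # right neighbour position
        edges <- rbind(edges, left, right)
    }
    newDynamicalModel("spring_chain", states, character(), flow, params, 0,
        edges, roles = "unassigned",
        groups = as.vector(rbind(paste0("p", seq_len(n)),
                                 paste0("p", seq_len(n)))),
        stateRanges = matrix(rep(c(-1, 1), 2 * n), nrow = 2,
                             dimnames = list(c("lo", "hi"), states)))
}

#' Conserved quantities of a spring chain
#'
#' `springChainEnergy` evaluates the Hamiltonian (kinetic plus spring
#' potential); `springChainMomentum` the total momentum. Both accept a state
#' vector or a trajectory matrix.
#'
#' @param model a [springChain()] model.
#' @param state named state vector or (time x state) matrix.
#' @return Numeric scalar or vector over time.
#' @export
springChainEnergy <- function(model, state) {
    p <- model@params
    if (is.null(dim(state))) state <- matrix(state, nrow = 1,
        dimnames = list(NULL, names(state)))
    a <- state[, paste0("a", seq_len(p$n)), drop = FALSE]
    mu <- state[, paste0("mu", seq_len(p$n)), drop = FALSE]
    kin <- 0.5 * as.vector(mu^2 %*% (1 / p$m))
    if (p$anchored) {
        ext <- cbind(0, a, 0)
        pot <- 0.5 * as.vector((t(diff(t(ext)))^2) %*% p$k)
    } else {
        pot <- 0.5 * as.vector((t(diff(t(a)))^2) %*% p$k)
    }
    kin + pot
}

#' @rdname springChainEnergy
#' @export
springChainMomentum <- function(model, state) {
    p <- model@params
    if (is.null(dim(state))) state <- matrix(state, nrow = 1,
        dimnames = list(NULL, names(state)))
    rowSums(state[, paste0("mu", seq_len(p$n)), drop = FALSE])
}

#' Blanket role partition for one particle of a spring chain
#'
#' From particle `i`'s perspective: its momentum is the internal state, its
#' position the active state, its neighbours' positions the sensory states,
#' and everything else external.
#'
#' @param model a [springChain()] model.
#' @param i particle index.
#' @return A [BlanketPartition-class] over the chain's states.
#' @export
springChainPartition <- function(model, i) {
    n <- model@params$n
    if (i < 1 || i > n) stop("particle index out of range")
    nb <- intersect(c(i - 1, i + 1), seq_len(n))
    internal <- paste0("mu", i)
    active <- paste0("a", i)
    sensory <- paste0("a", nb)
    external <- setdiff(model@stateLabels, c(internal, active, sensory))
    BlanketPartition(internal, sensory, active, external)
}

#' Static network-level blanket graph (synthetic schematic)
#'
#' A macro-scale dependency graph over six large-scale brain networks, built
#' as a synthetic schematic of the resting-state literature rather than from
#' any empirical connectome: two visual networks as internal states that
#' reciprocally influence the dorsal and ventral attention networks (active
#' states), the default-mode network as the sensory state mediating the
#' influence of the sensorimotor network (external state). The assignment is
#' equally valid with internal and external reversed, which swaps the
#' sensory and active labels.
#'
#' @return A [DependencyGraph-class] at scale 3 with roles assigned.
#' @export
networkBlanketGraph <- function() {
    nodes <- data.frame(
        id = c("VIS1", "VIS2", "DAN", "VAN", "DMN", "SMN"),
        role = c("internal", "internal", "active", "active", "sensory",
                 "external"),
        scale = 3L, group = NA_character_, stringsAsFactors = FALSE)
    edges <- rbind(
        c("VIS1", "VIS2"), c("VIS2", "VIS1"),   # within internal
        c("VIS1", "DAN"), c("DAN", "VIS1"),     # internal <-> active
        c("VIS2", "VAN"), c("VAN", "VIS2"),
        c("DAN", "VAN"), c("VAN", "DAN"),       # within blanket
        c("DMN", "VIS1"), c("DMN", "VIS2"),     # sensory -> internal
        c("DMN", "DAN"), c("DAN", "DMN"),       # sensory <-> active
        c("DAN", "SMN"), c("VAN", "SMN"),       # active -> external
        c("SMN", "DMN"))                        # external -> sensory
    DependencyGraph(nodes, edges)
}
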