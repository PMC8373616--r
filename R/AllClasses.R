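## Central S4 classes. Conventions:
##  - node roles follow the four-way Markov blanket partition: internal states
##    (often written mu), sensory (s), active (a) and external states (eta),
##    plus "unassigned" for nodes whose role has not been fixed;
##  - dependency edges point from parent (influencer) to child (the state whose
##    flow depends on the parent); self-loops are implicit (every flow depends
##    on its own state) and never stored.

.VALID_ROLES <- c("internal", "sensory", "active", "external", "unassigned")
.VALID_SIGNS <- c("excitatory", "inhibitory", "unsigned")

#' DependencyGraph: directed "who influences whose flow" structure
#'
#' A directed graph over named state nodes. Each node carries a blanket role
#' (`internal`, `sensory`, `active`, `external` or `unassigned`), a spatial
#' scale (0 = finest) and an optional macro-unit group label. Each edge carries
#' an optional sign (`excitatory`, `inhibitory`, `unsigned`); signs are
#' metadata only and are ignored by all blanket computations, which depend on
#' the presence of an influence, not its direction of effect.
#'
#' Self-loops are not stored: every state's flow implicitly depends on itself,
#' and [unrollOneStep()] reinstates the self-dependence as an `x_t -> x_{t+1}`
#' edge when the cyclic flow graph is converted to an acyclic time-slice graph.
#'
#' @slot nodes data.frame with columns `id` (unique character), `role`,
#'   `scale` (non-negative integer) and `group` (character, `NA` if ungrouped).
#' @slot edges data.frame with columns `from`, `to` and `sign`.
#' @export
setClass("DependencyGraph",
    representation(nodes = "data.frame", edges = "data.frame"))

setValidity("DependencyGraph", function(object) {
    nd <- object@nodes
    ed <- object@edges
    msg <- character()
    if (!all(c("id", "role", "scale", "group") %in% names(nd)))
        msg <- c(msg, "nodes must have columns id, role, scale, group")
    if (!all(c("from", "to", "sign") %in% names(ed)))
        msg <- c(msg, "edges must have columns from, to, sign")
    if (length(msg))
        return(msg)
    if (anyDuplicated(nd$id))
        msg <- c(msg, sprintf("duplicated node ids: %s",
            paste(unique(nd$id[duplicated(nd$id)]), collapse = ", ")))
    if (!all(nd$role %in% .VALID_ROLES))
        msg <- c(msg, sprintf("invalid roles: %s",
            paste(setdiff(nd$role, .VALID_ROLES), collapse = ", ")))
    if (any(nd$scale < 0))
        msg <- c(msg, "node scales must be non-negative")
    bad <- setdiff(c(ed$from, ed$to), nd$id)
    if (length(bad))
        msg <- c(msg, sprintf("edge endpoints not declared as nodes: %s",
            paste(unique(bad), collapse = ", ")))
    if (any(ed$from == ed$to))
        msg <- c(msg, "self-loops must not be stored (self-dependence is implicit)")
    if (anyDuplicated(paste(ed$from, ed$to)))
        msg <- c(msg, "duplicated edges")
    if (!all(ed$sign %in% .VALID_SIGNS))
        msg <- c(msg, sprintf("invalid edge signs: %s",
            paste(setdiff(ed$sign, .VALID_SIGNS), collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct a DependencyGraph
#'
#' @param nodes character vector of node ids, or a data.frame with column
#'   `id` and optionally `role`, `scale`, `group`.
#' @param edges two-column matrix or data.frame of (parent, child) id pairs,
#'   optionally with a third column/column named `sign`. `NULL` for no edges.
#' @param roles optional named character vector of roles, or a single role
#'   recycled to all nodes; overrides any `role` column.
#' @param scales optional integer vector (recycled) of node scales.
#' @param groups optional character vector (recycled) of macro-unit labels.
#'
#' @return A [DependencyGraph-class] object.
#' @examples
#' g <- DependencyGraph(c("s", "mu", "a"),
#'                      edges = rbind(c("s", "mu"), c("mu", "a")))
#' pearlBlanket(g, "mu")
#' @export
DependencyGraph <- function(nodes, edges = NULL, roles = NULL,
                            scales = NULL, groups = NULL) {
    if (is.character(nodes))
        nodes <- data.frame(id = nodes, stringsAsFactors = FALSE)
    nd <- data.frame(id = as.character(nodes$id), stringsAsFactors = FALSE)
    nd$role <- if (!is.null(nodes$role)) as.character(nodes$role)
               else rep_len("unassigned", nrow(nd))
    nd$scale <- if (!is.null(nodes$scale)) as.integer(nodes$scale)
                else rep_len(0L, nrow(nd))
    nd$group <- if (!is.null(nodes$group)) as.character(nodes$group)
                else rep_len(NA_character_, nrow(nd))
    if (!is.null(roles)) {
        if (is.null(names(roles))) {
            nd$role <- rep_len(roles, nrow(nd))
        } else {
            unknown <- setdiff(names(roles), nd$id)
            if (length(unknown))
                stop("roles given for unknown nodes: ",
                     paste(unknown, collapse = ", "))
            nd$role[match(names(roles), nd$id)] <- roles
        }
    }
    if (!is.null(scales)) nd$scale <- as.integer(rep_len(scales, nrow(nd)))
    if (!is.null(groups)) nd$group <- as.character(rep_len(groups, nrow(nd)))
    if (is.null(edges) || NROW(edges) == 0L) {
        ed <- data.frame(from = character(), to = character(),
                         sign = character(), stringsAsFactors = FALSE)
    } else {
        if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
        names(edges)[1:2] <- c("from", "to")
        ed <- data.frame(from = as.character(edges$from),
                         to = as.character(edges$to),
                         stringsAsFactors = FALSE)
        ed$sign <- if (!is.null(edges$sign)) as.character(edges$sign) else "unsigned"
    }
    rownames(nd) <- NULL
    rownames(ed) <- NULL
    new("DependencyGraph", nodes = nd, edges = ed)
}

#' BlanketPartition: four-way assignment of states
#'
#' Holds the partition of a graph's states into internal, sensory, active and
#' external sets. The defining sparsity constraint -- internal states cannot
#' influence sensory or external states, external states cannot influence
#' active or internal states -- is checked against a graph by
#' [validatePartition()], not by the class itself, so invalid candidate
#' partitions can be represented and diagnosed.
#'
#' @slot internal,sensory,active,external character vectors of node ids.
#' @export
setClass("BlanketPartition",
    representation(internal = "character", sensory = "character",
                   active = "character", external = "character"))

setValidity("BlanketPartition", function(object) {
    all4 <- c(object@internal, object@sensory, object@active, object@external)
    if (anyDuplicated(all4))
        sprintf("partition sets overlap: %s",
                paste(unique(all4[duplicated(all4)]), collapse = ", "))
    else TRUE
})

#' Construct a BlanketPartition
#'
#' @param internal,sensory,active,external character vectors of node ids;
#'   must be pairwise disjoint.
#' @return A [BlanketPartition-class] object.
#' @export
BlanketPartition <- function(internal = character(), sensory = character(),
                             active = character(), external = character()) {
    new("BlanketPartition",
        internal = as.character(internal), sensory = as.character(sensory),
        active = as.character(active), external = as.character(external))
}

#' DynamicalModel: flow, parameters, noise and declared dependency structure
#'
#' Couples a deterministic flow (drift) function with additive diagonal
#' Gaussian noise amplitudes and a declared [DependencyGraph-class] stating
#' which states and inputs each state's flow depends on. The declared graph is
#' the object blanket analysis operates on; [structuralGraph()] cross-checks it
#' against the flow by finite-difference probing.
#'
#' @slot name character model name.
#' @slot stateLabels character vector; order fixes the state vector layout.
#' @slot inputLabels character vector of exogenous input names (may be empty).
#' @slot flow function `(t, state, input, params) -> derivative vector` with
#'   the same length and order as `stateLabels`.
#' @slot params named list of constants.
#' @slot noise named numeric diffusion amplitude per state (state units per
#'   sqrt(time)); all zero means the model is deterministic.
#' @slot graph declared dependencies over `stateLabels` and `inputLabels`.
#' @slot stateRanges,inputRanges 2-row matrices (`lo`, `hi`) of plausible
#'   values, used for random probe/initialisation sampling.
#' @export
setClass("DynamicalModel",
    representation(name = "character", stateLabels = "character",
                   inputLabels = "character", flow = "function",
                   params = "list", noise = "numeric",
                   graph = "DependencyGraph",
                   stateRanges = "matrix", inputRanges = "matrix"))

setValidity("DynamicalModel", function(object) {
    msg <- character()
    if (!identical(names(object@noise), object@stateLabels))
        msg <- c(msg, "noise must be named by stateLabels, in order")
    if (any(object@noise < 0))
        msg <- c(msg, "noise amplitudes must be non-negative")
    declared <- nodeIds(object@graph)
    lbl <- c(object@stateLabels, object@inputLabels)
    if (length(setdiff(declared, lbl)) || length(setdiff(lbl, declared)))
        msg <- c(msg, "graph nodes must be exactly the states and inputs")
    if (!identical(dim(object@stateRanges),
                   c(2L, length(object@stateLabels))))
        msg <- c(msg, "stateRanges must be a 2 x nStates matrix")
    if (length(msg)) msg else TRUE
})

## internal constructor shared by the model zoo
newDynamicalModel <- function(name, states, inputs, flow, params, noise,
                              edges, roles, signs = NULL,
                              stateRanges = NULL, inputRanges = NULL,
                              groups = NULL) {
    g <- DependencyGraph(c(states, inputs), edges = edges, roles = roles,
                         groups = groups)
    if (!is.null(signs)) g@edges$sign <- signs
    noise <- rep_len(noise, length(states))
    names(noise) <- states
    if (is.null(stateRanges))
        stateRanges <- matrix(rep(c(-1, 1), length(states)), nrow = 2,
                              dimnames = list(c("lo", "hi"), states))
    if (is.null(inputRanges))
        inputRanges <- matrix(rep(c(-1, 1), length(inputs)), nrow = 2,
                              dimnames = list(c("lo", "hi"),
                                              if (length(inputs)) inputs))
    new("DynamicalModel", name = name, stateLabels = states,
        inputLabels = inputs, flow = flow, params = params, noise = noise,
        graph = g, stateRanges = stateRanges, inputRanges = inputRanges)
}

#' Trajectory: seeded, time-stamped simulation output
#'
#' @slot times strictly increasing time grid.
#' @slot states matrix (time x state), columns named and ordered as the
#'   model's state labels.
#' @slot inputs matrix (time x input) of the exogenous drive actually applied.
#' @slot seed integer RNG seed used for the noise draws.
#' @slot dt step size.
#' @slot integrator `"rk4"` (deterministic) or `"euler-maruyama"`.
#' @slot modelName name of the integrated model.
#' @export
setClass("Trajectory",
    representation(times = "numeric", states = "matrix", inputs = "matrix",
                   seed = "integer", dt = "numeric", integrator = "character",
                   modelName = "character"))

setValidity("Trajectory", function(object) {
    msg <- character()
    if (nrow(object@states) != length(object@times))
        msg <- c(msg, "states must have one row per time point")
    if (length(object@times) > 1 && any(diff(object@times) <= 0))
        msg <- c(msg, "times must be strictly increasing")
    if (!all(is.finite(object@states)))
        msg <- c(msg, "states must be finite")
    if (length(msg)) msg else TRUE
})

#' CoarseGraining: micro-to-macro node mapping
#'
#' @slot mapping named character vector: names are micro node ids, values the
#'   macro unit label each maps to.
#' @slot scaleIncrement integer >= 1 added to the finest micro scale to give
#'   the macro scale.
#' @export
setClass("CoarseGraining",
    representation(mapping = "character", scaleIncrement = "integer"))

setValidity("CoarseGraining", function(object) {
    msg <- character()
    if (is.null(names(object@mapping)) || any(!nzchar(names(object@mapping))))
        msg <- c(msg, "mapping must be named by micro node ids")
    if (any(is.na(object@mapping)) || any(!nzchar(object@mapping)))
        msg <- c(msg, "macro labels must be non-empty")
    if (object@scaleIncrement < 1L)
        msg <- c(msg, "scaleIncrement must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct a CoarseGraining
#'
#' @param mapping named character vector (micro id -> macro label), or a
#'   two-column data.frame (micro, macro).
#' @param scaleIncrement integer >= 1.
#' @return A [CoarseGraining-class] object.
#' @export
CoarseGraining <- function(mapping, scaleIncrement = 1L) {
    if (is.data.frame(mapping)) {
        m <- as.character(mapping[[2]])
        names(m) <- as.character(mapping[[1]])
        mapping <- m
    }
    new("CoarseGraining", mapping = mapping,
        scaleIncrement = as.integer(scaleIncrement))
}

#' CITestResult: outcome of a one-step conditional-independence test
#'
#' @slot statistic test statistic: the F statistic of the nested regression
#'   comparison for a single predicted component, or Rao's F transform of
#'   Wilks' Lambda for several.
#' @slot dof numeric length-2 degrees of freedom of the statistic.
#' @slot pValue p-value in `[0, 1]`.
#' @slot alpha level used for the verdict.
#' @slot verdict `"reject"` iff `pValue < alpha`, else `"accept"`.
#' @slot triple list naming the predicted set, candidate (added) parents, and
#'   conditioning set.
#' @slot nSamples number of one-step transitions used.
#' @slot componentPValues per-component exact F-test p-values.
#' @export
setClass("CITestResult",
    representation(statistic = "numeric", dof = "numeric", pValue = "numeric",
                   alpha = "numeric", verdict = "character", triple = "list",
                   nSamples = "integer", componentPValues = "numeric"))

setValidity("CITestResult", function(object) {
    msg <- character()
    if (object@pValue < 0 || object@pValue > 1)
        msg <- c(msg, "pValue must lie in [0, 1]")
    if (!object@verdict %in% c("reject", "accept"))
        msg <- c(msg, "verdict must be 'reject' or 'accept'")
    if (identical(object@verdict, "reject") != (object@pValue < object@alpha))
        msg <- c(msg, "verdict must be reject iff pValue < alpha")
    if (length(msg)) msg else TRUE
})
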