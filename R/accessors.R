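#' @include AllGenerics.R
NULL

#' Accessors for DependencyGraph
#'
#' `nodeIds`, `nodeRoles`, `nodeScales` and `nodeGroups` return per-node
#' attributes (the last three named by node id); `edgeTable` returns the edge
#' data.frame (`from`, `to`, `sign`); `numNodes`/`numEdges` count them.
#' `nodeRoles<-` accepts a named character vector and reassigns roles for the
#' named nodes only.
#'
#' @param x a [DependencyGraph-class].
#' @param value named character vector of roles.
#' @return See description.
#' @name DependencyGraph-accessors
#' @aliases nodeIds nodeRoles nodeRoles<- nodeScales nodeGroups edgeTable
#'   numNodes numEdges
NULL

#' @rdname DependencyGraph-accessors
#' @export
setMethod("nodeIds", "DependencyGraph", function(x) x@nodes$id)

#' @rdname DependencyGraph-accessors
#' @export
setMethod("nodeRoles", "DependencyGraph",
    function(x) structure(x@nodes$role, names = x@nodes$id))

#' @rdname DependencyGraph-accessors
#' @export
setMethod("nodeRoles<-", "DependencyGraph", function(x, value) {
    if (is.null(names(value)))
        stop("replacement roles must be named by node id")
    unknown <- setdiff(names(value), x@nodes$id)
    if (length(unknown))
        stop("unknown node ids: ", paste(unknown, collapse = ", "))
    x@nodes$role[match(names(value), x@nodes$id)] <- value
    validObject(x)
    x
})

#' @rdname DependencyGraph-accessors
#' @export
setMethod("nodeScales", "DependencyGraph",
    function(x) structure(x@nodes$scale, names = x@nodes$id))

#' @rdname DependencyGraph-accessors
#' @export
setMethod("nodeGroups", "DependencyGraph",
    function(x) structure(x@nodes$group, names = x@nodes$id))

#' @rdname DependencyGraph-accessors
#' @export
setMethod("edgeTable", "DependencyGraph", function(x) x@edges)

#' @rdname DependencyGraph-accessors
#' @export
setMethod("numNodes", "DependencyGraph", function(x) nrow(x@nodes))

#' @rdname DependencyGraph-accessors
#' @export
setMethod("numEdges", "DependencyGraph", function(x) nrow(x@edges))

setMethod("show", "DependencyGraph", function(object) {
    cat(sprintf("DependencyGraph with %d nodes and %d edges\n",
                numNodes(object), numEdges(object)))
    tab <- table(factor(object@nodes$role, levels = .VALID_ROLES))
    tab <- tab[tab > 0]
    if (length(tab))
        cat("  roles:", paste(sprintf("%s=%d", names(tab), tab),
                              collapse = ", "), "\n")
    sc <- unique(object@nodes$scale)
    if (length(sc) > 1L || any(sc != 0L))
        cat("  scales:", paste(sort(sc), collapse = ", "), "\n")
    invisible(NULL)
})

#' Accessors for BlanketPartition
#'
#' Return the id sets of a partition. `blanketStates` is the union of sensory
#' and active states.
#'
#' @param x a [BlanketPartition-class].
#' @return Character vector of node ids.
#' @name BlanketPartition-accessors
#' @aliases internalStates sensoryStates activeStates externalStates
#'   blanketStates
NULL

#' @rdname BlanketPartition-accessors
#' @export
setMethod("internalStates", "BlanketPartition", function(x) x@internal)

#' @rdname BlanketPartition-accessors
#' @export
setMethod("sensoryStates", "BlanketPartition", function(x) x@sensory)

#' @rdname BlanketPartition-accessors
#' @export
setMethod("activeStates", "BlanketPartition", function(x) x@active)

#' @rdname BlanketPartition-accessors
#' @export
setMethod("externalStates", "BlanketPartition", function(x) x@external)

#' @rdname BlanketPartition-accessors
#' @export
setMethod("blanketStates", "BlanketPartition",
    function(x) c(x@sensory, x@active))

setMethod("show", "BlanketPartition", function(object) {
    fmt <- function(v) if (length(v)) paste(v, collapse = ", ") else "(none)"
    cat("BlanketPartition\n")
    cat("  internal:", fmt(object@internal), "\n")
    cat("  sensory: ", fmt(object@sensory), "\n")
    cat("  active:  ", fmt(object@active), "\n")
    cat("  external:", fmt(object@external), "\n")
    invisible(NULL)
})

#' Accessors for DynamicalModel
#'
#' @param x a [DynamicalModel-class].
#' @return `stateLabels`/`inputLabels`: character vectors; `modelGraph`: the
#'   declared [DependencyGraph-class]; `modelParams`: named list;
#'   `noiseAmplitudes`: named numeric vector.
#' @name DynamicalModel-accessors
#' @aliases stateLabels inputLabels modelGraph modelParams noiseAmplitudes
NULL

#' @rdname DynamicalModel-accessors
#' @export
setMethod("stateLabels", "DynamicalModel", function(x) x@stateLabels)

#' @rdname DynamicalModel-accessors
#' @export
setMethod("inputLabels", "DynamicalModel", function(x) x@inputLabels)

#' @rdname DynamicalModel-accessors
#' @export
setMethod("modelGraph", "DynamicalModel", function(x) x@graph)

#' @rdname DynamicalModel-accessors
#' @export
setMethod("modelParams", "DynamicalModel", function(x) x@params)

#' @rdname DynamicalModel-accessors
#' @export
setMethod("noiseAmplitudes", "DynamicalModel", function(x) x@noise)

setMethod("show", "DynamicalModel", function(object) {
    cat(sprintf("DynamicalModel \"%s\": %d states, %d inputs, %d declared edges\n",
                object@name, length(object@stateLabels),
                length(object@inputLabels), numEdges(object@graph)))
    cat("  states:",
        paste(utils::head(object@stateLabels, 8), collapse = ", "),
        if (length(object@stateLabels) > 8) "...", "\n")
    cat("  noise: ", if (all(object@noise == 0)) "none (deterministic)"
        else paste0("additive diagonal, max amplitude ",
                    format(max(object@noise))), "\n")
    invisible(NULL)
})

#' Accessors for Trajectory
#'
#' @param x a [Trajectory-class].
#' @return `trajectoryStates`: the (time x state) matrix; `trajectoryTimes`:
#'   the time grid.
#' @name Trajectory-accessors
#' @aliases trajectoryStates trajectoryTimes
NULL

#' @rdname Trajectory-accessors
#' @export
setMethod("trajectoryStates", "Trajectory", function(x) x@states)

#' @rdname Trajectory-accessors
#' @export
setMethod("trajectoryTimes", "Trajectory", function(x) x@times)

setMethod("show", "Trajectory", function(object) {
    cat(sprintf("Trajectory of \"%s\": %d steps of dt = %g (%s), seed %d\n",
                object@modelName, length(object@times) - 1L, object@dt,
                object@integrator, object@seed))
    invisible(NULL)
})

#' Accessors for CoarseGraining
#'
#' @param x a [CoarseGraining-class].
#' @return `groupMapping`: named character vector micro id -> macro label;
#'   `scaleIncrement`: integer.
#' @name CoarseGraining-accessors
#' @aliases groupMapping scaleIncrement
NULL

#' @rdname CoarseGraining-accessors
#' @export
setMethod("groupMapping", "CoarseGraining", function(x) x@mapping)

#' @rdname CoarseGraining-accessors
#' @export
setMethod("scaleIncrement", "CoarseGraining", function(x) x@scaleIncrement)

setMethod("show", "CoarseGraining", function(object) {
    cat(sprintf("CoarseGraining: %d micro nodes -> %d macro units (+%d scale)\n",
                length(object@mapping), length(unique(object@mapping)),
                object@scaleIncrement))
    invisible(NULL)
})

#' Accessors for CITestResult
#'
#' @param x a [CITestResult-class].
#' @return `pValue`: numeric; `verdict`: `"accept"` or `"reject"`.
#' @name CITestResult-accessors
#' @aliases pValue verdict
NULL

#' @rdname CITestResult-accessors
#' @export
setMethod("pValue", "CITestResult", function(x) x@pValue)

#' @rdname CITestResult-accessors
#' @export
setMethod("verdict", "CITestResult", function(x) x@verdict)

setMethod("show", "CITestResult", function(object) {
    cat(sprintf(
        "CITestResult: %s (p = %.4g at alpha = %g; stat = %.4g, dof = %g/%g, n = %d)\n",
        object@verdict, object@pValue, object@alpha, object@statistic,
        object@dof[1], object@dof[2], object@nSamples))
    cat(sprintf("  predicted {%s} | conditioned {%s} + candidate {%s}\n",
                paste(object@triple$predicted, collapse = ", "),
                paste(object@triple$conditioning, collapse = ", "),
                paste(object@triple$candidate, collapse = ", ")))
    invisible(NULL)
})
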