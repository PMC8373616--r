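#' @include fixtures.R
NULL

#' Coarse-grain a dependency graph into macro-units
#'
#' Collapses every group of micro nodes into one macro node and draws a
#' macro edge `A -> B` whenever any micro edge runs from a node of `A` to a
#' node of `B` with `A != B` (within-group edges disappear; macro edges are
#' existential, not weighted). The macro scale is the maximum micro scale
#' plus the grouping's scale increment. A macro node inherits a role (or an
#' edge a sign) only when all its members agree; otherwise it is
#' `unassigned` (`unsigned`).
#'
#' @param graph a [DependencyGraph-class].
#' @param grouping a [CoarseGraining-class] covering every node of `graph`.
#' @return A [DependencyGraph-class] over the macro labels.
#' @export
coarseGrain <- function(graph, grouping) {
    map <- grouping@mapping
    ids <- graph@nodes$id
    missing <- setdiff(ids, names(map))
    if (length(missing))
        stop("grouping does not cover node(s): ",
             paste(missing, collapse = ", "))
    macro <- unique(unname(map[ids]))
    memberRole <- function(lbl) {
        r <- unique(graph@nodes$role[map[ids] == lbl])
        if (length(r) == 1L) r else "unassigned"
    }
    nodes <- data.frame(
        id = macro,
        role = vapply(macro, memberRole, character(1)),
        scale = max(graph@nodes$scale) + grouping@scaleIncrement,
        group = NA_character_, stringsAsFactors = FALSE)
    ed <- graph@edges
    edges <- NULL
    if (nrow(ed)) {
        mf <- unname(map[ed$from])
        mt <- unname(map[ed$to])
        keep <- mf != mt
        if (any(keep)) {
            key <- paste(mf[keep], mt[keep], sep = "\r")
            sgn <- vapply(split(ed$sign[keep], key), function(s)
                if (length(unique(s)) == 1L) s[[1]] else "unsigned",
                character(1))
            uk <- names(sgn)
            parts <- strsplit(uk, "\r", fixed = TRUE)
            edges <- data.frame(from = vapply(parts, `[`, "", 1),
                                to = vapply(parts, `[`, "", 2),
                                sign = unname(sgn), stringsAsFactors = FALSE)
        }
    }
    DependencyGraph(nodes, edges)
}

#' Compose two coarse grainings
#'
#' Returns the single grouping equivalent to applying `first` and then
#' `second`; [coarseGrain()] is functorial over this composition.
#'
#' @param first,second [CoarseGraining-class] objects, `second` defined over
#'   `first`'s macro labels.
#' @return A [CoarseGraining-class] from `first`'s micro nodes with the
#'   summed scale increment.
#' @export
composeGroupings <- function(first, second) {
    missing <- setdiff(unique(unname(first@mapping)), names(second@mapping))
    if (length(missing))
        stop("second grouping does not cover macro label(s): ",
             paste(missing, collapse = ", "))
    CoarseGraining(structure(unname(second@mapping[first@mapping]),
                             names = names(first@mapping)),
                   first@scaleIncrement + second@scaleIncrement)
}

#' Identity (singleton) grouping of a graph
#'
#' @param graph a [DependencyGraph-class].
#' @param scaleIncrement integer >= 1.
#' @return A [CoarseGraining-class] mapping every node to itself.
#' @export
singletonGrouping <- function(graph, scaleIncrement = 1L) {
    ids <- graph@nodes$id
    CoarseGraining(structure(ids, names = ids), scaleIncrement)
}

#' Recursive blanket analysis across scales
#'
#' Applies a ladder of coarse grainings; at each resulting scale, takes the
#' user-chosen internal set, computes its Markov blanket on the macro graph
#' ([pearlBlanket()]), declares everything else external, classifies the
#' blanket into sensory and active states ([classifyBlanket()]) and
#' validates the assembled partition ([validatePartition()]). The internal
#' choice is deliberately user-specified at every scale: blanket role
#' assignments are equally valid with internal and external reversed, so no
#' automatic choice is attempted.
#'
#' @param graph the finest-scale [DependencyGraph-class].
#' @param groupings list of [CoarseGraining-class], each defined over the
#'   previous macro graph.
#' @param internals list (same length) of character vectors: the internal
#'   macro node set chosen at each scale.
#' @param ambiguousTo how to fold ambiguous blanket nodes into the partition
#'   for validation (see [classifyBlanket()]); default `"sensory"`.
#' @return list of per-scale records, each with elements `scale`, `graph`,
#'   `internal`, `blanket`, `classification`, `partition`, `violations`.
#' @export
nestedBlankets <- function(graph, groupings, internals,
                           ambiguousTo = "sensory") {
    if (length(groupings) != length(internals))
        stop("need one internal-set choice per grouping")
    ladder <- vector("list", length(groupings))
    g <- graph
    for (i in seq_along(groupings)) {
        g <- tryCatch(coarseGrain(g, groupings[[i]]), error = function(e)
            stop("grouping at scale step ", i, " does not compose: ",
                 conditionMessage(e), call. = FALSE))
        internal <- internals[[i]]
        .checkIds(g, internal)
        blanket <- pearlBlanket(g, internal)
        external <- setdiff(g@nodes$id, c(internal, blanket))
        cls <- classifyBlanket(g, internal, external,
                               ambiguousTo = ambiguousTo)
        ## ambiguous nodes are folded inside classifyBlanket unless the
        ## caller asked for a report, in which case they default to sensory
        ## for the purpose of assembling a full partition
        part <- BlanketPartition(
            internal = internal,
            sensory = c(cls$sensory, cls$ambiguous),
            active = cls$active,
            external = external)
        viol <- validatePartition(g, part)
        ladder[[i]] <- list(scale = unique(g@nodes$scale), graph = g,
                            internal = internal, blanket = blanket,
                            classification = cls, partition = part,
                            violations = viol)
    }
    ladder
}

#' Does a macro-level blanket hold at the micro level?
#'
#' Soundness bridge between scales: given a grouping and a partition of the
#' macro graph, checks on the one-step unrolled *micro* graph that the micro
#' states of the macro-autonomous set (internal and active, the states not
#' influenced by external ones) at time `t+dt` are d-separated from the
#' micro states of the macro-external set at time `t`, given the time-`t`
#' micro states of the internal set and blanket. A valid macro partition
#' whose micro graph hides no forbidden influence passes; a single gained
#' micro edge from an external-group node into an active-group (or
#' internal-group) node breaks it.
#'
#' @param microGraph the fine-scale [DependencyGraph-class].
#' @param grouping the [CoarseGraining-class] used to build the macro graph.
#' @param macroPartition a [BlanketPartition-class] over the macro labels.
#' @return `TRUE` if the one-step conditional independence holds.
#' @export
macroCICheck <- function(microGraph, grouping, macroPartition) {
    map <- grouping@mapping
    micro <- function(lbls) names(map)[map %in% lbls]
    int <- micro(macroPartition@internal)
    ext <- micro(macroPartition@external)
    bl <- micro(blanketStates(macroPartition))
    auto <- c(int, micro(macroPartition@active))
    if (!length(auto) || !length(ext)) return(TRUE)
    un <- unrollOneStep(microGraph)
    dSeparated(un,
               A = sliceIds(auto, "t1"),
               B = sliceIds(ext, "t"),
               C = c(sliceIds(int, "t"), sliceIds(bl, "t")))
}
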