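#' @include accessors.R
NULL

## ---- basic graph queries ----------------------------------------------------

#' Parents and children of a node set
#'
#' @param graph a [DependencyGraph-class].
#' @param ids character vector of node ids.
#' @return Character vector of ids (excluding none; may overlap `ids`).
#' @export
parentsOf <- function(graph, ids) {
    .checkIds(graph, ids)
    ed <- graph@edges
    unique(ed$from[ed$to %in% ids])
}

#' @rdname parentsOf
#' @export
childrenOf <- function(graph, ids) {
    .checkIds(graph, ids)
    ed <- graph@edges
    unique(ed$to[ed$from %in% ids])
}

.checkIds <- function(graph, ids) {
    bad <- setdiff(ids, graph@nodes$id)
    if (length(bad))
        stop("unknown node id(s): ", paste(bad, collapse = ", "))
    invisible(TRUE)
}

## adjacency matrix (no self-loops), rows = parents, cols = children
.adjacency <- function(graph) {
    ids <- graph@nodes$id
    n <- length(ids)
    M <- matrix(FALSE, n, n, dimnames = list(ids, ids))
    if (nrow(graph@edges))
        M[cbind(match(graph@edges$from, ids), match(graph@edges$to, ids))] <- TRUE
    M
}

.isAcyclicAdj <- function(M) {
    ## Kahn's algorithm on a logical adjacency matrix
    n <- nrow(M)
    if (n == 0L) return(TRUE)
    indeg <- colSums(M)
    alive <- rep(TRUE, n)
    repeat {
        src <- which(alive & indeg == 0)
        if (!length(src)) break
        for (v in src) {
            indeg <- indeg - M[v, ]
            alive[v] <- FALSE
        }
    }
    !any(alive)
}

#' Is the dependency graph acyclic?
#'
#' Ignores the implicit self-dependence of every state (self-loops are never
#' stored), so this asks whether the stored between-state influences contain a
#' directed cycle.
#'
#' @param graph a [DependencyGraph-class].
#' @return `TRUE` or `FALSE`.
#' @export
isAcyclic <- function(graph) .isAcyclicAdj(.adjacency(graph))

## ---- Pearl blanket ----------------------------------------------------------

#' Markov blanket of a node set (Pearl's definition)
#'
#' The Markov blanket of a target set is the union of its parents, its
#' children, and the other parents of its children (co-parents), minus the
#' targets themselves. On a directed acyclic graph this is exactly the minimal
#' conditioning set that d-separates the targets from all remaining nodes.
#'
#' @param graph a [DependencyGraph-class].
#' @param targets character vector of node ids.
#' @return Character vector of blanket node ids (possibly empty), in graph
#'   node order.
#' @examples
#' g <- DependencyGraph(as.character(1:6),
#'   edges = rbind(c("1","3"), c("2","3"), c("3","4"), c("5","4"), c("4","6")))
#' pearlBlanket(g, "3")  # parents 1,2; child 4; co-parent 5
#' @export
pearlBlanket <- function(graph, targets) {
    .checkIds(graph, targets)
    ch <- childrenOf(graph, targets)
    bl <- unique(c(parentsOf(graph, targets), ch, parentsOf(graph, ch)))
    ids <- graph@nodes$id
    ids[ids %in% setdiff(bl, targets)]
}

## ---- partition validation ---------------------------------------------------

## the four influences forbidden by the blanket flow constraints
.FORBIDDEN <- data.frame(
    fromRole = c("internal", "internal", "external", "external"),
    toRole   = c("sensory",  "external", "active",   "internal"),
    rule     = c("internal->sensory", "internal->external",
                 "external->active",  "external->internal"),
    stringsAsFactors = FALSE)

.emptyViolations <- function()
    data.frame(from = character(), to = character(), rule = character(),
               stringsAsFactors = FALSE)

#' Validate a blanket partition against a dependency graph
#'
#' Checks the defining sparsity of a Markov blanket partition: the flows of
#' internal and external states must not depend on one another, internal
#' states cannot influence sensory states, and external states cannot
#' influence active states. Every edge violating one of the four exclusions
#' (internal->sensory, internal->external, external->active,
#' external->internal) is returned. Losing edges can never create a violation
#' (the check is monotone in the edge set), matching the principle that
#' blanket structure survives lost dependencies but not gained ones.
#'
#' @param graph a [DependencyGraph-class].
#' @param partition a [BlanketPartition-class] whose four sets together must
#'   cover exactly the graph's nodes.
#' @return data.frame with columns `from`, `to`, `rule`; zero rows iff the
#'   partition satisfies the blanket sparsity.
#' @export
validatePartition <- function(graph, partition) {
    ids <- graph@nodes$id
    all4 <- c(partition@internal, partition@sensory, partition@active,
              partition@external)
    if (anyDuplicated(all4))
        stop("partition sets are not disjoint: ",
             paste(unique(all4[duplicated(all4)]), collapse = ", "))
    if (length(setdiff(all4, ids)))
        stop("partition mentions nodes not in the graph: ",
             paste(setdiff(all4, ids), collapse = ", "))
    if (length(setdiff(ids, all4)))
        stop("partition does not cover the graph; missing: ",
             paste(setdiff(ids, all4), collapse = ", "))
    role <- character(length(ids))
    names(role) <- ids
    role[partition@internal] <- "internal"
    role[partition@sensory] <- "sensory"
    role[partition@active] <- "active"
    role[partition@external] <- "external"
    ed <- graph@edges
    if (!nrow(ed)) return(.emptyViolations())
    fr <- role[ed$from]
    tr <- role[ed$to]
    hit <- match(paste(fr, tr), paste(.FORBIDDEN$fromRole, .FORBIDDEN$toRole))
    keep <- !is.na(hit)
    data.frame(from = ed$from[keep], to = ed$to[keep],
               rule = .FORBIDDEN$rule[hit[keep]],
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a partition from node roles stored in a graph
#'
#' Convenience: reads the `role` attribute of every node. All nodes must have
#' one of the four blanket roles (no `unassigned`).
#'
#' @param graph a [DependencyGraph-class].
#' @return A [BlanketPartition-class].
#' @export
partitionFromRoles <- function(graph) {
    r <- nodeRoles(graph)
    if (any(r == "unassigned"))
        stop("nodes with unassigned roles: ",
             paste(names(r)[r == "unassigned"], collapse = ", "))
    BlanketPartition(internal = names(r)[r == "internal"],
                     sensory = names(r)[r == "sensory"],
                     active = names(r)[r == "active"],
                     external = names(r)[r == "external"])
}

## ---- sensory/active classification ------------------------------------------

#' Classify blanket states as sensory or active
#'
#' Given a choice of internal and external sets, the blanket (everything else)
#' splits according to who influences each blanket node: a node with a parent
#' in the internal set (and none in the external set) can only be an active
#' state; a node with a parent in the external set (and none internal) can
#' only be sensory; a node with parents in both cannot satisfy the blanket
#' flow constraints and is reported as a violation; a node with parents in
#' neither is ambiguous -- either assignment is consistent -- and is reported
#' rather than silently assigned (set `ambiguousTo` to force an assignment).
#'
#' @param graph a [DependencyGraph-class].
#' @param internal,external disjoint character vectors of node ids; the
#'   blanket is all remaining nodes.
#' @param ambiguousTo `"report"` (default) keeps ambiguous nodes separate;
#'   `"sensory"` or `"active"` folds them into that set.
#' @return list with components `sensory`, `active`, `ambiguous` (character
#'   vectors) and `violations` (data.frame as in [validatePartition()]).
#'   When `violations` has zero rows, the three vectors partition the blanket.
#' @export
classifyBlanket <- function(graph, internal, external,
                            ambiguousTo = c("report", "sensory", "active")) {
    ambiguousTo <- match.arg(ambiguousTo)
    .checkIds(graph, c(internal, external))
    if (length(intersect(internal, external)))
        stop("internal and external sets are not disjoint: ",
             paste(intersect(internal, external), collapse = ", "))
    ids <- graph@nodes$id
    blanket <- setdiff(ids, c(internal, external))
    ed <- graph@edges
    sensory <- character(); active <- character(); ambiguous <- character()
    viol <- .emptyViolations()
    for (b in blanket) {
        pa <- ed$from[ed$to == b]
        paInt <- intersect(pa, internal)
        paExt <- intersect(pa, external)
        if (length(paInt) && length(paExt)) {
            ## whichever half b joins, one exclusion breaks: as sensory it
            ## would be influenced by internal states, as active by external
            viol <- rbind(viol,
                data.frame(from = c(paInt, paExt), to = b,
                           rule = rep(c("internal->sensory", "external->active"),
                                      c(length(paInt), length(paExt))),
                           stringsAsFactors = FALSE))
        } else if (length(paInt)) {
            active <- c(active, b)
        } else if (length(paExt)) {
            sensory <- c(sensory, b)
        } else {
            ambiguous <- c(ambiguous, b)
        }
    }
    if (ambiguousTo == "sensory") {
        sensory <- c(sensory, ambiguous); ambiguous <- character()
    } else if (ambiguousTo == "active") {
        active <- c(active, ambiguous); ambiguous <- character()
    }
    list(sensory = ids[ids %in% sensory], active = ids[ids %in% active],
         ambiguous = ids[ids %in% ambiguous], violations = viol)
}

## ---- d-separation -----------------------------------------------------------

## d-separation on a logical adjacency matrix via the moralized ancestral
## graph: A _||_ B | C iff A and B are disconnected in the moralization of the
## subgraph induced on ancestors(A u B u C), after deleting C.
.dsepAdj <- function(M, A, B, C) {
    n <- nrow(M)
    want <- rep(FALSE, n)
    want[c(A, B, C)] <- TRUE
    ## ancestral closure by reverse reachability
    anc <- want
    repeat {
        more <- (M %*% anc > 0) & !anc   # parents of current set
        if (!any(more)) break
        anc <- anc | more
    }
    idx <- which(anc)
    S <- M[idx, idx, drop = FALSE]
    U <- S | t(S) | ((S %*% t(S)) > 0)   # moralize: link co-parents
    diag(U) <- FALSE
    pos <- match(seq_len(n), idx)
    keep <- setdiff(seq_along(idx), pos[C])
    U <- U[keep, keep, drop = FALSE]
    start <- match(pos[A], keep)
    targ <- match(pos[B], keep)
    reach <- rep(FALSE, nrow(U))
    reach[start] <- TRUE
    repeat {
        more <- (crossprod(U, reach) > 0) & !reach
        if (!any(more)) break
        reach <- reach | more
    }
    !any(reach[targ])
}

#' d-separation on an acyclic dependency graph
#'
#' Decides whether node sets `A` and `B` are d-separated given `C`, i.e.
#' whether the graph implies the conditional independence of `A` and `B`
#' given `C`. Implemented by moralizing the ancestral subgraph of
#' `AivBivC` and testing undirected separation, which is equivalent to
#' path-based d-separation. Symmetric in `A` and `B`.
#'
#' Only meaningful on acyclic graphs; flow graphs of dynamical systems are
#' generally cyclic and must first be converted to their one-step time-slice
#' form with [unrollOneStep()].
#'
#' @param graph an acyclic [DependencyGraph-class].
#' @param A,B,C disjoint character vectors of node ids (`C` may be empty).
#' @return `TRUE` if `A` and `B` are d-separated given `C`.
#' @examples
#' chain <- DependencyGraph(c("a","b","c"), rbind(c("a","b"), c("b","c")))
#' dSeparated(chain, "a", "c", "b")   # TRUE: blocked chain
#' coll <- DependencyGraph(c("a","b","c"), rbind(c("a","b"), c("c","b")))
#' dSeparated(coll, "a", "c", "b")    # FALSE: conditioning opens the collider
#' @export
dSeparated <- function(graph, A, B, C = character()) {
    .checkIds(graph, c(A, B, C))
    if (length(intersect(A, B)) || length(intersect(A, C)) ||
        length(intersect(B, C)))
        stop("A, B and C must be disjoint")
    M <- .adjacency(graph)
    if (!.isAcyclicAdj(M))
        stop("graph is cyclic; d-separation is defined on acyclic graphs -- ",
             "use unrollOneStep() to obtain the one-step time-slice graph")
    ids <- graph@nodes$id
    .dsepAdj(M, match(A, ids), match(B, ids), match(C, ids))
}

## ---- one-step unrolling -----------------------------------------------------

#' Unroll a flow graph into its one-step time-slice graph
#'
#' Converts the (generally cyclic) dependency graph of a dynamical system
#' into an acyclic two-slice graph with nodes `x_t` and `x_t1` for every
#' state `x`: `x_t1` has parents `{y_t : y -> x}` plus `x_t` itself (the
#' implicit self-dependence of every flow). Conditional-independence
#' statements about the flow constraints are then d-separation statements on
#' this graph.
#'
#' @param graph a [DependencyGraph-class].
#' @return An acyclic [DependencyGraph-class] with `2 * numNodes(graph)`
#'   nodes; roles, scales and groups are inherited by both copies.
#' @export
unrollOneStep <- function(graph) {
    nd <- graph@nodes
    ed <- graph@edges
    nodes <- data.frame(
        id = c(paste0(nd$id, "_t"), paste0(nd$id, "_t1")),
        role = rep(nd$role, 2), scale = rep(nd$scale, 2),
        group = rep(nd$group, 2), stringsAsFactors = FALSE)
    p0 <- function(x, suf) if (length(x)) paste0(x, suf) else character()
    edges <- data.frame(
        from = c(p0(ed$from, "_t"), p0(nd$id, "_t")),
        to = c(p0(ed$to, "_t1"), p0(nd$id, "_t1")),
        sign = c(ed$sign, rep("unsigned", nrow(nd))),
        stringsAsFactors = FALSE)
    DependencyGraph(nodes, edges)
}

#' Time-slice node names
#'
#' Helper mapping node ids to their names in the unrolled one-step graph.
#'
#' @param ids character vector of node ids.
#' @param slice `"t"` or `"t1"`.
#' @return Character vector of unrolled ids.
#' @export
sliceIds <- function(ids, slice = c("t", "t1")) {
    slice <- match.arg(slice)
    paste0(ids, "_", slice)
}
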