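## Independent oracles used to cross-check the package's graph algorithms.
## These deliberately use brute-force path enumeration, not the package's
## moralization-based implementation.

## all simple undirected paths between a and b in the skeleton of the DAG
.allPaths <- function(edges, a, b, nodes) {
    nbr <- lapply(stats::setNames(nodes, nodes), function(v)
        unique(c(edges$to[edges$from == v], edges$from[edges$to == v])))
    paths <- list()
    grow <- function(path) {
        last <- path[length(path)]
        if (last == b) {
            paths[[length(paths) + 1L]] <<- path
            return(invisible(NULL))
        }
        for (nx in setdiff(nbr[[last]], path)) grow(c(path, nx))
    }
    grow(a)
    paths
}

.descendants <- function(edges, v) {
    out <- character()
    frontier <- v
    while (length(frontier)) {
        nxt <- setdiff(unique(edges$to[edges$from %in% frontier]), out)
        out <- c(out, nxt)
        frontier <- nxt
    }
    out
}

## d-separation verdict by explicit enumeration of all paths and the
## chain/fork/collider blocking rules
oracleDsep <- function(graph, A, B, C) {
    ed <- edgeTable(graph)
    nodes <- nodeIds(graph)
    hasEdge <- function(x, y) any(ed$from == x & ed$to == y)
    for (a in A) for (b in B) {
        for (path in .allPaths(ed, a, b, nodes)) {
            if (length(path) == 2L) return(FALSE)  # direct edge, never blocked
            blocked <- FALSE
            for (k in 2:(length(path) - 1L)) {
                v <- path[k]
                into1 <- hasEdge(path[k - 1L], v)
                into2 <- hasEdge(path[k + 1L], v)
                if (into1 && into2) {           # collider
                    if (!(v %in% C) && !any(.descendants(ed, v) %in% C)) {
                        blocked <- TRUE; break
                    }
                } else if (v %in% C) {          # chain or fork
                    blocked <- TRUE; break
                }
            }
            if (!blocked) return(FALSE)
        }
    }
    TRUE
}

## minimal d-separating sets of {v} from all remaining nodes, by subset
## search in order of size; returns the character vectors of minimum size
## that separate (unique for DAGs: the Markov boundary)
minimalSeparators <- function(graph, v, dsep = NULL) {
    ids <- nodeIds(graph)
    others <- setdiff(ids, v)
    M <- MarkovBlankets:::.adjacency(graph)
    test <- function(S) {
        B <- setdiff(others, S)
        if (!length(B)) return(TRUE)
        MarkovBlankets:::.dsepAdj(M, match(v, ids), match(B, ids),
                                  match(S, ids))
    }
    for (size in 0:length(others)) {
        hits <- list()
        combos <- utils::combn(others, size, simplify = FALSE)
        for (S in combos) if (test(S)) hits[[length(hits) + 1L]] <- S
        if (length(hits)) return(hits)
    }
    list()
}

## every DAG whose edges respect the natural order 1 < 2 < ... < n
## (relabelling symmetry covers all labelled DAGs)
orderedDagEdgeSets <- function(n) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    nP <- nrow(pairs)
    lapply(seq_len(2^nP) - 1L, function(mask) {
        keep <- bitwAnd(mask, bitwShiftL(1L, seq_len(nP) - 1L)) != 0L
        pairs[keep, , drop = FALSE]
    })
}

## documented blanket partitions for the shipped model zoo
zooPartitions <- function() {
    cmc2 <- cmcChain(2)
    cmc4 <- cmcChain(4)
    cmc1 <- cmcChain(1)
    sc <- springChain(5)
    list(
        hodgkin_huxley = list(model = hodgkinHuxley(),
            partition = partitionFromRoles(modelGraph(hodgkinHuxley()))),
        classic_hh = list(model = classicHodgkinHuxley(),
            partition = partitionFromRoles(modelGraph(classicHodgkinHuxley()))),
        fitzhugh_nagumo = list(model = fitzhughNagumo(),
            partition = partitionFromRoles(modelGraph(fitzhughNagumo()))),
        morris_lecar = list(model = morrisLecar(),
            partition = partitionFromRoles(modelGraph(morrisLecar()))),
        neural_mass_pair = list(model = neuralMassPair(),
            partition = partitionFromRoles(modelGraph(neuralMassPair()))),
        cmc_chain_1 = list(model = cmc1,
            partition = BlanketPartition(internal = stateLabels(cmc1))),
        cmc_chain_2 = list(model = cmc2,
            partition = BlanketPartition(
                internal = cmcStates(cmc2, c("SS", "II"), 1),
                active = cmcStates(cmc2, c("SP", "DP"), 1),
                sensory = cmcStates(cmc2, c("SP", "DP"), 2),
                external = cmcStates(cmc2, c("SS", "II"), 2))),
        cmc_chain_4 = list(model = cmc4,
            partition = BlanketPartition(
                internal = cmcStates(cmc4, column = 1),
                active = cmcStates(cmc4, column = 2),
                sensory = cmcStates(cmc4, column = 3),
                external = cmcStates(cmc4, column = 4))),
        spring_chain = list(model = sc,
            partition = springChainPartition(sc, 3)))
}

## graph equality up to row order
expect_same_graph <- function(a, b) {
    expect_setequal(nodeIds(a), nodeIds(b))
    expect_equal(nodeRoles(a)[sort(nodeIds(a))], nodeRoles(b)[sort(nodeIds(b))])
    ea <- edgeTable(a); eb <- edgeTable(b)
    expect_setequal(paste(ea$from, ea$to), paste(eb$from, eb$to))
}
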