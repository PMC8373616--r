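test_that("randomDAG is acyclic, seeded and edge-probability faithful", {
    expect_identical(numEdges(randomDAG(6, 0, seed = 1)), 0L)
    full <- randomDAG(3, 1, seed = 2)
    expect_identical(numEdges(full), 3L)   # complete transitive tournament
    expect_true(isAcyclic(full))
    g1 <- randomDAG(10, 0.3, seed = 9)
    g2 <- randomDAG(10, 0.3, seed = 9)
    expect_identical(g1@edges, g2@edges)
    for (s in 1:20) expect_true(isAcyclic(randomDAG(8, 0.5, seed = s)))
    expect_error(randomDAG(0, 0.5), "n must be")
    expect_error(randomDAG(3, 1.5), "p must lie")
})

test_that("randomBlanketSystem has exact template sparsity and stability", {
    for (s in 1:20) {
        sys <- randomBlanketSystem(seed = s)
        g <- modelGraph(sys)
        p <- partitionFromRoles(g)
        expect_identical(nrow(validatePartition(g, p)), 0L)
        J <- sys@params$J
        roles <- nodeRoles(g)[rownames(J)]
        ## forbidden drift blocks are exactly zero
        expect_true(all(J[roles == "sensory", roles == "internal"] == 0))
        expect_true(all(J[roles == "external", roles == "internal"] == 0))
        expect_true(all(J[roles == "active", roles == "external"] == 0))
        expect_true(all(J[roles == "internal", roles == "external"] == 0))
        ## stability margin allows the Lyapunov solve
        expect_lte(max(Re(eigen(J, only.values = TRUE)$values)), -0.1 + 1e-9)
        expect_silent(stationaryCovariance(J, diag(nrow(J))))
    }
    s1 <- randomBlanketSystem(seed = 5)
    s2 <- randomBlanketSystem(seed = 5)
    expect_identical(s1@params$J, s2@params$J)
    expect_error(randomBlanketSystem(nSensory = 0), "block sizes")
})

test_that("perturbAddEdge gains exactly one influence, seeded, non-mutating", {
    sys <- randomBlanketSystem(seed = 4)
    before <- numEdges(modelGraph(sys))
    pert <- perturbAddEdge(sys, "external", "active", weight = 0.5, seed = 2)
    expect_identical(numEdges(modelGraph(sys)), before)   # original untouched
    expect_identical(numEdges(modelGraph(pert)), before + 1L)
    v <- validatePartition(modelGraph(pert),
                           partitionFromRoles(modelGraph(sys)))
    expect_identical(nrow(v), 1L)
    expect_identical(v$rule, "external->active")
    e <- attr(pert, "addedEdge")
    expect_identical(unname(sys@params$J[e["to"], e["from"]]), 0)
    expect_identical(unname(pert@params$J[e["to"], e["from"]]), 0.5)

    ## an allowed addition creates no violation
    ok <- perturbAddEdge(sys, "sensory", "internal", seed = 3)
    expect_identical(nrow(validatePartition(modelGraph(ok),
        partitionFromRoles(modelGraph(sys)))), 0L)

    ## a zero-weight gained edge is structurally present but dynamically null
    z <- perturbAddEdge(sys, "external", "internal", weight = 0, seed = 6)
    expect_identical(numEdges(modelGraph(z)), before + 1L)
    expect_identical(z@params$J[z@params$J != sys@params$J], numeric(0))

    expect_error(perturbAddEdge(modelGraph(sys), "unassigned", "active"),
                 "no nodes with role")
})

test_that("spring chain realizes the Newtonian blanket and its invariants", {
    sc <- springChain(5)
    g <- modelGraph(sc)
    ## middle particle: own position active, neighbour positions sensory
    cls <- classifyBlanket(g, internal = "mu3",
                           external = setdiff(nodeIds(g),
                               c("mu3", pearlBlanket(g, "mu3"))))
    expect_identical(cls$active, "a3")
    expect_setequal(cls$sensory, c("a2", "a4"))
    expect_identical(nrow(validatePartition(g, springChainPartition(sc, 3))),
                     0L)
    ## momentum parents are positions; position parents own momentum only
    expect_setequal(parentsOf(g, "mu3"), c("a2", "a3", "a4"))
    expect_setequal(parentsOf(g, "a3"), "mu3")

    ## free chain conserves total momentum along RK4 trajectories
    init <- structure(c(0.3, 0.5, -0.2, -1, 0.1, 0.4, 0, 0.2, -0.1, 0.3),
                      names = stateLabels(sc))
    tr <- integrateModel(sc, init, tEnd = 20, dt = 0.005)
    mom <- springChainMomentum(sc, trajectoryStates(tr))
    expect_lt(max(abs(mom - mom[1])), 1e-10)
    ## and energy to RK4 tolerance
    en <- springChainEnergy(sc, trajectoryStates(tr))
    expect_lt(max(abs(en - en[1])) / en[1], 1e-8)

    ## the role-collapsed graph instantiates the same blanket template as
    ## the neural-mass pair: identical mediating dependencies, no forbidden
    ## ones
    collapse <- function(graph, part) {
        roles <- c(structure(rep("internal", length(part@internal)),
                             names = part@internal),
                   structure(rep("sensory", length(part@sensory)),
                             names = part@sensory),
                   structure(rep("active", length(part@active)),
                             names = part@active),
                   structure(rep("external", length(part@external)),
                             names = part@external))
        cg <- coarseGrain(graph, CoarseGraining(roles[nodeIds(graph)]))
        paste(edgeTable(cg)$from, edgeTable(cg)$to)
    }
    scEdges <- collapse(g, springChainPartition(sc, 3))
    nm <- neuralMassPair()
    nmEdges <- collapse(modelGraph(nm), partitionFromRoles(modelGraph(nm)))
    mediating <- c("internal active", "active internal", "sensory internal",
                   "active external", "external sensory")
    expect_true(all(nmEdges %in% scEdges))
    expect_true(all(mediating %in% scEdges))
    forbidden <- c("internal sensory", "internal external",
                   "external active", "external internal")
    expect_false(any(forbidden %in% scEdges))
    expect_false(any(forbidden %in% nmEdges))

    expect_error(springChain(1), "n must be")
    expect_error(springChain(3, masses = c(1, -1, 1)), "masses must be")
})

test_that("the network-level fixture validates as documented", {
    g <- networkBlanketGraph()
    p <- partitionFromRoles(g)
    expect_identical(nrow(validatePartition(g, p)), 0L)
    expect_setequal(internalStates(p), c("VIS1", "VIS2"))
    expect_setequal(activeStates(p), c("DAN", "VAN"))
    expect_identical(sensoryStates(p), "DMN")
    expect_identical(externalStates(p), "SMN")
    ## reversing internal and external still yields a valid partition with
    ## sensory and active exchanged
    rev <- BlanketPartition(internal = "SMN", sensory = c("DAN", "VAN"),
                            active = "DMN", external = c("VIS1", "VIS2"))
    expect_identical(nrow(validatePartition(g, rev)), 0L)
})
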