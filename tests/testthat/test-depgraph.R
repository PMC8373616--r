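test_that("pearlBlanket returns parents, children and co-parents", {
    g <- DependencyGraph(as.character(1:6),
        edges = rbind(c("1", "3"), c("2", "3"), c("3", "4"), c("5", "4"),
                      c("4", "6")))
    expect_setequal(pearlBlanket(g, "3"), c("1", "2", "4", "5"))
    lone <- DependencyGraph(c("x", "a", "b"), rbind(c("a", "b")))
    expect_length(pearlBlanket(lone, "x"), 0)
    expect_length(pearlBlanket(g, as.character(1:6)), 0)
    expect_error(pearlBlanket(g, "nope"), "nope")
})

test_that("validatePartition flags exactly the four forbidden edge types", {
    sys <- randomBlanketSystem(seed = 7)
    g <- modelGraph(sys)
    part <- partitionFromRoles(g)
    expect_identical(nrow(validatePartition(g, part)), 0L)

    ## gaining a forbidden edge creates exactly one violation, with the rule
    ## matching the endpoint roles
    forb <- list(c("external", "active", "external->active"),
                 c("external", "internal", "external->internal"),
                 c("internal", "sensory", "internal->sensory"),
                 c("internal", "external", "internal->external"))
    for (f in forb) {
        pg <- perturbAddEdge(g, f[1], f[2], seed = 11)
        v <- validatePartition(pg, part)
        expect_identical(nrow(v), 1L)
        expect_identical(v$rule, f[3])
    }
    ## allowed additions create none
    for (f in list(c("sensory", "internal"), c("active", "external"),
                   c("sensory", "active"), c("internal", "active"))) {
        pg <- perturbAddEdge(g, f[1], f[2], seed = 11)
        expect_identical(nrow(validatePartition(pg, part)), 0L)
    }
    ## losing an edge never creates a violation (monotonicity)
    ed <- edgeTable(g)
    si <- which(ed$from %in% sensoryStates(part) &
                ed$to %in% internalStates(part))[1]
    g2 <- g
    g2@edges <- ed[-si, ]
    expect_identical(nrow(validatePartition(g2, part)), 0L)

    ## k gained forbidden edges yield exactly k violations
    gk <- g
    for (k in 1:3)
        gk <- perturbAddEdge(gk, "internal", "external", seed = k)
    expect_identical(nrow(validatePartition(gk, part)), 3L)

    ## coverage errors are explicit
    bad <- BlanketPartition(internal = internalStates(part))
    expect_error(validatePartition(g, bad), "cover")
})

test_that("classifyBlanket assigns sensory and active by parental role", {
    m <- neuralMassPair()
    g <- modelGraph(m)
    cls <- classifyBlanket(g, internal = "g1", external = "g2")
    expect_identical(cls$sensory, "v2")   # presynaptic potential
    expect_identical(cls$active, "v1")    # postsynaptic depolarisation
    expect_identical(nrow(cls$violations), 0L)

    ## a blanket node with no internal or external parent is ambiguous
    g2 <- DependencyGraph(c("i", "b", "e"), rbind(c("b", "i"), c("b", "e")))
    cls2 <- classifyBlanket(g2, "i", "e")
    expect_identical(cls2$ambiguous, "b")
    expect_identical(classifyBlanket(g2, "i", "e",
                                     ambiguousTo = "sensory")$sensory, "b")

    ## parents in both halves cannot satisfy the flow constraints
    g3 <- DependencyGraph(c("i", "b", "e"), rbind(c("i", "b"), c("e", "b")))
    cls3 <- classifyBlanket(g3, "i", "e")
    expect_identical(nrow(cls3$violations), 2L)
    expect_setequal(cls3$violations$rule,
                    c("internal->sensory", "external->active"))

    expect_error(classifyBlanket(g2, c("i", "b"), c("e", "b")), "disjoint")
})

test_that("classification swaps sensory/active when labels are reversed", {
    ## reversing the internal/external perspective must exchange the roles
    ## of the blanket states
    for (seed in 1:5) {
        sys <- randomBlanketSystem(seed = seed)
        g <- modelGraph(sys)
        p <- partitionFromRoles(g)
        a <- classifyBlanket(g, internalStates(p), externalStates(p))
        b <- classifyBlanket(g, externalStates(p), internalStates(p))
        expect_identical(a$sensory, b$active)
        expect_identical(a$active, b$sensory)
        expect_identical(a$ambiguous, b$ambiguous)
    }
    m <- neuralMassPair()
    sw <- classifyBlanket(modelGraph(m), "g2", "g1")
    expect_identical(sw$sensory, "v1")
    expect_identical(sw$active, "v2")
})

test_that("dSeparated matches path-enumeration on motifs and random DAGs", {
    chain <- DependencyGraph(c("a", "b", "c"),
                             rbind(c("a", "b"), c("b", "c")))
    expect_true(dSeparated(chain, "a", "c", "b"))
    expect_false(dSeparated(chain, "a", "c"))
    coll <- DependencyGraph(c("a", "b", "c"),
                            rbind(c("a", "b"), c("c", "b")))
    expect_false(dSeparated(coll, "a", "c", "b"))
    expect_true(dSeparated(coll, "a", "c"))
    g6 <- DependencyGraph(as.character(1:6),
        edges = rbind(c("1", "3"), c("2", "3"), c("3", "4"), c("5", "4"),
                      c("4", "6")))
    expect_true(dSeparated(g6, "3", "6", c("1", "2", "4", "5")))

    set.seed(42)
    for (rep in 1:60) {
        g <- randomDAG(6, 0.35, seed = rep)
        ids <- sample(nodeIds(g))
        A <- ids[1]; B <- ids[2]
        C <- if (rep %% 3 == 0) character() else ids[3:(3 + rep %% 3)]
        got <- dSeparated(g, A, B, C)
        expect_identical(got, oracleDsep(g, A, B, C),
            info = sprintf("seed %d: %s vs %s | %s", rep, A, B,
                           paste(C, collapse = ",")))
        expect_identical(got, dSeparated(g, B, A, C))  # symmetry
    }

    cyc <- DependencyGraph(c("a", "b"), rbind(c("a", "b"), c("b", "a")))
    expect_error(dSeparated(cyc, "a", "b"), "unrollOneStep")
    expect_error(dSeparated(chain, "a", "a"), "disjoint")
})

test_that("unrollOneStep produces the acyclic two-slice graph", {
    single <- DependencyGraph("x")
    u1 <- unrollOneStep(single)
    expect_setequal(nodeIds(u1), c("x_t", "x_t1"))
    expect_identical(edgeTable(u1)$from, "x_t")
    expect_identical(edgeTable(u1)$to, "x_t1")

    ## the four-role template: internal flow sees internal, sensory, active
    ## but never external
    tmpl <- DependencyGraph(c("mu", "s", "a", "eta"),
        edges = rbind(c("s", "mu"), c("a", "mu"), c("mu", "a"), c("s", "a"),
                      c("eta", "s"), c("a", "s"), c("a", "eta"),
                      c("s", "eta")),
        roles = c(mu = "internal", s = "sensory", a = "active",
                  eta = "external"))
    u <- unrollOneStep(tmpl)
    expect_setequal(parentsOf(u, "mu_t1"), c("mu_t", "s_t", "a_t"))
    expect_false("eta_t" %in% parentsOf(u, "mu_t1"))

    cyc <- DependencyGraph(c("a", "b"), rbind(c("a", "b"), c("b", "a")))
    expect_true(isAcyclic(unrollOneStep(cyc)))
    expect_identical(numNodes(unrollOneStep(cyc)), 4L)
})

test_that("valid partitions imply one-step d-separation on the unrolled graph", {
    for (seed in 1:10) {
        sys <- randomBlanketSystem(nInternal = 1 + seed %% 3,
                                   nExternal = 1 + (seed + 1) %% 4,
                                   seed = seed)
        g <- modelGraph(sys)
        p <- partitionFromRoles(g)
        expect_identical(nrow(validatePartition(g, p)), 0L)
        u <- unrollOneStep(g)
        expect_true(dSeparated(u,
            sliceIds(internalStates(p), "t1"),
            sliceIds(externalStates(p), "t"),
            sliceIds(c(internalStates(p), blanketStates(p)), "t")))
        ## and symmetrically for the external increment
        expect_true(dSeparated(u,
            sliceIds(externalStates(p), "t1"),
            sliceIds(internalStates(p), "t"),
            sliceIds(c(externalStates(p), blanketStates(p)), "t")))
    }
})
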