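test_that("integration reproduces closed-form behaviour", {
    ## zero flow: constant trajectory
    still <- fitzhughNagumo()
    still@flow <- function(t, x, u, p) c(0, 0)
    tr <- integrateModel(still, c(a = 0.3, mu = -0.2), tEnd = 1, dt = 0.01)
    expect_true(all(tr@states[, "a"] == 0.3 & tr@states[, "mu"] == -0.2))

    ## conductance-free membrane charges linearly at s/C
    m <- hodgkinHuxley(list(gK = 0, gNa = 0, gl = 0, C = 2))
    tr <- integrateModel(m, c(a = -65, mu_Na = 0.1, mu_K = 0.3, mu_l = 0.5),
                         tEnd = 10, dt = 0.01, inputFn = 4)
    aEnd <- trajectoryStates(tr)[nrow(tr@states), "a"]
    expect_equal(unname(aEnd), -65 + (4 / 2) * 10, tolerance = 1e-10)

    ## divergence is reported with state and time
    boom <- fitzhughNagumo()
    boom@flow <- function(t, x, u, p) c(x[1]^2 + 1, 0)
    expect_error(integrateModel(boom, c(a = 1, mu = 0), tEnd = 10, dt = 0.1),
                 "non-finite state")
    expect_error(integrateModel(m, c(-65, 0.1, 0.3, 0.5), tEnd = 1, dt = 0),
                 "dt must be positive")
})

test_that("deterministic convergence orders hold on a linear benchmark", {
    ## dx/dt = -x, exact solution exp(-t)
    dec <- linearModel(matrix(-1, dimnames = list("x", "x")), noise = 0)
    errAt <- function(dt, method) {
        tr <- integrateModel(dec, c(x = 1), tEnd = 1, dt = dt,
                             method = method)
        abs(tr@states[nrow(tr@states), "x"] - exp(-1))
    }
    ## RK4 is 4th order: halving dt cuts the error by about 16
    e1 <- errAt(0.02, "rk4"); e2 <- errAt(0.01, "rk4")
    expect_gt(e1 / e2, 12); expect_lt(e1 / e2, 20)
    ## forced Euler (EM with zero noise) is 1st order
    e1 <- errAt(0.02, "em"); e2 <- errAt(0.01, "em")
    expect_gt(e1 / e2, 1.8); expect_lt(e1 / e2, 2.2)
})

test_that("Ornstein-Uhlenbeck stationary variance matches sigma^2/(2 theta)", {
    theta <- 1; sigma <- 2
    ou <- linearModel(matrix(-theta, dimnames = list(c("x"), "x")),
                      noise = sigma)
    tr <- integrateModel(ou, c(x = 0), tEnd = 2000, dt = 0.01, seed = 4L)
    x <- tr@states[-(1:5000), "x"]
    ## batch-means Monte-Carlo standard error (correlated samples)
    nb <- 40
    bv <- vapply(split(x, cut(seq_along(x), nb)), stats::var, numeric(1))
    se <- stats::sd(bv) / sqrt(nb)
    expect_lt(abs(stats::var(x) - sigma^2 / (2 * theta)), 3 * se)
})

test_that("stationaryCovariance solves the Lyapunov equation", {
    expect_equal(stationaryCovariance(matrix(-0.5), matrix(4))[1, 1],
                 4 / (2 * 0.5))
    expect_true(all(stationaryCovariance(matrix(c(-1, 0.3, 0, -2), 2),
                                         matrix(0, 2, 2)) == 0))
    set.seed(8)
    J <- matrix(rnorm(36), 6); J <- J - (max(Re(eigen(J)$values)) + 0.5) * diag(6)
    Q <- diag(runif(6, 0.5, 2))
    S <- stationaryCovariance(J, Q)
    expect_equal(J %*% S + S %*% t(J) + Q, matrix(0, 6, 6),
                 tolerance = 1e-10)
    expect_equal(S, t(S))
    expect_true(all(eigen(S, only.values = TRUE)$values > 0))
    expect_error(stationaryCovariance(matrix(1), matrix(1)), "not stable")
})

test_that("linearization recovers exact Jacobians and declared sparsity", {
    sys <- randomBlanketSystem(seed = 2)
    lin <- linearizeModel(sys, rep(0.5, length(stateLabels(sys))))
    expect_equal(lin$J, sys@params$J, tolerance = 1e-7)

    fhn <- fitzhughNagumo()
    lin <- linearizeModel(fhn, c(a = 0, mu = 0))
    expect_equal(lin$J["a", "a"], 1, tolerance = 1e-6)

    ## symbolic-differentiation oracle for the gated-leak membrane equation
    p <- hhParams()
    dA <- stats::deriv(~ (s - gK * muK^4 * (a - vK) - gNa * muNa^3 *
                          (a - vNa) - gl * mul * (a - vl)) / C,
                       c("a", "muNa", "muK", "mul"))
    env <- list2env(list(a = -60, muNa = 0.2, muK = 0.4, mul = 0.5, s = 3,
                         gK = p$gK, gNa = p$gNa, gl = p$gl, vK = p$vK,
                         vNa = p$vNa, vl = p$vl, C = p$C))
    want <- attr(eval(dA, env), "gradient")
    m <- hodgkinHuxley()
    lin <- linearizeModel(m, c(a = -60, mu_Na = 0.2, mu_K = 0.4, mu_l = 0.5),
                          input = 3)
    expect_equal(unname(lin$J["a", ]), as.vector(want), tolerance = 1e-6)
    ## Jacobian sparsity at a generic point equals the declared pattern
    ## (up to the diagonal, which is the implicit self-dependence)
    offdiag <- abs(lin$J) > 1e-8 & !diag(TRUE, 4)
    dec <- edgeTable(modelGraph(m))
    dec <- dec[dec$from %in% stateLabels(m), ]
    expect_setequal(paste(colnames(lin$J)[which(offdiag, arr.ind = TRUE)[, 2]],
                          rownames(lin$J)[which(offdiag, arr.ind = TRUE)[, 1]]),
                    setdiff(paste(dec$from, dec$to), "a mu_l"))
    ## input sensitivity: da/ds = 1/C
    expect_equal(unname(lin$B["a", "s"]), 1 / p$C, tolerance = 1e-6)
})

test_that("one-step linear map inherits the blanket sparsity pattern", {
    for (seed in 1:5) {
        sys <- randomBlanketSystem(seed = seed)
        J <- sys@params$J
        A <- diag(nrow(J)) + 0.1 * J
        roles <- nodeRoles(modelGraph(sys))[rownames(J)]
        forb <- rbind(c("internal", "sensory"), c("internal", "external"),
                      c("external", "active"), c("external", "internal"))
        for (k in seq_len(nrow(forb))) {
            blk <- A[roles == forb[k, 2], roles == forb[k, 1], drop = FALSE]
            expect_true(all(blk == 0))
        }
    }
})

test_that("identical configuration and seed give bit-identical output", {
    sys <- randomBlanketSystem(seed = 3)
    t1 <- integrateModel(sys, rep(0, 11), tEnd = 50, dt = 0.1, seed = 77)
    t2 <- integrateModel(sys, rep(0, 11), tEnd = 50, dt = 0.1, seed = 77)
    expect_identical(t1@states, t2@states)
    t3 <- integrateModel(sys, rep(0, 11), tEnd = 50, dt = 0.1, seed = 78)
    expect_false(identical(t1@states, t3@states))

    ## the same holds for nonlinear models through the generic path
    m <- fitzhughNagumo(noise = 0.1)
    a <- integrateModel(m, c(a = 0, mu = 0), tEnd = 5, dt = 0.01,
                        inputFn = 0.3, seed = 5)
    b <- integrateModel(m, c(a = 0, mu = 0), tEnd = 5, dt = 0.01,
                        inputFn = 0.3, seed = 5)
    expect_identical(a@states, b@states)
})

test_that("too-large steps for a stable stiff system trigger a warning", {
    stiff <- linearModel(diag(-30, 2, 2) + matrix(c(0, 1, 0, 0), 2),
                         noise = 1)
    expect_warning(integrateModel(stiff, c(0, 0), tEnd = 10, dt = 0.1,
                                  seed = 1), "stability")
})
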