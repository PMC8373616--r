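#' @include neuromodels.R
NULL

.resolveInput <- function(model, inputFn) {
    nI <- length(model@inputLabels)
    if (nI == 0L) return(function(t) numeric())
    if (is.null(inputFn)) {
        zero <- numeric(nI)
        return(function(t) zero)
    }
    if (is.numeric(inputFn)) {
        const <- rep_len(inputFn, nI)
        return(function(t) const)
    }
    if (!is.function(inputFn)) stop("inputFn must be NULL, numeric or a function")
    inputFn
}

#' Integrate a dynamical model into a seeded Trajectory
#'
#' Deterministic models (all noise amplitudes zero) are integrated with
#' classical fixed-step RK4; models with noise use the Euler-Maruyama scheme
#' \deqn{x_{t+dt} = x_t + f(x_t)\,dt + \sigma\sqrt{dt}\,\varepsilon_t}
#' with independent standard-normal draws per state. The RNG is seeded at the
#' start of every call and noise is drawn one vector of `length(states)`
#' deviates per step, in state-label order, so identical `(seed, dt, init)`
#' give bit-identical trajectories.
#'
#' Before integrating, the flow is linearized at the initial state; if the
#' Jacobian indicates a stable system whose fastest eigenvalue would make the
#' explicit scheme unstable at this `dt` (spectral radius of `I + dt J`
#' above 1), a warning is emitted.
#'
#' @param model a [DynamicalModel-class].
#' @param init named or ordered numeric initial state vector.
#' @param tEnd end time (same units as the model, typically ms).
#' @param dt step size (> 0); defaults to 0.01.
#' @param inputFn exogenous drive: `NULL` (zeros), a constant vector, or a
#'   function `t -> input vector`.
#' @param seed integer RNG seed.
#' @param method `"auto"` (default: RK4 iff deterministic), `"rk4"` or
#'   `"em"`.
#' @return A [Trajectory-class].
#' @examples
#' m <- fitzhughNagumo()
#' tr <- integrateModel(m, c(a = 0, mu = 0), tEnd = 10, dt = 0.01,
#'                      inputFn = 0.5)
#' tail(trajectoryStates(tr), 1)
#' @export
integrateModel <- function(model, init, tEnd, dt = 0.01, inputFn = NULL,
                           seed = 1L, method = c("auto", "rk4", "em")) {
    method <- match.arg(method)
    if (dt <= 0) stop("dt must be positive")
    if (tEnd < dt) stop("tEnd must be at least dt")
    states <- model@stateLabels
    nS <- length(states)
    if (!is.null(names(init))) init <- init[states]
    if (length(init) != nS || any(is.na(init)))
        stop("init must provide one value per state")
    init <- as.numeric(init)
    stochastic <- any(model@noise > 0)
    if (method == "auto") method <- if (stochastic) "em" else "rk4"
    if (method == "rk4" && stochastic)
        stop("RK4 is only available for deterministic models")
    inFn <- .resolveInput(model, inputFn)
    nSteps <- floor(round(tEnd / dt, 8))
    times <- seq(0, by = dt, length.out = nSteps + 1L)
    .checkStepStability(model, init, inFn(0), dt)
    set.seed(seed)
    p <- model@params
    f <- model@flow
    out <- matrix(NA_real_, nSteps + 1L, nS, dimnames = list(NULL, states))
    nI <- length(model@inputLabels)
    uMat <- matrix(NA_real_, nSteps + 1L, nI,
                   dimnames = list(NULL, model@inputLabels))
    x <- init
    out[1L, ] <- x
    if (nI) uMat[1L, ] <- inFn(0)
    if (method == "em") {
        sig <- model@noise * sqrt(dt)
        fastJ <- isTRUE(p$linear) && !is.null(p$J) && nI == 0L
        if (fastJ) {
            ## one-step map precomputed for linear drift; the noise stream is
            ## drawn per step exactly as in the generic branch
            J <- p$J
            for (k in seq_len(nSteps)) {
                x <- x + dt * as.vector(J %*% x) + sig * stats::rnorm(nS)
                out[k + 1L, ] <- x
            }
        } else {
            for (k in seq_len(nSteps)) {
                t0 <- times[k]
                u <- inFn(t0)
                x <- x + dt * f(t0, x, u, p) + sig * stats::rnorm(nS)
                out[k + 1L, ] <- x
                if (nI) uMat[k + 1L, ] <- inFn(times[k + 1L])
            }
        }
    } else {
        half <- dt / 2
        for (k in seq_len(nSteps)) {
            t0 <- times[k]
            u0 <- inFn(t0)
            uh <- inFn(t0 + half)
            u1 <- inFn(t0 + dt)
            k1 <- f(t0, x, u0, p)
            k2 <- f(t0 + half, x + half * k1, uh, p)
            k3 <- f(t0 + half, x + half * k2, uh, p)
            k4 <- f(t0 + dt, x + dt * k3, u1, p)
            x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
            out[k + 1L, ] <- x
            if (nI) uMat[k + 1L, ] <- u1
        }
    }
    if (!all(is.finite(out))) {
        bad <- which(!is.finite(out), arr.ind = TRUE)
        stop(sprintf(
            "non-finite state during integration: first at t = %g, state \"%s\"",
            times[min(bad[, 1])], states[bad[which.min(bad[, 1]), 2]]))
    }
    new("Trajectory", times = times, states = out, inputs = uMat,
        seed = as.integer(seed), dt = dt,
        integrator = if (method == "em") "euler-maruyama" else "rk4",
        modelName = model@name)
}

.checkStepStability <- function(model, init, input, dt) {
    J <- tryCatch(linearizeModel(model, init, input)$J, error = function(e) NULL)
    if (is.null(J)) return(invisible(NULL))
    ev <- eigen(J, only.values = TRUE)$values
    if (all(Re(ev) < 0) && any(Mod(1 + dt * ev) > 1 + 1e-12))
        warning(sprintf(
            "dt = %g exceeds the explicit stability bound at the initial point ",
            dt), "(spectral radius of I + dt*J is ",
            sprintf("%.3f", max(Mod(1 + dt * ev))),
            "); consider a smaller step", call. = FALSE)
    invisible(NULL)
}

#' Linearize a model's flow at a point
#'
#' Central finite differences of the flow with respect to the states (and,
#' separately, the inputs) at a given operating point.
#'
#' @param model a [DynamicalModel-class].
#' @param point named or ordered state vector.
#' @param input input vector (defaults to zeros).
#' @param eps finite-difference step (scaled by `max(1, |x_j|)` per
#'   coordinate).
#' @return list with `J` (state Jacobian, dimnames = state labels), `B`
#'   (input Jacobian, possibly 0-column) and `f0` (the flow at the point).
#' @export
linearizeModel <- function(model, point, input = NULL, eps = 1e-5) {
    states <- model@stateLabels
    nS <- length(states)
    if (!is.null(names(point))) point <- point[states]
    point <- as.numeric(point)
    if (length(point) != nS || any(is.na(point)))
        stop("point must provide one value per state")
    nI <- length(model@inputLabels)
    if (is.null(input)) input <- numeric(nI)
    input <- rep_len(as.numeric(input), nI)
    f0 <- model@flow(0, point, input, model@params)
    if (!all(is.finite(f0))) stop("non-finite flow at the linearization point")
    J <- matrix(0, nS, nS, dimnames = list(states, states))
    for (j in seq_len(nS)) {
        h <- eps * max(1, abs(point[j]))
        xp <- point; xp[j] <- xp[j] + h
        xm <- point; xm[j] <- xm[j] - h
        d <- (model@flow(0, xp, input, model@params) -
              model@flow(0, xm, input, model@params)) / (2 * h)
        if (!all(is.finite(d))) stop("non-finite derivative in state ", states[j])
        J[, j] <- d
    }
    B <- matrix(0, nS, nI, dimnames = list(states, model@inputLabels))
    for (j in seq_len(nI)) {
        h <- eps * max(1, abs(input[j]))
        up <- input; up[j] <- up[j] + h
        um <- input; um[j] <- um[j] - h
        d <- (model@flow(0, point, up, model@params) -
              model@flow(0, point, um, model@params)) / (2 * h)
        if (!all(is.finite(d)))
            stop("non-finite derivative in input ", model@inputLabels[j])
        B[, j] <- d
    }
    list(J = J, B = B, f0 = f0)
}

#' Stationary covariance of a stable linear stochastic system
#'
#' For `dx = J x dt + dW` with noise covariance rate `Q`, the stationary
#' covariance solves the continuous-time Lyapunov equation
#' `J S + S J' + Q = 0`, solved here directly via the Kronecker-product
#' linear system (adequate for the system sizes this package works at).
#'
#' @param J square drift matrix; all eigenvalues must have negative real
#'   part.
#' @param Q symmetric positive semi-definite noise covariance rate (for
#'   per-state amplitudes `sigma`, `Q = diag(sigma^2)`).
#' @return Symmetric covariance matrix with `J`'s dimnames.
#' @examples
#' stationaryCovariance(matrix(-0.5), matrix(2))  # sigma^2/(2 theta) = 2
#' @export
stationaryCovariance <- function(J, Q) {
    J <- as.matrix(J); Q <- as.matrix(Q)
    n <- nrow(J)
    if (ncol(J) != n || !identical(dim(Q), dim(J)))
        stop("J and Q must be square matrices of the same size")
    ev <- eigen(J, only.values = TRUE)$values
    if (any(Re(ev) >= 0))
        stop("J is not stable; eigenvalues with non-negative real part: ",
             paste(format(ev[Re(ev) >= 0], digits = 4), collapse = ", "))
    In <- diag(n)
    S <- matrix(solve(kronecker(In, J) + kronecker(J, In), -as.vector(Q)), n, n)
    S <- (S + t(S)) / 2
    dimnames(S) <- dimnames(J)
    S
}

#' Draw an initial state from a linear model's stationary distribution
#'
#' For a stable linear stochastic model, samples `x0 ~ N(0, Sigma)` with
#' `Sigma` the Lyapunov stationary covariance. Starting simulations from the
#' stationary law removes the deterministic transient, which matters for
#' statistical calibration: the early rows of a from-rest trajectory have
#' systematically smaller scale and distort regression-based tests.
#'
#' @param model a linear [DynamicalModel-class] (as from
#'   [randomBlanketSystem()] or [linearModel()]) with stable drift.
#' @param seed RNG seed.
#' @return Named numeric state vector.
#' @export
stationaryInitialState <- function(model, seed = 1L) {
    if (!isTRUE(model@params$linear))
        stop("stationary initialization requires a linear model")
    S <- stationaryCovariance(model@params$J, diag(model@noise^2))
    set.seed(seed)
    structure(as.vector(t(chol(S)) %*% stats::rnorm(nrow(S))),
              names = model@stateLabels)
}

#' Empirical covariance of a trajectory
#'
#' Convenience wrapper discarding an initial transient before computing the
#' sample covariance of the states.
#'
#' @param traj a [Trajectory-class].
#' @param burnIn fraction of initial samples to discard (default 0.1).
#' @return Covariance matrix over states.
#' @export
empiricalCovariance <- function(traj, burnIn = 0.1) {
    X <- traj@states
    drop <- floor(nrow(X) * burnIn)
    stats::cov(X[(drop + 1):nrow(X), , drop = FALSE])
}
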