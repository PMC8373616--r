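#' @include multiscale.R
NULL

## column matrix of the named states (and inputs) of a trajectory at given rows
.trajColumns <- function(traj, ids, rows) {
    avail <- cbind(traj@states,
                   if (ncol(traj@inputs)) traj@inputs)
    bad <- setdiff(ids, colnames(avail))
    if (length(bad))
        stop("partition names states absent from the trajectory: ",
             paste(bad, collapse = ", "))
    avail[rows, ids, drop = FALSE]
}

## nested-regression comparison: per-response F-tests (exact for a single
## predicted component under linear dynamics, Gaussian noise and the
## Euler-Maruyama one-step map), and for several predicted components the
## multivariate nested comparison via Wilks' Lambda with Rao's F
## transformation, which accounts for the cross-component dependence induced
## by the shared (random) design
.nestedF <- function(Y, X0, X1added) {
    n <- nrow(Y)
    X0 <- cbind(`(intercept)` = 1, X0)
    X1 <- cbind(X0, X1added)
    q0 <- qr(X0)
    q1 <- qr(X1)
    if (q0$rank < ncol(X0) || q1$rank < ncol(X1)) {
        keep1 <- q1$pivot[seq_len(q1$rank)]
        dropped <- colnames(X1)[setdiff(seq_len(ncol(X1)), keep1)]
        stop("rank-deficient design matrix; collinear or constant columns: ",
             paste(dropped, collapse = ", "))
    }
    R0 <- qr.resid(q0, Y)
    R1 <- qr.resid(q1, Y)
    q <- ncol(X1) - ncol(X0)
    dfRes <- n - ncol(X1)
    rss0 <- colSums(R0^2)
    rss1 <- colSums(R1^2)
    Fstat <- ((rss0 - rss1) / q) / (rss1 / dfRes)
    p <- stats::pf(Fstat, q, dfRes, lower.tail = FALSE)
    m <- ncol(Y)
    if (m > 1L) {
        E <- crossprod(R1)
        H <- crossprod(R0) - E
        lam <- det(E) / det(E + H)
        tt <- if (m^2 + q^2 - 5 > 0)
            sqrt((m^2 * q^2 - 4) / (m^2 + q^2 - 5)) else 1
        df1 <- m * q
        df2 <- tt * (dfRes - (m - q + 1) / 2) - (m * q - 2) / 2
        raoF <- (1 - lam^(1 / tt)) / lam^(1 / tt) * df2 / df1
        list(F = Fstat, p = p, q = q, dfRes = dfRes,
             jointF = raoF, jointDof = c(df1, df2),
             jointP = stats::pf(raoF, df1, df2, lower.tail = FALSE))
    } else {
        list(F = Fstat, p = p, q = q, dfRes = dfRes)
    }
}

#' One-step conditional-independence test on a simulated trajectory
#'
#' Tests the dynamic reading of the blanket independence. Each of the four
#' flow constraints has its own direction, named after the predicted block:
#' `"internal"` -- external states must add no predictive power for the
#' internal increment beyond (internal, sensory, active); `"active"` -- the
#' same for the active increment (a gained external-to-active influence is
#' detected here); `"external"` -- internal states must add nothing for the
#' external increment beyond (external, sensory, active); `"sensory"` --
#' the same for the sensory increment. The
#' increment of the predicted block,
#' `x_{t+dt} - x_t`, is regressed on the conditioning block at time `t` with
#' and without the candidate block, and the nested models are compared by an
#' F-test: the ordinary F for a single predicted component (exact under
#' linear dynamics, Gaussian noise and the Euler-Maruyama one-step map,
#' conditional on the design), and for several components the multivariate
#' nested comparison via Wilks' Lambda in Rao's F form, which accounts for
#' the dependence between components induced by the shared design.
#' Per-component F p-values are kept as diagnostics.
#'
#' An empty candidate set (e.g. no external states) degenerates to an
#' `"accept"` verdict with `p = 1`.
#'
#' @param traj a [Trajectory-class]; must be at least ten times longer than
#'   the number of states, with nonzero noise on the predicted states.
#' @param partition a [BlanketPartition-class] over trajectory columns
#'   (states, or states plus recorded inputs).
#' @param alpha test level.
#' @param direction `"internal"` (default), `"active"`, `"external"` or
#'   `"sensory"`, as above.
#' @return A [CITestResult-class].
#' @export
dynamicCITest <- function(traj, partition, alpha = 0.05,
                          direction = c("internal", "active", "external",
                                        "sensory")) {
    direction <- match.arg(direction)
    autoCond <- c(partition@internal, partition@sensory, partition@active)
    extCond <- c(partition@external, partition@sensory, partition@active)
    predicted <- switch(direction,
        internal = partition@internal, active = partition@active,
        external = partition@external, sensory = partition@sensory)
    candidate <- switch(direction,
        internal = , active = partition@external,
        external = , sensory = partition@internal)
    conditioning <- switch(direction,
        internal = , active = autoCond,
        external = , sensory = extCond)
    predicted <- intersect(predicted, colnames(traj@states))
    nT <- length(traj@times)
    n <- nT - 1L
    if (!length(predicted))
        stop("no predicted states present in the trajectory")
    if (nT < 10L * ncol(traj@states))
        stop("trajectory too short: need at least 10 samples per state")
    triple <- list(predicted = predicted, conditioning = conditioning,
                   candidate = candidate)
    if (!length(candidate)) {
        return(new("CITestResult", statistic = 0, dof = c(0, Inf),
                   pValue = 1, alpha = alpha, verdict = "accept",
                   triple = triple, nSamples = n,
                   componentPValues = numeric()))
    }
    Y <- .trajColumns(traj, predicted, 2:nT) -
         .trajColumns(traj, predicted, 1:n)
    X0 <- .trajColumns(traj, conditioning, 1:n)
    XA <- .trajColumns(traj, candidate, 1:n)
    ft <- .nestedF(Y, X0, XA)
    m <- length(predicted)
    if (m == 1L) {
        stat <- unname(ft$F)
        dof <- c(ft$q, ft$dfRes)
        p <- unname(ft$p)
    } else {
        stat <- unname(ft$jointF)
        dof <- ft$jointDof
        p <- unname(ft$jointP)
    }
    new("CITestResult", statistic = stat, dof = dof, pValue = p,
        alpha = alpha, verdict = if (p < alpha) "reject" else "accept",
        triple = triple, nSamples = n,
        componentPValues = structure(unname(ft$p), names = predicted))
}

#' Stationary partial correlations between internal and external states
#'
#' Diagnostic companion to the dynamic test: from a stationary covariance,
#' computes the correlations between internal and external states after
#' conditioning on the blanket states. For Gaussian stationary densities
#' these vanish exactly when the joint density conditioned on the blanket
#' factorizes; for general flow-sparsity blankets the stationary density
#' need not inherit the independence, which is why this quantity is reported
#' as a diagnostic rather than a pass/fail criterion.
#'
#' @param Sigma positive-definite covariance matrix with state names.
#' @param partition a [BlanketPartition-class]; internal/external/blanket
#'   names must appear among `Sigma`'s dimnames.
#' @return Matrix of partial correlations, internal states in rows, external
#'   in columns; all values in `[-1, 1]`.
#' @export
stationaryPartialCorrelation <- function(Sigma, partition) {
    nm <- colnames(Sigma)
    mu <- intersect(partition@internal, nm)
    eta <- intersect(partition@external, nm)
    b <- intersect(blanketStates(partition), nm)
    if (!length(mu) || !length(eta))
        stop("Sigma must cover internal and external states")
    xy <- c(mu, eta)
    ok <- tryCatch({chol(Sigma[c(xy, b), c(xy, b)]); TRUE},
                   error = function(e) FALSE)
    if (!ok) stop("Sigma is singular (or not positive definite) on the ",
                  "partition's states")
    C <- Sigma[xy, xy]
    if (length(b)) {
        Sb <- Sigma[b, b]
        cross <- Sigma[xy, b, drop = FALSE]
        C <- C - cross %*% solve(Sb, t(cross))
    }
    d <- sqrt(diag(C))
    P <- C / tcrossprod(d)
    P[mu, eta, drop = FALSE]
}

#' Full blanket verification report for a model and partition
#'
#' Bundles into one machine-readable list: structural validation of the
#' partition against the declared dependency graph, the sensory/active
#' classification, one-step conditional-independence tests in every
#' applicable direction on a fresh seeded simulation (Bonferroni-corrected
#' across the tested directions), the stationary partial-correlation
#' diagnostic from the linearization at the operating point (when stable;
#' the report flags an unstable spectral abscissa), and a negative control
#' in which one forbidden external-to-active influence is added and both
#' the structural check and the active-direction test repeated. With
#' `tEnd = 0` the simulation-based sections are marked `"skipped"`.
#'
#' Nonlinear models are analysed in a small-noise regime around a stable
#' operating point: unless `init` is given, the model is first relaxed
#' noise-free from mid-range values and the simulation starts from the
#' relaxed state, where the linearization governs the dynamics.
#'
#' @param model a [DynamicalModel-class].
#' @param partition a [BlanketPartition-class] over the model's graph nodes.
#' @param tEnd,dt,seed,alpha simulation and test settings.
#' @param init initial state (default: deterministic relaxation from
#'   mid-range values).
#' @param inputFn exogenous drive passed to [integrateModel()].
#' @param negativeControl add the edge-gain control section (default TRUE
#'   when the model has external states).
#' @return A nested list with a `report_schema` field, serializable with
#'   [writeBlanketReport()].
#' @export
blanketReport <- function(model, partition, tEnd = 200, dt = 0.01,
                          seed = 1L, alpha = 0.05, init = NULL,
                          inputFn = NULL, negativeControl = NULL) {
    g <- model@graph
    if (numNodes(g) == 0L) {
        return(list(report_schema = "1.0", model = model@name,
                    empty = TRUE))
    }
    viol <- validatePartition(g, partition)
    cls <- classifyBlanket(g, partition@internal, partition@external)
    if (is.null(init))
        init <- .relaxToOperatingPoint(model, dt)
    stateExternal <- intersect(partition@external, model@stateLabels)
    if (is.null(negativeControl))
        negativeControl <- length(stateExternal) > 0
    ci <- list(status = "skipped")
    negative <- list(status = "skipped")
    if (tEnd > 0) {
        traj <- integrateModel(model, init, tEnd = tEnd, dt = dt,
                               inputFn = inputFn, seed = seed)
        ## a direction applies when its predicted block contains simulated
        ## states and its candidate block is non-empty
        sim <- function(ids) intersect(ids, model@stateLabels)
        dirs <- c("internal", "active", "external", "sensory")
        applies <- c(
            internal = length(sim(partition@internal)) > 0 &&
                length(partition@external) > 0,
            active = length(sim(partition@active)) > 0 &&
                length(partition@external) > 0,
            external = length(sim(partition@external)) > 0 &&
                length(partition@internal) > 0,
            sensory = length(sim(partition@sensory)) > 0 &&
                length(partition@internal) > 0)
        dirs <- dirs[applies[dirs]]
        aBonf <- if (length(dirs)) alpha / length(dirs) else alpha
        tests <- lapply(dirs, function(d)
            .ciAsList(dynamicCITest(traj, partition, aBonf, d)))
        names(tests) <- dirs
        ci <- c(list(status = "done", alpha = alpha,
                     bonferroniAlpha = aBonf, seed = seed, dt = dt,
                     tEnd = tEnd), tests)
        if (negativeControl) {
            pm <- perturbAddEdge(model, "external", "active",
                                 weight = 0.5, seed = seed)
            pviol <- validatePartition(pm@graph, partition)
            ptraj <- integrateModel(pm, init, tEnd = tEnd, dt = dt,
                                    inputFn = inputFn, seed = seed + 1L)
            pci <- dynamicCITest(ptraj, partition, aBonf, "active")
            negative <- list(status = "done",
                             addedEdge = attr(pm, "addedEdge"),
                             violations = pviol,
                             activeTest = .ciAsList(pci))
        }
    }
    stationary <- .stationaryDiagnostic(model, partition, init)
    list(report_schema = "1.0", model = model@name,
         partition = list(internal = partition@internal,
                          sensory = partition@sensory,
                          active = partition@active,
                          external = partition@external),
         structural = list(violations = viol, valid = nrow(viol) == 0L,
                           classification = cls[c("sensory", "active",
                                                  "ambiguous")]),
         ci = ci, stationary = stationary, negativeControl = negative)
}

## deterministic relaxation from mid-range values towards a stable fixed
## point, so nonlinear models are analysed where their linearization governs
.relaxToOperatingPoint <- function(model, dt, tRelax = 200) {
    init <- colMeans(model@stateRanges)
    relaxed <- model
    relaxed@noise[] <- 0
    tr <- tryCatch(suppressWarnings(
        integrateModel(relaxed, init, tEnd = tRelax, dt = dt,
                       method = "rk4")),
        error = function(e) NULL)
    if (is.null(tr)) init else tr@states[nrow(tr@states), ]
}

.ciAsList <- function(x)
    list(statistic = x@statistic, dof = x@dof, pValue = x@pValue,
         alpha = x@alpha, verdict = x@verdict, nSamples = x@nSamples)

.stationaryDiagnostic <- function(model, partition, init) {
    if (!any(model@noise > 0)) return(list(status = "skipped"))
    lin <- tryCatch(linearizeModel(model, init), error = function(e) NULL)
    if (is.null(lin)) return(list(status = "skipped"))
    ev <- eigen(lin$J, only.values = TRUE)$values
    abscissa <- max(Re(ev))
    if (abscissa >= 0)
        return(list(status = "unstable-operating-point",
                    spectralAbscissa = abscissa))
    S <- stationaryCovariance(lin$J, diag(model@noise^2))
    pc <- tryCatch(stationaryPartialCorrelation(S, partition),
                   error = function(e) NULL)
    list(status = "done", spectralAbscissa = abscissa,
         maxAbsPartialCorrelation = if (!is.null(pc)) max(abs(pc)),
         partialCorrelation = pc)
}
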