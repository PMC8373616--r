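#' @include verify.R
NULL

## ---- igraph bridge and graph formats ----------------------------------------

#' Convert between DependencyGraph and igraph
#'
#' Node attributes `role`, `scale`, `group` and the edge attribute `sign`
#' are carried across in both directions.
#'
#' @param graph a [DependencyGraph-class].
#' @return `asIgraph`: an [igraph::igraph] object; `fromIgraph`: a
#'   [DependencyGraph-class].
#' @export
asIgraph <- function(graph) {
    nd <- graph@nodes
    nd$group[is.na(nd$group)] <- ""   # GraphML has no NA notion
    igraph::graph_from_data_frame(graph@edges, directed = TRUE,
                                  vertices = nd)
}

#' @rdname asIgraph
#' @param ig an igraph object with the attributes above.
#' @export
fromIgraph <- function(ig) {
    df <- igraph::as_data_frame(ig, what = "both")
    nd <- df$vertices
    names(nd)[1] <- "id"
    if (!is.null(nd$group)) nd$group[nd$group %in% c("", "NA")] <- NA
    ed <- df$edges
    DependencyGraph(nd, if (nrow(ed)) ed)
}

#' Read and write dependency graphs in GraphML and DOT
#'
#' GraphML round-trips all node and edge attributes through igraph. The DOT
#' writer emits one node statement per node with `role`, `scale` and `group`
#' attributes and one edge statement per edge with its `sign`; the DOT
#' reader accepts exactly that dialect (it is a round-trip format for this
#' package, not a general DOT parser).
#'
#' @param graph a [DependencyGraph-class].
#' @param path file path.
#' @return The readers return a [DependencyGraph-class]; the writers return
#'   `path` invisibly.
#' @export
writeGraphML <- function(graph, path) {
    igraph::write_graph(asIgraph(graph), path, format = "graphml")
    invisible(path)
}

#' @rdname writeGraphML
#' @export
readGraphML <- function(path) {
    g <- fromIgraph(igraph::read_graph(path, format = "graphml"))
    g@nodes$scale <- as.integer(g@nodes$scale)
    validObject(g)
    g
}

#' @rdname writeGraphML
#' @export
writeDOT <- function(graph, path) {
    q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
    lines <- c("digraph dependency {",
        sprintf('  %s [role=%s, scale=%d, group=%s];',
                q(graph@nodes$id), q(graph@nodes$role), graph@nodes$scale,
                q(ifelse(is.na(graph@nodes$group), "", graph@nodes$group))))
    if (nrow(graph@edges))
        lines <- c(lines,
            sprintf('  %s -> %s [sign=%s];',
                    q(graph@edges$from), q(graph@edges$to),
                    q(graph@edges$sign)))
    writeLines(c(lines, "}"), path)
    invisible(path)
}

#' @rdname writeGraphML
#' @export
readDOT <- function(path) {
    lines <- trimws(readLines(path))
    nodeRe <- '^"(.*)" \\[role="(.*)", scale=([0-9]+), group="(.*)"\\];$'
    edgeRe <- '^"(.*)" -> "(.*)" \\[sign="(.*)"\\];$'
    nl <- grep(nodeRe, lines, value = TRUE)
    el <- grep(edgeRe, lines, value = TRUE)
    nodes <- data.frame(
        id = sub(nodeRe, "\\1", nl),
        role = sub(nodeRe, "\\2", nl),
        scale = as.integer(sub(nodeRe, "\\3", nl)),
        group = sub(nodeRe, "\\4", nl), stringsAsFactors = FALSE)
    nodes$group[nodes$group == ""] <- NA_character_
    edges <- if (length(el))
        data.frame(from = sub(edgeRe, "\\1", el),
                   to = sub(edgeRe, "\\2", el),
                   sign = sub(edgeRe, "\\3", el), stringsAsFactors = FALSE)
    DependencyGraph(nodes, edges)
}

## ---- model specification files ----------------------------------------------

## encode R values YAML/JSON-safely: functions are deparsed, matrices
## flattened, and atomic vectors tagged with their storage mode so the round
## trip preserves types exactly (YAML/JSON readers guess integer vs double)
.encodeValue <- function(x) {
    ## doubles travel as %.17g strings: exact through both YAML and JSON
    asText <- function(v) if (typeof(v) == "double")
        sprintf("%.17g", v) else v
    if (is.function(x))
        return(list(.function = paste(deparse(x), collapse = "\n")))
    if (is.matrix(x))
        return(list(.matrix = typeof(x), nrow = nrow(x),
                    data = as.list(asText(as.vector(x))),
                    rownames = as.list(rownames(x)),
                    colnames = as.list(colnames(x))))
    if (is.list(x))
        return(lapply(x, .encodeValue))
    list(.vector = typeof(x), names = as.list(names(x)),
         values = as.list(asText(unname(x))))
}

.decodeValue <- function(x) {
    if (!is.list(x)) return(x)
    if (!is.null(x$.function))
        return(eval(parse(text = x$.function), asNamespace("MarkovBlankets")))
    if (!is.null(x$.matrix)) {
        d <- as.vector(unlist(x$data), mode = x$.matrix)
        if (is.null(d)) d <- vector(x$.matrix, 0)
        m <- matrix(d, nrow = x$nrow)
        rn <- unlist(x$rownames); cn <- unlist(x$colnames)
        if (!is.null(rn) || !is.null(cn)) dimnames(m) <- list(rn, cn)
        return(m)
    }
    if (!is.null(x$.vector)) {
        v <- as.vector(unlist(x$values), mode = x$.vector)
        if (is.null(v)) v <- vector(x$.vector, 0)
        nm <- unlist(x$names)
        if (!is.null(nm)) names(v) <- nm
        return(v)
    }
    lapply(x, .decodeValue)
}

#' Write and read model specification files
#'
#' A specification records everything needed to reconstruct a shipped model:
#' its type, constructor parameters (functions are stored as deparsed
#' source), noise amplitudes and node roles. The format is chosen by file
#' extension (`.yaml`/`.yml` or `.json`) and the round trip is lossless:
#' reading a written spec reconstructs a model with an identical
#' [modelHash()].
#'
#' @param model a [DynamicalModel-class] produced by one of the package's
#'   constructors.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `writeModelSpec` returns `path` invisibly; `readModelSpec`
#'   returns the reconstructed [DynamicalModel-class].
#' @export
writeModelSpec <- function(model, path) {
    spec <- list(spec_schema = "1.0",
                 type = model@name,
                 params = .encodeValue(model@params),
                 noise = .encodeValue(model@noise),
                 roles = .encodeValue(nodeRoles(model@graph)))
    if (grepl("\\.ya?ml$", path))
        yaml::write_yaml(spec, path)
    else if (grepl("\\.json$", path))
        jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA,
                             null = "null")
    else stop("unsupported spec extension (use .yaml, .yml or .json): ", path)
    invisible(path)
}

#' @rdname writeModelSpec
#' @export
readModelSpec <- function(path) {
    spec <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
            else if (grepl("\\.json$", path)) jsonlite::read_json(path)
            else stop("unsupported spec extension: ", path)
    p <- .decodeValue(spec$params)
    noise <- .decodeValue(spec$noise)
    roles <- .decodeValue(spec$roles)
    type <- spec$type
    m <- switch(type,
        hodgkin_huxley = hodgkinHuxley(p, noise = noise),
        classic_hodgkin_huxley = classicHodgkinHuxley(p, noise = noise),
        fitzhugh_nagumo = fitzhughNagumo(p, noise = noise),
        morris_lecar = morrisLecar(p, noise = noise),
        neural_mass = ,
        neural_mass_pair = neuralMassNetwork(p$W, slope = p$slope,
            threshold = p$threshold, tauV = p$tauV, tauG = p$tauG,
            noise = noise, labels = p$labels),
        cmc_chain = cmcChain(p$L, intrinsic = p$intrinsic,
            forwardGain = p$forwardGain, backwardGain = p$backwardGain,
            forwardToDeep = p$forwardToDeep, slope = p$slope,
            threshold = p$threshold, tauV = p$tauV, tauG = p$tauG,
            noise = noise),
        spring_chain = springChain(p$n, masses = p$m, springK = p$k,
            anchored = p$anchored),
        random_blanket_system = ,
        linear = .linearModel(type, p$J, roles, noise),
        stop("unknown model type in spec: ", type))
    m@name <- type
    nodeRoles(m@graph) <- roles
    if (type == "spring_chain") m@noise <- structure(
        rep_len(noise, length(m@stateLabels)), names = m@stateLabels)
    validObject(m)
    m
}

#' Stable content hash of a model
#'
#' 32-bit FNV-1a hash of the model's canonical specification (type,
#' parameters with functions deparsed, noise, roles). Two models with the
#' same specification hash identically; the hash is recorded in trajectory
#' sidecar metadata so any simulation can be traced to its model.
#'
#' @param model a [DynamicalModel-class].
#' @return Character scalar, 8 hex digits.
#' @export
modelHash <- function(model) {
    spec <- list(type = model@name,
                 params = .encodeValue(model@params),
                 noise = .encodeValue(model@noise),
                 roles = .encodeValue(nodeRoles(model@graph)))
    txt <- paste(deparse(spec, control = c("keepNA", "niceNames")),
                 collapse = "\n")
    bytes <- utf8ToInt(txt) %% 256
    ## FNV-1a in 32 bits, carried in doubles: the byte is xor-ed into the
    ## low 8 bits, and the multiply by the FNV prime is split into 16-bit
    ## halves to stay within exact double-precision integer range
    h <- 2166136261
    p <- 16777619
    for (b in bytes) {
        lo8 <- h %% 256
        h <- h - lo8 + bitwXor(lo8, b)
        hLo <- h %% 65536
        hHi <- (h - hLo) / 65536
        h <- (((hHi * p) %% 65536) * 65536 + hLo * p) %% 4294967296
    }
    hLo <- h %% 65536
    sprintf("%04x%04x", as.integer((h - hLo) / 65536), as.integer(hLo))
}

## ---- trajectories ------------------------------------------------------------

#' Write and read trajectories as CSV plus JSON sidecar
#'
#' The CSV holds one `time` column, one column per state and (if present)
#' one `input.<name>` column per exogenous input. The sidecar
#' `<path>.meta.json` records seed, step size, integrator, model name and
#' model hash so a run is reconstructible from its artifacts.
#'
#' @param traj a [Trajectory-class].
#' @param path CSV file path.
#' @param model optional [DynamicalModel-class] whose hash to record.
#' @return `writeTrajectory` returns `path` invisibly; `readTrajectory`
#'   returns a [Trajectory-class].
#' @export
writeTrajectory <- function(traj, path, model = NULL) {
    df <- data.frame(time = traj@times, traj@states, check.names = FALSE)
    if (ncol(traj@inputs)) {
        ins <- traj@inputs
        colnames(ins) <- paste0("input.", colnames(ins))
        df <- cbind(df, ins)
    }
    utils::write.csv(df, path, row.names = FALSE)
    meta <- list(seed = traj@seed, dt = traj@dt,
                 integrator = traj@integrator, model = traj@modelName,
                 states = colnames(traj@states),
                 inputs = colnames(traj@inputs),
                 modelHash = if (!is.null(model)) modelHash(model))
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    meta <- jsonlite::read_json(paste0(path, ".meta.json"))
    states <- unlist(meta$states)
    inputs <- unlist(meta$inputs)
    new("Trajectory", times = df$time,
        states = as.matrix(df[, states, drop = FALSE]),
        inputs = {
            m <- as.matrix(df[, paste0("input.", inputs), drop = FALSE])
            colnames(m) <- inputs
            m
        },
        seed = as.integer(meta$seed), dt = as.numeric(meta$dt),
        integrator = meta$integrator, modelName = meta$model)
}

## ---- partitions, groupings, reports -----------------------------------------

#' Write and read blanket partitions
#'
#' Stored as a YAML or JSON map with keys `internal`, `sensory`, `active`,
#' `external`.
#'
#' @param partition a [BlanketPartition-class].
#' @param path file path (`.yaml`, `.yml` or `.json`).
#' @return `readPartition` returns a [BlanketPartition-class].
#' @export
writePartition <- function(partition, path) {
    x <- list(internal = as.list(partition@internal),
              sensory = as.list(partition@sensory),
              active = as.list(partition@active),
              external = as.list(partition@external))
    if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
    else jsonlite::write_json(x, path, auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writePartition
#' @export
readPartition <- function(path) {
    x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path)
    BlanketPartition(internal = unlist(x$internal),
                     sensory = unlist(x$sensory),
                     active = unlist(x$active),
                     external = unlist(x$external))
}

#' Write and read coarse grainings as two-column CSV
#'
#' Columns `micro` and `macro`; the scale increment travels as a
#' `# scaleIncrement:` comment line and defaults to 1 when absent.
#'
#' @param grouping a [CoarseGraining-class].
#' @param path CSV file path.
#' @return `readGrouping` returns a [CoarseGraining-class].
#' @export
writeGrouping <- function(grouping, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# scaleIncrement: %d", grouping@scaleIncrement), con)
    utils::write.csv(data.frame(micro = names(grouping@mapping),
                                macro = unname(grouping@mapping)),
                     con, row.names = FALSE)
    invisible(path)
}

#' @rdname writeGrouping
#' @export
readGrouping <- function(path) {
    first <- readLines(path, n = 1)
    inc <- if (grepl("^# scaleIncrement:", first))
        as.integer(sub("^# scaleIncrement:\\s*", "", first)) else 1L
    df <- utils::read.csv(path, comment.char = "#")
    CoarseGraining(df[, c("micro", "macro")], inc)
}

#' Serialize a blanket report to JSON
#'
#' @param report list as returned by [blanketReport()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBlanketReport <- function(report, path) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         null = "null", dataframe = "rows")
    invisible(path)
}
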