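#' @include AllClasses.R AllGenerics.R otu-table-io.R
NULL

#' Remove globally single-read OTUs
#'
#' Drops OTUs whose total count across all samples is exactly 1; singleton
#' OTUs are frequently sequencing artifacts and are excluded before
#' composition and network analysis.
#'
#' @param x an [OtuTable-class].
#' @return the filtered [OtuTable-class].
#' @export
removeGlobalSingletons <- function(x) {
    stopifnot(is(x, "OtuTable"))
    keep <- rowSums(otuCounts(x)) != 1L
    if (!any(keep)) stop("all OTUs are global singletons")
    x[keep, ]
}

#' Apply prevalence/abundance candidate filters
#'
#' Retains exactly the OTUs present (count >= 1) in at least
#' `minSamplesPresent` samples with at least `minTotalReads` reads summed
#' across samples.  Retention is monotone: raising either threshold never
#' adds OTUs.
#'
#' @param x an [OtuTable-class], typically after
#'   [removeGlobalSingletons()].
#' @param criteria a [FilterCriteria-class].
#' @return the filtered [OtuTable-class].
#' @export
filterCandidates <- function(x, criteria = FilterCriteria()) {
    stopifnot(is(x, "OtuTable"), is(criteria, "FilterCriteria"))
    m <- otuCounts(x)
    if (criteria@minSamplesPresent > ncol(m))
        stop("minSamplesPresent (", criteria@minSamplesPresent,
             ") exceeds the number of samples (", ncol(m), ")")
    keep <- rowSums(m > 0) >= criteria@minSamplesPresent &
        rowSums(m) >= criteria@minTotalReads
    if (!any(keep))
        stop("no OTUs pass the candidate filters")
    x[keep, ]
}

#' Pairwise Pearson correlation of OTU abundance profiles
#'
#' Correlates every pair of OTU profiles across samples, on per-sample
#' relative abundances (default, removing sequencing-depth artifacts) or on
#' raw counts.  OTUs with zero profile variance yield undefined r; their
#' rows/columns are `NA` and a warning names them.
#'
#' @param x an [OtuTable-class] with at least 3 samples and 2 OTUs.
#' @param useRelative correlate relative abundances (`TRUE`) or raw counts.
#' @return symmetric correlation matrix with unit diagonal; attribute
#'   `basis` records the profile scale used.
#' @export
profileCorrelation <- function(x, useRelative = TRUE) {
    stopifnot(is(x, "OtuTable"))
    m <- otuCounts(x)
    if (ncol(m) < 3L)
        stop("at least 3 samples required (r over 2 points is always +/-1)")
    if (nrow(m) < 2L) stop("at least 2 OTUs required")
    prof <- if (useRelative) relativeAbundance(m) else m
    sds <- apply(prof, 1L, stats::sd)
    flat <- rownames(prof)[sds == 0]
    if (length(flat))
        warning("zero-variance profile(s) excluded from edge formation: ",
                paste(flat, collapse = ", "))
    r <- suppressWarnings(stats::cor(t(prof), method = "pearson"))
    r[flat, ] <- NA_real_
    r[, flat] <- NA_real_
    diag(r) <- 1
    attr(r, "basis") <- if (useRelative) "relative" else "counts"
    r
}

.edgePValue <- function(r, nSamples) {
    df <- nSamples - 2L
    r2 <- pmin(r^2, 1)
    tstat <- abs(r) * sqrt(df / pmax(1 - r2, .Machine$double.eps))
    p <- 2 * stats::pt(tstat, df = df, lower.tail = FALSE)
    p[r2 >= 1] <- 0
    p
}

#' Build a co-occurrence network from a correlation matrix
#'
#' Draws an undirected edge between OTUs i and j when
#' `r(i, j) >= minPearsonR` (inclusive) and, when `positiveOnly`,
#' `r(i, j) > 0`.  Nodes carry total abundance, prevalence and taxonomy;
#' connected components are ordered by decreasing size (ties by smallest
#' member OTU id) and isolated nodes are reported separately.  A two-sided
#' t-based p-value accompanies each edge (df = samples - 2) for reporting;
#' edges are not filtered on it.
#'
#' @param rMatrix symmetric correlation matrix from [profileCorrelation()],
#'   computed on the filtered table.
#' @param x the filtered [OtuTable-class] the matrix was computed from.
#' @param criteria a [FilterCriteria-class].
#' @return a [CooccurrenceNetwork-class].
#' @export
buildNetwork <- function(rMatrix, x, criteria = FilterCriteria()) {
    stopifnot(is(x, "OtuTable"), is(criteria, "FilterCriteria"))
    m <- otuCounts(x)
    ids <- rownames(m)
    if (!identical(rownames(rMatrix), ids))
        stop("rMatrix rows must match the table's OTU ids")
    thr <- criteria@minPearsonR
    if (thr < -1 || thr > 1) stop("correlation threshold outside [-1, 1]")
    basis <- attr(rMatrix, "basis")
    if (is.null(basis)) basis <- "relative"

    n <- length(ids)
    ut <- which(upper.tri(rMatrix), arr.ind = TRUE)
    rv <- rMatrix[ut]
    sel <- !is.na(rv) & rv >= thr
    if (criteria@positiveOnly) sel <- sel & rv > 0
    edges <- data.frame(otu_a = ids[ut[sel, 1L]], otu_b = ids[ut[sel, 2L]],
                        r = rv[sel],
                        p_value = .edgePValue(rv[sel], ncol(m)),
                        stringsAsFactors = FALSE)
    # canonical order within and across pairs
    swap <- edges$otu_a > edges$otu_b
    tmp <- edges$otu_a[swap]
    edges$otu_a[swap] <- edges$otu_b[swap]
    edges$otu_b[swap] <- tmp
    edges <- edges[order(edges$otu_a, edges$otu_b), , drop = FALSE]
    rownames(edges) <- NULL

    g <- igraph::graph_from_data_frame(edges[, c("otu_a", "otu_b")],
                                       directed = FALSE,
                                       vertices = data.frame(name = ids))
    comp <- igraph::components(g)
    deg <- igraph::degree(g)[ids]

    tx <- taxonomy(x)
    nodes <- data.frame(otu_id = ids,
                        total_abundance = unname(rowSums(m)),
                        prevalence = unname(rowSums(m > 0)),
                        taxonomy = if (is.null(tx)) NA_character_ else unname(tx),
                        degree = unname(deg),
                        component = NA_integer_,
                        stringsAsFactors = FALSE)

    membership <- comp$membership[ids]
    connected <- split(ids[deg > 0], membership[deg > 0])
    if (length(connected)) {
        smallest <- vapply(connected, function(v) min(v), character(1L))
        ord <- order(-lengths(connected), smallest)
        connected <- lapply(connected[ord], function(v) sort(v))
        names(connected) <- NULL
        for (k in seq_along(connected))
            nodes$component[nodes$otu_id %in% connected[[k]]] <- k
    } else {
        connected <- list()
    }
    rownames(nodes) <- NULL
    new("CooccurrenceNetwork", nodes = nodes, edges = edges,
        components = connected, basis = basis, criteria = criteria)
}

#' Run the full co-occurrence pipeline on a count table
#'
#' Convenience wrapper: global singleton removal, candidate filtering,
#' profile correlation, and network construction, in the fixed order the
#' analysis prescribes.
#'
#' @param x an [OtuTable-class].
#' @param criteria a [FilterCriteria-class].
#' @param useRelative correlate relative abundances (default) or counts.
#' @param removeSingletons apply the global single-read exclusion first.
#' @return a [CooccurrenceNetwork-class].
#' @examples
#' sim <- simulateCommunity(communitySimSpec(nSamples = 10, seed = 1))
#' net <- cooccurrenceNetwork(sim$table)
#' networkSummary(net)$n_components
#' @export
cooccurrenceNetwork <- function(x, criteria = FilterCriteria(),
                                useRelative = TRUE, removeSingletons = TRUE) {
    if (removeSingletons) x <- removeGlobalSingletons(x)
    x <- filterCandidates(x, criteria)
    r <- profileCorrelation(x, useRelative = useRelative)
    buildNetwork(r, x, criteria)
}

#' Summarize a co-occurrence network
#'
#' @param net a [CooccurrenceNetwork-class].
#' @return list with `n_nodes`, `n_edges`, `n_components`,
#'   `component_sizes`, `degrees` (named), `n_isolated`.  The handshake
#'   identity `sum(degrees) == 2 * n_edges` always holds.
#' @export
networkSummary <- function(net) {
    stopifnot(is(net, "CooccurrenceNetwork"))
    list(n_nodes = nrow(net@nodes),
         n_edges = nrow(net@edges),
         n_components = length(net@components),
         component_sizes = lengths(net@components),
         degrees = stats::setNames(net@nodes$degree, net@nodes$otu_id),
         n_isolated = sum(net@nodes$degree == 0L))
}

#' Convert a network to an igraph object
#'
#' @param net a [CooccurrenceNetwork-class].
#' @return an [igraph::igraph] with node attributes (total_abundance,
#'   prevalence, taxonomy, component) and edge attributes (r, p_value).
#' @export
asIgraph <- function(net) {
    stopifnot(is(net, "CooccurrenceNetwork"))
    v <- net@nodes
    names(v)[names(v) == "otu_id"] <- "name"
    v$taxonomy[is.na(v$taxonomy)] <- ""
    v$component[is.na(v$component)] <- -1L
    igraph::graph_from_data_frame(net@edges, directed = FALSE, vertices = v)
}

#' Export a network as GraphML
#'
#' @param net a [CooccurrenceNetwork-class].
#' @param path output `.graphml` path.
#' @return invisibly, `path`.
#' @export
exportGraphML <- function(net, path) {
    igraph::write_graph(asIgraph(net), path, format = "graphml")
    invisible(path)
}

#' Export the edge list and component membership tables
#'
#' Tab-separated: `edges` with columns otu_a, otu_b, r, p_value; and
#' `components` with columns otu_id, component (NA for isolated nodes).
#'
#' @param net a [CooccurrenceNetwork-class].
#' @param edgePath,componentPath output paths.
#' @return invisibly, the paths.
#' @export
exportEdgeList <- function(net, edgePath, componentPath = NULL) {
    stopifnot(is(net, "CooccurrenceNetwork"))
    utils::write.table(net@edges, edgePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(componentPath))
        utils::write.table(net@nodes[, c("otu_id", "component")],
                           componentPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    invisible(c(edgePath, componentPath))
}
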