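#' @include AllClasses.R AllGenerics.R cooccurrence.R diversity.R stoichiometry.R
NULL

#' Read a pipeline configuration file
#'
#' YAML with top-level keys: `otu_table` (path) or `simulate` (arguments of
#' [communitySimSpec()]), `filters` (arguments of [FilterCriteria()]),
#' `correlation_basis` (`relative`|`counts`), `diversity` (`log_base`,
#' `simpson_complement`, `drop_global_singletons`), `cultures` (list of
#' blocks with `label`, `substrate`, `substrate_umol`, `measured_ch4_umol`,
#' and `ceiling_umol` or `reductant_umol`), `output_dir`, `seed`.
#'
#' @param path YAML config file.
#' @return a named list.
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
}

.cfg <- function(config, key, default = NULL) {
    if (is.null(config[[key]])) default else config[[key]]
}

#' Run the full analysis pipeline
#'
#' Executes, in order: diversity report, global singleton removal,
#' candidate filtering, profile correlation, network construction and
#' summary, and (when cultures are configured) the stoichiometric
#' conversion assessment.  Every artifact is written under `output_dir`
#' with a JSON manifest recording inputs, parameters, package version,
#' seed, and an MD5 checksum per emitted file.  Identical config and
#' inputs give identical outputs.
#'
#' @param config a list (see [readPipelineConfig()]) or a YAML path.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readPipelineConfig(config)
    outDir <- .cfg(config, "output_dir")
    if (is.null(outDir)) stop("config must set output_dir")
    for (d in file.path(outDir, c("", "diversity", "network", "stoich")))
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    files <- character()
    emit <- function(rel) {
        files[[length(files) + 1L]] <<- rel
        file.path(outDir, rel)
    }

    ## ---- input ----
    tbl <- stage("input", {
        if (!is.null(config$otu_table)) readOtuTable(config$otu_table)
        else if (!is.null(config$simulate)) {
            args <- config$simulate
            if (is.null(args$seed)) args$seed <- .cfg(config, "seed", 1L)
            sim <- simulateCommunity(do.call(communitySimSpec, args))
            sim$table
        } else stop("config must give otu_table or simulate")
    })

    divOpts <- .cfg(config, "diversity", list())
    ## ---- diversity ----
    stage("diversity", {
        alpha <- alphaDiversity(
            tbl,
            base = .cfg(divOpts, "log_base", exp(1)),
            simpsonComplement = isTRUE(divOpts$simpson_complement),
            dropGlobalSingletons = isTRUE(divOpts$drop_global_singletons))
        utils::write.table(alpha, emit("diversity/alpha_diversity.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        m <- otuCounts(tbl)
        rare <- do.call(rbind, lapply(colnames(m), function(s) {
            rc <- rarefactionCurve(m[, s])
            cbind(sample = s, rc)
        }))
        utils::write.table(rare, emit("diversity/rarefaction.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        d <- brayCurtisMatrix(tbl)
        utils::write.table(data.frame(sample = rownames(d), d,
                                      check.names = FALSE),
                           emit("diversity/bray_curtis.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (ncol(m) >= 2L)
            ape::write.tree(upgmaTree(d), emit("diversity/upgma.nwk"))
    })

    ## ---- network ----
    criteria <- do.call(FilterCriteria, lapply(.cfg(config, "filters", list()),
                                               identity))
    basis <- .cfg(config, "correlation_basis", "relative")
    net <- stage("network", {
        t2 <- removeGlobalSingletons(tbl)
        t2 <- filterCandidates(t2, criteria)
        r <- profileCorrelation(t2, useRelative = identical(basis, "relative"))
        buildNetwork(r, t2, criteria)
    })
    stage("network export", {
        exportEdgeList(net, emit("network/edges.tsv"),
                       emit("network/components.tsv"))
        exportGraphML(net, emit("network/network.graphml"))
        s <- networkSummary(net)
        utils::write.table(
            data.frame(metric = c("n_nodes", "n_edges", "n_components",
                                  "n_isolated",
                                  paste0("component_size_", seq_along(s$component_sizes))),
                       value = c(s$n_nodes, s$n_edges, s$n_components,
                                 s$n_isolated, s$component_sizes)),
            emit("network/summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
    })

    ## ---- stoichiometry ----
    cultures <- .cfg(config, "cultures", list())
    if (length(cultures)) stage("stoichiometry", {
        rows <- lapply(cultures, function(cu)
            assessConversion(cu$substrate, cu$substrate_umol,
                             cu$measured_ch4_umol,
                             ceilingUmol = .cfg(cu, "ceiling_umol", NA_real_),
                             reductantUmol = .cfg(cu, "reductant_umol", NA_real_),
                             label = .cfg(cu, "label", NA_character_)))
        utils::write.table(do.call(rbind, rows),
                           emit("stoich/assessments.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    })

    ## ---- manifest ----
    paths <- file.path(outDir, files)
    manifest <- list(
        package = "SyntrophNet",
        version = as.character(utils::packageVersion("SyntrophNet")),
        seed = .cfg(config, "seed", NA),
        parameters = list(
            filters = list(min_samples_present = criteria@minSamplesPresent,
                           min_total_reads = criteria@minTotalReads,
                           min_pearson_r = criteria@minPearsonR,
                           positive_only = criteria@positiveOnly),
            correlation_basis = basis,
            diversity = divOpts),
        input = if (!is.null(config$otu_table)) config$otu_table
                else "simulated",
        files = lapply(seq_along(files), function(i)
            list(path = files[[i]],
                 md5 = unname(tools::md5sum(paths[[i]]))))
    )
    writeLines(yaml::as.yaml(manifest), file.path(outDir, "manifest.yaml"))
    invisible(manifest)
}
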