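#' @include AllClasses.R
NULL

#' @export
setGeneric("otuIds", function(x) standardGeneric("otuIds"))

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))

#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' @export
setGeneric("relativeAbundance", function(x) standardGeneric("relativeAbundance"))

#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @export
setGeneric("networkComponents", function(x) standardGeneric("networkComponents"))

#' @export
setGeneric("methaneCoefficient", function(x) standardGeneric("methaneCoefficient"))

#' @export
setGeneric("coefficientTable", function(x) standardGeneric("coefficientTable"))

## ---------------------------------------------------------------------------
## OtuTable accessors
## ---------------------------------------------------------------------------

#' Accessors for OtuTable
#'
#' `otuIds`, `sampleIds`, `otuCounts` and `taxonomy` extract the OTU
#' identifiers, sample identifiers, integer count matrix and the named
#' lineage vector (or `NULL` when absent).
#'
#' @param x an [OtuTable-class].
#' @return character vector, integer matrix, or named character vector.
#' @name OtuTable-accessors
#' @examples
#' tbl <- OtuTable(matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s2"))))
#' otuIds(tbl); sampleIds(tbl); otuCounts(tbl)
NULL

#' @rdname OtuTable-accessors
#' @export
setMethod("otuIds", "OtuTable", function(x) rownames(x))

#' @rdname OtuTable-accessors
#' @export
setMethod("sampleIds", "OtuTable", function(x) colnames(x))

#' @rdname OtuTable-accessors
#' @export
setMethod("otuCounts", "OtuTable",
    function(x) SummarizedExperiment::assay(x, "counts"))

#' @rdname OtuTable-accessors
#' @export
setMethod("taxonomy", "OtuTable", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if (!"taxonomy" %in% colnames(rd)) return(NULL)
    stats::setNames(rd$taxonomy, rownames(x))
})

setMethod("show", "OtuTable", function(object) {
    m <- otuCounts(object)
    cat(sprintf("OtuTable: %d OTUs x %d samples\n", nrow(m), ncol(m)))
    cat("  total reads per sample: ",
        paste(sprintf("%s=%d", colnames(m), colSums(m)), collapse = ", "),
        "\n", sep = "")
    if (!is.null(taxonomy(object)))
        cat(sprintf("  taxonomy: %d/%d OTUs annotated\n",
                    sum(!is.na(taxonomy(object))), nrow(m)))
})

## ---------------------------------------------------------------------------
## CooccurrenceNetwork accessors
## ---------------------------------------------------------------------------

#' Accessors for CooccurrenceNetwork
#'
#' @param x a [CooccurrenceNetwork-class].
#' @return `networkNodes` and `networkEdges` return data.frames;
#'   `networkComponents` a list of character vectors (largest component
#'   first).
#' @name CooccurrenceNetwork-accessors
NULL

#' @rdname CooccurrenceNetwork-accessors
#' @export
setMethod("networkNodes", "CooccurrenceNetwork", function(x) x@nodes)

#' @rdname CooccurrenceNetwork-accessors
#' @export
setMethod("networkEdges", "CooccurrenceNetwork", function(x) x@edges)

#' @rdname CooccurrenceNetwork-accessors
#' @export
setMethod("networkComponents", "CooccurrenceNetwork", function(x) x@components)

setMethod("show", "CooccurrenceNetwork", function(object) {
    sizes <- lengths(object@components)
    iso <- sum(is.na(object@nodes$component))
    cat(sprintf("CooccurrenceNetwork: %d nodes, %d edges (basis: %s, r >= %.3g)\n",
                nrow(object@nodes), nrow(object@edges), object@basis,
                object@criteria@minPearsonR))
    cat(sprintf("  %d connected component(s): %s; %d isolated node(s)\n",
                length(sizes),
                if (length(sizes)) paste(sizes, collapse = ", ") else "-",
                iso))
})

setMethod("show", "FilterCriteria", function(object) {
    cat(sprintf(paste0("FilterCriteria: present in >= %d samples, ",
                       ">= %d total reads, Pearson r >= %.3g%s\n"),
                object@minSamplesPresent, object@minTotalReads,
                object@minPearsonR,
                if (object@positiveOnly) " (positive only)" else ""))
})

setMethod("show", "MolecularFormula", function(object) {
    cat("MolecularFormula:", formatFormula(object), "\n")
})

setMethod("show", "CommunitySimSpec", function(object) {
    cat(sprintf(paste0("CommunitySimSpec: %d samples, %d background OTUs, ",
                       "blocks [%s], seed %d\n"),
                object@nSamples, object@nBackgroundOtus,
                paste(object@blockSizes, collapse = ", "), object@seed))
})
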