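#' @include AllClasses.R AllGenerics.R
NULL

#' Read an OTU count table
#'
#' Reads a tab-separated OTU table: first column OTU ids, header row sample
#' ids, optional last column named `taxonomy` with semicolon-delimited
#' lineages.  Rows are OTUs, columns samples (the common amplicon
#' convention); the reader rejects malformed input rather than guessing.
#'
#' @param path path to a tab-separated file.
#' @return an [OtuTable-class].
#' @seealso [writeOtuTable()]
#' @export
readOtuTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character",
                            check.names = FALSE, quote = "")
    if (nrow(df) == 0L || ncol(df) < 2L)
        stop("empty OTU table: ", path)
    ids <- df[[1L]]
    if (anyDuplicated(ids))
        stop("duplicated OTU id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    body <- df[, -1L, drop = FALSE]
    taxonomy <- NULL
    if (tolower(colnames(body)[ncol(body)]) == "taxonomy") {
        taxonomy <- stats::setNames(body[[ncol(body)]], ids)
        body <- body[, -ncol(body), drop = FALSE]
        if (ncol(body) == 0L) stop("empty OTU table (no sample columns): ", path)
    }
    if (anyDuplicated(colnames(body)))
        stop("duplicated sample id(s): ",
             paste(unique(colnames(body)[duplicated(colnames(body))]),
                   collapse = ", "))
    m <- matrix(NA_integer_, nrow(body), ncol(body),
                dimnames = list(ids, colnames(body)))
    for (j in seq_len(ncol(body))) {
        v <- suppressWarnings(as.numeric(body[[j]]))
        bad <- which(is.na(v) | v < 0 | v != round(v))
        if (length(bad))
            stop(sprintf(
                "invalid count for OTU '%s', sample '%s': '%s' (counts must be non-negative integers)",
                ids[bad[1L]], colnames(body)[j], body[[j]][bad[1L]]))
        m[, j] <- as.integer(v)
    }
    OtuTable(m, taxonomy = taxonomy)
}

#' Write an OTU count table
#'
#' Writes the tab-separated format read by [readOtuTable()]; a `taxonomy`
#' column is appended verbatim when lineages are present.  All-zero sample
#' columns are preserved.
#'
#' @param x an [OtuTable-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeOtuTable <- function(x, path) {
    stopifnot(is(x, "OtuTable"))
    m <- otuCounts(x)
    out <- data.frame(otu_id = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    tx <- taxonomy(x)
    if (!is.null(tx)) out$taxonomy <- unname(tx)
    ok <- tryCatch({
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("cannot write OTU table to: ", path)
    invisible(path)
}

#' Per-sample relative abundances
#'
#' Divides each sample (column) by its total read count; every column of
#' the result sums to 1.
#'
#' @param x an [OtuTable-class] or a non-negative count matrix.
#' @return a numeric matrix of fractions with the input's dimnames.
#' @export
setMethod("relativeAbundance", "OtuTable",
          function(x) relativeAbundance(otuCounts(x)))

#' @rdname relativeAbundance-OtuTable-method
#' @export
setMethod("relativeAbundance", "matrix", function(x) {
    tot <- colSums(x)
    zero <- which(tot == 0)
    if (length(zero))
        stop("sample(s) with zero total count: ",
             paste(colnames(x)[zero], collapse = ", "))
    sweep(x, 2L, tot, "/")
})

#' Collapse OTUs at a taxonomic rank
#'
#' Sums count rows that share the lineage label at `rankIndex` (1-based,
#' semicolon-delimited; SILVA/RDP-style rank prefixes such as `g__` are
#' stripped).  OTUs whose lineage is shallower than `rankIndex` collapse
#' under their deepest available rank prefixed `unclassified_`.  Per-sample
#' totals are conserved exactly.
#'
#' @param x an [OtuTable-class] with taxonomy for every OTU.
#' @param rankIndex 1-based rank position (e.g. 1 = domain).
#' @return an [OtuTable-class] keyed by rank label.
#' @export
collapseByTaxonomy <- function(x, rankIndex) {
    stopifnot(is(x, "OtuTable"))
    tx <- taxonomy(x)
    if (is.null(tx) || any(is.na(tx)))
        stop("taxonomy must be present for every OTU to collapse by rank")
    rankIndex <- as.integer(rankIndex)
    if (rankIndex < 1L) stop("rankIndex must be >= 1")
    labels <- vapply(strsplit(tx, ";", fixed = TRUE), function(ranks) {
        ranks <- trimws(ranks)
        ranks <- sub("^[a-zA-Z]__", "", ranks)
        ranks <- ranks[nzchar(ranks)]
        if (!length(ranks)) return("unclassified_")
        if (length(ranks) >= rankIndex) ranks[rankIndex]
        else paste0("unclassified_", ranks[length(ranks)])
    }, character(1L))
    m <- rowsum(otuCounts(x), group = labels, reorder = TRUE)
    storage.mode(m) <- "integer"
    OtuTable(m, taxonomy = stats::setNames(rownames(m), rownames(m)))
}

#' Read nucleotide sequences from FASTA
#'
#' Reads a FASTA file, joins wrapped lines, uppercases residues, and
#' validates the alphabet (`A`, `C`, `G`, `T`, `N` only).
#'
#' @param path FASTA file path.
#' @return a [Biostrings::DNAStringSet].
#' @export
readFastaSequences <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    # read residues verbatim first so disallowed letters are caught, not
    # silently dropped by the DNA alphabet coercion
    raw <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                    error = function(e) stop("invalid FASTA '", path, "': ",
                                             conditionMessage(e)))
    if (length(raw) == 0L) stop("empty FASTA file: ", path)
    chars <- toupper(as.character(raw))
    widths <- nchar(chars)
    if (any(widths == 0L))
        stop("record(s) with empty sequence: ",
             paste(names(raw)[widths == 0L], collapse = ", "))
    bad <- grepl("[^ACGTN]", chars)
    if (any(bad))
        stop("record(s) with residues outside {A,C,G,T,N}: ",
             paste(names(raw)[bad], collapse = ", "))
    Biostrings::DNAStringSet(stats::setNames(chars, names(raw)))
}
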