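#' @include AllClasses.R
NULL

.asDNAStringSet <- function(seqs) {
    if (is(seqs, "DNAStringSet")) return(seqs)
    if (is.character(seqs)) {
        s <- Biostrings::DNAStringSet(toupper(seqs))
        if (is.null(names(s))) names(s) <- paste0("seq", seq_along(s))
        return(s)
    }
    stop("sequences must be a DNAStringSet or character vector")
}

#' Global pairwise alignment with percent identity
#'
#' Needleman–Wunsch global alignment (via [Biostrings::pairwiseAlignment])
#' under linear gap scoring (+1 match, -1 mismatch, -2 per gap position by
#' default), followed by percent-identity computation over the aligned
#' columns.  Terminal-gap overhangs — the maximal leading and trailing runs
#' of gapped columns — are excluded from the identity denominator by
#' default, appropriate for end-trimmed amplicon fragments of unequal
#' length; set `includeTerminalGaps = TRUE` to count them.
#'
#' @param a,b sequences (character or single-element `DNAStringSet`).
#' @param match,mismatch,gap scores (gap is the per-position penalty,
#'   negative).
#' @param includeTerminalGaps count terminal-gap columns in the identity
#'   denominator.
#' @return list with `aligned_a`, `aligned_b` (gapped strings), `score`,
#'   `matches`, `aligned_columns` (after terminal-gap handling) and
#'   `identity` (percent).
#' @examples
#' globalAlignment("ACGTACGT", "ACGACGT")$identity  # 87.5
#' @export
globalAlignment <- function(a, b, match = 1, mismatch = -1, gap = -2,
                            includeTerminalGaps = FALSE) {
    a <- as.character(.asDNAStringSet(if (length(a) > 1) a[1] else a)[[1]])
    b <- as.character(.asDNAStringSet(if (length(b) > 1) b[1] else b)[[1]])
    if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                    mismatch = mismatch,
                                                    baseOnly = FALSE)
    aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0,
                                         gapExtension = abs(gap))
    ga <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    gb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    nc <- length(ga)
    keep <- rep(TRUE, nc)
    if (!includeTerminalGaps) {
        gapped <- ga == "-" | gb == "-"
        i <- 1L
        while (i <= nc && gapped[i]) { keep[i] <- FALSE; i <- i + 1L }
        i <- nc
        while (i >= 1L && gapped[i]) { keep[i] <- FALSE; i <- i - 1L }
    }
    matches <- sum(ga[keep] == gb[keep] & ga[keep] != "-")
    cols <- sum(keep)
    list(aligned_a = paste(ga, collapse = ""),
         aligned_b = paste(gb, collapse = ""),
         score = Biostrings::score(aln),
         matches = matches,
         aligned_columns = cols,
         identity = if (cols > 0) 100 * matches / cols else NA_real_)
}

#' Mean pairwise identity of marker-gene fragments
#'
#' Globally aligns every pair among k sequences and reports each pairwise
#' percent identity plus their arithmetic mean — the summary typically
#' quoted for a set of near-identical amplicons.
#'
#' @param seqs `DNAStringSet` or character vector, length >= 2.
#' @param ... passed to [globalAlignment()].
#' @return list with `mean_identity` and `pairs` (data.frame: seq_a,
#'   seq_b, identity, matches, aligned_columns).
#' @examples
#' meanPairwiseIdentity(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGAACGT"))
#' @export
meanPairwiseIdentity <- function(seqs, ...) {
    seqs <- .asDNAStringSet(seqs)
    k <- length(seqs)
    if (k < 2L) stop("at least 2 sequences required")
    ids <- names(seqs)
    rows <- list()
    for (i in seq_len(k - 1L)) {
        for (j in seq.int(i + 1L, k)) {
            al <- globalAlignment(as.character(seqs[[i]]),
                                  as.character(seqs[[j]]), ...)
            rows[[length(rows) + 1L]] <- data.frame(
                seq_a = ids[i], seq_b = ids[j],
                identity = al$identity, matches = al$matches,
                aligned_columns = al$aligned_columns,
                stringsAsFactors = FALSE)
        }
    }
    pairs <- do.call(rbind, rows)
    list(mean_identity = mean(pairs$identity), pairs = pairs)
}

#' Pairwise identity matrix
#'
#' @param seqs `DNAStringSet` or character vector, length >= 2.
#' @param ... passed to [globalAlignment()].
#' @return symmetric percent-identity matrix (diagonal 100).
#' @export
pairwiseIdentityMatrix <- function(seqs, ...) {
    seqs <- .asDNAStringSet(seqs)
    res <- meanPairwiseIdentity(seqs, ...)
    ids <- names(seqs)
    m <- matrix(100, length(ids), length(ids), dimnames = list(ids, ids))
    for (r in seq_len(nrow(res$pairs))) {
        p <- res$pairs[r, ]
        m[p$seq_a, p$seq_b] <- m[p$seq_b, p$seq_a] <- p$identity
    }
    m
}
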