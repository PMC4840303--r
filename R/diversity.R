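#' @include AllClasses.R AllGenerics.R
NULL

.checkCounts <- function(counts) {
    if (!is.numeric(counts) || length(counts) == 0L)
        stop("counts must be a non-empty numeric vector")
    if (any(counts < 0) || any(counts != round(counts)))
        stop("counts must be non-negative integers")
    counts
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` over OTUs with positive counts,
#' `p_i = n_i / N`.  Natural log (nats) by default.
#'
#' @param counts per-OTU read counts for one sample.
#' @param base logarithm base (default `exp(1)`).
#' @return Shannon H.
#' @examples
#' shannonIndex(c(50, 50))  # log(2)
#' @export
shannonIndex <- function(counts, base = exp(1)) {
    counts <- .checkCounts(counts)
    counts <- counts[counts > 0]
    if (!length(counts)) stop("at least one positive count required")
    p <- counts / sum(counts)
    -sum(p * log(p, base = base))
}

#' Simpson dominance
#'
#' The finite-sample dominance form
#' `D = sum(n_i * (n_i - 1)) / (N * (N - 1))`: the probability that two
#' reads drawn without replacement belong to the same OTU.  Low values mean
#' high diversity.  Set `complement = TRUE` for the Simpson diversity
#' `1 - D`.
#'
#' @param counts per-OTU read counts for one sample (total `N >= 2`).
#' @param complement return `1 - D` instead of `D`.
#' @return dominance in `[0, 1]` (or its complement).
#' @examples
#' simpsonDominance(c(2, 2))  # 1/3
#' @export
simpsonDominance <- function(counts, complement = FALSE) {
    counts <- .checkCounts(counts)
    N <- sum(counts)
    if (N < 2) stop("Simpson dominance needs at least 2 reads")
    D <- sum(counts * (counts - 1)) / (N * (N - 1))
    if (complement) 1 - D else D
}

#' Chao1 richness estimate
#'
#' Bias-corrected Chao1: `S_obs + n1 * (n1 - 1) / (2 * (n2 + 1))`, where
#' `n1` and `n2` are singleton and doubleton OTU counts; the `+1`
#' denominator keeps the estimator defined when no doubletons exist.
#'
#' @param counts per-OTU read counts for one sample.
#' @return a list with `chao1`, `S_obs`, `n1`, `n2`.
#' @examples
#' chao1Richness(c(1, 1, 2))$chao1  # 3.5
#' @export
chao1Richness <- function(counts) {
    counts <- .checkCounts(counts)
    if (!any(counts > 0)) stop("at least one positive count required")
    S <- sum(counts > 0)
    n1 <- sum(counts == 1)
    n2 <- sum(counts == 2)
    list(chao1 = S + n1 * (n1 - 1) / (2 * (n2 + 1)),
         S_obs = S, n1 = n1, n2 = n2)
}

#' Expected rarefied richness
#'
#' Expected number of OTUs in a random subsample of `m` reads drawn without
#' replacement:
#' `E[S_m] = sum_i (1 - choose(N - n_i, m) / choose(N, m))`, evaluated in
#' log space (`lchoose`) to avoid overflow at realistic read depths.
#'
#' @param counts per-OTU read counts for one sample.
#' @param m subsample depth, `1 <= m <= sum(counts)`.
#' @return expected OTU count at depth `m`.
#' @examples
#' rarefactionExpected(c(2, 2), 2)  # 5/3
#' @export
rarefactionExpected <- function(counts, m) {
    counts <- .checkCounts(counts)
    counts <- counts[counts > 0]
    N <- sum(counts)
    if (length(m) != 1L || m != round(m) || m < 1 || m > N)
        stop("m must be a single integer in [1, ", N, "]")
    sum(1 - exp(lchoose(N - counts, m) - lchoose(N, m)))
}

#' Rarefaction curve for one sample
#'
#' Evaluates [rarefactionExpected()] at a grid of depths (default 20
#' evenly spaced values up to the sample total).
#'
#' @param counts per-OTU read counts for one sample.
#' @param depths increasing integer depths; default
#'   `unique(round(seq(1, N, length.out = 20)))`.
#' @return data.frame with `depth` and `expected_otus`.
#' @export
rarefactionCurve <- function(counts, depths = NULL) {
    counts <- .checkCounts(counts)
    N <- sum(counts)
    if (is.null(depths))
        depths <- unique(round(seq(1, N, length.out = min(20, N))))
    data.frame(depth = as.integer(depths),
               expected_otus = vapply(depths, function(m)
                   rarefactionExpected(counts, m), numeric(1L)))
}

#' Bray-Curtis dissimilarity between two samples
#'
#' `1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b))` over a shared OTU set;
#' 0 for identical vectors, 1 for disjoint supports.
#'
#' @param a,b equal-length count vectors over the same OTU set.
#' @return dissimilarity in `[0, 1]`.
#' @examples
#' brayCurtis(c(10, 0, 5), c(5, 5, 5))  # 1/3
#' @export
brayCurtis <- function(a, b) {
    a <- .checkCounts(a); b <- .checkCounts(b)
    if (length(a) != length(b))
        stop("samples must be over the same OTU set (equal length)")
    if (sum(a) == 0 || sum(b) == 0)
        stop("both samples must have positive total counts")
    1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b))
}

#' Bray-Curtis dissimilarity matrix across samples
#'
#' @param x an [OtuTable-class] or count matrix (OTU x sample).
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
brayCurtisMatrix <- function(x) {
    m <- if (is(x, "OtuTable")) otuCounts(x) else as.matrix(x)
    ns <- ncol(m)
    d <- matrix(0, ns, ns, dimnames = list(colnames(m), colnames(m)))
    for (i in seq_len(ns - 1L))
        for (j in seq.int(i + 1L, ns))
            d[i, j] <- d[j, i] <- brayCurtis(m[, i], m[, j])
    d
}

#' UPGMA clustering of samples
#'
#' Average-linkage (UPGMA) agglomeration of a sample dissimilarity matrix,
#' returned as an `ape` `phylo` tree whose node heights are the merge
#' dissimilarities (ultrametric).
#'
#' @param d symmetric dissimilarity matrix with zero diagonal (e.g. from
#'   [brayCurtisMatrix()]), or a `dist`.
#' @return an [ape::phylo] tree.
#' @seealso [ape::write.tree()] for Newick export.
#' @export
upgmaTree <- function(d) {
    if (inherits(d, "dist")) d <- as.matrix(d)
    d <- as.matrix(d)
    if (nrow(d) < 2L) stop("at least 2 samples required")
    if (!isSymmetric(unname(d)) || any(abs(diag(d)) > 1e-12))
        stop("dissimilarity matrix must be symmetric with zero diagonal")
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    ape::as.phylo(hc)
}

#' Per-sample alpha-diversity report
#'
#' Computes observed OTUs, Shannon H, Simpson dominance D, bias-corrected
#' Chao1 with singleton/doubleton counts, and total reads for every sample.
#' Singletons are kept by default — Chao1 is undefined without them; set
#' `dropGlobalSingletons = TRUE` to apply the global single-read exclusion
#' used by the compositional and network stages before estimating.
#'
#' @param x an [OtuTable-class].
#' @param base Shannon logarithm base.
#' @param simpsonComplement report `1 - D` instead of dominance D.
#' @param dropGlobalSingletons remove OTUs with a single read across all
#'   samples first.
#' @return data.frame with columns `sample`, `S_obs`, `shannon`, `simpson`,
#'   `chao1`, `n1`, `n2`, `N`.
#' @export
alphaDiversity <- function(x, base = exp(1), simpsonComplement = FALSE,
                           dropGlobalSingletons = FALSE) {
    stopifnot(is(x, "OtuTable"))
    if (dropGlobalSingletons) x <- removeGlobalSingletons(x)
    m <- otuCounts(x)
    rows <- lapply(colnames(m), function(s) {
        v <- m[, s]
        ch <- chao1Richness(v)
        data.frame(sample = s, S_obs = ch$S_obs,
                   shannon = shannonIndex(v, base = base),
                   simpson = simpsonDominance(v, complement = simpsonComplement),
                   chao1 = ch$chao1, n1 = ch$n1, n2 = ch$n2, N = sum(v),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
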