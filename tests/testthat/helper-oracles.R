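# Independent brute-force oracles used to cross-check the implementation.
# These deliberately recompute everything from first principles (explicit
# loops, direct sums) and never call the package's own code paths.

# Pearson product-moment correlation by direct summation
oraclePearson <- function(x, y) {
    n <- length(x)
    mx <- sum(x) / n
    my <- sum(y) / n
    sxy <- sxx <- syy <- 0
    for (k in seq_len(n)) {
        sxy <- sxy + (x[k] - mx) * (y[k] - my)
        sxx <- sxx + (x[k] - mx)^2
        syy <- syy + (y[k] - my)^2
    }
    if (sxx == 0 || syy == 0) return(NA_real_)
    sxy / sqrt(sxx * syy)
}

# full double loop over OTU pairs applying the threshold rule
oracleEdges <- function(mat, threshold = 0.75, positiveOnly = TRUE) {
    ids <- rownames(mat)
    out <- list()
    for (i in seq_len(nrow(mat) - 1L)) {
        for (j in seq.int(i + 1L, nrow(mat))) {
            r <- oraclePearson(mat[i, ], mat[j, ])
            if (is.na(r)) next
            if (r >= threshold && (!positiveOnly || r > 0))
                out[[length(out) + 1L]] <- data.frame(
                    otu_a = min(ids[i], ids[j]), otu_b = max(ids[i], ids[j]),
                    r = r, stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(otu_a = character(), otu_b = character(),
                          r = numeric()))
    e <- do.call(rbind, out)
    e[order(e$otu_a, e$otu_b), , drop = FALSE]
}

# Needleman-Wunsch with linear gaps, tie-break diagonal > up > left
oracleAlign <- function(a, b, match = 1, mismatch = -1, gap = -2) {
    a <- strsplit(a, "")[[1]]
    b <- strsplit(b, "")[[1]]
    n <- length(a); m <- length(b)
    S <- matrix(0, n + 1L, m + 1L)
    S[, 1L] <- gap * 0:n
    S[1L, ] <- gap * 0:m
    for (i in seq_len(n))
        for (j in seq_len(m)) {
            d <- S[i, j] + if (a[i] == b[j]) match else mismatch
            S[i + 1L, j + 1L] <- max(d, S[i, j + 1L] + gap, S[i + 1L, j] + gap)
        }
    # traceback
    ga <- gb <- character()
    i <- n; j <- m
    while (i > 0L || j > 0L) {
        if (i > 0L && j > 0L &&
            S[i + 1L, j + 1L] ==
            S[i, j] + (if (a[i] == b[j]) match else mismatch)) {
            ga <- c(a[i], ga); gb <- c(b[j], gb); i <- i - 1L; j <- j - 1L
        } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
            ga <- c(a[i], ga); gb <- c("-", gb); i <- i - 1L
        } else {
            ga <- c("-", ga); gb <- c(b[j], gb); j <- j - 1L
        }
    }
    list(score = S[n + 1L, m + 1L],
         aligned_a = paste(ga, collapse = ""),
         aligned_b = paste(gb, collapse = ""))
}

# naive UPGMA returning the cophenetic (merge-height) matrix
oracleUpgmaCophenetic <- function(d) {
    ids <- rownames(d)
    clusters <- as.list(ids)
    coph <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
    while (length(clusters) > 1L) {
        best <- NULL
        for (i in seq_len(length(clusters) - 1L)) {
            for (j in seq.int(i + 1L, length(clusters))) {
                h <- mean(d[clusters[[i]], clusters[[j]]])
                if (is.null(best) || h < best$h - 1e-15) {
                    best <- list(i = i, j = j, h = h)
                }
            }
        }
        coph[clusters[[best$i]], clusters[[best$j]]] <- best$h
        coph[clusters[[best$j]], clusters[[best$i]]] <- best$h
        clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
        clusters[[best$j]] <- NULL
    }
    coph
}

# Monte-Carlo expected richness under subsampling without replacement
oracleRarefactionMC <- function(counts, m, draws = 10000) {
    pool <- rep(seq_along(counts), counts)
    s <- replicate(draws, length(unique(sample(pool, m))))
    list(mean = mean(s), se = stats::sd(s) / sqrt(draws))
}

# small random OTU table (every sample non-empty)
randomCountMatrix <- function(nOtus, nSamples, lambda = 20) {
    repeat {
        m <- matrix(stats::rpois(nOtus * nSamples, lambda) *
                        stats::rbinom(nOtus * nSamples, 1L, 0.7),
                    nOtus, nSamples,
                    dimnames = list(sprintf("OTU_%03d", seq_len(nOtus)),
                                    sprintf("s%02d", seq_len(nSamples))))
        if (all(colSums(m) > 0) && all(rowSums(m) > 0)) return(m)
    }
}
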