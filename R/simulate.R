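#' @include AllClasses.R AllGenerics.R cooccurrence.R
NULL

## run expr under a local, seeded RNG stream without disturbing the caller's
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    force(expr)
}

.otuIdFmt <- function(n) sprintf("OTU_%04d", seq_len(n))

#' Simulate a synthetic enrichment-culture community
#'
#' Generates an OTU table with the statistical structure the co-occurrence
#' analysis assumes: a planted dominant OTU with a stable profile, planted
#' blocks of abundant OTUs that co-vary through a shared per-sample latent
#' factor, a heavy-tailed rare background of OTUs with independent factors,
#' and per-sample multinomial read-depth noise.
#'
#' Expected abundance is `e_ij = base_i * exp(f_b(i),j + eps_ij)` with the
#' block factor `f ~ N(0, blockSignalSd^2)` shared within a block
#' (independent per background OTU; `N(0, dominantOtuSd^2)` for the
#' dominant OTU) and `eps ~ N(0, withinBlockNoiseSd^2)`; counts are drawn
#' per sample as `Multinomial(depth_j, e_.j / sum(e_.j))` (optionally with
#' a Dirichlet overdispersion layer).  Baselines reproduce the composition
#' typical of enrichment-culture panels: the dominant OTU holds
#' `dominantOtuFraction` of the expected reads, the background rare tail
#' `backgroundFraction`, and the abundant block members the remainder.
#' Identical spec and seed give identical output.
#'
#' @param spec a [CommunitySimSpec-class].
#' @return list with `table` (an [OtuTable-class] with synthetic taxonomy)
#'   and `truth` (list: `block_membership`, named integer with `NA` for
#'   background and the dominant OTU; `dominant_otu`; `planted_edges`,
#'   data.frame of all within-block pairs; `depths`).
#' @examples
#' sim <- simulateCommunity(communitySimSpec(seed = 42))
#' colSums(otuCounts(sim$table))  # equals the drawn depths exactly
#' @export
simulateCommunity <- function(spec) {
    stopifnot(is(spec, "CommunitySimSpec"))
    validObject(spec)
    .withSeed(spec@seed, {
        nBlocks <- length(spec@blockSizes)
        nBlockOtus <- sum(spec@blockSizes)
        # OTU order: dominant, block members, background
        nOtus <- 1L + nBlockOtus + spec@nBackgroundOtus
        if (nOtus < 2L) stop("simulation needs at least 2 OTUs")
        ids <- .otuIdFmt(nOtus)
        membership <- rep(NA_integer_, nOtus)
        if (nBlocks)
            membership[1L + seq_len(nBlockOtus)] <-
                rep(seq_len(nBlocks), spec@blockSizes)
        names(membership) <- ids

        # baselines: expected composition shares dominant / blocks / rare tail
        fDom <- spec@dominantOtuFraction
        fBg <- spec@backgroundFraction
        base <- numeric(nOtus)
        base[1L] <- fDom
        if (nBlockOtus) {
            b <- stats::rlnorm(nBlockOtus, 0, spec@blockBaseLogSd)
            base[1L + seq_len(nBlockOtus)] <- (1 - fDom - fBg) * b / sum(b)
        }
        if (spec@nBackgroundOtus) {
            b <- stats::rlnorm(spec@nBackgroundOtus, spec@baseLogMean,
                               spec@baseLogSd)
            base[(1L + nBlockOtus) + seq_len(spec@nBackgroundOtus)] <-
                fBg * b / sum(b)
        }

        depths <- if (all(is.na(spec@depths)))
            sample(spec@depthRange[1L]:spec@depthRange[2L], spec@nSamples,
                   replace = TRUE)
        else as.integer(round(spec@depths))

        # shared latent factor per block and sample; background independent;
        # the dominant OTU moves little (stable dominance across samples)
        blockF <- matrix(stats::rnorm(max(nBlocks, 1L) * spec@nSamples,
                                      0, spec@blockSignalSd),
                         nrow = max(nBlocks, 1L))
        fac <- matrix(0, nOtus, spec@nSamples)
        fac[1L, ] <- stats::rnorm(spec@nSamples, 0, spec@dominantOtuSd)
        for (i in seq_len(nOtus)[-1L]) {
            fac[i, ] <- if (!is.na(membership[i])) blockF[membership[i], ]
                        else stats::rnorm(spec@nSamples, 0, spec@blockSignalSd)
        }
        eps <- matrix(stats::rnorm(nOtus * spec@nSamples,
                                   0, spec@withinBlockNoiseSd),
                      nOtus, spec@nSamples)
        e <- base * exp(fac + eps)

        counts <- matrix(0L, nOtus, spec@nSamples,
                         dimnames = list(ids, sprintf("sample_%02d",
                                                      seq_len(spec@nSamples))))
        for (j in seq_len(spec@nSamples)) {
            p <- e[, j] / sum(e[, j])
            if (!is.na(spec@dirichletConcentration)) {
                g <- stats::rgamma(nOtus, shape = spec@dirichletConcentration * p)
                if (sum(g) == 0) g <- p
                p <- g / sum(g)
            }
            counts[, j] <- stats::rmultinom(1L, size = depths[j], prob = p)[, 1L]
        }

        tax <- ifelse(is.na(membership),
                      sprintf("Bacteria;SimBackground;SimGenus_%s", ids),
                      sprintf("Bacteria;SimBlock_%d;SimGenus_%s",
                              membership, ids))
        tax[1L] <- sprintf("Bacteria;SimDominant;SimGenus_%s", ids[1L])
        list(table = OtuTable(counts, taxonomy = stats::setNames(tax, ids)),
             truth = list(block_membership = membership,
                          dominant_otu = ids[1L],
                          planted_edges = .plantedEdges(membership),
                          depths = stats::setNames(depths, colnames(counts))))
    })
}

.plantedEdges <- function(membership) {
    rows <- list()
    for (b in sort(unique(membership[!is.na(membership)]))) {
        ids <- sort(names(membership)[which(membership == b)])
        k <- length(ids)
        if (k < 2L) next
        idx <- utils::combn(k, 2L)
        rows[[length(rows) + 1L]] <- data.frame(otu_a = ids[idx[1L, ]],
                                                otu_b = ids[idx[2L, ]],
                                                stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(data.frame(otu_a = character(), otu_b = character()))
    do.call(rbind, rows)
}

#' Deterministic fixture community for exact-valued network tests
#'
#' Fixture mode: no within-block noise and no multinomial draw — counts are
#' expected abundances rounded to integers, so within-block profiles are
#' exactly proportional (Pearson r essentially 1) and every block passes
#' the default prevalence and abundance filters.  Background OTUs are
#' constructed sparse (present in exactly 2 samples) so the three-sample
#' prevalence rule removes them by construction, making the recovered
#' component sizes equal the planted block sizes exactly.
#'
#' @param blockSizes planted block sizes (default 18, 15, 4).
#' @param nBackgroundOtus sparse background OTUs (default 30).
#' @param nSamples samples (default 5).
#' @param seed RNG seed.
#' @return same structure as [simulateCommunity()].
#' @examples
#' fix <- fixtureCommunity(seed = 42)
#' lengths(networkComponents(cooccurrenceNetwork(fix$table)))
#' @export
fixtureCommunity <- function(blockSizes = c(18L, 15L, 4L),
                             nBackgroundOtus = 30L, nSamples = 5L,
                             seed = 42L) {
    .withSeed(seed, {
        blockSizes <- as.integer(blockSizes)
        nOtus <- sum(blockSizes) + nBackgroundOtus
        ids <- .otuIdFmt(nOtus)
        membership <- rep(NA_integer_, nOtus)
        membership[seq_len(sum(blockSizes))] <-
            rep(seq_along(blockSizes), blockSizes)
        names(membership) <- ids
        counts <- matrix(0L, nOtus, nSamples,
                         dimnames = list(ids, sprintf("sample_%02d",
                                                      seq_len(nSamples))))
        for (b in seq_along(blockSizes)) {
            rows <- which(membership == b)
            g <- stats::runif(nSamples, 0.8, 3)       # shared sample factor
            base <- sample(30:400, length(rows), replace = TRUE)
            counts[rows, ] <- t(vapply(base, function(x)
                as.integer(round(x * g)), integer(nSamples)))
        }
        bg <- which(is.na(membership))
        for (i in bg) {
            s <- sample(nSamples, 2L)                 # prevalence 2 < 3
            counts[i, s] <- sample(5:40, 2L, replace = TRUE)
        }
        list(table = OtuTable(counts),
             truth = list(block_membership = membership,
                          planted_edges = .plantedEdges(membership),
                          depths = colSums(counts)))
    })
}

#' Edge-recovery precision and recall
#'
#' Scores a network inferred from a simulated table against the planted
#' within-block edge set.  Precision is `NA` when the network has no edges.
#'
#' @param net a [CooccurrenceNetwork-class].
#' @param truth the `truth` element returned by [simulateCommunity()].
#' @return list with `precision`, `recall`, `n_found`, `n_planted`,
#'   `n_true_positive`.
#' @export
recoveryMetrics <- function(net, truth) {
    stopifnot(is(net, "CooccurrenceNetwork"))
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
    found <- if (nrow(net@edges))
        key(net@edges$otu_a, net@edges$otu_b) else character()
    planted <- with(truth$planted_edges, key(otu_a, otu_b))
    tp <- length(intersect(found, planted))
    list(precision = if (length(found)) tp / length(found) else NA_real_,
         recall = if (length(planted)) tp / length(planted) else NA_real_,
         n_found = length(found), n_planted = length(planted),
         n_true_positive = tp)
}

#' Synthetic near-identical marker fragments
#'
#' Generates `n` copies of a random ancestor sequence, each carrying
#' `substitutionsPerFragment` substitutions at positions distinct across
#' all fragments — a synthetic stand-in for a small set of near-identical
#' amplicon fragments with a known pairwise-difference structure (any two
#' fragments differ at exactly `2 * substitutionsPerFragment` sites).
#'
#' @param n number of fragments (default 3).
#' @param width fragment length (default 393 nt, a typical end-trimmed
#'   amplicon).
#' @param substitutionsPerFragment substitutions per fragment (default 1).
#' @param seed RNG seed.
#' @return a [Biostrings::DNAStringSet] named `frag_1` ... `frag_n`.
#' @examples
#' frags <- simulateMarkerFragments(seed = 7)
#' meanPairwiseIdentity(frags)$mean_identity
#' @export
simulateMarkerFragments <- function(n = 3L, width = 393L,
                                    substitutionsPerFragment = 1L,
                                    seed = 1L) {
    if (n < 2L) stop("at least 2 fragments required")
    k <- as.integer(substitutionsPerFragment)
    if (n * k > width) stop("too many substitutions for the fragment width")
    .withSeed(seed, {
        alpha <- c("A", "C", "G", "T")
        anc <- sample(alpha, width, replace = TRUE)
        pos <- sample(width, n * k)
        frags <- vapply(seq_len(n), function(i) {
            s <- anc
            for (p in pos[seq.int((i - 1L) * k + 1L, i * k)])
                s[p] <- sample(setdiff(alpha, s[p]), 1L)
            paste(s, collapse = "")
        }, character(1L))
        Biostrings::DNAStringSet(stats::setNames(frags,
                                                 sprintf("frag_%d", seq_len(n))))
    })
}
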