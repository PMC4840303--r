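#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData rowData<-
NULL

## ---------------------------------------------------------------------------
## OtuTable
## ---------------------------------------------------------------------------

#' OtuTable: an OTU-by-sample count container
#'
#' `OtuTable` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single `"counts"` assay holding non-negative integer read counts, rows
#' being OTUs and columns samples.  An optional `taxonomy` column in
#' `rowData` stores semicolon-delimited lineage strings.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#'
#' @export
setClass("OtuTable", contains = "SummarizedExperiment")

.validOtuTable <- function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        if (!is.numeric(m))
            msg <- c(msg, "counts must be numeric")
        else {
            if (any(!is.finite(m)))
                msg <- c(msg, "counts must be finite")
            if (any(m < 0))
                msg <- c(msg, "counts must be non-negative")
            if (any(m != round(m)))
                msg <- c(msg, "counts must be whole numbers (read counts)")
        }
        if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
            msg <- c(msg, "OTU ids must be present and unique")
        if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
            msg <- c(msg, "sample ids must be present and unique")
        if (nrow(m) == 0L || ncol(m) == 0L)
            msg <- c(msg, "table must have at least one OTU and one sample")
    }
    tx <- SummarizedExperiment::rowData(object)
    if ("taxonomy" %in% colnames(tx) && !is.character(tx$taxonomy))
        msg <- c(msg, "taxonomy must be a character vector")
    if (length(msg)) msg else TRUE
}

setValidity("OtuTable", .validOtuTable)

#' Construct an OtuTable
#'
#' @param counts integer matrix (OTU x sample) with row and column names.
#' @param taxonomy optional character vector of semicolon-delimited lineages,
#'   either named by OTU id or in row order; may cover a subset of OTUs
#'   (missing entries become `NA`).
#'
#' @return An [OtuTable-class] object.
#' @examples
#' m <- matrix(c(10L, 0L, 5L, 5L, 0L, 1L), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("OTU_", 1:3), c("s1", "s2")))
#' OtuTable(m)
#' @export
OtuTable <- function(counts, taxonomy = NULL) {
    counts <- as.matrix(counts)
    if (is.double(counts) && any(counts != round(counts)))
        stop("counts must be whole numbers (read counts)")
    storage.mode(counts) <- "integer"
    rd <- S4Vectors::DataFrame(row.names = rownames(counts))
    if (!is.null(taxonomy)) {
        tax <- rep(NA_character_, nrow(counts))
        names(tax) <- rownames(counts)
        if (is.null(names(taxonomy))) {
            if (length(taxonomy) != nrow(counts))
                stop("unnamed taxonomy must have one entry per OTU")
            tax[] <- as.character(taxonomy)
        } else {
            unknown <- setdiff(names(taxonomy), rownames(counts))
            if (length(unknown))
                stop("taxonomy given for unknown OTU id(s): ",
                     paste(unknown, collapse = ", "))
            tax[names(taxonomy)] <- as.character(taxonomy)
        }
        rd$taxonomy <- unname(tax)
    }
    new("OtuTable", SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), rowData = rd))
}

## ---------------------------------------------------------------------------
## FilterCriteria
## ---------------------------------------------------------------------------

#' Co-occurrence candidate filter criteria
#'
#' Holds the inclusion rules for the co-occurrence analysis: an OTU enters
#' the correlation stage when it occurs in at least `minSamplesPresent`
#' samples with at least `minTotalReads` reads summed over all samples; an
#' edge is drawn when the Pearson correlation of two profiles reaches
#' `minPearsonR` (and is positive, when `positiveOnly`).  The defaults are
#' the three-of-five / 50-read / r >= 0.75 rules commonly applied to small
#' enrichment-culture panels.
#'
#' @slot minSamplesPresent integer, minimum prevalence.
#' @slot minTotalReads integer, minimum total abundance.
#' @slot minPearsonR numeric in \[-1, 1\], inclusive edge threshold.
#' @slot positiveOnly logical, keep only positively correlated pairs.
#' @export
setClass("FilterCriteria",
    representation(minSamplesPresent = "integer",
                   minTotalReads = "integer",
                   minPearsonR = "numeric",
                   positiveOnly = "logical"))

setValidity("FilterCriteria", function(object) {
    msg <- character()
    if (length(object@minSamplesPresent) != 1L || object@minSamplesPresent < 1L)
        msg <- c(msg, "minSamplesPresent must be a single integer >= 1")
    if (length(object@minTotalReads) != 1L || object@minTotalReads < 0L)
        msg <- c(msg, "minTotalReads must be a single integer >= 0")
    if (length(object@minPearsonR) != 1L ||
        object@minPearsonR < -1 || object@minPearsonR > 1)
        msg <- c(msg, "minPearsonR must lie in [-1, 1]")
    if (length(object@positiveOnly) != 1L || is.na(object@positiveOnly))
        msg <- c(msg, "positiveOnly must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
})

#' @rdname FilterCriteria-class
#' @param minSamplesPresent,minTotalReads,minPearsonR,positiveOnly see slots.
#' @return `FilterCriteria()` returns a [FilterCriteria-class] object.
#' @examples
#' FilterCriteria()
#' @export
FilterCriteria <- function(minSamplesPresent = 3L, minTotalReads = 50L,
                           minPearsonR = 0.75, positiveOnly = TRUE) {
    new("FilterCriteria",
        minSamplesPresent = as.integer(minSamplesPresent),
        minTotalReads = as.integer(minTotalReads),
        minPearsonR = as.numeric(minPearsonR),
        positiveOnly = as.logical(positiveOnly))
}

## ---------------------------------------------------------------------------
## CooccurrenceNetwork
## ---------------------------------------------------------------------------

#' Co-occurrence network of OTUs
#'
#' Nodes are the OTUs that passed the candidate filters; undirected edges
#' connect OTU pairs whose abundance-profile Pearson correlation reached
#' the threshold.  Connected components ("distinct networks") are ordered
#' by decreasing size, ties broken by smallest member OTU id; isolated
#' nodes (degree 0) carry component `NA` and are reported separately.
#'
#' @slot nodes data.frame: otu_id, total_abundance, prevalence, taxonomy,
#'   degree, component.
#' @slot edges data.frame: otu_a, otu_b, r, p_value (two-sided t-based).
#' @slot components list of character vectors of member OTU ids, largest
#'   first.
#' @slot basis character, `"relative"` or `"counts"` — the profile scale the
#'   correlations were computed on.
#' @slot criteria the [FilterCriteria-class] used.
#' @export
setClass("CooccurrenceNetwork",
    representation(nodes = "data.frame",
                   edges = "data.frame",
                   components = "list",
                   basis = "character",
                   criteria = "FilterCriteria"))

setValidity("CooccurrenceNetwork", function(object) {
    msg <- character()
    need_n <- c("otu_id", "total_abundance", "prevalence", "degree", "component")
    if (!all(need_n %in% colnames(object@nodes)))
        msg <- c(msg, "nodes must have columns otu_id, total_abundance, prevalence, degree, component")
    need_e <- c("otu_a", "otu_b", "r", "p_value")
    if (!all(need_e %in% colnames(object@edges)))
        msg <- c(msg, "edges must have columns otu_a, otu_b, r, p_value")
    if (nrow(object@edges)) {
        ep <- c(object@edges$otu_a, object@edges$otu_b)
        if (!all(ep %in% object@nodes$otu_id))
            msg <- c(msg, "every edge endpoint must be a node")
        if (any(object@edges$otu_a == object@edges$otu_b))
            msg <- c(msg, "self-edges are not allowed")
    }
    comp_members <- unlist(object@components, use.names = FALSE)
    if (anyDuplicated(comp_members))
        msg <- c(msg, "components must be disjoint")
    if (!object@basis %in% c("relative", "counts"))
        msg <- c(msg, "basis must be 'relative' or 'counts'")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Stoichiometry classes
## ---------------------------------------------------------------------------

#' Molecular formula of a CcHhOoNnSs substrate
#'
#' @slot c,h,o,n,s non-negative integer atom counts (carbon and hydrogen
#'   must be at least 1).
#' @slot name optional compound label.
#' @export
setClass("MolecularFormula",
    representation(c = "integer", h = "integer", o = "integer",
                   n = "integer", s = "integer", name = "character"))

setValidity("MolecularFormula", function(object) {
    msg <- character()
    at <- c(object@c, object@h, object@o, object@n, object@s)
    if (length(at) != 5L || any(is.na(at)) || any(at < 0L))
        msg <- c(msg, "atom counts must be single non-negative integers")
    else {
        if (object@c < 1L) msg <- c(msg, "at least one carbon atom required")
        if (object@h < 1L) msg <- c(msg, "at least one hydrogen atom required")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname MolecularFormula-class
#' @param c,h,o,n,s atom counts.
#' @param name optional label.
#' @return a [MolecularFormula-class].
#' @examples
#' molecularFormula(16, 32, o = 2, name = "palmitate")
#' @export
molecularFormula <- function(c, h, o = 0, n = 0, s = 0, name = NA_character_) {
    new("MolecularFormula", c = as.integer(c), h = as.integer(h),
        o = as.integer(o), n = as.integer(n), s = as.integer(s),
        name = as.character(name))
}

#' Balanced methanogenic-conversion coefficients
#'
#' Per mole of substrate: water consumed and CH4, CO2, NH4+ and H2S
#' produced under complete conversion to methane and carbon dioxide
#' (Symons–Buswell stoichiometry extended with nitrogen and sulfur terms).
#' Coefficients are exact rationals stored as integer numerator/denominator
#' pairs; the validity method asserts elemental balance in integer
#' arithmetic (nitrogen leaves as NH4+, consuming one proton per N, which
#' the hydrogen balance tracks).
#'
#' @slot formula the [MolecularFormula-class] the coefficients balance.
#' @slot water,ch4,co2,nh4,h2s length-2 integer vectors `c(num, den)`.
#' @export
setClass("BuswellCoefficients",
    representation(formula = "MolecularFormula",
                   water = "integer", ch4 = "integer", co2 = "integer",
                   nh4 = "integer", h2s = "integer"))

setValidity("BuswellCoefficients", function(object) {
    msg <- character()
    for (sl in c("water", "ch4", "co2", "nh4", "h2s")) {
        v <- slot(object, sl)
        if (length(v) != 2L || v[2L] < 1L)
            msg <- c(msg, paste0(sl, " must be c(numerator, denominator>0)"))
    }
    if (length(msg)) return(msg)
    f <- object@formula
    # integer balance on a common x8 scale (all denominators divide 8)
    to8 <- function(v) {
        stopifnot(8L %% v[2L] == 0L)
        v[1L] * (8L %/% v[2L])
    }
    w8 <- to8(object@water); m8 <- to8(object@ch4); d8 <- to8(object@co2)
    n8 <- to8(object@nh4); s8 <- to8(object@h2s)
    if (8L * f@c != m8 + d8)
        msg <- c(msg, "carbon unbalanced")
    if (8L * f@o + w8 != 2L * d8)
        msg <- c(msg, "oxygen unbalanced")
    # H in: substrate + water + protons (one per NH4+); H out: CH4, NH4+, H2S
    if (8L * f@h + 2L * w8 + 8L * f@n != 4L * m8 + 4L * n8 + 2L * s8)
        msg <- c(msg, "hydrogen unbalanced")
    if (8L * f@n != n8) msg <- c(msg, "nitrogen unbalanced")
    if (8L * f@s != s8) msg <- c(msg, "sulfur unbalanced")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CommunitySimSpec
## ---------------------------------------------------------------------------

#' Synthetic community simulation parameters
#'
#' Describes a simulated panel of related enrichment-culture samples:
#' log-normal base abundances (heavy-tailed, with one planted dominant OTU),
#' planted blocks of co-varying OTUs driven by a shared per-sample latent
#' factor, independent background OTUs, and per-sample multinomial
#' sequencing-depth noise.
#'
#' @slot nSamples number of samples (default 5, a typical culture panel).
#' @slot nBackgroundOtus OTUs with independent latent factors (default 260).
#' @slot blockSizes sizes of planted co-varying blocks (default 18, 15, 4).
#' @slot baseLogMean,baseLogSd log-normal parameters of background
#'   (unstructured, rare-tail) baseline abundances (log scale).
#' @slot blockBaseLogSd log-normal spread of baseline abundance within the
#'   planted blocks (narrower than the background tail: block members
#'   emulate the abundant, detectable network taxa).
#' @slot backgroundFraction expected share of reads held by the background
#'   tail (default 0.12; the abundant taxa of a typical enrichment panel
#'   capture ~87-99% of reads, leaving the rare tail ~1-13%).
#' @slot blockSignalSd sd of the shared per-sample block factor (log scale).
#' @slot withinBlockNoiseSd sd of each OTU's deviation from its block factor.
#' @slot dominantOtuSd sd of the dominant OTU's own latent factor; small by
#'   default (0.25) so its relative abundance stays in the stable 30-60%
#'   band dominant genera show across related cultures.
#' @slot depths per-sample read totals; `NA` means draw uniformly from
#'   `depthRange`.
#' @slot depthRange integer range for drawn depths (default 5000–20000).
#' @slot dominantOtuFraction expected relative abundance of the planted
#'   dominant OTU (default 0.4).
#' @slot dirichletConcentration optional Dirichlet overdispersion layer;
#'   `NA` disables it (plain multinomial).
#' @slot seed integer RNG seed (required; identical spec + seed gives
#'   identical output).
#' @export
setClass("CommunitySimSpec",
    representation(nSamples = "integer", nBackgroundOtus = "integer",
                   blockSizes = "integer", baseLogMean = "numeric",
                   baseLogSd = "numeric", blockBaseLogSd = "numeric",
                   backgroundFraction = "numeric", blockSignalSd = "numeric",
                   withinBlockNoiseSd = "numeric", dominantOtuSd = "numeric",
                   depths = "numeric", depthRange = "integer",
                   dominantOtuFraction = "numeric",
                   dirichletConcentration = "numeric", seed = "integer"))

setValidity("CommunitySimSpec", function(object) {
    msg <- character()
    if (object@nSamples < 2L) msg <- c(msg, "nSamples must be >= 2")
    if (object@nBackgroundOtus < 0L) msg <- c(msg, "nBackgroundOtus must be >= 0")
    if (length(object@blockSizes) && any(object@blockSizes < 2L))
        msg <- c(msg, "each block needs at least 2 members")
    if (object@baseLogSd < 0 || object@blockBaseLogSd < 0 ||
        object@blockSignalSd < 0 || object@withinBlockNoiseSd < 0 ||
        object@dominantOtuSd < 0)
        msg <- c(msg, "spread parameters must be non-negative")
    if (object@backgroundFraction <= 0 || object@backgroundFraction >= 1)
        msg <- c(msg, "backgroundFraction must lie in (0, 1)")
    if (object@dominantOtuFraction + object@backgroundFraction >= 1)
        msg <- c(msg, "dominant and background fractions must sum to < 1")
    if (!all(is.na(object@depths))) {
        if (length(object@depths) != object@nSamples)
            msg <- c(msg, "depths must have one entry per sample")
        else if (any(object@depths < 1))
            msg <- c(msg, "depths must be positive")
    }
    if (object@dominantOtuFraction <= 0 || object@dominantOtuFraction >= 1)
        msg <- c(msg, "dominantOtuFraction must lie in (0, 1)")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "seed is required")
    if (length(msg)) msg else TRUE
})

#' @rdname CommunitySimSpec-class
#' @param nSamples,nBackgroundOtus,blockSizes,baseLogMean,baseLogSd see slots.
#' @param blockBaseLogSd,backgroundFraction,dominantOtuSd see slots.
#' @param blockSignalSd,withinBlockNoiseSd,depths,depthRange see slots.
#' @param dominantOtuFraction,dirichletConcentration,seed see slots.
#' @return a [CommunitySimSpec-class].
#' @examples
#' communitySimSpec(seed = 42)
#' @export
communitySimSpec <- function(nSamples = 5, nBackgroundOtus = 260,
                             blockSizes = c(18, 15, 4),
                             baseLogMean = 0, baseLogSd = 1.5,
                             blockBaseLogSd = 0.7, backgroundFraction = 0.05,
                             blockSignalSd = 1.0, withinBlockNoiseSd = 0.1,
                             dominantOtuSd = 0.25,
                             depths = NA, depthRange = c(5000L, 20000L),
                             dominantOtuFraction = 0.4,
                             dirichletConcentration = NA_real_, seed) {
    if (missing(seed)) stop("a seed is required for reproducible simulation")
    new("CommunitySimSpec",
        nSamples = as.integer(nSamples),
        nBackgroundOtus = as.integer(nBackgroundOtus),
        blockSizes = as.integer(blockSizes),
        baseLogMean = as.numeric(baseLogMean),
        baseLogSd = as.numeric(baseLogSd),
        blockBaseLogSd = as.numeric(blockBaseLogSd),
        backgroundFraction = as.numeric(backgroundFraction),
        blockSignalSd = as.numeric(blockSignalSd),
        withinBlockNoiseSd = as.numeric(withinBlockNoiseSd),
        dominantOtuSd = as.numeric(dominantOtuSd),
        depths = as.numeric(depths),
        depthRange = as.integer(depthRange),
        dominantOtuFraction = as.numeric(dominantOtuFraction),
        dirichletConcentration = as.numeric(dirichletConcentration),
        seed = as.integer(seed))
}
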