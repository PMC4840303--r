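fiveSampleTable <- function(rows) {
    m <- do.call(rbind, rows)
    dimnames(m) <- list(sprintf("OTU_%02d", seq_len(nrow(m))),
                        sprintf("s%d", seq_len(ncol(m))))
    OtuTable(m)
}

test_that("global singleton removal drops only total-count-1 OTUs", {
    tbl <- fiveSampleTable(list(c(1L, 0L, 0L, 0L, 0L),
                                c(1L, 1L, 0L, 0L, 0L),
                                c(9L, 9L, 9L, 9L, 9L)))
    out <- removeGlobalSingletons(tbl)
    expect_setequal(otuIds(out), c("OTU_02", "OTU_03"))

    none <- fiveSampleTable(list(c(2L, 0L, 0L, 0L, 0L),
                                 c(3L, 3L, 3L, 3L, 3L)))
    expect_identical(otuCounts(removeGlobalSingletons(none)),
                     otuCounts(none))
})

test_that("candidate filter applies prevalence and abundance thresholds inclusively", {
    tbl <- fiveSampleTable(list(c(25L, 25L, 0L, 0L, 0L),   # prevalence 2
                                c(20L, 20L, 9L, 0L, 0L),   # total 49
                                c(20L, 20L, 10L, 0L, 0L),  # boundary: keep
                                c(40L, 30L, 20L, 10L, 5L)))
    out <- filterCandidates(tbl, FilterCriteria())
    expect_setequal(otuIds(out), c("OTU_03", "OTU_04"))
    expect_error(filterCandidates(tbl, FilterCriteria(minSamplesPresent = 6)),
                 "exceeds")
})

test_that("candidate retention is monotone in both thresholds", {
    set.seed(31)
    tbl <- OtuTable(randomCountMatrix(40, 5, lambda = 8))
    loose <- otuIds(filterCandidates(tbl, FilterCriteria(2, 10)))
    for (cr in list(FilterCriteria(3, 10), FilterCriteria(2, 40),
                    FilterCriteria(4, 60))) {
        strict <- tryCatch(otuIds(filterCandidates(tbl, cr)),
                           error = function(e) character())
        expect_true(all(strict %in% loose))
    }
})

test_that("profile correlation matches hand-computed product-moment values", {
    tbl <- fiveSampleTable(list(c(1L, 2L, 3L, 4L, 5L),
                                c(2L, 4L, 6L, 8L, 10L),
                                c(5L, 4L, 3L, 2L, 1L),
                                c(1L, 3L, 2L, 5L, 4L)))
    r <- profileCorrelation(tbl, useRelative = FALSE)
    expect_equal(unname(r["OTU_01", "OTU_02"]), 1)
    expect_equal(unname(r["OTU_01", "OTU_03"]), -1)
    expect_equal(unname(r["OTU_01", "OTU_04"]), 0.8)
    expect_equal(r, t(r))
    expect_equal(unname(diag(r)), rep(1, 4))

    two <- OtuTable(matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s2"))))
    expect_error(profileCorrelation(two), "3 samples")
})

test_that("zero-variance profiles are excluded with a warning, not an error", {
    tbl <- fiveSampleTable(list(c(10L, 10L, 10L, 10L, 10L),
                                c(1L, 2L, 3L, 4L, 5L),
                                c(2L, 4L, 6L, 8L, 10L)))
    expect_warning(r <- profileCorrelation(tbl, useRelative = FALSE),
                   "OTU_01")
    expect_true(all(is.na(r["OTU_01", c("OTU_02", "OTU_03")])))
    net <- buildNetwork(r, tbl, FilterCriteria())
    expect_false("OTU_01" %in% c(net@edges$otu_a, net@edges$otu_b))
})

test_that("correlation basis matters when sequencing depths are unequal", {
    # depth-driven non-invariance: counts and relative abundances disagree
    tbl <- fiveSampleTable(list(c(10L, 100L, 20L, 200L, 40L),
                                c(90L, 900L, 60L, 600L, 30L),
                                c(50L, 500L, 80L, 800L, 10L)))
    rc <- profileCorrelation(tbl, useRelative = FALSE)
    rr <- profileCorrelation(tbl, useRelative = TRUE)
    expect_gt(max(abs(rc - rr), na.rm = TRUE), 0.1)
    expect_equal(attr(rc, "basis"), "counts")
    expect_equal(attr(rr, "basis"), "relative")
})

test_that("network construction obeys threshold boundary and handshake identity", {
    tbl <- fiveSampleTable(list(c(1L, 2L, 3L, 4L, 5L),
                                c(2L, 4L, 6L, 8L, 10L),
                                c(3L, 6L, 9L, 12L, 15L)))
    net <- cooccurrenceNetwork(tbl, FilterCriteria(minSamplesPresent = 3,
                                                   minTotalReads = 0),
                               useRelative = FALSE)
    s <- networkSummary(net)
    expect_equal(s$n_edges, 3L)
    expect_equal(s$n_components, 1L)
    expect_equal(unname(s$degrees), c(2L, 2L, 2L))
    expect_equal(sum(s$degrees), 2L * s$n_edges)

    # r just below an inclusive threshold forms no edge
    r <- matrix(c(1, 0.7499, 0.7499, 1), 2,
                dimnames = list(c("a", "b"), c("a", "b")))
    t2 <- OtuTable(matrix(c(1L, 2L, 3L, 2L, 3L, 5L), 2, byrow = TRUE,
                          dimnames = list(c("a", "b"), c("s1", "s2", "s3"))))
    expect_equal(nrow(buildNetwork(r, t2, FilterCriteria())@edges), 0L)
    r[1, 2] <- r[2, 1] <- 0.75
    expect_equal(nrow(buildNetwork(r, t2, FilterCriteria())@edges), 1L)
})

test_that("edge p-values are two-sided t-based with df = samples - 2", {
    set.seed(32)
    tbl <- OtuTable(randomCountMatrix(10, 5))
    net <- suppressWarnings(
        cooccurrenceNetwork(tbl, FilterCriteria(1, 0, 0.2), useRelative = FALSE))
    if (nrow(net@edges)) {
        e <- net@edges
        expected <- vapply(seq_len(nrow(e)), function(k) {
            stats::cor.test(
                otuCounts(tbl)[e$otu_a[k], ], otuCounts(tbl)[e$otu_b[k], ],
                method = "pearson")$p.value
        }, numeric(1))
        expect_equal(e$p_value, expected, tolerance = 1e-9)
    }
    # perfectly collinear profiles get p = 0, not NaN
    t3 <- fiveSampleTable(list(c(1L, 2L, 3L, 4L, 5L), c(2L, 4L, 6L, 8L, 10L)))
    net3 <- cooccurrenceNetwork(t3, FilterCriteria(3, 0), useRelative = FALSE)
    expect_equal(net3@edges$p_value, 0)
})

test_that("components partition connected nodes, isolated nodes set aside", {
    # two disjoint perfectly correlated pairs + one anticorrelated loner
    tbl <- fiveSampleTable(list(c(1L, 2L, 3L, 4L, 5L),
                                c(2L, 4L, 6L, 8L, 10L),
                                c(5L, 3L, 8L, 2L, 9L),
                                c(10L, 6L, 16L, 4L, 18L),
                                c(9L, 7L, 5L, 3L, 1L)))
    net <- cooccurrenceNetwork(tbl, FilterCriteria(3, 0), useRelative = FALSE)
    s <- networkSummary(net)
    expect_equal(s$n_components, 2L)
    expect_equal(unname(s$component_sizes), c(2L, 2L))
    expect_equal(s$n_isolated, 1L)
    expect_true(is.na(networkNodes(net)$component[
        networkNodes(net)$otu_id == "OTU_05"]))
    # every edge endpoint is a node; components cover exactly degree>0 nodes
    expect_setequal(unlist(networkComponents(net)),
                    networkNodes(net)$otu_id[networkNodes(net)$degree > 0])
})

test_that("full network equals the brute-force pairwise oracle on small tables", {
    set.seed(33)
    for (i in 1:25) {
        m <- randomCountMatrix(sample(5:20, 1), 5)
        tbl <- OtuTable(m)
        net <- suppressWarnings(
            cooccurrenceNetwork(tbl, FilterCriteria(1, 0), useRelative = FALSE,
                                removeSingletons = FALSE))
        oracle <- oracleEdges(m, 0.75, TRUE)
        got <- net@edges
        expect_equal(paste(got$otu_a, got$otu_b),
                     paste(oracle$otu_a, oracle$otu_b))
        expect_equal(got$r, oracle$r, tolerance = 1e-12)
    }
})

test_that("exports produce igraph-loadable GraphML and faithful edge lists", {
    set.seed(34)
    sim <- fixtureCommunity(blockSizes = c(5, 3), nBackgroundOtus = 5,
                            seed = 9)
    net <- cooccurrenceNetwork(sim$table)
    g <- withr::local_tempfile(fileext = ".graphml")
    e <- withr::local_tempfile(fileext = ".tsv")
    cpath <- withr::local_tempfile(fileext = ".tsv")
    exportGraphML(net, g)
    exportEdgeList(net, e, cpath)
    back <- igraph::read_graph(g, format = "graphml")
    expect_equal(igraph::gsize(back), nrow(net@edges))
    expect_equal(igraph::vcount(back), nrow(net@nodes))
    el <- utils::read.delim(e)
    expect_equal(nrow(el), nrow(net@edges))
    expect_equal(el$r, net@edges$r, tolerance = 1e-9)
    comp <- utils::read.delim(cpath)
    expect_equal(nrow(comp), nrow(net@nodes))
})
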