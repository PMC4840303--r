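test_that("simulation is byte-identical under a fixed seed", {
    sp <- communitySimSpec(seed = 42)
    a <- simulateCommunity(sp)
    b <- simulateCommunity(sp)
    expect_identical(otuCounts(a$table), otuCounts(b$table))
    expect_identical(a$truth, b$truth)
    expect_identical(serialize(otuCounts(a$table), NULL),
                     serialize(otuCounts(b$table), NULL))
    # a different seed changes the draw
    c <- simulateCommunity(communitySimSpec(seed = 43))
    expect_false(identical(otuCounts(a$table), otuCounts(c$table)))
})

test_that("per-sample totals equal the specified depths exactly", {
    sim <- simulateCommunity(communitySimSpec(seed = 42))
    expect_identical(as.integer(colSums(otuCounts(sim$table))),
                     as.integer(unname(sim$truth$depths)))
    fixed <- simulateCommunity(communitySimSpec(depths = c(5e3, 1e4, 2e4,
                                                           7e3, 9e3),
                                                seed = 7))
    expect_equal(unname(colSums(otuCounts(fixed$table))),
                 c(5000L, 10000L, 20000L, 7000L, 9000L))
})

test_that("simulation does not disturb the caller's RNG stream", {
    set.seed(99)
    before <- .Random.seed
    invisible(simulateCommunity(communitySimSpec(seed = 1)))
    expect_identical(.Random.seed, before)
})

test_that("dominant OTU holds its planted share and stays stable", {
    sim <- simulateCommunity(communitySimSpec(nSamples = 10, seed = 42))
    ra <- relativeAbundance(sim$table)[sim$truth$dominant_otu, ]
    expect_gt(mean(ra), 0.25)
    expect_lt(mean(ra), 0.55)
    expect_false(sim$truth$dominant_otu %in%
                     unlist(sim$truth$planted_edges))
})

test_that("planted edge set is the union of within-block complete graphs", {
    sim <- simulateCommunity(communitySimSpec(blockSizes = c(4, 3),
                                              nBackgroundOtus = 10,
                                              seed = 5))
    expect_equal(nrow(sim$truth$planted_edges), choose(4, 2) + choose(3, 2))
    mb <- sim$truth$block_membership
    with(sim$truth$planted_edges, {
        expect_true(all(mb[otu_a] == mb[otu_b]))
        expect_true(all(otu_a < otu_b))
    })
    expect_equal(sum(!is.na(mb)), 7L)
})

test_that("fixture mode plants exactly proportional blocks and sparse background", {
    fix <- fixtureCommunity(seed = 42)
    m <- otuCounts(fix$table)
    mb <- fix$truth$block_membership
    # within-block profiles are near-collinear (rounding only)
    b1 <- names(mb)[which(mb == 1L)]
    r <- stats::cor(t(m[b1, ]))
    expect_gt(min(r), 0.99)
    # background has prevalence exactly 2 (fails the 3-sample rule)
    bg <- names(mb)[is.na(mb)]
    expect_true(all(rowSums(m[bg, ] > 0) == 2L))
    # deterministic
    expect_identical(m, otuCounts(fixtureCommunity(seed = 42)$table))
})

test_that("recovery metrics score found against planted edges", {
    fix <- fixtureCommunity(blockSizes = c(4, 3), nBackgroundOtus = 6,
                            seed = 3)
    net <- cooccurrenceNetwork(fix$table)
    m <- recoveryMetrics(net, fix$truth)
    expect_equal(m$precision, 1)
    expect_equal(m$recall, 1)

    # empty network: precision undefined, recall zero
    empty <- new("CooccurrenceNetwork",
                 nodes = data.frame(otu_id = "a", total_abundance = 1,
                                    prevalence = 1, taxonomy = NA_character_,
                                    degree = 0L, component = NA_integer_),
                 edges = data.frame(otu_a = character(), otu_b = character(),
                                    r = numeric(), p_value = numeric()),
                 components = list(), basis = "relative",
                 criteria = FilterCriteria())
    m0 <- recoveryMetrics(empty, fix$truth)
    expect_true(is.na(m0$precision))
    expect_equal(m0$recall, 0)
})

test_that("overdispersion layer keeps depth conservation", {
    sim <- simulateCommunity(communitySimSpec(dirichletConcentration = 50,
                                              seed = 11))
    expect_identical(as.integer(colSums(otuCounts(sim$table))),
                     as.integer(unname(sim$truth$depths)))
})

test_that("spec validation rejects impossible parameters", {
    expect_error(communitySimSpec(nSamples = 1, seed = 1), "nSamples")
    expect_error(communitySimSpec(dominantOtuFraction = 1.2, seed = 1),
                 "dominantOtuFraction")
    expect_error(communitySimSpec(depths = c(100, 200), seed = 1),
                 "one entry per sample")
    expect_error(communitySimSpec(seed = 1, backgroundFraction = 0.7,
                                  dominantOtuFraction = 0.4), "sum")
    expect_error(communitySimSpec(nSamples = 5), "seed")
})

test_that("synthetic marker fragments differ at exactly the planted sites", {
    frags <- simulateMarkerFragments(n = 3, width = 393,
                                     substitutionsPerFragment = 1, seed = 7)
    expect_equal(length(frags), 3L)
    expect_true(all(Biostrings::width(frags) == 393L))
    ch <- lapply(as.character(frags), function(s) strsplit(s, "")[[1]])
    for (i in 1:2) for (j in (i + 1):3)
        expect_equal(sum(ch[[i]] != ch[[j]]), 2L)
    # determinism
    expect_identical(as.character(frags),
                     as.character(simulateMarkerFragments(seed = 7)))
})
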