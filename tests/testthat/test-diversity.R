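test_that("Shannon index matches closed forms and is maximal at uniformity", {
    expect_equal(shannonIndex(c(50, 50)), log(2))
    expect_equal(shannonIndex(7), 0)
    expect_equal(shannonIndex(c(1, 2, 3)), 1.011404, tolerance = 1e-6)
    expect_equal(shannonIndex(c(4, 4), base = 2), 1)

    # adding a zero-count OTU changes nothing; uniform is the maximum
    set.seed(11)
    for (i in 1:20) {
        v <- sample(1:50, sample(2:10, 1), replace = TRUE)
        expect_equal(shannonIndex(c(v, 0)), shannonIndex(v))
        expect_lte(shannonIndex(v), log(length(v)) + 1e-12)
    }
    expect_equal(shannonIndex(rep(13, 7)), log(7))
    expect_error(shannonIndex(c(0, 0)), "positive")
})

test_that("Shannon agrees with vegan on random count vectors", {
    skip_if_not_installed("vegan")
    set.seed(12)
    for (i in 1:10) {
        v <- sample(1:100, 8, replace = TRUE)
        expect_equal(shannonIndex(v), unname(vegan::diversity(v, "shannon")))
    }
})

test_that("Simpson dominance uses the finite-sample form", {
    expect_equal(simpsonDominance(c(9, 0)), 1)      # complete dominance
    expect_equal(simpsonDominance(c(1, 1)), 0)
    expect_equal(simpsonDominance(c(2, 2)), 1 / 3)
    expect_equal(simpsonDominance(c(2, 2), complement = TRUE), 2 / 3)
    # uniform community with n per OTU: D = (n-1)/(Sn-1), decreasing in S
    n <- 5
    D <- vapply(2:8, function(S) simpsonDominance(rep(n, S)), numeric(1))
    expect_equal(D, (n - 1) / ((2:8) * n - 1))
    expect_true(all(diff(D) < 0))
    expect_error(simpsonDominance(1), "at least 2")
})

test_that("Chao1 is bias-corrected and never below observed richness", {
    expect_equal(chao1Richness(c(5, 3, 2))$chao1, 3)      # no singletons
    expect_equal(chao1Richness(c(1, 1, 2))$chao1, 3.5)
    expect_equal(chao1Richness(1)$chao1, 1)
    set.seed(13)
    for (i in 1:20) {
        v <- stats::rpois(30, 2)
        if (!any(v > 0)) next
        ch <- chao1Richness(v)
        expect_gte(ch$chao1, ch$S_obs)
        expect_equal(ch$chao1 == ch$S_obs, ch$n1 * (ch$n1 - 1) == 0)
    }
})

test_that("Chao1 agrees with vegan's bias-corrected estimateR", {
    skip_if_not_installed("vegan")
    set.seed(14)
    for (i in 1:10) {
        v <- stats::rpois(40, 1.5)
        if (sum(v) < 2) next
        expect_equal(chao1Richness(v)$chao1,
                     unname(vegan::estimateR(v)["S.chao1"]))
    }
})

test_that("expected rarefied richness matches the hypergeometric form", {
    v <- c(2, 2)
    expect_equal(rarefactionExpected(v, 2), 5 / 3)
    expect_equal(rarefactionExpected(v, sum(v)), 2)   # full depth
    expect_equal(rarefactionExpected(v, 1), 1)
    expect_error(rarefactionExpected(v, 0), "m must be")
    expect_error(rarefactionExpected(v, 5), "m must be")

    # curve is non-decreasing and hits S_obs at N
    set.seed(15)
    v <- sample(1:40, 12, replace = TRUE)
    rc <- rarefactionCurve(v)
    expect_true(all(diff(rc$expected_otus) >= -1e-12))
    expect_equal(rc$expected_otus[nrow(rc)], sum(v > 0))
    # numerically stable at large depths (log-space evaluation)
    big <- c(50000, 30000, 1, 5)
    expect_true(is.finite(rarefactionExpected(big, 40000)))
})

test_that("rarefaction agrees with vegan::rarefy", {
    skip_if_not_installed("vegan")
    set.seed(16)
    for (i in 1:5) {
        v <- sample(1:30, 10, replace = TRUE)
        m <- sample(seq_len(sum(v)), 1)
        expect_equal(rarefactionExpected(v, m),
                     unname(c(suppressWarnings(vegan::rarefy(v, m)))))
    }
})

test_that("Bray-Curtis has the stated bounds and special values", {
    expect_equal(brayCurtis(c(3, 1, 4), c(3, 1, 4)), 0)
    expect_equal(brayCurtis(c(5, 0, 0), c(0, 2, 7)), 1)
    expect_equal(brayCurtis(c(10, 0, 5), c(5, 5, 5)), 1 / 3)
    set.seed(17)
    for (i in 1:20) {
        a <- stats::rpois(10, 5); b <- stats::rpois(10, 5)
        if (sum(a) == 0 || sum(b) == 0) next
        d <- brayCurtis(a, b)
        expect_equal(d, brayCurtis(b, a))
        expect_gte(d, 0); expect_lte(d, 1)
        expect_equal(d == 0, all(a == b))
    }
    expect_error(brayCurtis(c(0, 0), c(1, 2)), "positive")
})

test_that("Bray-Curtis matrix agrees with vegan::vegdist", {
    skip_if_not_installed("vegan")
    set.seed(18)
    m <- randomCountMatrix(12, 5)
    d <- brayCurtisMatrix(m)
    expect_equal(as.dist(d), vegan::vegdist(t(m), "bray"),
                 ignore_attr = TRUE)
})

test_that("UPGMA tree reproduces merge heights of a brute-force oracle", {
    # two samples: single merge at the pairwise dissimilarity
    d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"),
                                                       c("A", "B")))
    tr <- upgmaTree(d2)
    expect_equal(unname(ape::cophenetic.phylo(tr)["A", "B"]), 0.4)

    # clearly separated pair merges first
    d3 <- matrix(c(0, 0.1, 0.8,
                   0.1, 0, 0.8,
                   0.8, 0.8, 0), 3, byrow = TRUE,
                 dimnames = list(LETTERS[1:3], LETTERS[1:3]))
    co <- ape::cophenetic.phylo(upgmaTree(d3))
    expect_equal(unname(co["A", "B"]), 0.1)
    expect_gt(co["A", "C"], co["A", "B"])

    # random 4- and 5-sample matrices vs the naive oracle
    set.seed(19)
    for (n in c(4, 5)) {
        for (rep in 1:5) {
            d <- matrix(0, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
            d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2)
            d <- d + t(d)
            expect_equal(ape::cophenetic.phylo(upgmaTree(d))[LETTERS[1:n],
                                                             LETTERS[1:n]],
                         oracleUpgmaCophenetic(d), tolerance = 1e-12)
        }
    }
    expect_error(upgmaTree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("alpha-diversity report is consistent with the scalar estimators", {
    set.seed(20)
    tbl <- OtuTable(randomCountMatrix(25, 4))
    rep <- alphaDiversity(tbl)
    expect_equal(rep$sample, sampleIds(tbl))
    v <- otuCounts(tbl)[, 2]
    expect_equal(rep$shannon[2], shannonIndex(v))
    expect_equal(rep$simpson[2], simpsonDominance(v))
    expect_equal(rep$chao1[2], chao1Richness(v)$chao1)
    expect_equal(rep$N, unname(colSums(otuCounts(tbl))))
    # singleton handling flag changes n1 accounting but keeps samples
    rep2 <- alphaDiversity(tbl, dropGlobalSingletons = TRUE)
    expect_equal(rep2$sample, sampleIds(tbl))
})
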