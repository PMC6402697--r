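test_that("z-score standardization uses the n-1 denominator", {
    X <- cbind(a = c(0.2, 0.4), b = c(0.5, 0.5))
    Z <- standardizeProbs(X)
    expect_equal(unname(Z[, "a"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
    expect_identical(unname(Z[, "b"]), c(0, 0))
    expect_identical(attr(Z, "constant"), "b")
    set.seed(1)
    Y <- matrix(runif(60), 12, 5, dimnames = list(NULL, letters[1:5]))
    Zy <- standardizeProbs(Y)
    expect_true(all(abs(colMeans(Zy)) < 1e-12))
    expect_true(all(abs(apply(Zy, 2, sd) - 1) < 1e-12))
    # list input joins modalities column-wise
    Z2 <- standardizeProbs(list(Y[, 1:2], Y[, 3:5]))
    expect_identical(dim(Z2), dim(Zy))
})

test_that("Ward clustering separates blobs and respects cut modes", {
    set.seed(2)
    z <- rbind(matrix(rnorm(40, -5, 0.1), 20), matrix(rnorm(40, 5, 0.1), 20))
    rownames(z) <- paste0("s", 1:40)
    cl <- clusterSamples(z, cut = "fixed_k", k = 2)
    expect_identical(length(unique(cl$labels[1:20])), 1L)
    expect_identical(length(unique(cl$labels[21:40])), 1L)
    expect_false(cl$labels[1] == cl$labels[21])
    # identical rows collapse to one cluster
    zi <- matrix(1, 5, 3, dimnames = list(paste0("s", 1:5), NULL))
    cli <- clusterSamples(zi, cut = "fixed_k", k = 1)
    expect_true(all(cli$labels == 1))
    # Ward merge heights non-decreasing
    expect_true(all(diff(cl$hclust$height) >= -1e-12))
    # dynamic cut: all clusters at least minClusterSize
    cld <- clusterSamples(z, minClusterSize = 3, cut = "dynamic")
    expect_gte(min(table(cld$labels)), 3)
    expect_gte(length(unique(cld$labels)), 2)
    # deterministic and invariant to sample order up to relabeling
    perm <- sample(40)
    clp <- clusterSamples(z[perm, ], cut = "fixed_k", k = 2)
    agree <- table(cl$labels[perm], clp$labels)
    expect_identical(sum(agree > 0), 2L)  # one-to-one label correspondence
    expect_error(clusterSamples(z[1, , drop = FALSE]), "at least 2")
})

test_that("clustering recovers signature-defined groups (ARI > 0.9)", {
    # two groups differing by 2 SD in two signature z-scores (duplication- vs
    # deletion-dominated profiles), plus noise dimensions
    set.seed(3)
    D <- 60
    grp <- rep(1:2, each = D / 2)
    z <- cbind(
        dup = rnorm(D, ifelse(grp == 1, 1, -1), 0.5),
        del = rnorm(D, ifelse(grp == 1, -1, 1), 0.5),
        matrix(rnorm(D * 3, 0, 0.5), D))
    rownames(z) <- paste0("s", 1:D)
    cl <- clusterSamples(z, cut = "fixed_k", k = 2)
    ari <- mclust::adjustedRandIndex(cl$labels, grp)
    expect_gt(ari, 0.9)
})

test_that("cluster-signature enrichment uses one-sided Welch tests with BH", {
    set.seed(4)
    n <- 50
    labels <- rep(c(1, 2), each = n)
    theta <- cbind(sigA = c(rnorm(n, 0.8, 0.02), rnorm(n, 0.2, 0.02)),
        sigB = rnorm(2 * n, 0.5, 0.02))
    enr <- clusterSignatureEnrichment(theta, labels)
    expect_identical(nrow(enr), 4L)
    r1 <- enr[enr$cluster == 1 & enr$signature == "sigA", ]
    expect_lt(r1$p_value, 1e-6)
    r2 <- enr[enr$cluster == 2 & enr$signature == "sigA", ]
    expect_gt(r2$p_value, 0.99)  # one-sided: depletion is not enrichment
    expect_true(all(enr$q_value >= enr$p_value - 1e-15))
    # identical distributions give p about 0.5
    theta0 <- cbind(s = rep(c(1, 2, 3, 4), 2))
    enr0 <- clusterSignatureEnrichment(theta0, rep(c(1, 2), each = 4))
    expect_equal(enr0$p_value, c(0.5, 0.5), tolerance = 1e-9)
    # Welch statistic matches the hand formula on a 3+3 example
    x <- c(1, 2, 3)
    y <- c(4, 6, 8)
    tt <- t.test(x, y, alternative = "greater", var.equal = FALSE)
    t_hand <- (mean(x) - mean(y)) / sqrt(var(x) / 3 + var(y) / 3)
    expect_equal(unname(tt$statistic), t_hand, tolerance = 1e-12)
    enr_h <- clusterSignatureEnrichment(cbind(v = c(x, y)),
        rep(c(1, 2), each = 3))
    expect_equal(enr_h$p_value[1], tt$p.value, tolerance = 1e-12)
    # undersized cluster flagged as NA
    enr_na <- clusterSignatureEnrichment(cbind(v = c(1, 2, 3)), c(1, 2, 2))
    expect_true(is.na(enr_na$p_value[enr_na$cluster == 1]))
})

test_that("blocked permutation test matches exhaustive enumeration", {
    # constant annotation: s = 0 and p = 1
    r0 <- blockedPermutationTest(c(TRUE, TRUE, FALSE, FALSE),
        rep(1, 4), rep("b", 4), nPerm = 50, seed = 1)
    expect_identical(r0$s, 0)
    expect_identical(r0$p, 1)
    # tiny instance: sampled p within 3 MC SE of the exhaustive p over
    # all C(5,2) = 10 subsets
    member <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
    annot <- c(1, 1, 0, 1, 0)
    blocks <- rep("b", 5)
    ex <- oracle_blocked_perm(member, annot, blocks)
    expect_identical(ex$n, 10L)
    rs <- blockedPermutationTest(member, annot, blocks, nPerm = 10000,
        seed = 2)
    se <- sqrt(ex$p * (1 - ex$p) / 10000)
    expect_lt(abs(rs$p - ex$p), 3 * se + 2 / 10001)
    # package's exhaustive mode equals the independent oracle on random
    # instances with up to 8 samples and 1-3 blocks
    set.seed(5)
    for (i in 1:25) {
        n <- sample(4:8, 1)
        blocks <- sample(letters[1:sample(1:3, 1)], n, replace = TRUE)
        member <- rep(FALSE, n)
        member[sample(n, sample(2:(n - 2), 1))] <- TRUE
        annot <- sample(0:1, n, replace = TRUE)
        if (stats::runif(1) < 0.5) annot <- stats::rnorm(n)
        ex <- oracle_blocked_perm(member, annot, blocks)
        got <- blockedPermutationTest(member, annot, blocks,
            exhaustive = TRUE)
        expect_equal(got$p, ex$p, tolerance = 1e-12)
        expect_equal(got$s, ex$s, tolerance = 1e-12)
        expect_identical(got$nPerm, ex$n)
    }
    # a statistic beyond every achievable permuted value gives the minimal p
    member <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
    annot <- c(10, 10, 0, 0, 0, 0)
    ex <- oracle_blocked_perm(member, annot, rep("b", 6))
    expect_equal(ex$p, 1 / choose(6, 2), tolerance = 1e-12)
    rs <- blockedPermutationTest(member, annot, rep("b", 6), nPerm = 1000,
        seed = 3)
    expect_gte(rs$p, 1 / 1001)
    # block constraint: sampling respects per-block composition
    blocks2 <- c("x", "x", "y", "y", "y", "y")
    member2 <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
    ex2 <- oracle_blocked_perm(member2, c(1, 0, 1, 1, 0, 0), blocks2)
    got2 <- blockedPermutationTest(member2, c(1, 0, 1, 1, 0, 0), blocks2,
        exhaustive = TRUE)
    expect_equal(got2$p, ex2$p, tolerance = 1e-12)
    expect_error(blockedPermutationTest(c(TRUE, TRUE), c(1, 0),
        c("a", "b")), "every sample")
})

test_that("blocked permutation p-values are calibrated under the null", {
    # continuous annotation independent of cluster membership; two blocks;
    # nPerm = 199 makes P(p <= 0.05) = 10/200 = 0.05 exactly under the null
    set.seed(6)
    n <- 24
    blocks <- rep(c("u", "v"), each = n / 2)
    member <- rep(FALSE, n)
    member[c(1:4, 13:16)] <- TRUE
    reps <- 1000
    rej <- vapply(seq_len(reps), function(i) {
        annot <- stats::rnorm(n)
        blockedPermutationTest(member, annot, blocks, nPerm = 199,
            seed = 10000 + i)$p <= 0.05
    }, TRUE)
    rate <- mean(rej)
    bounds <- stats::qbinom(c(0.025, 0.975), reps, 0.05) / reps
    expect_gte(rate, bounds[1])
    expect_lte(rate, bounds[2])
})

test_that("annotation associations dispatch to the named tests", {
    # Fisher 2x2 [[5,0],[0,5]]: two-tailed p = 2/252
    values <- rep(c(TRUE, FALSE), each = 5)
    labels <- rep(c(1, 2), each = 5)
    fa <- annotationAssociation(values, labels, test = "fisher_2tail")
    expect_equal(fa$p_value[1], 2 / 252, tolerance = 1e-12)
    expect_equal(fa$p_value[2], 2 / 252, tolerance = 1e-12)
    # identical groups: Welch p = 1
    wa <- annotationAssociation(rep(c(1, 2, 3), 4), rep(c(1, 2), 6),
        test = "welch_2tail")
    expect_equal(wa$p_value, c(1, 1), tolerance = 1e-9)
    # rank test invariant under strictly monotone transforms
    set.seed(7)
    v <- rexp(20)
    lb <- rep(c(1, 2), 10)
    r1 <- annotationAssociation(v, lb, test = "welch_on_ranks")
    r2 <- annotationAssociation(exp(v) + 5, lb, test = "welch_on_ranks")
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
    # degenerate margins flagged with p = 1
    dg <- annotationAssociation(rep(TRUE, 6), rep(c(1, 2), 3),
        test = "fisher_2tail")
    expect_identical(dg$p_value, c(1, 1))
    expect_identical(dg$flag, rep("degenerate_margins", 2))
})

test_that("BH adjustment matches hand-worked values", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3),
        tolerance = 1e-12)
    expect_identical(bhAdjust(0.2), 0.2)
    expect_identical(bhAdjust(numeric(0)), numeric(0))
    set.seed(8)
    p <- runif(50)
    q <- bhAdjust(p)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    # monotone non-decreasing in sorted order
    expect_true(all(diff(q[order(p)]) >= -1e-15))
})
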