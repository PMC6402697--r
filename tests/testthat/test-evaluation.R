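test_that("CV plans partition samples with stratified fold sizes", {
    ids <- sprintf("s%03d", 1:560)
    plan <- makeCvPlan(ids, nFolds = 5, nRepeats = 10, seed = 1)
    a <- plan$assignments
    # 10 x 5 scheme: 50 train/test sets, 112-sample test folds
    expect_identical(nrow(unique(a[, c("repeat_", "fold")])), 50L)
    sizes <- table(a$repeat_, a$fold)
    expect_true(all(sizes == 112))
    # each sample in exactly one test fold per repeat
    for (r in 1:10) {
        expect_identical(sort(a$sample[a$repeat_ == r]), sort(ids))
    }
    fl <- cvFold(plan, 1, 1)
    expect_identical(length(fl$test), 112L)
    expect_identical(length(fl$train), 448L)
    expect_length(intersect(fl$train, fl$test), 0)
    # stratification: proportions preserved up to rounding
    strata <- rep(c("a", "b"), c(400, 160))
    p2 <- makeCvPlan(ids, strata, nFolds = 5, nRepeats = 2, seed = 2)
    a2 <- p2$assignments[p2$assignments$repeat_ == 1, ]
    tb <- table(a2$fold, a2$stratum)
    expect_true(all(tb[, "a"] == 80) && all(tb[, "b"] == 32))
    # reproducibility under seed
    p3 <- makeCvPlan(ids, strata, nFolds = 5, nRepeats = 2, seed = 2)
    expect_identical(p2$assignments, p3$assignments)
    # leave-one-out structure
    loo <- makeCvPlan(letters[1:6], nFolds = 6, nRepeats = 1, seed = 1)
    expect_true(all(table(loo$assignments$fold) == 1))
    expect_warning(makeCvPlan(letters[1:6], rep(c("x", "y"), c(4, 2)),
        nFolds = 3, nRepeats = 1, seed = 1), "round-robin")
})

test_that("observed/hidden splits conserve counts exactly", {
    tc <- tiny_corpus(K = 2, ncat = 8, D = 6, N = 80, seed = 3)
    sp <- splitObservedHidden(tc$catalog, fraction = 0.5, seed = 4)
    expect_identical(counts(sp$observed) + counts(sp$hidden),
        counts(tc$catalog))
    expect_true(all(counts(sp$observed) >= 0))
    # a single mutation ends up in exactly one half
    m1 <- matrix(1, 1, 1, dimnames = list("s", "c"))
    hits <- vapply(1:50, function(i) {
        s <- splitObservedHidden(m1, 0.5, seed = i)
        c(s$observed[1, 1], s$hidden[1, 1])
    }, numeric(2))
    expect_true(all(colSums(hits) == 1))
    # zero-count sample flagged
    m0 <- rbind(s1 = c(2, 3), s2 = c(0, 0))
    colnames(m0) <- c("a", "b")
    s0 <- splitObservedHidden(m0, 0.3, seed = 1)
    expect_identical(attr(s0, "zeroCountSamples"), "s2")
    # Monte-Carlo: observed fraction approaches the target
    mbig <- matrix(50, 4, 5, dimnames = list(paste0("s", 1:4), paste0("c",
        1:5)))
    fr <- vapply(1:1000, function(i) {
        sum(splitObservedHidden(mbig, 0.3, seed = 2000 + i)$observed) /
            sum(mbig)
    }, 0)
    n_tok <- sum(mbig)
    se <- sqrt(0.3 * 0.7 / (n_tok * 1000))
    expect_lt(abs(mean(fr) - 0.3), 3 * se)
    expect_error(splitObservedHidden(mbig, 0), "fraction")
})

test_that("predictive log-likelihood matches closed forms and the oracle", {
    # K=1 uniform signature over 4 categories
    phi <- matrix(0.25, 1, 4)
    theta <- matrix(1, 3, 1)
    hidden <- matrix(rpois(12, 3) + 1, 3, 4)
    expect_equal(predictiveLogLik(phi, theta, hidden), log(0.25),
        tolerance = 1e-12)
    # K=2 point masses, one hidden mutation at category 1
    phi2 <- rbind(c(1, 0), c(0, 1))
    theta2 <- matrix(0.5, 1, 2)
    hid2 <- matrix(c(1, 0), 1, 2)
    expect_equal(predictiveLogLik(phi2, theta2, hid2), log(0.5),
        tolerance = 1e-12)
    # oracle equivalence on random small instances
    set.seed(7)
    for (i in 1:100) {
        D <- sample(1:5, 1)
        V <- sample(2:6, 1)
        K <- sample(1:3, 1)
        g <- matrix(rgamma(K * V, 1), K, V)
        phi <- g / rowSums(g)
        g2 <- matrix(rgamma(D * K, 1), D, K)
        th <- g2 / rowSums(g2)
        hid <- matrix(rpois(D * V, 2), D, V)
        if (sum(hid) == 0) hid[1, 1] <- 1
        expect_equal(predictiveLogLik(phi, th, hid),
            oracle_predictive_ll(phi, th, hid), tolerance = 1e-12)
    }
    # probability floor for comparator methods with exact zeros
    phiz <- rbind(c(1, 0))
    thz <- matrix(1, 1, 1)
    hidz <- matrix(c(0, 2), 1, 2)
    expect_identical(predictiveLogLik(phiz, thz, hidz), -Inf)
    expect_equal(predictiveLogLik(phiz, thz, hidz, floor = 1e-16),
        log(1e-16), tolerance = 1e-9)
    expect_error(predictiveLogLik(phi2, theta2, matrix(0, 1, 2)),
        "all zero")
})

test_that("downsampling thins counts at the requested rate", {
    tc <- tiny_corpus(K = 2, ncat = 8, D = 5, N = 200, seed = 9)
    X <- counts(tc$catalog)
    expect_identical(counts(downsampleCounts(tc$catalog, 1, seed = 1)), X)
    expect_true(all(counts(downsampleCounts(tc$catalog, 0, seed = 1)) == 0))
    Y <- counts(downsampleCounts(tc$catalog, 0.4, seed = 2))
    expect_true(all(Y <= X))
    # Monte-Carlo mean retention at 10%
    tot <- vapply(1:1000, function(i) {
        sum(downsampleCounts(X, 0.1, seed = 3000 + i))
    }, 0)
    se <- sqrt(sum(X) * 0.1 * 0.9 / 1000)
    expect_lt(abs(mean(tot) - 0.1 * sum(X)), 3 * se)
    # exact mode keeps round(fraction * N_d) per sample
    Z <- downsampleCounts(X, 0.25, seed = 4, method = "exact")
    expect_identical(unname(rowSums(Z)), unname(round(0.25 * rowSums(X))))
    expect_true(all(Z <= X))
})

test_that("classifier benchmark is balanced, accurate when separable, and null at chance", {
    set.seed(10)
    # linearly separable features
    y <- rep(c(0, 1), each = 20)
    X <- cbind(y * 4 + rnorm(40, sd = 0.05), rnorm(40))
    acc <- classifierBenchmark(X, y, nFolds = 5, seed = 1)
    expect_length(acc, 5)
    expect_true(all(acc == 1))
    # balanced subsampling: majority class cut to the minority size
    y2 <- rep(c(0, 1), c(30, 10))
    keep <- mmctm:::balance_classes(y2, seed = 2)
    expect_identical(as.vector(table(y2[keep])), c(10L, 10L))
    # permutation null: mean accuracy near 0.5
    Xn <- matrix(rnorm(24 * 2), 24, 2)
    accs <- vapply(1:400, function(i) {
        set.seed(i)
        yp <- sample(rep(c(0, 1), each = 12))
        mean(classifierBenchmark(Xn, yp, nFolds = 4, seed = i))
    }, 0)
    # MC standard error of the mean of per-replicate accuracies
    se <- stats::sd(accs) / sqrt(length(accs))
    expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.01)
    expect_error(classifierBenchmark(Xn, rep(1, 24)), "two classes")
})

test_that("signature-number selection finds the plateau on simulated data", {
    phi <- syntheticSignatures(3, paste0("c", 1:30), seed = 12,
        concentration = 0.08)
    set.seed(13)
    g <- matrix(rgamma(40 * 3, 0.5), 40, 3)
    th <- g / rowSums(g)
    sim <- simulateCounts(list(phi), list(th), 1500, seed = 14)
    sel <- selectSignatureNumber(sim, kRange = 1:5, nReplicates = 2,
        nRestarts = 2, seed = 15)
    agg <- stats::aggregate(mean_ll ~ K, sel$table, mean)
    # the curve rises up to the true K
    expect_true(all(diff(agg$mean_ll[1:3]) > 0))
    expect_true(sel$suggestedK %in% c(3, 4))
    sel1 <- selectSignatureNumber(sim, kRange = 4, nReplicates = 1,
        nRestarts = 1, seed = 1)
    expect_identical(sel1$suggestedK, 4)
})

test_that("the predictive benchmark emits the tidy schema", {
    tc <- tiny_corpus(K = 2, ncat = 10, D = 16, N = 120, seed = 20)
    plan <- makeCvPlan(sampleIDs(tc$catalog), nFolds = 2, nRepeats = 1,
        seed = 1)
    tab <- benchmarkPredictive(tc$catalog, methods = c("mmctm", "lda"),
        kRange = 2, plan = plan, nRestarts = 1, seed = 3)
    expect_identical(names(tab), c("method", "evaluation", "k", "n", "fold",
        "ll"))
    expect_setequal(unique(tab$method), c("ctm", "lda"))
    expect_true(all(is.finite(tab$ll)))
})
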