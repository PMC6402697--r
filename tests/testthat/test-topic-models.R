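test_that("LDA K=1 reduces to the posterior mean of aggregate counts", {
    tc <- tiny_corpus(K = 1, ncat = 8, D = 6, N = 100, seed = 4)
    beta <- 1.0
    fit <- fitLda(tc$catalog, K = 1, beta = beta, seed = 1)
    expect_true(all(sampleProbs(fit, 1) == 1))
    X <- counts(tc$catalog)
    expected <- (beta + colSums(X)) / (ncol(X) * beta + sum(X))
    expect_equal(unname(signatures(fit, 1)[1, ]), unname(expected),
        tolerance = 1e-10)
    expect_fit_invariants(fit)
})

test_that("two samples on disjoint category halves separate at K=2", {
    cats <- paste0("c", 1:10)
    X <- rbind(s1 = c(rep(60, 5), rep(0, 5)), s2 = c(rep(0, 5), rep(60, 5)))
    colnames(X) <- cats
    cat <- MutationCatalog(X, modality = "SNV")
    ref <- rbind(c(rep(0.2, 5), rep(0, 5)), c(rep(0, 5), rep(0.2, 5)))
    for (fit in list(fitLda(cat, K = 2, seed = 2),
            fitMmctm(cat, K = 2, seed = 2))) {
        m <- matchSignatures(signatures(fit, 1), ref)
        expect_lt(max(m$signatureMAE), 0.05)
        expect_fit_invariants(fit)
    }
})

test_that("fits are deterministic under a fixed seed", {
    tc <- tiny_corpus(K = 2, ncat = 10, D = 10, N = 150, seed = 8)
    f1 <- fitMmctm(tc$catalog, K = 2, seed = 42)
    f2 <- fitMmctm(tc$catalog, K = 2, seed = 42)
    expect_identical(signatures(f1, 1), signatures(f2, 1))
    expect_identical(sampleProbs(f1, 1), sampleProbs(f2, 1))
    expect_identical(elboTrace(f1), elboTrace(f2))
    f3 <- fitMmctm(tc$catalog, K = 2, seed = 43)
    expect_false(identical(elboTrace(f1), elboTrace(f3)))
    l1 <- fitLda(tc$catalog, K = 2, seed = 7)
    l2 <- fitLda(tc$catalog, K = 2, seed = 7)
    expect_identical(signatures(l1, 1), signatures(l2, 1))
})

test_that("single-modality MMCTM is the CTM and matches itself across calls", {
    # the CTM is implemented as the one-modality case of the same engine:
    # giving the same counts under the same seed must reproduce the whole
    # parameter trajectory (ELBO trace) and all estimates
    tc <- tiny_corpus(K = 2, ncat = 12, D = 12, N = 200, seed = 10)
    ctm <- fitMmctm(tc$catalog, K = 2, seed = 5)
    mm <- fitMmctm(list(SNV = tc$catalog), K = 2, seed = 5)
    expect_identical(elboTrace(ctm), elboTrace(mm))
    expect_identical(signatures(ctm, 1), signatures(mm, 1))
    expect_identical(priorCov(ctm), priorCov(mm))
})

test_that("fixing the covariance to the identity is honored", {
    tc <- tiny_corpus(K = 2, ncat = 8, D = 8, N = 100, seed = 12)
    fit <- fitMmctm(tc$catalog, K = 2, seed = 1,
        fixCovarianceIdentity = TRUE)
    expect_identical(unname(priorCov(fit)), diag(2))
    expect_fit_invariants(fit)
})

test_that("correlated signature probabilities are recovered", {
    phiA <- syntheticSignatures(2, paste0("a", 1:24), seed = 21)
    phiB <- syntheticSignatures(2, paste0("b", 1:24), seed = 22)
    # coordinates 1 and 3 (one per modality block) share the same Gaussian
    # draw; coordinates 2 and 4 are nearly constant
    S <- diag(c(1, 1e-6, 1, 1e-6))
    S[1, 3] <- S[3, 1] <- 1
    S <- S + diag(1e-9, 4)
    th <- drawCorrelatedProbs(c(0, 0, 0, 0), S, D = 150,
        blockSizes = c(2, 2), seed = 23)
    expect_gt(stats::cor(th[[1]][, 1], th[[2]][, 1]), 0.95)
    sim <- simulateCounts(list(A = phiA, B = phiB), th, list(400, 400),
        seed = 24)
    fit <- fitMmctm(sim, K = c(2, 2), seed = 3)
    R <- signatureCorrelations(fit)
    cross <- abs(R[1:2, 3:4])
    expect_gt(max(cross), 0.8)
    expect_true(isSymmetric(unname(R)))
    expect_true(all(diag(R) == 1))
})

test_that("signature correlations handle trivial and constant cases", {
    th <- list(matrix(c(1, 1, 1), 3, 1, dimnames = list(NULL, "SNV1")))
    R <- signatureCorrelations(th)
    expect_identical(unname(R[1, 1]), 1)
    expect_identical(attr(R, "constant"), "SNV1")
    th2 <- list(cbind(A = c(0.2, 0.5, 0.9)), cbind(B = c(0.4, 1.0, 1.8)))
    R2 <- signatureCorrelations(th2)
    expect_equal(unname(R2["A", "B"]), 1)
    expect_error(signatureCorrelations(list(matrix(1, 2, 1))), "3 samples")
})

test_that("inferSampleProbs freezes signatures and flags empty samples", {
    tc <- tiny_corpus(K = 2, ncat = 10, D = 15, N = 250, seed = 30)
    fit <- fitMmctm(tc$catalog, K = 2, seed = 2)
    # K=1 fit: inferred theta is exactly 1
    f1 <- fitMmctm(tc$catalog, K = 1, seed = 2)
    th1 <- inferSampleProbs(f1, tc$catalog)
    expect_true(all(th1[[1]] == 1))
    # a sample made of the top categories of signature 2 loads on it
    phi <- signatures(fit, 1)
    j <- which.max(apply(phi, 2, function(col) col[2] - col[1]))
    Xnew <- matrix(0, 2, ncol(phi),
        dimnames = list(c("n1", "empty"), colnames(phi)))
    Xnew[1, j] <- 200
    th <- inferSampleProbs(fit, MutationCatalog(Xnew, modality = "SNV"))
    expect_gt(th[[1]]["n1", 2], th[[1]]["n1", 1])
    expect_identical(attr(th, "zeroCountSamples"), "empty")
    # empty sample gets the prior-mean-induced probabilities
    pri <- exp(priorMean(fit)) / sum(exp(priorMean(fit)))
    expect_equal(unname(th[[1]]["empty", ]), unname(pri), tolerance = 1e-6)
    # determinism
    th_b <- inferSampleProbs(fit, MutationCatalog(Xnew, modality = "SNV"))
    expect_identical(th, th_b)
    # category mismatch is rejected
    bad <- Xnew
    colnames(bad) <- paste0(colnames(Xnew), "_x")
    expect_error(inferSampleProbs(fit,
        MutationCatalog(bad, modality = "SNV")), "category space mismatch")
    # LDA inference
    lfit <- fitLda(tc$catalog, K = 2, seed = 2)
    thl <- inferSampleProbs(lfit, tc$catalog)
    expect_true(all(abs(rowSums(thl[[1]]) - 1) < 1e-8))
})

test_that("independent-feature fits factorize and recover marginals", {
    lv <- snvFeatureLevels()
    # K=1: per-feature distributions are the normalized marginal counts
    set.seed(40)
    mats <- lapply(lv, function(levels) {
        m <- matrix(rpois(5 * length(levels), 20), 5,
            dimnames = list(paste0("s", 1:5), levels))
        m
    })
    cat1 <- MutationCatalog(mats, modality = "SNV",
        encoding = "independent")
    fit1 <- fitMmctm(cat1, K = 1, beta = 1, seed = 1)
    sig <- signatures(fit1, 1)
    for (f in names(mats)) {
        expected <- (1 + colSums(mats[[f]])) /
            (ncol(mats[[f]]) + sum(mats[[f]]))
        expect_equal(unname(sig[[f]][1, ]), unname(expected),
            tolerance = 1e-6)
    }
    # product over features is a distribution over the 96 categories
    full <- productSignatures(sig)
    expect_equal(unname(rowSums(full)), 1, tolerance = 1e-10)
    # factorizable 2-signature corpus is recovered
    set.seed(41)
    mk <- function(n) {
        g <- matrix(stats::rgamma(2 * n, 0.4), 2, n)
        g / rowSums(g)
    }
    sigs <- list(substitution = mk(6), five_prime = mk(4),
        three_prime = mk(4))
    for (f in names(sigs)) colnames(sigs[[f]]) <- lv[[f]]
    fullref <- productSignatures(sigs)
    # sparse Dirichlet over samples: many near-pure samples pin down the
    # mixture endpoints, which the factorization needs for identifiability
    g <- matrix(stats::rgamma(80 * 2, 0.3), 80, 2)
    th <- g / rowSums(g)
    sim <- simulateCounts(list(fullref), list(th), 5000, seed = 42)
    X <- counts(sim[[1]])
    cats <- snvCategories()
    fm <- list(substitution = substr(cats, 3, 5),
        five_prime = substr(cats, 1, 1), three_prime = substr(cats, 7, 7))
    featmats <- lapply(names(lv), function(f) {
        vapply(lv[[f]], function(val) {
            rowSums(X[, fm[[f]] == val, drop = FALSE])
        }, numeric(nrow(X)))
    })
    names(featmats) <- names(lv)
    icat <- MutationCatalog(featmats, modality = "SNV",
        encoding = "independent")
    ifit <- fitWithRestarts(icat, K = 2, nRestarts = 5, seed = 7)
    est <- productSignatures(signatures(ifit, 1))
    m <- matchSignatures(est, fullref)
    expect_lt(max(m$signatureMAE), 0.05)
    # per-feature MAE against the reference factors
    estf <- signatures(ifit, 1)
    for (f in names(sigs)) {
        maef <- mean(abs(estf[[f]] - sigs[[f]][m$mapping, ]))
        expect_lt(maef, 0.05)
    }
    expect_fit_invariants(ifit)
})

test_that("restart protocol selects by best mean rank and then converges", {
    tc <- tiny_corpus(K = 3, ncat = 16, D = 25, N = 400, seed = 50)
    # n_restarts = 1 degenerates to a plain fit at the final tolerance
    r1 <- fitWithRestarts(tc$catalog, K = 3, nRestarts = 1, seed = 9,
        tolFinal = 1e-5)
    expect_s4_class(r1, "MmctmFit")
    expect_identical(r1@config$restarts$selected, 1L)
    rf <- fitWithRestarts(tc$catalog, K = 3, nRestarts = 6, seed = 9)
    tab <- rf@config$restarts$table
    expect_identical(nrow(tab), 6L)
    # argmin contract: the selected restart has the minimal mean rank
    expect_lte(tab$meanRank[rf@config$restarts$selected], min(tab$meanRank))
    expect_fit_invariants(rf)
    # the continued fit cannot be worse than the selected short fit
    expect_gte(trainingLogLik(rf)[1],
        tab[[paste0("ll_", modalityNames(rf)[1])]][
            rf@config$restarts$selected] - 1e-8)
    # restart selection uses mean rank across modalities for 2 modalities
    phiB <- syntheticSignatures(2, paste0("b", 1:12), seed = 51)
    set.seed(52)
    g <- matrix(stats::rgamma(25 * 2, 1), 25, 2)
    thB <- g / rowSums(g)
    rownames(thB) <- sampleIDs(tc$catalog)
    simB <- simulateCounts(list(phiB), list(thB), 100, seed = 53,
        modalities = "SV")
    rf2 <- fitWithRestarts(list(SNV = tc$catalog, SV = simB[[1]]),
        K = c(3, 2), nRestarts = 4, seed = 3)
    tab2 <- rf2@config$restarts$table
    expect_true(all(c("ll_SNV", "ll_SV") %in% names(tab2)))
    expect_equal(sort(rank(-tab2$ll_SNV)), 1:4)
})

test_that("parameter recovery improves with per-sample mutation totals", {
    phi <- syntheticSignatures(3, snvCategories(), seed = 60)
    set.seed(61)
    g <- matrix(stats::rgamma(40 * 3, 1), 40, 3)
    th <- g / rowSums(g)
    maes <- vapply(c(50, 500, 5000), function(N) {
        sim <- simulateCounts(list(phi), list(th), N, seed = 62)
        fit <- fitWithRestarts(sim, K = 3, nRestarts = 3, seed = 1)
        median(matchSignatures(signatures(fit, 1), phi)$signatureMAE)
    }, 0)
    expect_true(all(diff(maes) < 0))
})

test_that("degenerate inputs are rejected", {
    X <- matrix(0, 3, 4, dimnames = list(paste0("s", 1:3), paste0("c", 1:4)))
    cat0 <- MutationCatalog(X, modality = "SNV")
    expect_error(fitMmctm(cat0, K = 2, seed = 1), "all-zero")
    expect_error(fitLda(cat0, K = 2, seed = 1), "all-zero")
    tc <- tiny_corpus(K = 2, ncat = 6, D = 5, N = 60, seed = 70)
    expect_error(fitMmctm(list(tc$catalog, tc$catalog), K = 2, seed = 1),
        NA)  # same samples twice is structurally fine
    other <- tiny_corpus(K = 2, ncat = 6, D = 4, N = 60, seed = 71)
    expect_error(fitMmctm(list(tc$catalog, other$catalog), K = 2, seed = 1),
        "same samples")
    expect_error(fitMmctm(tc$catalog, K = c(2, 2), seed = 1), "one signature")
    expect_error(fitLda(list(tc$catalog, tc$catalog), K = 2), "single-modality")
})
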