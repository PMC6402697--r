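# Shared fixtures and independent oracles used across tests.

toy_genome <- function() {
    Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAC", chr2 = "TTGCANGCAT"))
}

extdata <- function(f) {
    system.file("extdata", f, package = "mmctm", mustWork = TRUE)
}

# small simulated corpus: K signatures over `ncat` categories, D samples,
# expected N mutations per sample
tiny_corpus <- function(K = 2, ncat = 12, D = 20, N = 300, seed = 1,
        modality = "SNV") {
    phi <- syntheticSignatures(K, paste0("c", seq_len(ncat)), seed = seed)
    set.seed(seed + 1)
    g <- matrix(stats::rgamma(D * K, 1), D, K)
    th <- g / rowSums(g)
    rownames(th) <- sprintf("s%03d", seq_len(D))
    sim <- simulateCounts(list(phi), list(th), N, seed = seed + 2,
        modalities = modality)
    list(phi = phi, theta = th, catalog = sim[[1L]])
}

# brute-force per-mutation predictive log-likelihood: explicit double loop
# over samples and category tokens
oracle_predictive_ll <- function(phi, theta, hidden, floor = 0) {
    tot <- 0
    n <- 0
    for (d in seq_len(nrow(hidden))) {
        for (v in seq_len(ncol(hidden))) {
            x <- hidden[d, v]
            if (x > 0) {
                p <- 0
                for (k in seq_len(nrow(phi))) {
                    p <- p + theta[d, k] * phi[k, v]
                }
                tot <- tot + x * log(p + floor)
                n <- n + x
            }
        }
    }
    tot / n
}

# exhaustive blocked permutation oracle: scan every subset of the right size
# of the full sample set, keep those matching the cluster's per-block
# composition, and report the fraction with |s'| >= |s|
oracle_blocked_perm <- function(member, annotation, blocks) {
    x <- as.numeric(annotation)
    n <- length(member)
    sz <- sum(member)
    stat <- function(idx) {
        mean(x[idx]) - mean(x[setdiff(seq_len(n), idx)])
    }
    s <- stat(which(member))
    lev <- sort(unique(blocks))
    comp <- table(factor(blocks[member], levels = lev))
    subsets <- utils::combn(n, sz)
    keep <- apply(subsets, 2L, function(idx) {
        all(table(factor(blocks[idx], levels = lev)) == comp)
    })
    sp <- apply(subsets[, keep, drop = FALSE], 2L, stat)
    list(s = s, p = mean(abs(sp) >= abs(s) - 1e-12), n = sum(keep))
}

elbo_nondecreasing <- function(fit, rtol = 1e-8) {
    e <- elboTrace(fit)
    all(diff(e) >= -abs(e[-length(e)]) * rtol)
}

expect_fit_invariants <- function(fit) {
    expect_true(elbo_nondecreasing(fit))
    for (m in modalityNames(fit)) {
        sig <- signatures(fit, m)
        if (is.matrix(sig)) sig <- list(sig)
        for (s in sig) {
            expect_true(all(abs(rowSums(s) - 1) < 1e-8))
            expect_true(all(s > 0))
        }
        expect_true(all(abs(rowSums(sampleProbs(fit, m)) - 1) < 1e-8))
    }
    ev <- eigen(priorCov(fit), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
}
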