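## Synthetic corpora with the generative structure the models assume, plus
## signature matching / similarity scoring of recovered solutions.

#' Well-separated synthetic reference signatures
#'
#' Draws K signature rows from a sparse symmetric Dirichlet and redraws until
#' all pairwise cosine similarities fall below `maxCosine`, giving
#' qualitatively distinct reference signatures for simulation studies. A
#' loader for externally supplied reference signature TSVs is
#' [readCountMatrix()]-compatible (signatures are plain matrices with
#' category colnames), so published references can be substituted directly.
#'
#' @param K number of signatures.
#' @param categories category labels (e.g. [snvCategories()]).
#' @param concentration Dirichlet concentration (default 0.1; small values
#'   give sparse, distinct signatures).
#' @param maxCosine pairwise cosine similarity ceiling (default 0.5).
#' @param seed RNG seed.
#' @param maxTries redraw limit.
#' @return K x V matrix, rows summing to 1.
#' @export
syntheticSignatures <- function(K, categories = snvCategories(),
        concentration = 0.1, maxCosine = 0.5, seed = 1L, maxTries = 200L) {
    V <- length(categories)
    set.seed(seed)
    for (i in seq_len(maxTries)) {
        g <- matrix(stats::rgamma(K * V, shape = concentration), K, V)
        phi <- g / rowSums(g)
        if (K == 1L) break
        cs <- cosineSimilarityTable(phi, phi)
        if (max(cs[upper.tri(cs)]) < maxCosine) break
        if (i == maxTries) {
            stop("could not draw signatures with pairwise cosine < ",
                maxCosine)
        }
    }
    dimnames(phi) <- list(paste0("ref", seq_len(K)), categories)
    phi
}

#' Simulate Poisson mutation counts from reference signatures
#'
#' For each modality, sample d and category v, draws
#' `counts[d, v] ~ Poisson(N_d * (theta_d %*% phi)_v)`: the per-sample total
#' multiplied by the mixture of reference signatures under the sample's
#' signature probabilities. Row sums therefore have mean N_d.
#'
#' @param signatures list of per-modality K x V reference signature matrices.
#' @param probs list of per-modality D x K reference sample-signature
#'   probability matrices (rows sum to 1).
#' @param totals per-sample expected totals: one number, a length-D vector,
#'   or a list of those per modality.
#' @param seed RNG seed; the same seed reproduces the matrices exactly.
#' @param modalities modality names (default names of `signatures` or
#'   "SNV"-style defaults).
#' @return named list of [MutationCatalog-class] objects.
#' @examples
#' phi <- syntheticSignatures(3, paste0("c", 1:10), seed = 2)
#' th <- drawCorrelatedProbs(rep(0, 3), diag(3), D = 20, blockSizes = 3,
#'     seed = 2)
#' sim <- simulateCounts(list(phi), th, totals = 100, seed = 3)
#' @export
simulateCounts <- function(signatures, probs, totals, seed = 1L,
        modalities = NULL) {
    M <- length(signatures)
    stopifnot(length(probs) == M)
    if (!is.list(totals)) totals <- rep(list(totals), M)
    if (is.null(modalities)) {
        modalities <- names(signatures)
        if (is.null(modalities)) {
            modalities <- if (M == 1L) "SNV" else paste0("MOD", seq_len(M))
        }
    }
    D <- nrow(probs[[1L]])
    set.seed(seed)
    out <- vector("list", M)
    for (m in seq_len(M)) {
        phi <- signatures[[m]]
        th <- probs[[m]]
        stopifnot(ncol(th) == nrow(phi), nrow(th) == D)
        N <- rep_len(totals[[m]], D)
        rate <- (th %*% phi) * N
        cnt <- matrix(stats::rpois(length(rate), as.vector(rate)),
            nrow = D)
        dimnames(cnt) <- list(
            if (is.null(rownames(th))) sprintf("s%03d", seq_len(D))
                else rownames(th),
            colnames(phi))
        out[[m]] <- MutationCatalog(cnt, modality = modalities[m])
    }
    names(out) <- modalities
    out
}

#' Draw correlated sample-signature probabilities
#'
#' Draws per-sample Gaussian vectors eta ~ N(mu, sigma) over the concatenated
#' signature dimensions and applies a softmax within each modality block —
#' the logistic-normal structure the correlated topic models assume. With a
#' non-zero off-diagonal covariance the resulting signature probabilities
#' are correlated across samples.
#'
#' @param mu mean vector (length = sum of block sizes).
#' @param sigma covariance matrix; must be symmetric positive semi-definite.
#' @param D number of samples.
#' @param blockSizes signatures per modality block.
#' @param seed RNG seed.
#' @return list of D x K probability matrices, one per block; rows sum to 1.
#' @export
drawCorrelatedProbs <- function(mu, sigma, D, blockSizes, seed = 1L) {
    Ktot <- length(mu)
    stopifnot(sum(blockSizes) == Ktot, all(dim(sigma) == Ktot))
    if (max(abs(sigma - t(sigma))) > 1e-8) {
        stop("sigma must be symmetric")
    }
    ev <- eigen(sigma, symmetric = TRUE)
    if (min(ev$values) < -1e-10 * max(abs(ev$values), 1)) {
        stop("sigma must be positive semi-definite")
    }
    rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
    set.seed(seed)
    Z <- matrix(stats::rnorm(D * Ktot), D, Ktot)
    Eta <- sweep(Z %*% rt, 2L, mu, `+`)
    blocks <- block_index(as.integer(blockSizes))
    lapply(blocks, function(b) {
        th <- softmax_rows(Eta[, b, drop = FALSE])
        rownames(th) <- sprintf("s%03d", seq_len(D))
        th
    })
}

mae_rows <- function(a, b) mean(abs(a - b))

#' Greedy signature matching by mean absolute error
#'
#' Matches estimated to reference signatures: repeatedly picks the
#' (estimated, reference) pair with the smallest mean absolute error among
#' the still-unassigned signatures, assigns it, and repeats until all are
#' matched. Ties are broken by (estimated index, reference index) order. The
#' result does not depend on the row order of either input beyond tie
#' breaking.
#'
#' @param estimated,reference K x V matrices over the same category space.
#' @param estimatedProbs,referenceProbs optional D x K sample-signature
#'   probability matrices; if both are given, per-signature MAEs of the
#'   matched probability columns are also returned.
#' @return list with `mapping` (for each estimated row, the matched reference
#'   row index), `signatureMAE` (per estimated signature), and
#'   `probMAE` (if probabilities were supplied).
#' @export
matchSignatures <- function(estimated, reference, estimatedProbs = NULL,
        referenceProbs = NULL) {
    K <- nrow(estimated)
    if (nrow(reference) != K) {
        stop("estimated and reference must have the same number of ",
            "signatures")
    }
    if (!identical(ncol(estimated), ncol(reference))) {
        stop("category spaces differ")
    }
    err <- matrix(NA_real_, K, K)
    for (i in seq_len(K)) {
        for (j in seq_len(K)) {
            err[i, j] <- mean(abs(estimated[i, ] - reference[j, ]))
        }
    }
    mapping <- rep(NA_integer_, K)
    free_e <- rep(TRUE, K)
    free_r <- rep(TRUE, K)
    for (step in seq_len(K)) {
        sub <- err
        sub[!free_e, ] <- Inf
        sub[, !free_r] <- Inf
        ## ties broken by (estimated index, reference index)
        best <- which(sub == min(sub), arr.ind = TRUE)
        best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
        mapping[best[1L]] <- best[2L]
        free_e[best[1L]] <- FALSE
        free_r[best[2L]] <- FALSE
    }
    sigmae <- vapply(seq_len(K), function(i) err[i, mapping[i]], 0)
    out <- list(mapping = mapping, signatureMAE = sigmae)
    if (!is.null(estimatedProbs) && !is.null(referenceProbs)) {
        out$probMAE <- vapply(seq_len(K), function(i) {
            mean(abs(estimatedProbs[, i] - referenceProbs[, mapping[i]]))
        }, 0)
    }
    out
}

#' Cosine similarity between signature sets
#'
#' @param a,b K_a x V and K_b x V matrices over the same category space.
#' @return K_a x K_b matrix of cosine similarities (in [0, 1] for
#'   non-negative rows). All-zero rows give similarity 0 and are flagged in
#'   the `"zeroRows"` attribute.
#' @export
cosineSimilarityTable <- function(a, b) {
    if (ncol(a) != ncol(b)) stop("category spaces differ")
    na <- sqrt(rowSums(a^2))
    nb <- sqrt(rowSums(b^2))
    S <- a %*% t(b)
    denom <- outer(na, nb)
    zero <- denom == 0
    S[!zero] <- S[!zero] / denom[!zero]
    S[zero] <- 0
    attr(S, "zeroRows") <- list(a = which(na == 0), b = which(nb == 0))
    S
}

#' Signature-recovery simulation study
#'
#' The package's desk-scale replication study: for each replicate dataset,
#' draws well-separated reference SNV signatures (pairwise cosine < 0.5),
#' Dirichlet(1) sample-signature probabilities, and Poisson counts with
#' per-sample rate `total * (theta %*% phi)`; fits the MMCTM with the restart
#' protocol; greedily matches estimated to reference signatures; and records
#' the per-signature mean absolute errors.
#'
#' @param nDatasets replicate datasets (default 10).
#' @param D samples per dataset (default 200).
#' @param K reference signatures (default 4).
#' @param total expected mutations per sample (default 5000).
#' @param nRestarts random restarts per dataset (default 50).
#' @param seed base seed; replicate r uses seed * 100 + r for its data and
#'   fits.
#' @param categories category space (default the 96 SNV categories).
#' @return list with `table` (dataset, signature, signature MAE, probability
#'   MAE) and `medianMAE` (median per-signature MAE across all datasets).
#' @export
signatureRecoveryStudy <- function(nDatasets = 10L, D = 200L, K = 4L,
        total = 5000L, nRestarts = 50L, seed = 1L,
        categories = snvCategories()) {
    rows <- list()
    for (r in seq_len(nDatasets)) {
        sd_r <- seed * 100L + r
        phi <- syntheticSignatures(K, categories, seed = sd_r,
            maxCosine = 0.5)
        set.seed(sd_r + 1L)
        g <- matrix(stats::rgamma(D * K, shape = 1), D, K)
        theta <- g / rowSums(g)
        rownames(theta) <- sprintf("s%03d", seq_len(D))
        sim <- simulateCounts(list(SNV = phi), list(theta), total,
            seed = sd_r + 2L)
        fit <- fitWithRestarts(sim, K = K, model = "mmctm",
            nRestarts = nRestarts, seed = sd_r + 3L)
        m <- matchSignatures(signatures(fit, 1L), phi,
            sampleProbs(fit)[[1L]], theta)
        rows[[r]] <- data.frame(dataset = r,
            signature = seq_len(K), signatureMAE = m$signatureMAE,
            probMAE = m$probMAE)
    }
    tab <- do.call(rbind, rows)
    list(table = tab, medianMAE = stats::median(tab$signatureMAE))
}
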