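## User-facing model fitting: LDA, CTM/MMCTM (and the independent-feature
## variants, which are the same models applied to independent-encoded
## catalogs).

signature_names <- function(modalities, K) {
    unlist(lapply(seq_along(K), function(m) {
        paste0(modalities[m], seq_len(K[m]))
    }))
}

build_fit <- function(res, catalogs, model, config) {
    catalogs <- check_catalog_list(catalogs)
    mods <- names(catalogs)
    K <- res$K
    samples <- sampleIDs(catalogs[[1L]])
    signames <- signature_names(mods, K)
    blocks <- block_index(K)
    sigs <- lapply(seq_along(catalogs), function(m) {
        feats <- counts(catalogs[[m]], simplify = FALSE)
        phis <- lapply(seq_along(feats), function(f) {
            phi <- point_phi(res$gamma[[m]][[f]])
            dimnames(phi) <- list(paste0(mods[m], seq_len(K[m])),
                colnames(feats[[f]]))
            phi
        })
        names(phis) <- names(feats)
        if (length(phis) == 1L) phis[[1L]] else phis
    })
    names(sigs) <- mods
    if (model == "mmctm") {
        theta <- lapply(seq_along(catalogs), function(m) {
            th <- softmax_rows(res$Lambda[, blocks[[m]], drop = FALSE])
            dimnames(th) <- list(samples, paste0(mods[m], seq_len(K[m])))
            th
        })
        lambda <- res$Lambda
        nu2 <- res$Nu2
        dimnames(lambda) <- dimnames(nu2) <- list(samples, signames)
        mu <- stats::setNames(res$mu, signames)
        sigma <- res$Sigma
        dimnames(sigma) <- list(signames, signames)
    } else {
        theta <- list(res$gtheta / rowSums(res$gtheta))
        dimnames(theta[[1L]]) <- list(samples, signames)
        lambda <- nu2 <- matrix(0, 0, sum(K))
        mu <- stats::setNames(rep(0, sum(K)), signames)
        sigma <- diag(sum(K))
        dimnames(sigma) <- list(signames, signames)
    }
    names(theta) <- mods
    zero <- lapply(catalogs, function(cat) {
        ids <- sampleIDs(cat)
        ids[Reduce(`+`, lapply(counts(cat, simplify = FALSE), rowSums)) == 0]
    })
    config$zeroCountSamples <- zero
    config$converged <- res$converged
    config$iterations <- res$niter
    config$bound <- "first-order auxiliary normalizer (profiled out)"
    state <- list(model = model, K = K, blocks = blocks, gamma = res$gamma,
        mu = res$mu, Sigma = res$Sigma, alpha = config$alpha,
        beta = config$beta)
    new("MmctmFit", model = model, modalities = mods, K = as.integer(K),
        signatures = sigs, theta = theta, mu = unname(mu), sigma = sigma,
        lambda = lambda, nu2 = nu2, elbo = res$elbo,
        trainingLL = stats::setNames(res$trainLL, mods), config = config,
        state = state)
}

check_K <- function(K, M) {
    if (length(K) == 1L) K <- rep(K, M)
    if (length(K) != M) stop("supply one signature count K per modality")
    if (any(K < 1)) stop("K must be >= 1")
    as.integer(K)
}

#' Fit the (multi-modal) correlated topic model
#'
#' Fits the MMCTM by mean-field variational EM: per-modality signatures with
#' Dirichlet(`beta`) priors, and per-sample logistic-normal sample-signature
#' probabilities whose Gaussian (mean `mu`, covariance `Sigma`) is shared
#' across the concatenated signature dimensions of all modalities, capturing
#' signature correlations within and between modalities. With a single
#' modality this is exactly the correlated topic model (CTM); applied to
#' independent-encoded catalogs it is the ICTM/IMMCTM. Iterations stop when
#' the relative change of the per-modality training predictive
#' log-likelihood falls below `tol`.
#'
#' @param counts a [MutationCatalog-class] or list of them (one per modality,
#'   same samples in the same order).
#' @param K signatures per modality (scalar recycled, or one per modality).
#' @param beta symmetric Dirichlet hyperparameter of the signatures
#'   (default 1.0).
#' @param fixCovarianceIdentity keep the prior covariance fixed to the
#'   identity matrix instead of re-estimating it in the M-step.
#' @param tol convergence tolerance on the relative change in training
#'   predictive log-likelihood (default 1e-5).
#' @param maxIter maximum variational EM iterations.
#' @param seed RNG seed for the random signature initialization (variational
#'   Dirichlet parameters start as random positive integers). Identical seed,
#'   data and settings reproduce the fit exactly.
#' @param ridge diagonal ridge added to the covariance M-step (default 1e-6).
#' @return a [MmctmFit-class].
#' @examples
#' sig <- syntheticSignatures(2, paste0("c", 1:8), seed = 1)
#' cnt <- simulateCounts(list(sig), list(matrix(0.5, 30, 2)), 200, seed = 1)
#' fit <- fitMmctm(cnt, K = 2, seed = 1)
#' @export
fitMmctm <- function(counts, K, beta = 1.0, fixCovarianceIdentity = FALSE,
        tol = 1e-5, maxIter = 1000L, seed = 1L, ridge = 1e-6) {
    catalogs <- check_catalog_list(counts)
    Xs <- prep_input(catalogs)
    K <- check_K(K, length(Xs))
    res <- mmctm_engine(Xs, K, beta = beta, fixSigma = fixCovarianceIdentity,
        tol = tol, maxIter = maxIter, seed = seed, ridge = ridge)
    build_fit(res, catalogs, "mmctm",
        list(beta = beta, alpha = NA_real_,
            fixCovarianceIdentity = fixCovarianceIdentity, tol = tol,
            maxIter = maxIter, seed = seed, ridge = ridge))
}

#' Fit latent Dirichlet allocation
#'
#' Mean-field variational Bayes LDA for a single modality: Dirichlet(`alpha`)
#' sample-signature distributions and Dirichlet(`beta`) signatures. Applied
#' to an independent-encoded catalog this is the ILDA variant (all features
#' share the sample-signature distribution).
#'
#' @param counts a single [MutationCatalog-class].
#' @param K number of signatures.
#' @param alpha symmetric Dirichlet hyperparameter of the sample-signature
#'   distributions (default 0.1).
#' @inheritParams fitMmctm
#' @return a [MmctmFit-class] (prior slots are identity/zero placeholders;
#'   LDA has no logistic-normal prior).
#' @export
fitLda <- function(counts, K, alpha = 0.1, beta = 1.0, tol = 1e-5,
        maxIter = 1000L, seed = 1L) {
    catalogs <- check_catalog_list(counts)
    if (length(catalogs) != 1L) {
        stop("LDA is a single-modality model; fit each modality separately")
    }
    Xs <- prep_input(catalogs)
    K <- check_K(K, 1L)
    res <- lda_engine(Xs[[1L]], K, alpha = alpha, beta = beta, tol = tol,
        maxIter = maxIter, seed = seed)
    build_fit(res, catalogs, "lda",
        list(beta = beta, alpha = alpha, fixCovarianceIdentity = FALSE,
            tol = tol, maxIter = maxIter, seed = seed))
}

#' Fit with random restarts and best-mean-rank selection
#'
#' Runs `nRestarts` short fits from random initializations (each to a
#' relative training log-likelihood tolerance `tolRestart`, at most
#' `maxRestartIter` iterations), ranks the restarts per modality by training
#' predictive log-likelihood, selects the restart with the best (lowest)
#' mean rank across modalities, and continues that fit to convergence at
#' `tolFinal`. With `nRestarts = 1` this is a plain fit at `tolFinal`.
#'
#' @inheritParams fitMmctm
#' @param model "mmctm" (default; CTM when one modality) or "lda".
#' @param nRestarts number of random restarts.
#' @param seed seed controlling the restart seed sequence.
#' @param tolRestart,tolFinal tolerances of the short and final phases.
#' @param maxRestartIter,maxFinalIter iteration caps of the two phases.
#' @param alpha LDA sample-signature hyperparameter (ignored for "mmctm").
#' @return a [MmctmFit-class]; restart metadata (per-restart log-likelihoods,
#'   ranks, the selected restart) is in `config$restarts`.
#' @export
fitWithRestarts <- function(counts, K, model = c("mmctm", "lda"),
        nRestarts = 50L, seed = 1L, tolRestart = 1e-4, tolFinal = 1e-5,
        maxRestartIter = 100L, maxFinalIter = 1000L, beta = 1.0,
        alpha = 0.1, fixCovarianceIdentity = FALSE, ridge = 1e-6) {
    model <- match.arg(model)
    catalogs <- check_catalog_list(counts)
    Xs <- prep_input(catalogs)
    M <- length(Xs)
    K <- check_K(K, M)
    if (model == "lda" && M != 1L) {
        stop("LDA is a single-modality model")
    }
    stopifnot(nRestarts >= 1L)
    set.seed(seed)
    rseeds <- sample.int(.Machine$integer.max - 1L, nRestarts)
    shorts <- vector("list", nRestarts)
    llmat <- matrix(NA_real_, nRestarts, M)
    for (r in seq_len(nRestarts)) {
        shorts[[r]] <- if (model == "mmctm") {
            mmctm_engine(Xs, K, beta = beta,
                fixSigma = fixCovarianceIdentity, tol = tolRestart,
                maxIter = maxRestartIter, seed = rseeds[r], ridge = ridge)
        } else {
            lda_engine(Xs[[1L]], K, alpha = alpha, beta = beta,
                tol = tolRestart, maxIter = maxRestartIter, seed = rseeds[r])
        }
        llmat[r, ] <- shorts[[r]]$trainLL
    }
    ranks <- apply(-llmat, 2L, rank, ties.method = "first")
    ranks <- matrix(ranks, nRestarts, M)
    meanrank <- rowMeans(ranks)
    best <- which.min(meanrank)
    bst <- shorts[[best]]
    init <- if (model == "mmctm") {
        list(gamma = bst$gamma, Lambda = bst$Lambda, Nu2 = bst$Nu2,
            mu = bst$mu, Sigma = bst$Sigma)
    } else {
        list(gamma = bst$gamma[[1L]], gtheta = bst$gtheta)
    }
    res <- if (model == "mmctm") {
        mmctm_engine(Xs, K, beta = beta, fixSigma = fixCovarianceIdentity,
            tol = tolFinal, maxIter = maxFinalIter, init = init,
            ridge = ridge)
    } else {
        lda_engine(Xs[[1L]], K, alpha = alpha, beta = beta, tol = tolFinal,
            maxIter = maxFinalIter, init = init)
    }
    res$elbo <- c(bst$elbo, res$elbo)
    meta <- data.frame(restart = seq_len(nRestarts), seed = rseeds, llmat,
        meanRank = meanrank)
    names(meta)[2L + seq_len(M)] <- paste0("ll_", names(Xs))
    cfg <- list(beta = beta, alpha = if (model == "lda") alpha else NA_real_,
        fixCovarianceIdentity = fixCovarianceIdentity, tol = tolFinal,
        tolRestart = tolRestart, maxRestartIter = maxRestartIter,
        maxIter = maxFinalIter, seed = seed,
        restarts = list(table = meta, selected = best))
    build_fit(res, catalogs, model, cfg)
}

#' Estimate sample-signature probabilities for new samples
#'
#' Holds the fitted signatures (and, for correlated models, the Gaussian
#' prior) fixed and runs only the per-sample variational updates on new
#' counts, as done for observed test counts in held-out evaluation. A sample
#' with zero counts across all modalities gets the prior-mean-induced
#' probabilities and is flagged in the `"zeroCountSamples"` attribute.
#'
#' @param fit a [MmctmFit-class].
#' @param counts a catalog or list of catalogs whose category spaces match
#'   the fitted signatures.
#' @param tol,maxIter convergence control of the per-sample updates.
#' @return named list of D x K sample-signature probability matrices.
#' @export
inferSampleProbs <- function(fit, counts, tol = 1e-6, maxIter = 200L) {
    catalogs <- check_catalog_list(counts)
    if (length(catalogs) != length(fit@modalities)) {
        stop("modality count mismatch with the fitted model")
    }
    for (m in seq_along(catalogs)) {
        fitted_cats <- fit@signatures[[m]]
        if (is.matrix(fitted_cats)) fitted_cats <- list(fitted_cats)
        new_cats <- counts(catalogs[[m]], simplify = FALSE)
        if (length(fitted_cats) != length(new_cats)) {
            stop("feature structure mismatch for modality ",
                fit@modalities[m])
        }
        for (f in seq_along(new_cats)) {
            if (!identical(colnames(new_cats[[f]]),
                    colnames(fitted_cats[[f]]))) {
                stop("category space mismatch for modality ",
                    fit@modalities[m])
            }
        }
    }
    Xs <- lapply(catalogs, function(cat) counts(cat, simplify = FALSE))
    samples <- sampleIDs(catalogs[[1L]])
    theta <- if (fit@model == "mmctm") {
        mmctm_infer(fit@state, Xs, tol = tol, maxIter = maxIter)
    } else {
        list(lda_infer(fit@state, Xs[[1L]], maxIter = maxIter))
    }
    for (m in seq_along(theta)) {
        dimnames(theta[[m]]) <- list(samples,
            paste0(fit@modalities[m], seq_len(fit@K[m])))
    }
    names(theta) <- fit@modalities
    zero <- samples[rowSums(token_totals(Xs)) == 0]
    attr(theta, "zeroCountSamples") <- zero
    theta
}

#' Pearson correlations between signature probabilities
#'
#' Correlates per-sample signature probabilities across samples, spanning
#' all modalities of the fit (the cross-modality entries are how, e.g.,
#' coupled SNV/SV signatures show up). Signatures with constant probability
#' across samples get correlation 0 and are flagged.
#'
#' @param fit a [MmctmFit-class] with at least 3 samples, or a list of theta
#'   matrices.
#' @return Ktot x Ktot symmetric correlation matrix with unit diagonal and a
#'   `"constant"` attribute naming flagged signatures.
#' @export
signatureCorrelations <- function(fit) {
    theta <- if (is(fit, "MmctmFit")) sampleProbs(fit) else fit
    Theta <- do.call(cbind, theta)
    if (nrow(Theta) < 3L) {
        stop("need at least 3 samples to correlate signature probabilities")
    }
    sds <- apply(Theta, 2L, stats::sd)
    const <- sds == 0
    R <- suppressWarnings(stats::cor(Theta))
    R[const, ] <- 0
    R[, const] <- 0
    diag(R) <- 1
    attr(R, "constant") <- colnames(Theta)[const]
    R
}
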