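#' MmctmFit: a fitted mutation-signature topic model
#'
#' Container for the variational fit of LDA, CTM, MMCTM or their
#' independent-feature variants. Signatures are variational posterior means of
#' the per-signature category distributions; sample-signature probabilities
#' are posterior means (LDA) or the softmax of the per-sample Gaussian
#' posterior mean (correlated models). The shared logistic-normal prior
#' (mean `mu`, covariance `sigma`) spans the concatenated signature dimensions
#' of all modalities, which is what lets the model capture within- and
#' cross-modality signature correlations.
#'
#' @slot model one of "lda", "mmctm" (CTM is the single-modality MMCTM; the
#'   independent variants are the same models on independent-encoded catalogs).
#' @slot modalities modality names, in the order of the concatenated blocks.
#' @slot K integer vector, signatures per modality.
#' @slot signatures per modality: a K x V matrix (full encoding) or a named
#'   list of per-feature K x V matrices (independent encoding); rows sum to 1.
#' @slot theta per modality D x K sample-signature probability matrices;
#'   rows sum to 1.
#' @slot mu,sigma logistic-normal prior mean/covariance over the Ktot
#'   concatenated dimensions (identity/zero placeholders for LDA).
#' @slot lambda,nu2 per-sample variational Gaussian means and variances
#'   (correlated models; zero-row matrices for LDA).
#' @slot elbo per-iteration evidence lower bound trace.
#' @slot trainingLL per-modality average per-mutation log-likelihood of the
#'   training counts under the point estimates.
#' @slot config list of fitting settings (hyperparameters, tolerances, seed,
#'   bound choice, restart metadata, flags such as zero-count samples).
#' @slot state internal variational state needed to freeze signatures and
#'   infer sample probabilities for new data.
#'
#' @export
setClass("MmctmFit",
    representation(
        model = "character",
        modalities = "character",
        K = "integer",
        signatures = "list",
        theta = "list",
        mu = "numeric",
        sigma = "matrix",
        lambda = "matrix",
        nu2 = "matrix",
        elbo = "numeric",
        trainingLL = "numeric",
        config = "list",
        state = "list"
    )
)

setValidity("MmctmFit", function(object) {
    msg <- NULL
    if (length(object@K) != length(object@modalities)) {
        msg <- c(msg, "one K per modality required")
    }
    if (length(object@theta) != length(object@modalities)) {
        msg <- c(msg, "one theta matrix per modality required")
    }
    for (m in seq_along(object@theta)) {
        th <- object@theta[[m]]
        if (ncol(th) != object@K[m]) {
            msg <- c(msg, "theta shape inconsistent with K")
        }
        if (any(abs(rowSums(th) - 1) > 1e-6)) {
            msg <- c(msg, "theta rows must sum to 1")
        }
    }
    for (m in seq_along(object@signatures)) {
        sig <- object@signatures[[m]]
        if (is.matrix(sig)) sig <- list(sig)
        for (s in sig) {
            if (any(abs(rowSums(s) - 1) > 1e-6)) {
                msg <- c(msg, "signature rows must sum to 1")
            }
        }
    }
    ktot <- sum(object@K)
    if (length(object@mu) != ktot || !all(dim(object@sigma) == ktot)) {
        msg <- c(msg, "prior dimensions must match total signature count")
    }
    if (is.null(msg)) TRUE else msg
})

#' @describeIn MmctmFit signature matrices. With `modality = NULL`, the named
#'   per-modality list; otherwise the K x V matrix (or per-feature list) for
#'   one modality.
#' @param object a MmctmFit
#' @param modality modality name or index, or NULL for all
#' @export
setMethod("signatures", "MmctmFit", function(object, modality = NULL) {
    if (is.null(modality)) object@signatures
    else object@signatures[[modality]]
})

#' @describeIn MmctmFit sample-signature probability matrices (D x K), per
#'   modality or for one modality.
#' @export
setMethod("sampleProbs", "MmctmFit", function(object, modality = NULL) {
    if (is.null(modality)) object@theta else object@theta[[modality]]
})

#' @describeIn MmctmFit logistic-normal prior mean
#' @export
setMethod("priorMean", "MmctmFit", function(object) object@mu)

#' @describeIn MmctmFit logistic-normal prior covariance
#' @export
setMethod("priorCov", "MmctmFit", function(object) object@sigma)

#' @describeIn MmctmFit per-iteration ELBO values
#' @export
setMethod("elboTrace", "MmctmFit", function(object) object@elbo)

#' @describeIn MmctmFit per-modality training average per-mutation log-lik
#' @export
setMethod("trainingLogLik", "MmctmFit", function(object) object@trainingLL)

#' @describeIn MmctmFit signatures per modality (named integer vector)
#' @export
setMethod("nSignatures", "MmctmFit", function(object) {
    stats::setNames(object@K, object@modalities)
})

#' @describeIn MmctmFit modality names
#' @export
setMethod("modalityNames", "MmctmFit", function(object) object@modalities)

#' @describeIn MmctmFit sample identifiers
#' @export
setMethod("sampleIDs", "MmctmFit", function(object) {
    rownames(object@theta[[1L]])
})

setMethod("show", "MmctmFit", function(object) {
    cat("MmctmFit (", toupper(object@model), ")\n", sep = "")
    cat("  modalities: ",
        paste0(object@modalities, " [K=", object@K, "]", collapse = ", "),
        "\n", sep = "")
    cat("  samples: ", nrow(object@theta[[1L]]), "\n", sep = "")
    cat("  iterations: ", length(object@elbo),
        ", final ELBO: ", format(utils::tail(object@elbo, 1L)), "\n", sep = "")
    cat("  training log-lik per mutation: ",
        paste0(object@modalities, "=",
            signif(object@trainingLL, 6), collapse = ", "),
        "\n", sep = "")
})
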