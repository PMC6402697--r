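## Benchmarking machinery: stratified repeated CV, observed/hidden test
## splits, per-mutation predictive log-likelihood, count downsampling,
## signature-number selection and the classifier benchmark harness.

#' Stratified repeated cross-validation plan
#'
#' Splits samples into `nFolds` test folds, preserving stratum proportions
#' per fold up to rounding, and repeats the split `nRepeats` times (e.g. a
#' 10 x 5 scheme gives 50 train/test sets). Within each repeat the test folds
#' partition the samples. Strata smaller than `nFolds` are distributed
#' round-robin with a warning.
#'
#' @param sampleIDs sample identifiers.
#' @param strata per-sample stratum labels (e.g. histotype); default one
#'   stratum.
#' @param nFolds folds per repeat (>= 2).
#' @param nRepeats repeats.
#' @param seed RNG seed.
#' @return list with `assignments` (data.frame: repeat_, fold, sample,
#'   stratum), `nFolds`, `nRepeats`, `seed`. Train sets are the complements
#'   of the test folds; see [cvFold()].
#' @export
makeCvPlan <- function(sampleIDs, strata = NULL, nFolds = 5L, nRepeats = 10L,
        seed = 1L) {
    stopifnot(nFolds >= 2L)
    n <- length(sampleIDs)
    if (is.null(strata)) strata <- rep("all", n)
    stopifnot(length(strata) == n)
    small <- names(which(table(strata) < nFolds))
    if (length(small)) {
        warning("strata smaller than nFolds (",
            paste(small, collapse = ", "),
            "); their samples are distributed round-robin")
    }
    set.seed(seed)
    rows <- vector("list", nRepeats)
    for (r in seq_len(nRepeats)) {
        fold <- integer(n)
        for (st in unique(strata)) {
            idx <- sample(which(strata == st))
            fold[idx] <- rep_len(seq_len(nFolds), length(idx))
        }
        rows[[r]] <- data.frame(repeat_ = r, fold = fold,
            sample = sampleIDs, stratum = strata, stringsAsFactors = FALSE)
    }
    list(assignments = do.call(rbind, rows), nFolds = nFolds,
        nRepeats = nRepeats, seed = seed)
}

#' Train/test samples of one CV fold
#'
#' @param plan a plan from [makeCvPlan()].
#' @param repeat_,fold which repeat and fold.
#' @return list with `train` and `test` sample ID vectors.
#' @export
cvFold <- function(plan, repeat_, fold) {
    a <- plan$assignments
    a <- a[a$repeat_ == repeat_, ]
    list(train = a$sample[a$fold != fold], test = a$sample[a$fold == fold])
}

subset_catalog <- function(catalog, samples) {
    mats <- lapply(counts(catalog, simplify = FALSE), function(X) {
        X[samples, , drop = FALSE]
    })
    out <- MutationCatalog(mats, modality = modality(catalog),
        encoding = catalog@encoding)
    out
}

#' Split mutations into observed and hidden sets
#'
#' Assigns each mutation token independently to the observed set with
#' probability `fraction` (binomial thinning per count cell); observed and
#' hidden counts sum to the input exactly. Used for document-completion
#' evaluation: sample-signature probabilities are estimated from the observed
#' half, the predictive log-likelihood from the hidden half.
#'
#' @param counts a [MutationCatalog-class] or bare count matrix.
#' @param fraction probability a mutation lands in the observed set
#'   (0 < fraction < 1; default 0.5).
#' @param seed RNG seed.
#' @return list with `observed` and `hidden` of the same class as the input;
#'   samples with zero mutations are flagged in the `"zeroCountSamples"`
#'   attribute.
#' @export
splitObservedHidden <- function(counts, fraction = 0.5, seed = 1L) {
    stopifnot(fraction > 0, fraction < 1)
    is_cat <- is(counts, "MutationCatalog")
    mats <- if (is_cat) counts(counts, simplify = FALSE) else
        list(full = counts)
    set.seed(seed)
    obs <- lapply(mats, function(X) {
        O <- X
        O[] <- stats::rbinom(length(X), size = as.integer(X), prob = fraction)
        O
    })
    hid <- Map(`-`, mats, obs)
    zero <- rownames(mats[[1L]])[Reduce(`+`, lapply(mats, rowSums)) == 0]
    if (is_cat) {
        out <- list(
            observed = MutationCatalog(obs, modality = modality(counts),
                encoding = counts@encoding),
            hidden = MutationCatalog(hid, modality = modality(counts),
                encoding = counts@encoding))
    } else {
        out <- list(observed = obs[[1L]], hidden = hid[[1L]])
    }
    attr(out, "zeroCountSamples") <- zero
    out
}

#' Average per-mutation predictive log-likelihood
#'
#' Computes
#' `l = sum_d sum_v X_dv log( sum_k theta_dk phi_kv ) / sum_d sum_v X_dv`
#' over hidden counts: the average log probability per held-out mutation of
#' the mixture implied by the signatures and the sample-signature
#' probabilities. For comparator methods whose (renormalized) outputs can be
#' exactly zero, `floor` (e.g. 1e-16, as used for NMF solutions) is added to
#' the inner sum; the topic models themselves never need it since their
#' posterior-mean probabilities are strictly positive.
#'
#' @param phi K x V signature matrix (rows sum to 1).
#' @param theta D x K sample-signature probabilities (rows sum to 1).
#' @param hidden D x V held-out count matrix (or [MutationCatalog-class] with
#'   a single feature).
#' @param floor non-negative constant added to the per-mutation probability
#'   (default 0).
#' @return scalar average per-mutation log-likelihood.
#' @examples
#' phi <- matrix(0.25, 1, 4)
#' predictiveLogLik(phi, matrix(1, 2, 1), matrix(3, 2, 4))  # log(1/4)
#' @export
predictiveLogLik <- function(phi, theta, hidden, floor = 0) {
    if (is(hidden, "MutationCatalog")) hidden <- counts(hidden)
    stopifnot(ncol(theta) == nrow(phi), nrow(theta) == nrow(hidden),
        ncol(phi) == ncol(hidden))
    if (sum(hidden) <= 0) {
        stop("hidden counts are all zero; the average is undefined")
    }
    P <- theta %*% phi + floor
    sum(hidden * log(P)) / sum(hidden)
}

#' Downsample mutation counts
#'
#' Retains a random subset of mutations: by default each category count is
#' thinned Binomial(count, fraction) per sample, which removes mutations in
#' proportion to their per-type relative frequencies in expectation. With
#' `method = "exact"`, exactly `round(fraction * N_d)` mutations are kept per
#' sample, drawn without replacement across categories (multivariate
#' hypergeometric).
#'
#' @param counts [MutationCatalog-class] or count matrix.
#' @param fraction fraction of mutations to retain (0 to 1).
#' @param seed RNG seed.
#' @param method "binomial" (default) or "exact".
#' @return object of the same class, elementwise <= the input.
#' @export
downsampleCounts <- function(counts, fraction, seed = 1L,
        method = c("binomial", "exact")) {
    stopifnot(fraction >= 0, fraction <= 1)
    method <- match.arg(method)
    is_cat <- is(counts, "MutationCatalog")
    mats <- if (is_cat) counts(counts, simplify = FALSE) else list(counts)
    set.seed(seed)
    thin <- lapply(mats, function(X) {
        if (method == "binomial") {
            Y <- X
            Y[] <- stats::rbinom(length(X), size = as.integer(X),
                prob = fraction)
            Y
        } else {
            Y <- X * 0
            for (d in seq_len(nrow(X))) {
                tot <- sum(X[d, ])
                keep <- round(fraction * tot)
                if (keep > 0) {
                    pool <- rep.int(seq_len(ncol(X)), X[d, ])
                    drawn <- pool[sample.int(length(pool), keep)]
                    Y[d, ] <- tabulate(drawn, nbins = ncol(X))
                }
            }
            Y
        }
    })
    if (is_cat) {
        MutationCatalog(thin, modality = modality(counts),
            encoding = counts@encoding)
    } else {
        thin[[1L]]
    }
}

balance_classes <- function(labels, seed) {
    set.seed(seed)
    tab <- table(labels)
    if (length(tab) != 2L) stop("labels must have exactly two classes")
    nmin <- min(tab)
    idx <- unlist(lapply(names(tab), function(cl) {
        i <- which(labels == cl)
        if (length(i) > nmin) sample(i, nmin) else i
    }))
    sort(idx)
}

#' Logistic-regression classifier benchmark
#'
#' Benchmarks how well sample-signature probabilities predict a binary label
#' (e.g. an HRD call): the majority class is subsampled to balance the
#' classes, then a stratified `nFolds`-fold cross-validation fits an
#' L2-regularized logistic regression (ridge penalty, strength mirroring a
#' unit-C solver: lambda = 1/n) per training fold and scores plain accuracy
#' on the held-out fold.
#'
#' @param features numeric matrix of per-sample features (e.g. theta).
#' @param labels binary labels (logical, factor or 0/1), length nrow(features).
#' @param nFolds folds (default 5).
#' @param seed RNG seed for subsampling and fold assignment.
#' @return numeric vector of per-fold accuracies.
#' @export
classifierBenchmark <- function(features, labels, nFolds = 5L, seed = 1L) {
    features <- as.matrix(features)
    y <- as.integer(as.factor(labels)) - 1L
    stopifnot(length(y) == nrow(features))
    if (min(table(y)) < 2L) stop("need at least 2 samples per class")
    keep <- balance_classes(y, seed)
    X <- features[keep, , drop = FALSE]
    y <- y[keep]
    if (ncol(X) < 2L) X <- cbind(X, 0)  # glmnet needs >= 2 columns
    ## stratified folds
    fold <- integer(length(y))
    for (cl in unique(y)) {
        i <- sample(which(y == cl))
        fold[i] <- rep_len(seq_len(nFolds), length(i))
    }
    acc <- numeric(nFolds)
    for (f in seq_len(nFolds)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 1L) {
            stop("a fold lacks both classes; use more data or fewer folds")
        }
        fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
            family = "binomial", alpha = 0, lambda = 1 / sum(tr),
            maxit = 10000L)
        p <- stats::predict(fit, X[!tr, , drop = FALSE], type = "response")
        acc[f] <- mean((p > 0.5) == (y[!tr] == 1L))
    }
    acc
}

#' Likelihood curve over the number of signatures
#'
#' Produces the held-out log-likelihood curve used to choose the number of
#' signatures. `"half_split"` fits the model to roughly half the mutations of
#' every sample and scores the average per-mutation log-likelihood on the
#' other half (all samples participate); `"cv"` uses a stratified sample-level
#' CV: the model is fitted on training samples, sample probabilities of test
#' samples are estimated from their observed half, and the hidden half is
#' scored. The suggested K is the smallest K whose successor improves the
#' mean log-likelihood by less than one standard error — an advisory elbow
#' heuristic; the final choice stays with the user.
#'
#' @param counts catalog or list of catalogs.
#' @param kRange candidate signature counts (applied to every modality).
#' @param mode "half_split" (default) or "cv".
#' @param model "mmctm" or "lda" (single modality).
#' @param nReplicates half-split replicates / CV (repeat, fold) pairs used.
#' @param nRestarts restarts per fit.
#' @param fraction observed fraction of the split (default 0.5).
#' @param seed RNG seed.
#' @param ... passed to [fitWithRestarts()].
#' @return list with `table` (K, mean_ll, se, per modality) and `suggestedK`.
#' @export
selectSignatureNumber <- function(counts, kRange,
        mode = c("half_split", "cv"), model = c("mmctm", "lda"),
        nReplicates = 3L, nRestarts = 5L, fraction = 0.5, seed = 1L, ...) {
    mode <- match.arg(mode)
    model <- match.arg(model)
    catalogs <- check_catalog_list(counts)
    stopifnot(length(kRange) >= 1L)
    rows <- list()
    for (K in kRange) {
        lls <- matrix(NA_real_, nReplicates, length(catalogs))
        for (r in seq_len(nReplicates)) {
            sd_r <- seed * 1000L + r
            if (mode == "half_split") {
                sp <- lapply(seq_along(catalogs), function(m) {
                    splitObservedHidden(catalogs[[m]], fraction,
                        seed = sd_r + m)
                })
                train <- lapply(sp, `[[`, "observed")
                names(train) <- names(catalogs)
                fit <- fitWithRestarts(train, K, model = model,
                    nRestarts = nRestarts, seed = sd_r, ...)
                for (m in seq_along(catalogs)) {
                    lls[r, m] <- predictiveLogLik(
                        flat_signatures(fit, m),
                        sampleProbs(fit)[[m]],
                        flat_counts(sp[[m]]$hidden))
                }
            } else {
                plan <- makeCvPlan(sampleIDs(catalogs[[1L]]),
                    nFolds = max(2L, nReplicates), nRepeats = 1L,
                    seed = sd_r)
                fl <- cvFold(plan, 1L, 1L + (r - 1L) %% plan$nFolds)
                train <- lapply(catalogs, subset_catalog, fl$train)
                test <- lapply(catalogs, subset_catalog, fl$test)
                fit <- fitWithRestarts(train, K, model = model,
                    nRestarts = nRestarts, seed = sd_r, ...)
                sp <- lapply(seq_along(test), function(m) {
                    splitObservedHidden(test[[m]], fraction, seed = sd_r + m)
                })
                obs <- lapply(sp, `[[`, "observed")
                names(obs) <- names(catalogs)
                th <- inferSampleProbs(fit, obs)
                for (m in seq_along(catalogs)) {
                    lls[r, m] <- predictiveLogLik(flat_signatures(fit, m),
                        th[[m]], flat_counts(sp[[m]]$hidden))
                }
            }
        }
        rows[[length(rows) + 1L]] <- data.frame(
            K = K,
            modality = names(catalogs),
            mean_ll = colMeans(lls),
            se = apply(lls, 2L, stats::sd) / sqrt(nReplicates),
            stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    ks <- sort(unique(tab$K))
    mean_by_k <- vapply(ks, function(k) mean(tab$mean_ll[tab$K == k]), 0)
    se_by_k <- vapply(ks, function(k) mean(tab$se[tab$K == k]), 0)
    se_by_k[is.na(se_by_k)] <- 0
    suggested <- ks[length(ks)]
    if (length(ks) > 1L) {
        for (i in seq_len(length(ks) - 1L)) {
            if (mean_by_k[i + 1L] - mean_by_k[i] < se_by_k[i + 1L]) {
                suggested <- ks[i]
                break
            }
        }
    }
    list(table = tab, suggestedK = suggested)
}

## full-category signatures of one modality (product over features for
## independent encodings, per-modality matrix otherwise)
flat_signatures <- function(fit, m) {
    sig <- fit@signatures[[m]]
    if (is.matrix(sig)) sig else productSignatures(sig)
}

## hidden counts on the full category space for predictive scoring
flat_counts <- function(catalog) {
    mats <- counts(catalog, simplify = FALSE)
    if (length(mats) == 1L) {
        return(mats[[1L]])
    }
    stop("predictive scoring on independent-encoded hidden counts needs the ",
        "full-context catalog; encode the hidden mutations with ",
        "encoding = \"full\"")
}

#' Held-out predictive benchmark over methods and signature counts
#'
#' Runs the document-completion benchmark: for each CV (repeat, fold), each
#' method is fitted on the training samples; test samples' mutations are
#' split into observed and hidden halves, their signature probabilities are
#' estimated from the observed half, and the average per-mutation predictive
#' log-likelihood of the hidden half is recorded per modality.
#'
#' @param counts catalog or list of catalogs (full encoding).
#' @param methods subset of c("mmctm", "lda"); "mmctm" with one modality is
#'   the CTM.
#' @param kRange signature counts to scan.
#' @param plan CV plan from [makeCvPlan()]; defaults to a 2 x 2 plan.
#' @param fraction observed fraction of the test split.
#' @param nRestarts restarts per fit.
#' @param seed RNG seed.
#' @return tidy data.frame with columns method, evaluation (modality), k,
#'   n (repeat), fold, ll.
#' @export
benchmarkPredictive <- function(counts, methods = c("mmctm", "lda"),
        kRange = 2:4, plan = NULL, fraction = 0.5, nRestarts = 3L,
        seed = 1L) {
    catalogs <- check_catalog_list(counts)
    ids <- sampleIDs(catalogs[[1L]])
    if (is.null(plan)) {
        plan <- makeCvPlan(ids, nFolds = 2L, nRepeats = 2L, seed = seed)
    }
    out <- list()
    for (r in seq_len(plan$nRepeats)) {
        for (f in seq_len(plan$nFolds)) {
            fl <- cvFold(plan, r, f)
            train <- lapply(catalogs, subset_catalog, fl$train)
            test <- lapply(catalogs, subset_catalog, fl$test)
            sp <- lapply(seq_along(test), function(m) {
                splitObservedHidden(test[[m]], fraction,
                    seed = seed + 97L * r + f + m)
            })
            obs <- lapply(sp, `[[`, "observed")
            names(obs) <- names(catalogs)
            for (K in kRange) {
                for (method in methods) {
                    if (method == "lda") {
                        for (m in seq_along(catalogs)) {
                            fit <- fitWithRestarts(train[[m]], K,
                                model = "lda", nRestarts = nRestarts,
                                seed = seed + r * 13L + f)
                            th <- inferSampleProbs(fit, obs[[m]])
                            ll <- predictiveLogLik(flat_signatures(fit, 1L),
                                th[[1L]], flat_counts(sp[[m]]$hidden))
                            out[[length(out) + 1L]] <- data.frame(
                                method = "lda",
                                evaluation = names(catalogs)[m], k = K,
                                n = r, fold = f, ll = ll,
                                stringsAsFactors = FALSE)
                        }
                    } else {
                        fit <- fitWithRestarts(train, K, model = "mmctm",
                            nRestarts = nRestarts,
                            seed = seed + r * 13L + f)
                        th <- inferSampleProbs(fit, obs)
                        for (m in seq_along(catalogs)) {
                            ll <- predictiveLogLik(flat_signatures(fit, m),
                                th[[m]], flat_counts(sp[[m]]$hidden))
                            out[[length(out) + 1L]] <- data.frame(
                                method = if (length(catalogs) == 1L) "ctm"
                                    else "mmctm",
                                evaluation = names(catalogs)[m], k = K,
                                n = r, fold = f, ll = ll,
                                stringsAsFactors = FALSE)
                        }
                    }
                }
            }
        }
    }
    do.call(rbind, out)
}
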