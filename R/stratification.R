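## Signature-based patient stratification: z-scored joint SNV+SV signature
## probabilities, Ward hierarchical clustering, cluster-signature enrichment
## tests, blocked permutation tests for confounded annotations, and BH
## correction.

#' Standardize signature probabilities to z-scores
#'
#' Converts each signature's probabilities to z-scores across samples
#' (column-wise; SD uses the n-1 denominator), which emphasizes inter-sample
#' differences of low-prevalence signatures relative to high-prevalence ones
#' before clustering. Zero-variance columns map to all zeros and are flagged.
#'
#' @param thetas D x K matrix, or list of them (joined column-wise; e.g.
#'   `sampleProbs(fit)` for joint SNV+SV stratification).
#' @return D x Ktot matrix of z-scores with a `"constant"` attribute naming
#'   flagged columns.
#' @export
standardizeProbs <- function(thetas) {
    X <- if (is.list(thetas)) do.call(cbind, thetas) else thetas
    if (nrow(X) < 2L) stop("need at least 2 samples to standardize")
    mu <- colMeans(X)
    sdv <- apply(X, 2L, stats::sd)
    const <- sdv == 0
    Z <- sweep(X, 2L, mu)
    Z[, !const] <- sweep(Z[, !const, drop = FALSE], 2L, sdv[!const], `/`)
    Z[, const] <- 0
    attr(Z, "constant") <- colnames(X)[const]
    Z
}

#' Hierarchical clustering of samples
#'
#' Agglomerates samples with Ward linkage on Euclidean distances
#' (`stats::hclust(method = "ward.D2")`) and cuts the tree by one of three
#' modes: `"dynamic"` picks the largest number of clusters such that every
#' cluster has at least `minClusterSize` members (a deterministic stand-in
#' for dynamic hybrid tree cutting), `"fixed_k"` cuts at `k` clusters, and
#' `"fixed_height"` cuts at height `h`.
#'
#' @param z sample-by-feature matrix (typically from [standardizeProbs()]).
#' @param minClusterSize minimum cluster size for the dynamic cut (default 3).
#' @param cut cut mode.
#' @param k,h cluster count / height for the fixed modes.
#' @return list with `sample_ids`, `labels` (integer assignment), `hclust`
#'   (the merge tree) and `params`.
#' @export
clusterSamples <- function(z, minClusterSize = 3L,
        cut = c("dynamic", "fixed_k", "fixed_height"), k = NULL, h = NULL) {
    cut <- match.arg(cut)
    if (nrow(z) < 2L) stop("need at least 2 samples to cluster")
    hc <- stats::hclust(stats::dist(z, method = "euclidean"),
        method = "ward.D2")
    labels <- switch(cut,
        fixed_k = {
            stopifnot(!is.null(k))
            stats::cutree(hc, k = k)
        },
        fixed_height = {
            stopifnot(!is.null(h))
            stats::cutree(hc, h = h)
        },
        dynamic = {
            if (nrow(z) < minClusterSize) {
                stop("fewer samples than minClusterSize")
            }
            best <- rep(1L, nrow(z))
            for (kk in seq(floor(nrow(z) / minClusterSize), 1L)) {
                lab <- stats::cutree(hc, k = kk)
                if (min(table(lab)) >= minClusterSize) {
                    best <- lab
                    break
                }
            }
            best
        })
    list(sample_ids = rownames(z), labels = unname(labels), hclust = hc,
        params = list(metric = "euclidean", linkage = "ward.D2", cut = cut,
            minClusterSize = minClusterSize, k = k, h = h))
}

welch_onesided <- function(x, y) {
    if (length(x) < 2L || length(y) < 2L || stats::sd(c(x, y)) == 0) {
        return(list(p = NA_real_, diff = mean(x) - mean(y),
            conf = c(NA_real_, NA_real_)))
    }
    tt <- stats::t.test(x, y, alternative = "greater", var.equal = FALSE)
    list(p = tt$p.value, diff = unname(diff(rev(tt$estimate))),
        conf = c(tt$conf.int[1L], tt$conf.int[2L]))
}

#' Cluster-signature enrichment tests
#'
#' For every (cluster, signature) pair, a one-sided Welch (unequal variance)
#' t-test of the in-cluster signature probabilities against those of all
#' other samples (alternative: greater), BH-adjusted across all tests.
#' Clusters with fewer than 2 members yield NA and are flagged.
#'
#' @param thetas D x K matrix or list of them (all modalities joined).
#' @param labels integer cluster assignment per sample.
#' @return data.frame with columns cluster, signature, p_value, mean_diff,
#'   conf_low, conf_high, q_value.
#' @export
clusterSignatureEnrichment <- function(thetas, labels) {
    X <- if (is.list(thetas)) do.call(cbind, thetas) else thetas
    stopifnot(nrow(X) == length(labels))
    sigs <- colnames(X)
    if (is.null(sigs)) sigs <- paste0("sig", seq_len(ncol(X)))
    rows <- list()
    for (cl in sort(unique(labels))) {
        inside <- labels == cl
        for (j in seq_len(ncol(X))) {
            r <- if (sum(inside) < 2L) {
                list(p = NA_real_, diff = NA_real_,
                    conf = c(NA_real_, NA_real_))
            } else {
                welch_onesided(X[inside, j], X[!inside, j])
            }
            rows[[length(rows) + 1L]] <- data.frame(cluster = cl,
                signature = sigs[j], p_value = r$p, mean_diff = r$diff,
                conf_low = r$conf[1L], conf_high = r$conf[2L],
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    out$q_value <- bhAdjust(out$p_value)
    out
}

enumerate_block_combos <- function(block_labels, take) {
    ## all ways to pick `take[b]` samples from each block b; returns a matrix
    ## of sample index sets (columns = draws)
    per_block <- lapply(names(take), function(b) {
        idx <- which(block_labels == b)
        if (length(idx) == 1L) {
            matrix(idx, 1L, 1L)
        } else {
            utils::combn(idx, take[[b]])
        }
    })
    grids <- lapply(per_block, function(m) seq_len(ncol(m)))
    combos <- expand.grid(grids)
    tot <- sum(vapply(per_block, nrow, 1L))
    res <- vapply(seq_len(nrow(combos)), function(i) {
        unlist(lapply(seq_along(per_block), function(b) {
            per_block[[b]][, combos[i, b]]
        }))
    }, numeric(tot))
    if (!is.matrix(res)) res <- matrix(res, nrow = tot)
    res
}

#' Blocked permutation test for cluster-annotation association
#'
#' Tests whether an annotation differs between a cluster and the remaining
#' samples while controlling for confounding strata: each permutation draws
#' a new "cluster" without replacement from the full dataset with the same
#' per-block composition as the original cluster (e.g. the same ER/PR/HER2 or
#' histotype make-up). The statistic s is the difference in annotation
#' proportion (binary annotation) or mean (numeric) between the cluster and
#' the rest; the two-tailed p-value is `(1 + #\{|s'| >= |s|\}) / (1 + N)`.
#' With `exhaustive = TRUE` all distinct per-block draws are enumerated and
#' the plain proportion `#\{|s'| >= |s|\} / n_total` is returned instead
#' (no +1 smoothing, since the enumeration is exact).
#'
#' @param member logical vector: cluster membership per sample.
#' @param annotation logical/0-1 (proportion statistic) or numeric (mean
#'   statistic) vector per sample.
#' @param blocks block label per sample (confounding strata).
#' @param nPerm number of permutations (default 10000).
#' @param seed RNG seed.
#' @param exhaustive enumerate all distinct draws instead of sampling.
#' @return list with `s` (observed statistic), `p`, and `nPerm` used.
#' @export
blockedPermutationTest <- function(member, annotation, blocks,
        nPerm = 10000L, seed = 1L, exhaustive = FALSE) {
    member <- as.logical(member)
    stopifnot(length(annotation) == length(member),
        length(blocks) == length(member), any(member))
    if (all(member)) {
        stop("the cluster contains every sample; no samples outside it")
    }
    blocks <- as.character(blocks)
    x <- as.numeric(annotation)
    stat <- function(mem) mean(x[mem]) - mean(x[!mem])
    s <- stat(member)
    take <- table(blocks[member])
    avail <- table(factor(blocks, levels = names(take)))
    if (any(avail < take)) {
        stop("a block has fewer samples than the cluster uses from it")
    }
    n <- length(member)
    if (exhaustive) {
        combos <- enumerate_block_combos(blocks, as.list(take))
        sp <- apply(combos, 2L, function(idx) {
            mem <- rep(FALSE, n)
            mem[idx] <- TRUE
            stat(mem)
        })
        ## full-membership draws leave no "rest"; guard (cannot happen when
        ## the cluster is a strict subset)
        p <- mean(abs(sp) >= abs(s) - 1e-12)
        return(list(s = s, p = p, nPerm = length(sp)))
    }
    set.seed(seed)
    idx_by_block <- split(seq_len(n), blocks)
    hits <- 0L
    for (i in seq_len(nPerm)) {
        mem <- rep(FALSE, n)
        for (b in names(take)) {
            pool <- idx_by_block[[b]]
            mem[pool[sample.int(length(pool), take[[b]])]] <- TRUE
        }
        if (abs(stat(mem)) >= abs(s) - 1e-12) hits <- hits + 1L
    }
    list(s = s, p = (1 + hits) / (1 + nPerm), nPerm = nPerm)
}

#' Cluster-annotation association tests
#'
#' Dispatches, per cluster versus the rest, to the named standard test:
#' two-tailed Fisher's exact test (binary annotations), two-tailed Welch
#' t-test (numeric), or the Welch t-test on midranks (robust to extreme
#' values, e.g. hypermutators). Degenerate 2x2 margins return p = 1 with a
#' flag. BH-adjusted across clusters.
#'
#' @param values annotation values per sample (binary for fisher, numeric
#'   otherwise).
#' @param labels integer cluster assignment per sample.
#' @param test "fisher_2tail", "welch_2tail" or "welch_on_ranks".
#' @param name annotation name recorded in the output.
#' @return data.frame with columns label, cluster, p_value, diff, conf_low,
#'   conf_high, test, q_value, flag.
#' @export
annotationAssociation <- function(values, labels,
        test = c("fisher_2tail", "welch_2tail", "welch_on_ranks"),
        name = "annotation") {
    test <- match.arg(test)
    stopifnot(length(values) == length(labels))
    v <- if (test == "welch_on_ranks") rank(values) else values
    rows <- list()
    for (cl in sort(unique(labels))) {
        inside <- labels == cl
        flag <- NA_character_
        conf <- c(NA_real_, NA_real_)
        if (test == "fisher_2tail") {
            b <- as.logical(values)
            tab <- table(factor(inside, c(FALSE, TRUE)),
                factor(b, c(FALSE, TRUE)))
            dif <- mean(b[inside]) - mean(b[!inside])
            if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
                p <- 1
                flag <- "degenerate_margins"
            } else {
                p <- stats::fisher.test(tab)$p.value
            }
        } else {
            xi <- as.numeric(v[inside])
            yo <- as.numeric(v[!inside])
            dif <- mean(xi) - mean(yo)
            if (length(xi) < 2L || length(yo) < 2L ||
                    stats::sd(c(xi, yo)) == 0) {
                p <- 1
                flag <- "degenerate_groups"
            } else {
                tt <- stats::t.test(xi, yo, var.equal = FALSE)
                p <- tt$p.value
                conf <- c(tt$conf.int[1L], tt$conf.int[2L])
            }
        }
        rows[[length(rows) + 1L]] <- data.frame(label = name, cluster = cl,
            p_value = p, diff = dif, conf_low = conf[1L],
            conf_high = conf[2L], test = test, flag = flag,
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out$q_value <- bhAdjust(out$p_value)
    out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wraps
#' `stats::p.adjust(method = "BH")`); NA p-values are passed through.
#'
#' @param p vector of p-values.
#' @return adjusted q-values, capped at 1.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # 0.03 0.03 0.03
#' @export
bhAdjust <- function(p) {
    if (length(p) == 0L) return(numeric(0))
    stats::p.adjust(p, method = "BH")
}
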