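#' MutationCatalog: per-modality mutation count matrices
#'
#' A `MutationCatalog` holds the sample-by-category mutation counts for one
#' modality (one mutation data type, e.g. SNV or SV). Counts are stored as a
#' list of matrices, one per feature: the full-context encoding has a single
#' feature (`"full"`, e.g. 96 trinucleotide categories for SNVs), while the
#' independent encoding stores one matrix per mutation feature (substitution
#' type, 5' flank, 3' flank). All matrices share the same samples (rows, in
#' the same order); columns are the category labels of each feature.
#'
#' @slot modality single string naming the mutation type (e.g. "SNV", "SV").
#' @slot encoding `"full"` or `"independent"`.
#' @slot counts named list of non-negative numeric matrices with identical
#'   rownames (sample IDs) and per-feature category labels as colnames.
#'
#' @export
setClass("MutationCatalog",
    representation(
        modality = "character",
        encoding = "character",
        counts = "list"
    )
)

setValidity("MutationCatalog", function(object) {
    msg <- NULL
    if (length(object@modality) != 1L) {
        msg <- c(msg, "'modality' must be a single string")
    }
    if (!object@encoding %in% c("full", "independent")) {
        msg <- c(msg, "'encoding' must be \"full\" or \"independent\"")
    }
    if (length(object@counts) == 0L) {
        msg <- c(msg, "'counts' must contain at least one matrix")
    } else {
        ids <- rownames(object@counts[[1L]])
        for (i in seq_along(object@counts)) {
            x <- object@counts[[i]]
            if (!is.matrix(x) || !is.numeric(x)) {
                msg <- c(msg, "all count elements must be numeric matrices")
                break
            }
            if (any(x < 0)) {
                msg <- c(msg, "counts must be non-negative")
                break
            }
            if (any(abs(x - round(x)) > 1e-8)) {
                msg <- c(msg, "counts must be integers")
                break
            }
            if (is.null(rownames(x)) || is.null(colnames(x))) {
                msg <- c(msg, "count matrices need sample rownames and category colnames")
                break
            }
            if (!identical(rownames(x), ids)) {
                msg <- c(msg, "all feature matrices must share identical sample rownames")
                break
            }
            if (anyDuplicated(colnames(x))) {
                msg <- c(msg, "category labels must be unique within a feature")
                break
            }
        }
        if (object@encoding == "full" && length(object@counts) != 1L) {
            msg <- c(msg, "full encoding must have exactly one feature matrix")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a MutationCatalog
#'
#' @param counts a single sample-by-category matrix (full encoding) or a named
#'   list of per-feature matrices (independent encoding). Rows are samples.
#' @param modality modality name, e.g. "SNV" or "SV".
#' @param encoding "full" (default when a single matrix is given) or
#'   "independent".
#'
#' @return A [MutationCatalog-class] object.
#' @examples
#' m <- matrix(rpois(6, 5), 2, 3,
#'     dimnames = list(c("s1", "s2"), c("a", "b", "c")))
#' MutationCatalog(m, modality = "SNV")
#' @export
MutationCatalog <- function(counts, modality = "SNV", encoding = NULL) {
    if (is.matrix(counts)) {
        counts <- list(full = counts)
        if (is.null(encoding)) encoding <- "full"
    } else if (is.null(encoding)) {
        encoding <- if (length(counts) > 1L) "independent" else "full"
    }
    counts <- lapply(counts, function(x) {
        storage.mode(x) <- "double"
        x
    })
    if (is.null(names(counts))) {
        names(counts) <- if (length(counts) == 1L) "full" else
            paste0("feature", seq_along(counts))
    }
    new("MutationCatalog", modality = modality, encoding = encoding,
        counts = counts)
}

#' @describeIn MutationCatalog count matrices; a single matrix for the full
#'   encoding, otherwise the named per-feature list (use `simplify = FALSE`
#'   to always get the list).
#' @param object,x a MutationCatalog
#' @param simplify return the bare matrix when there is a single feature
#' @export
setMethod("counts", "MutationCatalog", function(object, simplify = TRUE, ...) {
    if (simplify && length(object@counts) == 1L) object@counts[[1L]]
    else object@counts
})

#' @describeIn MutationCatalog modality name
#' @export
setMethod("modality", "MutationCatalog", function(object) object@modality)

#' @describeIn MutationCatalog sample identifiers
#' @export
setMethod("sampleIDs", "MutationCatalog", function(object) {
    rownames(object@counts[[1L]])
})

#' @describeIn MutationCatalog per-feature category labels (named list)
#' @export
setMethod("categories", "MutationCatalog", function(object, simplify = TRUE) {
    labs <- lapply(object@counts, colnames)
    if (simplify && length(labs) == 1L) labs[[1L]] else labs
})

#' @describeIn MutationCatalog feature names
#' @export
setMethod("modalityFeatures", "MutationCatalog", function(object) {
    names(object@counts)
})

setMethod("show", "MutationCatalog", function(object) {
    tot <- sum(object@counts[[1L]])
    cat("MutationCatalog (", object@modality, ", ", object@encoding,
        " encoding)\n", sep = "")
    cat("  samples: ", nrow(object@counts[[1L]]), "\n", sep = "")
    cat("  features: ",
        paste0(names(object@counts), " [",
            vapply(object@counts, ncol, 1L), "]", collapse = ", "),
        "\n", sep = "")
    cat("  total mutations (first feature): ", tot, "\n", sep = "")
    zero <- rownames(object@counts[[1L]])[rowSums(object@counts[[1L]]) == 0]
    if (length(zero)) {
        cat("  zero-count samples: ", paste(zero, collapse = ", "), "\n",
            sep = "")
    }
})

# internal: list of catalogs -> checked, with shared sample order
check_catalog_list <- function(catalogs) {
    if (is(catalogs, "MutationCatalog")) catalogs <- list(catalogs)
    stopifnot(length(catalogs) >= 1L)
    for (cat in catalogs) {
        if (!is(cat, "MutationCatalog")) {
            stop("expected MutationCatalog objects")
        }
    }
    ids <- sampleIDs(catalogs[[1L]])
    for (cat in catalogs[-1L]) {
        if (!identical(sampleIDs(cat), ids)) {
            stop("all modalities must share the same samples in the same ",
                "order; mismatch for modality '", modality(cat), "'")
        }
    }
    if (is.null(names(catalogs))) {
        names(catalogs) <- vapply(catalogs, modality, "")
    }
    catalogs
}
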