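## Readers and writers. The universal tabular dialect is TSV with a header
## row, UTF-8, "." for missing values; comment lines starting with '#' carry
## provenance (package version, seed, key parameters) and are skipped on
## reading.

provenance_header <- function(seed = NULL, params = list()) {
    bits <- c(paste0("mmctm ", as.character(utils::packageVersion("mmctm"))),
        if (!is.null(seed)) paste0("seed=", seed),
        if (length(params)) {
            paste(names(params), unlist(params), sep = "=", collapse = " ")
        })
    paste0("# ", paste(bits, collapse = " | "))
}

#' Write a count matrix (or any sample-keyed matrix) as TSV
#'
#' First column `sample_id`, remaining columns the category labels.
#'
#' @param m matrix with sample rownames, or a [MutationCatalog-class] with a
#'   single feature.
#' @param path output file.
#' @param provenance optional provenance comment line(s) written before the
#'   header.
#' @export
writeCountMatrix <- function(m, path, provenance = NULL) {
    if (is(m, "MutationCatalog")) m <- counts(m)
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
        stringsAsFactors = FALSE)
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    if (!is.null(provenance)) writeLines(provenance, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
        na = ".")
    invisible(path)
}

#' Read a count matrix TSV
#'
#' @param path file written by [writeCountMatrix()] (first column sample_id).
#' @param modality if non-NULL, wrap the matrix in a
#'   [MutationCatalog-class] with this modality name.
#' @return matrix (or catalog).
#' @export
readCountMatrix <- function(path, modality = NULL) {
    df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
        na.strings = ".")
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- as.character(df[[1L]])
    storage.mode(m) <- "double"
    if (is.null(modality)) m else MutationCatalog(m, modality = modality)
}

#' Read SNV calls from a VCF
#'
#' Returns one row per (record, alt, carrier sample). With genotypes present,
#' a record is attributed to every sample whose GT contains a non-reference
#' allele; without genotypes all records are attributed to a single sample
#' named after the file. Indels and multi-allelic alts are returned as-is and
#' skipped later by [buildSnvCatalog()].
#'
#' @param path VCF file (plain or bgzipped).
#' @param genome genome identifier passed to VariantAnnotation (informational).
#' @return data.frame with columns sample, chrom, pos, ref, alt.
#' @export
readSnvVcf <- function(path, genome = "unknown") {
    if (!file.exists(path)) stop("VCF not found: ", path)
    vcf <- VariantAnnotation::readVcf(path, genome = genome)
    rr <- SummarizedExperiment::rowRanges(vcf)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    pos <- BiocGenerics::start(rr)
    ref <- as.character(VariantAnnotation::ref(vcf))
    altl <- VariantAnnotation::alt(vcf)
    alts <- vapply(seq_along(altl), function(i) {
        a <- as.character(altl[[i]])
        if (length(a) == 1L) a else paste(a, collapse = ",")
    }, "")
    gt <- tryCatch(VariantAnnotation::geno(vcf)$GT, error = function(e) NULL)
    if (is.null(gt) || ncol(gt) == 0L) {
        sm <- sub("\\.vcf(\\.gz)?$", "", basename(path))
        return(data.frame(sample = sm, chrom = chrom, pos = pos, ref = ref,
            alt = alts, stringsAsFactors = FALSE))
    }
    rows <- list()
    for (j in seq_len(ncol(gt))) {
        carrier <- grepl("[1-9]", gt[, j])
        if (any(carrier)) {
            rows[[length(rows) + 1L]] <- data.frame(
                sample = colnames(gt)[j], chrom = chrom[carrier],
                pos = pos[carrier], ref = ref[carrier], alt = alts[carrier],
                stringsAsFactors = FALSE)
        }
    }
    if (!length(rows)) {
        stop("no carrier genotypes found in ", path)
    }
    do.call(rbind, rows)
}

#' Read a structural-variant call table
#'
#' Tab-separated with header columns chrom1, pos1, chrom2, pos2, type,
#' homology, sample (BEDPE-like; extra columns are kept).
#'
#' @param path TSV file.
#' @return data.frame of SV calls.
#' @export
readSvTable <- function(path) {
    if (!file.exists(path)) stop("SV table not found: ", path)
    df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
        na.strings = ".", stringsAsFactors = FALSE)
    need <- c("chrom1", "pos1", "chrom2", "pos2", "type", "homology",
        "sample")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
        stop("SV table ", path, " lacks column(s): ",
            paste(miss, collapse = ", "))
    }
    df
}

write_matrix_tsv <- function(m, path, rowlab = "row") {
    df <- data.frame(x = rownames(m), m, check.names = FALSE,
        stringsAsFactors = FALSE)
    names(df)[1L] <- rowlab
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE, na = ".")
}

#' Serialize a fit to a directory of TSVs
#'
#' Writes per-modality signature and sample-probability tables, the prior
#' mean/covariance, the ELBO trace, and a run-metadata text file (model,
#' seeds, tolerances, bound choice, restart selection).
#'
#' @param fit a [MmctmFit-class].
#' @param dir output directory (created if needed).
#' @export
writeFit <- function(fit, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (m in seq_along(fit@modalities)) {
        mod <- fit@modalities[m]
        sig <- fit@signatures[[m]]
        if (is.matrix(sig)) {
            write_matrix_tsv(sig, file.path(dir,
                paste0("signatures_", mod, ".tsv")), "signature")
        } else {
            for (f in names(sig)) {
                write_matrix_tsv(sig[[f]], file.path(dir,
                    paste0("signatures_", mod, "_", f, ".tsv")), "signature")
            }
        }
        write_matrix_tsv(fit@theta[[m]], file.path(dir,
            paste0("theta_", mod, ".tsv")), "sample")
    }
    utils::write.table(
        data.frame(signature = signature_names(fit@modalities, fit@K),
            mu = fit@mu),
        file.path(dir, "mu.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    write_matrix_tsv(fit@sigma, file.path(dir, "sigma.tsv"), "signature")
    utils::write.table(
        data.frame(iteration = seq_along(fit@elbo), elbo = fit@elbo),
        file.path(dir, "elbo.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    cfg <- fit@config
    meta <- c(
        paste0("model: ", fit@model),
        paste0("modalities: ", paste(fit@modalities, collapse = ",")),
        paste0("K: ", paste(fit@K, collapse = ",")),
        paste0("seed: ", cfg$seed),
        paste0("beta: ", cfg$beta),
        paste0("alpha: ", cfg$alpha),
        paste0("tol: ", cfg$tol),
        paste0("fixCovarianceIdentity: ", isTRUE(cfg$fixCovarianceIdentity)),
        paste0("bound: ", cfg$bound),
        paste0("converged: ", isTRUE(cfg$converged)),
        paste0("iterations: ", cfg$iterations),
        if (!is.null(cfg$restarts)) {
            paste0("selectedRestart: ", cfg$restarts$selected)
        },
        paste0("trainingLL: ", paste(signif(fit@trainingLL, 10),
            collapse = ",")))
    writeLines(meta, file.path(dir, "metadata.txt"))
    invisible(dir)
}
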