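## Feature encoding: raw SNV and SV calls -> categorical count matrices.
##
## SNVs use the pyrimidine-centric trinucleotide convention: every
## substitution is expressed with a C or T reference base (purine-reference
## calls are reverse complemented together with their flanks), giving
## 6 substitution types x 4 five-prime x 4 three-prime = 96 categories, or
## 6 + 4 + 4 = 14 feature values under the independent encoding.
##
## SVs are categorized by type, breakpoint homology bin (0-1, 2-5, >5 bp) and
## breakpoint distance bin (<10kbp, 10-100kbp, 100kbp-1Mbp, 1-10Mbp, >10Mbp);
## translocations carry no distance bin.

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' SNV substitution types
#'
#' The six pyrimidine-centric substitution types, in canonical order.
#' @return character vector of length 6.
#' @export
snvSubstitutionTypes <- function() {
    c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

#' Full-context SNV category labels
#'
#' The 96 trinucleotide categories "5'[ref>alt]3'", ordered by substitution
#' type, then 5' flank, then 3' flank (alphabetical).
#' @return character vector of length 96.
#' @examples
#' length(snvCategories())  # 96
#' @export
snvCategories <- function() {
    subs <- snvSubstitutionTypes()
    unlist(lapply(subs, function(s) {
        unlist(lapply(BASES, function(p5) paste0(p5, "[", s, "]", BASES)))
    }))
}

#' Independent SNV feature levels
#'
#' Category labels of the three independent SNV features: substitution type
#' (6 values), 5' flanking base (4) and 3' flanking base (4); 14 feature
#' values in total.
#' @return named list of character vectors.
#' @export
snvFeatureLevels <- function() {
    list(
        substitution = snvSubstitutionTypes(),
        five_prime = BASES,
        three_prime = BASES
    )
}

SV_TYPES <- c("DEL", "DUP", "INV", "FBI", "TR")
SV_HOM_BINS <- c("0-1", "2-5", ">5")
SV_DIST_BINS <- c("<10kbp", "10-100kbp", "100kbp-1Mbp", "1-10Mbp", ">10Mbp")

#' SV category labels
#'
#' Labels "TYPE:HOM:DIST" for deletions (DEL), tandem duplications (DUP),
#' inversions (INV) and optionally foldback inversions (FBI), plus "TR:HOM"
#' for translocations (breakpoint distance is not defined across
#' chromosomes). 63 categories with foldback inversions, 48 without.
#'
#' @param includeFoldback include the FBI type (default TRUE).
#' @return character vector of category labels.
#' @examples
#' length(svCategories())       # 63
#' length(svCategories(FALSE))  # 48
#' @export
svCategories <- function(includeFoldback = TRUE) {
    types <- if (includeFoldback) SV_TYPES else setdiff(SV_TYPES, "FBI")
    unlist(lapply(types, function(tp) {
        if (tp == "TR") {
            paste0("TR:", SV_HOM_BINS)
        } else {
            unlist(lapply(SV_HOM_BINS, function(h) {
                paste0(tp, ":", h, ":", SV_DIST_BINS)
            }))
        }
    }))
}

revcomp <- function(x) {
    vapply(strsplit(x, ""), function(b) {
        paste(rev(unname(COMP[b])), collapse = "")
    }, "")
}

## extract uppercase trinucleotide contexts [pos-1, pos+1]; genome is a
## DNAStringSet (names = chromosomes), an Rsamtools::FaFile, or a FASTA path
snv_contexts <- function(genome, chrom, pos) {
    if (is.character(genome)) {
        fai <- paste0(genome, ".fai")
        if (!file.exists(genome)) {
            stop("reference FASTA not found: ", genome)
        }
        if (!file.exists(fai)) {
            stop("FASTA index not found: ", fai,
                " (create it with Rsamtools::indexFa or samtools faidx)")
        }
        genome <- Rsamtools::FaFile(genome)
    }
    if (is(genome, "FaFile")) {
        info <- Rsamtools::scanFaIndex(genome)
        lens <- stats::setNames(BiocGenerics::width(info),
            as.character(GenomicRanges::seqnames(info)))
    } else if (is(genome, "DNAStringSet")) {
        lens <- stats::setNames(Biostrings::width(genome), names(genome))
    } else {
        stop("genome must be a DNAStringSet, FaFile or FASTA path")
    }
    bad <- !(chrom %in% names(lens))
    if (any(bad)) {
        stop("chromosome(s) absent from reference: ",
            paste(unique(chrom[bad]), collapse = ", "))
    }
    out <- !(pos - 1 >= 1 & pos + 1 <= lens[chrom])
    if (any(out)) {
        i <- which(out)[1L]
        stop("SNV context out of reference bounds at ", chrom[i], ":", pos[i])
    }
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = pos - 1, end = pos + 1))
    if (is(genome, "FaFile")) {
        ctx <- as.character(Biostrings::getSeq(genome, gr))
    } else {
        ctx <- vapply(seq_along(chrom), function(i) {
            as.character(Biostrings::subseq(genome[[chrom[i]]],
                start = pos[i] - 1, width = 3))
        }, "")
    }
    toupper(ctx)
}

## core per-call encoder; returns data.frame(substitution, five_prime,
## three_prime, label, skip_reason)
encode_snv_core <- function(chrom, pos, ref, alt, genome, sample = NULL) {
    n <- length(pos)
    ref <- toupper(ref)
    alt <- toupper(alt)
    skip <- rep(NA_character_, n)
    not_snv <- nchar(ref) != 1L | nchar(alt) != 1L |
        !(ref %in% BASES) | !(alt %in% BASES) | ref == alt
    skip[not_snv] <- "not_single_base_substitution"
    ok <- !not_snv
    sub_out <- p5_out <- p3_out <- rep(NA_character_, n)
    if (any(ok)) {
        ctx <- snv_contexts(genome, chrom[ok], pos[ok])
        ctx_ref <- substr(ctx, 2, 2)
        mism <- ctx_ref != ref[ok]
        if (any(mism)) {
            i <- which(ok)[which(mism)[1L]]
            who <- if (!is.null(sample)) paste0(" (sample ", sample[i], ")")
                else ""
            stop("reference base mismatch at ", chrom[i], ":", pos[i], who,
                ": expected ", ref[i], ", reference has ",
                ctx_ref[which(mism)[1L]])
        }
        flank_bad <- !(substr(ctx, 1, 1) %in% BASES) |
            !(substr(ctx, 3, 3) %in% BASES)
        skip[which(ok)[flank_bad]] <- "non_ACGT_flank"
        use <- which(ok)[!flank_bad]
        if (length(use)) {
            tri <- ctx[!flank_bad]
            a <- alt[use]
            r <- ref[use]
            pur <- r %in% c("A", "G")
            if (any(pur)) {
                tri[pur] <- revcomp(tri[pur])
                a[pur] <- unname(COMP[a[pur]])
                r[pur] <- unname(COMP[r[pur]])
            }
            sub_out[use] <- paste0(r, ">", a)
            p5_out[use] <- substr(tri, 1, 1)
            p3_out[use] <- substr(tri, 3, 3)
        }
    }
    label <- ifelse(is.na(sub_out), NA_character_,
        paste0(p5_out, "[", sub_out, "]", p3_out))
    data.frame(substitution = sub_out, five_prime = p5_out,
        three_prime = p3_out, label = label, skip_reason = skip,
        stringsAsFactors = FALSE)
}

#' Encode SNVs into trinucleotide-context categories
#'
#' Maps single-base substitutions to one of the 96 pyrimidine-centric
#' categories "5'[ref>alt]3'". Calls with a purine reference base are reverse
#' complemented together with both flanks, so the reported 5' flank of such a
#' call is the complement of its 3' reference neighbour. Vectorized over
#' calls.
#'
#' A reference-base mismatch is an error (reported with position and sample
#' context); indels, multi-allelic records and calls whose flanks contain
#' non-ACGT characters are skipped (returned as NA, reasons in the
#' `"skipped"` attribute).
#'
#' @param chrom,pos,ref,alt call fields; `pos` is the 1-based reference
#'   position, `ref`/`alt` single bases.
#' @param genome reference genome: a named [Biostrings::DNAStringSet], an
#'   [Rsamtools::FaFile], or a path to an indexed FASTA.
#' @param sample optional sample IDs used in error messages.
#' @return character vector of category labels (NA where skipped), with a
#'   `"skipped"` attribute (data.frame of index + reason).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
#' encodeSnvContext("chr1", 2, "C", "T", g)  # "A[C>T]G"
#' @export
encodeSnvContext <- function(chrom, pos, ref, alt, genome, sample = NULL) {
    enc <- encode_snv_core(chrom, pos, ref, alt, genome, sample)
    out <- enc$label
    sk <- which(!is.na(enc$skip_reason))
    attr(out, "skipped") <- data.frame(index = sk,
        reason = enc$skip_reason[sk], stringsAsFactors = FALSE)
    out
}

#' Encode SNVs into independent feature values
#'
#' Decomposes each substitution into three independent features after
#' pyrimidine-centric normalization: substitution type (6 values), 5'
#' flanking base (4) and 3' flanking base (4). The full-context label and
#' this tuple are mutually convertible.
#'
#' @inheritParams encodeSnvContext
#' @return data.frame with columns substitution, five_prime, three_prime
#'   (NA rows where skipped), with a `"skipped"` attribute.
#' @export
encodeSnvIndependent <- function(chrom, pos, ref, alt, genome, sample = NULL) {
    enc <- encode_snv_core(chrom, pos, ref, alt, genome, sample)
    out <- enc[, c("substitution", "five_prime", "three_prime")]
    sk <- which(!is.na(enc$skip_reason))
    attr(out, "skipped") <- data.frame(index = sk,
        reason = enc$skip_reason[sk], stringsAsFactors = FALSE)
    out
}

normalize_sv_type <- function(type) {
    key <- gsub("[ _-]", "", tolower(type))
    map <- c(deletion = "DEL", del = "DEL",
        tandemduplication = "DUP", duplication = "DUP", dup = "DUP",
        inversion = "INV", inv = "INV",
        foldbackinversion = "FBI", foldback = "FBI", fbi = "FBI",
        translocation = "TR", tr = "TR", tra = "TR")
    out <- unname(map[key])
    if (anyNA(out)) {
        stop("unknown SV type(s): ",
            paste(unique(type[is.na(out)]), collapse = ", "))
    }
    out
}

sv_hom_bin <- function(homology) {
    if (any(homology < 0)) stop("breakpoint homology must be >= 0")
    SV_HOM_BINS[findInterval(homology, c(0, 2, 6))]
}

sv_dist_bin <- function(dist) {
    SV_DIST_BINS[findInterval(dist, c(0, 1e4, 1e5, 1e6, 1e7))]
}

#' Encode structural variants into rearrangement categories
#'
#' Returns "TYPE:HOM:DIST" labels with breakpoint distance |pos2 - pos1|,
#' except translocations which are encoded "TR:HOM". Homology bins are
#' 0-1 = \{0,1\}, 2-5 = \{2..5\}, >5 = 6 bp and more; distance bins are the
#' half-open intervals [0,10kbp), [10kbp,100kbp), [100kbp,1Mbp), [1Mbp,10Mbp),
#' [10Mbp, Inf). Homology lengths are taken from the input, never recomputed
#' from sequence. Vectorized over calls.
#'
#' @param type SV type: deletion, tandem_duplication, inversion,
#'   foldback_inversion or translocation (abbreviations DEL/DUP/INV/FBI/TR
#'   accepted, case-insensitive).
#' @param homology non-negative breakpoint homology length in bp.
#' @param chrom1,pos1,chrom2,pos2 breakpoint coordinates (1-based). A
#'   non-translocation with chrom1 != chrom2 is an error.
#' @return character vector of category labels.
#' @examples
#' encodeSv("deletion", 3, "chr1", 1000, "chr1", 51000)  # "DEL:2-5:10-100kbp"
#' encodeSv("translocation", 0, "chr1", 1, "chr2", 1)    # "TR:0-1"
#' @export
encodeSv <- function(type, homology, chrom1, pos1, chrom2, pos2) {
    tp <- normalize_sv_type(type)
    bad <- tp != "TR" & chrom1 != chrom2
    if (any(bad)) {
        i <- which(bad)[1L]
        stop("non-translocation SV with breakpoints on different ",
            "chromosomes at record ", i, " (", chrom1[i], " vs ", chrom2[i],
            ")")
    }
    hb <- sv_hom_bin(homology)
    out <- character(length(tp))
    tr <- tp == "TR"
    out[tr] <- paste0("TR:", hb[tr])
    if (any(!tr)) {
        db <- sv_dist_bin(abs(pos2[!tr] - pos1[!tr]))
        out[!tr] <- paste0(tp[!tr], ":", hb[!tr], ":", db)
    }
    out
}

#' Tally encoded calls into a count matrix
#'
#' @param sample per-call sample IDs.
#' @param label per-call category labels; NA entries (skipped calls) are
#'   ignored.
#' @param categories full ordered category space (matrix columns).
#' @param samples optional sample universe/order; defaults to sorted unique
#'   sample IDs. Samples without calls yield all-zero rows.
#' @return sample-by-category numeric matrix of counts.
#' @export
buildCountMatrix <- function(sample, label, categories, samples = NULL) {
    keep <- !is.na(label)
    if (is.null(samples)) samples <- sort(unique(sample))
    unknown <- setdiff(unique(label[keep]), categories)
    if (length(unknown)) {
        stop("labels outside the category space: ",
            paste(unknown, collapse = ", "))
    }
    if (!all(sample[keep] %in% samples)) {
        stop("calls from samples outside the given sample universe")
    }
    m <- matrix(0, length(samples), length(categories),
        dimnames = list(samples, categories))
    if (any(keep)) {
        tab <- table(factor(sample[keep], levels = samples),
            factor(label[keep], levels = categories))
        m[] <- as.numeric(tab)
    } else {
        warning("no encodable calls; returning an all-zero count matrix")
    }
    m
}

encoding_report <- function(sample, skipped_idx, samples) {
    enc <- table(factor(sample[setdiff(seq_along(sample), skipped_idx)],
        levels = samples))
    skp <- table(factor(sample[skipped_idx], levels = samples))
    data.frame(sample = samples, encoded = as.integer(enc),
        skipped = as.integer(skp), stringsAsFactors = FALSE)
}

#' Build an SNV MutationCatalog from calls
#'
#' Encodes single-base substitutions (full trinucleotide or independent
#' feature encoding) and tallies them per sample. Skipped calls (indels,
#' multi-allelic alts, non-ACGT flanks) are logged in the catalog's
#' `"report"` attribute; zero-count samples are retained and flagged with a
#' warning.
#'
#' @param calls data.frame with columns sample, chrom, pos, ref, alt.
#' @param genome reference genome (see [encodeSnvContext()]).
#' @param encoding "full" (96 categories) or "independent" (3 features,
#'   14 values).
#' @param samples optional sample universe/order.
#' @return a [MutationCatalog-class] with attributes `"report"` (per-sample
#'   encoded/skipped counts) and `"skipped"`.
#' @export
buildSnvCatalog <- function(calls, genome, encoding = c("full", "independent"),
        samples = NULL) {
    encoding <- match.arg(encoding)
    if (is.null(samples)) samples <- sort(unique(as.character(calls$sample)))
    if (nrow(calls) == 0L) {
        warning("empty call list; returning an all-zero catalog")
        mats <- if (encoding == "full") {
            list(full = matrix(0, length(samples), 96,
                dimnames = list(samples, snvCategories())))
        } else {
            lapply(snvFeatureLevels(), function(lv) {
                matrix(0, length(samples), length(lv),
                    dimnames = list(samples, lv))
            })
        }
        return(MutationCatalog(mats, modality = "SNV", encoding = encoding))
    }
    enc <- encode_snv_core(as.character(calls$chrom), calls$pos,
        as.character(calls$ref), as.character(calls$alt), genome,
        sample = as.character(calls$sample))
    sk <- which(!is.na(enc$skip_reason))
    sm <- as.character(calls$sample)
    if (encoding == "full") {
        mats <- list(full = buildCountMatrix(sm, enc$label, snvCategories(),
            samples))
    } else {
        lv <- snvFeatureLevels()
        mats <- list(
            substitution = buildCountMatrix(sm, enc$substitution,
                lv$substitution, samples),
            five_prime = buildCountMatrix(sm, enc$five_prime, lv$five_prime,
                samples),
            three_prime = buildCountMatrix(sm, enc$three_prime,
                lv$three_prime, samples)
        )
    }
    obj <- MutationCatalog(mats, modality = "SNV", encoding = encoding)
    zero <- samples[rowSums(mats[[1L]]) == 0]
    if (length(zero)) {
        warning("samples with zero encoded SNVs: ",
            paste(zero, collapse = ", "))
    }
    attr(obj, "report") <- encoding_report(sm, sk, samples)
    attr(obj, "skipped") <- data.frame(index = sk, reason = enc$skip_reason[sk],
        sample = sm[sk], stringsAsFactors = FALSE)
    obj
}

#' Build an SV MutationCatalog from calls
#'
#' @param calls data.frame with columns sample, chrom1, pos1, chrom2, pos2,
#'   type, homology.
#' @param includeFoldback include the foldback-inversion (FBI) type in the
#'   category space (63 categories; 48 without).
#' @param samples optional sample universe/order.
#' @return a [MutationCatalog-class] with a `"report"` attribute.
#' @export
buildSvCatalog <- function(calls, includeFoldback = TRUE, samples = NULL) {
    if (is.null(samples)) samples <- sort(unique(as.character(calls$sample)))
    space <- svCategories(includeFoldback)
    if (nrow(calls) == 0L) {
        warning("empty call list; returning an all-zero catalog")
        m <- matrix(0, length(samples), length(space),
            dimnames = list(samples, space))
        return(MutationCatalog(m, modality = "SV"))
    }
    lab <- encodeSv(as.character(calls$type), calls$homology,
        as.character(calls$chrom1), calls$pos1,
        as.character(calls$chrom2), calls$pos2)
    sm <- as.character(calls$sample)
    m <- buildCountMatrix(sm, lab, space, samples)
    obj <- MutationCatalog(m, modality = "SV")
    zero <- samples[rowSums(m) == 0]
    if (length(zero)) {
        warning("samples with zero SVs: ", paste(zero, collapse = ", "))
    }
    attr(obj, "report") <- encoding_report(sm, integer(0), samples)
    obj
}

#' Convert independent SNV signatures to the 96-category space
#'
#' Under the independent encoding a signature's probability of a full
#' mutation category is the product of its per-feature probabilities; the
#' resulting distribution over the 96 trinucleotide categories sums to 1.
#'
#' @param sigList named list of per-feature K x V signature matrices with
#'   elements substitution, five_prime, three_prime.
#' @return K x 96 matrix over [snvCategories()].
#' @export
productSignatures <- function(sigList) {
    stopifnot(all(c("substitution", "five_prime", "three_prime") %in%
        names(sigList)))
    cats <- snvCategories()
    p5 <- substr(cats, 1, 1)
    sub <- substr(cats, 3, 5)
    p3 <- substr(cats, 7, 7)
    K <- nrow(sigList$substitution)
    out <- matrix(NA_real_, K, length(cats),
        dimnames = list(rownames(sigList$substitution), cats))
    for (k in seq_len(K)) {
        out[k, ] <- sigList$substitution[k, sub] *
            sigList$five_prime[k, p5] * sigList$three_prime[k, p3]
    }
    out
}
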