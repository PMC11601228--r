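#' @import methods
NULL

#' GuideLibrary: an sgRNA library of targeting guides and non-targeting controls
#'
#' The universe of a pooled CRISPRi screen: one record per sgRNA, holding the
#' guide identifier, the targeted gene symbol (or the sentinel `"NTC"` for
#' non-targeting controls), and the 19-21 nt protospacer sequence that serves
#' as the countable barcode in sequencing data.
#'
#' Validity requires unique guide identifiers, unique protospacers, uppercase
#' A/C/G/T protospacers of length 19-21, consistency between the NTC flag and
#' the gene label, and at least two NTC guides (the empirical-FDR machinery
#' needs NTC pairs to build pseudogenes).
#'
#' @slot guides data.frame with columns `guide_id`, `gene`, `protospacer`,
#'   `is_ntc`, one row per sgRNA, in library order.
#'
#' @seealso [readGuideLibrary()], [simulateGuideLibrary()],
#'   [validateGuideLibrary()]
#' @export
setClass("GuideLibrary", representation(guides = "data.frame"))

.guideViolations <- function(guides) {
    v <- character(0)
    need <- c("guide_id", "gene", "protospacer", "is_ntc")
    miss <- setdiff(need, names(guides))
    if (length(miss) > 0) {
        return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
    }
    if (nrow(guides) == 0) {
        return("library is empty")
    }
    dup <- unique(guides$guide_id[duplicated(guides$guide_id)])
    if (length(dup) > 0) {
        v <- c(v, sprintf("duplicate guide_id: %s", paste(dup, collapse = ", ")))
    }
    dup <- unique(guides$protospacer[duplicated(guides$protospacer)])
    if (length(dup) > 0) {
        v <- c(v, sprintf("duplicate protospacer: %s", paste(dup, collapse = ", ")))
    }
    bad <- guides$guide_id[grepl("[^ACGT]", guides$protospacer)]
    if (length(bad) > 0) {
        v <- c(v, sprintf("non-ACGT protospacer for guide(s): %s",
                          paste(bad, collapse = ", ")))
    }
    len <- nchar(guides$protospacer)
    bad <- guides$guide_id[len < 19L | len > 21L]
    if (length(bad) > 0) {
        v <- c(v, sprintf("protospacer length outside 19-21 nt for guide(s): %s",
                          paste(bad, collapse = ", ")))
    }
    inc <- guides$is_ntc != (toupper(guides$gene) == "NTC")
    if (any(inc)) {
        v <- c(v, sprintf("is_ntc inconsistent with gene label for guide(s): %s",
                          paste(guides$guide_id[inc], collapse = ", ")))
    }
    if (sum(guides$is_ntc) < 2L) {
        v <- c(v, sprintf("insufficient NTC guides: %d found, >= 2 required",
                          sum(guides$is_ntc)))
    }
    v
}

setValidity("GuideLibrary", function(object) {
    v <- .guideViolations(object@guides)
    if (length(v) == 0) TRUE else v
})

#' Construct a GuideLibrary from guide records
#'
#' @param guide_id character vector of unique guide labels.
#' @param gene character vector of gene symbols; non-targeting controls carry
#'   the literal gene `"NTC"`.
#' @param protospacer character vector of protospacer sequences; lower or
#'   mixed case is normalised to uppercase before validation.
#' @param is_ntc optional logical; inferred from `gene == "NTC"` when missing.
#'
#' @return A validated [GuideLibrary-class] object.
#' @examples
#' lib <- GuideLibrary(
#'     guide_id = c("ADNP_1", "ADNP_2", "NTC_1", "NTC_2"),
#'     gene = c("ADNP", "ADNP", "NTC", "NTC"),
#'     protospacer = c("GGTGGGAGAGGCGGCTTCAC", "GCGTCGAGCGGTGCAGACAA",
#'                     "GGATCGCGTCTAGTGCAGAT", "GGGGTGAGGGTCCAATTCGG"))
#' nGenes(lib)
#' @export
GuideLibrary <- function(guide_id, gene, protospacer, is_ntc = NULL) {
    protospacer <- toupper(as.character(protospacer))
    gene <- as.character(gene)
    if (is.null(is_ntc)) is_ntc <- toupper(gene) == "NTC"
    guides <- data.frame(guide_id = as.character(guide_id), gene = gene,
                         protospacer = protospacer, is_ntc = as.logical(is_ntc),
                         stringsAsFactors = FALSE)
    new("GuideLibrary", guides = guides)
}

#' List invariant violations of a guide library without throwing
#'
#' Checks the same invariants as the class validity method but returns the
#' violations as a character vector (empty when the library is valid), so a
#' caller can report all problems at once.
#'
#' @param lib a [GuideLibrary-class], or a bare data.frame of guide records.
#' @return character vector of human-readable violation descriptions.
#' @export
validateGuideLibrary <- function(lib) {
    guides <- if (is(lib, "GuideLibrary")) lib@guides else as.data.frame(lib)
    .guideViolations(guides)
}

#' @describeIn GuideLibrary-class number of guides
#' @param x,object a GuideLibrary
#' @export
setMethod("length", "GuideLibrary", function(x) nrow(x@guides))

#' Accessors for GuideLibrary components
#'
#' `guideIds`, `targetGenes`, `protospacers` and `isNTC` return the per-guide
#' columns in library order; `nGenes`, `nNTC` and `guidesPerGene` summarise
#' the library composition (`guidesPerGene` is the modal number of guides per
#' targeting gene).
#'
#' @param lib a [GuideLibrary-class] object.
#' @return vectors parallel to the guides, or scalar summaries.
#' @name guide-accessors
NULL

#' @rdname guide-accessors
#' @export
guideIds <- function(lib) lib@guides$guide_id

#' @rdname guide-accessors
#' @export
targetGenes <- function(lib) lib@guides$gene

#' @rdname guide-accessors
#' @export
protospacers <- function(lib) {
    stats::setNames(lib@guides$protospacer, lib@guides$guide_id)
}

#' @rdname guide-accessors
#' @export
isNTC <- function(lib) stats::setNames(lib@guides$is_ntc, lib@guides$guide_id)

#' @rdname guide-accessors
#' @export
nGenes <- function(lib) length(unique(lib@guides$gene[!lib@guides$is_ntc]))

#' @rdname guide-accessors
#' @export
nNTC <- function(lib) sum(lib@guides$is_ntc)

#' @rdname guide-accessors
#' @export
guidesPerGene <- function(lib) {
    tg <- lib@guides$gene[!lib@guides$is_ntc]
    if (length(tg) == 0) return(0L)
    tab <- table(table(tg))
    as.integer(names(tab)[which.max(tab)])
}

setMethod("show", "GuideLibrary", function(object) {
    cat(sprintf("GuideLibrary: %d guides (%d genes, modal %d guides/gene, %d NTCs)\n",
                length(object), nGenes(object), guidesPerGene(object),
                nNTC(object)))
    cat(sprintf("  protospacer length: %s nt\n",
                paste(sort(unique(nchar(object@guides$protospacer))),
                      collapse = "/")))
})

#' Read an sgRNA library from CSV
#'
#' Expects a comma-separated file with a header row and columns `guide_id`,
#' `gene` and `protospacer`; an `is_ntc` column is optional and is otherwise
#' inferred from the gene label or the guide id. Protospacers are upper-cased
#' on ingest; the returned object has passed full validation.
#'
#' @param path path to the CSV file.
#' @param ntc_pattern regular expression applied (case-insensitively) to the
#'   gene label and guide id to flag non-targeting controls when no `is_ntc`
#'   column is present. The default matches the conventional "NTC" labels.
#' @return A [GuideLibrary-class].
#' @export
readGuideLibrary <- function(path, ntc_pattern = "^NTC") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("guide_id", "gene", "protospacer")
    miss <- setdiff(need, names(tab))
    if (length(miss) > 0) {
        stop(sprintf("library CSV '%s' lacks required column(s): %s",
                     path, paste(miss, collapse = ", ")))
    }
    is_ntc <- if ("is_ntc" %in% names(tab)) {
        as.logical(tab$is_ntc)
    } else {
        grepl(ntc_pattern, tab$gene, ignore.case = TRUE) |
            grepl(ntc_pattern, tab$guide_id, ignore.case = TRUE)
    }
    gene <- ifelse(is_ntc, "NTC", tab$gene)
    lib <- GuideLibrary(tab$guide_id, gene, tab$protospacer, is_ntc)
    lib
}

#' Write an sgRNA library to CSV
#'
#' @param lib a [GuideLibrary-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeGuideLibrary <- function(lib, path) {
    stopifnot(is(lib, "GuideLibrary"))
    utils::write.csv(lib@guides, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Export library protospacers as FASTA
#'
#' Record ids are guide ids; sequences are the protospacers.
#'
#' @param lib a [GuideLibrary-class].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @importFrom Biostrings DNAStringSet writeXStringSet
#' @export
writeGuideFasta <- function(lib, path) {
    stopifnot(is(lib, "GuideLibrary"))
    seqs <- Biostrings::DNAStringSet(protospacers(lib))
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}

#' Generate a synthetic sgRNA library
#'
#' Draws distinct random protospacers for `n_genes` targeting genes (labelled
#' `G0001`, `G0002`, ...) with `guides_per_gene` guides each, plus `n_ntc`
#' non-targeting controls, mirroring the composition of a compact
#' arrayed-oligo CRISPRi library (the default emulates 102 genes x 2 guides
#' + 28 NTCs).
#'
#' @param n_genes number of targeting genes (>= 1).
#' @param guides_per_gene guides per targeting gene (>= 1).
#' @param n_ntc number of non-targeting controls (>= 2).
#' @param protospacer_length protospacer length in nt (>= 10; default 20).
#' @param seed integer seed; output is fully deterministic given the seed.
#' @return A [GuideLibrary-class].
#' @export
simulateGuideLibrary <- function(n_genes = 102L, guides_per_gene = 2L,
                                 n_ntc = 28L, protospacer_length = 20L,
                                 seed = 1L) {
    stopifnot(n_genes >= 1, guides_per_gene >= 1, n_ntc >= 1,
              protospacer_length >= 10)
    n_total <- n_genes * guides_per_gene + n_ntc
    if (n_total > 4^protospacer_length) {
        stop(sprintf(
            "cannot draw %d distinct protospacers of length %d (4^%d = %g)",
            n_total, protospacer_length, protospacer_length,
            4^protospacer_length))
    }
    set.seed(seed)
    seqs <- character(0)
    while (length(seqs) < n_total) {
        draw <- vapply(seq_len(n_total - length(seqs)), function(i) {
            paste(sample(c("A", "C", "G", "T"), protospacer_length,
                         replace = TRUE), collapse = "")
        }, character(1))
        seqs <- unique(c(seqs, draw))
    }
    gene <- c(rep(sprintf("G%04d", seq_len(n_genes)), each = guides_per_gene),
              rep("NTC", n_ntc))
    idx <- c(rep(seq_len(guides_per_gene), times = n_genes), seq_len(n_ntc))
    guide_id <- paste(gene, idx, sep = "_")
    GuideLibrary(guide_id, gene, seqs, gene == "NTC")
}
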