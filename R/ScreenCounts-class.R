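#' ScreenCounts: guide x sample read counts from a sorted screen
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' the `counts` assay (non-negative integers, guides as rows, sorted-bin
#' samples as columns), per-guide gene annotation in `rowData`
#' (`gene`, `is_ntc`) and per-sample metadata in `colData` (`replicate`,
#' `bin` in `{low, high}`, and `unassigned`: reads that matched no library
#' protospacer, so that assigned + unassigned equals the reads processed for
#' the sample).
#'
#' @seealso [countReads()], [simulateScreen()], [normalizeCounts()]
#' @import SummarizedExperiment
#' @export
setClass("ScreenCounts", contains = "SummarizedExperiment")

setValidity("ScreenCounts", function(object) {
    v <- character(0)
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        v <- c(v, "assay 'counts' is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        if (any(m < 0)) v <- c(v, "counts must be non-negative")
    }
    cd <- SummarizedExperiment::colData(object)
    for (col in c("replicate", "bin", "unassigned"))
        if (!(col %in% names(cd))) v <- c(v, sprintf("colData$%s is required", col))
    if ("bin" %in% names(cd) && !all(cd$bin %in% c("low", "high")))
        v <- c(v, "colData$bin must be 'low' or 'high'")
    rd <- SummarizedExperiment::rowData(object)
    for (col in c("gene", "is_ntc"))
        if (!(col %in% names(rd))) v <- c(v, sprintf("rowData$%s is required", col))
    if (length(v) == 0) TRUE else v
})

#' Construct a ScreenCounts object
#'
#' @param counts integer matrix, guides x samples, with dimnames.
#' @param library a [GuideLibrary-class] covering the rows (used to annotate
#'   genes and NTC status).
#' @param replicate integer vector, replicate index per sample.
#' @param bin character vector per sample, `"low"` or `"high"`.
#' @param unassigned integer vector per sample of unmatched reads (default 0,
#'   appropriate for simulated counts).
#' @return A [ScreenCounts-class].
#' @importFrom S4Vectors DataFrame
#' @export
ScreenCounts <- function(counts, library, replicate, bin,
                         unassigned = rep(0L, ncol(counts))) {
    stopifnot(is(library, "GuideLibrary"),
              !is.null(rownames(counts)), !is.null(colnames(counts)))
    gene_of <- stats::setNames(targetGenes(library), guideIds(library))
    ntc_of <- isNTC(library)
    if (anyNA(gene_of[rownames(counts)]))
        stop("counts rows contain guides absent from the library")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(gene = unname(gene_of[rownames(counts)]),
                                       is_ntc = unname(ntc_of[rownames(counts)])),
        colData = S4Vectors::DataFrame(replicate = replicate, bin = bin,
                                       unassigned = as.integer(unassigned),
                                       row.names = colnames(counts)))
    new("ScreenCounts", se)
}

#' Accessors for ScreenCounts
#'
#' `screenCountsMatrix` returns the raw counts assay; `unassignedReads` the
#' per-sample tally of reads matching no library protospacer;
#' `replicatePairs` the low/high sample pairing per replicate used for
#' enrichment statistics.
#'
#' @param x a [ScreenCounts-class].
#' @return matrix / named integer vector / data.frame respectively.
#' @name screencounts-accessors
NULL

#' @rdname screencounts-accessors
#' @export
screenCountsMatrix <- function(x) SummarizedExperiment::assay(x, "counts")

#' @rdname screencounts-accessors
#' @export
unassignedReads <- function(x) {
    stats::setNames(SummarizedExperiment::colData(x)$unassigned, colnames(x))
}

#' @rdname screencounts-accessors
#' @export
replicatePairs <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    reps <- sort(unique(cd$replicate))
    out <- data.frame(replicate = reps, low = NA_character_,
                      high = NA_character_)
    for (i in seq_along(reps)) {
        lo <- rownames(cd)[cd$replicate == reps[i] & cd$bin == "low"]
        hi <- rownames(cd)[cd$replicate == reps[i] & cd$bin == "high"]
        if (length(lo) != 1 || length(hi) != 1)
            stop(sprintf("replicate %s lacks a unique low/high sample pair",
                         reps[i]))
        out$low[i] <- lo
        out$high[i] <- hi
    }
    out
}

setMethod("show", "ScreenCounts", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat(sprintf("ScreenCounts: %d guides x %d samples (%d replicate(s))\n",
                nrow(object), ncol(object), length(unique(cd$replicate))))
    cat(sprintf("  depth: %s reads/sample; unassigned: %s\n",
                paste(format(colSums(screenCountsMatrix(object)), trim = TRUE),
                      collapse = "/"),
                paste(cd$unassigned, collapse = "/")))
})

#' Write / read a guide x sample count table as TSV
#'
#' The TSV has a `guide_id` column followed by one column per sample; the
#' per-sample unassigned-read tallies are stored as a trailing `#unassigned`
#' comment row on write and recovered on read.
#'
#' @param x a [ScreenCounts-class].
#' @param path TSV path.
#' @param library a [GuideLibrary-class] (read path only).
#' @return `writeCountMatrix`: `path` invisibly; `readCountMatrix`: a
#'   [ScreenCounts-class].
#' @export
writeCountMatrix <- function(x, path) {
    m <- screenCountsMatrix(x)
    tab <- data.frame(guide_id = rownames(m), m, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    cat(paste(c("#unassigned", unassignedReads(x)), collapse = "\t"),
        "\n", sep = "", file = path, append = TRUE)
    invisible(path)
}

#' @rdname writeCountMatrix
#' @export
readCountMatrix <- function(path, library) {
    lines <- readLines(path)
    meta <- grep("^#unassigned", lines, value = TRUE)
    tab <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                             header = TRUE, check.names = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab$guide_id
    storage.mode(m) <- "integer"
    unass <- rep(0L, ncol(m))
    if (length(meta) == 1) {
        unass <- as.integer(strsplit(meta, "\t")[[1]][-1])
    }
    samp <- colnames(m)
    rep_id <- as.integer(sub("^rep(\\d+)_.*$", "\\1", samp))
    bin <- sub("^rep\\d+_", "", samp)
    ScreenCounts(m, library, replicate = rep_id, bin = bin, unassigned = unass)
}
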