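#' Match a single read to a library protospacer
#'
#' Extracts the candidate protospacer according to the read structure and
#' looks it up in the library. At `max_mismatch = 0` only exact matches
#' assign; at `max_mismatch = 1` a read assigns to the unique guide within
#' Hamming distance 1 (exact matches take precedence), and any tie between
#' two or more guides at the minimal distance leaves the read unassigned.
#' In `sliding` mode every offset is scanned 5' to 3' and the first offset
#' producing an assignment wins; an ambiguous best offset leaves the read
#' unassigned. Reads too short to contain a protospacer are unassigned, not
#' an error.
#'
#' @param read nucleotide string.
#' @param library a [GuideLibrary-class].
#' @param structure a [readStructure()].
#' @param max_mismatch 0 or 1.
#' @return The matching guide id, or `"unassigned"`.
#' @export
matchRead <- function(read, library, structure = readStructure(),
                      max_mismatch = 0L) {
    idx <- .protoIndex(library)
    .matchOne(toupper(read), idx, structure, max_mismatch)
}

# exact-lookup environment: protospacer -> guide_id
.protoIndex <- function(library) {
    proto <- protospacers(library)
    idx <- new.env(hash = TRUE, parent = emptyenv(), size = length(proto) * 2L)
    for (i in seq_along(proto)) assign(proto[[i]], names(proto)[i], envir = idx)
    idx
}

.lookupExact <- function(seqs, idx) {
    vapply(seqs, function(s) {
        hit <- mget(s, envir = idx, ifnotfound = list(NA_character_))[[1]]
        hit
    }, character(1), USE.NAMES = FALSE)
}

# all guides within Hamming distance 1 of seq; returns guide ids
.neighborHits <- function(seq, idx) {
    n <- nchar(seq)
    bases <- c("A", "C", "G", "T")
    hits <- character(0)
    chars <- strsplit(seq, "")[[1]]
    for (pos in seq_len(n)) {
        for (b in bases[bases != chars[pos]]) {
            cand <- chars
            cand[pos] <- b
            hit <- mget(paste(cand, collapse = ""), envir = idx,
                        ifnotfound = list(NA_character_))[[1]]
            if (!is.na(hit)) hits <- c(hits, hit)
        }
    }
    unique(hits)
}

.matchOne <- function(read, idx, structure, max_mismatch) {
    L <- structure$protospacer_length
    if (nchar(read) < L) return("unassigned")
    offs <- if (structure$search_mode == "anchored") {
        nchar(structure$five_prime_constant)
    } else {
        0:(nchar(read) - L)
    }
    for (off in offs) {
        if (off < 0 || nchar(read) < off + L) next
        cand <- substr(read, off + 1L, off + L)
        hit <- mget(cand, envir = idx, ifnotfound = list(NA_character_))[[1]]
        if (!is.na(hit)) return(hit)
        if (max_mismatch >= 1L) {
            hits <- .neighborHits(cand, idx)
            if (length(hits) == 1) return(hits)
            if (length(hits) > 1) return("unassigned")   # ambiguous offset
        }
    }
    "unassigned"
}

#' Count screen reads against a guide library
#'
#' Reads each sample's FASTQ (plain or gzipped), matches every read with the
#' [matchRead()] rules, and assembles the guide x sample [ScreenCounts-class]
#' with per-sample unassigned tallies, so assigned + unassigned always equals
#' the number of reads processed.
#'
#' @param fastq_paths named character vector, sample label -> FASTQ path.
#'   Sample labels are expected as `rep<i>_<low|high>`; other labels are
#'   accepted with `replicate`/`bin` passed explicitly.
#' @param library a [GuideLibrary-class].
#' @param structure a [readStructure()].
#' @param max_mismatch 0 or 1.
#' @param replicate,bin optional per-sample metadata overriding the label
#'   parsing.
#' @return A [ScreenCounts-class] with samples in input order.
#' @importFrom Biostrings readDNAStringSet
#' @export
countReads <- function(fastq_paths, library, structure = readStructure(),
                       max_mismatch = 0L, replicate = NULL, bin = NULL) {
    stopifnot(length(fastq_paths) >= 1)
    if (is.null(names(fastq_paths)))
        names(fastq_paths) <- sub("\\.f(ast)?q(\\.gz)?$", "",
                                  basename(fastq_paths))
    idx <- .protoIndex(library)
    ids <- guideIds(library)
    counts <- matrix(0L, nrow = length(ids), ncol = length(fastq_paths),
                     dimnames = list(ids, names(fastq_paths)))
    unassigned <- integer(length(fastq_paths))
    L <- structure$protospacer_length
    off <- nchar(structure$five_prime_constant)
    for (j in seq_along(fastq_paths)) {
        reads <- tryCatch(
            as.character(Biostrings::readDNAStringSet(fastq_paths[[j]],
                                                      format = "fastq")),
            error = function(e) stop(sprintf(
                "malformed FASTQ '%s': %s", fastq_paths[[j]],
                conditionMessage(e))))
        if (length(reads) == 0) next
        assigned <- rep(NA_character_, length(reads))
        if (structure$search_mode == "anchored") {
            # vectorised exact pass at the anchored offset
            ok <- nchar(reads) >= off + L
            cand <- substr(reads[ok], off + 1L, off + L)
            assigned[ok] <- .lookupExact(cand, idx)
        }
        todo <- which(is.na(assigned))
        if (length(todo) > 0 &&
            (max_mismatch >= 1L || structure$search_mode == "sliding")) {
            assigned[todo] <- vapply(reads[todo], function(r) {
                hit <- .matchOne(r, idx, structure, max_mismatch)
                if (hit == "unassigned") NA_character_ else hit
            }, character(1), USE.NAMES = FALSE)
        }
        tab <- table(factor(assigned[!is.na(assigned)], levels = ids))
        counts[, j] <- as.integer(tab)
        unassigned[j] <- sum(is.na(assigned))
    }
    samp <- names(fastq_paths)
    if (is.null(replicate)) {
        replicate <- suppressWarnings(
            as.integer(sub("^rep(\\d+)_.*$", "\\1", samp)))
        if (anyNA(replicate)) replicate <- seq_along(samp)
    }
    if (is.null(bin)) {
        bin <- ifelse(grepl("_high$", samp), "high",
                      ifelse(grepl("_low$", samp), "low", NA))
        if (anyNA(bin)) stop(
            "cannot infer low/high bin from sample labels; pass `bin`")
    }
    ScreenCounts(counts, library, replicate = replicate, bin = bin,
                 unassigned = unassigned)
}
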