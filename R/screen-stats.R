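#' Normalize screen counts to reads per million
#'
#' Adds the pseudocount to every entry before scaling each sample to 1e6, so
#' guides unobserved in one bin still yield finite log fold changes.
#'
#' @param counts a [ScreenCounts-class] or a guide x sample count matrix.
#' @param pseudocount added to every count before scaling (default 0.5).
#' @return Numeric matrix of reads-per-million values, same dimnames.
#' @export
normalizeCounts <- function(counts, pseudocount = 0.5) {
    m <- if (is(counts, "ScreenCounts")) screenCountsMatrix(counts) else counts
    if (any(colSums(m) == 0)) stop("sample with all-zero counts")
    m <- m + pseudocount
    sweep(m, 2, colSums(m), "/") * 1e6
}

#' Per-guide log2 fold changes between high and low sort bins
#'
#' For each replicate, `lfc_r = log2(RPM_high / RPM_low)`; `lfc_mean`
#' averages over replicates. Each guide also receives a robust z-score of
#' `lfc_mean` against the NTC guide distribution:
#' `z = (lfc_mean - median(NTC)) / (1.4826 * MAD(NTC))`.
#'
#' @param normalized RPM matrix from [normalizeCounts()].
#' @param pairs data.frame with columns `replicate`, `low`, `high` naming the
#'   sample columns of each replicate (see [replicatePairs()]).
#' @param library a [GuideLibrary-class] annotating the rows.
#' @return data.frame (one row per guide): `guide_id`, `gene`, `is_ntc`,
#'   `lfc_rep<i>`..., `lfc_mean`, `z`.
#' @export
guideLfc <- function(normalized, pairs, library) {
    miss <- setdiff(c(pairs$low, pairs$high), colnames(normalized))
    if (length(miss) > 0)
        stop(sprintf("missing high/low sample(s): %s",
                     paste(miss, collapse = ", ")))
    gene_of <- stats::setNames(targetGenes(library), guideIds(library))
    ntc_of <- isNTC(library)
    .guideLfcAnnotated(normalized, pairs, gene_of, ntc_of)
}

#' Gene-level two-sided Mann-Whitney test against NTC guides
#'
#' Compares a gene's guide-level mean log fold changes with the NTC guide
#' distribution. The p-value is exact (full rank enumeration) when the gene
#' has at most 3 guides, at most 40 NTCs are supplied and there are no ties;
#' otherwise the normal approximation with continuity and tie correction is
#' used. With the conventional 2-guides-vs-28-NTC design the most extreme
#' possible p is 2/choose(30, 2) = 2/435.
#'
#' @param gene_lfcs numeric, the gene's guide `lfc_mean` values.
#' @param ntc_lfcs numeric, NTC guide `lfc_mean` values.
#' @return Two-sided p-value in (0, 1].
#' @importFrom stats wilcox.test
#' @export
geneTest <- function(gene_lfcs, ntc_lfcs) {
    if (length(gene_lfcs) == 0 || length(ntc_lfcs) == 0)
        stop("empty input to geneTest")
    ties <- anyDuplicated(c(gene_lfcs, ntc_lfcs)) > 0
    exact <- length(gene_lfcs) <= 3 && length(ntc_lfcs) <= 40 && !ties
    p <- suppressWarnings(
        stats::wilcox.test(gene_lfcs, ntc_lfcs, alternative = "two.sided",
                           exact = exact, correct = TRUE)$p.value)
    min(p, 1)
}

#' Aggregate guide fold changes into a gene phenotype
#'
#' Computes the weighted geometric mean of the guides' fold changes: in log2
#' space, `phenotype_lfc = sum(w_i * lfc_i)` with weights summing to 1. In
#' `"zscore"` mode weights are proportional to `max(|z_i|, 0.25)` so that
#' consistent, NTC-atypical guides dominate while no guide is zeroed out;
#' `"equal"` mode gives the plain geometric mean.
#'
#' @param lfc_means numeric, guide-level mean log2 fold changes.
#' @param z numeric, guide robust z-scores (ignored in equal mode).
#' @param weight_mode `"zscore"` or `"equal"`.
#' @return list with `phenotype_lfc`, `phenotype_fc` (= 2^lfc) and `weights`.
#' @export
genePhenotype <- function(lfc_means, z = NULL,
                          weight_mode = c("zscore", "equal")) {
    weight_mode <- match.arg(weight_mode)
    stopifnot(length(lfc_means) >= 1)
    w <- if (weight_mode == "equal" || is.null(z) || all(is.na(z))) {
        rep(1, length(lfc_means))
    } else {
        pmax(abs(z), 0.25)
    }
    w <- w / sum(w)
    lfc <- sum(w * lfc_means)
    list(phenotype_lfc = lfc, phenotype_fc = 2^lfc, weights = w)
}

#' Build NTC pseudogenes for the empirical FDR
#'
#' Groups NTC guides into pseudo-genes of `group_size` guides. All
#' `choose(n_ntc, group_size)` combinations are enumerated when that count is
#' at most `max_enumerate` (28 NTCs in pairs give 378 pseudogenes); larger
#' spaces are sampled without replacement within each group under the seed.
#'
#' @param ntc_ids character, NTC guide ids.
#' @param group_size guides per pseudogene (usually the library's
#'   guides-per-gene).
#' @param seed integer seed for the sampling path.
#' @param max_enumerate enumeration cutoff (default 10000).
#' @param n_sampled number of groups drawn on the sampling path (default
#'   1000).
#' @return list of character vectors, one per pseudogene, named `pseudo_<i>`.
#' @export
makePseudogenes <- function(ntc_ids, group_size, seed = 1L,
                            max_enumerate = 10000L, n_sampled = 1000L) {
    n <- length(ntc_ids)
    if (group_size > n)
        stop(sprintf("group_size %d exceeds the %d available NTC guides",
                     group_size, n))
    total <- choose(n, group_size)
    groups <- if (total <= max_enumerate) {
        cmb <- utils::combn(ntc_ids, group_size)
        lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
    } else {
        set.seed(seed)
        lapply(seq_len(n_sampled), function(i) sample(ntc_ids, group_size))
    }
    names(groups) <- sprintf("pseudo_%d", seq_along(groups))
    groups
}

#' Empirical false discovery rate from pseudogene scores
#'
#' Decoy-based FDR: at a score threshold `t` in the positive tail, the raw
#' FDR is the pseudogene tail frequency divided by the gene tail frequency,
#' `[(#pseudo >= t)/N_pseudo] / [(#gene >= t)/N_gene]`, clipped to `[0, 1]`.
#' A gene's q-value is the minimum raw FDR over all thresholds that would
#' include it, making q monotone in score. The negative tail mirrors with
#' `<=` comparisons.
#'
#' @param gene_scores numeric scores of real genes.
#' @param pseudo_scores numeric scores of NTC pseudogenes, computed
#'   identically.
#' @param tail `"positive"` or `"negative"`.
#' @return numeric q-values parallel to `gene_scores`.
#' @export
empiricalFdr <- function(gene_scores, pseudo_scores,
                         tail = c("positive", "negative")) {
    tail <- match.arg(tail)
    if (length(pseudo_scores) == 0) stop("need at least one pseudogene score")
    s <- if (tail == "positive") gene_scores else -gene_scores
    ps <- if (tail == "positive") pseudo_scores else -pseudo_scores
    ng <- length(s)
    np <- length(ps)
    ord <- order(s, decreasing = TRUE)
    sorted <- s[ord]
    raw <- vapply(sorted, function(t) {
        gene_tail <- sum(s >= t) / ng
        pseudo_tail <- sum(ps >= t) / np
        min(1, pseudo_tail / gene_tail)
    }, numeric(1))
    # q at rank i = min raw FDR over this and all less extreme thresholds
    q_sorted <- rev(cummin(rev(raw)))
    q <- numeric(ng)
    q[ord] <- q_sorted
    q
}

#' Score a screen: gene phenotypes, tests, empirical FDR and hit calls
#'
#' Runs the full gene-level pipeline on a count matrix: RPM normalisation,
#' per-replicate guide log fold changes, gene aggregation by weighted
#' geometric mean, a two-sided Mann-Whitney test of each gene's guides
#' against the NTC guides, a signed significance score
#' `phenotype_lfc * (-log10 p)`, NTC-pseudogene empirical FDRs for each tail,
#' Benjamini-Hochberg adjusted p-values, and hit calls at `alpha`.
#'
#' @param counts a [ScreenCounts-class].
#' @param library optional [GuideLibrary-class]; defaults to the annotation
#'   already carried by `counts`.
#' @param alpha empirical-FDR hit threshold (default 0.01).
#' @param pseudocount RPM pseudocount (default 0.5).
#' @param weight_mode guide weighting for the phenotype, `"zscore"` or
#'   `"equal"`.
#' @param pooled if `TRUE`, counts are summed across replicates before a
#'   single LFC is computed (one pooled pseudo-replicate) instead of
#'   averaging per-replicate LFCs.
#' @param seed seed for pseudogene sampling (only used when the NTC
#'   combination space is too large to enumerate).
#' @return list with `genes` (data.frame: `gene`, `n_guides`,
#'   `phenotype_lfc`, `phenotype_fc`, `p_value`, `score`, `q_pos`, `q_neg`,
#'   `empirical_fdr`, `bh_q`, `hit_class`), `guides` (the [guideLfc()]
#'   table) and `pseudogenes` (pseudogene score table).
#' @export
scoreScreen <- function(counts, library = NULL, alpha = 0.01,
                        pseudocount = 0.5,
                        weight_mode = c("zscore", "equal"),
                        pooled = FALSE, seed = 1L) {
    weight_mode <- match.arg(weight_mode)
    stopifnot(is(counts, "ScreenCounts"))
    if (is.null(library)) {
        rd <- SummarizedExperiment::rowData(counts)
        lib_df <- data.frame(guide_id = rownames(counts), gene = rd$gene,
                             protospacer = strrep("A", 20), is_ntc = rd$is_ntc)
        gene_of <- stats::setNames(lib_df$gene, lib_df$guide_id)
        ntc_of <- stats::setNames(lib_df$is_ntc, lib_df$guide_id)
    } else {
        gene_of <- stats::setNames(targetGenes(library), guideIds(library))
        ntc_of <- isNTC(library)
    }
    pairs <- replicatePairs(counts)
    m <- screenCountsMatrix(counts)
    if (pooled) {
        low <- rowSums(m[, pairs$low, drop = FALSE])
        high <- rowSums(m[, pairs$high, drop = FALSE])
        m <- cbind(rep1_low = low, rep1_high = high)
        pairs <- data.frame(replicate = 1L, low = "rep1_low",
                            high = "rep1_high")
    }
    rpm <- normalizeCounts(m, pseudocount)
    guides <- .guideLfcAnnotated(rpm, pairs, gene_of, ntc_of)
    ntc_rows <- which(guides$is_ntc)
    n_ntc <- length(ntc_rows)
    genes <- unique(guides$gene[!guides$is_ntc])
    gidx <- split(which(!guides$is_ntc), guides$gene[!guides$is_ntc])[genes]
    gsize <- as.integer(round(stats::median(lengths(gidx))))
    # Exchangeable nulls: a pseudogene is never compared against its own
    # guides, and each real gene excludes a rotating (data-independent)
    # subset of the same size, so every scored unit faces an identically
    # sized NTC null with identical attainable p-values.
    scoreGroup <- function(idx, excl) {
        null_lfcs <- guides$lfc_mean[setdiff(ntc_rows, excl)]
        ph <- genePhenotype(guides$lfc_mean[idx], guides$z[idx], weight_mode)
        p <- geneTest(guides$lfc_mean[idx], null_lfcs)
        c(phenotype_lfc = ph$phenotype_lfc, p_value = p,
          score = ph$phenotype_lfc * (-log10(p)))
    }
    gstats <- t(vapply(seq_along(gidx), function(j) {
        drop <- ntc_rows[(((j - 1) * gsize + seq_len(gsize) - 1L) %% n_ntc) + 1L]
        scoreGroup(gidx[[j]], drop)
    }, numeric(3)))
    rownames(gstats) <- names(gidx)
    ntc_ids <- guides$guide_id[ntc_rows]
    pgroups <- makePseudogenes(ntc_ids, gsize, seed = seed)
    pidx <- lapply(pgroups, function(ids) match(ids, guides$guide_id))
    pstats <- t(vapply(pidx, function(idx) scoreGroup(idx, idx), numeric(3)))
    q_pos <- empiricalFdr(gstats[, "score"], pstats[, "score"], "positive")
    q_neg <- empiricalFdr(gstats[, "score"], pstats[, "score"], "negative")
    res <- data.frame(gene = genes, n_guides = lengths(gidx),
                      phenotype_lfc = gstats[, "phenotype_lfc"],
                      phenotype_fc = 2^gstats[, "phenotype_lfc"],
                      p_value = gstats[, "p_value"],
                      score = gstats[, "score"],
                      q_pos = q_pos, q_neg = q_neg,
                      bh_q = stats::p.adjust(gstats[, "p_value"], "BH"),
                      row.names = NULL)
    res$empirical_fdr <- ifelse(res$phenotype_lfc >= 0, res$q_pos, res$q_neg)
    res <- callHits(res, alpha)
    pseudo <- data.frame(pseudogene = names(pgroups),
                         phenotype_lfc = pstats[, "phenotype_lfc"],
                         p_value = pstats[, "p_value"],
                         score = pstats[, "score"], row.names = NULL)
    list(genes = res, guides = guides, pseudogenes = pseudo)
}

.guideLfcAnnotated <- function(rpm, pairs, gene_of, ntc_of) {
    lfcs <- sapply(seq_len(nrow(pairs)), function(i) {
        log2(rpm[, pairs$high[i]] / rpm[, pairs$low[i]])
    })
    lfcs <- matrix(lfcs, nrow = nrow(rpm),
                   dimnames = list(rownames(rpm),
                                   sprintf("lfc_rep%d", pairs$replicate)))
    out <- data.frame(guide_id = rownames(rpm),
                      gene = unname(gene_of[rownames(rpm)]),
                      is_ntc = unname(ntc_of[rownames(rpm)]),
                      lfcs, lfc_mean = rowMeans(lfcs), row.names = NULL)
    ntc_lfc <- out$lfc_mean[out$is_ntc]
    spread <- stats::mad(ntc_lfc)
    out$z <- if (isTRUE(spread > 0))
        (out$lfc_mean - stats::median(ntc_lfc)) / spread else NA_real_
    out
}

#' Classify genes as hits at an empirical-FDR threshold
#'
#' A gene is an `increase` hit when its phenotype log fold change is positive
#' and its positive-tail empirical q is below `alpha`; `decrease` mirrors in
#' the negative tail. The tails partition by phenotype sign, so no gene can
#' be called in both.
#'
#' @param results gene results data.frame with `phenotype_lfc`, `q_pos`,
#'   `q_neg`.
#' @param alpha threshold in (0, 1).
#' @return `results` with `hit_class` set to
#'   `"increase"`/`"decrease"`/`"none"`.
#' @export
callHits <- function(results, alpha = 0.01) {
    stopifnot(alpha > 0, alpha <= 1)
    up <- results$phenotype_lfc > 0 & results$q_pos < alpha
    dn <- results$phenotype_lfc < 0 & results$q_neg < alpha
    results$hit_class <- ifelse(up, "increase", ifelse(dn, "decrease", "none"))
    results
}

#' Compare gene phenotypes across screens
#'
#' Restricts to genes called a hit in at least one screen and returns their
#' phenotype log fold changes side by side with per-cell significance flags,
#' the cross-substrate comparison used to contrast bead, synaptosome and
#' synaptic-pruning screens.
#'
#' @param results named list of gene-result data.frames from [scoreScreen()]
#'   (the `$genes` element), sharing one gene universe.
#' @return list with `lfc` (gene x screen matrix) and `significant` (logical
#'   matrix of the same shape); zero rows when nothing is a hit anywhere.
#' @export
compareScreens <- function(results) {
    stopifnot(length(results) >= 2, !is.null(names(results)))
    sets <- lapply(results, function(r) sort(r$gene))
    for (i in seq_along(sets)[-1]) {
        if (!identical(sets[[1]], sets[[i]])) {
            diffs <- c(setdiff(sets[[1]], sets[[i]]),
                       setdiff(sets[[i]], sets[[1]]))
            stop(sprintf("gene sets differ between screens '%s' and '%s': %s",
                         names(results)[1], names(results)[i],
                         paste(diffs, collapse = ", ")))
        }
    }
    genes <- results[[1]]$gene
    lfc <- sapply(results, function(r) r$phenotype_lfc[match(genes, r$gene)])
    sig <- sapply(results, function(r)
        r$hit_class[match(genes, r$gene)] != "none")
    rownames(lfc) <- rownames(sig) <- genes
    keep <- rowSums(sig) > 0
    list(lfc = lfc[keep, , drop = FALSE],
         significant = sig[keep, , drop = FALSE])
}

#' Write gene-level screen results as TSV
#'
#' @param results the `$genes` data.frame from [scoreScreen()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeGeneResults <- function(results, path) {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Volcano plot of gene-level screen results
#'
#' Phenotype log2 fold change against -log10 Mann-Whitney p, with hits
#' highlighted: increases in red, decreases in blue, other genes grey.
#'
#' @param results the `$genes` data.frame from [scoreScreen()].
#' @param label_hits annotate hit genes with their names (default TRUE).
#' @param ... passed to [graphics::plot()].
#' @return `results`, invisibly.
#' @importFrom graphics plot text legend
#' @export
plotVolcano <- function(results, label_hits = TRUE, ...) {
    col <- ifelse(results$hit_class == "increase", "firebrick",
                  ifelse(results$hit_class == "decrease", "steelblue",
                         "grey50"))
    graphics::plot(results$phenotype_lfc, -log10(results$p_value),
                   pch = 19, col = col,
                   xlab = expression(log[2] ~ "phenotype fold change"),
                   ylab = expression(-log[10] ~ "p"), ...)
    if (label_hits && any(results$hit_class != "none")) {
        hit <- results$hit_class != "none"
        graphics::text(results$phenotype_lfc[hit],
                       -log10(results$p_value[hit]),
                       labels = results$gene[hit], pos = 3, cex = 0.7)
    }
    graphics::legend("topleft", legend = c("increase", "decrease", "other"),
                     col = c("firebrick", "steelblue", "grey50"), pch = 19,
                     bty = "n", cex = 0.8)
    invisible(results)
}
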