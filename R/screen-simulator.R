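#' ScreenConfig: parameters of a simulated FACS-sort CRISPRi screen
#'
#' Bundles the generative model for one screen: lentiviral infection at low
#' multiplicity (Poisson number of guides per cell, zero-guide cells removed
#' by selection), a guide-dependent log-normal fluorescence phenotype, sorting
#' of the bottom and top `sort_fraction` of cells by fluorescence, and
#' Dirichlet-multinomial sequencing of each sorted bin.
#'
#' @slot library the [GuideLibrary-class] being screened.
#' @slot moi mean lentiviral integrations per cell (Poisson rate; default
#'   0.15, the upper bound of the low-MOI design).
#' @slot cells_per_guide mean post-selection coverage per library element
#'   (default 500).
#' @slot mu0 baseline log2 fluorescence of unperturbed cells (default 10).
#' @slot noise_sd cell-to-cell fluorescence SD in log2 units (default 1).
#' @slot effects named numeric: per-gene log2-fluorescence shift gamma; genes
#'   absent from the map (and NTC) have shift 0.
#' @slot sort_fraction fraction sorted into each of the low and high bins
#'   (default 0.25, i.e. bottom and top quartiles; must lie in (0, 0.5]).
#' @slot reads_per_bin sequencing depth per sorted bin (default 1e6).
#' @slot overdispersion Dirichlet-multinomial overdispersion phi >= 0
#'   (default 0.01); phi = 0 degenerates to pure multinomial sampling.
#' @slot n_replicates independent screen replicates (default 3).
#' @slot seed master integer seed; replicate/stage sub-seeds are derived
#'   deterministically from it.
#' @seealso [screenConfig()], [simulateScreen()]
#' @export
setClass("ScreenConfig", representation(
    library = "GuideLibrary", moi = "numeric", cells_per_guide = "numeric",
    mu0 = "numeric", noise_sd = "numeric", effects = "numeric",
    sort_fraction = "numeric", reads_per_bin = "numeric",
    overdispersion = "numeric", n_replicates = "integer", seed = "integer"))

setValidity("ScreenConfig", function(object) {
    v <- character(0)
    if (!(object@sort_fraction > 0 && object@sort_fraction <= 0.5))
        v <- c(v, "sort_fraction must lie in (0, 0.5]")
    if (object@noise_sd <= 0) v <- c(v, "noise_sd must be > 0")
    if (object@moi <= 0) v <- c(v, "moi must be > 0")
    if (object@reads_per_bin < 1) v <- c(v, "reads_per_bin must be >= 1")
    if (object@overdispersion < 0) v <- c(v, "overdispersion must be >= 0")
    if (object@n_replicates < 1) v <- c(v, "n_replicates must be >= 1")
    if (length(v) == 0) TRUE else v
})

#' Build a ScreenConfig
#'
#' @param library a [GuideLibrary-class].
#' @param moi,cells_per_guide,mu0,noise_sd,sort_fraction,reads_per_bin,overdispersion,n_replicates,seed
#'   see [ScreenConfig-class] for meanings and defaults.
#' @param effects named numeric vector of per-gene log2 shifts; unnamed genes
#'   and NTCs are null.
#' @return A validated [ScreenConfig-class].
#' @export
screenConfig <- function(library, moi = 0.15, cells_per_guide = 500,
                         mu0 = 10, noise_sd = 1, effects = numeric(0),
                         sort_fraction = 0.25, reads_per_bin = 1e6,
                         overdispersion = 0.01, n_replicates = 3L,
                         seed = 1L) {
    new("ScreenConfig", library = library, moi = moi,
        cells_per_guide = cells_per_guide, mu0 = mu0, noise_sd = noise_sd,
        effects = effects, sort_fraction = sort_fraction,
        reads_per_bin = reads_per_bin, overdispersion = overdispersion,
        n_replicates = as.integer(n_replicates), seed = as.integer(seed))
}

setMethod("show", "ScreenConfig", function(object) {
    cat(sprintf(paste0(
        "ScreenConfig: %d guides, MOI %.3g, coverage %g cells/guide,\n",
        "  sort fraction %.2f, depth %g reads/bin, phi %.3g, %d replicate(s)\n"),
        length(object@library), object@moi, object@cells_per_guide,
        object@sort_fraction, object@reads_per_bin, object@overdispersion,
        object@n_replicates))
})

# Deterministic sub-seed: master * 1000 + stage index, folded into int range.
.subSeed <- function(seed, k) {
    as.integer((as.numeric(seed) * 1000 + k) %% 2147483647)
}

.effectOf <- function(effects, genes) {
    g <- effects[genes]
    g[is.na(g)] <- 0
    unname(g)
}

#' Assign guides to cells by Poisson infection
#'
#' Each plated cell receives `k ~ Poisson(moi)` guides drawn uniformly with
#' replacement from the library; cells with `k = 0` are discarded, modelling
#' antibiotic selection of transduced cells.
#'
#' @param n_cells number of plated cells (before selection).
#' @param library a [GuideLibrary-class].
#' @param moi mean guides per cell.
#' @param seed integer seed.
#' @return A list of class `CellPopulation` with elements `n_cells`
#'   (surviving cells), `cell` and `guide` (parallel integer/character
#'   vectors: one row per cell-guide pairing), and `log2_fluor` (`NULL`
#'   until [simulateFluorescence()] is applied).
#' @export
assignGuides <- function(n_cells, library, moi, seed = 1L) {
    stopifnot(n_cells >= 1, moi > 0)
    if (length(library) == 0) stop("empty guide library")
    set.seed(seed)
    k <- stats::rpois(n_cells, moi)
    k <- k[k > 0]
    n_surv <- length(k)
    if (n_surv == 0) stop("no cells survived selection; increase n_cells or moi")
    ids <- guideIds(library)
    draws <- sample.int(length(ids), sum(k), replace = TRUE)
    structure(list(n_cells = n_surv,
                   cell = rep.int(seq_len(n_surv), k),
                   guide = ids[draws],
                   log2_fluor = NULL),
              class = "CellPopulation")
}

#' Simulate per-cell fluorescence from guide effects
#'
#' Sets `log2_fluor = mu0 + mean(gamma over the cell's guides) + eps`, with
#' `eps ~ Normal(0, noise_sd^2)`. Cells carrying several guides (about 7% of
#' survivors at MOI 0.15) average their guides' effects.
#'
#' @param cells a `CellPopulation` from [assignGuides()].
#' @param config a [ScreenConfig-class] (supplies `mu0`, `noise_sd`,
#'   `effects` and the gene map of its library).
#' @param seed integer seed.
#' @return The `CellPopulation` with `log2_fluor` filled in.
#' @export
simulateFluorescence <- function(cells, config, seed = 1L) {
    stopifnot(inherits(cells, "CellPopulation"))
    lib <- config@library
    gene_of <- stats::setNames(targetGenes(lib), guideIds(lib))
    gam <- .effectOf(config@effects, gene_of[cells$guide])
    mean_gamma <- as.vector(
        rowsum(gam, cells$cell) / tabulate(cells$cell, nbins = cells$n_cells))
    set.seed(seed)
    cells$log2_fluor <- config@mu0 + mean_gamma +
        stats::rnorm(cells$n_cells, 0, config@noise_sd)
    cells
}

#' Sort cells into low and high fluorescence bins
#'
#' Ranks cells by `log2_fluor` and collects the bottom `floor(q * n)` cells
#' into the low bin and the top `floor(q * n)` into the high bin; the middle
#' of the distribution is discarded, as in a two-gate FACS sort. Ties are
#' broken by stable input order, so a fully degenerate population fills the
#' low bin from the first cells and the high bin from the last.
#'
#' @param cells a `CellPopulation` with fluorescence set.
#' @param q fraction per bin, in (0, 0.5].
#' @return A list with `low` and `high` (named integer vectors,
#'   guide -> number of sorted cells carrying it), `n_cells_total`, and
#'   `bin_size`.
#' @export
sortCells <- function(cells, q = 0.25) {
    stopifnot(inherits(cells, "CellPopulation"), !is.null(cells$log2_fluor))
    if (!(q > 0 && q <= 0.5)) stop("sort fraction q must lie in (0, 0.5]")
    n <- cells$n_cells
    if (n < 4) stop("need at least 4 cells to sort")
    m <- floor(q * n)
    ord <- order(cells$log2_fluor)    # radix: stable in input order
    low_cells <- ord[seq_len(m)]
    high_cells <- ord[seq.int(n - m + 1L, n)]
    tally <- function(sel) {
        keep <- cells$cell %in% sel
        tab <- table(cells$guide[keep])
        stats::setNames(as.integer(tab), names(tab))
    }
    list(low = tally(low_cells), high = tally(high_cells),
         n_cells_total = n, bin_size = m)
}

#' Sequence one sorted bin with Dirichlet-multinomial noise
#'
#' Converts a guide -> cell tally into read counts at fixed total depth.
#' With overdispersion `phi > 0`, read proportions are drawn from
#' `Dirichlet(alpha_g = tally_g / phi)` and counts from
#' `Multinomial(reads, proportions)`, giving negative-binomial-like marginal
#' overdispersion while conserving depth exactly; `phi = 0` uses the tally
#' proportions directly. Guides absent from the tally have zero expected
#' reads.
#'
#' @param tally named integer vector, guide -> sorted cell count.
#' @param library a [GuideLibrary-class]; output covers every library guide.
#' @param reads total reads for the bin.
#' @param phi overdispersion (>= 0).
#' @param seed integer seed.
#' @return Named integer vector of read counts over all library guides,
#'   summing exactly to `reads`.
#' @export
sequenceBin <- function(tally, library, reads = 1e6, phi = 0.01, seed = 1L) {
    stopifnot(reads >= 1, phi >= 0)
    ids <- guideIds(library)
    alpha <- stats::setNames(numeric(length(ids)), ids)
    known <- intersect(names(tally), ids)
    alpha[known] <- as.numeric(tally[known])
    if (sum(alpha) <= 0) stop("all-zero tally: nothing to sequence")
    set.seed(seed)
    if (phi > 0) {
        w <- stats::rgamma(length(alpha), shape = alpha / phi, rate = 1)
    } else {
        w <- alpha
    }
    p <- w / sum(w)
    counts <- as.integer(stats::rmultinom(1, size = round(reads), prob = p))
    stats::setNames(counts, ids)
}

#' Simulate a complete FACS-sort screen
#'
#' Runs infection, fluorescence, quartile sorting and sequencing
#' independently for each replicate, using sub-seeds derived from the master
#' seed, and assembles the guide x sample count matrix together with the
#' ground-truth effect table used to generate it.
#'
#' @param config a [ScreenConfig-class].
#' @return A list with `counts` (a [ScreenCounts-class]: samples named
#'   `rep<i>_low` / `rep<i>_high`) and `truth` (data.frame `gene`, `gamma`
#'   covering every targeting gene).
#' @export
simulateScreen <- function(config) {
    validObject(config)
    lib <- config@library
    # every integration lands in a surviving cell, so expected cell-guide
    # pairings = n_plated * moi; coverage per guide = n_plated * moi / n_guides
    n_plated <- ceiling(length(lib) * config@cells_per_guide / config@moi)
    mats <- vector("list", config@n_replicates)
    unass <- integer(0)
    for (r in seq_len(config@n_replicates)) {
        cells <- assignGuides(n_plated, lib, config@moi,
                              seed = .subSeed(config@seed, 10 * r + 1))
        cells <- simulateFluorescence(cells, config,
                                      seed = .subSeed(config@seed, 10 * r + 2))
        bins <- sortCells(cells, config@sort_fraction)
        low <- sequenceBin(bins$low, lib, config@reads_per_bin,
                           config@overdispersion,
                           seed = .subSeed(config@seed, 10 * r + 3))
        high <- sequenceBin(bins$high, lib, config@reads_per_bin,
                            config@overdispersion,
                            seed = .subSeed(config@seed, 10 * r + 4))
        mats[[r]] <- cbind(low, high)
        colnames(mats[[r]]) <- sprintf("rep%d_%s", r, c("low", "high"))
    }
    counts <- do.call(cbind, mats)
    rownames(counts) <- guideIds(lib)
    genes <- unique(targetGenes(lib)[!isNTC(lib)])
    truth <- data.frame(gene = genes,
                        gamma = .effectOf(config@effects, genes))
    sc <- ScreenCounts(counts, library = lib,
                       replicate = rep(seq_len(config@n_replicates), each = 2),
                       bin = rep(c("low", "high"), config@n_replicates))
    list(counts = sc, truth = truth)
}

#' ReadStructure: where the protospacer sits inside a sequencing read
#'
#' Amplicon reads carry the protospacer between constant vector flanks.
#' `anchored` mode extracts the protospacer at the fixed offset
#' `nchar(five_prime_constant)`; `sliding` mode scans every offset and takes
#' the 5'-most one that yields an assignment.
#'
#' @param five_prime_constant constant 5' sequence preceding the protospacer
#'   (may be empty).
#' @param protospacer_length protospacer length in nt.
#' @param three_prime_constant constant 3' sequence used when writing reads.
#' @param search_mode `"anchored"` or `"sliding"`.
#' @return A list of class `ReadStructure`.
#' @export
readStructure <- function(five_prime_constant = "GTGGAAAGGACGAAACACCG",
                          protospacer_length = 20L,
                          three_prime_constant = "GTTTAAGAGCTAAGCTGGAA",
                          search_mode = c("anchored", "sliding")) {
    search_mode <- match.arg(search_mode)
    structure(list(five_prime_constant = toupper(five_prime_constant),
                   protospacer_length = as.integer(protospacer_length),
                   three_prime_constant = toupper(three_prime_constant),
                   search_mode = search_mode),
              class = "ReadStructure")
}

#' Write simulated screen reads as FASTQ
#'
#' Emits one read per count unit, `five_prime_constant + protospacer +
#' three_prime_constant`, with a constant Phred+33 quality string (`I`), in
#' a deterministic shuffled order for the given seed. One file per sample,
#' named `<sample>.fastq` under `dir`.
#'
#' @param counts named integer vector (guide -> reads) or a guide x sample
#'   integer matrix with column names.
#' @param library a [GuideLibrary-class].
#' @param structure a [readStructure()].
#' @param dir output directory (created if needed).
#' @param seed integer seed controlling read order.
#' @return Named character vector of file paths, one per sample.
#' @export
writeScreenFastq <- function(counts, library, structure = readStructure(),
                             dir = ".", seed = 1L) {
    if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1,
                                               dimnames = list(names(counts),
                                                               "sample1"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    proto <- protospacers(library)
    paths <- character(0)
    for (j in seq_len(ncol(counts))) {
        sample <- colnames(counts)[j]
        cnt <- counts[, j]
        cnt <- cnt[cnt > 0]
        guides <- rep(names(cnt), cnt)
        set.seed(.subSeed(seed, j))
        if (length(guides) > 1) guides <- sample(guides)
        seqs <- paste0(structure$five_prime_constant, proto[guides],
                       structure$three_prime_constant)
        qual <- vapply(nchar(seqs),
                       function(n) paste(rep("I", n), collapse = ""),
                       character(1))
        path <- file.path(dir, paste0(sample, ".fastq"))
        if (length(seqs) == 0) {
            writeLines(character(0), path)
        } else {
            rec <- rbind(sprintf("@%s_read%06d", sample, seq_along(seqs)),
                         seqs, "+", qual)
            writeLines(as.vector(rec), path)
        }
        paths[sample] <- path
    }
    paths
}

#' Read or write a ScreenConfig as YAML
#'
#' The library itself is stored by reference to a CSV path, keeping the YAML
#' a plain parameter file.
#'
#' @param config a [ScreenConfig-class].
#' @param path YAML path.
#' @param library_path where the library CSV is written / read from; defaults
#'   to `<path>_library.csv` alongside the YAML.
#' @return `writeScreenConfig`: `path` invisibly. `readScreenConfig`: a
#'   [ScreenConfig-class].
#' @export
writeScreenConfig <- function(config, path,
                              library_path = paste0(path, "_library.csv")) {
    writeGuideLibrary(config@library, library_path)
    eff <- as.list(config@effects)
    yaml::write_yaml(list(
        library = library_path, moi = config@moi,
        cells_per_guide = config@cells_per_guide, mu0 = config@mu0,
        noise_sd = config@noise_sd, effects = eff,
        sort_fraction = config@sort_fraction,
        reads_per_bin = config@reads_per_bin,
        overdispersion = config@overdispersion,
        n_replicates = config@n_replicates, seed = config@seed), path)
    invisible(path)
}

#' @rdname writeScreenConfig
#' @export
readScreenConfig <- function(path) {
    y <- yaml::read_yaml(path)
    lib <- readGuideLibrary(y$library)
    eff <- unlist(y$effects)
    if (is.null(eff)) eff <- numeric(0)
    screenConfig(lib, moi = y$moi, cells_per_guide = y$cells_per_guide,
                 mu0 = y$mu0, noise_sd = y$noise_sd, effects = eff,
                 sort_fraction = y$sort_fraction,
                 reads_per_bin = y$reads_per_bin,
                 overdispersion = y$overdispersion,
                 n_replicates = y$n_replicates, seed = y$seed)
}
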