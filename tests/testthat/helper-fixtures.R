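# shared fixtures, built in code

# the ten Methods-table protospacers shipped as a CSV fixture
printedGuidesPath <- function() {
    system.file("extdata", "printed_guides.csv", package = "phagoScreen")
}

printedGuideLibrary <- function() {
    readGuideLibrary(printedGuidesPath())
}

# a small deterministic cell population with fluorescence already set
madeCells <- function(fluor, guides = as.character(seq_along(fluor))) {
    structure(list(n_cells = length(fluor),
                   cell = seq_along(fluor),
                   guide = guides,
                   log2_fluor = fluor),
              class = "CellPopulation")
}

# brute-force Hamming-distance matcher over the whole library: the oracle
# for matchRead
hammingScanOracle <- function(read, lib, structure, max_mismatch) {
    L <- structure$protospacer_length
    off <- nchar(structure$five_prime_constant)
    if (nchar(read) < off + L) return("unassigned")
    cand <- substr(read, off + 1L, off + L)
    proto <- protospacers(lib)
    dist <- vapply(proto, function(p) {
        sum(utf8ToInt(p) != utf8ToInt(cand))
    }, numeric(1))
    dmin <- min(dist)
    if (dmin > max_mismatch) return("unassigned")
    hits <- names(proto)[dist == dmin]
    if (length(hits) == 1) hits else "unassigned"
}

# exact two-sided Mann-Whitney p by full enumeration of rank placements:
# the oracle for geneTest on small no-tie inputs
mwuEnumerationOracle <- function(x, y) {
    n1 <- length(x)
    pooled <- c(x, y)
    stopifnot(!anyDuplicated(pooled))
    u_obs <- sum(outer(x, y, ">"))
    combos <- utils::combn(length(pooled), n1)
    us <- apply(combos, 2, function(idx) {
        sum(outer(pooled[idx], pooled[-idx], ">"))
    })
    mu <- n1 * length(y) / 2
    mean(abs(us - mu) >= abs(u_obs - mu))
}
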