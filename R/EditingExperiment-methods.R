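#' Construct an EditingExperiment
#'
#' Assemble sites-by-samples editing counts into an [EditingExperiment].
#'
#' @param alt,total integer matrices (sites x samples) of edited and total
#'   read counts. `NA` (in both, jointly) marks NO_COVERAGE cells.
#' @param sites either a [GenomicRanges::GRanges] with metadata columns
#'   `ref` and `alt`, or a data.frame with columns `chrom`, `pos`, `strand`,
#'   `ref`, `alt` (1-based positions).
#' @param colData optional [S4Vectors::DataFrame] of sample annotations
#'   (for example a `group` column used by [diffEditing()]).
#' @return An [EditingExperiment].
#' @examples
#' sites <- data.frame(chrom = "chr1", pos = c(100, 200),
#'                     strand = c("+", "-"), ref = c("A", "T"),
#'                     alt = c("G", "C"))
#' alt <- matrix(c(5L, 0L, 3L, NA), 2, 2,
#'               dimnames = list(NULL, c("s1", "s2")))
#' tot <- matrix(c(50L, 40L, 30L, NA), 2, 2,
#'               dimnames = list(NULL, c("s1", "s2")))
#' ee <- EditingExperiment(alt, tot, sites)
#' editingLevels(ee)
#' @export
EditingExperiment <- function(alt, total, sites, colData = NULL) {
    if (is.data.frame(sites))
        sites <- sitesAsGRanges(sites)
    alt <- as.matrix(alt)
    total <- as.matrix(total)
    storage.mode(alt) <- "integer"
    storage.mode(total) <- "integer"
    if (is.null(colnames(alt)))
        colnames(alt) <- colnames(total) <-
            paste0("s", seq_len(ncol(alt)))
    rownames(alt) <- rownames(total) <- siteKey(sites)
    names(sites) <- siteKey(sites)
    if (is.null(colData))
        colData <- S4Vectors::DataFrame(row.names = colnames(alt))
    se <- SummarizedExperiment(
        assays = list(alt = alt, total = total),
        rowRanges = sites, colData = colData)
    new("EditingExperiment", se)
}

## canonical "chrom:pos:strand" site key
siteKey <- function(gr) {
    paste(as.character(seqnames(gr)), start(gr),
          as.character(strand(gr)), sep = ":")
}

sitesAsGRanges <- function(df) {
    need <- c("chrom", "pos", "strand", "ref", "alt")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("site table lacks column(s): ", paste(miss, collapse = ", "))
    gr <- GRanges(df$chrom, IRanges(df$pos, width = 1L),
                  strand = df$strand)
    mcols(gr)$ref <- as.character(df$ref)
    mcols(gr)$alt <- as.character(df$alt)
    gr
}

#' Accessors for EditingExperiment
#'
#' `altReads()` and `totalReads()` return the count assays; `refReads()`
#' their difference; `editingLevels()` the per-cell editing level
#' `alt/total` (`NA` for NO_COVERAGE cells); `isObserved()` the logical
#' coverage mask; `siteIds()` the canonical `chrom:pos:strand` keys.
#'
#' @param x an [EditingExperiment].
#' @param ... ignored.
#' @return Matrices of the same dimension as `x`, except `siteIds()`, which
#'   returns a character vector.
#' @name EditingExperiment-accessors
NULL

#' @rdname EditingExperiment-accessors
#' @export
setMethod("altReads", "EditingExperiment", function(x, ...)
    assay(x, "alt"))

#' @rdname EditingExperiment-accessors
#' @export
setMethod("totalReads", "EditingExperiment", function(x, ...)
    assay(x, "total"))

#' @rdname EditingExperiment-accessors
#' @export
setMethod("refReads", "EditingExperiment", function(x, ...)
    assay(x, "total") - assay(x, "alt"))

#' @rdname EditingExperiment-accessors
#' @export
setMethod("editingLevels", "EditingExperiment", function(x, ...) {
    lev <- assay(x, "alt") / assay(x, "total")
    lev[is.na(assay(x, "total"))] <- NA_real_
    lev
})

#' @rdname EditingExperiment-accessors
#' @export
setMethod("isObserved", "EditingExperiment", function(x, ...)
    !is.na(assay(x, "total")))

#' @rdname EditingExperiment-accessors
#' @export
setMethod("siteIds", "EditingExperiment", function(x, ...)
    siteKey(rowRanges(x)))

setMethod("show", "EditingExperiment", function(object) {
    obs <- isObserved(object)
    cat("EditingExperiment:", nrow(object), "sites x",
        ncol(object), "samples\n")
    cat(sprintf("  observed cells: %d/%d (%.1f%%)\n",
                sum(obs), length(obs),
                if (length(obs)) 100 * mean(obs) else 0))
    str <- as.character(strand(rowRanges(object)))
    cat(sprintf("  strands: +%d (A>G)  -%d (T>C)\n",
                sum(str == "+"), sum(str == "-")))
    if (ncol(colData(object)))
        cat("  colData:", paste(colnames(colData(object)),
                                collapse = ", "), "\n")
})

setMethod("show", "BetaBinFit", function(object) {
    cat(sprintf(
        "BetaBinFit: alpha=%.4g beta=%.4g mean=%.4g loglik=%.4f%s%s\n",
        object@alpha, object@beta, object@mean, object@loglik,
        if (object@converged) "" else " [not converged]",
        if (object@boundary) " [boundary]" else ""))
})
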