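## Readers/writers for the external file formats the pipeline touches.
## Conventions: in-memory positions are 1-based (VCF-like) throughout; BED
## 0-based half-open intervals are converted at the boundary by rtracklayer.

.repeatClasses <- c("ALU", "NON_ALU_REPEAT")

#' Read a per-sample site-count table
#'
#' Ingests a REDITools-style tab-delimited pileup count table with columns
#' `chrom`, `pos` (1-based), `strand` (+/-), `ref_base`, `A`, `C`, `G`, `T`.
#' Edited (alt) reads are resolved by the strand rule: the G count on the
#' plus strand, the C count on the minus strand; ref reads are the A count
#' on the plus strand and the T count on the minus strand. Reads carrying
#' any other mismatch are ignored, so `total = ref_reads + alt_reads`.
#'
#' @param path path to the TSV file.
#' @param sample_id sample identifier attached to every observation.
#' @return A data.frame with columns `sample_id`, `chrom`, `pos`, `strand`,
#'   `ref`, `alt`, `ref_reads`, `alt_reads`. Rows are OBSERVED cells only;
#'   positions absent from the file have no coverage in this sample.
#' @export
readSiteCounts <- function(path, sample_id) {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      colClasses = "character", check.names = FALSE)
    need <- c("chrom", "pos", "strand", "ref_base", "A", "C", "G", "T")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
    if (!nrow(tab))
        return(data.frame(sample_id = character(), chrom = character(),
                          pos = integer(), strand = character(),
                          ref = character(), alt = character(),
                          ref_reads = integer(), alt_reads = integer()))
    line <- seq_len(nrow(tab)) + 1L  # header is line 1
    badStrand <- !tab$strand %in% c("+", "-")
    if (any(badStrand))
        stop(path, " line ", line[badStrand][1L],
             ": unknown strand symbol '", tab$strand[badStrand][1L], "'")
    counts <- suppressWarnings(
        vapply(tab[c("A", "C", "G", "T")], as.integer,
               integer(nrow(tab))))
    counts <- matrix(counts, nrow = nrow(tab),
                     dimnames = list(NULL, c("A", "C", "G", "T")))
    badCount <- apply(is.na(counts) | counts < 0, 1L, any) |
        is.na(suppressWarnings(as.integer(tab$pos)))
    if (any(badCount))
        stop(path, " line ", line[badCount][1L],
             ": non-integer or negative count/position")
    wantRef <- ifelse(tab$strand == "+", "A", "T")
    badRef <- tab$ref_base != wantRef
    if (any(badRef))
        stop(path, " line ", line[badRef][1L], ": ref_base '",
             tab$ref_base[badRef][1L], "' inconsistent with strand '",
             tab$strand[badRef][1L], "' (expect A on +, T on -)")
    key <- paste(tab$chrom, tab$pos, tab$strand)
    if (anyDuplicated(key))
        stop(path, " line ", line[duplicated(key)][1L],
             ": duplicate (chrom, pos, strand)")
    plus <- tab$strand == "+"
    data.frame(
        sample_id = sample_id,
        chrom = tab$chrom,
        pos = as.integer(tab$pos),
        strand = tab$strand,
        ref = ifelse(plus, "A", "T"),
        alt = ifelse(plus, "G", "C"),
        ref_reads = ifelse(plus, counts[, "A"], counts[, "T"]),
        alt_reads = ifelse(plus, counts[, "G"], counts[, "C"]))
}

#' Write a per-sample site-count table
#'
#' Inverse of [readSiteCounts()]: writes one sample's OBSERVED cells of an
#' [EditingExperiment] (or a long observation data.frame) as a REDITools
#' style count TSV. Base columns other than the strand-rule pair are zero.
#'
#' @param x an [EditingExperiment] or a data.frame as returned by
#'   [readSiteCounts()].
#' @param path output file.
#' @param sample sample name (required for an `EditingExperiment`).
#' @return `path`, invisibly.
#' @export
writeSiteCounts <- function(x, path, sample = NULL) {
    if (is(x, "EditingExperiment")) {
        stopifnot(!is.null(sample))
        keep <- isObserved(x)[, sample]
        rr <- rowRanges(x)[keep]
        obs <- data.frame(
            chrom = as.character(seqnames(rr)), pos = start(rr),
            strand = as.character(strand(rr)),
            ref_reads = refReads(x)[keep, sample],
            alt_reads = altReads(x)[keep, sample])
    } else {
        obs <- x
    }
    plus <- obs$strand == "+"
    out <- data.frame(
        chrom = obs$chrom, pos = obs$pos, strand = obs$strand,
        ref_base = ifelse(plus, "A", "T"),
        A = ifelse(plus, obs$ref_reads, 0L),
        C = ifelse(plus, 0L, obs$alt_reads),
        G = ifelse(plus, obs$alt_reads, 0L),
        T = ifelse(plus, 0L, obs$ref_reads))
    writeTsv(out, path)
}

#' Read genomic variants from a VCF
#'
#' Loads a VCF 4.x variant list as a set of `(chrom, pos, ref, alt)` tuples
#' for RNA-DNA difference subtraction. Multi-allelic records are expanded
#' to one tuple per alternate allele.
#'
#' @param path path to an (uncompressed or gzipped) VCF.
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`, one row
#'   per allele, without duplicates.
#' @export
readVcfVariants <- function(path) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    empty <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character())
    if (is.null(fix) || nrow(fix) == 0L)
        return(empty)
    alts <- strsplit(as.character(fix[, "ALT"]), ",", fixed = TRUE)
    nalt <- lengths(alts)
    out <- data.frame(
        chrom = rep(as.character(fix[, "CHROM"]), nalt),
        pos = rep(as.integer(fix[, "POS"]), nalt),
        ref = rep(as.character(fix[, "REF"]), nalt),
        alt = unlist(alts, use.names = FALSE))
    unique(out)
}

#' Write a minimal VCF 4.2 variant list
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeVcfVariants <- function(variants, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    if (nrow(variants))
        writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                           variants$chrom, as.integer(variants$pos),
                           variants$ref, variants$alt), con)
    invisible(path)
}

#' Read repeat annotation intervals from BED
#'
#' Reads BED3+class repeat intervals (4th column one of `ALU`,
#' `NON_ALU_REPEAT`). The 0-based half-open BED coordinates are converted
#' to 1-based closed [GenomicRanges::GRanges] at this boundary, so a BED
#' line `chr1 99 200` covers 1-based positions 100..200. Overlapping
#' intervals are accepted verbatim (no merging).
#'
#' @param path path to the BED file.
#' @return A `GRanges` with metadata column `repeat_class`.
#' @export
readBedRepeats <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    if (any(width(gr) < 1L))
        stop(path, ": interval with start >= end")
    cls <- mcols(gr)$name
    if (is.null(cls) || anyNA(cls))
        stop(path, ": repeat class column (BED field 4) required")
    bad <- !cls %in% .repeatClasses
    if (any(bad))
        stop(path, ": unknown repeat class token '", cls[bad][1L], "'")
    mcols(gr) <- S4Vectors::DataFrame(repeat_class = cls)
    gr
}

#' Write repeat intervals as BED3+class
#'
#' @param repeats `GRanges` with metadata column `repeat_class` (1-based).
#' @param path output file; written 0-based half-open.
#' @return `path`, invisibly.
#' @export
writeBedRepeats <- function(repeats, path) {
    lines <- sprintf("%s\t%d\t%d\t%s",
                     as.character(seqnames(repeats)),
                     start(repeats) - 1L, end(repeats),
                     mcols(repeats)$repeat_class)
    writeLines(lines, path)
    invisible(path)
}

#' Read a precomputed coordinate map
#'
#' Loads an old-assembly to new-assembly coordinate mapping (for example a
#' LiftOver result exported as a table). Expected columns: `chrom_old`,
#' `pos_old`, `chrom_new`, `pos_new`, `status` (`MAPPED` or `FAILED`);
#' `chrom_new`/`pos_new` are ignored on FAILED rows.
#'
#' @param path path to the TSV file.
#' @return A data.frame coordinate map.
#' @export
readCoordMap <- function(path) {
    map <- read.delim(path, header = TRUE, sep = "\t")
    need <- c("chrom_old", "pos_old", "chrom_new", "pos_new", "status")
    miss <- setdiff(need, names(map))
    if (length(miss))
        stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
    ok <- map$status == "MAPPED"
    if (anyDuplicated(paste(map$chrom_new[ok], map$pos_new[ok])))
        stop(path, ": coordinate map is not injective on MAPPED rows")
    map
}

#' Apply a coordinate map to sites
#'
#' Partitions sites into those successfully converted to the new assembly
#' and those that failed (absent from the map or marked FAILED), mirroring
#' how LiftOver results are consumed downstream.
#'
#' @param sites data.frame with columns `chrom`, `pos` (plus any others,
#'   carried along).
#' @param map coordinate map from [readCoordMap()].
#' @return A list with elements `mapped` (sites with `chrom`/`pos` replaced
#'   by new coordinates, old ones kept as `chrom_old`/`pos_old`) and
#'   `failed` (unchanged rows).
#' @export
applyCoordMap <- function(sites, map) {
    key <- paste(sites$chrom, sites$pos)
    mkey <- paste(map$chrom_old, map$pos_old)
    idx <- match(key, mkey)
    okRow <- !is.na(idx) & map$status[idx] == "MAPPED"
    mapped <- sites[okRow, , drop = FALSE]
    if (nrow(mapped)) {
        hit <- idx[okRow]
        mapped$chrom_old <- mapped$chrom
        mapped$pos_old <- mapped$pos
        mapped$chrom <- map$chrom_new[hit]
        mapped$pos <- map$pos_new[hit]
    }
    failed <- sites[!okRow, , drop = FALSE]
    message(sprintf("coordinate map: %d mapped, %d failed",
                    nrow(mapped), nrow(failed)))
    list(mapped = mapped, failed = failed)
}

#' Plain TSV helpers
#'
#' Thin wrappers fixing the dialect used for every tabular interchange file
#' (IC50 tables, survival tables, DES results, KM tables): UTF-8,
#' tab-delimited, headered, no quoting, no row names.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `readTsv()` returns a data.frame; `writeTsv()` returns `path`
#'   invisibly.
#' @export
writeTsv <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
    read.delim(path, header = TRUE, sep = "\t", fileEncoding = "UTF-8")
}

#' Serialize an EditingExperiment to a matrix TSV
#'
#' Writes the long form (one row per observed cell) with columns `chrom`,
#' `pos`, `strand`, `ref`, `alt`, `sample_id`, `alt_reads`, `total_reads`.
#' NO_COVERAGE cells are omitted and restored as `NA` on read, given the
#' site and sample universes stored in the header comment lines.
#'
#' @param ee an [EditingExperiment].
#' @param path file path.
#' @return `path` invisibly (writer); an `EditingExperiment` (reader).
#' @export
writeEditingMatrix <- function(ee, path) {
    obs <- which(isObserved(ee), arr.ind = TRUE)
    rr <- rowRanges(ee)[obs[, 1L]]
    long <- data.frame(
        chrom = as.character(seqnames(rr)), pos = start(rr),
        strand = as.character(strand(rr)),
        ref = mcols(rr)$ref, alt = mcols(rr)$alt,
        sample_id = colnames(ee)[obs[, 2L]],
        alt_reads = altReads(ee)[obs],
        total_reads = totalReads(ee)[obs])
    long <- long[order(long$chrom, long$pos, long$strand, long$sample_id), ]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        paste0("# samples: ", paste(colnames(ee), collapse = ",")),
        paste0("# sites: ", paste(siteIds(ee), collapse = ","))), con)
    write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeEditingMatrix
#' @export
readEditingMatrix <- function(path) {
    hdr <- readLines(path, n = 2L)
    samples <- strsplit(sub("^# samples: ?", "", hdr[1L]), ",")[[1L]]
    ids <- strsplit(sub("^# sites: ?", "", hdr[2L]), ",")[[1L]]
    long <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#")
    parts <- do.call(rbind, strsplit(ids, ":", fixed = TRUE))
    sites <- data.frame(
        chrom = parts[, 1L], pos = as.integer(parts[, 2L]),
        strand = parts[, 3L],
        ref = ifelse(parts[, 3L] == "+", "A", "T"),
        alt = ifelse(parts[, 3L] == "+", "G", "C"))
    alt <- matrix(NA_integer_, length(ids), length(samples),
                  dimnames = list(ids, samples))
    tot <- alt
    if (nrow(long)) {
        i <- match(paste(long$chrom, long$pos, long$strand, sep = ":"), ids)
        j <- match(long$sample_id, samples)
        alt[cbind(i, j)] <- long$alt_reads
        tot[cbind(i, j)] <- long$total_reads
    }
    EditingExperiment(alt, tot, sites)
}
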