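# Programmatic fixtures shared across test files.

# One long-format observation row.
obsRow <- function(sample, chrom, pos, strand, ref_reads, alt_reads) {
    plus <- strand == "+"
    data.frame(sample_id = sample, chrom = chrom, pos = pos,
               strand = strand, ref = if (plus) "A" else "T",
               alt = if (plus) "G" else "C",
               ref_reads = ref_reads, alt_reads = alt_reads)
}

# Small deterministic EditingExperiment: `cells` is a list of (alt, total)
# matrices? Simpler: build from explicit matrices.
makeEE <- function(alt, total, strand = NULL) {
    n <- nrow(alt)
    if (is.null(strand)) strand <- rep(c("+", "-"), length.out = n)
    sites <- data.frame(chrom = "chr1", pos = seq_len(n) * 100L,
                        strand = strand,
                        ref = ifelse(strand == "+", "A", "T"),
                        alt = ifelse(strand == "+", "G", "C"))
    if (is.null(colnames(alt)))
        colnames(alt) <- colnames(total) <- paste0("s", seq_len(ncol(alt)))
    EditingExperiment(alt, total, sites)
}

# The 20-site, 4-sample toy cohort with hand-enumerated cascade outcomes.
# Layout (sites by 1-based index, all plus-strand A>G at pos i*1000):
#   1-8   : alt=10/total=100 in every sample -> called everywhere
#   9-10  : alt=4/total=8 everywhere        -> never called (< 5 edited)
#   11-12 : alt=6/total=240 everywhere      -> never called (AF 0.025)
#   13-16 : alt=10/total=100 in s1 only, no coverage elsewhere
#             -> called, but observed in 1/4 samples (prevalence 0.25)
#   17-18 : called in every sample; 17 matches a DNA variant (removed),
#             18's variant record has a mismatching alt allele (kept)
#   19    : alt=5/total=100 everywhere (AF exactly 0.05) -> called
#   20    : alt=10/total=100 in s1,s2; no coverage in s3,s4
#             -> observed in exactly 50% of samples (removed, strict >)
# Expected FilterReport: 20 -> calling removes 4 (9:12) -> 16;
# prevalence removes 5 (13:16, 20) -> 11; variants remove 1 (17) -> 10.
toyCohort <- function() {
    samples <- paste0("s", 1:4)
    rows <- list()
    add <- function(sample, i, ref_reads, alt_reads)
        rows[[length(rows) + 1L]] <<- obsRow(sample, "chr1", i * 1000L,
                                             "+", ref_reads, alt_reads)
    for (s in samples) {
        for (i in 1:8) add(s, i, 90L, 10L)
        for (i in 9:10) add(s, i, 4L, 4L)
        for (i in 11:12) add(s, i, 234L, 6L)
        for (i in 17:18) add(s, i, 90L, 10L)
        add(s, 19L, 95L, 5L)
    }
    for (i in 13:16) add("s1", i, 90L, 10L)
    for (s in c("s1", "s2")) add(s, 20L, 90L, 10L)
    obs <- do.call(rbind, rows)
    variants <- data.frame(
        chrom = "chr1", pos = c(17000L, 18000L), ref = "A",
        alt = c("G", "T"))  # 18's alt mismatches -> retained
    list(obs = obs, variants = variants, samples = samples,
         expectedReport = data.frame(
             stage = c("candidate_calling", "resolve_missing",
                       "prevalence", "variant_subtraction"),
             n_in = c(20L, 16L, 16L, 11L),
             n_removed = c(4L, 0L, 5L, 1L),
             n_out = c(16L, 16L, 11L, 10L)))
}
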