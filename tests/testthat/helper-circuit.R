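# Shared fixtures: a five-part circuit with known ground truth used for
# parameter-recovery tests, plus a narrow fragment-length distribution.

recovery_circuit <- function() {
  parts <- data.frame(
    name = c("Pdemo", "RzDemo", "gene1", "Tdemo", "gene2"),
    part_type = c("promoter", "ribozyme", "cds", "terminator", "cds"),
    start = c(101L, 136L, 310L, 1620L, 1700L),
    end = c(135L, 300L, 1600L, 1680L, 2800L),
    strand = "+",
    cut_site = c(NA, 285, NA, NA, NA),
    tss = c(135, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  circuit_annotation(parts, "demo", 3000L)
}

# truth: deltaJ = 2.01 au/s (plateau 300 au), Ts = 20, p_c = 0.9
recovery_truth <- function(sigma = 0) {
  ground_truth(
    promoter_activities = list(s1 = c(Pdemo = 2.01)),
    terminator_Ts = c(Tdemo = 20),
    ribozyme_pc = c(RzDemo = 0.9),
    gamma = 0.0067, sigma = sigma)
}

demo_fld <- function() fld(c(80L, 100L, 120L), c(0.25, 0.5, 0.25))

# flat profile helper
flat_profile <- function(value, length, ref = "demo", strand = "sense") {
  transcription_profile(rep(value, length), ref, strand)
}

# brute-force union-mode counting oracle: for each fragment enumerate the
# overlapping genes on the matching strand; count only unambiguous hits
union_count_oracle <- function(fragments, genes, min_mapq = 10) {
  counts <- setNames(integer(nrow(genes)), genes$name)
  for (i in seq_len(nrow(fragments))) {
    f <- fragments[i, ]
    if (!is.na(f$mapq) && f$mapq < min_mapq) next
    hits <- which(genes$start <= f$end & genes$end >= f$start &
                    (genes$strand == "+") == (f$strand_class == "sense"))
    if (length(hits) == 1) counts[hits] <- counts[hits] + 1L
  }
  counts
}
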