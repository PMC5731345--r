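#' Construct a table of fragment alignments
#'
#' Fragments are template-level units (a properly paired read pair spans one
#' fragment). Coordinates are 1-based inclusive on the reference.
#'
#' @param reference_id Character vector of reference names.
#' @param start,end Integer vectors, 1-based inclusive, `end >= start`.
#' @param strand_class `"sense"` or `"antisense"` relative to the annotated
#'   circuit orientation.
#' @param mapq Optional mapping quality; `NA` when unknown.
#' @return data.frame of class `FragmentAlignment` with one row per fragment.
#' @export
fragment_alignments <- function(reference_id, start, end, strand_class,
                                mapq = NA_integer_) {
  df <- data.frame(reference_id = as.character(reference_id),
                   start = as.integer(start), end = as.integer(end),
                   strand_class = as.character(strand_class),
                   mapq = as.integer(mapq), stringsAsFactors = FALSE)
  bad <- df$end < df$start
  if (any(bad)) {
    warning(sum(bad), " fragment(s) with end < start dropped")
    df <- df[!bad, , drop = FALSE]
  }
  if (!all(df$strand_class %in% c("sense", "antisense"))) {
    stop("strand_class must be 'sense' or 'antisense'")
  }
  class(df) <- c("FragmentAlignment", "data.frame")
  df
}

# SAM flag pairs for a reverse-stranded library: read1 on the reverse strand
# (83) with mate on the forward strand (163) means the transcript is on the
# annotated sense strand; 99/147 is the antisense configuration.
.SENSE_FLAGS <- c(83L, 163L)
.ANTISENSE_FLAGS <- c(99L, 147L)

#' Load fragment alignments from a BED6 table or paired-flag records
#'
#' Two input forms are supported. (1) A path to (or data.frame of) a
#' 6-column BED table (`chrom start end name score strand`; BED starts are
#' 0-based half-open and are converted to 1-based inclusive). The BED strand
#' column is interpreted according to `library_orientation`: for a `forward`
#' library a `+` interval is a sense fragment; for a `reverse` library it is
#' antisense. (2) A data.frame of paired alignment records with columns
#' `reference_id`, `pos` (1-based leftmost), `flag` (SAM flag) and `isize`
#' (template length), from which one fragment per proper pair is built; flag
#' pairs {83,163} map to sense and {99,147} to antisense (the reverse-stranded
#' library convention). Records with unknown flags are skipped and tallied in
#' a warning.
#'
#' @param path_or_records BED path, BED data.frame, or paired-record
#'   data.frame (identified by a `flag` column).
#' @param library_orientation `"reverse"` (default, strand-flipped library)
#'   or `"forward"`; used for BED input only.
#' @return A [fragment_alignments()] table.
#' @export
load_fragments <- function(path_or_records, library_orientation = c("reverse", "forward")) {
  library_orientation <- match.arg(library_orientation)
  x <- path_or_records
  if (is.character(x)) {
    x <- read.table(x, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x))
  if ("flag" %in% names(x)) {
    return(.fragments_from_pairs(x))
  }
  if (ncol(x) < 6) stop("BED input must have 6 columns")
  names(x)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  keep <- x$end > x$start
  if (any(!keep)) {
    warning(sum(!keep), " BED interval(s) with end <= start dropped")
    x <- x[keep, , drop = FALSE]
  }
  plus_is_sense <- library_orientation == "forward"
  sc <- ifelse((x$strand == "+") == plus_is_sense, "sense", "antisense")
  # the BED score column is ignored (it is not a mapping quality)
  mq <- if ("mapq" %in% names(x)) x$mapq else NA_integer_
  fragment_alignments(x$chrom, x$start + 1L, x$end, sc, mq)
}

.fragments_from_pairs <- function(rec) {
  needed <- c("reference_id", "pos", "flag", "isize")
  missing_cols <- setdiff(needed, names(rec))
  if (length(missing_cols) > 0) {
    stop("paired records need columns: ", paste(missing_cols, collapse = ", "))
  }
  known <- rec$flag %in% c(.SENSE_FLAGS, .ANTISENSE_FLAGS)
  n_skip <- sum(!known)
  if (n_skip > 0) warning(n_skip, " record(s) with unhandled SAM flags skipped")
  rec <- rec[known, , drop = FALSE]
  # one fragment per pair: anchor on the leftmost (forward, isize > 0) mate
  fw <- rec[rec$isize > 0, , drop = FALSE]
  if (nrow(fw) == 0) stop("no forward-oriented proper-pair records found")
  sc <- ifelse(fw$flag %in% .SENSE_FLAGS, "sense", "antisense")
  mq <- if ("mapq" %in% names(fw)) fw$mapq else NA_integer_
  fragment_alignments(fw$reference_id, fw$pos, fw$pos + fw$isize - 1L, sc, mq)
}

#' Load fragments from a SAM/BAM file
#'
#' Thin adapter over Rsamtools: proper pairs with primary alignments are read
#' and handed to the paired-record path of [load_fragments()].
#'
#' @param path SAM or BAM file path.
#' @return A [fragment_alignments()] table.
#' @export
load_fragments_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required for SAM/BAM input")
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  prm <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isProperPair = TRUE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("rname", "pos", "flag", "isize", "mapq"))
  b <- Rsamtools::scanBam(bam, param = prm)[[1]]
  rec <- data.frame(reference_id = as.character(b$rname), pos = b$pos,
                    flag = b$flag, isize = b$isize, mapq = b$mapq,
                    stringsAsFactors = FALSE)
  load_fragments(rec)
}

#' Build strand-specific transcription profiles from fragments
#'
#' The profile value at position x is the number of fragments of that strand
#' class covering x. Raw units are fragment counts; between-sample
#' normalization rescales them later.
#'
#' @param fragments A [fragment_alignments()] table on a single reference.
#' @param reference_length Reference length in nt.
#' @param reference_id Reference name; defaults to the fragments' reference.
#' @param sample_id Optional sample label stored on the profiles.
#' @return List with elements `sense` and `antisense`, each a
#'   [transcription_profile()].
#' @export
build_strand_profiles <- function(fragments, reference_length,
                                  reference_id = NULL, sample_id = NA_character_) {
  if (nrow(fragments) > 0) {
    refs <- unique(fragments$reference_id)
    if (length(refs) > 1) stop("fragments span multiple references")
    if (is.null(reference_id)) reference_id <- refs
    if (any(fragments$start < 1) || any(fragments$end > reference_length)) {
      stop("fragment exceeds reference bounds")
    }
  } else if (is.null(reference_id)) {
    reference_id <- "reference"
  }
  one <- function(class) {
    f <- fragments[fragments$strand_class == class, , drop = FALSE]
    vals <- if (nrow(f) == 0) numeric(reference_length) else
      as.numeric(IRanges::coverage(IRanges::IRanges(f$start, f$end),
                                   width = reference_length))
    transcription_profile(vals, reference_id, class, sample_id)
  }
  list(sense = one("sense"), antisense = one("antisense"))
}

#' Empirical fragment-length distribution
#'
#' Normalized histogram of template lengths, the only input the transcript-end
#' curvature correction needs.
#'
#' @param fragments A [fragment_alignments()] table (or anything with
#'   `start`/`end` columns), or an integer vector of lengths.
#' @return Object of class `FragmentLengthDistribution` with fields `lengths`
#'   (sorted unique lengths) and `probabilities` (summing to 1).
#' @export
fragment_length_distribution <- function(fragments) {
  if (is.data.frame(fragments)) {
    if (nrow(fragments) == 0) stop("no fragments to estimate length distribution")
    lens <- fragments$end - fragments$start + 1L
  } else {
    lens <- as.integer(fragments)
    if (length(lens) == 0) stop("no fragments to estimate length distribution")
  }
  if (any(lens < 1)) stop("fragment lengths must be >= 1")
  tab <- table(lens)
  fld(as.integer(names(tab)), as.numeric(tab) / sum(tab))
}

#' Construct a fragment-length distribution directly
#'
#' @param lengths Integer lengths (>= 1).
#' @param probabilities Probabilities summing to 1.
#' @return A `FragmentLengthDistribution`.
#' @export
fld <- function(lengths, probabilities) {
  stopifnot(length(lengths) == length(probabilities))
  if (any(lengths < 1)) stop("lengths must be >= 1")
  if (any(probabilities < 0)) stop("probabilities must be non-negative")
  if (abs(sum(probabilities) - 1) > 1e-9) stop("probabilities must sum to 1")
  structure(list(lengths = as.integer(lengths),
                 probabilities = as.numeric(probabilities)),
            class = "FragmentLengthDistribution")
}

#' Count fragments per gene (union mode)
#'
#' Union-mode counting on the matching strand: a fragment overlapping exactly
#' one gene increments that gene; a fragment overlapping two or more genes is
#' ambiguous and counted for none; fragments below the mapping-quality cutoff
#' are excluded (fragments with unknown mapq are kept).
#'
#' @param fragments A [fragment_alignments()] table.
#' @param gene_annotation data.frame with columns `name`, `start`, `end`,
#'   `strand` (as from [annotation_genes()]); genes on `+` are sense-strand
#'   genes.
#' @param min_mapq Minimum mapping quality (default 10).
#' @param sample_id Column label for the counts.
#' @return Object of class `GeneCountTable`: list with `counts` (gene x
#'   sample integer matrix), `gene_lengths` (nt) and `totals` (total mapped
#'   fragments per sample, including those outside annotated genes).
#' @export
count_gene_fragments <- function(fragments, gene_annotation, min_mapq = 10,
                                 sample_id = "sample1") {
  stopifnot(all(c("name", "start", "end", "strand") %in% names(gene_annotation)))
  total <- nrow(fragments)
  keep <- is.na(fragments$mapq) | fragments$mapq >= min_mapq
  f <- fragments[keep, , drop = FALSE]
  counts <- setNames(integer(nrow(gene_annotation)), gene_annotation$name)
  if (nrow(f) > 0 && nrow(gene_annotation) > 0) {
    gene_strand_class <- ifelse(gene_annotation$strand == "+", "sense", "antisense")
    fr <- IRanges::IRanges(f$start, f$end)
    gr <- IRanges::IRanges(gene_annotation$start, gene_annotation$end)
    hits <- IRanges::findOverlaps(fr, gr)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    strand_ok <- f$strand_class[qh] == gene_strand_class[sh]
    qh <- qh[strand_ok]; sh <- sh[strand_ok]
    n_hits <- tabulate(qh, nbins = nrow(f))
    unambig <- n_hits[qh] == 1
    tab <- tabulate(sh[unambig], nbins = nrow(gene_annotation))
    counts[] <- tab
  }
  structure(
    list(counts = matrix(counts, ncol = 1,
                         dimnames = list(gene_annotation$name, sample_id)),
         gene_lengths = setNames(gene_annotation$end - gene_annotation$start + 1L,
                                 gene_annotation$name),
         totals = setNames(total, sample_id)),
    class = "GeneCountTable"
  )
}

#' Combine per-sample gene count tables
#'
#' @param ... `GeneCountTable` objects over the same genes.
#' @return A merged `GeneCountTable` with one column per sample.
#' @export
bind_gene_counts <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && is.list(tabs[[1]]) && !inherits(tabs[[1]], "GeneCountTable")) {
    tabs <- tabs[[1]]
  }
  g <- rownames(tabs[[1]]$counts)
  for (t in tabs) stopifnot(identical(rownames(t$counts), g))
  structure(
    list(counts = do.call(cbind, lapply(tabs, `[[`, "counts")),
         gene_lengths = tabs[[1]]$gene_lengths,
         totals = do.call(c, lapply(tabs, `[[`, "totals"))),
    class = "GeneCountTable"
  )
}
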