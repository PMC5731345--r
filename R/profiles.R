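#' Construct a transcription profile
#'
#' A per-nucleotide track M(x) over one strand of one reference, in fragment
#' counts (raw) or arbitrary units (au, after normalization).
#'
#' @param values Non-negative numeric vector, one value per nucleotide.
#' @param reference_id Reference sequence name.
#' @param strand_class `"sense"` or `"antisense"`.
#' @param sample_id Optional sample/state label.
#' @return Object of class `TranscriptionProfile`.
#' @export
transcription_profile <- function(values, reference_id,
                                  strand_class = c("sense", "antisense"),
                                  sample_id = NA_character_) {
  strand_class <- match.arg(strand_class)
  values <- as.numeric(values)
  if (any(values < 0)) stop("profile values must be non-negative")
  structure(list(values = values, reference_id = reference_id,
                 strand_class = strand_class, sample_id = sample_id),
            class = "TranscriptionProfile")
}

#' @export
print.TranscriptionProfile <- function(x, ...) {
  cat(sprintf("TranscriptionProfile %s/%s: %d nt, mean %.3g, max %.3g\n",
              x$reference_id, x$strand_class, length(x$values),
              mean(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.TranscriptionProfile <- function(x) length(x$values)

#' Write a transcription profile as bedGraph
#'
#' Runs of equal value are collapsed into bedGraph intervals (0-based
#' half-open, the bedGraph convention). Values are written at full precision
#' so a round trip through [read_profile_bedgraph()] is exact.
#'
#' @param profile A [transcription_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_bedgraph <- function(profile, path) {
  r <- rle(profile$values)
  ends <- cumsum(r$lengths)
  starts0 <- c(0L, head(ends, -1L))
  lines <- sprintf("%s\t%d\t%d\t%s", profile$reference_id, starts0, ends,
                   format(r$values, digits = 17, trim = TRUE, scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file back into a transcription profile
#'
#' @param path bedGraph path written by [write_profile_bedgraph()].
#' @param strand_class Strand label to attach.
#' @param reference_length Profile length; defaults to the last interval end.
#' @param sample_id Optional sample label.
#' @return A [transcription_profile()].
#' @export
read_profile_bedgraph <- function(path, strand_class = "sense",
                                  reference_length = NULL,
                                  sample_id = NA_character_) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("chrom", "start", "end", "value"))
  if (is.null(reference_length)) reference_length <- max(x$end)
  vals <- numeric(reference_length)
  for (i in seq_len(nrow(x))) {
    vals[(x$start[i] + 1L):x$end[i]] <- x$value[i]
  }
  transcription_profile(vals, x$chrom[1], strand_class, sample_id)
}

#' Mean profile height over an interval
#'
#' @param profile A [transcription_profile()].
#' @param start,end 1-based inclusive interval bounds.
#' @return Arithmetic mean of the profile over `[start, end]`.
#' @export
profile_mean <- function(profile, start, end) {
  if (start > end) stop("empty interval")
  if (start < 1 || end > length(profile$values)) {
    stop("interval [", start, ", ", end, "] outside profile bounds")
  }
  mean(profile$values[start:end])
}

#' Scale a profile by a constant
#'
#' @param profile A [transcription_profile()].
#' @param scale Multiplier applied to every value.
#' @return The rescaled profile.
#' @export
scale_profile <- function(profile, scale) {
  profile$values <- profile$values * scale
  profile
}
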