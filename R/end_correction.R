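#' Expected relative end coverage, closed form
#'
#' For a transcription unit of length `N` sequenced with fragments of fixed
#' length `L` placed uniformly among the `N - L + 1` valid starts, the
#' expected number of fragments covering position `x` is proportional to the
#' number of valid starts whose fragment covers `x`:
#' `min(x, L, N - x + 1, N - L + 1)`. This is the independent oracle for the
#' Monte-Carlo hypothetical profile.
#'
#' @param x Position, 1-based, `1 <= x <= N` (vectorized).
#' @param L Fragment length, `1 <= L <= N`.
#' @param N Transcription unit length.
#' @return Number of covering start positions (relative coverage).
#' @export
analytic_end_coverage <- function(x, L, N) {
  if (any(x < 1) || any(x > N)) stop("x out of range [1, N]")
  if (L < 1 || L > N) stop("L out of range [1, N]")
  pmin(x, L, N - x + 1, N - L + 1)
}

#' Monte-Carlo hypothetical end-curvature profile
#'
#' Draws fragment lengths from the fragment-length distribution and maps each
#' uniformly at random to a start position such that the fragment falls
#' entirely within a hypothetical transcription unit of `unit_length` nt
#' (default 2000). Counting covering fragments per position yields T(x), the
#' expected coverage curvature at transcript ends.
#'
#' @param fld A [fld()] / [fragment_length_distribution()] object.
#' @param unit_length Length of the hypothetical unit (default 2000 nt).
#' @param draws Number of fragments to draw (default 1e6).
#' @param seed Integer seed; recorded in the result.
#' @return Object of class `HypotheticalProfile`: list with `values` T(x)
#'   (length `unit_length`), `draws`, `seed`, `unit_length`.
#' @export
hypothetical_profile <- function(fld, unit_length = 2000, draws = 1e6, seed = 1) {
  if (any(fld$lengths > unit_length)) {
    stop("fragment length distribution has lengths exceeding the unit length")
  }
  if (draws < 1) stop("draws must be >= 1")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  L <- fld$lengths[sample.int(length(fld$lengths), draws, replace = TRUE,
                              prob = fld$probabilities)]
  starts <- 1L + floor(runif(draws) * (unit_length - L + 1))
  # coverage via difference array: +1 at start, -1 one past the end, cumsum
  tb <- tabulate(starts, nbins = unit_length)
  te <- tabulate(starts + L, nbins = unit_length + 1L)
  vals <- cumsum(tb - te[seq_len(unit_length)])
  structure(list(values = vals, draws = draws, seed = seed,
                 unit_length = unit_length),
            class = "HypotheticalProfile")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Correction factor profile from a hypothetical profile
#'
#' The curvature is fully contained in the first `window` nt of the
#' hypothetical unit; that region is extracted and normalized by its maximum
#' to give C(x), the factor by which observed coverage at distance x from a
#' transcript end underestimates the interior plateau.
#'
#' @param hyp A [hypothetical_profile()].
#' @param window Number of end positions the correction covers (default 500).
#' @return Object of class `CorrectionFactorProfile`: list with `values`
#'   (length `window`, in (0, 1], max 1) and `window`.
#' @export
correction_factor <- function(hyp, window = 500) {
  v <- hyp$values[seq_len(window)]
  m <- max(v)
  if (m <= 0) stop("hypothetical profile is zero over the correction window; increase draws")
  structure(list(values = v / m, window = window),
            class = "CorrectionFactorProfile")
}

#' Apply the end-curvature correction to a transcription-unit profile
#'
#' Divides P(x) by C(x_n) for positions whose distance `x_n` to the nearest
#' end of the transcription unit is within the correction window; interior
#' positions (and everything outside the unit) are untouched. The same C is
#' used at the 5' and 3' ends. The profile passed in should be built from
#' fragments mapping entirely within the unit (see
#' [unit_profile_from_fragments()]); read-through, internal-promoter and
#' antisense signal keep their uncorrected profiles.
#'
#' @param profile A [transcription_profile()].
#' @param unit Interval of the transcription unit: list/data.frame with
#'   `start`, `end` (1-based inclusive).
#' @param C A [correction_factor()] profile.
#' @return The corrected [transcription_profile()].
#' @export
apply_correction <- function(profile, unit, C) {
  a <- unit$start; b <- unit$end
  if (a < 1 || b > length(profile$values) || a > b) stop("unit outside profile")
  x <- a:b
  xn <- pmin(x - a + 1L, b - x + 1L)
  in_window <- xn <= C$window
  cf <- C$values[xn[in_window]]
  if (any(cf == 0)) stop("correction factor is zero; insufficient Monte-Carlo depth")
  vals <- profile$values
  vals[x[in_window]] <- vals[x[in_window]] / cf
  profile$values <- vals
  profile
}

#' Rebuild a unit-local profile from fully contained fragments
#'
#' Selects fragments of the given strand class mapping entirely within the
#' transcription-unit boundaries and counts coverage, which is the profile
#' the end correction is defined on.
#'
#' @param fragments A [fragment_alignments()] table.
#' @param unit Interval with `start`, `end` (1-based inclusive).
#' @param reference_length Reference length.
#' @param strand_class `"sense"` or `"antisense"`.
#' @return A [transcription_profile()] that is zero outside the unit.
#' @export
unit_profile_from_fragments <- function(fragments, unit, reference_length,
                                        strand_class = "sense") {
  keep <- fragments$strand_class == strand_class &
    fragments$start >= unit$start & fragments$end <= unit$end
  build_strand_profiles(fragments[keep, , drop = FALSE], reference_length,
                        reference_id = unique(fragments$reference_id)[1])[[strand_class]]
}

#' Write a correction factor profile as TSV
#'
#' @param C A [correction_factor()] profile.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correction_factor <- function(C, path) {
  write.table(data.frame(distance_nt = seq_len(C$window), C = C$values),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
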