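#' Between-sample TMM scaling factors
#'
#' Computes one overall scaling factor per sample using the trimmed mean of
#' M-values (TMM), via edgeR. The factor returned here is the *overall*
#' between-sample scale: the TMM compositional factor multiplied by the
#' sample's library size, centered so the factors have geometric mean 1.
#' Dividing a sample's raw coverage by its factor (times a common constant)
#' makes samples directly comparable.
#'
#' The reference sample is chosen by edgeR as the one whose upper-quartile
#' count fraction is closest to the mean; genes with a zero count in either
#' member of a pair are excluded from that pair's M/A values.
#'
#' @param counts A `GeneCountTable` (from [count_gene_fragments()] /
#'   [bind_gene_counts()]) or a gene x sample count matrix.
#' @param trim_logratio Two-sided trim fraction on M-values (default 0.30).
#' @param trim_intensity Two-sided trim fraction on A-values (default 0.05).
#' @return Object of class `NormalizationFactors`: list with `factors`
#'   (named, geometric mean 1), `lib_sizes`, and `reference_sample`.
#' @export
tmm_factors <- function(counts, trim_logratio = 0.30, trim_intensity = 0.05) {
  m <- if (inherits(counts, "GeneCountTable")) counts$counts else as.matrix(counts)
  lib <- if (inherits(counts, "GeneCountTable")) counts$totals else colSums(m)
  if (any(lib == 0) || any(colSums(m) == 0)) {
    stop("sample with all-zero counts: ",
         colnames(m)[which(colSums(m) == 0)[1]])
  }
  if (ncol(m) == 1) {
    return(structure(list(factors = setNames(1, colnames(m)),
                          lib_sizes = lib, reference_sample = colnames(m)[1]),
                     class = "NormalizationFactors"))
  }
  comp <- edgeR::calcNormFactors(m, lib.size = unname(lib), method = "TMM",
                                 logratioTrim = trim_logratio,
                                 sumTrim = trim_intensity)
  # reference sample: upper-quartile count fraction closest to the mean
  uq <- apply(m, 2, function(x) quantile(x, 0.75)) / lib
  ref <- colnames(m)[which.min(abs(uq - mean(uq)))]
  raw <- comp * lib
  f <- raw / exp(mean(log(raw)))
  structure(list(factors = setNames(as.numeric(f), colnames(m)),
                 lib_sizes = lib, reference_sample = ref),
            class = "NormalizationFactors")
}

#' Effective library sizes implied by normalization factors
#'
#' The effective library size of a sample is its overall factor times the
#' geometric-mean raw library size, which reproduces the usual
#' library-size-times-compositional-factor convention up to a common constant.
#'
#' @param factors A `NormalizationFactors` object.
#' @return Named numeric vector of effective library sizes.
#' @export
effective_library_sizes <- function(factors) {
  factors$factors * exp(mean(log(factors$lib_sizes)))
}

#' FPKM gene expression
#'
#' Fragments per kilobase of gene per million effectively mapped fragments:
#' `count / (length_kb * effective_library_size_millions)`.
#'
#' @param counts A `GeneCountTable`.
#' @param factors A `NormalizationFactors` object from [tmm_factors()]; if
#'   `NULL`, factors of 1 (raw library sizes) are used.
#' @return Gene x sample numeric matrix of FPKM values.
#' @export
fpkm <- function(counts, factors = NULL) {
  stopifnot(inherits(counts, "GeneCountTable"))
  eff <- if (is.null(factors)) counts$totals else effective_library_sizes(factors)
  if (any(eff <= 0)) stop("zero effective library size")
  len_kb <- counts$gene_lengths[rownames(counts$counts)] / 1000
  if (any(len_kb <= 0)) stop("gene lengths must be > 0")
  sweep(counts$counts / len_kb, 2, eff[colnames(counts$counts)] / 1e6, "/")
}

#' Gene expression in profile units (au)
#'
#' The profile-unit (au) expression of a gene is the average transcription
#' profile height along the gene, directly comparable to part fluxes.
#'
#' @param profile A [transcription_profile()] (normalized to au).
#' @param gene One-row data.frame or list with `start` and `end` (1-based
#'   inclusive), e.g. a row of [annotation_genes()].
#' @return Mean profile value over the gene, in au.
#' @export
gene_expression_au <- function(profile, gene) {
  if (gene$end < gene$start) stop("zero-length gene")
  profile_mean(profile, gene$start, gene$end)
}

#' Rescale a raw coverage profile to comparable units
#'
#' Divides every value by `factor * library_size / 1e6`, the same
#' effective-library-size convention FPKM uses, so profiles are comparable
#' between samples.
#'
#' @param profile A raw-count [transcription_profile()].
#' @param factor Overall normalization factor for the sample (> 0).
#' @param library_size Library-size term of the scaling (default `1e6`, i.e.
#'   divide by the factor alone in millions-of-fragments units). The pipeline
#'   passes the geometric-mean total so overall factors compose correctly.
#' @return The rescaled [transcription_profile()].
#' @export
normalize_profiles <- function(profile, factor, library_size = 1e6) {
  if (factor <= 0) stop("normalization factor must be > 0")
  if (library_size <= 0) stop("library size must be > 0")
  scale_profile(profile, 1 / (factor * library_size / 1e6))
}
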