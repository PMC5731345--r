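#' Construct a ground-truth parameter set for simulation
#'
#' Holds the per-state promoter activities and per-part parameters from
#' which expected transcription profiles are traced and fragments sampled.
#'
#' @param promoter_activities Named list: state id -> named numeric vector of
#'   promoter activities deltaJ in au/s (>= 0).
#' @param terminator_Ts Named numeric vector: terminator -> fold strength
#'   (>= 1).
#' @param ribozyme_pc Named numeric vector: ribozyme -> cleavage efficiency
#'   in \\[0, 1\\].
#' @param antisense_promoters Optional data.frame with columns `name`,
#'   `position` (1-based TSS on the minus strand), `activity` (au/s):
#'   reverse promoters transcribing 3'->5'.
#' @param gamma mRNA degradation rate, s^-1 (default 0.0067).
#' @param sigma Lognormal noise sd applied multiplicatively to activities per
#'   state (default 0, noiseless).
#' @return Object of class `GroundTruth`.
#' @export
ground_truth <- function(promoter_activities, terminator_Ts = numeric(),
                         ribozyme_pc = numeric(),
                         antisense_promoters = NULL,
                         gamma = 0.0067, sigma = 0) {
  if (any(unlist(promoter_activities) < 0)) stop("activities must be >= 0")
  if (length(terminator_Ts) && any(terminator_Ts < 1)) stop("Ts must be >= 1")
  if (length(ribozyme_pc) && any(ribozyme_pc < 0 | ribozyme_pc > 1)) {
    stop("p_c must be in [0, 1]")
  }
  structure(list(promoter_activities = promoter_activities,
                 terminator_Ts = terminator_Ts, ribozyme_pc = ribozyme_pc,
                 antisense_promoters = antisense_promoters,
                 gamma = gamma, sigma = sigma),
            class = "GroundTruth")
}

#' Expected (noise-free) transcription profiles for one state
#'
#' Traces the deterministic steady-state profile M(x) = J(x) / gamma using
#' the same 5'->3' rules as [predict_profile()], with truth activities used
#' directly (no RPU conversion). Antisense promoters are traced 3'->5' on
#' the minus strand by mirroring the coordinate system.
#'
#' @param annotation A [circuit_annotation()] object.
#' @param truth A [ground_truth()].
#' @param state State id naming an element of `truth$promoter_activities`.
#' @param activities Optional override of the per-promoter activities for
#'   this state (used internally to inject noise).
#' @return List with `sense` and `antisense` [transcription_profile()]s in au.
#' @export
simulate_expected_profile <- function(annotation, truth, state,
                                      activities = NULL) {
  act <- if (is.null(activities)) truth$promoter_activities[[state]] else activities
  if (is.null(act)) stop("no activities for state '", state, "'")
  parts <- annotation$parts[annotation$parts$strand == "+", , drop = FALSE]
  N <- annotation$reference_length
  sense_vals <- .trace_profile(parts, act / truth$gamma, truth$terminator_Ts,
                               truth$ribozyme_pc, N)
  anti_vals <- numeric(N)
  ap <- truth$antisense_promoters
  if (!is.null(ap) && nrow(ap) > 0) {
    # mirror: an antisense promoter at position p transcribes toward 1, so in
    # mirrored coordinates (x' = N - x + 1) it is a forward promoter at
    # N - p + 1 with no downstream parts; height holds to the mirrored end.
    mirrored <- data.frame(name = ap$name, part_type = "promoter",
                           start = N - ap$position + 1L,
                           end = N - ap$position + 1L,
                           strand = "+", cut_site = NA_real_, tss = NA_real_,
                           stringsAsFactors = FALSE)
    strengths <- setNames(ap$activity / truth$gamma, ap$name)
    anti_mirror <- suppressWarnings(
      .trace_profile(mirrored, strengths, numeric(), numeric(), N))
    anti_vals <- rev(anti_mirror)
  }
  list(sense = transcription_profile(sense_vals, annotation$reference_id,
                                     "sense", state),
       antisense = transcription_profile(anti_vals, annotation$reference_id,
                                         "antisense", state))
}

# split a nonnegative piecewise-constant profile into maximal constant runs
# with positive value: the transcription-unit segments fragments come from
.profile_segments <- function(values, tol = 1e-9) {
  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  keep <- r$values > tol
  data.frame(start = starts[keep], end = ends[keep],
             abundance = r$values[keep],
             length = ends[keep] - starts[keep] + 1L)
}

#' Sample sequencing fragments from an expected profile
#'
#' The expected profile is decomposed into constant-abundance
#' transcription-unit segments. Each fragment first draws a length from the
#' fragment-length distribution (restricted to lengths that fit some
#' segment), then a segment with probability proportional to abundance times
#' the number of valid start positions, then a start uniform over those
#' positions. Fragments never cross segment boundaries, so interior coverage
#' is exactly proportional to segment abundance and the ends show exactly
#' the curvature the correction model expects.
#'
#' @param true_profile A [transcription_profile()] of expected abundance.
#' @param fld A [fld()] object.
#' @param depth Number of fragments to sample (>= 1).
#' @param seed Integer seed.
#' @param strand_class Strand label for the emitted fragments.
#' @return A [fragment_alignments()] table.
#' @export
sample_fragments <- function(true_profile, fld, depth, seed = 1,
                             strand_class = NULL) {
  if (depth < 1) stop("depth must be >= 1")
  if (is.null(strand_class)) strand_class <- true_profile$strand_class
  seg <- .profile_segments(true_profile$values)
  if (nrow(seg) == 0) {
    return(fragment_alignments(character(), integer(), integer(), character()))
  }
  usable <- fld$lengths <= max(seg$length)
  if (!any(usable)) {
    stop("every fragment length exceeds every transcription-unit segment")
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  pr <- fld$probabilities[usable] / sum(fld$probabilities[usable])
  len_pool <- fld$lengths[usable]
  lens <- len_pool[sample.int(length(len_pool), depth, replace = TRUE,
                              prob = pr)]
  starts <- integer(depth)
  for (L in unique(lens)) {
    pick <- lens == L
    m <- sum(pick)
    ok <- seg$length >= L
    w <- seg$abundance[ok] * (seg$length[ok] - L + 1)
    which_seg <- which(ok)[sample.int(sum(ok), m, replace = TRUE, prob = w / sum(w))]
    starts[pick] <- seg$start[which_seg] +
      floor(runif(m) * (seg$length[which_seg] - L + 1))
  }
  fragment_alignments(rep(true_profile$reference_id, depth),
                      starts, starts + lens - 1L,
                      rep(strand_class, depth))
}

#' Simulate a complete multi-state experiment
#'
#' For each state: apply lognormal noise (sd `truth$sigma`) to the promoter
#' activities, trace the expected sense/antisense profiles, and sample
#' fragments from both strands (depth split between strands in proportion to
#' profile mass). The truth record is bundled for recovery scoring, and the
#' whole experiment is reproducible from the seed.
#'
#' @param annotation A [circuit_annotation()] object.
#' @param truth A [ground_truth()].
#' @param states Character vector of state ids (subset of the truth's
#'   states); must be non-empty.
#' @param fld A [fld()] object.
#' @param depth Fragments per state.
#' @param seed Integer seed.
#' @return Object of class `SyntheticExperiment`: list with `annotation`,
#'   `truth`, `states`, `fld`, `depth`, `seed`, and per-state lists
#'   `fragments`, `profiles` (expected, in au) and `noisy_activities`.
#' @export
simulate_experiment <- function(annotation, truth, states, fld, depth,
                                seed = 1) {
  if (length(states) == 0) stop("state list is empty")
  missing_states <- setdiff(states, names(truth$promoter_activities))
  if (length(missing_states) > 0) {
    stop("truth has no activities for state(s): ",
         paste(missing_states, collapse = ", "))
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  fragments <- list(); profiles <- list(); noisy <- list()
  for (st in states) {
    act <- truth$promoter_activities[[st]]
    if (truth$sigma > 0) {
      act <- act * rlnorm(length(act), meanlog = 0, sdlog = truth$sigma)
    }
    noisy[[st]] <- act
    prof <- simulate_expected_profile(annotation, truth, st, activities = act)
    profiles[[st]] <- prof
    mass <- c(sense = sum(prof$sense$values),
              antisense = sum(prof$antisense$values))
    sub_seed <- sample.int(.Machine$integer.max, 2)
    fr <- list()
    if (mass["sense"] > 0) {
      n_sense <- if (mass["antisense"] > 0) {
        rbinom(1, depth, mass["sense"] / sum(mass))
      } else depth
      if (n_sense > 0) {
        fr$sense <- sample_fragments(prof$sense, fld, n_sense, sub_seed[1])
      }
      n_anti <- depth - n_sense
      if (mass["antisense"] > 0 && n_anti > 0) {
        fr$antisense <- sample_fragments(prof$antisense, fld, n_anti,
                                         sub_seed[2], "antisense")
      }
    } else if (mass["antisense"] > 0) {
      fr$antisense <- sample_fragments(prof$antisense, fld, depth,
                                       sub_seed[2], "antisense")
    }
    fragments[[st]] <- if (length(fr) == 0) {
      fragment_alignments(character(), integer(), integer(), character())
    } else do.call(rbind, c(fr, list(make.row.names = FALSE)))
  }
  structure(list(annotation = annotation, truth = truth, states = states,
                 fld = fld, depth = depth, seed = seed,
                 fragments = fragments, profiles = profiles,
                 noisy_activities = noisy),
            class = "SyntheticExperiment")
}

#' Recover part parameters from a synthetic experiment
#'
#' Runs the measurement pipeline on the sampled fragments of one state:
#' builds the strand profiles, rebuilds unit-local profiles, applies the
#' end-curvature correction, calibrates counts to au against one designated
#' reference gene (mirroring the RPU-conversion calibration the absolute au
#' scale requires; sequencing depth is relative), and measures every part.
#'
#' @param experiment A [simulate_experiment()] result.
#' @param state State id to analyse.
#' @param config An [analysis_config()]; its `gamma` should match the truth.
#' @param reference_gene Name of the calibration gene (default: the last CDS
#'   on the sense strand, i.e. the circuit output).
#' @param draws Monte-Carlo draws for the correction factor (default 1e6).
#' @return List with `measurements` (the [measure_parts()] table),
#'   `profile_au` (corrected, calibrated sense profile) and `calibration`
#'   (au per fragment-count scale factor).
#' @export
recover_parameters <- function(experiment, state,
                               config = analysis_config(gamma = experiment$truth$gamma),
                               reference_gene = NULL, draws = 1e6) {
  ann <- experiment$annotation
  frags <- experiment$fragments[[state]]
  N <- ann$reference_length
  genes <- annotation_genes(ann)
  genes <- genes[genes$strand == "+", , drop = FALSE]
  if (is.null(reference_gene)) reference_gene <- tail(genes$name, 1)

  emp_fld <- fragment_length_distribution(frags[frags$strand_class == "sense", ])
  C <- correction_factor(hypothetical_profile(emp_fld, draws = draws,
                                              seed = experiment$seed))
  raw <- build_strand_profiles(frags, N, reference_id = ann$reference_id,
                               sample_id = state)

  # correct each expected-plateau segment as its own transcription unit,
  # rebuilt from fully contained fragments (the correction's domain)
  segs <- .profile_segments(experiment$profiles[[state]]$sense$values)
  corrected <- raw$sense
  for (i in seq_len(nrow(segs))) {
    unit <- list(start = segs$start[i], end = segs$end[i])
    local <- unit_profile_from_fragments(frags, unit, N, "sense")
    fixed <- apply_correction(local, unit, C)
    corrected$values[unit$start:unit$end] <- fixed$values[unit$start:unit$end]
  }

  # calibrate counts -> au on the reference gene's true expected height
  g <- genes[genes$name == reference_gene, , drop = FALSE]
  if (nrow(g) == 0) stop("reference gene '", reference_gene, "' not found")
  true_au <- profile_mean(experiment$profiles[[state]]$sense, g$start, g$end)
  meas_cov <- profile_mean(corrected, g$start, g$end)
  if (meas_cov <= 0) stop("no coverage on reference gene; cannot calibrate")
  scale <- true_au / meas_cov
  profile_au <- scale_profile(corrected, scale)
  anti_au <- scale_profile(raw$antisense, scale)

  list(measurements = measure_parts(profile_au, ann, config, state, anti_au),
       profile_au = profile_au, calibration = scale)
}
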