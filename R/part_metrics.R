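#' Analysis configuration for part quantification
#'
#' @param gamma mRNA degradation rate in s^-1 (default 0.0067). At steady
#'   state the RNAP flux past a position is J(x) = gamma * M(x).
#' @param window_n Averaging window length in nt applied on either side of a
#'   part boundary to damp profile fluctuations (default 10).
#' @param min_flux_filter Minimum incoming RNAP flux in au/s below which
#'   terminator strengths and ribozyme cleavage efficiencies are flagged as
#'   unreliable rather than reported (default 1.0).
#' @return Object of class `AnalysisConfig`.
#' @export
analysis_config <- function(gamma = 0.0067, window_n = 10, min_flux_filter = 1.0) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (window_n < 1) stop("window_n must be >= 1")
  if (min_flux_filter < 0) stop("min_flux_filter must be >= 0")
  structure(list(gamma = gamma, window_n = as.integer(window_n),
                 min_flux_filter = min_flux_filter),
            class = "AnalysisConfig")
}

#' RNAP flux at a position
#'
#' At steady state dM/dt = J(x) - gamma * M(x) = 0, so J(x) = gamma * M(x).
#'
#' @param profile A [transcription_profile()] in au.
#' @param x Position, 1-based.
#' @param config An [analysis_config()].
#' @return Flux in au/s.
#' @export
rnap_flux_at <- function(profile, x, config = analysis_config()) {
  if (x < 1 || x > length(profile$values)) stop("position out of bounds")
  config$gamma * profile$values[x]
}

# mean of the n positions immediately upstream (ending at boundary - 1) or
# downstream (starting at boundary + 1) of a part boundary
.window_mean <- function(profile, boundary, n, side = c("upstream", "downstream")) {
  side <- match.arg(side)
  if (side == "upstream") {
    lo <- boundary - n; hi <- boundary - 1
  } else {
    lo <- boundary + 1; hi <- boundary + n
  }
  if (lo < 1 || hi > length(profile$values)) {
    stop(side, " window [", lo, ", ", hi, "] out of profile bounds")
  }
  mean(profile$values[lo:hi])
}

#' Promoter activity from a transcription profile
#'
#' The activity is the rise in RNAP flux across the part:
#' `deltaJ = (gamma / n) * (sum of M over the n nt just downstream of the
#' part - sum over the n nt just upstream)`. The upstream window subtracts
#' background flux originating upstream of the promoter. For a promoter
#' followed by a ribozyme insulator, pass the cleavage site as both
#' boundaries: the cleaved 5' RNA is lost during library preparation so the
#' profile rise occurs at the cut site, not at the promoter.
#'
#' @param profile A [transcription_profile()] in au.
#' @param boundary_up Last position before the part (windows end at
#'   `boundary_up - 1`); typically the part start.
#' @param boundary_down Last position of the part (downstream window starts
#'   at `boundary_down + 1`); typically the part end, or the ribozyme cut
#'   site for insulated promoters.
#' @param config An [analysis_config()].
#' @return Promoter activity deltaJ in au/s (may be negative; floor before
#'   log-scale fitting).
#' @export
promoter_activity <- function(profile, boundary_up, boundary_down,
                              config = analysis_config()) {
  n <- config$window_n
  up <- .window_mean(profile, boundary_up, n, "upstream")
  down <- .window_mean(profile, boundary_down, n, "downstream")
  config$gamma * (down - up)
}

#' Promoter activity for an annotated part
#'
#' Resolves the measurement boundaries for a promoter part. The upstream
#' (background) window always sits just before the promoter part, because
#' the background flux to subtract is whatever enters from upstream of the
#' promoter. If a ribozyme with an annotated cut site lies between the
#' promoter and the next terminator, the downstream window moves past the
#' cleavage site: the cleaved 5' RNA is lost during library preparation, so
#' the full promoter flux only appears in the profile downstream of the cut.
#'
#' @param profile A [transcription_profile()] in au.
#' @param part One-row data.frame for the promoter (row of
#'   `annotation$parts`).
#' @param annotation A [circuit_annotation()] object.
#' @param config An [analysis_config()].
#' @return deltaJ in au/s.
#' @export
promoter_activity_part <- function(profile, part, annotation,
                                   config = analysis_config()) {
  boundary_down <- .promoter_downstream_boundary(part, annotation)
  promoter_activity(profile, part$start, boundary_down, config)
}

# downstream measurement boundary for a promoter: the cut site of the next
# ribozyme before the next terminator, else the part's own end
.promoter_downstream_boundary <- function(part, annotation) {
  p <- annotation$parts
  downstream <- p[p$start > part$end & p$strand == "+", , drop = FALSE]
  if (nrow(downstream) > 0) {
    nxt_term <- suppressWarnings(
      min(downstream$start[downstream$part_type == "terminator"]))
    rz <- downstream[downstream$part_type == "ribozyme" &
                       downstream$start < nxt_term, , drop = FALSE]
    if (nrow(rz) > 0 && !is.na(rz$cut_site[1])) return(rz$cut_site[1])
  }
  part$end
}

# group sense-strand promoters that share a downstream measurement boundary
# (tandem pairs feeding one ribozyme are only measurable combined)
.promoter_groups <- function(annotation) {
  p <- annotation$parts
  idx <- which(p$part_type == "promoter" & p$strand == "+")
  if (length(idx) == 0) return(list())
  bnd <- vapply(idx, function(i) .promoter_downstream_boundary(p[i, ], annotation),
                numeric(1))
  split(idx, bnd)[order(unique(bnd))]
}

#' Terminator strength from a transcription profile
#'
#' The fold decrease in transcript level across the terminator:
#' `Ts = mean(M over n nt upstream of the part) / mean(M over n nt
#' downstream)`. The read-through fraction is approximately 1/Ts. The
#' measurement is flagged (`filtered = TRUE`) when the incoming flux
#' `gamma * upstream mean` is below `config$min_flux_filter`, because a
#' terminator fed by almost no RNAP cannot be quantified reliably.
#'
#' @param profile A [transcription_profile()] in au.
#' @param part One-row data.frame/list with `start`, `end` of the terminator.
#' @param config An [analysis_config()].
#' @return List with `Ts` (fold; `Inf` when the downstream window is zero),
#'   `incoming_flux` (au/s), `filtered` (logical) and `reason`.
#' @export
terminator_strength <- function(profile, part, config = analysis_config()) {
  n <- config$window_n
  up <- .window_mean(profile, part$start, n, "upstream")
  down <- .window_mean(profile, part$end, n, "downstream")
  incoming <- config$gamma * up
  filtered <- incoming < config$min_flux_filter
  reason <- if (filtered) "low input flux" else NA_character_
  Ts <- if (down == 0) {
    if (!filtered) reason <- "zero downstream window"
    Inf
  } else up / down
  list(Ts = Ts, incoming_flux = incoming,
       filtered = filtered || !is.finite(Ts), reason = reason)
}

#' Ribozyme cleavage efficiency from a transcription profile
#'
#' The self-cleaving ribozyme releases the 5' UTR, which is lost during
#' library preparation, so coverage upstream of the cut site comes only from
#' the uncleaved fraction. With the background flux J_bg entering from
#' upstream of the driving promoter's TSS:
#' `p_c = 1 - (J_before_cut - J_bg) / (J_after_cut - J_bg)`, clamped to
#' `[0, 1]`. Flagged when the flux leaving the ribozyme is below the
#' low-flux filter.
#'
#' @param profile A [transcription_profile()] in au.
#' @param ribozyme One-row data.frame/list with `start`, `end`, `cut_site`.
#' @param config An [analysis_config()].
#' @param background_boundary Position upstream of which the background
#'   window is taken (typically the driving promoter's start); `NULL` for no
#'   background subtraction.
#' @return List with `p_c` (fraction in \\[0, 1\\]), `leaving_flux` (au/s),
#'   `filtered`, `reason`.
#' @export
ribozyme_cleavage_efficiency <- function(profile, ribozyme,
                                         config = analysis_config(),
                                         background_boundary = NULL) {
  if (is.na(ribozyme$cut_site)) stop("ribozyme has no annotated cut_site")
  n <- config$window_n
  cut <- ribozyme$cut_site
  bg <- if (is.null(background_boundary)) 0 else
    config$gamma * .window_mean(profile, background_boundary, n, "upstream")
  before <- config$gamma * .window_mean(profile, cut, n, "upstream")
  after <- config$gamma * .window_mean(profile, cut, n, "downstream")
  leaving <- after
  filtered <- leaving < config$min_flux_filter
  denom <- after - bg
  p_c <- if (denom <= 0) NA_real_ else 1 - (before - bg) / denom
  if (!is.na(p_c)) p_c <- min(max(p_c, 0), 1)
  list(p_c = p_c, leaving_flux = leaving, filtered = filtered || is.na(p_c),
       reason = if (filtered) "low flux leaving ribozyme" else
         if (is.na(p_c)) "no net flux through ribozyme" else NA_character_)
}

#' Antisense transcription activity over a region
#'
#' @param antisense_profile The antisense-strand [transcription_profile()].
#' @param region List/data.frame with `start`, `end` (1-based inclusive).
#' @param config An [analysis_config()].
#' @return gamma times the mean antisense profile height, in au/s.
#' @export
antisense_activity <- function(antisense_profile, region,
                               config = analysis_config()) {
  config$gamma * profile_mean(antisense_profile, region$start, region$end)
}

#' Measure every promoter, terminator and ribozyme in a circuit
#'
#' Convenience wrapper producing the long-format part measurement table the
#' pipeline writes: one row per part per metric with filter flags.
#'
#' @param profile Sense-strand [transcription_profile()] in au.
#' @param annotation A [circuit_annotation()] object.
#' @param config An [analysis_config()].
#' @param state State/sample label for the rows.
#' @param antisense_profile Optional antisense profile; adds `antisense_J`
#'   rows per gene when given.
#' @return data.frame with columns `part`, `state`, `metric`, `value`,
#'   `units`, `filtered`, `reason`.
#' @export
measure_parts <- function(profile, annotation, config = analysis_config(),
                          state = NA_character_, antisense_profile = NULL) {
  p <- annotation$parts
  rows <- list()
  add <- function(part, metric, value, units, filtered = FALSE, reason = NA_character_) {
    rows[[length(rows) + 1]] <<- data.frame(
      part = part, state = state, metric = metric, value = value,
      units = units, filtered = filtered, reason = reason,
      stringsAsFactors = FALSE)
  }
  for (grp in .promoter_groups(annotation)) {
    first <- grp[which.min(p$start[grp])]
    boundary_down <- .promoter_downstream_boundary(p[first, ], annotation)
    dj <- tryCatch(
      promoter_activity(profile, p$start[first], boundary_down, config),
      error = function(e) NA_real_)
    add(paste(p$name[grp], collapse = "-"), "delta_J", dj, "au/s",
        filtered = is.na(dj),
        reason = if (is.na(dj)) "window out of bounds" else NA_character_)
  }
  for (i in which(p$part_type == "terminator" & p$strand == "+")) {
    ts <- tryCatch(terminator_strength(profile, p[i, ], config),
                   error = function(e) list(Ts = NA_real_, filtered = TRUE,
                                            reason = "window out of bounds"))
    add(p$name[i], "Ts", ts$Ts, "fold", ts$filtered, ts$reason)
  }
  for (i in which(p$part_type == "ribozyme" & p$strand == "+")) {
    # background is whatever enters the first promoter of the group driving
    # this ribozyme (promoters between the previous terminator and the cut)
    prev_term <- p$end[p$part_type == "terminator" & p$strand == "+" &
                         p$end < p$start[i]]
    lower <- if (length(prev_term) > 0) max(prev_term) else 0
    upstream_prom <- p[p$part_type == "promoter" & p$strand == "+" &
                         p$end < p$start[i] & p$start > lower, , drop = FALSE]
    bgb <- if (nrow(upstream_prom) > 0) min(upstream_prom$start) else NULL
    pc <- tryCatch(
      ribozyme_cleavage_efficiency(profile, p[i, ], config, bgb),
      error = function(e) list(p_c = NA_real_, filtered = TRUE,
                               reason = "window out of bounds"))
    add(p$name[i], "p_c", pc$p_c, "fraction", pc$filtered, pc$reason)
  }
  if (!is.null(antisense_profile)) {
    for (i in which(p$part_type == "cds" & p$strand == "+")) {
      aj <- tryCatch(antisense_activity(antisense_profile, p[i, ], config),
                     error = function(e) NA_real_)
      add(p$name[i], "antisense_J", aj, "au/s", filtered = is.na(aj))
    }
  }
  if (length(rows) == 0) {
    return(data.frame(part = character(), state = character(),
                      metric = character(), value = numeric(),
                      units = character(), filtered = logical(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
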