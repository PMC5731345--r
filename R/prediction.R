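#' Fit the RPU-to-au conversion factor
#'
#' Design tools report promoter strengths in relative promoter units (RPU)
#' measured by fluorescent-reporter cytometry; transcription profiles are in
#' arbitrary units (au). When both are available for the same output gene
#' across states, a zero-intercept least-squares fit of au on RPU gives the
#' proportional conversion factor.
#'
#' @param rpu Numeric vector of RPU values per state.
#' @param au Numeric vector of matching mean profile heights (au) per state.
#' @param intercept Fit an intercept too (diagnostics only; default FALSE).
#' @return Object of class `RpuConversion`: list with `slope` (au per RPU),
#'   `intercept`, `r_squared`, `n`.
#' @export
fit_rpu_conversion <- function(rpu, au, intercept = FALSE) {
  stopifnot(length(rpu) == length(au))
  ok <- !(rpu == 0 & au == 0)
  if (sum(ok) < 2) stop("need >= 2 states with nonzero values")
  x <- rpu[ok]; y <- au[ok]
  if (all(x == 0)) stop("all RPU values are zero")
  if (intercept) {
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2]); b0 <- unname(stats::coef(fit)[1])
    r2 <- summary(fit)$r.squared
  } else {
    slope <- sum(x * y) / sum(x * x)
    b0 <- 0
    ss_res <- sum((y - slope * x)^2)
    r2 <- 1 - ss_res / sum(y^2)
  }
  if (slope <= 0) stop("conversion slope must be > 0")
  structure(list(slope = slope, intercept = b0, r_squared = r2, n = sum(ok)),
            class = "RpuConversion")
}

#' Construct a design prediction
#'
#' @param promoter_strengths Named list: state id -> named numeric vector of
#'   per-promoter strengths (RPU, or au if `units = "au"`).
#' @param terminator_Ts Named numeric vector: terminator -> strength (fold,
#'   >= 1).
#' @param ribozyme_pc Named numeric vector: ribozyme -> cleavage efficiency
#'   in \\[0, 1\\].
#' @param units `"RPU"` (convert via [fit_rpu_conversion()]) or `"au"`.
#' @return Object of class `DesignPrediction`.
#' @export
design_prediction <- function(promoter_strengths, terminator_Ts, ribozyme_pc,
                              units = c("RPU", "au")) {
  units <- match.arg(units)
  if (any(unlist(promoter_strengths) < 0)) stop("promoter strengths must be >= 0")
  if (any(terminator_Ts < 1)) stop("terminator strengths must be >= 1")
  if (any(ribozyme_pc < 0 | ribozyme_pc > 1)) stop("p_c must be in [0, 1]")
  structure(list(promoter_strengths = promoter_strengths,
                 terminator_Ts = terminator_Ts, ribozyme_pc = ribozyme_pc,
                 units = units),
            class = "DesignPrediction")
}

# Trace a predicted piecewise-constant profile along ordered sense-strand
# parts. strengths_au: named per-promoter heights in au. Returns a numeric
# vector of length reference_length.
#
# Scan 5'->3'. At a promoter TSS the height rises by strength * (1 - p_c of
# the next downstream ribozyme before the next terminator). At a ribozyme
# cut site the height is set to (sum of strengths of promoters since the
# last terminator) + read-through level entering that promoter group. At a
# terminator end the height is multiplied by 1/Ts.
.trace_profile <- function(parts, strengths_au, terminator_Ts, ribozyme_pc,
                           reference_length, initial_height = 0) {
  vals <- numeric(reference_length)
  h <- initial_height
  pending <- 0          # summed strengths of promoters since last terminator
  read_through <- initial_height
  pos <- 1L
  emit <- function(upto) {
    if (upto >= pos) vals[pos:upto] <<- h
    pos <<- upto + 1L
  }
  p <- parts[order(parts$start), , drop = FALSE]
  next_rz_pc <- function(i) {
    # p_c of the next downstream ribozyme before the next terminator; 0 for
    # an uninsulated but terminated promoter; warn when the unit just runs
    # off the end of the reference
    for (j in seq_len(nrow(p))[-seq_len(i)]) {
      if (p$part_type[j] == "terminator") return(0)
      if (p$part_type[j] == "ribozyme") {
        pc <- ribozyme_pc[p$name[j]]
        return(if (is.na(pc)) 0 else unname(pc))
      }
    }
    warning("promoter '", p$name[i],
            "' has no downstream ribozyme or terminator before the ",
            "reference end; using p_c = 0")
    0
  }
  for (i in seq_len(nrow(p))) {
    ty <- p$part_type[i]
    if (ty == "promoter") {
      s <- strengths_au[p$name[i]]
      if (is.na(s)) s <- 0
      tss <- if (!is.na(p$tss[i])) p$tss[i] else p$start[i]
      emit(tss - 1L)
      if (pending == 0) read_through <- h   # level entering this promoter group
      h <- h + unname(s) * (1 - next_rz_pc(i))
      pending <- pending + unname(s)
    } else if (ty == "ribozyme" && !is.na(p$cut_site[i])) {
      emit(p$cut_site[i])
      h <- pending + read_through
    } else if (ty == "terminator") {
      emit(p$end[i])
      Ts <- terminator_Ts[p$name[i]]
      if (is.na(Ts)) Ts <- 1
      h <- h / unname(Ts)
      pending <- 0
      read_through <- h
    }
  }
  emit(reference_length)
  vals
}

#' Trace the predicted transcription profile for one state
#'
#' Scans the circuit 5' to 3' and traces the design-tool prediction: each
#' promoter raises the profile at its TSS by its predicted strength (in au)
#' times `(1 - p_c)` of the next downstream ribozyme; at a ribozyme cut site
#' the height is set to the combined strength of the upstream promoters
#' driving expression plus any read-through from the nearest upstream
#' terminator; past the end of a terminator the height is multiplied by
#' `1/Ts`.
#'
#' @param annotation A [circuit_annotation()] object (sense-strand parts are
#'   traced).
#' @param prediction A [design_prediction()].
#' @param conversion A [fit_rpu_conversion()] result; required when the
#'   prediction is in RPU, ignored for au.
#' @param state State id (must name an element of
#'   `prediction$promoter_strengths`).
#' @param initial_height Read-through entering the circuit 5' end, in au
#'   (default 0).
#' @return A sense-strand [transcription_profile()] in au.
#' @export
predict_profile <- function(annotation, prediction, conversion = NULL, state,
                            initial_height = 0) {
  s <- prediction$promoter_strengths[[state]]
  if (is.null(s)) stop("no predicted strengths for state '", state, "'")
  if (prediction$units == "RPU") {
    if (is.null(conversion)) stop("RPU predictions need a conversion factor")
    s <- s * conversion$slope
  }
  parts <- annotation$parts[annotation$parts$strand == "+", , drop = FALSE]
  vals <- .trace_profile(parts, s, prediction$terminator_Ts,
                         prediction$ribozyme_pc, annotation$reference_length,
                         initial_height)
  transcription_profile(vals, annotation$reference_id, "sense", state)
}

#' Compare predicted and observed per-gene expression
#'
#' @param predicted Named list: state -> predicted [transcription_profile()].
#' @param observed Named list: state -> observed profile in au (same states,
#'   same reference).
#' @param genes data.frame as from [annotation_genes()].
#' @return List with `table` (per gene/state predicted au, observed au and
#'   log-ratio) and `summary`: `slope` is the zero-intercept proportional fit
#'   of observed on predicted (2 means observed is uniformly twice the
#'   prediction), `r_squared` the squared correlation of log10 expression
#'   over positive pairs.
#' @export
compare_predicted_observed <- function(predicted, observed, genes) {
  if (nrow(genes) == 0) stop("empty gene list")
  states <- names(predicted)
  stopifnot(identical(sort(states), sort(names(observed))))
  rows <- list()
  for (st in states) {
    if (!identical(predicted[[st]]$reference_id, observed[[st]]$reference_id)) {
      stop("predicted and observed profiles are on different references")
    }
    for (i in seq_len(nrow(genes))) {
      pv <- profile_mean(predicted[[st]], genes$start[i], genes$end[i])
      ov <- profile_mean(observed[[st]], genes$start[i], genes$end[i])
      rows[[length(rows) + 1]] <- data.frame(
        gene = genes$name[i], state = st, predicted_au = pv, observed_au = ov,
        log10_ratio = ifelse(pv > 0 & ov > 0, log10(ov / pv), NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  ok <- tab$predicted_au > 0 & tab$observed_au > 0
  p <- tab$predicted_au[ok]; o <- tab$observed_au[ok]
  r2 <- if (length(unique(p)) > 1) stats::cor(log10(p), log10(o))^2 else 1
  list(table = tab,
       summary = list(slope = sum(p * o) / sum(p * p),
                      r_squared = r2, n = sum(ok)))
}
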