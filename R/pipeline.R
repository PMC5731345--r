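#' Build a pipeline run configuration
#'
#' @param annotation Path to the circuit GFF3 annotation.
#' @param fragments Named list/vector: sample id -> BED6 fragment table path
#'   (needed by `profile`).
#' @param truth Path to a YAML ground-truth file (needed by `simulate`); see
#'   the package vignette for the schema.
#' @param devices Path to a YAML device-definition file (needed by
#'   `devices`).
#' @param predictions Path to a YAML/JSON design-prediction file (needed by
#'   `predict`).
#' @param outdir Output directory.
#' @param gamma,window_n,min_flux mRNA degradation rate (s^-1), averaging
#'   window (nt), low-flux filter (au/s).
#' @param seed Integer seed used for every stochastic step.
#' @param depth Fragments per state for `simulate`.
#' @param draws Monte-Carlo draws for the correction factor.
#' @param library_orientation BED strand convention (`"reverse"` default).
#' @return Object of class `RunConfig` (a named list).
#' @export
run_config <- function(annotation = NULL, fragments = NULL, truth = NULL,
                       devices = NULL, predictions = NULL,
                       outdir = "circuitseq_out", gamma = 0.0067,
                       window_n = 10, min_flux = 1.0, seed = 1,
                       depth = 1e5, draws = 1e6,
                       library_orientation = "reverse") {
  structure(list(annotation = annotation, fragments = fragments,
                 truth = truth, devices = devices, predictions = predictions,
                 outdir = outdir, gamma = gamma, window_n = window_n,
                 min_flux = min_flux, seed = as.integer(seed),
                 depth = depth, draws = draws,
                 library_orientation = library_orientation),
            class = "RunConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(run_config, yaml::read_yaml(path))
}

.write_run_metadata <- function(config, subcommand, outputs) {
  meta <- list(
    tool = "circuitseq",
    version = as.character(utils::packageVersion("circuitseq")),
    subcommand = subcommand,
    seed = config$seed,
    config = config[!vapply(config, is.null, logical(1))],
    config_hash = digest_config(config),
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(config$outdir, paste0(subcommand, ".run.json"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' Stable hash of a run configuration
#'
#' @param config A `RunConfig`.
#' @return Hex md5 string over the serialized non-path options.
#' @export
digest_config <- function(config) {
  cfg <- config[!vapply(config, is.null, logical(1))]
  cfg$outdir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(cfg), vapply(cfg, function(x)
    paste(format(x), collapse = ","), character(1)), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a YAML ground-truth file
#'
#' Schema: `gamma`, `sigma`, `promoter_activities` (state -> promoter ->
#' au/s), `terminator_Ts`, `ribozyme_pc`, optional `antisense_promoters`
#' (list of `name`/`position`/`activity`).
#'
#' @param path YAML path.
#' @return A [ground_truth()].
#' @export
read_ground_truth <- function(path) {
  y <- yaml::read_yaml(path)
  ap <- NULL
  if (!is.null(y$antisense_promoters)) {
    ap <- do.call(rbind, lapply(y$antisense_promoters, function(a)
      data.frame(name = a$name, position = a$position, activity = a$activity,
                 stringsAsFactors = FALSE)))
  }
  ground_truth(
    promoter_activities = lapply(y$promoter_activities, function(s) unlist(s)),
    terminator_Ts = unlist(y$terminator_Ts %||% list()),
    ribozyme_pc = unlist(y$ribozyme_pc %||% list()),
    antisense_promoters = ap,
    gamma = y$gamma %||% 0.0067,
    sigma = y$sigma %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one pipeline subcommand
#'
#' Orchestrates the package over files: `simulate` writes per-state BED6
#' fragment tables and true-profile bedGraphs from a YAML truth file;
#' `profile` turns BED6 fragment tables into strand-specific bedGraph
#' profiles and a gene-count TSV; `normalize` computes TMM factors and FPKM
#' from a count TSV; `correct` applies the end-curvature correction to every
#' annotated gene of each profile; `parts` measures every part per sample;
#' `devices` fits sensor/gate response functions from a part-measurement
#' table plus a device YAML; `predict` traces predicted profiles from a
#' design-prediction file. Every subcommand writes a run-metadata JSON
#' (version, config hash, seed) beside its outputs; on error, partial
#' outputs are removed.
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @param subcommand One of `"simulate"`, `"profile"`, `"correct"`,
#'   `"normalize"`, `"parts"`, `"devices"`, `"predict"`.
#' @return Invisible character vector of output paths.
#' @export
run_pipeline <- function(config, subcommand = c("simulate", "profile",
                                                "correct", "normalize",
                                                "parts", "devices",
                                                "predict")) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  note <- function(p) { written <<- c(written, p); p }
  ok <- FALSE
  on.exit(if (!ok) unlink(written))

  need <- function(field) {
    p <- config[[field]]
    if (is.null(p)) stop("config is missing '", field, "' (required by ",
                         subcommand, ")")
    missing_files <- unlist(p)[!file.exists(unlist(p))]
    if (length(missing_files) > 0) stop("file not found: ", missing_files[1])
    p
  }
  cfg_analysis <- analysis_config(config$gamma, config$window_n,
                                  config$min_flux)

  if (subcommand == "simulate") {
    ann <- load_annotation(need("annotation"))
    truth <- read_ground_truth(need("truth"))
    states <- names(truth$promoter_activities)
    flen <- fld(100L, 1)  # default: 100-nt fragments; override via truth yaml
    exp_ <- simulate_experiment(ann, truth, states, flen, config$depth,
                                config$seed)
    for (st in states) {
      f <- exp_$fragments[[st]]
      bed <- data.frame(chrom = f$reference_id, start = f$start - 1L,
                        end = f$end,
                        name = sprintf("frag%06d", seq_len(nrow(f))),
                        score = 0L,
                        strand = ifelse((f$strand_class == "sense") ==
                                          (config$library_orientation == "forward"),
                                        "+", "-"))
      bp <- file.path(config$outdir, paste0(st, ".fragments.bed"))
      write.table(bed, note(bp), sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
      note(write_profile_bedgraph(
        exp_$profiles[[st]]$sense,
        file.path(config$outdir, paste0(st, ".true.sense.bedgraph"))))
    }
  } else if (subcommand == "profile") {
    ann <- load_annotation(need("annotation"))
    frag_paths <- need("fragments")
    genes <- annotation_genes(ann)
    tabs <- list()
    for (sid in names(frag_paths)) {
      fr <- load_fragments(frag_paths[[sid]], config$library_orientation)
      prof <- build_strand_profiles(fr, ann$reference_length,
                                    ann$reference_id, sid)
      for (sc in c("sense", "antisense")) {
        note(write_profile_bedgraph(
          prof[[sc]],
          file.path(config$outdir, sprintf("%s.%s.bedgraph", sid, sc))))
      }
      tabs[[sid]] <- count_gene_fragments(fr, genes, sample_id = sid)
    }
    counts <- bind_gene_counts(tabs)
    cp <- file.path(config$outdir, "gene_counts.tsv")
    write.table(data.frame(gene = rownames(counts$counts),
                           length_nt = counts$gene_lengths,
                           counts$counts, check.names = FALSE),
                note(cp), sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (subcommand == "normalize") {
    frag_paths <- need("fragments")  # reuse: sample -> gene_counts col
    cp <- file.path(config$outdir, "gene_counts.tsv")
    if (!file.exists(cp)) stop("run 'profile' first: ", cp, " not found")
    tab <- read.table(cp, header = TRUE, sep = "\t", check.names = FALSE)
    m <- as.matrix(tab[, -(1:2), drop = FALSE])
    rownames(m) <- tab$gene
    counts <- structure(list(counts = m,
                             gene_lengths = setNames(tab$length_nt, tab$gene),
                             totals = colSums(m)),
                        class = "GeneCountTable")
    nf <- tmm_factors(counts)
    note(file.path(config$outdir, "tmm_factors.tsv"))
    write.table(data.frame(sample = names(nf$factors), factor = nf$factors,
                           reference_sample = nf$reference_sample),
                file.path(config$outdir, "tmm_factors.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    fp <- fpkm(counts, nf)
    note(file.path(config$outdir, "fpkm.tsv"))
    write.table(data.frame(gene = rownames(fp), fp, check.names = FALSE),
                file.path(config$outdir, "fpkm.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (subcommand == "correct") {
    ann <- load_annotation(need("annotation"))
    frag_paths <- need("fragments")
    for (sid in names(frag_paths)) {
      fr <- load_fragments(frag_paths[[sid]], config$library_orientation)
      emp <- fragment_length_distribution(fr)
      C <- correction_factor(hypothetical_profile(emp, draws = config$draws,
                                                  seed = config$seed))
      prof <- build_strand_profiles(fr, ann$reference_length,
                                    ann$reference_id, sid)$sense
      for (i in seq_len(nrow(ann$parts))) {
        if (ann$parts$part_type[i] != "cds") next
        unit <- list(start = ann$parts$start[i], end = ann$parts$end[i])
        local <- unit_profile_from_fragments(fr, unit, ann$reference_length)
        fixed <- apply_correction(local, unit, C)
        prof$values[unit$start:unit$end] <- fixed$values[unit$start:unit$end]
      }
      note(write_profile_bedgraph(
        prof, file.path(config$outdir,
                        sprintf("%s.sense.corrected.bedgraph", sid))))
      note(write_correction_factor(
        C, file.path(config$outdir, sprintf("%s.correction.tsv", sid))))
    }
  } else if (subcommand == "parts") {
    ann <- load_annotation(need("annotation"))
    frag_paths <- need("fragments")
    all_rows <- list()
    for (sid in names(frag_paths)) {
      fr <- load_fragments(frag_paths[[sid]], config$library_orientation)
      prof <- build_strand_profiles(fr, ann$reference_length,
                                    ann$reference_id, sid)
      all_rows[[sid]] <- measure_parts(prof$sense, ann, cfg_analysis, sid,
                                       prof$antisense)
    }
    mp <- file.path(config$outdir, "part_measurements.tsv")
    write.table(do.call(rbind, all_rows), note(mp), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else if (subcommand == "devices") {
    dev <- yaml::read_yaml(need("devices"))
    mp <- file.path(config$outdir, "part_measurements.tsv")
    if (!file.exists(mp)) stop("run 'parts' first: ", mp, " not found")
    meas <- read.table(mp, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    results <- list()
    for (d in dev$devices) {
      obs <- do.call(rbind, lapply(d$states, function(s) {
        out <- meas$value[meas$part == d$output_promoter &
                            meas$state == s$id & meas$metric == "delta_J"]
        jin <- sum(vapply(d$input_promoters, function(ip)
          max(meas$value[meas$part == ip & meas$state == s$id &
                           meas$metric == "delta_J"], 0), numeric(1))) +
          (s$J0 %||% 0)
        data.frame(state = s$id, J_in = jin, dJ_out = max(out, 0))
      }))
      fit <- fit_gate_response(obs)
      results[[d$name]] <- list(parameters = fit$rf[c("dJ_min", "dJ_max",
                                                      "K", "n_coop")],
                                residual = fit$residual,
                                converged = fit$converged,
                                observations = obs)
    }
    jp <- file.path(config$outdir, "device_fits.json")
    jsonlite::write_json(results, note(jp), auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else if (subcommand == "predict") {
    ann <- load_annotation(need("annotation"))
    pred_y <- yaml::read_yaml(need("predictions"))
    pred <- design_prediction(
      lapply(pred_y$promoter_strengths, unlist),
      unlist(pred_y$terminator_Ts %||% list()),
      unlist(pred_y$ribozyme_pc %||% list()),
      units = pred_y$units %||% "au")
    conv <- if (!is.null(pred_y$rpu_slope)) {
      structure(list(slope = pred_y$rpu_slope, intercept = 0,
                     r_squared = NA_real_, n = NA_integer_),
                class = "RpuConversion")
    } else NULL
    for (st in names(pred$promoter_strengths)) {
      pp <- predict_profile(ann, pred, conv, st)
      note(write_profile_bedgraph(
        pp, file.path(config$outdir,
                      sprintf("%s.predicted.sense.bedgraph", st))))
    }
  }

  note(.write_run_metadata(config, subcommand, written))
  ok <- TRUE
  invisible(written)
}
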