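#' Part types recognized by the pipeline
#'
#' @return Character vector of valid part type names.
#' @export
part_types <- function() {
  c("promoter", "ribozyme", "rbs", "cds", "terminator", "scar", "other")
}

#' Construct a circuit annotation
#'
#' A `CircuitAnnotation` holds the ordered (5'->3' on the sense strand) list
#' of genetic parts making up a circuit on one reference sequence. All
#' coordinates are 1-based inclusive, the GFF/GRanges convention.
#'
#' @param parts data.frame with columns `name`, `part_type`, `start`, `end`,
#'   `strand` (`"+"` or `"-"`), and optionally `cut_site` (absolute 1-based
#'   coordinate of a ribozyme cleavage site) and `tss` (absolute transcription
#'   start site for promoters). `NA` where an attribute does not apply.
#' @param reference_id Name of the reference sequence the parts live on.
#' @param reference_length Length of the reference in nucleotides.
#' @return An object of class `CircuitAnnotation`.
#' @export
circuit_annotation <- function(parts, reference_id, reference_length) {
  stopifnot(is.data.frame(parts), nrow(parts) >= 1)
  required <- c("name", "part_type", "start", "end", "strand")
  missing_cols <- setdiff(required, names(parts))
  if (length(missing_cols) > 0) {
    stop("parts is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"cut_site" %in% names(parts)) parts$cut_site <- NA_real_
  if (!"tss" %in% names(parts)) parts$tss <- NA_real_
  bad_type <- !parts$part_type %in% part_types()
  if (any(bad_type)) {
    stop("unknown part type '", parts$part_type[which(bad_type)[1]],
         "' for part '", parts$name[which(bad_type)[1]], "'")
  }
  if (any(parts$start > parts$end)) {
    stop("part with start > end: ", parts$name[which(parts$start > parts$end)[1]])
  }
  if (any(parts$end > reference_length)) {
    stop("part extends beyond reference: ",
         parts$name[which(parts$end > reference_length)[1]])
  }
  cs <- parts$cut_site
  bad_cut <- !is.na(cs) & (cs < parts$start | cs > parts$end)
  if (any(bad_cut)) {
    stop("cut_site outside part boundaries for part '",
         parts$name[which(bad_cut)[1]], "'")
  }
  parts <- parts[order(parts$start, parts$end), , drop = FALSE]
  rownames(parts) <- NULL
  .check_same_type_overlaps(parts)
  structure(
    list(parts = parts, reference_id = reference_id,
         reference_length = as.integer(reference_length)),
    class = "CircuitAnnotation"
  )
}

.check_same_type_overlaps <- function(parts) {
  for (ty in unique(parts$part_type)) {
    for (st in unique(parts$strand)) {
      p <- parts[parts$part_type == ty & parts$strand == st, , drop = FALSE]
      if (nrow(p) < 2) next
      p <- p[order(p$start), , drop = FALSE]
      overlap <- p$start[-1] <= p$end[-nrow(p)]
      if (any(overlap)) {
        i <- which(overlap)[1]
        stop("overlapping parts of the same type (", ty, ") on strand ", st,
             ": '", p$name[i], "' and '", p$name[i + 1], "'")
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.CircuitAnnotation <- function(x, ...) {
  cat("CircuitAnnotation:", nrow(x$parts), "parts on", x$reference_id,
      sprintf("(%d nt)\n", x$reference_length))
  print(table(x$parts$part_type))
  invisible(x)
}

#' Load a circuit part annotation from a GFF3 file
#'
#' Parses a GFF3 file whose feature types (column 3) or `part_type`
#' attributes name the part classes returned by [part_types()]. GFF
#' coordinates are 1-based inclusive and are kept as such. Recognized
#' attributes: `Name` (part identifier), `part_type`, `cut_site` (absolute
#' ribozyme cleavage coordinate), `tss` (absolute transcription start site).
#'
#' @param gff_path Path to a GFF3 file.
#' @param reference_length Reference length in nt; if `NULL`, taken from a
#'   `##sequence-region` pragma or the maximum feature end.
#' @return A [circuit_annotation()] object.
#' @export
load_annotation <- function(gff_path, reference_length = NULL) {
  if (!file.exists(gff_path)) stop("annotation file not found: ", gff_path)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  if (length(gr) == 0) stop("no features in ", gff_path)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  if ("part_type" %in% names(md)) {
    pt <- as.character(md$part_type)
    type <- ifelse(is.na(pt), type, pt)
  }
  # "gene" rows are tolerated (used by gene-level counting) and mapped to cds
  type[type == "gene"] <- "cds"
  bad <- !type %in% part_types()
  if (any(bad)) {
    i <- which(bad)[1]
    stop("unknown part type '", type[i], "' at ", gff_path, " line for feature '",
         if (!is.null(md$Name)) md$Name[i] else i, "'")
  }
  nm <- if ("Name" %in% names(md)) as.character(md$Name) else
    if ("ID" %in% names(md)) as.character(md$ID) else
      paste0("part", seq_along(gr))
  to_num <- function(col) {
    if (col %in% names(md)) suppressWarnings(as.numeric(as.character(md[[col]])))
    else rep(NA_real_, length(gr))
  }
  parts <- data.frame(
    name = nm,
    part_type = type,
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    cut_site = to_num("cut_site"),
    tss = to_num("tss"),
    stringsAsFactors = FALSE
  )
  parts$strand[!parts$strand %in% c("+", "-")] <- "+"
  ref <- as.character(GenomeInfoDb::seqnames(gr))[1]
  if (is.null(reference_length)) {
    sl <- GenomeInfoDb::seqlengths(gr)[ref]
    if (is.na(sl)) {
      # rtracklayer does not surface ##sequence-region pragmas; parse directly
      hdr <- grep("^##sequence-region", readLines(gff_path, n = 100), value = TRUE)
      tok <- strsplit(hdr, "[[:space:]]+")
      m <- vapply(tok, function(t) identical(t[2], ref), logical(1))
      sl <- if (any(m)) as.numeric(tok[[which(m)[1]]][4]) else NA_real_
    }
    reference_length <- if (!is.na(sl)) sl else max(parts$end)
  }
  circuit_annotation(parts, ref, reference_length)
}

#' Write a circuit annotation to GFF3
#'
#' @param annotation A [circuit_annotation()] object.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  p <- annotation$parts
  attrs <- paste0("Name=", p$name)
  attrs <- ifelse(is.na(p$cut_site), attrs,
                  paste0(attrs, ";cut_site=", format(p$cut_site, scientific = FALSE)))
  attrs <- ifelse(is.na(p$tss), attrs,
                  paste0(attrs, ";tss=", format(p$tss, scientific = FALSE)))
  lines <- c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d", annotation$reference_id,
            annotation$reference_length),
    sprintf("%s\tcircuitseq\t%s\t%d\t%d\t.\t%s\t.\t%s",
            annotation$reference_id, p$part_type, p$start, p$end, p$strand, attrs)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Extract gene (CDS) intervals from an annotation
#'
#' @param annotation A [circuit_annotation()] object.
#' @return data.frame with columns `name`, `start`, `end`, `strand`, `length`.
#' @export
annotation_genes <- function(annotation) {
  g <- annotation$parts[annotation$parts$part_type == "cds", , drop = FALSE]
  data.frame(name = g$name, start = g$start, end = g$end, strand = g$strand,
             length = g$end - g$start + 1L, stringsAsFactors = FALSE)
}
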