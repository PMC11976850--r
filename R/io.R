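# File formats: evidence tables (native + MaxQuant dialect), MS1 point
# lists, and result tables.

EVIDENCE_SCHEMA <- c("modified_sequence", "charge", "rt_obs", "rt_start",
                     "rt_end", "im_center", "im_length", "intensity")

# declarative column-name maps per dialect; applied before schema checks
COLUMN_DIALECTS <- list(
  maxquant = c(
    "Modified sequence" = "modified_sequence",
    "Charge" = "charge",
    "Retention time" = "rt_obs",
    "Calibrated retention time start" = "rt_start",
    "Calibrated retention time finish" = "rt_end",
    "Retention time start" = "rt_start",
    "Retention time finish" = "rt_end",
    "1/K0" = "im_center",
    "1/K0 length" = "im_length",
    "Intensity" = "intensity",
    "Species" = "species",
    "Proteins" = "proteins"
  )
)

#' Read an evidence table
#'
#' Tab-separated evidence with the native schema columns
#' (`modified_sequence`, `charge`, `rt_obs`, `rt_start`, `rt_end`,
#' `im_center`, `im_length`, `intensity`[, `species`]). MaxQuant-style
#' headers ("Modified sequence", "1/K0", ...) are mapped automatically;
#' unknown extra columns are ignored. Rows violating the record
#' invariants (`rt_start <= rt_obs <= rt_end`, `im_length >= 0`,
#' `charge >= 1`, nonnegative intensity) are dropped with a logged count.
#'
#' @param path TSV file.
#' @param source_tag `"experiment"` or `"reference"`.
#' @return evidence data.frame with a `source` column.
#' @export
read_evidence_table <- function(path, source_tag = c("experiment", "reference")) {
  source_tag <- match.arg(source_tag)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  for (dialect in COLUMN_DIALECTS) {
    hit <- names(tab) %in% names(dialect)
    names(tab)[hit] <- dialect[names(tab)[hit]]
  }
  missing <- setdiff(EVIDENCE_SCHEMA, names(tab))
  if (length(missing)) {
    stop("evidence table ", path, " is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"species" %in% names(tab)) tab$species <- NA_character_
  out <- tab[, c(EVIDENCE_SCHEMA, "species"), drop = FALSE]
  out$charge <- as.integer(out$charge)
  for (col in setdiff(EVIDENCE_SCHEMA, c("modified_sequence", "charge"))) {
    out[[col]] <- as.numeric(out[[col]])
  }
  valid <- !is.na(out$modified_sequence) & nzchar(out$modified_sequence) &
    !is.na(out$charge) & out$charge >= 1 &
    !is.na(out$rt_obs) & !is.na(out$rt_start) & !is.na(out$rt_end) &
    out$rt_start <= out$rt_obs & out$rt_obs <= out$rt_end &
    !is.na(out$im_length) & out$im_length >= 0 &
    !is.na(out$im_center) &
    !is.na(out$intensity) & out$intensity >= 0
  if (any(!valid)) {
    stage_log("read_evidence_table", nrow(out), sum(valid),
              sprintf("%s: %d invalid rows dropped", basename(path),
                      sum(!valid)))
  }
  out <- out[valid, , drop = FALSE]
  out$source <- source_tag
  rownames(out) <- NULL
  out
}

#' Write an evidence table in the native schema
#'
#' @param evidence evidence data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_evidence_table <- function(evidence, path) {
  cols <- c(EVIDENCE_SCHEMA, intersect("species", names(evidence)))
  utils::write.table(evidence[, cols, drop = FALSE], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read MS1 frames from a point-list table
#'
#' TSV with columns `frame_id`, `scan_time_min`, `mz`, `inv_k0`,
#' `intensity`. Points are grouped by frame id and frames ordered by scan
#' time; scan time must increase strictly with frame id.
#'
#' @param path TSV file.
#' @return list of `ms1_frame`.
#' @export
read_frames <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("frame_id", "scan_time_min", "mz", "inv_k0", "intensity")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("frame table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(tab) == 0) return(list())
  ids <- sort(unique(tab$frame_id))
  times <- vapply(ids, function(id) {
    tab$scan_time_min[match(id, tab$frame_id)]
  }, numeric(1))
  if (any(diff(times) <= 0)) {
    stop("scan_time_min must increase strictly with frame_id")
  }
  lapply(seq_along(ids), function(i) {
    sub <- tab[tab$frame_id == ids[i], , drop = FALSE]
    ms1_frame(ids[i], times[i],
              data.frame(mz = sub$mz, im = sub$inv_k0,
                         intensity = sub$intensity))
  })
}

#' Write MS1 frames as a point-list table
#'
#' @param frames list of `ms1_frame`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  rows <- lapply(frames, function(f) {
    if (nrow(f$points) == 0) return(NULL)
    data.frame(frame_id = f$frame_id, scan_time_min = f$scan_time,
               mz = f$points$mz, inv_k0 = f$points$im,
               intensity = f$points$intensity)
  })
  rows <- Filter(Negate(is.null), rows)
  tab <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(frame_id = integer(0), scan_time_min = numeric(0),
               mz = numeric(0), inv_k0 = numeric(0), intensity = numeric(0))
  }
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

RESULT_COLUMNS <- c("sequence", "charge", "is_decoy", "inferred_intensity",
                    "confidence", "passed_intensity_filter", "passed_tdc",
                    "passed_signal_competition", "fdr_at_score")

#' Write the per-candidate report and the FDR table
#'
#' Two TSVs: `<prefix>_candidates.tsv` with one row per scored candidate
#' and its filter-stage flags, and `<prefix>_fdr.tsv` with the
#' threshold-vs-FDR table. Values survive a write/read round trip to at
#' least 6 significant digits.
#'
#' @param scored data.frame with the result columns (see the candidates
#'   report schema); extra columns are carried along after the schema
#'   columns.
#' @param fdr_table the FDR sweep table.
#' @param prefix output path prefix.
#' @return named list of the two paths, invisibly.
#' @export
write_results <- function(scored, fdr_table, prefix) {
  p1 <- paste0(prefix, "_candidates.tsv")
  p2 <- paste0(prefix, "_fdr.tsv")
  cols <- c(RESULT_COLUMNS, setdiff(names(scored), RESULT_COLUMNS))
  if (nrow(scored) == 0) {
    scored <- stats::setNames(
      data.frame(matrix(ncol = length(RESULT_COLUMNS), nrow = 0)),
      RESULT_COLUMNS)
    cols <- RESULT_COLUMNS
  }
  utils::write.table(format(scored[, cols, drop = FALSE], digits = 15,
                            trim = TRUE, scientific = NA),
                     p1, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(format(fdr_table, digits = 15, trim = TRUE),
                     p2, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(candidates = p1, fdr = p2))
}

#' Read back result tables written by [write_results()]
#'
#' @param prefix the prefix used when writing.
#' @return list with `candidates` and `fdr` data.frames.
#' @export
read_results <- function(prefix) {
  list(candidates = utils::read.delim(paste0(prefix, "_candidates.tsv"),
                                      stringsAsFactors = FALSE),
       fdr = utils::read.delim(paste0(prefix, "_fdr.tsv"),
                               stringsAsFactors = FALSE))
}
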