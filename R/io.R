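#' Write a force-extension curve to TSV with a JSON sidecar
#'
#' The TSV has header `extension_nm<TAB>force_pN`; molecule metadata (n_bp,
#' concentration_nM, pulling_rate_nm_s, direction) and a row-count checksum go
#' in `<path>.json`.
#'
#' @param curve A [fec()] object.
#' @param path Output TSV path.
#' @param digits Significant digits written (default 9).
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, digits = 9) {
  stopifnot(inherits(curve, "fec"))
  d <- data.frame(extension_nm = signif(curve$extension, digits),
                  force_pN = signif(curve$force, digits))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(n_bp = curve$n_bp, concentration_nM = curve$concentration,
               pulling_rate_nm_s = curve$pulling_rate, direction = curve$direction,
               n_rows = nrow(d))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a force-extension curve from TSV + JSON sidecar
#'
#' @param path TSV path written by [write_curve()] (sidecar at `<path>.json`).
#' @return A [fec()] object.
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop(sprintf("missing sidecar: %s", side), call. = FALSE)
  d <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("extension_nm", "force_pN")
  if (!all(need %in% names(d)))
    stop(sprintf("missing columns: %s", paste(setdiff(need, names(d)), collapse = ", ")),
         call. = FALSE)
  num <- lapply(need, function(col) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad) > 0)
      stop(sprintf("non-numeric value in column '%s' at data row %d: '%s'",
                   col, bad[1], d[[col]][bad[1]]), call. = FALSE)
    v
  })
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!is.null(meta$n_rows) && meta$n_rows != nrow(d))
    stop(sprintf("row-count checksum mismatch: sidecar says %d, file has %d (truncated file?)",
                 meta$n_rows, nrow(d)), call. = FALSE)
  if (is.null(meta$n_bp)) stop("sidecar lacks n_bp", call. = FALSE)
  fec(num[[1]], num[[2]], n_bp = meta$n_bp,
      concentration = meta$concentration_nM %||% 0,
      pulling_rate = meta$pulling_rate_nm_s %||% NA_real_,
      direction = meta$direction %||% "extend")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

#' Write traced molecules to TSV (plus optional annotation TSV)
#'
#' Trace dialect: `molecule_id<TAB>point_index<TAB>x_nm<TAB>y_nm`; annotation
#' dialect: `molecule_id<TAB>kind<TAB>start_index<TAB>end_index`.
#'
#' @param traces List of [trace2d()] objects.
#' @param path Output trace TSV path.
#' @param annotations_path Optional annotation TSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, annotations_path = NULL) {
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(molecule_id = tr$molecule_id,
               point_index = seq_len(nrow(tr$points)),
               x_nm = tr$points[, 1], y_nm = tr$points[, 2])
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(annotations_path)) {
    ann <- do.call(rbind, lapply(traces, function(tr) {
      if (is.null(tr$annotations) || nrow(tr$annotations) == 0) return(NULL)
      cbind(molecule_id = tr$molecule_id,
            tr$annotations[, c("kind", "start_index", "end_index")])
    }))
    if (is.null(ann))
      ann <- data.frame(molecule_id = character(0), kind = character(0),
                        start_index = integer(0), end_index = integer(0))
    utils::write.table(ann, annotations_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read traced molecules from TSV (plus optional annotation TSV)
#'
#' Points are grouped by `molecule_id` and ordered by `point_index` (shuffled
#' rows are accepted); annotations are attached by molecule id.
#'
#' @param path Trace TSV path (dialect of [write_traces()]).
#' @param annotations_path Optional annotation TSV path.
#' @param n_bp Molecule size recorded on every trace (default NA).
#' @return A named list of [trace2d()] objects.
#' @export
read_traces <- function(path, annotations_path = NULL, n_bp = NA_real_) {
  d <- utils::read.delim(path, check.names = FALSE)
  need <- c("molecule_id", "point_index", "x_nm", "y_nm")
  if (!all(need %in% names(d)))
    stop(sprintf("missing columns: %s", paste(setdiff(need, names(d)), collapse = ", ")),
         call. = FALSE)
  ann <- NULL
  if (!is.null(annotations_path)) {
    ann <- utils::read.delim(annotations_path, check.names = FALSE)
    unknown <- setdiff(unique(ann$molecule_id), unique(d$molecule_id))
    if (length(unknown) > 0)
      stop(sprintf("annotations reference unknown molecule(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
  }
  ids <- unique(d$molecule_id)
  out <- lapply(ids, function(id) {
    di <- d[d$molecule_id == id, , drop = FALSE]
    di <- di[order(di$point_index), , drop = FALSE]
    ai <- if (!is.null(ann)) {
      a <- ann[ann$molecule_id == id, c("kind", "start_index", "end_index"), drop = FALSE]
      if (nrow(a) > 0) a else NULL
    } else NULL
    trace2d(id, cbind(di$x_nm, di$y_nm), n_bp = n_bp, annotations = ai)
  })
  names(out) <- as.character(ids)
  out
}

#' Write a versioned JSON analysis report
#'
#' Serializes analysis results into a versioned JSON document with metadata:
#' `{tool_version, schema_version, seed, config, results}`. Keys are written in
#' deterministic (insertion) order; reports from two runs with the same seed
#' and inputs are identical except for the timestamp.
#'
#' @param results Named list of per-analysis blocks (values, uncertainties,
#'   units). May be empty.
#' @param path Output JSON path.
#' @param seed Seed echoed into the report (default NA).
#' @param config Configuration echoed into the report (default empty list).
#' @param timestamp Logical: include a timestamp (default TRUE).
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, seed = NA_integer_, config = list(),
                         timestamp = TRUE) {
  doc <- list(
    tool_version = as.character(utils::packageVersion("smtether")),
    schema_version = "1.0",
    seed = seed,
    config = config,
    results = results)
  if (timestamp) doc$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ok <- tryCatch({jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                                   force = FALSE); TRUE},
                 error = function(e) e)
  if (!isTRUE(ok)) stop(sprintf("unserializable report entry: %s", conditionMessage(ok)),
                        call. = FALSE)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}
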