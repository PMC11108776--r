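#' Construct a per-specimen cell table
#'
#' A cell table is the segmentation-level export this pipeline consumes:
#' one row per nucleated cell with planar coordinates in micrometres, a
#' tumor/stroma compartment label, and binary calls for the six panel
#' markers. Intensity thresholding is upstream (done in the image-analysis
#' platform); this container only holds its result.
#'
#' @param specimen_id Specimen identifier (single string).
#' @param cell_id Character vector of cell identifiers, unique within the
#'   specimen.
#' @param x,y Numeric coordinates in micrometres; finite and non-negative.
#'   The origin is arbitrary and per-specimen: no cross-specimen geometry
#'   is ever computed.
#' @param compartment Character vector, each `"tumor"` or `"stroma"`.
#' @param markers Data frame (or list) of logical columns named as in
#'   [PANEL_MARKERS].
#' @return A `cell_table`: a data.frame with columns `cell_id`, `x`, `y`,
#'   `compartment` and one logical column per marker, plus a
#'   `specimen_id` attribute.
#' @export
cell_table <- function(specimen_id, cell_id, x, y, compartment, markers) {
  stopifnot(length(specimen_id) == 1L, is.character(cell_id))
  n <- length(cell_id)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != n || length(y) != n || length(compartment) != n)
    stop("cell_table: column lengths differ", call. = FALSE)
  if (anyDuplicated(cell_id))
    stop("cell_table: duplicate cell_id within specimen '", specimen_id, "'",
         call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("cell_table: non-finite coordinates", call. = FALSE)
  if (any(x < 0) || any(y < 0))
    stop("cell_table: negative coordinates", call. = FALSE)
  compartment <- as.character(compartment)
  bad <- setdiff(unique(compartment), c("tumor", "stroma"))
  if (length(bad))
    stop("cell_table: unknown compartment label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  markers <- as.data.frame(markers)
  missing <- setdiff(PANEL_MARKERS, names(markers))
  if (length(missing))
    stop("cell_table: missing marker column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  markers <- markers[PANEL_MARKERS]
  for (m in PANEL_MARKERS) {
    v <- markers[[m]]
    if (!is.logical(v)) stop("cell_table: marker ", m, " not logical",
                             call. = FALSE)
    if (anyNA(v)) stop("cell_table: NA marker call in ", m, call. = FALSE)
  }
  out <- data.frame(cell_id = cell_id, x = x, y = y,
                    compartment = compartment, markers,
                    stringsAsFactors = FALSE)
  attr(out, "specimen_id") <- specimen_id
  class(out) <- c("cell_table", "data.frame")
  out
}

#' @export
print.cell_table <- function(x, ...) {
  cat("Cell table for specimen '", specimen_id(x), "': ", nrow(x),
      " cells (", sum(x$compartment == "tumor"), " tumor / ",
      sum(x$compartment == "stroma"), " stroma)\n", sep = "")
  invisible(x)
}

#' Specimen identifier of a cell table
#' @param ct A [cell_table].
#' @return The specimen id string.
#' @export
specimen_id <- function(ct) attr(ct, "specimen_id")

# default header aliases absorbing common exporter dialects
.default_aliases <- function() {
  list(cell_id = c("cell_id", "cell", "object_id", "id"),
       x = c("x", "x_um", "x_position", "xmin_centroid", "centroid_x"),
       y = c("y", "y_um", "y_position", "centroid_y"),
       compartment = c("compartment", "region", "tissue_category"),
       CD8 = c("CD8", "cd8", "CD8_positive"),
       PD1 = c("PD1", "pd1", "PD-1", "PD1_positive"),
       TOX = c("TOX", "tox", "TOX_positive"),
       FOXP3 = c("FOXP3", "foxp3", "FoxP3", "FOXP3_positive"),
       PDL1 = c("PDL1", "pdl1", "PD-L1", "PDL1_positive"),
       PAX8 = c("PAX8", "pax8", "Pax8", "PAX8_positive"))
}

.parse_marker <- function(v, name) {
  if (is.logical(v)) return(list(value = v, bad = integer(0)))
  s <- trimws(tolower(as.character(v)))
  out <- rep(NA, length(s))
  out[s %in% c("1", "true", "t", "yes", "pos", "positive")] <- TRUE
  out[s %in% c("0", "false", "f", "no", "neg", "negative")] <- FALSE
  list(value = out, bad = which(is.na(out)))
}

#' Read a cell table from delimited text
#'
#' Reads one specimen's comma-separated cell export (UTF-8, header row
#' required). Header names are mapped to the required fields through a
#' configurable alias list so different exporter dialects are absorbed
#' without editing files. Marker values may be logical, 0/1 or
#' pos/neg text; unparseable values are reported with their row numbers.
#'
#' @param path Path to a CSV file.
#' @param specimen_id Specimen id; defaults to the file name without
#'   extension.
#' @param aliases Named list mapping each required field to accepted
#'   header names; defaults cover common dialects.
#' @return A validated [cell_table].
#' @export
read_cell_table <- function(path, specimen_id = NULL, aliases = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(specimen_id))
    specimen_id <- sub("\\.[^.]*$", "", basename(path))
  al <- .default_aliases()
  if (!is.null(aliases)) al[names(aliases)] <- aliases
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, fileEncoding = "UTF-8")
  cols <- list()
  for (field in names(al)) {
    hit <- intersect(al[[field]], names(df))
    if (!length(hit))
      stop("schema error in ", basename(path), ": no column for required ",
           "field '", field, "' (accepted: ",
           paste(al[[field]], collapse = ", "), ")", call. = FALSE)
    cols[[field]] <- df[[hit[1L]]]
  }
  for (coord in c("x", "y")) {
    v <- suppressWarnings(as.numeric(cols[[coord]]))
    bad <- which(is.na(v) & !is.na(cols[[coord]]))
    if (length(bad))
      stop("parse error in ", basename(path), ": non-numeric ", coord,
           " at data row(s) ", paste(utils::head(bad, 5L), collapse = ", "),
           call. = FALSE)
    cols[[coord]] <- v
  }
  mk <- list()
  for (m in PANEL_MARKERS) {
    p <- .parse_marker(cols[[m]], m)
    if (length(p$bad))
      stop("parse error in ", basename(path), ": unparseable ", m,
           " call at data row(s) ",
           paste(utils::head(p$bad, 5L), collapse = ", "), call. = FALSE)
    mk[[m]] <- p$value
  }
  cell_table(specimen_id, as.character(cols$cell_id), cols$x, cols$y,
             tolower(cols$compartment), mk)
}

#' Write a cell table to delimited text
#'
#' Inverse of [read_cell_table()]: writes canonical headers so a
#' round-trip reproduces the table exactly.
#'
#' @param ct A [cell_table].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(ct, path) {
  utils::write.csv(as.data.frame(ct), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write the supporting cohort tables
#'
#' Plain CSV readers and writers for the manifest
#' (`specimen_id,patient_id`), the outcomes table (best overall response,
#' PFS/OS times in months with event flags, PFS24 status), the mutation
#' table (patient by gene pathogenic flags plus nonsynonymous count,
#' capture size in Mb and MSIsensor score) and the signature-exposure
#' table (patient by signature id, weights in \[0,1\]).
#'
#' @param path CSV path.
#' @return A data.frame.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "patient_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' @rdname cohort_io
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "bor", "pfs_months", "pfs_event",
            "os_months", "os_event", "pfs24")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("outcomes lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$pfs_event <- as.logical(df$pfs_event)
  df$os_event <- as.logical(df$os_event)
  bad <- setdiff(unique(df$bor), c("CR", "PR", "SD", "PD", "NE"))
  if (length(bad)) stop("unknown BOR categories: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  df
}

#' @rdname cohort_io
#' @export
read_mutations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "n_nonsyn", "capture_mb", "msisensor")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("mutations lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' @rdname cohort_io
#' @export
read_exposures <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"patient_id" %in% names(df))
    stop("exposures lacks patient_id", call. = FALSE)
  df
}

#' Cross-check a cohort before analysis
#'
#' Reconciles cell tables, the specimen-to-patient manifest and the
#' outcomes table. Findings are returned as a report rather than thrown,
#' so a caller can log warnings and refuse to run only on fatal ones:
#' duplicate patient or specimen ids are fatal; orphan specimens (cells
#' with no manifest entry, or manifest entries with no outcome record)
#' and patients without specimens are warnings, because the imaging
#' subcohort of a trial is typically smaller than the treated cohort.
#'
#' @param cells List of [cell_table] objects.
#' @param manifest Data frame with `specimen_id`, `patient_id`.
#' @param outcomes Data frame with at least `patient_id`.
#' @return A `cohort_report`: data.frame with columns `level`
#'   (`"fatal"`/`"warning"`) and `message`, zero rows when consistent.
#' @export
validate_cohort <- function(cells, manifest, outcomes) {
  findings <- list()
  add <- function(level, msg)
    findings[[length(findings) + 1L]] <<- data.frame(level = level,
                                                     message = msg)
  spec_ids <- vapply(cells, specimen_id, character(1))
  if (anyDuplicated(spec_ids))
    add("fatal", paste0("duplicate specimen id(s): ",
        paste(sort(unique(spec_ids[duplicated(spec_ids)])), collapse = ", ")))
  if (anyDuplicated(outcomes$patient_id))
    add("fatal", paste0("duplicate patient id(s) in outcomes: ",
        paste(sort(unique(outcomes$patient_id[duplicated(outcomes$patient_id)])),
              collapse = ", ")))
  orphan <- setdiff(spec_ids, manifest$specimen_id)
  for (s in sort(orphan))
    add("warning", paste0("specimen '", s, "' referenced by no patient"))
  unknown <- setdiff(manifest$patient_id, outcomes$patient_id)
  for (p in sort(unique(unknown)))
    add("warning", paste0("manifest patient '", p, "' has no outcome record"))
  no_spec <- setdiff(outcomes$patient_id, manifest$patient_id)
  for (p in sort(no_spec))
    add("warning", paste0("patient '", p, "' has zero specimens"))
  both <- !is.na(outcomes$pfs_event) & !is.na(outcomes$os_event) &
    outcomes$pfs_event & outcomes$os_event
  viol <- both & outcomes$pfs_months > outcomes$os_months
  for (p in outcomes$patient_id[which(viol)])
    add("warning", paste0("patient '", p, "': PFS exceeds OS with both ",
                          "events observed"))
  out <- if (length(findings)) do.call(rbind, findings) else
    data.frame(level = character(0), message = character(0))
  out <- out[order(out$level, out$message), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort_report", "data.frame")
  out
}

#' Does a cohort report contain fatal findings?
#' @param report A report from [validate_cohort()].
#' @return Logical.
#' @export
has_fatal <- function(report) any(report$level == "fatal")
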