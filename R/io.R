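# File formats: plain-text channel images and ratio maps, plain-text PPM for
# pseudocolor renders, long-format trace CSVs, schedule CSVs and flat
# key = value configuration files. All formats are text so that datasets and
# results remain diff-able and portable.

#' Read and write channel images as plain text
#'
#' The image text format is a single header line
#' `imgtxt <rows> <cols> <label>` followed by `<rows>` lines of
#' space-separated intensities (full double precision). `label` is a channel
#' label or `ratio`; `NA` encodes masked-out pixels in ratio maps. The
#' round trip is lossless to double precision.
#'
#' @param path File path.
#' @param img A [channel_image()] or numeric matrix.
#' @param label Label written to the header (defaults to the image's channel
#'   label, or `"ratio"` for bare matrices).
#' @return `read_channel_image()`: a matrix with attribute `channel_label`
#'   (a `channel_image` when the label is a known channel).
#' @export
write_channel_image <- function(img, path, label = NULL) {
  if (is.null(label))
    label <- if (!is.null(attr(img, "channel_label"))) attr(img, "channel_label") else "ratio"
  m <- unclass(img)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("imgtxt %d %d %s", nrow(m), ncol(m), label), con)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_channel_image
#' @export
read_channel_image <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  hdr <- strsplit(readLines(path, n = 1), "\\s+")[[1]]
  if (length(hdr) != 4 || hdr[1] != "imgtxt")
    stop("not an imgtxt file: ", path)
  nr <- as.integer(hdr[2]); nc <- as.integer(hdr[3]); label <- hdr[4]
  m <- as.matrix(utils::read.table(path, skip = 1, header = FALSE,
                                   colClasses = "numeric", nrows = nr))
  dimnames(m) <- NULL
  if (!identical(dim(m), c(nr, nc)))
    stop(sprintf("corrupt imgtxt: header says %dx%d, data is %dx%d",
                 nr, nc, nrow(m), ncol(m)))
  if (label %in% c("ex405", "ex488", "autofluor430_470"))
    channel_image(m, label)
  else structure(m, channel_label = label)
}

#' Read labeled channel images
#'
#' @param paths Character vector of imgtxt file paths.
#' @param labels Optional channel labels overriding the file headers (same
#'   length as `paths`).
#' @return Named list of channel images; shapes are checked against each
#'   other with a diagnostic naming the files.
#' @export
read_image_inputs <- function(paths, labels = NULL) {
  if (!is.null(labels) && length(labels) != length(paths))
    stop("labels must match paths in length")
  imgs <- lapply(seq_along(paths), function(i) {
    img <- read_channel_image(paths[i])
    if (!is.null(labels)) img <- channel_image(unclass(img), labels[i])
    img
  })
  names(imgs) <- vapply(imgs, function(x) attr(x, "channel_label"), "")
  dims <- lapply(imgs, dim)
  for (i in seq_along(imgs)[-1]) {
    if (!identical(dims[[i]], dims[[1]]))
      stop(sprintf("shape mismatch: %s is %s but %s is %s",
                   paths[1], paste(dims[[1]], collapse = "x"),
                   paths[i], paste(dims[[i]], collapse = "x")))
  }
  imgs
}

#' Write an RGB array as plain-text PPM (P3)
#'
#' @param rgb Array `rows x cols x 3` with values in \[0, 1\] (e.g. from
#'   [pseudocolor()]).
#' @param path Output path.
#' @param maxval Maximum channel value of the PPM.
#' @return The path, invisibly.
#' @export
write_ppm <- function(rgb, path, maxval = 255) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  nr <- dim(rgb)[1]; nc <- dim(rgb)[2]
  vals <- round(pmin(pmax(rgb, 0), 1) * maxval)  # rgb first: keep dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", sprintf("%d %d", nc, nr), as.character(maxval)), con)
  # PPM is row-major, channels interleaved
  for (r in seq_len(nr))
    writeLines(paste(as.integer(t(vals[r, , ])), collapse = " "), con)
  invisible(path)
}

#' Read and validate a long-format trace table
#'
#' Expects a traces CSV with header exactly
#' `time_s, well_id, excitation, intensity` and a wells CSV with header
#' `well_id, genotype, treatment, is_blank`. Duplicate
#' (time, well, excitation) rows, unknown excitation labels and wells without
#' metadata are rejected with row numbers.
#'
#' @param traces_path,wells_path CSV file paths.
#' @return A validated [trace_set()].
#' @export
read_trace_table <- function(traces_path, wells_path) {
  for (p in c(traces_path, wells_path))
    if (!file.exists(p)) stop("unreadable file: ", p)
  traces <- utils::read.csv(traces_path, stringsAsFactors = FALSE)
  wells <- utils::read.csv(wells_path, stringsAsFactors = FALSE)
  if (!identical(sort(names(traces)),
                 sort(c("time_s", "well_id", "excitation", "intensity"))))
    stop("traces header must be exactly time_s, well_id, excitation, intensity")
  if (!identical(sort(names(wells)),
                 sort(c("well_id", "genotype", "treatment", "is_blank"))))
    stop("wells header must be exactly well_id, genotype, treatment, is_blank")
  trace_set(traces, wells)
}

#' @rdname read_trace_table
#' @param ts A [trace_set()].
#' @param dir Output directory.
#' @return `write_trace_table()`: the two paths, invisibly.
#' @export
write_trace_table <- function(ts, dir) {
  stopifnot(inherits(ts, "trace_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tp <- file.path(dir, "traces.csv"); wp <- file.path(dir, "wells.csv")
  utils::write.csv(ts$traces, tp, row.names = FALSE)
  utils::write.csv(ts$wells, wp, row.names = FALSE)
  invisible(c(tp, wp))
}

#' Read a phase schedule from CSV
#'
#' Columns: `name, start_s, end_s, o2_percent` and optional `dtt_uM`.
#'
#' @param path CSV path.
#' @param dead_time_s Dead-volume delay in seconds.
#' @return A [phase_schedule()].
#' @export
read_schedule <- function(path, dead_time_s = 0) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  phase_schedule(utils::read.csv(path, stringsAsFactors = FALSE),
                 dead_time_s = dead_time_s)
}

#' Flat key = value configuration files
#'
#' One `key = value` pair per line; `#` starts a comment; values are parsed
#' as numbers when possible, else kept as strings. `write_config()`
#' serializes a flat named list the same way (used to store the generating
#' configuration beside every output).
#'
#' @param path File path.
#' @return `read_config()`: a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' @rdname read_config
#' @param config Flat named list.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k,
            if (is.numeric(v)) format(v, digits = 15) else as.character(v))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
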