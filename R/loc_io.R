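#' Read a localization table
#'
#' Reads the coordinate lists exported by SMLM reconstruction software into a
#' [loc_table]. Two dialects are supported:
#'
#' * `generic_csv` — header row `x_nm,y_nm,frame,photons` (the `photons`
#'   column is optional), comma-separated.
#' * `rapidstorm_txt` — whitespace-separated values with an optional leading
#'   `#` comment header. When the header names fields (`Position-0-0`,
#'   `Position-1-0`, `ImageNumber-0-0`, `Amplitude-0-0`), columns are mapped by
#'   name; otherwise columns are taken positionally as x, y, frame, intensity.
#'   Coordinates are assumed to be in nm (the exporter's pixel size having been
#'   applied upstream); this is a convention of the reader, not something the
#'   format declares.
#'
#' Rows with non-finite or non-numeric coordinates (fit failures are common in
#' real exports) are skipped with a message reporting the count rather than
#' aborting the read.
#'
#' @param path Path to the file.
#' @param dialect One of `"generic_csv"`, `"rapidstorm_txt"`.
#' @return A [loc_table] in nm.
#' @seealso [write_localizations()], [crop_region()]
#' @export
read_localizations <- function(path, dialect = c("generic_csv", "rapidstorm_txt")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- switch(dialect,
    generic_csv = read_generic_csv(path),
    rapidstorm_txt = read_rapidstorm_txt(path)
  )
  n_raw <- nrow(raw)
  keep <- is.finite(raw$x) & is.finite(raw$y) & is.finite(raw$frame)
  skipped <- n_raw - sum(keep)
  if (skipped > 0) {
    inform(sprintf("read_localizations: skipped %d row(s) with non-finite coordinates", skipped))
  }
  raw <- raw[keep, , drop = FALSE]
  tbl <- loc_table(x = raw$x, y = raw$y, frame = as.integer(raw$frame),
                   photons = raw[["photons"]])
  if (skipped > 0) attr(tbl, "skipped_rows") <- skipped
  tbl
}

read_generic_csv <- function(path) {
  # non-numeric cells become NA here and are counted/skipped by the caller
  dat <- suppressWarnings(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE, show_col_types = FALSE))
  if (nrow(dat) == 0 && ncol(dat) == 0) abort(sprintf("empty localization file: %s", path))
  required <- c("x_nm", "y_nm", "frame")
  missing <- setdiff(required, names(dat))
  if (length(missing)) {
    abort(sprintf("generic_csv file %s is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(x = dat$x_nm, y = dat$y_nm, frame = dat$frame)
  if ("photons" %in% names(dat)) out$photons <- dat$photons
  out
}

read_rapidstorm_txt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    abort(sprintf("empty localization file: %s", path))
  }
  header <- NULL
  if (startsWith(trimws(lines[[1]]), "#")) {
    header <- lines[[1]]
    lines <- lines[-1]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("no data rows in localization file: %s", path))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  ncol_data <- max(lengths(fields))
  if (ncol_data < 3) {
    abort(sprintf("rapidstorm_txt file %s has %d column(s); need at least x, y, frame",
                  path, ncol_data))
  }
  mat <- t(vapply(fields, function(f) {
    suppressWarnings(as.numeric(f[seq_len(ncol_data)]))
  }, double(ncol_data)))
  # rapidSTORM writes its schema into the comment header; fall back to
  # positional x, y, frame, intensity when it is absent
  idx <- c(x = 1L, y = 2L, frame = 3L, photons = if (ncol_data >= 4) 4L else NA_integer_)
  if (!is.null(header)) {
    toks <- regmatches(header, gregexpr("[A-Za-z0-9._-]+", header))[[1]]
    find1 <- function(pat) {
      hit <- grep(pat, toks, value = FALSE)
      if (length(hit)) hit[[1]] else NA_integer_
    }
    named <- c(x = find1("^Position-0"), y = find1("^Position-1"),
               frame = find1("^ImageNumber"), photons = find1("^Amplitude"))
    if (!any(is.na(named[c("x", "y", "frame")]))) {
      # token order in the header mirrors column order
      ord <- rank(named, na.last = "keep")
      idx <- c(x = ord[["x"]], y = ord[["y"]], frame = ord[["frame"]],
               photons = if (!is.na(named[["photons"]])) ord[["photons"]] else NA_integer_)
    }
  }
  out <- tibble::tibble(x = mat[, idx[["x"]]], y = mat[, idx[["y"]]],
                        frame = mat[, idx[["frame"]]])
  if (!is.na(idx[["photons"]]) && idx[["photons"]] <= ncol_data) {
    out$photons <- mat[, idx[["photons"]]]
  }
  out
}

#' Write a localization table
#'
#' Writes `generic_csv` (header `x_nm,y_nm,frame,photons`; the `photons`
#' column appears only when the table carries it). Full double precision is
#' preserved, so `read_localizations()` on the written file reproduces the
#' table exactly.
#'
#' @param table A [loc_table].
#' @param path Output path.
#' @param dialect Only `"generic_csv"` is writable.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path, dialect = "generic_csv") {
  dialect <- match.arg(dialect, "generic_csv")
  table <- validate_loc_table(table)
  out <- tibble::tibble(x_nm = table$x, y_nm = table$y, frame = table$frame)
  if ("photons" %in% names(table)) out$photons <- table$photons
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Crop a localization table to a rectangular region
#'
#' Retains exactly the rows with `x_min <= x < x_max` and
#' `y_min <= y < y_max` — half-open on the max edges, so tiling a field with
#' adjacent windows partitions it. Row order is preserved and an empty result
#' is allowed.
#'
#' @param table A [loc_table].
#' @param region A [region].
#' @return The cropped [loc_table].
#' @examples
#' t <- loc_table(x = c(0, 500, 1000), y = c(0, 0, 0), frame = 0:2)
#' crop_region(t, region(0, 1000, -10, 10))  # the x = 1000 point is dropped
#' @export
crop_region <- function(table, region) {
  table <- validate_loc_table(table)
  stopifnot(inherits(region, "region"))
  table[in_region(table$x, table$y, region), , drop = FALSE]
}
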