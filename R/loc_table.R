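#' Localization tables
#'
#' A localization table is the universal currency of the pipeline: one row per
#' single-molecule localization, with planar coordinates in nanometres, the
#' acquisition frame index, and (optionally) the fitted photon count. It is a
#' tibble with class `loc_table`, so all dplyr/tidyr verbs apply; the
#' constructor only validates and stamps the class.
#'
#' Coordinates are always stored in nm internally, whatever the input dialect
#' used; densities throughout the package are localizations per square
#' micrometre.
#'
#' @param x,y Numeric vectors, coordinates in nm. Must be finite.
#' @param frame Integer vector of non-negative acquisition frame indices.
#' @param photons Optional numeric vector of non-negative fitted photon counts.
#' @return A `loc_table` tibble with columns `x`, `y`, `frame` and, when
#'   supplied, `photons`.
#' @examples
#' loc_table(x = c(100, 250), y = c(80, 90), frame = c(1L, 7L))
#' @export
loc_table <- function(x = double(), y = double(), frame = integer(),
                      photons = NULL) {
  tbl <- tibble::tibble(x = as.double(x), y = as.double(y),
                        frame = as.integer(frame))
  if (!is.null(photons)) tbl$photons <- as.double(photons)
  validate_loc_table(new_loc_table(tbl))
}

new_loc_table <- function(tbl) {
  class(tbl) <- unique(c("loc_table", class(tbl)))
  tbl
}

#' Validate a localization table
#'
#' Checks the class invariants: finite coordinates, integral non-negative
#' frames, non-negative photon counts where present.
#'
#' @param table A `loc_table` (or coercible data frame with columns `x`, `y`,
#'   `frame`).
#' @return The validated `loc_table`, invisibly classed.
#' @export
validate_loc_table <- function(table) {
  if (!all(c("x", "y", "frame") %in% names(table))) {
    abort("a localization table needs columns `x`, `y` and `frame`")
  }
  if (!all(is.finite(table$x)) || !all(is.finite(table$y))) {
    abort("localization coordinates must be finite")
  }
  fr <- table$frame
  if (length(fr) && (any(fr < 0) || any(fr != as.integer(fr)))) {
    abort("`frame` must contain non-negative integers")
  }
  if ("photons" %in% names(table) &&
      any(table$photons[is.finite(table$photons)] < 0)) {
    abort("`photons` must be non-negative")
  }
  if (!inherits(table, "loc_table")) table <- new_loc_table(tibble::as_tibble(table))
  table
}

#' Rectangular observation windows
#'
#' An axis-aligned rectangle with edges in nm. The window area enters Ripley's
#' K estimator (the symbol A) and normalizes localization densities. Region
#' membership everywhere in the package is half-open, `[min, max)` on both
#' axes, so that tilings of adjacent windows never double-count a point.
#'
#' @param x_min,x_max,y_min,y_max Edges in nm; `x_max > x_min`,
#'   `y_max > y_min`.
#' @return An object of class `region`.
#' @examples
#' region(0, 5000, 0, 5000)        # the 5 x 5 um^2 analysis window
#' region_area(region(0, 5000, 0, 5000)) / 1e6  # area in um^2
#' @export
region <- function(x_min, x_max, y_min, y_max) {
  vals <- c(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max)
  if (!all(is.finite(vals))) abort("region edges must be finite")
  if (x_max <= x_min || y_max <= y_min) {
    abort("region must have positive extent: x_max > x_min and y_max > y_min")
  }
  structure(as.list(vals), class = "region")
}

#' @rdname region
#' @param r A `region`.
#' @return `region_area()`: the window area in nm^2.
#' @export
region_area <- function(r) {
  stopifnot(inherits(r, "region"))
  (r$x_max - r$x_min) * (r$y_max - r$y_min)
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region> [%g, %g) x [%g, %g) nm  (area %.4g um^2)\n",
              x$x_min, x$x_max, x$y_min, x$y_max, region_area(x) / 1e6))
  invisible(x)
}

# grow a region symmetrically by `pad` nm on every side
region_buffer <- function(r, pad) {
  region(r$x_min - pad, r$x_max + pad, r$y_min - pad, r$y_max + pad)
}

# shrink a region symmetrically; errors if it would collapse
region_inset <- function(r, pad) {
  region(r$x_min + pad, r$x_max - pad, r$y_min + pad, r$y_max - pad)
}

in_region <- function(x, y, r) {
  x >= r$x_min & x < r$x_max & y >= r$y_min & y < r$y_max
}
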