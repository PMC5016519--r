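#' Sliding-window localization density
#'
#' Moves a circular window of fixed diameter over a regular step grid and
#' reports, for each window position, the localization count inside the
#' circle per um^2. This is the labeling-efficiency diagnostic: the median
#' window density of a region summarizes how densely the membrane is labeled,
#' and comparing medians between regions exposes projection artifacts such as
#' overlapping (two-fold) membranes.
#'
#' Only window positions whose full circle lies inside `region` are evaluated
#' — there is no partial-window area correction, so densities near the region
#' edge are simply not reported rather than biased. Membership in a window
#' uses a strict `< diameter/2` radius comparison.
#'
#' @param table A [loc_table].
#' @param region A [region]; must admit at least one full window.
#' @param diameter Window diameter in nm (default 1000, i.e. 1 um).
#' @param step Grid step in nm (default 100).
#' @return A `density_map`: a tibble with columns `x`, `y` (window centers,
#'   nm) and `density` (localizations per um^2), carrying the window geometry
#'   as attributes.
#' @examples
#' t <- simulate_csr(500, region(0, 3000, 0, 3000), seed = 1)
#' dm <- sliding_window_density(t, region(0, 3000, 0, 3000))
#' summarize_density(dm)
#' @export
sliding_window_density <- function(table, region, diameter = 1000, step = 100) {
  table <- validate_loc_table(table)
  stopifnot(inherits(region, "region"))
  if (diameter <= 0 || step <= 0) abort("diameter and step must be positive")
  r <- diameter / 2
  cx <- seq_grid(region$x_min + r, region$x_max - r, step)
  cy <- seq_grid(region$y_min + r, region$y_max - r, step)
  if (length(cx) == 0 || length(cy) == 0) {
    abort("region is smaller than one full window; no densities to report")
  }
  area_um2 <- pi * r^2 / 1e6

  # pre-sort by x so each window only sees the points in its x-slab
  ord <- order(table$x)
  xs <- table$x[ord]
  ys <- table$y[ord]
  counts <- matrix(0L, nrow = length(cx), ncol = length(cy))
  for (i in seq_along(cx)) {
    lo <- findInterval(cx[i] - r, xs) + 1L
    hi <- findInterval(cx[i] + r, xs)
    if (hi < lo) next
    dx2 <- (xs[lo:hi] - cx[i])^2
    yy <- ys[lo:hi]
    for (j in seq_along(cy)) {
      counts[i, j] <- sum(dx2 + (yy - cy[j])^2 < r^2)
    }
  }
  map <- tibble::tibble(x = rep(cx, times = length(cy)),
                        y = rep(cy, each = length(cx)),
                        density = as.vector(counts) / area_um2)
  structure(map, class = c("density_map", class(map)),
            diameter = diameter, step = step, region = region)
}

seq_grid <- function(from, to, by) {
  if (to < from) return(double())
  seq(from, to, by = by)
}

#' Summarize a density map
#'
#' Median, mean and quartiles of the per-window densities, plus a bootstrap
#' standard error of the median (the SE that density-vs-titration plots carry
#' as error bars; "SE of a median" has no closed form, so it is estimated by
#' resampling windows).
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7), so the toy example `{1,2,3,4,5}` gives median 3
#' and quartiles 2 and 4.
#'
#' @param map A `density_map` from [sliding_window_density()] (any data frame
#'   with a `density` column works).
#' @param boot_n Bootstrap resamples for the median SE (default 1000).
#' @param seed Seed for the bootstrap.
#' @return A one-row tibble: `median`, `mean`, `q25`, `q75`, `n_windows`,
#'   `median_se`.
#' @export
summarize_density <- function(map, boot_n = 1000, seed = 1) {
  if (nrow(map) == 0) abort("cannot summarize an empty density map")
  d <- map$density
  qs <- quantile(d, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  med_se <- withr::with_seed(seed, {
    reps <- vapply(seq_len(boot_n),
                   function(i) median(d[sample.int(length(d), replace = TRUE)]),
                   double(1))
    sd(reps)
  })
  tibble::tibble(median = qs[2], mean = mean(d), q25 = qs[1], q75 = qs[3],
                 n_windows = length(d), median_se = med_se)
}

#' @export
tidy.density_map <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("x", "y", "density")])
}

#' @export
glance.density_map <- function(x, ...) summarize_density(x, ...)

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d windows (diameter %g nm, step %g nm)\n",
              nrow(x), attr(x, "diameter"), attr(x, "step")))
  NextMethod()
}
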