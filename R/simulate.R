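#' Neyman-Scott parameter sets
#'
#' Bundles the parameters of the clustered (Neyman-Scott) point process used
#' as the blinking null model: Poisson-distributed parents, each spawning a
#' Poisson number of offspring localizations Gauss-scattered around the parent
#' with standard deviation equal to the localization precision.
#'
#' The process intensity can be matched to data in two ways: directly via
#' `parent_intensity` (parents per um^2), or via `loc_intensity`
#' (localizations per um^2), from which the parent intensity is derived by
#' dividing by the expected localizations per parent. Matching per
#' localization is what equating simulated and experimental localization
#' densities requires, and is the default entry point in the pipeline.
#'
#' With `condition_on_detection = TRUE` (default) the per-parent offspring
#' count is Poisson conditioned on being at least 1: an undetected fluorophore
#' contributes no localizations, so it should not appear as an empty cluster.
#' The conditional mean is `offspring_mean / (1 - exp(-offspring_mean))`
#' (about 5.034 for a mean of 5, a +0.7\% shift).
#'
#' @param parent_intensity Parents per um^2. Supply this or `loc_intensity`.
#' @param loc_intensity Target localization density (per um^2); converted to a
#'   parent intensity using the (conditional) mean offspring count.
#' @param offspring_mean Expected localizations per parent; default 5, the
#'   average number of blinks per fluorophore.
#' @param offspring_sigma Gaussian scatter of offspring around the parent, nm;
#'   default 8, the localization precision.
#' @param condition_on_detection Condition offspring counts on >= 1?
#' @return A list of class `ns_params`.
#' @examples
#' neyman_scott_params(loc_intensity = 1000)   # matched to 1000 loc/um^2
#' @export
neyman_scott_params <- function(parent_intensity = NULL, loc_intensity = NULL,
                                offspring_mean = 5, offspring_sigma = 8,
                                condition_on_detection = TRUE) {
  if (offspring_mean < 0 || offspring_sigma < 0) {
    abort("offspring_mean and offspring_sigma must be non-negative")
  }
  mean_per_parent <- if (condition_on_detection && offspring_mean > 0) {
    offspring_mean / (1 - exp(-offspring_mean))
  } else {
    offspring_mean
  }
  if (is.null(parent_intensity)) {
    if (is.null(loc_intensity)) abort("supply `parent_intensity` or `loc_intensity`")
    if (mean_per_parent <= 0) abort("cannot match a localization density with zero offspring mean")
    parent_intensity <- loc_intensity / mean_per_parent
  }
  if (parent_intensity < 0) abort("parent_intensity must be non-negative")
  structure(list(parent_intensity = parent_intensity,
                 offspring_mean = offspring_mean,
                 offspring_sigma = offspring_sigma,
                 condition_on_detection = condition_on_detection,
                 mean_per_parent = mean_per_parent),
            class = "ns_params")
}

# Poisson count conditioned on >= 1, by inversion of the truncated CDF
rpois_positive <- function(n, lambda) {
  if (lambda <= 0) return(rep(1L, n))
  p0 <- exp(-lambda)
  qpois(runif(n, p0, 1), lambda)
}

uniform_frames <- function(n, n_frames) sample.int(n_frames, n, replace = TRUE)

#' Simulate complete spatial randomness
#'
#' Homogeneous Poisson point process in a rectangular window: the number of
#' localizations is Poisson(intensity x area) and positions are i.i.d. uniform.
#' This is the no-clustering null against which Ripley's h is read. Frame
#' indices are assigned i.i.d. uniform over the stack (the process itself is
#' purely spatial).
#'
#' @param intensity Localizations per um^2.
#' @param region A [region].
#' @param seed Integer seed; same seed, same table.
#' @param n_frames Stack length for the uniform frame assignment.
#' @return A [loc_table].
#' @examples
#' simulate_csr(100, region(0, 2000, 0, 2000), seed = 1)
#' @export
simulate_csr <- function(intensity, region, seed, n_frames = 20000) {
  if (intensity < 0) abort("intensity must be non-negative")
  stopifnot(inherits(region, "region"))
  withr::with_seed(seed, {
    n <- rpois(1, intensity * region_area(region) / 1e6)
    loc_table(x = runif(n, region$x_min, region$x_max),
              y = runif(n, region$y_min, region$y_max),
              frame = uniform_frames(n, n_frames))
  })
}

#' Simulate a Neyman-Scott clustered field
#'
#' Parents are sampled as a Poisson process in the window buffered outward by
#' `5 * offspring_sigma` so that clusters straddling the boundary contribute
#' their share of offspring (no artificial edge depletion); offspring are
#' Gauss-scattered around their parent and only those falling inside the
#' observation window are returned. Per-parent offspring counts are Poisson,
#' conditioned on >= 1 when the parameter set says so.
#'
#' The returned truth records each parent's position and the parent index of
#' every emitted localization, for parameter-recovery tests.
#'
#' @param params A [neyman_scott_params()] set.
#' @param region A [region].
#' @param seed Integer seed.
#' @param n_frames Stack length for the uniform frame assignment.
#' @return A list with elements `locs` (a [loc_table]) and `truth` (list with
#'   `parents`, a tibble of parent positions, and `assignment`, the parent row
#'   index of each localization).
#' @examples
#' sim <- simulate_neyman_scott(neyman_scott_params(loc_intensity = 200),
#'                              region(0, 2000, 0, 2000), seed = 1)
#' nrow(sim$locs)
#' @export
simulate_neyman_scott <- function(params, region, seed, n_frames = 20000) {
  stopifnot(inherits(params, "ns_params"), inherits(region, "region"))
  withr::with_seed(seed, {
    buf <- region_buffer(region, 5 * params$offspring_sigma)
    n_par <- rpois(1, params$parent_intensity * region_area(buf) / 1e6)
    px <- runif(n_par, buf$x_min, buf$x_max)
    py <- runif(n_par, buf$y_min, buf$y_max)
    counts <- if (params$condition_on_detection) {
      rpois_positive(n_par, params$offspring_mean)
    } else {
      rpois(n_par, params$offspring_mean)
    }
    parent_of <- rep.int(seq_len(n_par), counts)
    n_off <- length(parent_of)
    ox <- px[parent_of] + rnorm(n_off, 0, params$offspring_sigma)
    oy <- py[parent_of] + rnorm(n_off, 0, params$offspring_sigma)
    keep <- in_region(ox, oy, region)
    locs <- loc_table(x = ox[keep], y = oy[keep],
                      frame = uniform_frames(sum(keep), n_frames))
    list(locs = locs,
         truth = list(parents = tibble::tibble(id = seq_len(n_par), x = px, y = py),
                      assignment = parent_of[keep]))
  })
}

#' Simulate a diluted blinking-fluorophore scene
#'
#' Emulates a diluted reference sample: fluorophores scattered uniformly in
#' the window, each producing a Poisson (conditioned >= 1) number of
#' localizations Gauss-scattered around its true position with the
#' localization precision, on frames drawn uniformly without replacement from
#' the stack. This is the scene on which the radius-sweep calibration and the
#' precision estimate are validated.
#'
#' Localizations scattered outside the window are dropped (the documented
#' clipping rule); a fluorophore whose every localization is clipped is
#' removed from the truth.
#'
#' @param fluorophore_density Fluorophores per um^2; the reference regime is
#'   about 2/um^2, keeping localization density well below 20/um^2.
#' @param blink_mean Poisson mean of localizations per fluorophore (default 5).
#' @param precision_sigma Localization precision sigma in nm (default 8).
#' @param n_frames Stack length in frames (default 20000).
#' @param region A [region].
#' @param seed Integer seed.
#' @return A list with `locs` (a [loc_table]) and `truth` (list with
#'   `fluorophores` tibble and per-localization `assignment`).
#' @examples
#' sc <- simulate_blinking_scene(2, region = region(0, 5000, 0, 5000), seed = 1)
#' nrow(sc$locs) / 25       # localization density, per um^2
#' @export
simulate_blinking_scene <- function(fluorophore_density, blink_mean = 5,
                                    precision_sigma = 8, n_frames = 20000,
                                    region, seed) {
  if (fluorophore_density < 0) abort("fluorophore_density must be non-negative")
  if (n_frames < 1) abort("n_frames must be at least 1")
  stopifnot(inherits(region, "region"))
  withr::with_seed(seed, {
    n_f <- rpois(1, fluorophore_density * region_area(region) / 1e6)
    fx <- runif(n_f, region$x_min, region$x_max)
    fy <- runif(n_f, region$y_min, region$y_max)
    counts <- rpois_positive(n_f, blink_mean)
    if (any(counts > n_frames)) {
      warn("some fluorophores blink more often than there are frames; sampling frames with replacement for those")
    }
    frames <- lapply(counts, function(k) {
      sample.int(n_frames, k, replace = k > n_frames)
    })
    who <- rep.int(seq_len(n_f), counts)
    n_loc <- length(who)
    lx <- fx[who] + rnorm(n_loc, 0, precision_sigma)
    ly <- fy[who] + rnorm(n_loc, 0, precision_sigma)
    keep <- in_region(lx, ly, region)
    locs <- loc_table(x = lx[keep], y = ly[keep], frame = unlist(frames)[keep])
    ord <- order(locs$frame)
    list(locs = locs[ord, ],
         truth = list(fluorophores = tibble::tibble(id = seq_len(n_f), x = fx, y = fy),
                      assignment = who[keep][ord]))
  })
}

#' Simulate a two-fold (double) membrane
#'
#' Superposition of two independent homogeneous layers of equal intensity,
#' emulating the overlapping-membrane projection artifact: the apparent
#' localization density doubles relative to a single membrane while each layer
#' remains spatially random.
#'
#' @param single_intensity Localizations per um^2 of one layer.
#' @param region A [region].
#' @param seed Integer seed (two sub-seeds are derived deterministically).
#' @param n_frames Stack length for frame assignment.
#' @return A [loc_table] of the superposed layers.
#' @export
simulate_double_membrane <- function(single_intensity, region, seed,
                                     n_frames = 20000) {
  a <- simulate_csr(single_intensity, region, seed = seed, n_frames = n_frames)
  b <- simulate_csr(single_intensity, region, seed = seed + 1000003L, n_frames = n_frames)
  new_loc_table(dplyr::bind_rows(a, b))
}

#' Simulate a membrane field with vesicle projection artifacts
#'
#' A homogeneous background plus `vesicle_count` dense discs of radius
#' `vesicle_radius`, each containing exactly `vesicle_loc_count` uniformly
#' placed localizations — the 2D projection of labeled vesicles sitting above
#' the plasma membrane, which read as protein clusters in a reconstruction.
#' Disc centers are placed uniformly in the window inset by the vesicle radius
#' so every disc lies fully inside and the vesicle contribution to the total
#' count is exact.
#'
#' @param background_intensity Background localizations per um^2.
#' @param vesicle_count Number of vesicles.
#' @param vesicle_radius Disc radius in nm.
#' @param vesicle_loc_count Localizations per vesicle disc.
#' @param region A [region]; must be wider than `2 * vesicle_radius`.
#' @param seed Integer seed.
#' @param n_frames Stack length for frame assignment.
#' @return A [loc_table].
#' @export
simulate_vesicle_field <- function(background_intensity, vesicle_count,
                                   vesicle_radius, vesicle_loc_count,
                                   region, seed, n_frames = 20000) {
  if (vesicle_radius <= 0) abort("vesicle_radius must be positive")
  stopifnot(inherits(region, "region"))
  bg <- simulate_csr(background_intensity, region, seed = seed, n_frames = n_frames)
  if (vesicle_count == 0) return(bg)
  withr::with_seed(seed + 2000029L, {
    inner <- region_inset(region, vesicle_radius)
    cx <- runif(vesicle_count, inner$x_min, inner$x_max)
    cy <- runif(vesicle_count, inner$y_min, inner$y_max)
    which_v <- rep.int(seq_len(vesicle_count), rep(vesicle_loc_count, vesicle_count))
    n_v <- length(which_v)
    rr <- vesicle_radius * sqrt(runif(n_v))
    th <- runif(n_v, 0, 2 * pi)
    ves <- loc_table(x = cx[which_v] + rr * cos(th),
                     y = cy[which_v] + rr * sin(th),
                     frame = uniform_frames(n_v, n_frames))
    new_loc_table(dplyr::bind_rows(bg, ves))
  })
}
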