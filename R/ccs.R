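#' Projection-approximation collision cross section of a frame
#'
#' Orientation-averaged shadow area: for each uniformly random rotation
#' (quaternion-uniform, seeded), atoms project onto the viewing plane as
#' disks of radius `r_i + probe_radius`, and the union area of the disks is
#' estimated by uniform point sampling over their bounding box. The CCS is
#' the mean area over orientations, with early stopping once the running
#' standard error drops below `tolerance` (after a minimum of 20
#' orientations).
#'
#' @param coords `n x 3` coordinate matrix (Angstrom).
#' @param radii Per-atom collision radii (> 0, Angstrom).
#' @param probe_radius Buffer-gas probe radius added to every atom
#'   (default 1.0 Angstrom).
#' @param n_orientations Maximum number of random orientations (default
#'   300).
#' @param n_area_samples Sample points per orientation (default 4000).
#' @param seed Optional integer seed for a self-contained RNG stream; when
#'   `NULL` the current RNG state is used.
#' @param tolerance Early-stop threshold on the standard error of the mean
#'   area, in A^2 (default 1).
#' @return A one-row tibble: `ccs` (A^2), `se`, `n_orientations`,
#'   `probe_radius`.
#' @export
pa_ccs <- function(coords, radii, probe_radius = 1.0, n_orientations = 300L,
                   n_area_samples = 4000L, seed = NULL, tolerance = 1.0) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L) rlang::abort("frame has no atoms")
  if (any(radii <= 0)) rlang::abort("radii must be > 0")
  if (n_orientations < 1L) rlang::abort("n_orientations must be >= 1")
  r <- radii + probe_radius
  run <- function() {
    areas <- numeric(n_orientations)
    used <- 0L
    for (k in seq_len(n_orientations)) {
      rot <- random_rotation()
      xy <- coords %*% t(rot)
      xy <- xy[, 1:2, drop = FALSE]
      areas[k] <- union_disk_area(xy, r, n_area_samples)
      used <- k
      if (k >= 20L) {
        se <- stats::sd(areas[1:k]) / sqrt(k)
        if (se < tolerance) break
      }
    }
    list(areas = areas[1:used], used = used)
  }
  res <- with_local_seed(seed, run())
  a <- res$areas
  tibble::tibble(
    ccs = mean(a),
    se = if (res$used > 1L) stats::sd(a) / sqrt(res$used) else 0,
    n_orientations = res$used,
    probe_radius = probe_radius
  )
}

# Monte Carlo union-of-disks area over the disks' bounding box.
union_disk_area <- function(xy, r, n_samples) {
  lo_x <- min(xy[, 1] - r); hi_x <- max(xy[, 1] + r)
  lo_y <- min(xy[, 2] - r); hi_y <- max(xy[, 2] + r)
  px <- stats::runif(n_samples, lo_x, hi_x)
  py <- stats::runif(n_samples, lo_y, hi_y)
  d2 <- outer(px^2 + py^2, rowSums(xy^2), "+") -
    2 * (cbind(px, py) %*% t(xy))
  hit <- rowSums(sweep(d2, 2, r^2, "<=")) > 0
  (hi_x - lo_x) * (hi_y - lo_y) * mean(hit)
}

# uniform random rotation matrix from a uniform unit quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Per-frame CCS over an ensemble
#'
#' Applies [pa_ccs()] to each (possibly subsampled) frame, using the atom
#' table's GB radii as collision radii unless `radii` is given. Per-frame
#' seeds are derived deterministically from `seed`.
#'
#' @param ens A [conformer_ensemble].
#' @param radii Optional per-atom radii; defaults to the `gb_radius`
#'   column.
#' @param frames Optional frame indices (default: all).
#' @param seed Optional integer seed.
#' @inheritParams pa_ccs
#' @return A tibble with one row per frame (`frame`, `ccs`, `se`,
#'   `n_orientations`); attributes `ccs_mean` and `ccs_sd` summarize over
#'   frames.
#' @export
ensemble_ccs <- function(ens, radii = NULL, frames = NULL,
                         probe_radius = 1.0, n_orientations = 300L,
                         n_area_samples = 4000L, seed = NULL,
                         tolerance = 1.0) {
  if (is.null(radii)) radii <- ens$atoms$gb_radius
  if (anyNA(radii)) {
    rlang::abort("no radii available: merge parameters or pass radii")
  }
  if (is.null(frames)) frames <- seq_len(n_frames(ens))
  out <- purrr::map_dfr(seq_along(frames), function(k) {
    fseed <- if (is.null(seed)) NULL else seed + k
    res <- pa_ccs(ens$frames[[frames[k]]], radii,
      probe_radius = probe_radius, n_orientations = n_orientations,
      n_area_samples = n_area_samples, seed = fseed, tolerance = tolerance)
    dplyr::bind_cols(tibble::tibble(frame = frames[k]),
      res[c("ccs", "se", "n_orientations")])
  })
  attr(out, "ccs_mean") <- mean(out$ccs)
  attr(out, "ccs_sd") <- if (nrow(out) > 1L) stats::sd(out$ccs) else 0
  out
}

#' Linear CCS calibration
#'
#' Maps projection-approximation areas onto an experimental scale via
#' `scale * ccs + offset`. Identity by default: absolute parity with
#' drift-gas measurements requires an instrument calibration that is out of
#' scope here, so uncalibrated values support ordering comparisons only.
#'
#' @param ccs CCS value(s) in A^2.
#' @param scale,offset Calibration coefficients.
#' @return Calibrated value(s).
#' @export
calibrate_ccs <- function(ccs, scale = 1, offset = 0) {
  scale * ccs + offset
}

#' Per-element van der Waals radii
#'
#' A small default radii table (Bondi-style values) for use as collision
#' radii when an ensemble lacks parameters.
#'
#' @param elements Character vector of element symbols.
#' @return Numeric radii in Angstrom.
#' @export
element_vdw_radius <- function(elements) {
  tab <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8)
  r <- tab[toupper(elements)]
  r[is.na(r)] <- 1.7
  unname(r)
}
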