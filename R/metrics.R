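#' Radius of gyration of a single frame
#'
#' Mass-weighted root-mean-square distance of atoms from their mass-weighted
#' centroid, the standard compactness proxy for disordered peptides.
#'
#' @param coords `n x 3` coordinate matrix in Angstrom.
#' @param masses Per-atom masses (> 0); unit masses give the geometric
#'   radius of gyration.
#' @return R_g in Angstrom.
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)), c(1, 1)) # 1
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  if (any(masses <= 0)) rlang::abort("masses must be > 0")
  w <- masses / sum(masses)
  com <- colSums(coords * w)
  d2 <- rowSums(sweep(coords, 2, com)^2)
  sqrt(sum(w * d2))
}

#' Per-frame radius-of-gyration series
#'
#' @param ens A [conformer_ensemble]; masses are taken from the atom table
#'   (unit masses where `NA`).
#' @param ... Selection arguments forwarded to [select_atoms()] (e.g.
#'   `residues = 101:150`).
#' @return A tibble with columns `frame` and `rg` (Angstrom), frame-ordered.
#' @export
rg_series <- function(ens, ...) {
  if (...length() > 0L) ens <- select_atoms(ens, ...)
  masses <- ens$atoms$mass
  if (anyNA(masses)) masses <- rep(1, n_atoms(ens))
  tibble::tibble(
    frame = seq_len(n_frames(ens)),
    rg = purrr::map_dbl(ens$frames, radius_of_gyration, masses = masses)
  )
}

rg_values <- function(x) {
  if (is.data.frame(x)) x$rg else as.numeric(x)
}

#' Normalized R_g histogram
#'
#' Histogram of per-frame R_g values with frequencies normalized to sum to
#' one, the form in which reference and probe ensembles are overlaid and
#' compared. The default 1-Angstrom bins on a 0-40 Angstrom range cover the
#' compact-to-extended span of 50-residue peptides.
#'
#' @param series An `rg` tibble from [rg_series()] or a numeric vector.
#' @param bin_width Bin width in Angstrom (> 0). Ignored when `bin_count`
#'   is given.
#' @param bin_count Alternative: number of equal bins over the data range.
#' @param range Histogram range; extended automatically if data fall
#'   outside.
#' @return A tibble with columns `bin_lo`, `bin_hi`, `bin_mid`,
#'   `frequency`; frequencies sum to 1.
#' @export
rg_histogram <- function(series, bin_width = 1, bin_count = NULL,
                         range = c(0, 40)) {
  x <- rg_values(series)
  if (length(x) < 1L) rlang::abort("need at least one value")
  if (is.null(bin_count)) {
    if (bin_width <= 0) rlang::abort("bin_width must be > 0")
    lo <- min(range[1], floor(min(x) / bin_width) * bin_width)
    hi <- max(range[2], ceiling(max(x) / bin_width) * bin_width)
    edges <- seq(lo, hi, by = bin_width)
    if (max(x) >= edges[length(edges)]) {
      edges <- c(edges, edges[length(edges)] + bin_width)
    }
  } else {
    if (bin_count < 1) rlang::abort("bin_count must be >= 1")
    lo <- min(x)
    hi <- max(x)
    if (lo == hi) hi <- lo + 1e-9
    edges <- seq(lo, hi, length.out = bin_count + 1L)
  }
  counts <- graphics::hist(x, breaks = edges, plot = FALSE,
    right = FALSE, include.lowest = TRUE)$counts
  tibble::tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
    frequency = counts / length(x)
  )
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' Supremum distance between the empirical CDFs of two R_g series — a
#' quantitative counterpart to overlaying normalized distributions. Exact
#' for tied values.
#'
#' @param a,b `rg` tibbles or numeric vectors (non-empty).
#' @return D in `[0, 1]`.
#' @export
ks_statistic <- function(a, b) {
  a <- rg_values(a)
  b <- rg_values(b)
  if (length(a) < 1L || length(b) < 1L) rlang::abort("series must be non-empty")
  pts <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a)(pts)
  fb <- stats::ecdf(b)(pts)
  max(abs(fa - fb))
}

#' Order statistics of an R_g series
#'
#' Mean, SD, IQR, 5th/95th percentiles and the fraction of frames above an
#' extendedness threshold (default 15 Angstrom, the boundary between
#' compact-centered and broad distributions for 50-residue peptides).
#' Percentiles use linear interpolation (type 7).
#'
#' @param series An `rg` tibble or numeric vector.
#' @param threshold Extendedness threshold in Angstrom.
#' @return A one-row tibble: `n`, `mean`, `sd`, `iqr`, `p5`, `p95`,
#'   `width_p5_p95`, `frac_above`.
#' @export
spread_stats <- function(series, threshold = 15) {
  x <- rg_values(series)
  if (length(x) < 1L) rlang::abort("series must be non-empty")
  q <- stats::quantile(x, c(0.05, 0.25, 0.75, 0.95), names = FALSE, type = 7)
  tibble::tibble(
    n = length(x),
    mean = mean(x),
    sd = if (length(x) > 1L) stats::sd(x) else 0,
    iqr = q[3] - q[2],
    p5 = q[1],
    p95 = q[4],
    width_p5_p95 = q[4] - q[1],
    frac_above = mean(x > threshold)
  )
}

#' Switch rule thresholds
#'
#' Defaults operationalizing a "pronounced transformation from a wide to a
#' narrow R_g distribution": the perturbed ensemble must lose at least half
#' the reference IQR, deplete the extended tail (R_g above
#' `tail_threshold`) by at least 0.25, and differ by KS distance >= 0.3.
#'
#' @param spread_reduction_min,tail_depletion_min,ks_min Flagging
#'   thresholds.
#' @param tail_threshold Extendedness boundary in Angstrom.
#' @return A named list of thresholds.
#' @export
switch_rule <- function(spread_reduction_min = 0.5, tail_depletion_min = 0.25,
                        ks_min = 0.3, tail_threshold = 15) {
  list(
    spread_reduction_min = spread_reduction_min,
    tail_depletion_min = tail_depletion_min,
    ks_min = ks_min,
    tail_threshold = tail_threshold
  )
}

#' Switch statistic between reference and perturbed ensembles
#'
#' Compares the R_g series of a peptide in a reference condition (water)
#' and a perturbed condition (probe or ligand) and flags
#' probe-induced compaction. Components: `mean_shift = mean(ref) -
#' mean(pert)`; `spread_reduction = 1 - IQR(pert)/IQR(ref)`;
#' `tail_depletion = P_ref(Rg > T) - P_pert(Rg > T)`; `ks_D` from
#' [ks_statistic()]. The tile is flagged when all three of spread
#' reduction, tail depletion and KS distance meet the rule's thresholds.
#'
#' @param reference,perturbed `rg` tibbles or numeric vectors.
#' @param rule A [switch_rule()] list.
#' @return A one-row tibble: `mean_shift`, `spread_reduction`,
#'   `tail_depletion`, `ks_D`, `flagged`, `degenerate_reference`. When the
#'   reference IQR is zero, `spread_reduction` is reported as 0 with
#'   `degenerate_reference = TRUE` and a warning.
#' @export
switch_statistic <- function(reference, perturbed, rule = switch_rule()) {
  ref <- rg_values(reference)
  pert <- rg_values(perturbed)
  if (length(ref) < 1L || length(pert) < 1L) {
    rlang::abort("both series must be non-empty")
  }
  thr <- rule$tail_threshold
  iqr_ref <- stats::IQR(ref, type = 7)
  iqr_pert <- stats::IQR(pert, type = 7)
  degenerate <- iqr_ref == 0
  if (degenerate) {
    rlang::warn("reference IQR is zero; spread_reduction reported as 0")
    spread_reduction <- 0
  } else {
    spread_reduction <- 1 - iqr_pert / iqr_ref
  }
  tail_depletion <- mean(ref > thr) - mean(pert > thr)
  ks_d <- ks_statistic(ref, pert)
  tibble::tibble(
    mean_shift = mean(ref) - mean(pert),
    spread_reduction = spread_reduction,
    tail_depletion = tail_depletion,
    ks_D = ks_d,
    flagged = !degenerate &&
      spread_reduction >= rule$spread_reduction_min &&
      tail_depletion >= rule$tail_depletion_min &&
      ks_d >= rule$ks_min,
    degenerate_reference = degenerate
  )
}

#' R_g-energy landscape
#'
#' Pairs per-frame R_g with min-max normalized per-frame energies, the 2-D
#' view in which compact conformations spread along the energy axis while
#' extended ones concentrate at unfavorable energies. When two conditions
#' are compared, normalization defaults to the joint domain (both pooled)
#' so the conditions share an energy scale.
#'
#' @param rg Per-frame R_g values (tibble or numeric).
#' @param energy Per-frame energies, same length (kcal/mol).
#' @param condition Optional per-frame condition labels (recycled scalar
#'   allowed).
#' @param domain `"joint"` (normalize over all points pooled) or
#'   `"separate"` (normalize within each condition).
#' @return A tibble with columns `condition`, `rg`, `energy`,
#'   `energy_norm` (in `[0, 1]`). If all energies in a normalization domain
#'   are identical, `energy_norm` is 0 there, with a warning.
#' @export
rg_landscape <- function(rg, energy, condition = "all",
                         domain = c("joint", "separate")) {
  domain <- match.arg(domain)
  rg <- rg_values(rg)
  if (length(rg) != length(energy)) {
    rlang::abort("rg and energy must have equal length")
  }
  df <- tibble::tibble(
    condition = rep_len(as.character(condition), length(rg)),
    rg = rg,
    energy = as.numeric(energy)
  )
  norm01 <- function(e) {
    rng <- range(e)
    if (rng[1] == rng[2]) {
      rlang::warn("all energies identical; normalized values set to 0")
      rep(0, length(e))
    } else {
      (e - rng[1]) / (rng[2] - rng[1])
    }
  }
  if (domain == "joint") {
    df$energy_norm <- norm01(df$energy)
  } else {
    df <- dplyr::mutate(dplyr::group_by(df, .data$condition),
      energy_norm = norm01(.data$energy))
    df <- dplyr::ungroup(df)
  }
  attr(df, "domain") <- domain
  df
}
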