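#' Configure a tiling switch screen
#'
#' Assembles the inputs of an end-to-end screen: a sequence to tile, per
#' tile a reference and a perturbed ensemble (either multi-model PDB files
#' or synthetic generator regimes), the switch-rule thresholds, and a
#' single top-level seed behind all randomness.
#'
#' In synthetic mode each tile is assigned a regime: `"compact"` tiles
#' sample the compact model in both conditions (narrow, probe-insensitive
#' peptides), `"broad"` tiles sample a 50/50 compact/extended mixture in
#' both conditions, and `"hit"` tiles sample the mixture as reference but
#' the compact model as perturbed — a planted probe-induced switch. The
#' default regime layout mirrors a nine-tile screen of a 439-residue
#' disordered protein with one switch at tile 3 (positions 101-150):
#' compact, compact, hit, compact, broad, broad, broad, compact, compact.
#'
#' @param seq A [protein_sequence] to tile (default the synthetic
#'   439-residue scaffold).
#' @param window,step,offset,keep_partial Tiling parameters (see
#'   [tile_sequence()]).
#' @param mode `"synthetic"` (generate ensembles) or `"files"` (read
#'   them).
#' @param regimes In synthetic mode, a character vector (one of
#'   `"compact"`, `"broad"`, `"hit"` per tile, recycled if length 1) or
#'   `NULL` for the default layout.
#' @param n_frames Frames per condition per tile (synthetic mode).
#' @param compact,extended Component [chain_model()]s (synthetic mode).
#' @param p_compact Mixture weight of the compact component in the broad
#'   regime.
#' @param reference_paths,perturbed_paths In files mode, named character
#'   vectors of multi-model PDB paths keyed by tile name (missing or
#'   unreadable perturbed entries mark the tile "untested").
#' @param rule A [switch_rule()] list.
#' @param seed Integer top-level seed.
#' @param out_dir Optional output directory for TSV reports.
#' @return A `screen_config` list, validated.
#' @export
screen_config <- function(seq = myc_scaffold_synthetic(), window = 50L,
                          step = window, offset = 0L, keep_partial = TRUE,
                          mode = c("synthetic", "files"), regimes = NULL,
                          n_frames = 150L, compact = compact_chain_model(),
                          extended = extended_chain_model(),
                          p_compact = 0.5, reference_paths = NULL,
                          perturbed_paths = NULL, rule = switch_rule(),
                          seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  tiles <- tile_sequence(seq, window, step, offset, keep_partial)
  if (mode == "synthetic") {
    if (is.null(regimes)) {
      regimes <- rep("compact", nrow(tiles))
      broad_default <- c(3L, 5L, 6L, 7L)
      regimes[broad_default[broad_default <= nrow(tiles)]] <- "broad"
      if (nrow(tiles) >= 3L) regimes[3L] <- "hit"
    }
    regimes <- rep_len(regimes, nrow(tiles))
    bad <- setdiff(unique(regimes), c("compact", "broad", "hit"))
    if (length(bad) > 0) {
      rlang::abort(sprintf("unknown regime(s): %s", paste(bad, collapse = ", ")))
    }
  } else {
    if (is.null(reference_paths)) {
      rlang::abort("files mode requires reference_paths")
    }
    missing_ref <- setdiff(tiles$name, names(reference_paths))
    if (length(missing_ref) > 0) {
      rlang::abort(sprintf(
        "no reference ensemble for tile(s): %s",
        paste(missing_ref, collapse = ", ")
      ))
    }
    regimes <- rep(NA_character_, nrow(tiles))
  }
  structure(
    list(
      tiles = tiles, mode = mode, regimes = regimes, n_frames = n_frames,
      compact = compact, extended = extended, p_compact = p_compact,
      reference_paths = reference_paths, perturbed_paths = perturbed_paths,
      rule = rule, seed = as.integer(seed), out_dir = out_dir
    ),
    class = "screen_config"
  )
}

#' Run a tiling switch screen
#'
#' For every tile, computes the per-frame R_g series of the reference and
#' perturbed ensembles, their spread statistics and [switch_statistic()],
#' and returns a one-row-per-tile report with a ranked flag list. Tiles
#' whose perturbed ensemble is missing are reported `"untested"`, never
#' flagged; per-tile read errors are recorded and the run continues. The
#' run is deterministic given the config seed.
#'
#' @param config A [screen_config()].
#' @return A `switch_report`: a tibble with one row per tile (tile
#'   coordinates, per-condition mean/IQR/extended-tail statistics, switch
#'   components, `flagged`, `status`), with the config attached as an
#'   attribute. `tidy()` returns the tibble; `glance()` a one-row summary.
#'   If `out_dir` is set, writes `switch_report.tsv` there.
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  tiles <- config$tiles
  rows <- vector("list", nrow(tiles))
  for (i in seq_len(nrow(tiles))) {
    pair <- tryCatch(
      screen_tile_series(config, i),
      error = function(e) e
    )
    if (inherits(pair, "error")) {
      rows[[i]] <- tibble::tibble(
        tile = tiles$name[i], start = tiles$start[i], end = tiles$end[i],
        status = paste0("error: ", conditionMessage(pair))
      )
      next
    }
    ref_stats <- spread_stats(pair$reference,
      threshold = config$rule$tail_threshold)
    row <- tibble::tibble(
      tile = tiles$name[i], start = tiles$start[i], end = tiles$end[i],
      ref_mean = ref_stats$mean, ref_iqr = ref_stats$iqr,
      ref_frac_extended = ref_stats$frac_above
    )
    if (is.null(pair$perturbed)) {
      rows[[i]] <- dplyr::bind_cols(row, tibble::tibble(
        pert_mean = NA_real_, pert_iqr = NA_real_,
        pert_frac_extended = NA_real_, mean_shift = NA_real_,
        spread_reduction = NA_real_, tail_depletion = NA_real_,
        ks_D = NA_real_, flagged = FALSE, status = "untested"
      ))
      next
    }
    pert_stats <- spread_stats(pair$perturbed,
      threshold = config$rule$tail_threshold)
    sw <- switch_statistic(pair$reference, pair$perturbed, config$rule)
    rows[[i]] <- dplyr::bind_cols(
      row,
      tibble::tibble(
        pert_mean = pert_stats$mean, pert_iqr = pert_stats$iqr,
        pert_frac_extended = pert_stats$frac_above
      ),
      sw[c("mean_shift", "spread_reduction", "tail_depletion", "ks_D",
        "flagged")],
      tibble::tibble(status = "ok")
    )
  }
  report <- dplyr::bind_rows(rows)
  report$flagged[is.na(report$flagged)] <- FALSE
  class(report) <- c("switch_report", class(report))
  attr(report, "config") <- config
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(
      as.data.frame(report)[order(-replace(report$ks_D, is.na(report$ks_D), -1)), ],
      file.path(config$out_dir, "switch_report.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  report
}

# reference/perturbed R_g series for tile i (synthetic or file mode)
screen_tile_series <- function(config, i) {
  if (config$mode == "synthetic") {
    base_seed <- config$seed + 1000L * i
    regime <- config$regimes[i]
    ref_ens <- switch(regime,
      compact = sample_chain(config$compact, config$n_frames,
        seed = base_seed),
      mixture_ensemble(config$p_compact, config$compact, config$extended,
        config$n_frames, seed = base_seed)
    )
    pert_ens <- switch(regime,
      hit = sample_chain(config$compact, config$n_frames,
        seed = base_seed + 500L),
      compact = sample_chain(config$compact, config$n_frames,
        seed = base_seed + 500L),
      mixture_ensemble(config$p_compact, config$compact, config$extended,
        config$n_frames, seed = base_seed + 500L)
    )
    list(reference = rg_series(ref_ens), perturbed = rg_series(pert_ens))
  } else {
    name <- config$tiles$name[i]
    ref_ens <- read_multimodel_pdb(config$reference_paths[[name]])
    pert <- NULL
    if (name %in% names(config$perturbed_paths)) {
      pert_path <- config$perturbed_paths[[name]]
      if (file.exists(pert_path)) {
        pert <- rg_series(read_multimodel_pdb(pert_path))
      }
    }
    list(reference = rg_series(ref_ens), perturbed = pert)
  }
}

#' @export
print.switch_report <- function(x, ...) {
  cat(sprintf(
    "<switch_report> %d tiles, %d flagged\n", nrow(x), sum(x$flagged)
  ))
  if (any(x$flagged)) {
    cat("  flagged:", paste(x$tile[x$flagged], collapse = ", "), "\n")
  }
  NextMethod()
}

#' @rdname run_screen
#' @param x A `switch_report`.
#' @param ... Unused.
#' @method tidy switch_report
#' @export
tidy.switch_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "switch_report")
  attr(out, "config") <- NULL
  out
}

#' @rdname run_screen
#' @method glance switch_report
#' @export
glance.switch_report <- function(x, ...) {
  tibble::tibble(
    n_tiles = nrow(x),
    n_flagged = sum(x$flagged),
    n_untested = sum(x$status == "untested"),
    n_errors = sum(startsWith(x$status, "error"))
  )
}

#' Probe molecules for a target concentration
#'
#' Number of co-solvent probe molecules corresponding to a molar
#' concentration in a simulation box of given volume:
#' `round(molarity * N_A * 1e-27 * volume)` with volume in cubic Angstrom.
#'
#' @param box_volume Box volume in A^3 (> 0).
#' @param molarity Target concentration in mol/L (>= 0).
#' @return Integer molecule count.
#' @examples
#' probe_count(1e5, 0.4) # 24
#' @export
probe_count <- function(box_volume, molarity) {
  if (box_volume <= 0) rlang::abort("box_volume must be > 0")
  if (molarity < 0) rlang::abort("molarity must be >= 0")
  as.integer(round(molarity * 6.02214076e-4 * box_volume))
}

#' Reproducibility manifest for a screen
#'
#' Records package version, seed, tiling and rule parameters, and MD5
#' digests of any input files, so a run can be reproduced and inputs
#' verified. Round-trips through JSON.
#'
#' @param config A [screen_config()].
#' @return A named list (class `screen_manifest`).
#' @export
make_manifest <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  files <- c(config$reference_paths, config$perturbed_paths)
  digests <- if (length(files) > 0) {
    existing <- files[file.exists(files)]
    as.list(tools::md5sum(existing))
  } else {
    list()
  }
  structure(
    list(
      package = "switchtile",
      version = as.character(utils::packageVersion("switchtile")),
      mode = config$mode,
      seed = config$seed,
      n_tiles = nrow(config$tiles),
      tile_names = config$tiles$name,
      regimes = config$regimes,
      n_frames = config$n_frames,
      p_compact = config$p_compact,
      rule = config$rule,
      input_digests = digests
    ),
    class = "screen_manifest"
  )
}

#' @rdname make_manifest
#' @param manifest A `screen_manifest`.
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname make_manifest
#' @export
read_manifest <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
    class = "screen_manifest")
}
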