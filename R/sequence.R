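#' Protein sequence objects
#'
#' A lightweight container for a one-letter amino-acid sequence with an
#' identifier and a 1-based numbering offset (the parent-sequence position
#' of the first residue). All positions reported by profile and tiling
#' functions are in parent coordinates.
#'
#' @param sequence Character scalar of one-letter codes, or a character
#'   vector of single codes.
#' @param id Text label.
#' @param offset 1-based parent position of the first residue (default 1).
#' @return An object of class `protein_sequence`.
#' @examples
#' protein_sequence("MVTELL", id = "demo")
#' @export
protein_sequence <- function(sequence, id = "seq", offset = 1L) {
  res <- if (length(sequence) == 1L) {
    strsplit(toupper(sequence), "")[[1]]
  } else {
    toupper(as.character(sequence))
  }
  if (length(res) < 1L) {
    rlang::abort("sequence must contain at least one residue")
  }
  bad <- which(!res %in% names(.residue_avg_mass))
  if (length(bad) > 0L) {
    rlang::abort(sprintf(
      "non-standard residue code '%s' at position %d of '%s'",
      res[bad[1]], bad[1], id
    ))
  }
  if (!is.numeric(offset) || length(offset) != 1L || offset < 1) {
    rlang::abort("offset must be a single integer >= 1")
  }
  structure(
    list(id = as.character(id), residues = res, offset = as.integer(offset)),
    class = "protein_sequence"
  )
}

#' @export
print.protein_sequence <- function(x, ...) {
  n <- length(x$residues)
  cat(sprintf(
    "<protein_sequence> %s: %d residues (positions %d-%d)\n",
    x$id, n, x$offset, x$offset + n - 1L
  ))
  seq_str <- paste(x$residues, collapse = "")
  if (nchar(seq_str) > 60) seq_str <- paste0(substr(seq_str, 1, 57), "...")
  cat(" ", seq_str, "\n")
  invisible(x)
}

#' @export
length.protein_sequence <- function(x) length(x$residues)

#' @rdname protein_sequence
#' @param x A `protein_sequence`.
#' @export
residues <- function(x) x$residues

#' Residue positions in parent coordinates
#' @param x A `protein_sequence`.
#' @return Integer vector of 1-based parent positions.
#' @export
positions <- function(x) x$offset + seq_along(x$residues) - 1L

as_protein_sequence <- function(x, id = "seq") {
  if (inherits(x, "protein_sequence")) x else protein_sequence(x, id = id)
}

#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings for single- and multi-record protein
#' FASTA files, returning/accepting [protein_sequence] objects.
#'
#' @param path File path.
#' @return `read_fasta()` returns a list of [protein_sequence] objects,
#'   named by record id.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    rlang::abort("reading FASTA requires the Biostrings package")
  }
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  out <- purrr::map2(
    as.character(set), ids,
    function(s, id) protein_sequence(s, id = id)
  )
  stats::setNames(out, ids)
}

#' @rdname read_fasta
#' @param seqs A [protein_sequence] or list of them.
#' @export
write_fasta <- function(seqs, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    rlang::abort("writing FASTA requires the Biostrings package")
  }
  if (inherits(seqs, "protein_sequence")) seqs <- list(seqs)
  strs <- purrr::map_chr(seqs, function(s) paste(s$residues, collapse = ""))
  set <- Biostrings::AAStringSet(strs)
  names(set) <- purrr::map_chr(seqs, "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Tile a sequence into peptide windows
#'
#' Divides a protein sequence into fixed-width tiles, the reductionist move
#' that turns one disordered protein into an ensemble-simulatable peptide
#' library. With `step = window` the tiles are non-overlapping; a 439-residue
#' sequence yields nine tiles of which the last spans positions 401-439
#' (39 residues). Starting from `offset = 24` with `keep_partial = FALSE`
#' gives the eight overlapping 50-residue derivatives 25-74 ... 375-424.
#'
#' @param seq A [protein_sequence] (or character scalar).
#' @param window Tile width in residues (>= 1).
#' @param step Stride between tile starts (default `window`:
#'   non-overlapping).
#' @param offset Number of leading residues to skip before the first tile
#'   (0 <= offset < length).
#' @param keep_partial If `TRUE` (default) a final shorter tile is emitted
#'   when the window overruns the sequence end; if `FALSE` such tiles are
#'   dropped.
#' @return A tibble with columns `parent_id`, `start`, `end` (1-based
#'   inclusive parent coordinates), `sequence`, and `name`
#'   (`"<parent>_<start>-<end>"`).
#' @examples
#' tile_sequence(myc_scaffold_synthetic(), window = 50)
#' @export
tile_sequence <- function(seq, window, step = window, offset = 0L,
                          keep_partial = TRUE) {
  seq <- as_protein_sequence(seq)
  n <- length(seq$residues)
  if (window < 1 || step < 1) {
    rlang::abort("window and step must be >= 1")
  }
  if (offset < 0 || offset >= n) {
    rlang::abort(sprintf("offset must satisfy 0 <= offset < %d", n))
  }
  starts <- seq.int(offset + 1L, n, by = step)
  ends <- pmin(starts + window - 1L, n)
  if (!keep_partial) {
    keep <- (starts + window - 1L) <= n
    starts <- starts[keep]
    ends <- ends[keep]
  }
  # drop zero-length leftovers (start past the end can't occur by seq.int)
  seq_chr <- purrr::map2_chr(starts, ends, function(s, e) {
    paste(seq$residues[s:e], collapse = "")
  })
  par_start <- seq$offset + starts - 1L
  par_end <- seq$offset + ends - 1L
  tibble::tibble(
    parent_id = seq$id,
    start = par_start,
    end = par_end,
    sequence = seq_chr,
    name = sprintf("%s_%d-%d", seq$id, par_start, par_end)
  )
}

#' Sliding-window hydropathy profile
#'
#' Per-residue hydropathy scores smoothed by a centered sliding mean. At the
#' termini the window is truncated to the available residues, so the profile
#' has one value per position. `window = 1` returns the raw scale values.
#'
#' @param seq A [protein_sequence].
#' @param scale A scale name understood by [hydropathy_scale()], or a named
#'   numeric vector covering all 20 standard residues.
#' @param window Odd smoothing width in residues (default 9).
#' @return A tibble with columns `position` (parent coordinates), `residue`,
#'   and `value`; attributes `scale_name` and `window`.
#' @export
hydropathy_profile <- function(seq, scale = "miyazawa", window = 9L) {
  seq <- as_protein_sequence(seq)
  if (is.character(scale) && length(scale) == 1L) {
    scale_name <- scale
    scale <- hydropathy_scale(scale)
  } else {
    scale_name <- "custom"
  }
  missing_codes <- setdiff(names(.residue_avg_mass), names(scale))
  if (length(missing_codes) > 0L) {
    rlang::abort(sprintf(
      "scale does not define residue(s): %s",
      paste(missing_codes, collapse = ", ")
    ))
  }
  check_odd_window(window)
  raw <- unname(scale[seq$residues])
  prof <- tibble::tibble(
    position = positions(seq),
    residue = seq$residues,
    value = sliding_mean(raw, window)
  )
  attr(prof, "scale_name") <- scale_name
  attr(prof, "window") <- as.integer(window)
  prof
}

check_odd_window <- function(window) {
  if (window < 1 || window %% 2 == 0) {
    rlang::abort("window must be a positive odd integer")
  }
}

# centered sliding mean, truncated at the ends
sliding_mean <- function(x, window) {
  h <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Fraction of hydrophobic residues
#'
#' The proportion of residues belonging to a hydrophobic set; with the
#' default bulky-hydrophobic set \{A,C,F,I,L,M,V,W\} the coreMYC epitope is
#' exactly 0.5.
#'
#' @param seq A [protein_sequence].
#' @param hydrophobic Character vector of one-letter codes counted as
#'   hydrophobic (default [hydrophobic_residues()]).
#' @return Numeric scalar in `[0, 1]`.
#' @export
hydrophobic_fraction <- function(seq, hydrophobic = hydrophobic_residues()) {
  seq <- as_protein_sequence(seq)
  mean(seq$residues %in% hydrophobic)
}

#' Fold-index style disorder proxy
#'
#' A deterministic per-residue disorder score for use when external
#' predictor output (e.g. VSL2 scores read with [read_disorder_csv()]) is
#' unavailable. It is the negated fold index of Prilusky et al. (2005)
#' computed over a sliding window: windowed mean Kyte-Doolittle hydropathy
#' rescaled to `[0, 1]`, `H`, and windowed mean absolute net charge `|q|`,
#' combined as `score = -(2.785 * H - |q| - 1.151)`. Higher values mean more
#' disordered; positive values fall in the predicted-disordered half of the
#' scale.
#'
#' @param seq A [protein_sequence].
#' @param window Odd window width (default 9).
#' @return A tibble with columns `position`, `residue`, `value`.
#' @export
disorder_proxy <- function(seq, window = 9L) {
  seq <- as_protein_sequence(seq)
  check_odd_window(window)
  kd <- hydropathy_scale("kyte_doolittle")
  h_scaled <- (unname(kd[seq$residues]) + 4.5) / 9
  q <- unname(.residue_charge[seq$residues])
  q[is.na(q)] <- 0
  h_win <- sliding_mean(h_scaled, window)
  q_win <- abs(sliding_mean(q, window))
  tibble::tibble(
    position = positions(seq),
    residue = seq$residues,
    value = -(2.785 * h_win - q_win - 1.151)
  )
}

#' Read per-residue disorder scores from CSV
#'
#' Accepts external disorder-predictor output as a two-column CSV
#' (`position,score`), e.g. VSL2 scores exported from its web service.
#'
#' @param path CSV file path (header required; `#` comments and blank lines
#'   tolerated).
#' @return A tibble with columns `position` and `value`.
#' @export
read_disorder_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", blank.lines.skip = TRUE)
  if (ncol(df) < 2L) {
    rlang::abort("disorder CSV must have columns position,score")
  }
  tibble::tibble(
    position = as.integer(df[[1]]),
    value = as.numeric(df[[2]])
  )
}

#' Correlation between two residue profiles
#'
#' Pearson or Spearman correlation of two profiles aligned on identical
#' positions — e.g. the inverse correlation between disorder and
#' hydrophobicity along a disordered protein.
#'
#' @param a,b Profile tibbles with `position` and `value` columns (as
#'   returned by [hydropathy_profile()] or [disorder_proxy()]).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
profile_correlation <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(a) != nrow(b) || !all(a$position == b$position)) {
    rlang::abort("profiles must be aligned on identical positions")
  }
  if (stats::sd(a$value) == 0 || stats::sd(b$value) == 0) {
    rlang::abort("correlation undefined: a profile has zero variance")
  }
  stats::cor(a$value, b$value, method = method)
}

#' Average peptide mass
#'
#' Average (not monoisotopic) isotopic mass of a peptide: the sum of residue
#' masses plus one water, adjusted for terminal modifications. Supports the
#' N-terminal acetylation and C-terminal amidation used for synthetic
#' peptides in native MS work.
#'
#' @param seq A [protein_sequence].
#' @param nterm N-terminal state: `"free"`, `"acetyl"` (+42.0367 Da) or
#'   `"formyl"` (+28.0101 Da).
#' @param cterm C-terminal state: `"free"` or `"amide"` (-0.9847 Da).
#' @return Mass in Da.
#' @examples
#' peptide_average_mass(protein_sequence("G")) # 75.07
#' @export
peptide_average_mass <- function(seq, nterm = c("free", "acetyl", "formyl"),
                                 cterm = c("free", "amide")) {
  seq <- as_protein_sequence(seq)
  nterm <- match.arg(nterm)
  cterm <- match.arg(cterm)
  mass <- sum(.residue_avg_mass[seq$residues]) + .water_avg_mass
  mass <- mass + switch(nterm, free = 0, acetyl = 42.0367, formyl = 28.0101)
  mass <- mass + switch(cterm, free = 0, amide = -0.9847)
  unname(mass)
}

#' m/z series for a neutral mass
#'
#' Positive-mode m/z values `(M + z * m_p) / z` for a set of charge states,
#' as observed in native electrospray spectra.
#'
#' @param mass Neutral mass in Da (> 0).
#' @param charges Integer charge states (>= 1).
#' @return A tibble with columns `charge` and `mz`, ordered as given.
#' @export
mz_series <- function(mass, charges) {
  if (!is.numeric(mass) || mass <= 0) rlang::abort("mass must be > 0")
  charges <- as.integer(charges)
  if (any(charges < 1L)) rlang::abort("charges must be >= 1")
  tibble::tibble(
    charge = charges,
    mz = (mass + charges * .proton_mass) / charges
  )
}
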