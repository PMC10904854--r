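#' Read a multi-model PDB file as a conformer ensemble
#'
#' One frame per `MODEL`/`ENDMDL` block (a file without `MODEL` records is a
#' single frame). Elements are taken from PDB columns 77-78, falling back to
#' the first letter of the atom name. Parameter columns are left `NA` until
#' [merge_parameters()] is applied. Blank lines and `#` comments are
#' tolerated. Parsing is delegated to bio3d after a consistency pre-scan
#' that reports the offending model or line on malformed input.
#'
#' @param path PDB file path.
#' @return A [conformer_ensemble].
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  line_no <- which(keep)

  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  is_model <- grepl("^MODEL", lines)
  # model id per atom line: 1 if no MODEL records at all
  model_of <- cumsum(is_model)
  model_of[model_of == 0L] <- 1L
  atom_models <- model_of[is_atom]
  if (!any(is_atom)) rlang::abort("no ATOM/HETATM records found")
  counts <- table(atom_models)
  if (length(unique(as.integer(counts))) > 1L) {
    bad <- names(counts)[which(as.integer(counts) != as.integer(counts)[1])[1]]
    rlang::abort(sprintf(
      "inconsistent atom count in model %s (%s atoms; model 1 has %s)",
      bad, counts[[bad]], counts[[1]]
    ))
  }
  coord_txt <- substr(lines[is_atom], 31, 54)
  ok <- grepl("^[-+ .0-9]{24}$", coord_txt)
  if (!all(ok)) {
    bad_line <- line_no[is_atom][which(!ok)[1]]
    rlang::abort(sprintf("unparseable coordinates at line %d", bad_line))
  }

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, multi = TRUE, verbose = FALSE)

  at <- pdb$atom
  elem <- trimws(at$elesy)
  fallback <- toupper(substr(trimws(at$elety), 1, 1))
  elem[is.na(elem) | elem == ""] <- fallback[is.na(elem) | elem == ""]
  atoms <- tibble::tibble(
    index = seq_len(nrow(at)),
    name = trimws(at$elety),
    element = elem,
    residue_id = as.integer(at$resno),
    residue_name = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- purrr::map(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  })
  conformer_ensemble(atoms, frames,
    provenance = sprintf("read_multimodel_pdb(%s)", path)
  )
}

#' @rdname read_multimodel_pdb
#' @param ens A [conformer_ensemble].
#' @details `write_multimodel_pdb()` emits standard fixed-column records
#'   with occupancy 1.00 and B-factor 0.00; `CONECT` records are not
#'   written.
#' @export
write_multimodel_pdb <- function(ens, path) {
  at <- ens$atoms
  xyz <- do.call(rbind, purrr::map(ens$frames, function(f) as.vector(t(f))))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    resno = at$residue_id, resid = at$residue_name,
    eleno = at$index, elety = at$name, chain = at$chain,
    o = rep(1, nrow(at)), b = rep(0, nrow(at)),
    elesy = at$element
  )
  invisible(path)
}

#' Read and write XYZ trajectories
#'
#' Plain multi-frame XYZ files (per frame: atom count line, comment line,
#' then `element x y z` rows). An existing ensemble supplies the topology;
#' frames are appended in file order, in Angstrom. Blank lines and `#`
#' comments between frames are tolerated.
#'
#' @param path XYZ file path.
#' @param template A [conformer_ensemble] providing the topology; frame
#'   atom counts must match.
#' @return A [conformer_ensemble] with the template topology and the file's
#'   frames.
#' @export
read_xyz_traj <- function(path, template) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  n_want <- n_atoms(template)
  frames <- list()
  i <- 1L
  frame_idx <- 0L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    frame_idx <- frame_idx + 1L
    if (is.na(n)) {
      rlang::abort(sprintf("frame %d: expected an atom-count line", frame_idx))
    }
    if (n != n_want) {
      rlang::abort(sprintf(
        "frame %d has %d atoms; template has %d", frame_idx, n, n_want
      ))
    }
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(coords)) {
      rlang::abort(sprintf("frame %d: unparseable coordinates", frame_idx))
    }
    frames[[frame_idx]] <- coords
    i <- i + 2L + n
  }
  conformer_ensemble(template$atoms, frames,
    provenance = sprintf("read_xyz_traj(%s)", path)
  )
}

#' @rdname read_xyz_traj
#' @param ens A [conformer_ensemble] to write.
#' @export
write_xyz_traj <- function(ens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  elem <- ens$atoms$element
  for (i in seq_len(n_frames(ens))) {
    f <- ens$frames[[i]]
    writeLines(c(
      as.character(nrow(f)),
      sprintf("frame %d", i),
      sprintf("%-2s %12.6f %12.6f %12.6f", elem, f[, 1], f[, 2], f[, 3])
    ), con)
  }
  invisible(path)
}

#' Per-atom parameter tables
#'
#' Parameter tables assign mass, charge, Lennard-Jones parameters and
#' generalized-Born radii to atoms, keyed by `(residue_name, atom_name)`.
#' The shipped default table covers the one-bead-per-residue representation
#' used by the synthetic generators plus a minimal backbone heavy-atom set;
#' it is a simplified, package-defined parameterization, not a molecular
#' mechanics force field.
#'
#' @param path TSV file with header columns `residue_name`, `atom_name`,
#'   `mass`, `charge`, `lj_epsilon`, `lj_rmin_half`, `gb_radius`. Blank
#'   lines and `#` comments are tolerated.
#' @return A tibble keyed by `(residue_name, atom_name)`.
#' @export
read_param_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", blank.lines.skip = TRUE,
    stringsAsFactors = FALSE)
  required <- c("residue_name", "atom_name", "mass", "charge",
    "lj_epsilon", "lj_rmin_half", "gb_radius")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    rlang::abort(sprintf(
      "parameter table missing column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  key <- paste(df$residue_name, df$atom_name)
  if (anyDuplicated(key)) {
    rlang::abort(sprintf(
      "duplicate parameter key: %s", key[anyDuplicated(key)]
    ))
  }
  tibble::as_tibble(df[required])
}

#' @rdname read_param_table
#' @export
default_param_table <- function() {
  read_param_table(
    system.file("extdata", "bead_params.tsv", package = "switchtile",
      mustWork = TRUE)
  )
}

#' Merge a parameter table onto an ensemble
#'
#' Fills the `mass`, `charge`, `lj_epsilon`, `lj_rmin_half` and `gb_radius`
#' columns of the atom table by `(residue_name, atom_name)` lookup. Every
#' atom must be covered.
#'
#' @param ens A [conformer_ensemble].
#' @param params A parameter tibble from [read_param_table()] (default: the
#'   shipped table).
#' @return The ensemble with parameter columns filled.
#' @export
merge_parameters <- function(ens, params = default_param_table()) {
  key <- paste(ens$atoms$residue_name, ens$atoms$name)
  pkey <- paste(params$residue_name, params$atom_name)
  idx <- match(key, pkey)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    rlang::abort(sprintf(
      "no parameters for atom %d (%s %s)",
      miss, ens$atoms$residue_name[miss], ens$atoms$name[miss]
    ))
  }
  for (col in c("mass", "charge", "lj_epsilon", "lj_rmin_half", "gb_radius")) {
    ens$atoms[[col]] <- params[[col]][idx]
  }
  ens
}
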