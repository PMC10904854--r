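#' Conformer ensembles
#'
#' The central container for a conformational ensemble: an atom table
#' (topology plus per-atom parameters) and an ordered list of coordinate
#' frames. Frame order is the only time axis; the topology is shared by all
#' frames. Units are Angstrom, Da, elementary charges and kcal/mol
#' throughout.
#'
#' @param atoms A tibble (or data frame) with at least columns `index`,
#'   `name`, `element`, `residue_id`, `residue_name`, `chain`. The parameter
#'   columns `mass`, `charge`, `lj_epsilon`, `lj_rmin_half`, `gb_radius` may
#'   be `NA` until [merge_parameters()] fills them.
#' @param frames A list of numeric matrices, each `n_atoms x 3`, in
#'   Angstrom.
#' @param provenance Free-text metadata (character vector).
#' @return An object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(atoms, frames, provenance = character()) {
  atoms <- tibble::as_tibble(atoms)
  required <- c("index", "name", "element", "residue_id", "residue_name", "chain")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    rlang::abort(sprintf(
      "atoms table missing column(s): %s", paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in c("mass", "charge", "lj_epsilon", "lj_rmin_half", "gb_radius")) {
    if (!col %in% names(atoms)) atoms[[col]] <- NA_real_
  }
  if (!is.list(frames) || length(frames) < 1L) {
    rlang::abort("frames must be a non-empty list of coordinate matrices")
  }
  frames <- purrr::imap(frames, function(f, i) {
    f <- as.matrix(f)
    if (ncol(f) != 3L || nrow(f) != nrow(atoms)) {
      rlang::abort(sprintf(
        "frame %d has dimensions %d x %d; expected %d x 3",
        i, nrow(f), ncol(f), nrow(atoms)
      ))
    }
    storage.mode(f) <- "double"
    dimnames(f) <- NULL
    f
  })
  structure(
    list(atoms = atoms, frames = frames, provenance = provenance),
    class = "conformer_ensemble"
  )
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf(
    "<conformer_ensemble> %d atoms, %d residues, %d frames\n",
    n_atoms(x), length(unique(x$atoms$residue_id)), n_frames(x)
  ))
  if (length(x$provenance) > 0) cat(" provenance:", x$provenance[1], "\n")
  invisible(x)
}

#' @rdname conformer_ensemble
#' @param ens A `conformer_ensemble`.
#' @export
n_frames <- function(ens) length(ens$frames)

#' @rdname conformer_ensemble
#' @export
n_atoms <- function(ens) nrow(ens$atoms)

#' Select a subset of atoms from an ensemble
#'
#' Restricts an ensemble to the atoms matching every supplied predicate
#' (`NULL` predicates are ignored). Atom order is preserved and every frame
#' is sliced consistently, so selection is idempotent.
#'
#' @param ens A [conformer_ensemble].
#' @param residues Integer vector of residue ids to keep (ranges welcome,
#'   e.g. `101:150`).
#' @param atom_names,residue_names,chains,elements Character vectors of
#'   values to keep.
#' @param indices Integer vector of atom indices (positions in the atom
#'   table) to keep.
#' @return A [conformer_ensemble] restricted to the matching atoms.
#' @export
select_atoms <- function(ens, residues = NULL, atom_names = NULL,
                         residue_names = NULL, chains = NULL,
                         elements = NULL, indices = NULL) {
  keep <- rep(TRUE, n_atoms(ens))
  if (!is.null(residues)) keep <- keep & ens$atoms$residue_id %in% residues
  if (!is.null(atom_names)) keep <- keep & ens$atoms$name %in% atom_names
  if (!is.null(residue_names)) {
    keep <- keep & ens$atoms$residue_name %in% residue_names
  }
  if (!is.null(chains)) keep <- keep & ens$atoms$chain %in% chains
  if (!is.null(elements)) keep <- keep & ens$atoms$element %in% elements
  if (!is.null(indices)) keep <- keep & seq_len(n_atoms(ens)) %in% indices
  if (!any(keep)) rlang::abort("selection matches no atoms")
  conformer_ensemble(
    ens$atoms[keep, , drop = FALSE],
    purrr::map(ens$frames, function(f) f[keep, , drop = FALSE]),
    provenance = ens$provenance
  )
}

#' Atom indices matching a selection
#'
#' @inheritParams select_atoms
#' @return Integer vector of atom positions in the atom table.
#' @export
atom_indices <- function(ens, residues = NULL, atom_names = NULL,
                         residue_names = NULL, chains = NULL,
                         elements = NULL) {
  keep <- rep(TRUE, n_atoms(ens))
  if (!is.null(residues)) keep <- keep & ens$atoms$residue_id %in% residues
  if (!is.null(atom_names)) keep <- keep & ens$atoms$name %in% atom_names
  if (!is.null(residue_names)) {
    keep <- keep & ens$atoms$residue_name %in% residue_names
  }
  if (!is.null(chains)) keep <- keep & ens$atoms$chain %in% chains
  if (!is.null(elements)) keep <- keep & ens$atoms$element %in% elements
  which(keep)
}

#' Evenly spaced frame subsample
#'
#' Selects up to `n` evenly spaced frame indices covering the whole
#' trajectory, mirroring the convention of extracting a fixed number of
#' structures spanning the entire simulation period.
#'
#' @param total Number of frames available.
#' @param n Number of frames wanted.
#' @return Integer vector of frame indices.
#' @export
evenly_spaced_frames <- function(total, n) {
  if (n >= total) return(seq_len(total))
  unique(round(seq(1, total, length.out = n)))
}
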