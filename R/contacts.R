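#' Ligand-residue contact scores over an ensemble
#'
#' For each protein residue, the mean number of ligand heavy atoms within
#' the cutoff of any of its heavy atoms, averaged over frames. A score
#' above 1 means more than one ligand atom engaged on average — the
#' threshold used to highlight contact residues of a dynamically bound
#' ligand. Hydrogens are excluded on both sides (heavy-atom convention).
#'
#' @param ens A [conformer_ensemble].
#' @param ligand Integer atom indices of the ligand (e.g.
#'   `atom_indices(ens, residue_names = "LIG")`).
#' @param residue_sel Optional integer atom indices restricting the protein
#'   side (default: all non-ligand atoms).
#' @param cutoff Contact distance in Angstrom (default 4.5).
#' @return A tibble with columns `residue_id`, `residue_name`, `chain`,
#'   `score`; attribute `cutoff` and `n_frames`.
#' @export
contact_score <- function(ens, ligand, residue_sel = NULL, cutoff = 4.5) {
  cs <- contact_counts(ens, ligand, residue_sel, cutoff)
  out <- tibble::tibble(
    residue_id = cs$residue_id,
    residue_name = cs$residue_name,
    chain = cs$chain,
    score = colMeans(cs$counts)
  )
  attr(out, "cutoff") <- cutoff
  attr(out, "n_frames") <- nrow(cs$counts)
  out
}

# shared machinery: per-frame per-residue ligand-heavy-atom counts
contact_counts <- function(ens, ligand, residue_sel = NULL, cutoff = 4.5) {
  n <- n_atoms(ens)
  ligand <- sort(unique(as.integer(ligand)))
  if (length(ligand) < 1L) rlang::abort("ligand selection is empty")
  if (is.null(residue_sel)) residue_sel <- setdiff(seq_len(n), ligand)
  residue_sel <- sort(unique(as.integer(residue_sel)))
  if (length(residue_sel) < 1L) rlang::abort("residue selection is empty")
  if (length(intersect(ligand, residue_sel)) > 0) {
    rlang::abort("ligand and residue selections overlap")
  }
  heavy <- ens$atoms$element != "H"
  ligand <- ligand[heavy[ligand]]
  residue_sel <- residue_sel[heavy[residue_sel]]
  if (length(ligand) < 1L || length(residue_sel) < 1L) {
    rlang::abort("selections contain no heavy atoms")
  }
  rid <- ens$atoms$residue_id[residue_sel]
  key <- paste(ens$atoms$chain[residue_sel], rid)
  ukey <- unique(key)
  first <- match(ukey, key)
  counts <- matrix(0L, nrow = n_frames(ens), ncol = length(ukey))
  for (fi in seq_len(n_frames(ens))) {
    f <- ens$frames[[fi]]
    lig_xyz <- f[ligand, , drop = FALSE]
    prot_xyz <- f[residue_sel, , drop = FALSE]
    # ligand-atom x protein-atom distance matrix
    d2 <- outer(rowSums(lig_xyz^2), rowSums(prot_xyz^2), "+") -
      2 * lig_xyz %*% t(prot_xyz)
    within <- d2 <= cutoff^2
    for (ri in seq_along(ukey)) {
      cols <- which(key == ukey[ri])
      # ligand atoms touching any heavy atom of this residue
      counts[fi, ri] <- sum(matrixStats_any_row(within[, cols, drop = FALSE]))
    }
  }
  list(
    counts = counts,
    residue_id = rid[first],
    residue_name = ens$atoms$residue_name[residue_sel][first],
    chain = ens$atoms$chain[residue_sel][first]
  )
}

matrixStats_any_row <- function(m) rowSums(m) > 0

#' Per-frame binary contact fingerprints
#'
#' Bit `i` of frame `f`'s fingerprint is set when residue `i` has at least
#' one ligand heavy atom within the cutoff in that frame. Fingerprints
#' depend only on their own frame, making them a stable substrate for pose
#' clustering.
#'
#' @inheritParams contact_score
#' @return A logical matrix (frames x residues) with residue ids as column
#'   names; attribute `cutoff`.
#' @export
contact_fingerprint <- function(ens, ligand, residue_sel = NULL,
                                cutoff = 4.5) {
  cs <- contact_counts(ens, ligand, residue_sel, cutoff)
  fp <- cs$counts > 0
  colnames(fp) <- as.character(cs$residue_id)
  attr(fp, "cutoff") <- cutoff
  fp
}

# Jaccard distance between binary fingerprint rows; identical empty
# fingerprints are at distance 0.
jaccard_dist <- function(fp) {
  fp <- fp * 1L
  inter <- fp %*% t(fp)
  sums <- rowSums(fp)
  uni <- outer(sums, sums, "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0
  stats::as.dist(d)
}

#' Cluster bound poses by contact fingerprint
#'
#' Average-linkage (UPGMA) agglomerative clustering of per-frame contact
#' fingerprints under Jaccard distance: the closest pair of clusters is
#' merged repeatedly while the average cross distance stays at or below the
#' threshold. Binary fingerprints produce exactly tied merge distances, so
#' the tie-break is part of the definition: among tied pairs, the one whose
#' lowest member frame indices come first lexicographically is merged. The
#' representative frame of each cluster minimizes the summed distance to
#' its members (ties broken by lowest frame index). The whole procedure is
#' deterministic given input order.
#'
#' @param fingerprints Logical frames-x-residues matrix from
#'   [contact_fingerprint()].
#' @param distance_threshold Merge cutoff in Jaccard distance (default
#'   0.5).
#' @return A tibble with one row per frame: `frame`, `cluster`,
#'   `representative` (logical). Clusters are numbered by first-occurring
#'   frame.
#' @export
cluster_poses <- function(fingerprints, distance_threshold = 0.5) {
  fp <- as.matrix(fingerprints)
  nf <- nrow(fp)
  if (nf < 1L) rlang::abort("need at least one fingerprint")
  if (nf == 1L) {
    return(tibble::tibble(frame = 1L, cluster = 1L, representative = TRUE))
  }
  dm <- as.matrix(jaccard_dist(fp))
  # cluster-level state: average-linkage distances (Lance-Williams exact
  # update for UPGMA), sizes, and lowest member frame per cluster
  d <- dm
  active <- rep(TRUE, nf)
  sizes <- rep(1L, nf)
  low <- seq_len(nf)
  membership <- seq_len(nf)
  diag(d) <- Inf
  d[lower.tri(d)] <- Inf
  repeat {
    live <- which(active)
    if (length(live) < 2L) break
    sub <- d[live, live, drop = FALSE]
    md <- min(sub)
    if (md > distance_threshold + 1e-12) break
    tied <- which(sub - md <= 1e-9, arr.ind = TRUE)
    keys <- cbind(pmin(low[live[tied[, 1]]], low[live[tied[, 2]]]),
      pmax(low[live[tied[, 1]]], low[live[tied[, 2]]]))
    pick <- order(keys[, 1], keys[, 2])[1]
    a <- live[min(tied[pick, ])]
    b <- live[max(tied[pick, ])]
    # merge b into a with exact size-weighted average update
    for (k in which(active)) {
      if (k == a || k == b) next
      dak <- if (k < a) d[k, a] else d[a, k]
      dbk <- if (k < b) d[k, b] else d[b, k]
      dnew <- (sizes[a] * dak + sizes[b] * dbk) / (sizes[a] + sizes[b])
      if (k < a) d[k, a] <- dnew else d[a, k] <- dnew
    }
    sizes[a] <- sizes[a] + sizes[b]
    low[a] <- min(low[a], low[b])
    active[b] <- FALSE
    membership[membership == b] <- a
  }
  cl <- match(membership, unique(membership))
  rep_flag <- rep(FALSE, nf)
  for (c_id in unique(cl)) {
    members <- which(cl == c_id)
    tot <- rowSums(dm[members, members, drop = FALSE])
    rep_flag[members[which.min(tot)]] <- TRUE
  }
  tibble::tibble(frame = seq_len(nf), cluster = cl, representative = rep_flag)
}

#' Residues exceeding a contact-score rule
#'
#' @param scores A tibble from [contact_score()].
#' @param min_score Report residues with `score > min_score` (default 1,
#'   i.e. more than one ligand atom engaged on average). Ignored when
#'   `top_k` is given.
#' @param top_k Alternative rule: the `k` highest-scoring residues (among
#'   those with positive score).
#' @return The filtered score tibble, sorted by decreasing score.
#' @export
top_contact_residues <- function(scores, min_score = 1, top_k = NULL) {
  sorted <- dplyr::arrange(scores, dplyr::desc(.data$score))
  if (!is.null(top_k)) {
    dplyr::slice_head(dplyr::filter(sorted, .data$score > 0), n = top_k)
  } else {
    dplyr::filter(sorted, .data$score > min_score)
  }
}
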