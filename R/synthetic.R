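#' Bead-chain models for synthetic ensembles
#'
#' A one-bead-per-residue chain with hard-core repulsion and a square-well
#' attraction of depth `epsilon` (in kT units) between designated "sticky"
#' (hydrophobic) beads. Positive `epsilon` drives hydrophobic collapse
#' toward compact states; negative `epsilon` penalizes contacts and swells
#' the chain toward extended states. This deliberately reduced
#' representation replaces all-atom ensembles: it reproduces the
#' statistical structure the analysis consumes (R_g regimes, planted
#' contacts, two-chain energetics) without any force-field realism.
#'
#' @param n_residues Number of beads (>= 2).
#' @param bond_length Bond length in Angstrom (default 3.8, the C-alpha
#'   virtual bond).
#' @param epsilon Square-well depth in kT; >= 0 attracts sticky pairs,
#'   < 0 repels them.
#' @param sticky Residue indices of sticky beads, or `"all"` (default).
#' @param well_range Square-well outer radius in Angstrom.
#' @param hard_core Hard-core diameter in Angstrom (non-bonded pairs).
#' @param kT Temperature-like parameter (default 1).
#' @return A `chain_model` list.
#' @export
chain_model <- function(n_residues = 50L, bond_length = 3.8, epsilon = 0,
                        sticky = "all", well_range = 6.5, hard_core = 3.5,
                        kT = 1) {
  if (n_residues < 2L) rlang::abort("n_residues must be >= 2")
  if (identical(sticky, "all")) sticky <- seq_len(n_residues)
  sticky <- sort(unique(as.integer(sticky)))
  if (length(sticky) > 0 &&
      (min(sticky) < 1L || max(sticky) > n_residues)) {
    rlang::abort("sticky indices out of range")
  }
  structure(
    list(
      n_residues = as.integer(n_residues), bond_length = bond_length,
      epsilon = epsilon, sticky = sticky, well_range = well_range,
      hard_core = hard_core, kT = kT
    ),
    class = "chain_model"
  )
}

#' Reference two-state chain models
#'
#' The default compact and extended 50-bead models behind the mixture
#' generator. The compact model (`epsilon = 0.3`, just past the collapse
#' transition) samples narrow compact ensembles (mean R_g near 10-12
#' Angstrom, almost no mass above 15 Angstrom), the compact regime; the
#' extended model (`epsilon = -4`) samples swollen conformations with mean
#' R_g above 20 Angstrom, so a 50/50 mixture spans roughly 5-35 Angstrom,
#' the broad regime of switch-prone 50-residue peptides. Sitting exactly on
#' the collapse transition is avoided deliberately: there, independent runs
#' drift between basins and the ensemble is not narrow.
#'
#' @param n_residues Number of beads.
#' @return A `chain_model`.
#' @export
compact_chain_model <- function(n_residues = 50L) {
  chain_model(n_residues, epsilon = 0.3)
}

#' @rdname compact_chain_model
#' @export
extended_chain_model <- function(n_residues = 50L) {
  chain_model(n_residues, epsilon = -4)
}

#' Sample a bead-chain ensemble by pivot Monte Carlo
#'
#' Seeded pivot-move Metropolis Monte Carlo: a random tail rotation about a
#' random bead, accepted by the Metropolis rule under the model's
#' square-well energy, with hard-core overlaps rejected outright. Frames
#' are recorded every `stride` moves after `burn_in` moves; the defaults
#' decorrelate successive frames for 50-bead chains (pivot moves decorrelate
#' global size in a few accepted moves). Fully reproducible by seed.
#'
#' @param model A [chain_model()].
#' @param n_frames Number of frames to record.
#' @param seed Integer seed.
#' @param burn_in Moves discarded before recording.
#' @param stride Moves between recorded frames.
#' @return A [conformer_ensemble] with one `BB` bead per residue (sticky
#'   beads as `LEU`, others as `SER`) and the shipped bead parameters
#'   merged.
#' @export
sample_chain <- function(model, n_frames = 200L, seed = 1L,
                         burn_in = 1000L, stride = 25L) {
  stopifnot(inherits(model, "chain_model"))
  sticky_flags <- as.integer(seq_len(model$n_residues) %in% model$sticky)
  mat <- with_local_seed(seed, sample_chain_cpp(
    model$n_residues, model$bond_length, model$hard_core,
    model$well_range, model$epsilon, sticky_flags, model$kT,
    as.integer(n_frames), as.integer(burn_in), as.integer(stride)
  ))
  # sample_chain_cpp stores (x, y, z) triples per bead, row per frame
  frames <- purrr::map(seq_len(nrow(mat)), function(i) {
    matrix(mat[i, ], ncol = 3, byrow = TRUE)
  })
  atoms <- tibble::tibble(
    index = seq_len(model$n_residues),
    name = "BB",
    element = "C",
    residue_id = seq_len(model$n_residues),
    residue_name = ifelse(sticky_flags == 1L, "LEU", "SER"),
    chain = "A"
  )
  ens <- conformer_ensemble(atoms, frames,
    provenance = sprintf(
      "sample_chain(n=%d, eps=%g, seed=%d)", model$n_residues,
      model$epsilon, seed
    ))
  merge_parameters(ens)
}

#' Calibrate the well depth to a target mean R_g
#'
#' Bisection on `epsilon` until the sampled mean R_g is within `tolerance`
#' of the target — e.g. to build a compact ensemble matching a 12-Angstrom
#' mean. Mean R_g decreases monotonically with `epsilon` over the default
#' bracket; evaluations share a seed so the objective is deterministic.
#'
#' @param target_mean_rg Target mean R_g in Angstrom.
#' @param model Template [chain_model()]; its `epsilon` is replaced.
#' @param bracket Lower/upper `epsilon` bounds (default `c(-4, 3)`).
#' @param n_frames Frames per evaluation.
#' @param seed Integer seed shared by evaluations.
#' @param tolerance Acceptable |mean R_g - target| in Angstrom.
#' @param max_iter Maximum bisection steps.
#' @return The calibrated `chain_model`, with attributes `achieved_rg` and
#'   `epsilon_path`.
#' @export
calibrate_compaction <- function(target_mean_rg, model = chain_model(),
                                 bracket = c(-4, 3), n_frames = 150L,
                                 seed = 1L, tolerance = 0.5,
                                 max_iter = 20L) {
  eval_rg <- function(eps) {
    m <- model
    m$epsilon <- eps
    mean(rg_series(sample_chain(m, n_frames = n_frames, seed = seed))$rg)
  }
  rg_lo <- eval_rg(bracket[1]) # small epsilon -> larger R_g
  rg_hi <- eval_rg(bracket[2])
  if (target_mean_rg > rg_lo + tolerance ||
      target_mean_rg < rg_hi - tolerance) {
    rlang::abort(sprintf(
      "target %.1f A outside achievable range [%.1f, %.1f] A for epsilon in [%g, %g]",
      target_mean_rg, rg_hi, rg_lo, bracket[1], bracket[2]
    ))
  }
  lo <- bracket[1]
  hi <- bracket[2]
  path <- numeric(0)
  achieved <- NA_real_
  eps_mid <- mean(bracket)
  for (it in seq_len(max_iter)) {
    eps_mid <- (lo + hi) / 2
    rg_mid <- eval_rg(eps_mid)
    path <- c(path, eps_mid)
    achieved <- rg_mid
    if (abs(rg_mid - target_mean_rg) < tolerance) break
    if (rg_mid > target_mean_rg) lo <- eps_mid else hi <- eps_mid
  }
  out <- model
  out$epsilon <- eps_mid
  attr(out, "achieved_rg") <- achieved
  attr(out, "epsilon_path") <- path
  out
}

#' Two-state mixture ensembles with ground-truth labels
#'
#' Frames drawn from a compact and an extended chain model with
#' probability `p_compact` for the compact component, emulating the
#' two-state (closed/open) picture of a switch peptide. The per-frame
#' component labels are recorded as ground truth.
#'
#' @param p_compact Probability of the compact component, in `[0, 1]`.
#' @param compact,extended [chain_model()]s sharing `n_residues` and
#'   sticky set.
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @return A [conformer_ensemble]; attribute `labels` is a character
#'   vector (`"compact"`/`"extended"`, one per frame).
#' @export
mixture_ensemble <- function(p_compact = 0.5,
                             compact = compact_chain_model(),
                             extended = extended_chain_model(),
                             n_frames = 200L, seed = 1L) {
  if (p_compact < 0 || p_compact > 1) {
    rlang::abort("p_compact must be in [0, 1]")
  }
  if (compact$n_residues != extended$n_residues) {
    rlang::abort("component models must share n_residues")
  }
  labels <- with_local_seed(seed,
    ifelse(stats::runif(n_frames) < p_compact, "compact", "extended"))
  n_c <- sum(labels == "compact")
  n_e <- n_frames - n_c
  frames <- vector("list", n_frames)
  template <- NULL
  if (n_c > 0) {
    ens_c <- sample_chain(compact, n_frames = n_c, seed = seed + 1L)
    frames[labels == "compact"] <- ens_c$frames
    template <- ens_c
  }
  if (n_e > 0) {
    ens_e <- sample_chain(extended, n_frames = n_e, seed = seed + 2L)
    frames[labels == "extended"] <- ens_e$frames
    if (is.null(template)) template <- ens_e
  }
  out <- conformer_ensemble(template$atoms, frames,
    provenance = sprintf("mixture_ensemble(p=%g, seed=%d)", p_compact, seed))
  attr(out, "labels") <- labels
  out
}

#' Append a pseudo-ligand with planted contacts
#'
#' Adds `n_ligand_atoms` ligand atoms (residue `LIG`, chain `L`) to every
#' frame. With probability `occupancy` the ligand cluster is placed within
#' `contact_distance` of a randomly chosen target residue's bead;
#' otherwise it is placed far outside any contact cutoff. The per-frame
#' ground truth (contacted residue or `NA`) is recorded, emulating a
#' dynamically associating ligand with known occupancy.
#'
#' @param ens A bead [conformer_ensemble] (e.g. from [sample_chain()]).
#' @param target_residues Residue ids eligible for contact (default: the
#'   sticky `LEU` beads).
#' @param occupancy Per-frame contact probability in `[0, 1]`.
#' @param contact_distance Placement distance bound in Angstrom (default
#'   3.0; keep below the scoring cutoff).
#' @param n_ligand_atoms Ligand heavy-atom count (1-4).
#' @param seed Integer seed.
#' @return The extended [conformer_ensemble]; attribute `truth` is a
#'   tibble (`frame`, `in_contact`, `residue_id`).
#' @export
plant_ligand <- function(ens, target_residues = NULL, occupancy = 0.5,
                         contact_distance = 3.0, n_ligand_atoms = 2L,
                         seed = 1L) {
  if (occupancy < 0 || occupancy > 1) {
    rlang::abort("occupancy must be in [0, 1]")
  }
  if (n_ligand_atoms < 1L || n_ligand_atoms > 4L) {
    rlang::abort("n_ligand_atoms must be between 1 and 4")
  }
  if (is.null(target_residues)) {
    target_residues <- unique(
      ens$atoms$residue_id[ens$atoms$residue_name == "LEU"])
  }
  if (length(target_residues) < 1L) {
    rlang::abort("no target residues available")
  }
  bead_of <- match(target_residues, ens$atoms$residue_id)
  params <- default_param_table()
  lig_rows <- params[params$residue_name == "LIG", ][seq_len(n_ligand_atoms), ]
  lig_atoms <- tibble::tibble(
    index = n_atoms(ens) + seq_len(n_ligand_atoms),
    name = lig_rows$atom_name,
    element = "C",
    residue_id = max(ens$atoms$residue_id) + 1L,
    residue_name = "LIG",
    chain = "L",
    mass = lig_rows$mass,
    charge = lig_rows$charge,
    lj_epsilon = lig_rows$lj_epsilon,
    lj_rmin_half = lig_rows$lj_rmin_half,
    gb_radius = lig_rows$gb_radius
  )
  nf <- n_frames(ens)
  build <- function() {
    truth <- tibble::tibble(
      frame = seq_len(nf),
      in_contact = stats::runif(nf) < occupancy,
      residue_id = NA_integer_
    )
    frames <- vector("list", nf)
    for (fi in seq_len(nf)) {
      f <- ens$frames[[fi]]
      if (truth$in_contact[fi]) {
        ri <- sample(length(target_residues), 1L)
        truth$residue_id[fi] <- target_residues[ri]
        center_bead <- f[bead_of[ri], ]
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        base <- center_bead + dir * stats::runif(1, 1.5, contact_distance)
      } else {
        com <- colMeans(f)
        reach <- max(sqrt(rowSums(sweep(f, 2, com)^2)))
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        base <- com + dir * (reach + 25)
      }
      lig <- matrix(rep(base, each = n_ligand_atoms), ncol = 3)
      if (n_ligand_atoms > 1L) {
        jit <- matrix(stats::rnorm(3 * n_ligand_atoms, sd = 0.15), ncol = 3)
        lig <- lig + jit
      }
      frames[[fi]] <- rbind(f, lig)
    }
    list(truth = truth, frames = frames)
  }
  res <- with_local_seed(seed, build())
  out <- conformer_ensemble(
    dplyr::bind_rows(ens$atoms, lig_atoms), res$frames,
    provenance = c(ens$provenance,
      sprintf("plant_ligand(occupancy=%g, seed=%d)", occupancy, seed))
  )
  attr(out, "truth") <- res$truth
  out
}

#' Toy two-chain complex for binding-energy tests
#'
#' A deterministic two-chain bead complex (6 + 5 beads) with assigned
#' charges and Lennard-Jones parameters, jittered over frames by a small
#' seeded Gaussian. Beads A3 and B3 carry opposite unit charges and a deep
#' shared Lennard-Jones well at contact distance, planting one strongly
#' favorable residue pair; the remaining beads carry small alternating
#' charges. Serves as the test bed for binding energies and per-residue
#' decomposition against brute-force oracles.
#'
#' @param seed Integer seed for the coordinate jitter.
#' @param n_frames Number of frames (default 25).
#' @param jitter_sd Gaussian jitter SD in Angstrom.
#' @return A [conformer_ensemble] of chains `A` (residues 1-6) and `B`
#'   (residues 7-11) with parameter columns set.
#' @export
toy_complex <- function(seed = 1L, n_frames = 25L, jitter_sd = 0.15) {
  n_a <- 6L
  n_b <- 5L
  base_a <- cbind((seq_len(n_a) - 1) * 3.8, 0, 0)
  base_b <- cbind((seq_len(n_b) - 1) * 3.8 + 1.9, 4.4, 0)
  base <- rbind(base_a, base_b)
  q_a <- c(0.1, -0.1, 1.0, -0.1, 0.1, -0.1)
  q_b <- c(-0.1, 0.1, -1.0, 0.1, -0.1)
  special <- c(3L, n_a + 3L) # the planted contact pair
  atoms <- tibble::tibble(
    index = seq_len(n_a + n_b),
    name = "BB",
    element = "C",
    residue_id = seq_len(n_a + n_b),
    residue_name = "BED",
    chain = rep(c("A", "B"), c(n_a, n_b)),
    mass = 110,
    charge = c(q_a, q_b),
    lj_epsilon = ifelse(seq_len(n_a + n_b) %in% special, 4.0, 0.2),
    lj_rmin_half = ifelse(seq_len(n_a + n_b) %in% special, 2.4, 2.2),
    gb_radius = 2.0
  )
  frames <- with_local_seed(seed, purrr::map(seq_len(n_frames), function(i) {
    base + matrix(stats::rnorm(3 * (n_a + n_b), sd = jitter_sd), ncol = 3)
  }))
  conformer_ensemble(atoms, frames,
    provenance = sprintf("toy_complex(seed=%d)", seed))
}
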