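#' Generalized Born / surface-area settings
#'
#' Settings for the implicit-solvent energy model. Defaults follow the
#' standard MM/GBSA protocol for peptide ensembles: solvent dielectric 80,
#' solute dielectric 1, 150 mM salt, surface tension 0.0072 kcal/mol/A^2
#' with zero offset, and the OBC-I generalized Born variant (the AMBER
#' `igb = 2` parameterization: alpha 0.8, beta 0, gamma 2.909125, dielectric
#' offset 0.09 A). Salt enters as exponential Debye screening of the GB
#' pair term with the conventional 0.73 prefactor on kappa.
#'
#' @param solvent_dielectric,solute_dielectric Relative dielectrics (> 0).
#' @param salt_molar Monovalent salt concentration in mol/L.
#' @param surface_tension gamma in kcal/mol/A^2 for the nonpolar term
#'   `gamma * SASA + b`.
#' @param sasa_offset The additive constant b in kcal/mol.
#' @param gb_variant Tag; only `"OBC-I"` is implemented.
#' @param sasa_probe_radius Water probe radius in Angstrom.
#' @param sasa_points Sphere points per atom for Shrake-Rupley SASA.
#' @param gb_offset Dielectric offset in Angstrom.
#' @param gb_screen Uniform descreening scaling factor applied to scaled
#'   neighbour radii (bead systems); element-specific values are not used.
#' @return A named list of settings.
#' @export
gb_settings <- function(solvent_dielectric = 80, solute_dielectric = 1,
                        salt_molar = 0.15, surface_tension = 0.0072,
                        sasa_offset = 0, gb_variant = "OBC-I",
                        sasa_probe_radius = 1.4, sasa_points = 960L,
                        gb_offset = 0.09, gb_screen = 0.8) {
  if (solvent_dielectric <= 0 || solute_dielectric <= 0) {
    rlang::abort("dielectrics must be > 0")
  }
  if (surface_tension < 0) rlang::abort("surface_tension must be >= 0")
  if (gb_variant != "OBC-I") {
    rlang::abort("only the OBC-I generalized Born variant is implemented")
  }
  list(
    solvent_dielectric = solvent_dielectric,
    solute_dielectric = solute_dielectric,
    salt_molar = salt_molar,
    surface_tension = surface_tension,
    sasa_offset = sasa_offset,
    gb_variant = gb_variant,
    sasa_probe_radius = sasa_probe_radius,
    sasa_points = as.integer(sasa_points),
    gb_offset = gb_offset,
    gb_screen = gb_screen
  )
}

# Coulomb constant in kcal*A/mol/e^2
.coulomb_k <- 332.0637
# OBC-I (igb = 2) rescaling coefficients (Onufriev, Bashford & Case 2004)
.obc1 <- c(alpha = 0.8, beta = 0, gamma = 2.909125)
# 1-4 scaling divisors (AMBER convention)
.scee <- 1.2
.scnb <- 2.0

# inverse Debye length in 1/A for monovalent salt in water near 300 K,
# with the conventional GB-specific 0.73 prefactor
gb_kappa <- function(salt_molar) {
  if (salt_molar <= 0) return(0)
  0.73 * sqrt(salt_molar) / 3.04
}

# Rotate coordinates into a molecule-fixed principal-axes frame with a
# deterministic sign convention (third-moment skew, right-handed), so the
# sphere-point SASA lattice is carried with the molecule and SASA is
# exactly invariant under rigid rotation/translation.
canonical_coords <- function(coords) {
  n <- nrow(coords)
  centered <- sweep(coords, 2, colMeans(coords))
  if (n < 3L) return(centered)
  ev <- eigen(stats::cov(centered), symmetric = TRUE)
  v <- ev$vectors
  for (j in 1:2) {
    proj <- centered %*% v[, j]
    s <- sum(proj^3)
    if (abs(s) > 1e-8) {
      v[, j] <- v[, j] * sign(s)
    } else {
      k <- which.max(abs(v[, j]))
      v[, j] <- v[, j] * sign(v[k, j])
    }
  }
  v[, 3] <- pracma_cross(v[, 1], v[, 2])
  centered %*% v
}

# deterministic quasi-uniform sphere points (Fibonacci / golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Per-atom SASA by the sphere-point method: each atom's radius is
#' augmented by the probe radius, test points are placed on a deterministic
#' quasi-uniform spherical lattice, and points buried inside any
#' neighbour's augmented sphere are discarded. Coordinates are first
#' rotated into a molecule-fixed principal-axes frame, so areas are
#' deterministic for a given `sasa_points` and exactly invariant under
#' rigid rotation and translation.
#'
#' @param coords `n x 3` coordinate matrix (Angstrom).
#' @param radii Per-atom intrinsic radii (> 0, Angstrom).
#' @param settings A [gb_settings()] list (probe radius and point count are
#'   read from it).
#' @return Numeric vector of per-atom areas in A^2.
#' @export
sasa <- function(coords, radii, settings = gb_settings()) {
  coords <- canonical_coords(as.matrix(coords))
  n <- nrow(coords)
  if (any(radii <= 0)) rlang::abort("radii must be > 0")
  probe <- settings$sasa_probe_radius
  pts <- sphere_points(settings$sasa_points)
  aug <- radii + probe
  areas <- numeric(n)
  if (n > 1) dmat <- as.matrix(stats::dist(coords))
  for (i in seq_len(n)) {
    p <- sweep(pts * aug[i], 2, coords[i, ], "+")
    accessible <- rep(TRUE, nrow(p))
    if (n > 1) {
      nbr <- which(dmat[i, ] < aug[i] + aug & seq_len(n) != i)
      for (j in nbr) {
        d2 <- (p[, 1] - coords[j, 1])^2 + (p[, 2] - coords[j, 2])^2 +
          (p[, 3] - coords[j, 3])^2
        accessible <- accessible & d2 >= aug[j]^2
        if (!any(accessible)) break
      }
    }
    areas[i] <- 4 * pi * aug[i]^2 * mean(accessible)
  }
  areas
}

#' Effective Born radii (OBC-I)
#'
#' Pairwise-descreening (HCT) integrals with the OBC-I tanh rescaling.
#' An isolated atom's effective radius equals its intrinsic radius minus
#' the dielectric offset; effective radii grow as neighbours approach and
#' descreen the atom.
#'
#' @param coords `n x 3` coordinate matrix (Angstrom).
#' @param gb_radii Per-atom intrinsic GB radii (> 0, Angstrom).
#' @param settings A [gb_settings()] list.
#' @return Numeric vector of per-atom effective radii in Angstrom.
#' @export
born_radii <- function(coords, gb_radii, settings = gb_settings()) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (any(gb_radii <= 0)) rlang::abort("gb radii must be > 0")
  rho_t <- gb_radii - settings$gb_offset
  s <- settings$gb_screen * rho_t
  integral <- numeric(n)
  if (n > 1) {
    dmat <- as.matrix(stats::dist(coords))
    for (i in seq_len(n)) {
      acc <- 0
      for (j in seq_len(n)) {
        if (j == i) next
        d <- dmat[i, j]
        sj <- s[j]
        if (rho_t[i] >= d + sj) next
        L <- max(rho_t[i], abs(d - sj))
        U <- d + sj
        h <- 0.5 * (1 / L - 1 / U +
          0.25 * (d - sj^2 / d) * (1 / U^2 - 1 / L^2) +
          1 / (2 * d) * log(L / U))
        if (rho_t[i] < sj - d) h <- h + (1 / rho_t[i] - 1 / L)
        acc <- acc + h
      }
      integral[i] <- acc
    }
  }
  psi <- rho_t * integral
  a <- .obc1[["alpha"]]; b <- .obc1[["beta"]]; g <- .obc1[["gamma"]]
  inv_r <- 1 / rho_t - tanh(a * psi - b * psi^2 + g * psi^3) / gb_radii
  1 / pmax(inv_r, 1e-8)
}

# GB pair/self energy with optional per-atom attribution.
# Returns list(total, per_atom): pair terms split half/half, self terms to
# the owning atom.
gb_energy_core <- function(coords, charges, eff_radii, settings) {
  n <- length(charges)
  kappa <- gb_kappa(settings$salt_molar)
  ein <- settings$solute_dielectric
  eout <- settings$solvent_dielectric
  d2 <- as.matrix(stats::dist(coords))^2
  rr <- outer(eff_radii, eff_radii)
  f <- sqrt(d2 + rr * exp(-d2 / (4 * rr)))
  pref <- 1 / ein - exp(-kappa * f) / eout
  qq <- outer(charges, charges)
  emat <- -0.5 * .coulomb_k * qq * pref / f
  per_atom <- 0.5 * (rowSums(emat) + colSums(emat))
  list(total = sum(emat), per_atom = per_atom)
}

#' Generalized Born polar solvation energy
#'
#' The standard GB pair expression summed over all atom pairs including
#' self terms, with Debye-Huckel exponential salt screening. For a single
#' charged atom this is the analytic Born self-energy
#' `-(k/2) (1/eps_in - 1/eps_out) q^2 / R`.
#'
#' @param coords `n x 3` coordinate matrix.
#' @param charges Per-atom charges in elementary units.
#' @param eff_radii Effective radii from [born_radii()].
#' @param settings A [gb_settings()] list.
#' @return Polar solvation energy in kcal/mol.
#' @export
gb_polar_energy <- function(coords, charges, eff_radii,
                            settings = gb_settings()) {
  gb_energy_core(as.matrix(coords), charges, eff_radii, settings)$total
}

# Exclusion masks from a bonded topology: 0 for excluded 1-2/1-3 pairs,
# 1/scale for 1-4, 1 otherwise. Returns list(ele, vdw) n x n matrices.
exclusion_masks <- function(n, topology) {
  ele <- matrix(1, n, n)
  vdw <- matrix(1, n, n)
  if (is.null(topology) || is.null(topology$bonds) ||
      nrow(topology$bonds) == 0) {
    return(list(ele = ele, vdw = vdw))
  }
  adj <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(topology$bonds))) {
    i <- topology$bonds$i[r]; j <- topology$bonds$j[r]
    adj[i, j] <- TRUE; adj[j, i] <- TRUE
  }
  # path lengths 2 and 3 via boolean matrix products
  a2 <- (adj %*% adj) > 0
  a3 <- (a2 %*% adj) > 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (adj[i, j] || (a2[i, j] && !adj[i, j])) {
        ele[i, j] <- 0; vdw[i, j] <- 0
      } else if (a3[i, j]) {
        ele[i, j] <- 1 / .scee; vdw[i, j] <- 1 / .scnb
      }
    }
  }
  list(ele = ele, vdw = vdw)
}

#' Molecular-mechanics energy terms
#'
#' Lennard-Jones 12-6 and Coulomb nonbonded energies, plus bonded terms
#' (harmonic bonds and angles, cosine dihedrals) when a topology is
#' supplied. Without a topology all atom pairs interact and `e_bon` is 0 —
#' appropriate for bead systems and for single-trajectory binding
#' differences, where bonded terms cancel exactly. With a topology, 1-2 and
#' 1-3 pairs are excluded and 1-4 pairs are scaled by 1/1.2 (electrostatic)
#' and 1/2 (Lennard-Jones).
#'
#' @param coords `n x 3` coordinate matrix.
#' @param atoms Atom tibble with `charge`, `lj_epsilon`, `lj_rmin_half`
#'   columns (no `NA`s).
#' @param topology Optional list with tibbles `bonds` (`i`, `j`, `k`,
#'   `r0`), `angles` (`i`, `j`, `k`, `ktheta`, `theta0` in radians) and
#'   `dihedrals` (`i`, `j`, `k`, `l`, `pk`, `per`, `phase` in radians).
#' @param settings A [gb_settings()] list (solute dielectric).
#' @return A list with `e_bon`, `e_vdw`, `e_ele` (kcal/mol) and the
#'   per-atom attributions `vdw_atom`, `ele_atom`, `bon_atom`.
#' @export
mm_terms <- function(coords, atoms, topology = NULL,
                     settings = gb_settings()) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  q <- atoms$charge
  eps <- atoms$lj_epsilon
  rmh <- atoms$lj_rmin_half
  if (anyNA(q) || anyNA(eps) || anyNA(rmh)) {
    bad <- which(is.na(q) | is.na(eps) | is.na(rmh))[1]
    rlang::abort(sprintf(
      "missing nonbonded parameters for atom %d (%s %s)",
      bad, atoms$residue_name[bad], atoms$name[bad]
    ))
  }
  masks <- exclusion_masks(n, topology)
  vdw_atom <- numeric(n)
  ele_atom <- numeric(n)
  e_vdw <- 0
  e_ele <- 0
  if (n > 1) {
    d <- as.matrix(stats::dist(coords))
    diag(d) <- Inf
    epair <- sqrt(outer(eps, eps))
    rmin <- outer(rmh, rmh, "+")
    ratio6 <- (rmin / d)^6
    vmat <- epair * (ratio6^2 - 2 * ratio6) * masks$vdw
    emat <- .coulomb_k * outer(q, q) / (settings$solute_dielectric * d) *
      masks$ele
    diag(vmat) <- 0
    diag(emat) <- 0
    e_vdw <- sum(vmat) / 2
    e_ele <- sum(emat) / 2
    vdw_atom <- rowSums(vmat) / 2
    ele_atom <- rowSums(emat) / 2
  }
  e_bon <- 0
  bon_atom <- numeric(n)
  if (!is.null(topology)) {
    if (!is.null(topology$bonds) && nrow(topology$bonds) > 0) {
      b <- topology$bonds
      r <- sqrt(rowSums((coords[b$i, , drop = FALSE] -
        coords[b$j, , drop = FALSE])^2))
      e <- b$k * (r - b$r0)^2
      e_bon <- e_bon + sum(e)
      for (r_i in seq_along(e)) {
        bon_atom[b$i[r_i]] <- bon_atom[b$i[r_i]] + e[r_i] / 2
        bon_atom[b$j[r_i]] <- bon_atom[b$j[r_i]] + e[r_i] / 2
      }
    }
    if (!is.null(topology$angles) && nrow(topology$angles) > 0) {
      a <- topology$angles
      for (r_i in seq_len(nrow(a))) {
        v1 <- coords[a$i[r_i], ] - coords[a$j[r_i], ]
        v2 <- coords[a$k[r_i], ] - coords[a$j[r_i], ]
        th <- acos(pmin(1, pmax(-1,
          sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
        e <- a$ktheta[r_i] * (th - a$theta0[r_i])^2
        e_bon <- e_bon + e
        for (at in c(a$i[r_i], a$j[r_i], a$k[r_i])) {
          bon_atom[at] <- bon_atom[at] + e / 3
        }
      }
    }
    if (!is.null(topology$dihedrals) && nrow(topology$dihedrals) > 0) {
      dh <- topology$dihedrals
      for (r_i in seq_len(nrow(dh))) {
        phi <- dihedral_angle(coords[dh$i[r_i], ], coords[dh$j[r_i], ],
          coords[dh$k[r_i], ], coords[dh$l[r_i], ])
        e <- dh$pk[r_i] * (1 + cos(dh$per[r_i] * phi - dh$phase[r_i]))
        e_bon <- e_bon + e
        for (at in c(dh$i[r_i], dh$j[r_i], dh$k[r_i], dh$l[r_i])) {
          bon_atom[at] <- bon_atom[at] + e / 4
        }
      }
    }
  }
  list(e_bon = e_bon, e_vdw = e_vdw, e_ele = e_ele,
    vdw_atom = vdw_atom, ele_atom = ele_atom, bon_atom = bon_atom)
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Full single-frame energy with per-atom attribution.
frame_energy_core <- function(coords, atoms, settings, topology = NULL) {
  mm <- mm_terms(coords, atoms, topology, settings)
  radii <- atoms$gb_radius
  if (anyNA(radii) || anyNA(atoms$charge)) {
    bad <- which(is.na(radii) | is.na(atoms$charge))[1]
    rlang::abort(sprintf(
      "missing GB parameters for atom %d (%s %s)",
      bad, atoms$residue_name[bad], atoms$name[bad]
    ))
  }
  reff <- born_radii(coords, radii, settings)
  gb <- gb_energy_core(as.matrix(coords), atoms$charge, reff, settings)
  areas <- sasa(coords, radii, settings)
  e_npol_atom <- settings$surface_tension * areas
  e_npol <- sum(e_npol_atom) + settings$sasa_offset
  list(
    e_bon = mm$e_bon, e_vdw = mm$e_vdw, e_ele = mm$e_ele,
    e_pol = gb$total, e_npol = e_npol,
    g_total = mm$e_bon + mm$e_vdw + mm$e_ele + gb$total + e_npol,
    per_atom = mm$bon_atom + mm$vdw_atom + mm$ele_atom + gb$per_atom +
      e_npol_atom
  )
}

#' Total MM/GBSA energy of a frame
#'
#' The enthalpic energy `G = E_bon + E_vdw + E_ele + E_pol + E_npol` of a
#' single conformation; the quantity paired with R_g in
#' [rg_landscape()] displays.
#'
#' @inheritParams mm_terms
#' @return A one-row tibble with columns `e_bon`, `e_vdw`, `e_ele`,
#'   `e_pol`, `e_npol`, `g_total` (kcal/mol).
#' @export
total_energy <- function(coords, atoms, settings = gb_settings(),
                         topology = NULL) {
  fe <- frame_energy_core(as.matrix(coords), atoms, settings, topology)
  tibble::tibble(
    e_bon = fe$e_bon, e_vdw = fe$e_vdw, e_ele = fe$e_ele,
    e_pol = fe$e_pol, e_npol = fe$e_npol, g_total = fe$g_total
  )
}

#' Per-frame MM/GBSA energies of an ensemble
#'
#' Applies [total_energy()] to a (possibly subsampled) set of frames.
#' Defaults to 5000 evenly spaced frames, the peptide-ensemble convention.
#'
#' @param ens A [conformer_ensemble] with parameters merged.
#' @param settings A [gb_settings()] list.
#' @param topology Optional bonded topology (see [mm_terms()]).
#' @param n_sample Maximum number of evenly spaced frames to evaluate.
#' @return A tibble with `frame` plus the energy-component columns.
#' @export
energy_series <- function(ens, settings = gb_settings(), topology = NULL,
                          n_sample = 5000) {
  idx <- evenly_spaced_frames(n_frames(ens), n_sample)
  purrr::map_dfr(idx, function(i) {
    dplyr::bind_cols(
      tibble::tibble(frame = i),
      total_energy(ens$frames[[i]], ens$atoms, settings, topology)
    )
  })
}
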