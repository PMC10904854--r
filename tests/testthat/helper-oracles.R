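# Independent brute-force oracles, written as literal transcriptions of the
# documented formulas (plain loops, no reuse of package internals).

# textbook Pearson correlation
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# centered truncated sliding mean by explicit loop
oracle_sliding_mean <- function(x, window) {
  h <- (window - 1) %/% 2
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    lo <- max(1, i - h)
    hi <- min(length(x), i + h)
    out[i] <- sum(x[lo:hi]) / (hi - lo + 1)
  }
  out
}

# KS distance by explicit ECDF sweep over all observed points
oracle_ks <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  dmax <- 0
  for (x in pts) {
    d <- abs(mean(a <= x) - mean(b <= x))
    if (d > dmax) dmax <- d
  }
  dmax
}

# mass-weighted radius of gyration by explicit sums
oracle_rg <- function(coords, masses) {
  M <- sum(masses)
  cx <- sum(coords[, 1] * masses) / M
  cy <- sum(coords[, 2] * masses) / M
  cz <- sum(coords[, 3] * masses) / M
  s <- 0
  for (i in seq_len(nrow(coords))) {
    s <- s + masses[i] * ((coords[i, 1] - cx)^2 + (coords[i, 2] - cy)^2 +
      (coords[i, 3] - cz)^2)
  }
  sqrt(s / M)
}

# --- energy oracles -------------------------------------------------------

ORACLE_KE <- 332.0637

# OBC-I effective radii: literal transcription of the published pairwise
# descreening integral and tanh rescaling (alpha 0.8, beta 0, gamma
# 2.909125, offset 0.09)
oracle_obc_radii <- function(coords, rho, offset = 0.09, screen = 0.8) {
  n <- nrow(coords)
  rho_t <- rho - offset
  out <- numeric(n)
  for (i in seq_len(n)) {
    I <- 0
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      sj <- screen * rho_t[j]
      if (rho_t[i] >= d + sj) next
      L <- max(rho_t[i], abs(d - sj))
      U <- d + sj
      h <- 0.5 * (1 / L - 1 / U +
        0.25 * (d - sj^2 / d) * (1 / U^2 - 1 / L^2) +
        (1 / (2 * d)) * log(L / U))
      if (rho_t[i] < sj - d) h <- h + (1 / rho_t[i] - 1 / L)
      I <- I + h
    }
    psi <- rho_t[i] * I
    inv_r <- 1 / rho_t[i] -
      tanh(0.8 * psi - 0 * psi^2 + 2.909125 * psi^3) / rho[i]
    out[i] <- 1 / inv_r
  }
  out
}

# GB pair + self energy, double loop over ordered pairs
oracle_gb_energy <- function(coords, q, reff, ein = 1, eout = 80,
                             kappa = 0) {
  n <- length(q)
  e <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d2 <- sum((coords[i, ] - coords[j, ])^2)
      f <- sqrt(d2 + reff[i] * reff[j] * exp(-d2 / (4 * reff[i] * reff[j])))
      e <- e - 0.5 * ORACLE_KE * q[i] * q[j] *
        (1 / ein - exp(-kappa * f) / eout) / f
    }
  }
  e
}

# LJ 12-6 + Coulomb by explicit i<j double loop (no exclusions)
oracle_mm <- function(coords, q, eps, rmh, ein = 1) {
  n <- nrow(coords)
  e_vdw <- 0
  e_ele <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      epair <- sqrt(eps[i] * eps[j])
      rmin <- rmh[i] + rmh[j]
      e_vdw <- e_vdw + epair * ((rmin / r)^12 - 2 * (rmin / r)^6)
      e_ele <- e_ele + ORACLE_KE * q[i] * q[j] / (ein * r)
    }
  }
  list(e_vdw = e_vdw, e_ele = e_ele)
}

# Shrake-Rupley SASA, plain loops over the same documented construction
# (principal-axes canonical frame, golden-spiral lattice)
oracle_sasa <- function(coords, radii, probe = 1.4, n_points = 960) {
  n <- nrow(coords)
  centered <- sweep(coords, 2, colMeans(coords))
  if (n >= 3) {
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
    v3 <- c(
      v[2, 1] * v[3, 2] - v[3, 1] * v[2, 2],
      v[3, 1] * v[1, 2] - v[1, 1] * v[3, 2],
      v[1, 1] * v[2, 2] - v[2, 1] * v[1, 2]
    )
    v[, 3] <- v3
    centered <- centered %*% v
  }
  idx <- seq_len(n_points) - 0.5
  z <- 1 - 2 * idx / n_points
  phi <- idx * pi * (3 - sqrt(5))
  rr <- sqrt(pmax(0, 1 - z^2))
  lattice <- cbind(rr * cos(phi), rr * sin(phi), z)
  aug <- radii + probe
  areas <- numeric(n)
  for (i in seq_len(n)) {
    n_acc <- 0
    for (p in seq_len(n_points)) {
      pt <- centered[i, ] + aug[i] * lattice[p, ]
      buried <- FALSE
      for (j in seq_len(n)) {
        if (j == i) next
        if (sum((pt - centered[j, ])^2) < aug[j]^2) {
          buried <- TRUE
          break
        }
      }
      if (!buried) n_acc <- n_acc + 1
    }
    areas[i] <- 4 * pi * aug[i]^2 * n_acc / n_points
  }
  areas
}

# full single-frame G by composing the oracle pieces
oracle_frame_g <- function(coords, atoms, ein = 1, eout = 80, kappa = 0,
                           gamma = 0.0072, probe = 1.4, n_points = 960) {
  mm <- oracle_mm(coords, atoms$charge, atoms$lj_epsilon,
    atoms$lj_rmin_half, ein)
  reff <- oracle_obc_radii(coords, atoms$gb_radius)
  gb <- oracle_gb_energy(coords, atoms$charge, reff, ein, eout, kappa)
  np <- gamma * sum(oracle_sasa(coords, atoms$gb_radius, probe, n_points))
  mm$e_vdw + mm$e_ele + gb + np
}

# analytic union area of two equal circles at center distance d
oracle_two_circle_union <- function(d, r) {
  if (d >= 2 * r) return(2 * pi * r^2)
  lens <- 2 * r^2 * acos(d / (2 * r)) - d / 2 * sqrt(4 * r^2 - d^2)
  2 * pi * r^2 - lens
}

# O(n^3) naive agglomerative average-linkage clustering under Jaccard
# distance: repeatedly merge the closest cluster pair while the average
# cross distance is <= h; among ties (within 1e-9), merge the pair whose
# sorted lowest member frame indices are lexicographically first. Returns
# cluster labels.
oracle_avg_linkage <- function(fp, h) {
  n <- nrow(fp)
  jac <- function(a, b) {
    u <- sum(a | b)
    if (u == 0) 0 else 1 - sum(a & b) / u
  }
  clusters <- lapply(seq_len(n), identity)
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA)
    best_d <- Inf
    best_key <- c(Inf, Inf)
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        dsum <- 0
        for (i in clusters[[a]]) {
          for (j in clusters[[b]]) dsum <- dsum + jac(fp[i, ], fp[j, ])
        }
        dbar <- dsum / (length(clusters[[a]]) * length(clusters[[b]]))
        key <- sort(c(min(clusters[[a]]), min(clusters[[b]])))
        better <- dbar < best_d - 1e-9 ||
          (abs(dbar - best_d) <= 1e-9 &&
            (key[1] < best_key[1] ||
              (key[1] == best_key[1] && key[2] < best_key[2])))
        if (better) {
          best_d <- dbar
          best <- c(a, b)
          best_key <- key
        }
      }
    }
    if (best_d > h + 1e-12) break
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  labels <- integer(n)
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
  labels
}

# canonical form of a partition (labels renumbered by first occurrence)
canon_partition <- function(labels) {
  match(labels, unique(labels))
}
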