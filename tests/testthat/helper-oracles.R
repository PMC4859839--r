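# Independent oracles used across the suite.  Everything here is written
# against first principles (closed forms, quadrature, brute-force
# enumeration) and deliberately avoids the code paths it checks.

BOHR <- 0.52917721067

# --- closed-form s-type Gaussian integrals (unnormalized primitives) -------

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

boys0 <- function(x) {
  ifelse(x < 1e-12, 1 - x / 3, 0.5 * sqrt(pi / x) * erf(sqrt(x)))
}

ss_overlap <- function(a, A, b, B) {
  p <- a + b
  AB2 <- sum((A - B)^2)
  (pi / p)^1.5 * exp(-a * b / p * AB2)
}

ss_attraction <- function(a, A, b, B, C) {
  # <s_A | 1/|r-C| | s_B>, unnormalized
  p <- a + b
  P <- (a * A + b * B) / p
  AB2 <- sum((A - B)^2)
  2 * pi / p * exp(-a * b / p * AB2) * boys0(p * sum((P - C)^2))
}

ssss_eri <- function(a, A, b, B, c_, C, d, D) {
  p <- a + b
  q <- c_ + d
  P <- (a * A + b * B) / p
  Q <- (c_ * C + d * D) / q
  K1 <- exp(-a * b / p * sum((A - B)^2))
  K2 <- exp(-c_ * d / q * sum((C - D)^2))
  2 * pi^2.5 / (p * q * sqrt(p + q)) * K1 * K2 *
    boys0(p * q / (p + q) * sum((P - Q)^2))
}

# raw (unnormalized) shell for direct engine calls; center in bohr
raw_shell <- function(l, center, exps, coefs = rep(1, length(exps))) {
  list(l = as.integer(l), center = as.numeric(center),
       exponents = as.numeric(exps), coefficients = as.numeric(coefs))
}

# --- nonorthogonal Slater-determinant energy -------------------------------
# Closed-shell determinant built from possibly nonorthogonal doubly occupied
# spatial orbitals C_occ (AO x m), via the generalized Slater rules with the
# inverse spin-orbital overlap; independent of the Lowdin route used by the
# implementation.
nonorthogonal_determinant_energy <- function(C_occ, S, h, eri, enuc = 0) {
  m <- ncol(C_occ)
  n <- nrow(C_occ)
  Ssp <- crossprod(C_occ, S %*% C_occ)
  hsp <- crossprod(C_occ, h %*% C_occ)
  K <- kronecker(C_occ, C_occ)
  Gmo <- crossprod(K, matrix(eri, n * n, n * n) %*% K)
  g <- array(Gmo, c(m, m, m, m))  # chemist (pq|rs) over spatial MOs
  ns <- 2L * m
  spat <- rep(seq_len(m), each = 2)
  spin <- rep(c(1L, 2L), m)
  M <- matrix(0, ns, ns)
  hso <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (spin[i] == spin[j]) {
        M[i, j] <- Ssp[spat[i], spat[j]]
        hso[i, j] <- hsp[spat[i], spat[j]]
      }
    }
  }
  Minv <- solve(M)
  e1 <- sum(Minv * hso)
  e2 <- 0
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    for (k in seq_len(ns)) for (l in seq_len(ns)) {
      w <- Minv[k, i] * Minv[l, j]
      if (w == 0) next
      # physicist <ij|kl> = chemist (ik|jl) with spin deltas
      d1 <- if (spin[i] == spin[k] && spin[j] == spin[l])
        g[spat[i], spat[k], spat[j], spat[l]] else 0
      d2 <- if (spin[i] == spin[l] && spin[j] == spin[k])
        g[spat[i], spat[l], spat[j], spat[k]] else 0
      e2 <- e2 + 0.5 * w * (d1 - d2)
    }
  }
  e1 + e2 + enuc
}

# --- brute-force representative-frame selector -----------------------------
# Direct enumeration of the selection criteria over all frames; hmat/rmat are
# frames x series matrices, intervals are lists of c(low, high).
brute_force_select <- function(hmat, intervals_h, rmat = NULL,
                               intervals_r = NULL, mode = "strict") {
  nf <- nrow(hmat)
  inside <- function(x, iv) x >= iv[1] & x < iv[2]
  member <- matrix(FALSE, nf, 0)
  for (k in seq_len(ncol(hmat))) {
    member <- cbind(member, inside(hmat[, k], intervals_h[[k]]))
  }
  if (!is.null(rmat)) {
    for (k in seq_len(ncol(rmat))) {
      member <- cbind(member, inside(rmat[, k], intervals_r[[k]]))
    }
  }
  counts <- rowSums(member)
  totals <- rowSums(hmat)
  strict_frames <- which(counts == ncol(member))
  if (mode == "strict" && length(strict_frames) > 0) {
    cand <- strict_frames
    keys <- data.frame(totals[cand], cand)
  } else {
    cand <- seq_len(nf)
    keys <- data.frame(-counts, totals, cand)
  }
  cand[do.call(order, keys)[1]]
}

# --- misc helpers -----------------------------------------------------------

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

tiny_hbond_traj <- function(distances, bond_id = "toy") {
  # trajectory realizing a given distance series exactly (one bond)
  spec <- hbond_spec(bond_id, 1, 2.0, 0, length(distances))
  traj <- make_hbond_trajectory(list(spec), seed = 1)
  traj$coords[3, 1, ] <- traj$coords[2, 1, 1] + distances
  traj$distances[, 1] <- distances
  traj
}
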