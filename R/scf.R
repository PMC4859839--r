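# Restricted Hartree-Fock over the dimer-centered basis set.
#
# A `dimer_context` carries everything both monomer and supermolecular
# calculations share: the shell list spanning BOTH fragments (so every SCF is
# performed in the full dimer basis and the decomposition is free of basis-set
# superposition error by construction), the one-electron matrices split by
# nuclear ownership, and the two-electron integrals pre-reshaped for fast
# Coulomb/exchange contraction.

nuclear_repulsion <- function(xyz_bohr, Z) {
  n <- nrow(xyz_bohr)
  if (n < 2) return(0)
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      r <- sqrt(sum((xyz_bohr[i, ] - xyz_bohr[j, ])^2))
      e <- e + Z[i] * Z[j] / r
    }
  }
  e
}

#' Restricted HF energy of a single fragment
#'
#' Standalone SCF for one fragment, optionally with a ghost fragment whose
#' atoms contribute basis functions but no nuclear charge or electrons.
#'
#' @param fragment A [molecular_fragment()].
#' @param basis Basis-set name.
#' @param ghost Optional [molecular_fragment()] providing ghost centers.
#' @param ... Convergence options passed to the SCF driver.
#' @return The converged wavefunction (total energy in hartree).
#' @export
fragment_scf <- function(fragment, basis = "sto-3g", ghost = NULL, ...) {
  stopifnot(inherits(fragment, "molecular_fragment"))
  if (fragment$multiplicity != 1) {
    stop("only closed-shell (multiplicity 1) fragments are supported")
  }
  elements <- fragment$elements
  xyz <- fragment$xyz
  if (!is.null(ghost)) {
    elements <- c(elements, ghost$elements)
    xyz <- rbind(xyz, ghost$xyz)
  }
  shells <- build_shells(elements, xyz, basis)
  onee <- cpp_overlap_kinetic(shells)
  xyz_bohr <- fragment$xyz * .BOHR_PER_ANGSTROM
  Z <- element_number(fragment$elements)
  V <- cpp_nuclear_attraction(shells, cbind(xyz_bohr, Z))
  n <- n_basis_functions(shells)
  eri <- cpp_eri(shells)
  ctx <- list(nbf = n, S = onee$S,
              Jmat = matrix(eri, n * n, n * n),
              Kmat = matrix(aperm(array(eri, c(n, n, n, n)),
                                  c(1, 3, 2, 4)), n * n, n * n))
  rhf_scf(ctx, onee$T + V, n_electrons(fragment),
          nuclear_repulsion(xyz_bohr, Z), ...)
}

#' Build the shared integral context for a dimer
#'
#' Computes overlap, kinetic, per-fragment nuclear attraction and the full
#' two-electron integral array over the dimer-centered basis, once, for reuse
#' by the monomer SCFs, the Heitler-London determinant and the supermolecular
#' SCF.
#'
#' @param dimer A [dimer_system()].
#' @param basis Basis-set name; defaults to the dimer's `basis_name`.
#' @return An object of class `dimer_context`.
#' @export
dimer_context <- function(dimer, basis = NULL) {
  stopifnot(inherits(dimer, "dimer_system"))
  basis <- tolower(basis %||% dimer$basis_name)
  a <- dimer$fragment_a
  b <- dimer$fragment_b
  na <- nrow(a$xyz)
  elements <- c(a$elements, b$elements)
  xyz <- rbind(a$xyz, b$xyz)
  xyz_bohr <- xyz * .BOHR_PER_ANGSTROM
  Z <- element_number(elements)
  frag <- rep(c("A", "B"), c(na, nrow(b$xyz)))
  shells <- build_shells(elements, xyz, basis)
  onee <- cpp_overlap_kinetic(shells)
  chg <- function(sel) cbind(xyz_bohr[sel, , drop = FALSE], Z[sel])
  V_a <- cpp_nuclear_attraction(shells, chg(frag == "A"))
  V_b <- cpp_nuclear_attraction(shells, chg(frag == "B"))
  eri <- cpp_eri(shells)
  n <- n_basis_functions(shells)
  Jmat <- matrix(eri, n * n, n * n)
  Kmat <- matrix(aperm(array(eri, c(n, n, n, n)), c(1, 3, 2, 4)), n * n, n * n)
  # AO ownership (per basis function) for cross-basis bookkeeping
  ao_frag <- unlist(lapply(shells, function(s) {
    rep(frag[s$atom], (s$l + 1L) * (s$l + 2L) / 2L)
  }))
  ia <- frag == "A"
  enuc_a <- nuclear_repulsion(xyz_bohr[ia, , drop = FALSE], Z[ia])
  enuc_b <- nuclear_repulsion(xyz_bohr[!ia, , drop = FALSE], Z[!ia])
  enuc_ab <- nuclear_repulsion(xyz_bohr, Z) - enuc_a - enuc_b
  structure(
    list(dimer = dimer, basis = basis, shells = shells, nbf = n,
         S = onee$S, T = onee$T, V_a = V_a, V_b = V_b,
         Jmat = Jmat, Kmat = Kmat, ao_frag = ao_frag,
         enuc_a = enuc_a, enuc_b = enuc_b, enuc_ab = enuc_ab,
         n_elec_a = n_electrons(a), n_elec_b = n_electrons(b),
         xyz_bohr = xyz_bohr, Z = Z, frag = frag),
    class = "dimer_context")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

coulomb_matrix <- function(ctx, D) {
  matrix(ctx$Jmat %*% as.vector(D), ctx$nbf, ctx$nbf)
}

exchange_matrix <- function(ctx, D) {
  matrix(ctx$Kmat %*% as.vector(D), ctx$nbf, ctx$nbf)
}

# Canonical orthogonalization; columns spanning eigenvalues > thresh.
orthogonalizer <- function(S, thresh = 1e-6) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > thresh
  if (!any(keep)) stop("overlap matrix is numerically singular")
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), sum(keep))
}

# Closed-shell SCF with DIIS; h is the one-electron Hamiltonian for whichever
# set of nuclei is "real", enuc the matching nuclear repulsion.  Returns the
# total energy and the occupied orbital coefficients over the full basis.
rhf_scf <- function(ctx, h, n_elec, enuc,
                    conv_energy = 1e-11, conv_density = 1e-8,
                    max_iter = 256L, ortho_thresh = 1e-6,
                    diis_size = 8L, damping = 0.3,
                    occupation = c("aufbau", "mom"), C_init = NULL) {
  occupation <- match.arg(occupation)
  if (n_elec %% 2 != 0) {
    stop("closed-shell RHF requires an even electron count, got ", n_elec)
  }
  n_occ <- n_elec / 2L
  n <- ctx$nbf
  X <- orthogonalizer(ctx$S, ortho_thresh)
  solve_fock <- function(F) {
    Ft <- crossprod(X, F %*% X)
    ev <- eigen((Ft + t(Ft)) / 2, symmetric = TRUE)
    ord <- order(ev$values)  # eigen() sorts decreasing; occupy lowest first
    C <- X %*% ev$vectors[, ord, drop = FALSE]
    list(C = C, eps = ev$values[ord])
  }
  # occupied orbitals: lowest-eigenvalue (aufbau) or, in maximum-overlap
  # mode, the orbitals that best continue the previous occupied space --
  # this keeps an anionic monomer's electrons off ghost-centered virtuals
  pick_occ <- function(C, C_prev) {
    if (occupation == "aufbau" || is.null(C_prev)) {
      return(C[, seq_len(n_occ), drop = FALSE])
    }
    ov <- crossprod(C, ctx$S %*% C_prev)
    score <- rowSums(ov^2)
    C[, order(score, decreasing = TRUE)[seq_len(n_occ)], drop = FALSE]
  }
  if (n_occ == 0) {
    return(list(energy = enuc, C_occ = matrix(0, n, 0),
                D = matrix(0, n, n), converged = TRUE, n_iter = 0L,
                eps = numeric(0)))
  }
  if (is.null(C_init)) {
    sol <- solve_fock(h)
    C_occ <- sol$C[, seq_len(n_occ), drop = FALSE]
  } else {
    stopifnot(ncol(C_init) == n_occ)
    C_occ <- C_init
  }
  D <- 2 * tcrossprod(C_occ)
  e_old <- Inf
  fock_hist <- list()
  err_hist <- list()
  for (it in seq_len(max_iter)) {
    J <- coulomb_matrix(ctx, D)
    K <- exchange_matrix(ctx, D)
    F <- h + J - 0.5 * K
    e_elec <- 0.5 * sum(D * (h + F))
    energy <- e_elec + enuc
    err <- F %*% D %*% ctx$S - ctx$S %*% D %*% F
    err <- crossprod(X, err %*% X)
    de <- abs(energy - e_old)
    if (de < conv_energy && max(abs(err)) < conv_density) {
      return(list(energy = energy, C_occ = C_occ, D = D, converged = TRUE,
                  n_iter = it, eps = sol$eps))
    }
    e_old <- energy
    fock_hist[[length(fock_hist) + 1L]] <- F
    err_hist[[length(err_hist) + 1L]] <- err
    if (length(fock_hist) > diis_size) {
      fock_hist <- fock_hist[-1]
      err_hist <- err_hist[-1]
    }
    m <- length(fock_hist)
    if (m >= 2) {
      B <- matrix(0, m + 1, m + 1)
      for (i in seq_len(m)) {
        for (j in seq_len(m)) B[i, j] <- sum(err_hist[[i]] * err_hist[[j]])
      }
      B[m + 1, seq_len(m)] <- -1
      B[seq_len(m), m + 1] <- -1
      rhs <- c(rep(0, m), -1)
      cf <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
      if (!is.null(cf) && all(is.finite(cf))) {
        F <- Reduce(`+`, Map(`*`, fock_hist, cf))
      }
    }
    sol <- solve_fock(F)
    C_occ <- pick_occ(sol$C, C_occ)
    D_new <- 2 * tcrossprod(C_occ)
    # light damping in the first iterations stabilizes the core guess
    D <- if (it <= 2 && m < 2) (1 - damping) * D_new + damping * D else D_new
  }
  stop(sprintf(paste0("SCF failed to converge within %d cycles ",
                      "(last dE = %.3e); tighten the geometry or basis"),
               max_iter, de))
}
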