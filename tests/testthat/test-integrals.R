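# Gaussian integral engine against closed forms and derivative identities.
# s-type integrals are pinned by their analytic expressions; p-type integrals
# are pinned through the translational-derivative identity
#   p_x(A) = (1/2a) d/dA_x s(A)
# applied to the (already verified) s-type results with unnormalized
# primitives.

ok <- pocketEDA:::cpp_overlap_kinetic
va <- pocketEDA:::cpp_nuclear_attraction
er <- pocketEDA:::cpp_eri

test_that("s-type overlap, attraction and repulsion match closed forms", {
  set.seed(5)
  for (rep in 1:3) {
    A <- rnorm(3)
    B <- rnorm(3) + c(1.5, 0, 0)
    a <- runif(1, 0.2, 2)
    b <- runif(1, 0.2, 2)
    sh <- list(raw_shell(0, A, a), raw_shell(0, B, b))
    one <- ok(sh)
    expect_equal(one$S[1, 2], ss_overlap(a, A, b, B), tolerance = 1e-12)
    C <- rnorm(3)
    V <- va(sh, matrix(c(C, 2.0), 1, 4))
    expect_equal(V[1, 2], -2.0 * ss_attraction(a, A, b, B, C),
                 tolerance = 1e-10)
    eri <- er(sh)
    expect_equal(eri[1, 2, 1, 2], ssss_eri(a, A, b, B, a, A, b, B),
                 tolerance = 1e-10)
    expect_equal(eri[1, 1, 2, 2], ssss_eri(a, A, a, A, b, B, b, B),
                 tolerance = 1e-10)
  }
})

test_that("contracted s shells match the closed-form double sum", {
  A <- c(0, 0, 0)
  B <- c(0.8, -0.4, 1.1)
  ea <- c(3.4, 0.6, 0.17)
  ca <- c(0.25, 0.8, 0.3)
  eb <- c(1.2, 0.35)
  cb <- c(0.5, 0.6)
  sh <- list(raw_shell(0, A, ea, ca), raw_shell(0, B, eb, cb))
  S <- ok(sh)$S
  want <- 0
  for (i in seq_along(ea)) for (j in seq_along(eb)) {
    want <- want + ca[i] * cb[j] * ss_overlap(ea[i], A, eb[j], B)
  }
  expect_equal(S[1, 2], want, tolerance = 1e-12)
})

test_that("p integrals obey the translational-derivative identity", {
  A <- c(0.3, -0.2, 0.5)
  B <- c(1.4, 0.7, -0.3)
  a <- 0.9
  b <- 0.6
  h <- 1e-5
  shift <- function(d) raw_shell(0, A + c(d, 0, 0), a)
  sB <- raw_shell(0, B, b)
  # overlap: <p_x(A)|s(B)> vs central difference of <s|s>
  p_shell <- raw_shell(1, A, a)
  S_ps <- ok(list(p_shell, sB))$S[1, 4]  # px component vs s on B
  fd_S <- (ok(list(shift(h), sB))$S[1, 2] -
             ok(list(shift(-h), sB))$S[1, 2]) / (2 * h)
  expect_equal(S_ps, fd_S / (2 * a), tolerance = 1e-7)
  # nuclear attraction, same identity
  C <- matrix(c(0.5, 0.5, 0.5, 1.0), 1, 4)
  V_ps <- va(list(p_shell, sB), C)[1, 4]
  fd_V <- (va(list(shift(h), sB), C)[1, 2] -
             va(list(shift(-h), sB), C)[1, 2]) / (2 * h)
  expect_equal(V_ps, fd_V / (2 * a), tolerance = 1e-7)
  # two-electron: (p_x s | s s)
  sC <- raw_shell(0, c(-0.6, 0.2, 0.1), 1.1)
  eri_p <- er(list(p_shell, sB, sC))[1, 4, 5, 5]
  eri_hi <- er(list(shift(h), sB, sC))[1, 2, 3, 3]
  eri_lo <- er(list(shift(-h), sB, sC))[1, 2, 3, 3]
  expect_equal(eri_p, (eri_hi - eri_lo) / (2 * h) / (2 * a),
               tolerance = 1e-7)
})

test_that("kinetic energy matches quadrature for an s-p pair", {
  # T_ij = 0.5 * integral grad(phi_i) . grad(phi_j); evaluate on a grid
  a <- 0.8
  b <- 0.5
  A <- c(0, 0, 0)
  B <- c(1.0, 0.4, -0.2)
  sh <- list(raw_shell(0, A, a), raw_shell(1, B, b))
  T <- ok(sh)$T
  g <- seq(-6, 7, by = 0.15)
  w <- 0.15^3
  gx <- expand.grid(x = g, y = g, z = g)
  rA2 <- (gx$x - A[1])^2 + (gx$y - A[2])^2 + (gx$z - A[3])^2
  phi_s <- exp(-a * rA2)
  dxB <- gx$x - B[1]; dyB <- gx$y - B[2]; dzB <- gx$z - B[3]
  rB2 <- dxB^2 + dyB^2 + dzB^2
  phi_p <- dxB * exp(-b * rB2)  # p_x on B
  # grad(s_A) = -2a (r-A) phi_s ; grad(p_x) components
  gs <- cbind(-2 * a * (gx$x - A[1]), -2 * a * (gx$y - A[2]),
              -2 * a * (gx$z - A[3])) * phi_s
  gp <- cbind(exp(-b * rB2) - 2 * b * dxB^2 * exp(-b * rB2),
              -2 * b * dxB * dyB * exp(-b * rB2),
              -2 * b * dxB * dzB * exp(-b * rB2))
  quad <- 0.5 * sum(rowSums(gs * gp)) * w
  expect_equal(T[1, 2], quad, tolerance = 1e-4)
})

test_that("the two-electron array has full 8-fold permutation symmetry", {
  frag <- water_molecule()
  sh <- pocketEDA:::build_shells(frag$elements, frag$xyz, "sto-3g")
  eri <- er(sh)
  set.seed(2)
  idx <- matrix(sample(dim(eri)[1], 4 * 40, replace = TRUE), ncol = 4)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]; l <- idx[r, 4]
    v <- eri[i, j, k, l]
    expect_equal(eri[j, i, k, l], v, tolerance = 1e-12)
    expect_equal(eri[i, j, l, k], v, tolerance = 1e-12)
    expect_equal(eri[k, l, i, j], v, tolerance = 1e-12)
    expect_equal(eri[l, k, j, i], v, tolerance = 1e-12)
  }
})

test_that("overlap matrices are symmetric with unit diagonal", {
  frag <- formamide_molecule()
  sh <- pocketEDA:::build_shells(frag$elements, frag$xyz, "sto-3g")
  S <- ok(sh)$S
  expect_equal(S, t(S), tolerance = 1e-12)
  expect_equal(diag(S), rep(1, nrow(S)), tolerance = 1e-10)
  expect_true(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > 0)
})

test_that("known closed-shell reference energies are reproduced", {
  # standard published RHF/STO-3G results for the textbook geometries
  h2 <- molecular_fragment(c("H", "H"),
                           rbind(c(0, 0, 0), c(0, 0, 1.4 * BOHR)),
                           label = "H2")
  expect_equal(fragment_scf(h2)$energy, -1.116714, tolerance = 2e-6)
  expect_equal(fragment_scf(helium_atom())$energy, -2.807784,
               tolerance = 2e-6)
})
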