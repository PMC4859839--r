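# Variational-perturbational decomposition: physical limits, oracle
# equivalence, invariances.  Shared systems are computed once at file scope
# (small STO-3G problems; every SCF is seconds at most).

water_near <- eda_decompose(water_dimer(3.0))
water_far <- eda_decompose(water_dimer(100))

test_that("monomer SCF in the DCBS matches the isolated monomer at 100 A", {
  he_far <- dimer_system(helium_atom("He_a"),
                         translate_fragment(helium_atom("He_b"),
                                            c(100, 0, 0)))
  ctx <- dimer_context(he_far)
  wfn <- scf_monomer_dcbs(ctx, "A")
  isolated <- fragment_scf(helium_atom())
  expect_lt(abs(wfn$energy - isolated$energy), 1e-8)
})

test_that("ghost functions can only lower the monomer energy (variational)", {
  d <- water_dimer(3.0)
  ctx <- dimer_context(d)
  in_dcbs <- scf_monomer_dcbs(ctx, "A")$energy
  isolated <- fragment_scf(d$fragment_a)$energy
  expect_lte(in_dcbs, isolated + 1e-12)
})

test_that("charged fragments carry the right electron count", {
  d <- dimer_system(lithium_cation(),
                    translate_fragment(hydride_anion(), c(20, 0, 0)))
  ctx <- dimer_context(d)
  expect_equal(ctx$n_elec_a, 2)  # Z = 3, charge +1
  expect_equal(ctx$n_elec_b, 2)  # Z = 1, charge -1
})

test_that("every component vanishes in the non-interacting 100 A limit", {
  for (comp in c("e_hl", "e_el_10", "e_ex_hl", "e_del_hf", "e_hf")) {
    expect_lt(abs(water_far[[comp]]), 1e-4)
  }
})

test_that("component additivity holds to 1e-8 kcal/mol by construction", {
  for (res in list(water_near, water_far)) {
    expect_lt(abs(res$e_hf - (res$e_el_10 + res$e_ex_hl + res$e_del_hf)),
              1e-8)
    expect_lt(abs(res$e_hl - (res$e_el_10 + res$e_ex_hl)), 1e-8)
  }
})

test_that("the water dimer shows the hydrogen-bond sign pattern", {
  expect_lt(water_near$e_el_10, 0)
  expect_gt(water_near$e_ex_hl, 0)
  expect_lt(water_near$e_del_hf, 0)
  expect_lt(water_near$e_hf, 0)
  # counterpoise supermolecular oracle assembled from independent SCF calls
  d <- water_dimer(3.0)
  e_ab <- fragment_scf(
    molecular_fragment(c(d$fragment_a$elements, d$fragment_b$elements),
                       rbind(d$fragment_a$xyz, d$fragment_b$xyz),
                       label = "super"))$energy
  e_a <- fragment_scf(d$fragment_a, ghost = d$fragment_b)$energy
  e_b <- fragment_scf(d$fragment_b, ghost = d$fragment_a)$energy
  expect_equal(water_near$e_hf, (e_ab - e_a - e_b) * hartree_to_kcal,
               tolerance = 1e-6)
})

test_that("Heitler-London exchange is positive and decays on a He...He scan", {
  seps <- c(2.5, 3.0, 3.5, 4.0)
  scan <- make_dimer_scan(dimer_scan_spec(helium_atom("He_a"),
                                          helium_atom("He_b"),
                                          separations = seps))
  ex <- vapply(scan, function(d) eda_decompose(d)$e_ex_hl, numeric(1))
  expect_true(all(ex > 0))
  expect_true(all(diff(ex) < 0))
  # faster than any inverse power: successive ratios shrink rapidly
  expect_lt(ex[4] / ex[1], (seps[1] / seps[4])^12)
})

test_that("exchange vanishes in the zero-overlap limit", {
  expect_lt(abs(water_far$e_ex_hl / hartree_to_kcal), 1e-8)
})

test_that("ion-pair electrostatics follows the -1/R point-charge law", {
  d <- dimer_system(lithium_cation(),
                    translate_fragment(hydride_anion(), c(20, 0, 0)))
  ctx <- dimer_context(d)
  wa <- scf_monomer_dcbs(ctx, "A")
  wb <- scf_monomer_dcbs(ctx, "B")
  e_el <- electrostatic_first_order(ctx, wa, wb)
  R <- 20 / BOHR
  expect_lt(abs(e_el - (-1 / R)) / (1 / R), 0.01)
})

test_that("electrostatics of neutral polar monomers decays as R^-3", {
  seps <- c(8, 12, 16, 20)
  e_el <- vapply(seps, function(r) {
    ctx <- dimer_context(water_dimer(r))
    electrostatic_first_order(ctx, scf_monomer_dcbs(ctx, "A"),
                              scf_monomer_dcbs(ctx, "B"))
  }, numeric(1))
  slope <- coef(lm(log(abs(e_el)) ~ log(seps)))[2]
  expect_lt(abs(slope - (-3)) / 3, 0.05)
})

test_that("E^HL matches the brute-force nonorthogonal-determinant oracle", {
  systems <- list(
    he = make_dimer_scan(dimer_scan_spec(helium_atom("He_a"),
                                         helium_atom("He_b"),
                                         separations = 3.0))[[1]],
    h2 = make_dimer_scan(dimer_scan_spec(hydrogen_molecule(),
                                         hydrogen_molecule(),
                                         separations = 5.0,
                                         axis = c(1, 0, 0)))[[1]])
  for (d in systems) {
    ctx <- dimer_context(d)
    wa <- scf_monomer_dcbs(ctx, "A")
    wb <- scf_monomer_dcbs(ctx, "B")
    hl <- heitler_london(ctx, wa, wb)
    sh <- ctx$shells
    eri <- pocketEDA:::cpp_eri(sh)
    h1 <- ctx$T + ctx$V_a + ctx$V_b
    enuc <- ctx$enuc_a + ctx$enuc_b + ctx$enuc_ab
    oracle <- nonorthogonal_determinant_energy(
      cbind(wa$C_occ, wb$C_occ), ctx$S, h1, eri, enuc)
    expect_lt(abs(hl$e_det - oracle), 1e-8)
  }
})

test_that("the electron-electron Coulomb term matches grid quadrature", {
  d <- make_dimer_scan(dimer_scan_spec(hydrogen_molecule(),
                                       hydrogen_molecule(),
                                       separations = 5.0,
                                       axis = c(1, 0, 0)))[[1]]
  ctx <- dimer_context(d)
  wa <- scf_monomer_dcbs(ctx, "A")
  wb <- scf_monomer_dcbs(ctx, "B")
  e_ee <- sum(wa$D * pocketEDA:::coulomb_matrix(ctx, wb$D))
  g <- seq(-5, 5, by = 0.15)
  gx <- as.matrix(expand.grid(g, g, g + 0.0))  # box around fragment A (bohr)
  rho_a <- pocketEDA:::cpp_density_at_points(ctx$shells, wa$D, gx)
  phi_b <- pocketEDA:::cpp_esp_at_points(ctx$shells, wb$D, gx)
  quad <- sum(rho_a * phi_b) * 0.15^3
  expect_lt(abs(quad - e_ee), 1e-4)
})

test_that("the decomposition is invariant under rigid rotation+translation", {
  d <- water_dimer(3.0)
  R <- rotation_matrix(c(1, 2, 3), 0.7)
  rot <- dimer_system(
    translate_fragment(rotate_fragment(d$fragment_a, R), c(1.5, -2, 0.7)),
    translate_fragment(rotate_fragment(d$fragment_b, R), c(1.5, -2, 0.7)))
  moved <- eda_decompose(rot)
  for (comp in c("e_hl", "e_el_10", "e_ex_hl", "e_del_hf", "e_hf")) {
    expect_lt(abs(moved[[comp]] - water_near[[comp]]), 1e-7)
  }
})

test_that("swapping fragment labels of a symmetric dimer changes nothing", {
  a <- helium_atom("He_a")
  b <- translate_fragment(helium_atom("He_b"), c(3, 0, 0))
  r1 <- eda_decompose(dimer_system(a, b))
  r2 <- eda_decompose(dimer_system(b, a))
  for (comp in c("e_hl", "e_el_10", "e_ex_hl", "e_del_hf", "e_hf")) {
    expect_lt(abs(r1[[comp]] - r2[[comp]]), 1e-10)
  }
})

test_that("open-shell fragments and odd electron counts are rejected", {
  li_rad <- molecular_fragment("Li", matrix(0, 1, 3), charge = 0L,
                               label = "Li radical")
  d <- dimer_system(li_rad, translate_fragment(helium_atom(), c(5, 0, 0)))
  expect_error(scf_monomer_dcbs(dimer_context(d), "A"), "even electron")
  doub <- molecular_fragment("He", matrix(0, 1, 3), multiplicity = 3L)
  d2 <- dimer_system(doub, translate_fragment(helium_atom(), c(5, 0, 0)))
  expect_error(scf_monomer_dcbs(dimer_context(d2), "A"), "closed-shell")
})
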