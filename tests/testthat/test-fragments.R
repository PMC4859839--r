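# Residue-ligand dimer extraction: caps, charges, idempotency.

# Toy tripeptide + water complex written through bio3d; geometry is a simple
# planar chain with conventional-ish bond lengths (only connectivity and
# directions matter here).
make_complex_pdb <- function(middle_resid = "GLY") {
  xyz <- NULL
  resno <- c()
  resid <- c()
  elety <- c()
  for (i in 1:3) {
    x0 <- 3.5 * (i - 1)
    xyz <- rbind(xyz,
                 c(x0, 0, 0),          # N
                 c(x0 + 1.45, 0.3, 0), # CA
                 c(x0 + 2.2, -0.6, 0), # C
                 c(x0 + 2.2, -1.83, 0))  # O
    resno <- c(resno, rep(i, 4))
    resid <- c(resid, rep(if (i == 2) middle_resid else "GLY", 4))
    elety <- c(elety, "N", "CA", "C", "O")
  }
  xyz <- rbind(xyz, c(1.5, 5, 0), c(2.3, 5.4, 0), c(0.8, 5.7, 0))
  resno <- c(resno, rep(4, 3))
  resid <- c(resid, rep("HOH", 3))
  elety <- c(elety, "O", "H1", "H2")
  path <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = path, xyz = as.vector(t(xyz)), resno = resno,
                   resid = resid, elety = elety,
                   eleno = seq_along(resno),
                   chain = rep("A", length(resno)))
  path
}

test_that("backbone extraction caps both cut peptide bonds with hydrogens", {
  d <- extract_residue_dimer(make_complex_pdb(), resno = 2,
                             ligand_resid = "HOH", ligand_charge = 0)
  expect_equal(nrow(d$fragment_a$xyz), 6)  # N, CA, C, O + 2 caps
  expect_equal(sum(d$fragment_a$elements == "H"), 2)
  expect_equal(d$fragment_a$charge, 0L)
  expect_equal(d$fragment_b$charge, 0L)
  expect_equal(nrow(d$fragment_b$xyz), 3)
})

test_that("cap hydrogens sit exactly on the broken-bond vectors", {
  pdb <- bio3d::read.pdb(make_complex_pdb(), verbose = FALSE)
  d <- extract_residue_dimer(pdb, resno = 2, ligand_resid = "HOH",
                             ligand_charge = 0)
  xyz1 <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  n2 <- xyz1[5, ]   # N of residue 2
  c1 <- xyz1[3, ]   # C of residue 1 (removed neighbor)
  c2 <- xyz1[7, ]   # C of residue 2
  n3 <- xyz1[9, ]   # N of residue 3 (removed neighbor)
  caps <- d$fragment_a$xyz[5:6, ]
  # cap 1 on N at 1.01 A toward C(i-1); cap 2 on C at 1.09 A toward N(i+1)
  expect_equal(sqrt(sum((caps[1, ] - n2)^2)), 1.01, tolerance = 1e-9)
  expect_equal(sqrt(sum((caps[2, ] - c2)^2)), 1.09, tolerance = 1e-9)
  collinearity <- function(p, origin, towards) {
    u <- p - origin
    v <- towards - origin
    cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    sqrt(sum(cr^2))
  }
  expect_lt(collinearity(caps[1, ], n2, c1), 1e-9)
  expect_lt(collinearity(caps[2, ], c2, n3), 1e-9)
})

test_that("charged residues get their table charge; unknowns are refused", {
  d <- extract_residue_dimer(make_complex_pdb("ASP"), resno = 2,
                             ligand_resid = "HOH", ligand_charge = 0)
  expect_equal(d$fragment_a$charge, -1L)
  expect_equal(d$fragment_a$label, "ASP2")
  expect_error(
    extract_residue_dimer(make_complex_pdb("XYZ"), resno = 2,
                          ligand_resid = "HOH", ligand_charge = 0),
    "not guessed")
  expect_error(
    extract_residue_dimer(make_complex_pdb(), resno = 2,
                          ligand_resid = "HOH"),
    "ligand_charge")
})

test_that("sidechain scheme keeps CA plus side chain with CA caps", {
  d <- extract_residue_dimer(make_complex_pdb(), resno = 2,
                             ligand_resid = "HOH", ligand_charge = 0,
                             cap_scheme = "sidechain")
  # glycine: side chain reduces to CA + two caps (a methylene-like cap unit)
  expect_equal(nrow(d$fragment_a$xyz), 3)
  expect_equal(d$fragment_a$elements, c("C", "H", "H"))
  expect_equal(sqrt(sum((d$fragment_a$xyz[2, ] -
                           d$fragment_a$xyz[1, ])^2)), 1.09,
               tolerance = 1e-9)
})

test_that("re-extracting an emitted dimer is the identity", {
  d <- extract_residue_dimer(make_complex_pdb(), resno = 2,
                             ligand_resid = "HOH", ligand_charge = 0)
  # write the capped dimer back out as a PDB and extract again
  a <- d$fragment_a
  b <- d$fragment_b
  path <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(rbind(a$xyz, b$xyz))),
    resno = c(rep(2, nrow(a$xyz)), rep(4, nrow(b$xyz))),
    resid = c(rep("GLY", nrow(a$xyz)), rep("HOH", nrow(b$xyz))),
    elety = c("N", "CA", "C", "O", "H8", "H9", "O", "H1", "H2"),
    eleno = 1:9, chain = rep("A", 9))
  d2 <- extract_residue_dimer(path, resno = 2, ligand_resid = "HOH",
                              ligand_charge = 0)
  expect_equal(nrow(d2$fragment_a$xyz), nrow(a$xyz))  # no new caps
  expect_equal(d2$fragment_a$xyz, a$xyz, tolerance = 1e-3)  # PDB precision
  expect_equal(d2$fragment_b$xyz, b$xyz, tolerance = 1e-3)
})

test_that("an extracted glycine-water dimer survives the SCF pipeline", {
  d <- extract_residue_dimer(make_complex_pdb(), resno = 2,
                             ligand_resid = "HOH", ligand_charge = 0,
                             cap_scheme = "sidechain")
  ctx <- dimer_context(d)
  expect_equal(ctx$n_elec_a %% 2, 0)
  expect_equal(ctx$n_elec_b %% 2, 0)
})
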