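#' Molecular fragment
#'
#' The unit of the energy-decomposition workflow: a set of atoms with
#' Cartesian coordinates, a net charge and a spin multiplicity.  All model
#' systems in this package are closed-shell (multiplicity 1); open-shell
#' fragments are rejected at SCF time.
#'
#' @param elements Character vector of element symbols.
#' @param xyz Numeric matrix (n x 3) of coordinates in angstrom.
#' @param charge Integer net charge in units of e.
#' @param multiplicity Integer spin multiplicity (must be 1).
#' @param label Short text label used in reports.
#' @return An object of class `molecular_fragment`.
#' @export
molecular_fragment <- function(elements, xyz, charge = 0L, multiplicity = 1L,
                               label = "fragment") {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (nrow(xyz) != length(elements) || ncol(xyz) != 3) {
    stop("xyz must be an n x 3 matrix matching length(elements)")
  }
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  if (charge != round(charge)) stop("net charge must be integral")
  element_number(elements)  # validates symbols
  structure(
    list(elements = as.character(elements), xyz = unname(xyz),
         charge = as.integer(charge), multiplicity = as.integer(multiplicity),
         label = label),
    class = "molecular_fragment")
}

#' @export
print.molecular_fragment <- function(x, ...) {
  cat(sprintf("<molecular_fragment> %s: %d atoms, charge %+d\n",
              x$label, nrow(x$xyz), x$charge))
  invisible(x)
}

n_electrons <- function(fragment) {
  sum(element_number(fragment$elements)) - fragment$charge
}

#' Rigid-body transforms of a fragment
#'
#' @param fragment A [molecular_fragment()].
#' @param shift Numeric length-3 translation (angstrom).
#' @return The transformed fragment.
#' @export
translate_fragment <- function(fragment, shift) {
  fragment$xyz <- sweep(fragment$xyz, 2, shift, "+")
  fragment
}

#' @rdname translate_fragment
#' @param R 3x3 rotation matrix.
#' @param center Point the rotation is taken about (angstrom).
#' @export
rotate_fragment <- function(fragment, R, center = c(0, 0, 0)) {
  fragment$xyz <- sweep(sweep(fragment$xyz, 2, center, "-") %*% t(R),
                        2, center, "+")
  fragment
}

min_interfragment_distance <- function(a, b) {
  d2 <- outer(rowSums(a$xyz^2), rowSums(b$xyz^2), "+") -
    2 * a$xyz %*% t(b$xyz)
  sqrt(max(0, min(d2)))
}

#' Residue-ligand dimer system
#'
#' Two molecular fragments treated as an interacting pair; one Table-2-style
#' row of the decomposition is computed per dimer.
#'
#' @param fragment_a,fragment_b [molecular_fragment()] objects.
#' @param basis_name Basis set used when the dimer is decomposed.
#' @return An object of class `dimer_system`.
#' @export
dimer_system <- function(fragment_a, fragment_b, basis_name = "sto-3g") {
  stopifnot(inherits(fragment_a, "molecular_fragment"),
            inherits(fragment_b, "molecular_fragment"))
  dmin <- min_interfragment_distance(fragment_a, fragment_b)
  if (dmin < 0.5) {
    stop(sprintf(paste0("fragments overlap: closest inter-fragment atom pair ",
                        "at %.3f angstrom (< 0.5)"), dmin))
  }
  structure(
    list(fragment_a = fragment_a, fragment_b = fragment_b,
         basis_name = basis_name),
    class = "dimer_system")
}

#' @export
print.dimer_system <- function(x, ...) {
  cat(sprintf("<dimer_system> %s (%+d) ... %s (%+d), basis %s\n",
              x$fragment_a$label, x$fragment_a$charge,
              x$fragment_b$label, x$fragment_b$charge, x$basis_name))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Rigid geometry templates for the scan fixtures.  Bond lengths and angles are
# conventional gas-phase values; orientations are chosen so that the scan
# anchors line up with hydrogen-bonding motifs.

.rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Water monomer template
#'
#' r(OH) = 0.9572 angstrom, HOH angle 104.52 degrees; oxygen at the origin,
#' C2 axis along +z with the hydrogens above the oxygen.
#' @return A [molecular_fragment()].
#' @export
water_molecule <- function() {
  half <- 104.52 / 2 * pi / 180
  r <- 0.9572
  molecular_fragment(
    c("O", "H", "H"),
    rbind(c(0, 0, 0),
          c(r * sin(half), 0, r * cos(half)),
          c(-r * sin(half), 0, r * cos(half))),
    label = "water")
}

#' Hydrogen-bonded water dimer
#'
#' Canonical near-linear arrangement: donor O-H points along +x at the
#' acceptor oxygen placed `r_oo` angstrom away; acceptor hydrogens point away
#' from the donor.  Fragment A is the donor.
#' @param r_oo Oxygen-oxygen separation in angstrom.
#' @return A [dimer_system()].
#' @export
water_dimer <- function(r_oo = 3.0) {
  r <- 0.9572
  ang <- 104.52 * pi / 180
  donor <- molecular_fragment(
    c("O", "H", "H"),
    rbind(c(0, 0, 0),
          c(r, 0, 0),
          c(r * cos(ang), 0, r * sin(ang))),
    label = "water-donor")
  half <- ang / 2
  acceptor <- molecular_fragment(
    c("O", "H", "H"),
    rbind(c(r_oo, 0, 0),
          c(r_oo + r * cos(half), r * sin(half), 0),
          c(r_oo + r * cos(half), -r * sin(half), 0)),
    label = "water-acceptor")
  dimer_system(donor, acceptor)
}

#' Helium atom template
#' @param label Fragment label.
#' @return A [molecular_fragment()].
#' @export
helium_atom <- function(label = "He") {
  molecular_fragment("He", matrix(0, 1, 3), label = label)
}

#' Hydrogen molecule template
#'
#' Bond along z, centered at the origin, r = 0.7414 angstrom.
#' @return A [molecular_fragment()].
#' @export
hydrogen_molecule <- function() {
  molecular_fragment(c("H", "H"),
                     rbind(c(0, 0, -0.3707), c(0, 0, 0.3707)),
                     label = "H2")
}

#' Lithium cation / hydride anion templates
#'
#' Spherical closed-shell +1/-1 ions used for long-range point-charge checks
#' of the electrostatic component.
#' @return A [molecular_fragment()].
#' @export
lithium_cation <- function() {
  molecular_fragment("Li", matrix(0, 1, 3), charge = 1L, label = "Li+")
}

#' @rdname lithium_cation
#' @export
hydride_anion <- function() {
  molecular_fragment("H", matrix(0, 1, 3), charge = -1L, label = "H-")
}

#' Formamide monomer template
#'
#' Planar HCONH2 with conventional bond lengths; the carbonyl C=O points
#' along +x from the carbon at the origin.  Atom order: C, O, N, H(C),
#' H(N, syn), H(N, anti).
#' @return A [molecular_fragment()].
#' @export
formamide_molecule <- function() {
  C <- c(0, 0)
  O <- 1.219 * c(cos(0), sin(0))
  N <- 1.352 * c(cos(125 * pi / 180), sin(125 * pi / 180))
  HC <- 1.098 * c(cos(-117.5 * pi / 180), sin(-117.5 * pi / 180))
  u <- (C - N) / sqrt(sum((C - N)^2))
  h1 <- N + 1.010 * as.numeric(.rot2(2 * pi / 3) %*% u)
  h2 <- N + 1.010 * as.numeric(.rot2(-2 * pi / 3) %*% u)
  xyz <- rbind(C, O, N, HC, h1, h2)
  molecular_fragment(c("C", "O", "N", "H", "H", "H"),
                     cbind(xyz, 0), label = "formamide")
}

.tetrahedral_caps <- function(center, axis, bond = 1.09) {
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  th <- 109.47 * pi / 180
  t(vapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi) {
    center + bond * (cos(th) * axis +
                       sin(th) * (cos(phi) * e1 + sin(phi) * e2))
  }, numeric(3)))
}

#' Methylguanidinium cation template
#'
#' Planar guanidinium core (three N at 1.33 angstrom, 120 degrees apart)
#' with a methyl group on one nitrogen; models the charged arginine side
#' chain.  Net charge +1.
#' @return A [molecular_fragment()].
#' @export
methylguanidinium_molecule <- function() {
  C0 <- c(0, 0)
  ang <- c(90, 210, 330) * pi / 180
  N <- t(vapply(ang, function(a) 1.33 * c(cos(a), sin(a)), numeric(2)))
  to0 <- function(n) (C0 - n) / sqrt(sum((C0 - n)^2))
  cme <- N[1, ] + 1.46 * as.numeric(.rot2(2 * pi / 3) %*% to0(N[1, ]))
  h_n1 <- N[1, ] + 1.01 * as.numeric(.rot2(-2 * pi / 3) %*% to0(N[1, ]))
  h_n2a <- N[2, ] + 1.01 * as.numeric(.rot2(2 * pi / 3) %*% to0(N[2, ]))
  h_n2b <- N[2, ] + 1.01 * as.numeric(.rot2(-2 * pi / 3) %*% to0(N[2, ]))
  h_n3a <- N[3, ] + 1.01 * as.numeric(.rot2(2 * pi / 3) %*% to0(N[3, ]))
  h_n3b <- N[3, ] + 1.01 * as.numeric(.rot2(-2 * pi / 3) %*% to0(N[3, ]))
  plane <- cbind(rbind(C0, N, cme, h_n1, h_n2a, h_n2b, h_n3a, h_n3b), 0)
  me_axis <- c(cme - N[1, ], 0)
  hme <- .tetrahedral_caps(c(cme, 0), me_axis)
  molecular_fragment(
    c("C", "N", "N", "N", "C", "H", "H", "H", "H", "H", "H", "H", "H"),
    rbind(plane, hme), charge = 1L, label = "methylguanidinium")
}

#' Acetate anion template
#'
#' CH3COO- with the carboxylate carbon at the origin and the two oxygens
#' symmetric about the C-C axis (along -x).  Net charge -1.
#' @return A [molecular_fragment()].
#' @export
acetate_molecule <- function() {
  C1 <- c(0, 0, 0)
  C2 <- c(-1.52, 0, 0)
  O1 <- c(1.25 * cos(60 * pi / 180), 1.25 * sin(60 * pi / 180), 0)
  O2 <- c(1.25 * cos(60 * pi / 180), -1.25 * sin(60 * pi / 180), 0)
  hme <- .tetrahedral_caps(C2, C2 - C1)
  molecular_fragment(c("C", "C", "O", "O", "H", "H", "H"),
                     rbind(C1, C2, O1, O2, hme),
                     charge = -1L, label = "acetate")
}

# ---------------------------------------------------------------------------
# Rigid dimer scans

#' Specify a rigid dimer separation scan
#'
#' Monomer A stays fixed; monomer B is rigidly translated so that the
#' distance between the two anchor atoms equals each requested separation,
#' with the anchor of B placed along `axis` from the anchor of A.
#'
#' @param monomer_a,monomer_b [molecular_fragment()] templates.
#' @param separations Strictly increasing positive separations (angstrom).
#' @param axis Direction of the scan (need not be normalized).
#' @param anchor_a,anchor_b 1-based atom indices of the anchor atoms.
#' @param basis_name Basis recorded on the emitted dimers.
#' @return An object of class `dimer_scan_spec`.
#' @export
dimer_scan_spec <- function(monomer_a, monomer_b, separations,
                            axis = c(1, 0, 0), anchor_a = 1L, anchor_b = 1L,
                            basis_name = "sto-3g") {
  stopifnot(inherits(monomer_a, "molecular_fragment"),
            inherits(monomer_b, "molecular_fragment"))
  if (any(separations <= 0) || is.unsorted(separations, strictly = TRUE)) {
    stop("separations must be strictly positive and strictly increasing")
  }
  if (sqrt(sum(axis^2)) < 1e-12) stop("axis must be a nonzero vector")
  structure(
    list(monomer_a = monomer_a, monomer_b = monomer_b,
         separations = as.numeric(separations),
         axis = axis / sqrt(sum(axis^2)),
         anchor_a = as.integer(anchor_a), anchor_b = as.integer(anchor_b),
         basis_name = basis_name),
    class = "dimer_scan_spec")
}

#' Generate the dimers of a separation scan
#'
#' @param spec A [dimer_scan_spec()].
#' @return A list of [dimer_system()] objects, one per separation.  A
#'   separation that brings any inter-fragment atom pair closer than 0.5
#'   angstrom is refused.
#' @export
make_dimer_scan <- function(spec) {
  stopifnot(inherits(spec, "dimer_scan_spec"))
  a <- spec$monomer_a
  lapply(spec$separations, function(d) {
    target <- a$xyz[spec$anchor_a, ] + d * spec$axis
    b <- translate_fragment(spec$monomer_b,
                            target - spec$monomer_b$xyz[spec$anchor_b, ])
    dmin <- min_interfragment_distance(a, b)
    if (dmin < 0.5) {
      stop(sprintf(paste0("separation %.3f angstrom brings fragments within ",
                          "%.3f angstrom (< 0.5): refusing to build ",
                          "overlapping dimer"), d, dmin))
    }
    dimer_system(a, b, basis_name = spec$basis_name)
  })
}
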