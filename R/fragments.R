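# Residue-ligand dimer extraction from a complex structure.
#
# A pocket residue is excised from the protein and paired with the ligand as
# a two-fragment system for the decomposition.  Broken bonds are capped with
# hydrogen link atoms placed exactly on the original bond vector at standard
# X-H lengths, so cap placement is testable to machine precision.

.CAP_NH <- 1.01  # angstrom, cap on backbone N
.CAP_CH <- 1.09  # angstrom, cap on backbone C / C-alpha

#' Formal residue charges
#'
#' Loads the packaged residue-charge table (YAML): +1 for ARG/LYS/HIP, -1
#' for ASP/GLU, 0 for the remaining standard amino acids and for
#' acetyllysine (ALY).  An unknown residue name is a hard error -- charges
#' are never guessed.
#'
#' @return Named integer vector of formal charges.
#' @export
default_residue_charges <- function() {
  path <- system.file("extdata", "residue_charges.yaml",
                      package = "pocketEDA", mustWork = TRUE)
  unlist(yaml::read_yaml(path))
}

residue_charge <- function(resid, charge_table) {
  if (!resid %in% names(charge_table)) {
    stop("no formal charge known for residue '", resid,
         "': add it to the charge table explicitly (charges are not guessed)")
  }
  as.integer(charge_table[[resid]])
}

.pdb_elements <- function(atom) {
  el <- atom$elesy
  if (is.null(el) || anyNA(el) || any(!nzchar(el))) {
    el <- sub("[0-9'].*$", "", trimws(atom$elety))
    el <- paste0(substr(el, 1, 1),
                 tolower(substr(el, 2, nchar(el))))
    el <- ifelse(substr(el, 1, 1) %in% c("H", "C", "N", "O", "S", "P"),
                 substr(el, 1, 1), el)
  }
  trimws(el)
}

.cap_hydrogen <- function(keep_xyz, removed_xyz, length) {
  v <- removed_xyz - keep_xyz
  keep_xyz + length * v / sqrt(sum(v^2))
}

#' Extract a capped residue-ligand dimer from a complex
#'
#' Excises one residue and pairs it with the ligand.  Under the `"backbone"`
#' scheme the residue keeps its full backbone: the flanking peptide bonds
#' C(i-1)-N(i) and C(i)-N(i+1) are cut and hydrogen caps are placed along
#' the broken-bond vectors at 1.01 angstrom (on N) and 1.09 angstrom (on C).
#' Under the `"sidechain"` scheme the N-CA and C-CA bonds are cut instead:
#' the residue keeps CA plus the side chain, with 1.09-angstrom C-H caps on
#' CA.  A terminal residue with no neighbor on one side simply gets no cap
#' there, which makes re-extraction of an emitted dimer the identity.
#'
#' @param pdb A `bio3d` pdb object (or path to a single-model PDB).
#' @param resno Residue number of the pocket residue.
#' @param chain Optional chain identifier disambiguating `resno`.
#' @param ligand_resid Residue name (resid) of the ligand.
#' @param cap_scheme `"backbone"` or `"sidechain"`.
#' @param ligand_charge Net charge of the ligand (integer); must be given
#'   explicitly, it is never inferred.
#' @param charge_table Named residue-charge vector; defaults to
#'   [default_residue_charges()].
#' @param basis_name Basis recorded on the dimer.
#' @return A [dimer_system()] (fragment A: capped residue; fragment B:
#'   ligand).
#' @export
extract_residue_dimer <- function(pdb, resno, chain = NULL, ligand_resid,
                                  cap_scheme = c("backbone", "sidechain"),
                                  ligand_charge = NULL,
                                  charge_table = default_residue_charges(),
                                  basis_name = "sto-3g") {
  cap_scheme <- match.arg(cap_scheme)
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb, verbose = FALSE)
  if (is.null(ligand_charge)) {
    stop("ligand_charge must be set explicitly (formal charges are never ",
         "guessed)")
  }
  atom <- pdb$atom
  in_chain <- if (is.null(chain)) rep(TRUE, nrow(atom)) else
    atom$chain == chain
  res_sel <- which(atom$resno == resno & in_chain &
                     atom$resid != ligand_resid)
  lig_sel <- which(atom$resid == ligand_resid)
  if (length(res_sel) == 0) stop("residue ", resno, " not found")
  if (length(lig_sel) == 0) stop("ligand '", ligand_resid, "' not found")
  if (length(intersect(res_sel, lig_sel)) > 0) {
    stop("residue and ligand selections share atoms")
  }
  resid <- unique(atom$resid[res_sel])
  if (length(resid) != 1) {
    stop("residue selection spans several residue names: ",
         paste(resid, collapse = ", "))
  }
  xyz1 <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  elements <- .pdb_elements(atom)

  find_atom <- function(sel, name) {
    i <- sel[trimws(atom$elety[sel]) == name]
    if (length(i) == 0) NA_integer_ else i[1]
  }
  neighbor <- function(delta, name) {
    i <- which(atom$resno == resno + delta & in_chain &
                 atom$resid != ligand_resid & trimws(atom$elety) == name)
    if (length(i) == 0) NA_integer_ else i[1]
  }

  if (cap_scheme == "backbone") {
    keep <- res_sel
    cuts <- list(
      list(keep = find_atom(res_sel, "N"), removed = neighbor(-1, "C"),
           length = .CAP_NH),
      list(keep = find_atom(res_sel, "C"), removed = neighbor(+1, "N"),
           length = .CAP_CH))
  } else {
    backbone <- c("N", "C", "O", "H", "HN", "OXT")
    keep <- res_sel[!trimws(atom$elety[res_sel]) %in% backbone]
    ca <- find_atom(res_sel, "CA")
    if (is.na(ca)) stop("residue has no CA atom; cannot cut side chain")
    cuts <- list(
      list(keep = ca, removed = find_atom(res_sel, "N"), length = .CAP_CH),
      list(keep = ca, removed = find_atom(res_sel, "C"), length = .CAP_CH))
  }

  res_xyz <- xyz1[keep, , drop = FALSE]
  res_el <- elements[keep]
  for (cut in cuts) {
    if (is.na(cut$keep) || is.na(cut$removed)) next
    if (cut$removed %in% keep) next  # nothing was actually cut
    res_xyz <- rbind(res_xyz,
                     .cap_hydrogen(xyz1[cut$keep, ], xyz1[cut$removed, ],
                                   cut$length))
    res_el <- c(res_el, "H")
  }

  frag_res <- molecular_fragment(
    res_el, res_xyz, charge = residue_charge(resid, charge_table),
    label = sprintf("%s%d", resid, resno))
  frag_lig <- molecular_fragment(
    elements[lig_sel], xyz1[lig_sel, , drop = FALSE],
    charge = as.integer(ligand_charge), label = ligand_resid)
  dimer_system(frag_res, frag_lig, basis_name = basis_name)
}
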