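# File interfaces: multi-model PDB and concatenated-XYZ trajectories,
# fragment-annotated XYZ dimers, YAML mixture configs.

#' Write a trajectory as a multi-model PDB
#'
#' Hydrogen-bond triples are emitted as residues named `HBD` (atoms N, H, O;
#' one residue per monitored bond, in spec order) and ring pairs as residues
#' named `RNG` (12 C atoms), so the monitored topology survives a round
#' trip through the file.
#'
#' @param trajectory A `toy_trajectory`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_trajectory_pdb <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "toy_trajectory"))
  coords <- trajectory$coords
  n_atoms <- dim(coords)[1]
  nf <- dim(coords)[3]
  xyz <- t(vapply(seq_len(nf),
                  function(f) as.vector(t(coords[, , f])),
                  numeric(3 * n_atoms)))
  nb <- nrow(trajectory$monitored)
  resid <- rep("HBD", 3 * nb)
  resno <- rep(seq_len(nb), each = 3)
  nr <- length(trajectory$ring_pairs)
  if (nr > 0) {
    resid <- c(resid, rep("RNG", 12 * nr))
    resno <- c(resno, rep(nb + seq_len(nr), each = 12))
  }
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = resno, resid = resid,
                   elety = trajectory$elements,
                   eleno = seq_len(n_atoms),
                   chain = rep("A", n_atoms))
  invisible(path)
}

#' Read a trajectory from a multi-model PDB
#'
#' Reconstructs monitored hydrogen-bond triples from `HBD` residues and ring
#' pairs from `RNG` residues when present (the dialect written by
#' [write_trajectory_pdb()]); arbitrary multi-model PDBs are read with an
#' empty monitored table.
#'
#' @param path A PDB file.
#' @return A `toy_trajectory`.
#' @export
read_trajectory_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nf <- nrow(pdb$xyz)
  n_atoms <- ncol(pdb$xyz) / 3
  coords <- array(NA_real_, c(n_atoms, 3, nf))
  for (f in seq_len(nf)) coords[, , f] <- matrix(pdb$xyz[f, ], ncol = 3,
                                                 byrow = TRUE)
  elements <- pdb$atom$elesy
  if (is.null(elements) || anyNA(elements)) {
    elements <- substr(trimws(pdb$atom$elety), 1, 1)
  }
  monitored <- data.frame(bond_id = character(0), donor = integer(0),
                          hydrogen = integer(0), acceptor = integer(0),
                          stringsAsFactors = FALSE)
  ring_pairs <- list()
  is_hbd <- pdb$atom$resid == "HBD"
  if (any(is_hbd)) {
    for (rn in unique(pdb$atom$resno[is_hbd])) {
      idx <- which(is_hbd & pdb$atom$resno == rn)
      if (length(idx) == 3) {
        monitored <- rbind(monitored, data.frame(
          bond_id = sprintf("bond_%d", rn), donor = idx[1],
          hydrogen = idx[2], acceptor = idx[3], stringsAsFactors = FALSE))
      }
    }
  }
  is_rng <- pdb$atom$resid == "RNG"
  if (any(is_rng)) {
    for (rn in unique(pdb$atom$resno[is_rng])) {
      idx <- which(is_rng & pdb$atom$resno == rn)
      if (length(idx) == 12) {
        ring_pairs[[sprintf("ring_%d", rn)]] <- list(a = idx[1:6],
                                                     b = idx[7:12])
      }
    }
  }
  structure(list(coords = coords, elements = elements,
                 monitored = monitored, ring_pairs = ring_pairs,
                 distances = NULL, ring_distances = NULL,
                 n_frames = nf, seed = NA),
            class = "toy_trajectory")
}

#' Write a trajectory as concatenated XYZ frames
#'
#' @param trajectory A `toy_trajectory`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_trajectory_xyz <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "toy_trajectory"))
  coords <- trajectory$coords
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(dim(coords)[3])) {
    writeLines(c(as.character(dim(coords)[1]), sprintf("frame %d", f)), con)
    writeLines(sprintf("%-2s %14.8f %14.8f %14.8f", trajectory$elements,
                       coords[, 1, f], coords[, 2, f], coords[, 3, f]), con)
  }
  invisible(path)
}

#' Write one trajectory frame as a PDB file
#'
#' @param trajectory A `toy_trajectory`.
#' @param frame Frame index.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_frame_pdb <- function(trajectory, frame, path) {
  one <- trajectory
  one$coords <- trajectory$coords[, , frame, drop = FALSE]
  one$n_frames <- 1L
  write_trajectory_pdb(one, path)
}

# ---------------------------------------------------------------------------
# Fragment-annotated XYZ dimer dialect:
#   line 1: atom count
#   line 2: FRAG_A=1..k FRAG_B=k+1..n CHARGE_A=q CHARGE_B=q
#   then one "element x y z" line per atom (angstrom)

#' Write a dimer as fragment-annotated XYZ
#'
#' @param dimer A [dimer_system()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_dimer_xyz <- function(dimer, path) {
  stopifnot(inherits(dimer, "dimer_system"))
  a <- dimer$fragment_a
  b <- dimer$fragment_b
  na <- nrow(a$xyz)
  nb <- nrow(b$xyz)
  lines <- c(
    as.character(na + nb),
    sprintf("FRAG_A=1..%d FRAG_B=%d..%d CHARGE_A=%d CHARGE_B=%d",
            na, na + 1, na + nb, a$charge, b$charge),
    sprintf("%-2s %14.8f %14.8f %14.8f",
            c(a$elements, b$elements),
            c(a$xyz[, 1], b$xyz[, 1]),
            c(a$xyz[, 2], b$xyz[, 2]),
            c(a$xyz[, 3], b$xyz[, 3])))
  writeLines(lines, path)
  invisible(path)
}

#' Read a fragment-annotated XYZ dimer
#'
#' @param path File written by [write_dimer_xyz()].
#' @param basis_name Basis recorded on the dimer.
#' @return A [dimer_system()].
#' @export
read_dimer_xyz <- function(path, basis_name = "sto-3g") {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  hdr <- lines[2]
  get <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "=(-?[0-9]+)(?:\\.\\.(-?[0-9]+))?"),
                                 hdr))[[1]]
    if (length(m) == 0) stop("malformed dimer XYZ header: missing ", key)
    as.integer(m[-1][m[-1] != ""])
  }
  ra <- get("FRAG_A")
  rb <- get("FRAG_B")
  qa <- get("CHARGE_A")
  qb <- get("CHARGE_B")
  toks <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  elements <- vapply(toks, `[`, character(1), 1)
  xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  ia <- ra[1]:ra[2]
  ib <- rb[1]:rb[2]
  dimer_system(
    molecular_fragment(elements[ia], xyz[ia, , drop = FALSE], charge = qa,
                       label = "fragment_a"),
    molecular_fragment(elements[ib], xyz[ib, , drop = FALSE], charge = qb,
                       label = "fragment_b"),
    basis_name = basis_name)
}

# ---------------------------------------------------------------------------
# YAML configs

#' Read hydrogen-bond mixture specs from YAML
#'
#' The file holds a list of blocks with fields `bond_id`, `weights`,
#' `means`, `sds` and `n_frames` (see [hbond_spec()]).
#'
#' @param path YAML file.
#' @param n_frames Optional override applied to every spec.
#' @return Named list of [hbond_spec()].
#' @export
read_hbond_specs_yaml <- function(path, n_frames = NULL) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(b) {
    hbond_spec(b$bond_id, as.numeric(b$weights), as.numeric(b$means),
               as.numeric(b$sds), n_frames %||% b$n_frames)
  })
  setNames(out, vapply(out, function(s) s$bond_id, character(1)))
}

#' Write hydrogen-bond mixture specs to YAML
#'
#' @param specs List of [hbond_spec()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_hbond_specs_yaml <- function(specs, path) {
  if (inherits(specs, "hbond_spec")) specs <- list(specs)
  blocks <- lapply(specs, function(s) {
    list(bond_id = s$bond_id, weights = s$weights, means = s$means,
         sds = s$sds, n_frames = s$n_frames)
  })
  yaml::write_yaml(unname(blocks), path)
  invisible(path)
}
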