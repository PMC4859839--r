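# Trajectory statistics: per-bond distance series, binned frequency tables,
# occupancies, ring-centroid distances and RMSD series.

.traj_coords <- function(trajectory) {
  stopifnot(inherits(trajectory, "toy_trajectory"))
  trajectory$coords
}

.pair_distances <- function(coords, i, j) {
  d <- matrix(coords[i, , ], nrow = 3) - matrix(coords[j, , ], nrow = 3)
  sqrt(colSums(d^2))
}

# Optimal rigid-body superposition (Kabsch, via SVD with reflection guard);
# robust for degenerate (collinear/planar) atom sets.
.kabsch_rmsd <- function(ref, cur) {
  B <- sweep(ref, 2, colMeans(ref))
  A <- sweep(cur, 2, colMeans(cur))
  sv <- svd(crossprod(A, B))
  d <- sign(det(sv$u) * det(sv$v))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  sqrt(mean(rowSums((A %*% R - B)^2)))
}

#' Hydrogen-bond distance series
#'
#' Euclidean H...acceptor distance per frame for one monitored pair.
#'
#' @param trajectory A `toy_trajectory` (from [make_hbond_trajectory()] or
#'   [read_trajectory_pdb()]).
#' @param hydrogen,acceptor 1-based atom indices; if omitted, looked up from
#'   the trajectory's monitored-pair table via `bond_id`.
#' @param bond_id Label; required when indices are omitted.
#' @param donor Optional donor atom index carried through to the result.
#' @return An object of class `hbond_series`: the per-frame distances plus
#'   the atom indices.
#' @export
hbond_series <- function(trajectory, hydrogen = NULL, acceptor = NULL,
                         bond_id = NULL, donor = NA_integer_) {
  coords <- .traj_coords(trajectory)
  if (is.null(hydrogen) || is.null(acceptor)) {
    if (is.null(bond_id)) stop("give either atom indices or a bond_id")
    row <- trajectory$monitored[trajectory$monitored$bond_id == bond_id, ]
    if (nrow(row) != 1) stop("bond_id '", bond_id, "' not monitored")
    hydrogen <- row$hydrogen
    acceptor <- row$acceptor
    donor <- row$donor
  }
  n_atoms <- dim(coords)[1]
  idx <- c(hydrogen, acceptor)
  if (any(idx < 1 | idx > n_atoms)) {
    stop("atom index out of range (trajectory has ", n_atoms, " atoms)")
  }
  structure(list(bond_id = bond_id %||% sprintf("H%d..A%d", hydrogen,
                                                acceptor),
                 distances = .pair_distances(coords, hydrogen, acceptor),
                 donor_atom = donor, hydrogen_atom = hydrogen,
                 acceptor_atom = acceptor),
            class = "hbond_series")
}

#' All monitored hydrogen-bond series of a trajectory
#'
#' @param trajectory A `toy_trajectory`.
#' @return Named list of [hbond_series()].
#' @export
monitored_hbond_series <- function(trajectory) {
  stopifnot(nrow(trajectory$monitored) > 0)
  out <- lapply(trajectory$monitored$bond_id, function(id) {
    hbond_series(trajectory, bond_id = id)
  })
  setNames(out, trajectory$monitored$bond_id)
}

.series_values <- function(series) {
  if (inherits(series, "hbond_series")) series$distances
  else as.numeric(series)
}

#' Bin a distance series into a frequency-of-occurrence table
#'
#' Bin k covers the half-open interval
#' `[center_k - w/2, center_k + w/2)`; a value exactly on an edge goes to the
#' upper bin.  Frequencies are percentages of the total frame count, so
#' frames outside the binned window count in the denominator but in no bin
#' and the frequencies sum to at most 100.
#'
#' @param series An [hbond_series()] or numeric vector (angstrom).
#' @param bin_width Bin width in angstrom.
#' @param first_center Center of the first bin (angstrom); the defaults give
#'   the eight 0.25-angstrom bins 1.625, 1.875, ..., 3.375.
#' @param n_bins Number of bins.
#' @return An object of class `histogram_table` with bin centers, raw
#'   counts, percent frequencies, the out-of-range count and the total frame
#'   count.
#' @export
bin_hbond_series <- function(series, bin_width = 0.25, first_center = 1.625,
                             n_bins = 8L) {
  x <- .series_values(series)
  if (length(x) == 0) stop("cannot bin an empty series")
  stopifnot(bin_width > 0, n_bins >= 1)
  centers <- first_center + (seq_len(n_bins) - 1) * bin_width
  edges <- c(centers - bin_width / 2, centers[n_bins] + bin_width / 2)
  # findInterval uses [edge_i, edge_{i+1}): edge values go to the upper bin
  bin <- findInterval(x, edges)
  counts <- tabulate(bin[bin >= 1 & bin <= n_bins], nbins = n_bins)
  structure(list(
    bond_id = if (inherits(series, "hbond_series")) series$bond_id else NA,
    bin_centers = centers,
    counts = counts,
    frequencies = 100 * counts / length(x),
    n_out_of_range = length(x) - sum(counts),
    n_frames_total = length(x),
    bin_width = bin_width),
    class = "histogram_table")
}

#' @export
print.histogram_table <- function(x, ...) {
  cat(sprintf("<histogram_table> %s (n = %d, %.0f%% in range)\n",
              x$bond_id, x$n_frames_total,
              100 - 100 * x$n_out_of_range / x$n_frames_total))
  df <- data.frame(center = x$bin_centers, percent = round(x$frequencies, 1))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Occupancy of a monitored contact
#'
#' Percentage of frames in which the distance is at or below the cutoff.
#'
#' @param series An [hbond_series()] or numeric vector.
#' @param cutoff Distance cutoff in angstrom (default 3.5, the upper end of
#'   the binned window).
#' @return Percent in `[0, 100]`.
#' @export
occupancy <- function(series, cutoff = 3.5) {
  x <- .series_values(series)
  if (length(x) == 0) stop("cannot compute occupancy of an empty series")
  stopifnot(cutoff > 0)
  100 * sum(x <= cutoff) / length(x)
}

#' Ring-centroid distance series
#'
#' Per-frame distance between the unweighted centroids of two atom sets
#' (default), or the minimum over all inter-ring atom pairs.
#'
#' @param trajectory A `toy_trajectory`.
#' @param ring_a,ring_b Atom index vectors (>= 3 atoms each, disjoint); if
#'   omitted, looked up from the trajectory's ring-pair table via `pair_id`.
#' @param pair_id Ring-pair label.
#' @param method `"centroid"` or `"min_pair"`.
#' @return Numeric vector of distances (angstrom), one per frame.
#' @export
ring_centroid_series <- function(trajectory, ring_a = NULL, ring_b = NULL,
                                 pair_id = NULL,
                                 method = c("centroid", "min_pair")) {
  method <- match.arg(method)
  coords <- .traj_coords(trajectory)
  if (is.null(ring_a) || is.null(ring_b)) {
    if (is.null(pair_id)) stop("give ring atom indices or a pair_id")
    rp <- trajectory$ring_pairs[[pair_id]]
    if (is.null(rp)) stop("ring pair '", pair_id, "' not monitored")
    ring_a <- rp$a
    ring_b <- rp$b
  }
  if (length(ring_a) < 3 || length(ring_b) < 3) {
    stop("each ring needs at least 3 atoms")
  }
  if (length(intersect(ring_a, ring_b)) > 0) {
    stop("ring atom sets must be disjoint")
  }
  if (method == "centroid") {
    ca <- apply(coords[ring_a, , , drop = FALSE], c(2, 3), mean)
    cb <- apply(coords[ring_b, , , drop = FALSE], c(2, 3), mean)
    sqrt(colSums((ca - cb)^2))
  } else {
    vapply(seq_len(dim(coords)[3]), function(f) {
      a <- coords[ring_a, , f, drop = FALSE][, , 1]
      b <- coords[ring_b, , f, drop = FALSE][, , 1]
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
      sqrt(max(0, min(d2)))
    }, numeric(1))
  }
}

#' Fraction of frames at or below a distance threshold
#'
#' @param series Numeric distance series (angstrom).
#' @param threshold Threshold in angstrom (default 5.0, the conventional
#'   aromatic-stacking distance limit).
#' @return Fraction in `[0, 1]`.
#' @export
fraction_below <- function(series, threshold = 5.0) {
  x <- .series_values(series)
  if (length(x) == 0) stop("empty series")
  sum(x <= threshold) / length(x)
}

#' RMSD series relative to a reference frame
#'
#' Root-mean-square deviation of a selection, per frame, optionally after
#' optimal rigid-body (Kabsch) superposition onto the reference frame.
#'
#' @param trajectory A `toy_trajectory`.
#' @param reference_frame Index of the reference frame.
#' @param atom_selection Atom indices (default: all atoms).
#' @param superpose Remove rigid-body motion before measuring (needs >= 3
#'   atoms).
#' @return Numeric vector of RMSD values (angstrom), one per frame.
#' @export
rmsd_series <- function(trajectory, reference_frame = 1L,
                        atom_selection = NULL, superpose = TRUE) {
  coords <- .traj_coords(trajectory)
  n_atoms <- dim(coords)[1]
  nf <- dim(coords)[3]
  if (is.null(atom_selection)) atom_selection <- seq_len(n_atoms)
  if (length(atom_selection) == 0) stop("atom selection is empty")
  if (superpose && length(atom_selection) < 3) {
    stop("superposition needs at least 3 atoms")
  }
  stopifnot(reference_frame >= 1, reference_frame <= nf)
  ref <- matrix(coords[atom_selection, , reference_frame],
                ncol = 3)
  vapply(seq_len(nf), function(f) {
    cur <- matrix(coords[atom_selection, , f], ncol = 3)
    if (superpose) .kabsch_rmsd(ref, cur)
    else sqrt(mean(rowSums((cur - ref)^2)))
  }, numeric(1))
}

#' Conventional binding-power label for a hydrogen-bond length
#'
#' "Strong / medium / weak" vocabulary for report text.  The thresholds are
#' package conventions, not measured quantities, and are fully configurable.
#'
#' @param distance Hydrogen-bond length(s) in angstrom.
#' @param strong_below Upper bound of the "strong" label (angstrom).
#' @param medium_below Upper bound of the "medium" label (angstrom).
#' @return Character vector of labels.
#' @export
hbond_strength_label <- function(distance, strong_below = 2.0,
                                 medium_below = 2.6) {
  stopifnot(strong_below < medium_below)
  ifelse(distance < strong_below, "strong",
         ifelse(distance < medium_below, "medium", "weak"))
}

#' Assemble per-bond histograms into a frequency table
#'
#' One row per bond, columns are the bin centers plus the out-of-range count,
#' matching the layout of the published occupancy table (percent, 1 decimal).
#'
#' @param histograms List of [bin_hbond_series()] results.
#' @param digits Decimals for the percent columns.
#' @return A `data.frame`.
#' @export
hbond_frequency_table <- function(histograms, digits = 1) {
  stopifnot(length(histograms) > 0)
  centers <- histograms[[1]]$bin_centers
  rows <- lapply(histograms, function(h) {
    stopifnot(identical(h$bin_centers, centers))
    c(round(h$frequencies, digits),
      out_of_range = round(100 * h$n_out_of_range / h$n_frames_total,
                           digits))
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c(format(centers, nsmall = 3, trim = TRUE), "out_of_range")
  cbind(bond_id = vapply(histograms, function(h) as.character(h$bond_id),
                         character(1)),
        df, row.names = NULL)
}
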