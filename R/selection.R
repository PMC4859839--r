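# Representative-frame selection.
#
# Two criteria, mirroring the study design: (1) every monitored distance
# should fall in the most-represented (modal) interval of its simulation-time
# distribution, and (2) among such frames the total hydrogen-bond length
# should be smallest (shorter bonds ~ stronger binding).  Ring distances take
# part in the modal-membership criterion only; the minimized total runs over
# hydrogen bonds alone.  All ties break deterministically toward the lowest
# frame index.

#' Modal interval of a binned distribution
#'
#' The half-open interval of the maximal-frequency bin; ties break toward
#' the shorter-distance bin.
#'
#' @param histogram A [bin_hbond_series()] result.
#' @return Numeric `c(low, high)` in angstrom.
#' @export
modal_interval <- function(histogram) {
  stopifnot(inherits(histogram, "histogram_table"))
  if (all(histogram$frequencies == 0)) {
    stop("all-zero histogram: no modal interval (every frame out of range)")
  }
  k <- which.max(histogram$frequencies)  # first maximum = shortest distance
  c(histogram$bin_centers[k] - histogram$bin_width / 2,
    histogram$bin_centers[k] + histogram$bin_width / 2)
}

.in_interval <- function(x, interval) x >= interval[1] & x < interval[2]

#' Select the most representative trajectory frame
#'
#' Strict mode: among frames in which EVERY monitored distance lies in its
#' modal interval, pick the one minimizing the total hydrogen-bond length;
#' if no frame satisfies all modal intervals, fall back to lexicographic
#' mode.  Lexicographic mode: maximize the number of in-modal-interval
#' distances, then minimize the total length.  Remaining ties go to the
#' lowest frame index.
#'
#' @param hbond_series_list List of [hbond_series()] (>= 1).
#' @param ring_series Optional named list of numeric ring-distance series
#'   (same frame count); they join the membership criterion but not the
#'   minimized total.
#' @param mode `"strict"` or `"lexicographic"`.
#' @param hbond_binning,ring_binning Binning parameters (lists of arguments
#'   for [bin_hbond_series()]) used to locate the modal intervals.
#' @return An object of class `selection_report`: chosen frame, per-frame
#'   totals and membership counts, modal intervals, and the configuration.
#' @export
select_representative <- function(hbond_series_list, ring_series = NULL,
                                  mode = c("strict", "lexicographic"),
                                  hbond_binning = list(),
                                  ring_binning = list(bin_width = 0.25,
                                                      first_center = 3.125,
                                                      n_bins = 16L)) {
  mode <- match.arg(mode)
  if (inherits(hbond_series_list, "hbond_series")) {
    hbond_series_list <- list(hbond_series_list)
  }
  if (length(hbond_series_list) == 0) {
    stop("at least one monitored hydrogen-bond series is required")
  }
  hmat <- vapply(hbond_series_list, .series_values,
                 numeric(length(.series_values(hbond_series_list[[1]]))))
  hmat <- matrix(hmat, ncol = length(hbond_series_list))
  nf <- nrow(hmat)
  if (nf == 0) stop("empty trajectory")
  rmat <- NULL
  if (!is.null(ring_series) && length(ring_series) > 0) {
    rmat <- vapply(ring_series, .series_values, numeric(nf))
    rmat <- matrix(rmat, ncol = length(ring_series))
  }

  intervals_h <- apply(hmat, 2, function(x) {
    modal_interval(do.call(bin_hbond_series, c(list(x), hbond_binning)))
  })
  member <- sapply(seq_len(ncol(hmat)), function(k) {
    .in_interval(hmat[, k], intervals_h[, k])
  })
  member <- matrix(member, nrow = nf)
  intervals_r <- NULL
  if (!is.null(rmat)) {
    intervals_r <- apply(rmat, 2, function(x) {
      modal_interval(do.call(bin_hbond_series, c(list(x), ring_binning)))
    })
    member_r <- sapply(seq_len(ncol(rmat)), function(k) {
      .in_interval(rmat[, k], intervals_r[, k])
    })
    member <- cbind(member, matrix(member_r, nrow = nf))
  }

  totals <- rowSums(hmat)
  counts <- rowSums(member)
  n_monitored <- ncol(member)
  strict_set <- which(counts == n_monitored)

  mode_used <- mode
  if (mode == "strict" && length(strict_set) > 0) {
    cand <- strict_set
  } else {
    mode_used <- "lexicographic"
    cand <- which(counts == max(counts))
  }
  chosen <- cand[order(totals[cand], cand)][1]

  structure(list(
    chosen_frame = chosen,
    mode_requested = mode,
    mode_used = mode_used,
    total_hbond_length = totals,
    modal_membership_count = counts,
    n_monitored = n_monitored,
    strict_set_size = length(strict_set),
    modal_intervals_hbond = intervals_h,
    modal_intervals_ring = intervals_r,
    criteria_config = list(hbond_binning = hbond_binning,
                           ring_binning = ring_binning)),
    class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf(paste0("<selection_report> frame %d (%s mode; %d/%d criteria ",
                     "frames in strict set)\n"),
              x$chosen_frame, x$mode_used, x$strict_set_size,
              length(x$total_hbond_length)))
  cat(sprintf("  total H-bond length at chosen frame: %.3f angstrom\n",
              x$total_hbond_length[x$chosen_frame]))
  cat(sprintf("  modal membership: %d of %d monitored distances\n",
              x$modal_membership_count[x$chosen_frame], x$n_monitored))
  invisible(x)
}

#' Write a selection report to JSON
#'
#' @param report A [select_representative()] result.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_selection_report <- function(report, path) {
  stopifnot(inherits(report, "selection_report"))
  out <- report
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
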