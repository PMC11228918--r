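#' Angle-distance free-energy landscape of ring stacking
#'
#' For every pair of solute molecules carrying a 6-atom ring and every
#' frame, computes the minimum-image distance between ring centroids and the
#' angle between the ring-plane normals (least-squares plane through the six
#' ring atoms; the normal's sign is indeterminate, so the angle spreads over
#' [0, 180] degrees and parallel stacking shows up near both 0 and 180).
#' The 2-D histogram is converted to a free energy
#' F = -kB T ln(P / Pmax) in kJ/mol, zero at the modal bin; empty bins carry
#' +Inf (masked), never zero.
#'
#' @param trajectory An `md_trajectory`.
#' @param topo A [topology()] whose solute molecules have `ring_pos` 1-6.
#' @param temperature Absolute temperature, K (default 298.15).
#' @param angle_bin Angle bin width, degrees (default 5; grid 0-180).
#' @param dist_bin Distance bin width, nm (default 0.01).
#' @param max_dist Largest centroid distance binned, nm (default 1.5);
#'   farther pairs are not counted.
#' @return An object of class `stacking_landscape`: `angle_mid`, `dist_mid`
#'   (bin centers), `F` (matrix angle x distance, kJ/mol), `counts`,
#'   `n_skipped` (degenerate ring geometries skipped, with a warning if
#'   any).
#' @export
stacking_landscape <- function(trajectory, topo, temperature = 298.15,
                               angle_bin = 5, dist_bin = 0.01,
                               max_dist = 1.5) {
  stopifnot(inherits(topo, "topology"))
  at <- topo$atoms
  ring_mols <- sort(unique(at$molecule_id[at$ring_pos > 0 &
                                            at$molecule_type == "solute"]))
  if (length(ring_mols) < 2)
    stop("need at least two solute molecules with ring atoms", call. = FALSE)
  if (length(trajectory) < 1) stop("need at least one frame", call. = FALSE)
  ring_idx <- lapply(ring_mols, function(m) {
    i <- which(at$molecule_id == m & at$ring_pos > 0)
    i[order(at$ring_pos[i])]
  })
  na_bins <- ceiling(180 / angle_bin)
  nd_bins <- ceiling(max_dist / dist_bin)
  counts <- matrix(0, na_bins, nd_bins)
  n_skipped <- 0L
  pairs <- utils::combn(seq_along(ring_mols), 2)
  for (f in trajectory) {
    cent <- matrix(NA_real_, length(ring_mols), 3)
    norm <- matrix(NA_real_, length(ring_mols), 3)
    ok <- logical(length(ring_mols))
    for (i in seq_along(ring_mols)) {
      xyz <- f$coords[ring_idx[[i]], , drop = FALSE]
      disp <- min_image_displacement(sweep(xyz, 2, xyz[1, ]), f$box)
      cen_local <- colMeans(disp)
      cent[i, ] <- xyz[1, ] + cen_local
      sv <- svd(sweep(disp, 2, cen_local))
      if (sv$d[2] < 1e-8) { ok[i] <- FALSE; next }  # collinear ring atoms
      norm[i, ] <- sv$v[, 3]
      ok[i] <- TRUE
    }
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      if (!ok[i] || !ok[j]) { n_skipped <- n_skipped + 1L; next }
      d <- min_image_distance(cent[i, ], cent[j, ], f$box)
      if (d >= max_dist) next
      ct <- sum(norm[i, ] * norm[j, ])
      ang <- acos(max(-1, min(1, ct))) * 180 / pi
      ai <- min(floor(ang / angle_bin) + 1L, na_bins)
      di <- min(floor(d / dist_bin) + 1L, nd_bins)
      counts[ai, di] <- counts[ai, di] + 1
    }
  }
  if (n_skipped > 0)
    warning(n_skipped, " ring pair(s) skipped (degenerate ring geometry)",
            call. = FALSE)
  if (max(counts) == 0)
    stop("no ring pairs fell inside the landscape grid", call. = FALSE)
  kt <- prenuc_constants$kB_kJ_mol * temperature
  F <- -kt * log(counts / max(counts))   # empty bins -> +Inf
  structure(list(
    angle_mid = (seq_len(na_bins) - 0.5) * angle_bin,
    dist_mid = (seq_len(nd_bins) - 0.5) * dist_bin,
    F = F, counts = counts, n_skipped = n_skipped,
    temperature = temperature),
    class = "stacking_landscape")
}
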