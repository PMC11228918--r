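#' Geometric hydrogen-bond criteria
#'
#' @param da_cutoff Donor-acceptor distance cutoff, nm (default 0.35,
#'   inclusive).
#' @param hda_angle_max Maximum hydrogen-donor-acceptor angle, degrees
#'   (default 30, inclusive): the angle at the donor between the donor-to-H
#'   and donor-to-acceptor vectors.
#' @param mode Lifetime definition used downstream: "continuous" survival or
#'   "intermittent" autocorrelation.
#' @return An object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(da_cutoff = 0.35, hda_angle_max = 30,
                           mode = c("continuous", "intermittent")) {
  if (!is.numeric(da_cutoff) || da_cutoff <= 0)
    stop("da_cutoff must be positive", call. = FALSE)
  if (!is.numeric(hda_angle_max) || hda_angle_max <= 0 || hda_angle_max > 90)
    stop("hda_angle_max must lie in (0, 90] degrees", call. = FALSE)
  structure(list(da_cutoff = da_cutoff, hda_angle_max = hda_angle_max,
                 mode = match.arg(mode)),
            class = "hbond_criteria")
}

#' Detect hydrogen-bond events along a trajectory
#'
#' A bond between a flagged donor hydrogen (with its donor heavy atom) and a
#' flagged acceptor on a different molecule is present in a frame when the
#' donor-acceptor minimum-image distance is at most `da_cutoff` and the
#' hydrogen-donor-acceptor angle (vertex at the donor) is at most
#' `hda_angle_max`. Both cutoffs are inclusive, so the stated criteria are
#' reproducible bit for bit.
#'
#' @param trajectory An `md_trajectory`.
#' @param topo A [topology()] with donor/acceptor/hydrogen role flags.
#' @param criteria An [hbond_criteria()].
#' @param solute_only If TRUE (default) restrict both partners to solute
#'   molecules.
#' @return An object of class `hbond_events`: `pairs` (data.frame with
#'   0-based atom ids `hydrogen`, `donor`, `acceptor` and molecule ids),
#'   `present` (logical matrix, pairs x frames) and `times` (ps).
#' @export
hbond_events <- function(trajectory, topo, criteria = hbond_criteria(),
                         solute_only = TRUE) {
  stopifnot(inherits(topo, "topology"), inherits(criteria, "hbond_criteria"))
  at <- topo$atoms
  hsel <- at$is_donor_h
  asel <- at$is_acceptor
  if (solute_only) {
    hsel <- hsel & at$molecule_type == "solute"
    asel <- asel & at$molecule_type == "solute"
  }
  h_idx <- which(hsel); a_idx <- which(asel)
  if (!length(h_idx) || !length(a_idx))
    stop("topology flags no donor hydrogens or no acceptors", call. = FALSE)
  d_idx <- at$donor_of[h_idx] + 1L
  grid <- expand.grid(h = seq_along(h_idx), a = seq_along(a_idx))
  keep <- at$molecule_id[h_idx[grid$h]] != at$molecule_id[a_idx[grid$a]]
  grid <- grid[keep, , drop = FALSE]
  pairs <- data.frame(
    hydrogen = at$atom_id[h_idx[grid$h]],
    donor = at$atom_id[d_idx[grid$h]],
    acceptor = at$atom_id[a_idx[grid$a]],
    donor_mol = at$molecule_id[h_idx[grid$h]],
    acceptor_mol = at$molecule_id[a_idx[grid$a]])
  cosmax <- cos(criteria$hda_angle_max * pi / 180)
  present <- matrix(FALSE, nrow(pairs), length(trajectory))
  for (k in seq_along(trajectory)) {
    f <- trajectory[[k]]
    D <- f$coords[pairs$donor + 1L, , drop = FALSE]
    H <- f$coords[pairs$hydrogen + 1L, , drop = FALSE]
    A <- f$coords[pairs$acceptor + 1L, , drop = FALSE]
    dh <- min_image_displacement(H - D, f$box)
    da <- min_image_displacement(A - D, f$box)
    r_da <- sqrt(rowSums(da^2))
    cosang <- rowSums(dh * da) / (sqrt(rowSums(dh^2)) * r_da)
    # inclusive boundaries with a float guard so the stated criteria are
    # reproducible exactly (1e-12 nm is far below any physical scale)
    present[, k] <- r_da <= criteria$da_cutoff + 1e-12 &
      cosang >= cosmax - 1e-12
  }
  structure(list(pairs = pairs, present = present,
                 times = vapply(trajectory, function(f) f$time, numeric(1))),
            class = "hbond_events")
}

#' Hydrogen-bond lifetime curve P(t)
#'
#' Continuous mode: the survival probability that a bond present at an
#' origin frame remains present at every intermediate frame through lag t,
#' averaged over bonds and time origins. Intermittent mode: the normalized
#' presence autocorrelation <h(t0) h(t0+t)> / <h>, which permits breaking
#' and reforming. Both start at P(0) = 1; continuous P(t) never exceeds
#' intermittent P(t). Lag times are reported on the frame-interval grid
#' using the mean frame spacing.
#'
#' @param events An [hbond_events()] object, or a plain logical matrix
#'   (bonds x frames) with an optional `times` attribute.
#' @param mode "continuous" (default) or "intermittent".
#' @return A data.frame with columns `time_ps` and `P`; zero rows (flagged
#'   with attribute `empty = TRUE`) if no bond is ever present.
#' @export
hbond_lifetime <- function(events, mode = c("continuous", "intermittent")) {
  mode <- match.arg(mode)
  if (inherits(events, "hbond_events")) {
    h <- events$present; times <- events$times
  } else {
    h <- as.matrix(events)
    times <- attr(events, "times")
    if (is.null(times)) times <- seq_len(ncol(h)) - 1
  }
  storage.mode(h) <- "logical"
  nfr <- ncol(h)
  if (nfr < 2) stop("need at least 2 frames", call. = FALSE)
  if (!any(h)) {
    out <- data.frame(time_ps = numeric(0), P = numeric(0))
    attr(out, "empty") <- TRUE
    return(out)
  }
  dt <- mean(diff(times))
  lags <- 0:(nfr - 1)
  num <- numeric(nfr); den <- numeric(nfr)
  if (mode == "continuous") {
    # run-length decomposition: a run of L consecutive TRUE frames supplies
    # max(L - k, 0) surviving origins at lag k
    for (b in seq_len(nrow(h))) {
      r <- rle(h[b, ])
      lens <- r$lengths[r$values]
      for (L in lens) {
        k <- 0:(L - 1)
        num[k + 1] <- num[k + 1] + (L - k)
      }
    }
    tot <- colSums(matrix(h, nrow = nrow(h)))
    # valid origins for lag k: frames 1 .. nfr-k
    cs <- cumsum(tot)
    den <- cs[nfr - lags]
  } else {
    for (k in lags) {
      i <- seq_len(nfr - k)
      num[k + 1] <- sum(h[, i, drop = FALSE] & h[, i + k, drop = FALSE])
      den[k + 1] <- sum(h[, i, drop = FALSE])
    }
  }
  P <- ifelse(den > 0, num / den, NA_real_)
  out <- data.frame(time_ps = lags * dt, P = P)
  attr(out, "empty") <- FALSE
  out
}
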