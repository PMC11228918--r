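#' Center-of-mass radial distribution function
#'
#' g(r) between the mass-weighted molecular centers of two groups of
#' molecules, averaged over frames. Distances use the minimum-image
#' convention; counts are normalized by the spherical-shell volume, the
#' number of frames, the number of reference (group A) molecules and the
#' mean number density of group B, so an ideal uniform system gives
#' g(r) = 1 at all r.
#'
#' @param trajectory An `md_trajectory`.
#' @param topo A [topology()].
#' @param group_a,group_b Either a molecule-type label ("solute"/"solvent")
#'   or an integer vector of molecule ids.
#' @param r_max Histogram range, nm (default 3). Must not exceed half the
#'   smallest box edge in any frame; violation is an error, never a silent
#'   truncation.
#' @param bin_width Bin width, nm (default 0.02).
#' @return An object of class `rdf_result`: data.frame `table` with columns
#'   `r` (bin centers) and `g`, plus `bin_width`, `r_max`, `density`
#'   (mean reference density of group B, 1/nm^3) and `n_pairs` (total pair
#'   distances counted, including those beyond `r_max`).
#' @export
rdf <- function(trajectory, topo, group_a = "solute", group_b = "solute",
                r_max = 3, bin_width = 0.02) {
  stopifnot(inherits(topo, "topology"))
  resolve <- function(g) {
    if (is.character(g))
      sort(unique(topo$atoms$molecule_id[topo$atoms$molecule_type == g]))
    else as.integer(g)
  }
  a_ids <- resolve(group_a); b_ids <- resolve(group_b)
  if (!length(a_ids) || !length(b_ids))
    stop("empty molecule group", call. = FALSE)
  same <- identical(a_ids, b_ids)
  nbin <- ceiling(r_max / bin_width)
  counts <- numeric(nbin)
  dens_sum <- 0; n_pairs_total <- 0
  for (f in trajectory) {
    if (r_max > min(f$box) / 2)
      stop("r_max (", r_max, " nm) exceeds half the smallest box edge (",
           min(f$box) / 2, " nm)", call. = FALSE)
    com_a <- molecule_com(f, topo, a_ids)
    com_b <- if (same) com_a else molecule_com(f, topo, b_ids)
    D <- pairwise_min_image(com_a, com_b, f$box)
    if (same) diag(D) <- Inf
    d <- as.vector(D)
    n_pairs_total <- n_pairs_total + sum(is.finite(d))
    d <- d[d < r_max]
    if (length(d))
      counts <- counts + tabulate(pmin(floor(d / bin_width) + 1L, nbin), nbin)
    v <- prod(f$box)
    dens_sum <- dens_sum + (length(b_ids) - same) / v
  }
  nf <- length(trajectory)
  rho <- dens_sum / nf
  edges <- seq(0, by = bin_width, length.out = nbin + 1)
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nbin + 1)]^3)
  g <- counts / (nf * length(a_ids) * rho * shell)
  structure(list(table = data.frame(r = (edges[-1] + edges[-(nbin + 1)]) / 2,
                                    g = g),
                 bin_width = bin_width, r_max = r_max,
                 density = rho, n_pairs = n_pairs_total,
                 counts = counts),
            class = "rdf_result")
}
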