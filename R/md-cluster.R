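#' Distance-cutoff clustering criteria
#'
#' @param cutoff Linkage distance, nm (default 0.35, i.e. 3.5 Angstrom).
#' @param linkage Which inter-molecular distance defines a contact:
#'   `"heavy"` (minimum over heavy-atom pairs, the default), `"any"`
#'   (minimum over all atom pairs) or `"com"` (center-of-mass distance).
#' @param min_size Smallest cluster size reported (default 1: singletons
#'   count as clusters).
#' @return An object of class `cluster_criteria`.
#' @export
cluster_criteria <- function(cutoff = 0.35,
                             linkage = c("heavy", "any", "com"),
                             min_size = 1) {
  if (!is.numeric(cutoff) || cutoff <= 0)
    stop("cutoff must be positive (nm)", call. = FALSE)
  structure(list(cutoff = cutoff, linkage = match.arg(linkage),
                 min_size = min_size),
            class = "cluster_criteria")
}

# Solute-molecule adjacency matrix under the criteria for one frame.
solute_adjacency <- function(frame, topo, criteria) {
  at <- topo$atoms
  sol_mols <- sort(unique(at$molecule_id[at$molecule_type == "solute"]))
  n <- length(sol_mols)
  if (n == 0) stop("no solute molecules in topology", call. = FALSE)
  if (criteria$linkage == "com") {
    com <- molecule_com(frame, topo, sol_mols)
    D <- pairwise_min_image(com, com, frame$box)
    adj <- D <= criteria$cutoff
  } else {
    keep <- at$molecule_type == "solute"
    if (criteria$linkage == "heavy") keep <- keep & at$element != "H"
    idx <- which(keep)
    xyz <- frame$coords[idx, , drop = FALSE]
    mol_of <- match(at$molecule_id[idx], sol_mols)
    D <- pairwise_min_image(xyz, xyz, frame$box)
    A <- D <= criteria$cutoff
    S <- matrix(0, length(idx), n)
    S[cbind(seq_along(idx), mol_of)] <- 1
    adj <- (t(S) %*% A %*% S) > 0
  }
  diag(adj) <- TRUE
  dimnames(adj) <- list(sol_mols, sol_mols)
  adj
}

#' Single-linkage clustering of solute molecules in one frame
#'
#' Two solute molecules are connected when their linkage distance (minimum
#' over heavy-atom pairs by default) under the minimum-image convention is at
#' most the cutoff (inclusive); clusters are the connected components of that
#' contact graph. Cluster labels are deterministic: each cluster is labeled
#' by its smallest member molecule id.
#'
#' @param frame One frame of an `md_trajectory`.
#' @param topo A [topology()].
#' @param criteria A [cluster_criteria()].
#' @return A list with `membership` (named integer vector: cluster label per
#'   solute molecule id), `sizes` (named integer vector per cluster label)
#'   and `n_clusters` (clusters with size >= `min_size`).
#' @export
cluster_frame <- function(frame, topo, criteria = cluster_criteria()) {
  stopifnot(inherits(topo, "topology"), inherits(criteria, "cluster_criteria"))
  adj <- solute_adjacency(frame, topo, criteria)
  sol_mols <- as.integer(rownames(adj))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # relabel each component by its smallest member molecule id
  lab <- vapply(split(sol_mols, comp), min, integer(1))
  membership <- lab[comp]
  names(membership) <- sol_mols
  sizes <- table(membership)
  sizes <- stats::setNames(as.integer(sizes), names(sizes))
  list(membership = membership,
       sizes = sizes,
       n_clusters = sum(sizes >= criteria$min_size))
}

#' Cluster-count time series with a second-order fit
#'
#' Counts clusters per frame via [cluster_frame()] and fits a degree-2
#' polynomial in time to the counts (the conventional smooth summary of
#' early-stage cluster coalescence). With fewer than 3 frames the fit is
#' skipped and flagged.
#'
#' @param trajectory An `md_trajectory`.
#' @param topo A [topology()].
#' @param criteria A [cluster_criteria()].
#' @return A list with `series` (data.frame `time_ps`, `n_clusters`),
#'   `fit` (named coefficients c0, c1, c2 of c0 + c1 t + c2 t^2, or NULL)
#'   and `fitted` (logical).
#' @export
cluster_count_series <- function(trajectory, topo,
                                 criteria = cluster_criteria()) {
  counts <- vapply(trajectory, function(f)
    cluster_frame(f, topo, criteria)$n_clusters, numeric(1))
  times <- vapply(trajectory, function(f) f$time, numeric(1))
  series <- data.frame(time_ps = times, n_clusters = counts)
  if (length(trajectory) < 3)
    return(list(series = series, fit = NULL, fitted = FALSE))
  cf <- stats::lm(n_clusters ~ time_ps + I(time_ps^2), data = series)
  list(series = series,
       fit = stats::setNames(as.numeric(stats::coef(cf)),
                             c("c0", "c1", "c2")),
       fitted = TRUE)
}
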