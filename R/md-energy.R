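#' Pairwise nonbonded interaction energy between two molecule groups
#'
#' Sum over inter-group atom pairs within the cutoff of the Coulomb term
#' f q_i q_j / r (f = 138.935458 kJ nm / (mol e^2)) and the Lennard-Jones
#' term 4 eps_ij [(sig_ij/r)^12 - (sig_ij/r)^6] with Lorentz-Berthelot
#' combination (arithmetic sigma, geometric epsilon), under the
#' minimum-image convention, normalized per molecule of group A. Plain
#' cutoff electrostatics; no Ewald summation.
#'
#' @param frame One frame of an `md_trajectory`.
#' @param topo A [topology()] with charges and LJ parameters.
#' @param group_a,group_b Molecule-type label ("solute"/"solvent") or
#'   integer molecule ids. Intra-molecular pairs are always excluded.
#' @param cutoff Pair distance cutoff, nm (default 1.2, inclusive).
#' @return Energy in kJ/mol per group-A molecule.
#' @export
pair_interaction_energy <- function(frame, topo, group_a = "solute",
                                    group_b = "solvent", cutoff = 1.2) {
  stopifnot(inherits(topo, "topology"))
  at <- topo$atoms
  resolve <- function(g) {
    if (is.character(g)) which(at$molecule_type == g)
    else which(at$molecule_id %in% g)
  }
  ia <- resolve(group_a); ib <- resolve(group_b)
  if (!length(ia) || !length(ib)) stop("empty atom group", call. = FALSE)
  bad <- union(ia, ib)
  bad <- bad[!is.finite(at$charge[bad]) | !is.finite(at$lj_epsilon[bad]) |
               !is.finite(at$lj_sigma[bad])]
  if (length(bad))
    stop("missing charge/LJ parameters for atom id(s): ",
         paste(at$atom_id[bad], collapse = ", "), call. = FALSE)
  D <- pairwise_min_image(frame$coords[ia, , drop = FALSE],
                          frame$coords[ib, , drop = FALSE], frame$box)
  samemol <- outer(at$molecule_id[ia], at$molecule_id[ib], "==")
  overlap <- intersect(ia, ib)
  half <- length(overlap) > 0   # symmetric overlap double counts pairs
  mask <- D <= cutoff & !samemol
  if (half) {
    # for atoms present in both groups, keep each unordered pair once
    both <- outer(ia %in% overlap, ib %in% overlap, "&")
    idmat <- outer(ia, ib, ">=")
    mask <- mask & !(both & idmat)
  }
  if (!any(mask)) return(0)
  r <- D[mask]
  qa <- matrix(at$charge[ia], length(ia), length(ib))[mask]
  qb <- matrix(at$charge[ib], length(ia), length(ib), byrow = TRUE)[mask]
  ea <- matrix(at$lj_epsilon[ia], length(ia), length(ib))[mask]
  eb <- matrix(at$lj_epsilon[ib], length(ia), length(ib), byrow = TRUE)[mask]
  sa <- matrix(at$lj_sigma[ia], length(ia), length(ib))[mask]
  sb <- matrix(at$lj_sigma[ib], length(ia), length(ib), byrow = TRUE)[mask]
  eps <- sqrt(ea * eb)
  sig <- (sa + sb) / 2
  sr6 <- (sig / r)^6
  e <- sum(prenuc_constants$f_coulomb * qa * qb / r) +
    sum(4 * eps * (sr6^2 - sr6))
  n_a <- length(unique(at$molecule_id[ia]))
  e / n_a
}
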