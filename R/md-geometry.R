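#' Minimum-image displacement
#'
#' Wraps a displacement (or matrix of displacements, one per row) into the
#' primary periodic image of an orthorhombic box.
#'
#' @param d Numeric length-3 vector or n x 3 matrix of raw displacements, nm.
#' @param box Orthorhombic box edges, nm (length 3).
#' @return Same shape as `d`, minimum-image convention applied.
#' @export
min_image_displacement <- function(d, box) {
  if (is.matrix(d)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    d
  } else {
    d - box * round(d / box)
  }
}

#' Minimum-image distance between two points
#'
#' @param a,b Length-3 coordinate vectors, nm.
#' @param box Orthorhombic box edges, nm.
#' @return Euclidean distance under the minimum-image convention, nm.
#' @export
min_image_distance <- function(a, b, box) {
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0))
    stop("box must be three positive edge lengths", call. = FALSE)
  sqrt(sum(min_image_displacement(as.numeric(a) - as.numeric(b), box)^2))
}

# All minimum-image distances between rows of A (na x 3) and rows of B
# (nb x 3); returns na x nb matrix. Memory ~ 3 * na * nb doubles.
pairwise_min_image <- function(A, B, box) {
  d2 <- 0
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

# Mass-weighted molecular centers of mass with minimum-image unwrapping:
# each atom is taken in the image closest to the molecule's first atom, so
# molecules straddling the boundary get a physical COM. Returns an
# n_molecules x 3 matrix; rows follow molecule id order. `which_mols`
# restricts to a subset of molecule ids.
molecule_com <- function(frame, topo, which_mols = NULL) {
  at <- topo$atoms
  mols <- if (is.null(which_mols)) seq_len(topo$n_molecules) else which_mols
  out <- matrix(NA_real_, length(mols), 3)
  for (i in seq_along(mols)) {
    idx <- which(at$molecule_id == mols[i])
    xyz <- frame$coords[idx, , drop = FALSE]
    ref <- xyz[1, ]
    disp <- sweep(xyz, 2, ref)
    disp <- min_image_displacement(disp, frame$box)
    m <- at$mass[idx]
    out[i, ] <- ref + colSums(disp * m) / sum(m)
  }
  out
}
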