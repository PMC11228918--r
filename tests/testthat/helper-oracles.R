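# Independent brute-force oracles and small fixture builders. Everything here
# deliberately avoids the package's vectorized code paths: distances by
# explicit image enumeration, clustering by transitive closure, energies by a
# double loop.

make_frame <- function(coords, box, time = 0) {
  list(time = time, box = rep(box, length.out = 3), coords = as.matrix(coords))
}

# topology of n single-site molecules (unit mass, no charge/LJ unless given)
point_topology <- function(n, charge = 0, eps = 0, sigma = 0.3,
                           type = "solute", mass = 1) {
  topology(data.frame(
    atom_id = seq_len(n) - 1L, element = "X", mass = mass,
    charge = rep_len(charge, n), lj_epsilon = rep_len(eps, n),
    lj_sigma = rep_len(sigma, n),
    molecule_id = seq_len(n), molecule_type = rep_len(type, n)))
}

# minimum-image distance by enumerating all 27 periodic images
bf_min_image <- function(a, b, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- a - (b + c(i, j, k) * box)
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# single-linkage partition of point molecules by transitive closure
bf_clusters <- function(coords, box, cutoff) {
  n <- nrow(coords)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- bf_min_image(coords[i, ], coords[j, ], box) <= cutoff
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0 | reach
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  # label each molecule by the smallest index it can reach
  apply(reach, 1, function(row) min(which(row)))
}

# nonbonded energy between atom index sets by a plain double loop
bf_pair_energy <- function(coords, box, atoms, ia, ib, cutoff,
                           f = 138.935458) {
  e <- 0
  seen <- character(0)
  for (i in ia) for (j in ib) {
    if (atoms$molecule_id[i] == atoms$molecule_id[j]) next
    key <- paste(sort(c(i, j)), collapse = "-")
    if (i %in% ib && j %in% ia) {       # overlapping groups: count pair once
      if (key %in% seen) next
      seen <- c(seen, key)
    }
    r <- bf_min_image(coords[i, ], coords[j, ], box)
    if (r > cutoff) next
    e <- e + f * atoms$charge[i] * atoms$charge[j] / r
    eps <- sqrt(atoms$lj_epsilon[i] * atoms$lj_epsilon[j])
    sig <- (atoms$lj_sigma[i] + atoms$lj_sigma[j]) / 2
    e <- e + 4 * eps * ((sig / r)^12 - (sig / r)^6)
  }
  e
}

# canonical form of a partition for label-free comparison
partition_key <- function(membership) {
  groups <- split(seq_along(membership), membership)
  paste(sort(vapply(groups, function(g) paste(sort(g), collapse = ","),
                    character(1))), collapse = "|")
}
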