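#' Rigid 12-atom salicylamide-like molecular template
#'
#' A planar synthetic molecule exercising every topology feature the
#' trajectory analyses need: a 6-carbon aromatic ring (for plane fitting and
#' stacking), an amide group with carbonyl oxygen acceptor and N-H donor,
#' and a phenolic O-H donor/acceptor. Charges and Lennard-Jones parameters
#' are plausible synthetic values (net charge zero), not a force field.
#'
#' @return A list with `coords` (12 x 3 matrix, nm, molecule-local frame)
#'   and `atoms` (data.frame of element, mass, charge, lj_epsilon, lj_sigma,
#'   ring_pos, is_donor, is_acceptor, is_donor_h, donor_of_local).
#' @export
salicylamide_template <- function() {
  ang <- (0:5) * pi / 3
  ring <- cbind(0.139 * cos(ang), 0.139 * sin(ang), 0)
  coords <- rbind(
    ring,                                  # C1..C6 (C1 at +x, C2 at 60 deg)
    c(0.289, 0.000, 0),                    # C7 amide carbon on C1
    c(0.349, 0.105, 0),                    # O8 carbonyl oxygen
    c(0.359, -0.120, 0),                   # N9 amide nitrogen
    c(0.454, -0.150, 0),                   # H10 amide hydrogen
    c(0.1375, 0.2381, 0),                  # O11 phenolic oxygen on C2
    c(0.190, 0.310, 0)                     # H12 phenolic hydrogen
  )
  atoms <- data.frame(
    element = c(rep("C", 6), "C", "O", "N", "H", "O", "H"),
    mass = c(rep(12.011, 6), 12.011, 15.999, 14.007, 1.008, 15.999, 1.008),
    charge = c(0.2, rep(0, 5), 0.5, -0.5, -0.4, 0.3, -0.4, 0.3),
    lj_epsilon = c(rep(0.36, 6), 0.36, 0.65, 0.71, 0.0657, 0.65, 0.0657),
    lj_sigma = c(rep(0.34, 6), 0.34, 0.30, 0.33, 0.10, 0.30, 0.10),
    ring_pos = c(1:6, rep(0L, 6)),
    is_donor = c(rep(FALSE, 8), TRUE, FALSE, TRUE, FALSE),
    is_acceptor = c(rep(FALSE, 7), TRUE, FALSE, FALSE, TRUE, FALSE),
    is_donor_h = c(rep(FALSE, 9), TRUE, FALSE, TRUE),
    donor_of_local = c(rep(NA_integer_, 9), 9L, NA_integer_, 11L)
  )
  list(coords = coords, atoms = atoms)
}

random_rotation <- function() {
  # uniform random rotation via QR of a Gaussian matrix, det forced to +1
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a periodic-box configuration with a planted cluster partition
#'
#' Solute molecules are laid out as rigid chains (one chain per planted
#' cluster, common orientation within a chain, nearest-neighbour spacing
#' below the clustering cutoff) whose centers are rejection-sampled so that
#' inter-cluster atom distances exceed cutoff + margin under the
#' minimum-image convention. The planted partition is therefore exactly the
#' single-linkage partition at the stated cutoff. Optional single-site
#' solvent atoms fill the box uniformly without overlap, and an optional
#' merge schedule emits a multi-frame trajectory in which listed clusters
#' coalesce at scripted frames.
#'
#' @param box Orthorhombic box edges, nm (length 3 or scalar).
#' @param cluster_sizes Integer vector: planted cluster sizes (sums to the
#'   number of solute molecules).
#' @param spacing Intra-chain nearest-neighbour spacing, nm; must be below
#'   `cutoff` (default 0.30).
#' @param cutoff Clustering cutoff the plant is built against, nm (default
#'   0.35).
#' @param margin Extra inter-cluster clearance beyond the cutoff, nm
#'   (default 0.30).
#' @param n_solvent Number of single-site solvent molecules (default 0).
#' @param n_frames Number of frames (default 1); frame times are
#'   `(0:(n_frames-1)) * dt_ps`.
#' @param dt_ps Frame interval, ps (default 20).
#' @param merge_schedule Optional data.frame with columns `frame`, `from`,
#'   `to` (1-based frame index and planted-cluster indices): from the given
#'   frame on, cluster `from` is appended to cluster `to`'s chain.
#' @param seed Integer RNG seed.
#' @param max_tries Rejection-sampling attempts per placement before
#'   declaring the packing infeasible (default 2000).
#' @return A list with `topology`, `trajectory` (class `md_trajectory`) and
#'   `truth` (planted sizes, membership, schedule, seed).
#' @export
gen_planted_config <- function(box = 8, cluster_sizes = c(5, 3, 1),
                               spacing = 0.30, cutoff = 0.35, margin = 0.30,
                               n_solvent = 0, n_frames = 1, dt_ps = 20,
                               merge_schedule = NULL, seed = 1,
                               max_tries = 2000) {
  if (length(box) == 1) box <- rep(box, 3)
  stopifnot(all(box > 0), all(cluster_sizes >= 1), spacing < cutoff,
            margin > 0, n_frames >= 1)
  set.seed(seed)
  tmpl <- salicylamide_template()
  r_tmpl <- max(sqrt(rowSums(tmpl$coords^2)))
  n_clusters <- length(cluster_sizes)
  n_solute <- sum(cluster_sizes)
  # conservative chain extent: if merges happen, a chain can grow to all
  # solute molecules
  max_chain <- if (is.null(merge_schedule)) max(cluster_sizes) else n_solute
  ext <- (max_chain - 1) * spacing / 2 + r_tmpl
  if (2 * (2 * ext + cutoff + margin) > min(box))
    stop("infeasible packing: box too small for the planted clusters",
         call. = FALSE)
  # cluster centers by rejection sampling (minimum-image separation)
  centers <- matrix(NA_real_, n_clusters, 3)
  for (c in seq_len(n_clusters)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- stats::runif(3) * box
      if (c == 1 || all(apply(centers[seq_len(c - 1), , drop = FALSE], 1,
                              function(p) min_image_distance(p, cand, box)) >=
                        2 * ext + cutoff + margin)) {
        centers[c, ] <- cand; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("infeasible packing: could not place cluster ", c,
           " after ", max_tries, " tries", call. = FALSE)
  }
  orients <- lapply(seq_len(n_clusters), function(i) random_rotation())
  dirs <- lapply(seq_len(n_clusters), function(i) {
    u <- stats::rnorm(3); u / sqrt(sum(u^2))
  })
  # membership plan: molecules numbered cluster by cluster
  membership0 <- rep(seq_len(n_clusters), cluster_sizes)

  render_chain <- function(mol_ids, c_idx) {
    # positions along cluster c_idx's direction, centered on its center
    k <- length(mol_ids)
    offs <- (seq_len(k) - (k + 1) / 2) * spacing
    lapply(seq_len(k), function(j) {
      pos <- centers[c_idx, ] + offs[j] * dirs[[c_idx]]
      sweep(tmpl$coords %*% t(orients[[c_idx]]), 2, pos, "+")
    })
  }

  solvent_pos <- NULL
  if (n_solvent > 0) {
    # place against frame-1 solute coordinates only (solvent is static)
    coords1 <- do.call(rbind, unlist(lapply(seq_len(n_clusters), function(c)
      render_chain(which(membership0 == c), c)), recursive = FALSE))
    solvent_pos <- matrix(NA_real_, n_solvent, 3)
    occupied <- coords1
    for (s in seq_len(n_solvent)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- stats::runif(3) * box
        dmin <- min(pairwise_min_image(matrix(cand, 1), occupied, box))
        if (dmin >= 0.25) {
          solvent_pos[s, ] <- cand
          occupied <- rbind(occupied, cand)
          placed <- TRUE; break
        }
      }
      if (!placed)
        stop("infeasible packing: could not place solvent molecule ", s,
             call. = FALSE)
    }
  }

  # topology
  nat_t <- nrow(tmpl$coords)
  sol_atoms <- do.call(rbind, lapply(seq_len(n_solute), function(m) {
    a <- tmpl$atoms
    base <- (m - 1) * nat_t
    data.frame(atom_id = base + seq_len(nat_t) - 1L,
               element = a$element, mass = a$mass, charge = a$charge,
               lj_epsilon = a$lj_epsilon, lj_sigma = a$lj_sigma,
               molecule_id = m, molecule_type = "solute",
               is_donor = a$is_donor, is_acceptor = a$is_acceptor,
               is_donor_h = a$is_donor_h,
               donor_of = ifelse(is.na(a$donor_of_local), NA_integer_,
                                 base + a$donor_of_local - 1L),
               ring_pos = a$ring_pos)
  }))
  atoms <- sol_atoms
  if (n_solvent > 0) {
    base <- n_solute * nat_t
    atoms <- rbind(atoms, data.frame(
      atom_id = base + seq_len(n_solvent) - 1L,
      element = "X", mass = 32, charge = 0,
      lj_epsilon = 0.5, lj_sigma = 0.35,
      molecule_id = n_solute + seq_len(n_solvent),
      molecule_type = "solvent",
      is_donor = FALSE, is_acceptor = FALSE, is_donor_h = FALSE,
      donor_of = NA_integer_, ring_pos = 0L))
  }
  topo <- topology(atoms)

  # frames: apply merge schedule cumulatively
  frames <- vector("list", n_frames)
  for (fidx in seq_len(n_frames)) {
    eff <- membership0
    if (!is.null(merge_schedule)) {
      sched <- merge_schedule[order(merge_schedule$frame), , drop = FALSE]
      for (s in seq_len(nrow(sched))) {
        if (fidx >= sched$frame[s]) {
          eff[eff == sched$from[s]] <- sched$to[s]
        }
      }
    }
    coords <- matrix(NA_real_, n_solute * nat_t, 3)
    for (c_idx in sort(unique(eff))) {
      mols <- which(eff == c_idx)
      chains <- render_chain(mols, c_idx)
      for (j in seq_along(mols)) {
        rows <- (mols[j] - 1) * nat_t + seq_len(nat_t)
        coords[rows, ] <- chains[[j]]
      }
    }
    if (n_solvent > 0) coords <- rbind(coords, solvent_pos)
    # store wrapped into the primary box
    for (k in 1:3) coords[, k] <- coords[, k] %% box[k]
    frames[[fidx]] <- new_frame((fidx - 1) * dt_ps, box, coords)
  }

  list(topology = topo,
       trajectory = structure(frames, class = "md_trajectory"),
       truth = list(cluster_sizes = cluster_sizes,
                    membership = membership0,
                    merge_schedule = merge_schedule,
                    cutoff = cutoff, spacing = spacing, seed = seed))
}

#' Generate an ideal-gas configuration of point molecules
#'
#' Uniform random single-site molecules in an orthorhombic box: the
#' reference system whose radial distribution function is 1 at every
#' distance.
#'
#' @param n_molecules Number of molecules.
#' @param box Box edges, nm (scalar or length 3).
#' @param n_frames Number of independent frames.
#' @param seed Integer RNG seed.
#' @return A list with `topology` and `trajectory`.
#' @export
gen_ideal_gas_config <- function(n_molecules = 500, box = 10, n_frames = 50,
                                 seed = 1) {
  if (length(box) == 1) box <- rep(box, 3)
  set.seed(seed)
  topo <- topology(data.frame(
    atom_id = seq_len(n_molecules) - 1L,
    element = "X", mass = 1, charge = 0, lj_epsilon = 0, lj_sigma = 0.3,
    molecule_id = seq_len(n_molecules), molecule_type = "solute"))
  frames <- lapply(seq_len(n_frames), function(k)
    new_frame((k - 1) * 20,
              box,
              cbind(stats::runif(n_molecules) * box[1],
                    stats::runif(n_molecules) * box[2],
                    stats::runif(n_molecules) * box[3])))
  list(topology = topo, trajectory = structure(frames,
                                               class = "md_trajectory"))
}

#' Generate planted ring-pair frames with a parallel/T-shaped mixture
#'
#' Each frame holds two ring-bearing molecules at a scripted stacking
#' geometry: with probability `frac_parallel` a parallel pair (inter-plane
#' angle near 0, centroid distance `d_parallel`), otherwise a T-shaped pair
#' (angle near 90 degrees, distance `d_tshape`). Small jitter keeps each
#' population inside a single landscape bin by default.
#'
#' @param n_frames Number of frames.
#' @param frac_parallel Probability of the parallel geometry (default 0.7).
#' @param d_parallel,d_tshape Centroid distances, nm (defaults 0.35, 0.50).
#' @param jitter_deg,jitter_nm Uniform jitter half-widths (defaults 1.5 deg,
#'   0.003 nm).
#' @param box Box edge, nm (default 6).
#' @param seed Integer RNG seed.
#' @return A list with `topology`, `trajectory` and `truth` (per-frame
#'   planted geometry labels).
#' @export
gen_stacked_pair_frames <- function(n_frames = 1000, frac_parallel = 0.7,
                                    d_parallel = 0.35, d_tshape = 0.50,
                                    jitter_deg = 1.5, jitter_nm = 0.003,
                                    box = 6, seed = 1) {
  if (length(box) == 1) box <- rep(box, 3)
  set.seed(seed)
  tmpl <- salicylamide_template()
  nat_t <- nrow(tmpl$coords)
  atoms <- do.call(rbind, lapply(1:2, function(m) {
    a <- tmpl$atoms
    base <- (m - 1) * nat_t
    data.frame(atom_id = base + seq_len(nat_t) - 1L,
               element = a$element, mass = a$mass, charge = a$charge,
               lj_epsilon = a$lj_epsilon, lj_sigma = a$lj_sigma,
               molecule_id = m, molecule_type = "solute",
               is_donor = a$is_donor, is_acceptor = a$is_acceptor,
               is_donor_h = a$is_donor_h,
               donor_of = ifelse(is.na(a$donor_of_local), NA_integer_,
                                 base + a$donor_of_local - 1L),
               ring_pos = a$ring_pos)
  }))
  topo <- topology(atoms)
  # center the template on its ring centroid so centroid distances are exact
  ring_cent <- colMeans(tmpl$coords[1:6, ])
  local <- sweep(tmpl$coords, 2, ring_cent)
  center <- box / 2
  rot_y <- function(deg) {
    th <- deg * pi / 180
    matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  }
  parallel <- stats::runif(n_frames) < frac_parallel
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    ang <- if (parallel[k]) 0 else 90
    ang <- ang + stats::runif(1, -jitter_deg, jitter_deg)
    d <- (if (parallel[k]) d_parallel else d_tshape) +
      stats::runif(1, -jitter_nm, jitter_nm)
    a_xyz <- sweep(local, 2, center, "+")                  # ring in xy plane
    b_xyz <- sweep(local %*% t(rot_y(ang)), 2,
                   center + c(0, 0, d), "+")
    frames[[k]] <- new_frame((k - 1) * 20, box, rbind(a_xyz, b_xyz))
  }
  list(topology = topo,
       trajectory = structure(frames, class = "md_trajectory"),
       truth = list(parallel = parallel, frac_parallel = frac_parallel,
                    d_parallel = d_parallel, d_tshape = d_tshape,
                    seed = seed))
}

#' Simulate telegraph-process hydrogen-bond events
#'
#' Each bond is an independent two-state Markov chain sampled at the frame
#' interval: a present bond breaks in one step with probability
#' 1 - exp(-k_break dt); an absent bond reforms with probability
#' 1 - exp(-k_reform dt). All bonds start present, so the continuous
#' survival of the ensemble decays as exp(-k_break t).
#'
#' @param n_bonds Number of bonds.
#' @param n_frames Number of frames (>= 2).
#' @param dt_ps Frame interval, ps (default 20).
#' @param k_break Breaking rate, 1/ps.
#' @param k_reform Reforming rate, 1/ps (default 0).
#' @param seed Integer RNG seed.
#' @return A logical matrix (bonds x frames) with attributes `times` (ps)
#'   and `truth`.
#' @export
gen_bond_telegraph <- function(n_bonds, n_frames, dt_ps = 20, k_break = 0.01,
                               k_reform = 0, seed = 1) {
  stopifnot(n_bonds >= 1, n_frames >= 2, k_break >= 0, k_reform >= 0)
  set.seed(seed)
  p_break <- 1 - exp(-k_break * dt_ps)
  p_reform <- 1 - exp(-k_reform * dt_ps)
  h <- matrix(FALSE, n_bonds, n_frames)
  h[, 1] <- TRUE
  for (k in 2:n_frames) {
    u <- stats::runif(n_bonds)
    h[, k] <- ifelse(h[, k - 1], u >= p_break, u < p_reform)
  }
  attr(h, "times") <- (seq_len(n_frames) - 1) * dt_ps
  attr(h, "truth") <- list(k_break = k_break, k_reform = k_reform,
                           dt_ps = dt_ps, seed = seed)
  h
}
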