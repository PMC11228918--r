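test_that("parallel offset rings put the free-energy minimum at the right bin", {
  tmpl <- salicylamide_template()
  atoms <- do.call(rbind, lapply(1:2, function(m) {
    a <- tmpl$atoms
    data.frame(atom_id = (m - 1) * 12 + 0:11, element = a$element,
               mass = a$mass, charge = a$charge, lj_epsilon = a$lj_epsilon,
               lj_sigma = a$lj_sigma, molecule_id = m,
               molecule_type = "solute", is_donor = a$is_donor,
               is_acceptor = a$is_acceptor, is_donor_h = a$is_donor_h,
               donor_of = ifelse(is.na(a$donor_of_local), NA,
                                 (m - 1) * 12 + a$donor_of_local - 1),
               ring_pos = a$ring_pos)
  }))
  topo <- topology(atoms)
  ring_cent <- colMeans(tmpl$coords[1:6, ])
  local <- sweep(tmpl$coords, 2, ring_cent)
  a_xyz <- sweep(local, 2, c(3, 3, 3), "+")
  b_xyz <- sweep(local, 2, c(3, 3, 3.35), "+")   # parallel, 0.35 nm offset
  fr <- make_frame(rbind(a_xyz, b_xyz), 6)
  L <- stacking_landscape(list(fr), topo)
  expect_equal(min(L$F[is.finite(L$F)]), 0)
  idx <- which(L$F == 0, arr.ind = TRUE)
  ang <- L$angle_mid[idx[1]]
  expect_true(ang < 5 || ang > 175)
  expect_equal(L$dist_mid[idx[2]], 0.355, tolerance = 0.02)
  # empty bins carry +Inf, not zero
  expect_true(any(is.infinite(L$F)))
  expect_false(any(L$F < 0, na.rm = TRUE))
})

test_that("the landscape is invariant under a rigid rotation of every frame", {
  sp <- gen_stacked_pair_frames(n_frames = 60, seed = 8)
  L0 <- stacking_landscape(sp$trajectory, sp$topology)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  center <- sp$trajectory[[1]]$box / 2
  rot <- lapply(sp$trajectory, function(f) {
    co <- sweep(sweep(f$coords, 2, center) %*% t(R), 2, center, "+")
    make_frame(co, f$box, f$time)
  })
  L1 <- stacking_landscape(rot, sp$topology)
  # ring-normal signs are frame-dependent (a plane has no canonical normal),
  # so the strict invariant is the angle-folded landscape theta ~ 180 - theta
  fold <- function(C) C + C[nrow(C):1, ]
  expect_equal(fold(L1$counts), fold(L0$counts))
})

test_that("planted stacking mixtures reproduce their basin weights", {
  sp <- gen_stacked_pair_frames(n_frames = 400, frac_parallel = 0.7, seed = 9)
  L <- stacking_landscape(sp$trajectory, sp$topology)
  par_mask <- (L$angle_mid < 15 | L$angle_mid > 165)
  t_mask <- (L$angle_mid > 75 & L$angle_mid < 105)
  m_par <- sum(L$counts[par_mask, ])
  m_t <- sum(L$counts[t_mask, ])
  expect_equal(m_par + m_t, 400)   # every planted frame lands in a basin
  expect_equal(m_par / 400, mean(sp$truth$parallel), tolerance = 1e-12)
  # binomial agreement with the planted weight
  expect_lt(abs(m_par / 400 - 0.7), 3 * sqrt(0.7 * 0.3 / 400))
})

test_that("degenerate ring geometries are skipped with a warning", {
  tmpl <- salicylamide_template()
  atoms <- do.call(rbind, lapply(1:3, function(m) {
    a <- tmpl$atoms
    data.frame(atom_id = (m - 1) * 12 + 0:11, element = a$element,
               mass = a$mass, charge = a$charge, lj_epsilon = a$lj_epsilon,
               lj_sigma = a$lj_sigma, molecule_id = m,
               molecule_type = "solute", is_donor = FALSE,
               is_acceptor = FALSE, is_donor_h = FALSE,
               donor_of = NA, ring_pos = a$ring_pos)
  }))
  topo <- topology(atoms)
  good1 <- sweep(tmpl$coords, 2, c(3, 3, 3), "+")
  good2 <- sweep(tmpl$coords, 2, c(3, 3, 3.35), "+")
  collinear <- tmpl$coords
  collinear[1:6, ] <- cbind(seq(0, 0.5, length.out = 6), 0, 0)
  bad <- sweep(collinear, 2, c(3, 3, 3.7), "+")
  expect_warning(
    L <- stacking_landscape(list(make_frame(rbind(good1, good2, bad), 6)),
                            topo),
    "skipped")
  expect_equal(L$n_skipped, 2L)
  expect_equal(sum(L$counts), 1)
})
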