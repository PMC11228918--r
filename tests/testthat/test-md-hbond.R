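# minimal donor/acceptor system: molecule 1 = O-H donor, molecule 2 = O acceptor
hb_topo <- topology(data.frame(
  atom_id = 0:2, element = c("O", "H", "O"), mass = c(16, 1, 16),
  charge = 0, lj_epsilon = 0, lj_sigma = 0.3,
  molecule_id = c(1, 1, 2), molecule_type = "solute",
  is_donor = c(TRUE, FALSE, FALSE),
  is_acceptor = c(FALSE, FALSE, TRUE),
  is_donor_h = c(FALSE, TRUE, FALSE),
  donor_of = c(NA, 0L, NA)))

hb_frame <- function(d_da, angle_deg, box = 10) {
  # donor at origin-ish, H on +x, acceptor at distance d in the plane
  th <- angle_deg * pi / 180
  make_frame(rbind(c(1, 1, 1),
                   c(1.1, 1, 1),
                   c(1, 1, 1) + d_da * c(cos(th), sin(th), 0)), box)
}

test_that("geometric criteria are inclusive at the stated boundaries", {
  crit <- hbond_criteria(0.35, 30)
  expect_true(hbond_events(list(hb_frame(0.29, 0)), hb_topo, crit)$present[1])
  expect_true(hbond_events(list(hb_frame(0.35, 0)), hb_topo, crit)$present[1])
  expect_false(hbond_events(list(hb_frame(0.36, 0)), hb_topo, crit)$present[1])
  expect_true(hbond_events(list(hb_frame(0.30, 30)), hb_topo, crit)$present[1])
  expect_false(hbond_events(list(hb_frame(0.30, 31)), hb_topo, crit)$present[1])
})

test_that("events match an independent vector-math recomputation", {
  set.seed(21)
  crit <- hbond_criteria(0.35, 30)
  frames <- lapply(1:50, function(k) {
    don <- stats::runif(3, 0, 2)
    h <- don + stats::runif(3, -0.12, 0.12)
    acc <- don + stats::runif(3, -0.45, 0.45)
    make_frame(rbind(don, h, acc), 10, time = (k - 1) * 20)
  })
  ev <- hbond_events(frames, hb_topo, crit)
  manual <- vapply(frames, function(f) {
    v_dh <- f$coords[2, ] - f$coords[1, ]
    v_da <- f$coords[3, ] - f$coords[1, ]
    r <- sqrt(sum(v_da^2))
    ang <- acos(sum(v_dh * v_da) / (sqrt(sum(v_dh^2)) * r)) * 180 / pi
    r <= 0.35 && ang <= 30
  }, logical(1))
  expect_identical(as.vector(ev$present), manual)
})

test_that("missing role flags raise an error", {
  topo_norole <- point_topology(3)
  expect_error(hbond_events(list(hb_frame(0.3, 0)), topo_norole), "flags")
})

test_that("lifetime curves start at 1 and obey mode ordering", {
  # bond present in every frame
  always <- matrix(TRUE, 3, 10)
  P <- hbond_lifetime(always, "continuous")
  expect_equal(P$P, rep(1, 10))
  # continuous never exceeds intermittent on random event sets
  set.seed(22)
  for (k in 1:20) {
    h <- matrix(stats::runif(8 * 15) < 0.5, 8, 15)
    if (!any(h)) next
    pc <- hbond_lifetime(h, "continuous")$P
    pi_ <- hbond_lifetime(h, "intermittent")$P
    expect_equal(pc[1], 1)
    expect_equal(pi_[1], 1)
    ok <- !is.na(pc) & !is.na(pi_)
    expect_true(all(pc[ok] <= pi_[ok] + 1e-12))
    # continuous survival is non-increasing
    pcc <- pc[!is.na(pc)]
    expect_true(all(diff(pcc) <= 1e-12))
  }
  # never-present bonds give a flagged empty result
  empty <- hbond_lifetime(matrix(FALSE, 2, 5), "continuous")
  expect_true(attr(empty, "empty"))
  expect_equal(nrow(empty), 0)
})

test_that("telegraph events are deterministic and degenerate cases behave", {
  a <- gen_bond_telegraph(50, 40, 20, 0.01, seed = 5)
  b <- gen_bond_telegraph(50, 40, 20, 0.01, seed = 5)
  expect_identical(a, b)
  expect_true(all(a[, 1]))
  # zero breaking rate: all bonds stay, P(t) = 1
  z <- gen_bond_telegraph(20, 30, 20, 0, seed = 1)
  expect_true(all(z))
  expect_equal(hbond_lifetime(z, "continuous")$P, rep(1, 30))
})

test_that("lifetime uses the actual frame spacing", {
  h <- matrix(TRUE, 1, 5)
  attr(h, "times") <- c(0, 40, 80, 120, 160)
  P <- hbond_lifetime(h, "continuous")
  expect_equal(P$time_ps, c(0, 40, 80, 120, 160))
})
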