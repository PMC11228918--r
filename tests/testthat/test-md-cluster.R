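test_that("well-separated molecules form singleton clusters", {
  coords <- rbind(c(1, 1, 1), c(4, 1, 1), c(1, 4, 1), c(4, 4, 4))
  topo <- point_topology(4)
  cl <- cluster_frame(make_frame(coords, 9), topo)
  expect_equal(cl$n_clusters, 4)
  expect_true(all(cl$sizes == 1))
})

test_that("planted partitions are recovered exactly", {
  pc <- gen_planted_config(box = 8, cluster_sizes = c(5, 3, 1), seed = 2)
  cl <- cluster_frame(pc$trajectory[[1]], pc$topology)
  expect_equal(sort(as.integer(cl$sizes)), c(1, 3, 5))
  expect_identical(partition_key(cl$membership),
                   partition_key(pc$truth$membership))
  # conservation: cluster sizes sum to the number of solute molecules
  expect_equal(sum(cl$sizes), 9)
})

test_that("single-linkage equals brute-force transitive closure", {
  set.seed(7)
  for (k in 1:20) {
    n <- sample(4:20, 1)
    box <- 4
    coords <- matrix(stats::runif(3 * n, 0, box), ncol = 3)
    topo <- point_topology(n)
    cl <- cluster_frame(make_frame(coords, box), topo,
                        cluster_criteria(cutoff = 0.9, linkage = "any"))
    expect_identical(partition_key(cl$membership),
                     partition_key(bf_clusters(coords, rep(box, 3), 0.9)))
  }
})

test_that("the partition is invariant to translation and periodic wrapping", {
  pc <- gen_planted_config(box = 8, cluster_sizes = c(4, 2), seed = 3)
  fr <- pc$trajectory[[1]]
  key0 <- partition_key(cluster_frame(fr, pc$topology)$membership)
  for (shift in list(c(1.7, -2.3, 0.4), c(7.9, 7.9, 7.9))) {
    co <- sweep(fr$coords, 2, shift, "+")
    for (k in 1:3) co[, k] <- co[, k] %% fr$box[k]
    fr2 <- make_frame(co, fr$box, fr$time)
    expect_identical(partition_key(cluster_frame(fr2, pc$topology)$membership),
                     key0)
  }
})

test_that("a cluster spanning the periodic boundary stays one cluster", {
  pc <- gen_planted_config(box = 8, cluster_sizes = 5, seed = 4)
  fr <- pc$trajectory[[1]]
  # slide the chain so it straddles the box edge, then wrap
  co <- sweep(fr$coords, 2, c(8, 0, 0) - fr$coords[1, ], "+")
  for (k in 1:3) co[, k] <- co[, k] %% fr$box[k]
  cl <- cluster_frame(make_frame(co, fr$box), pc$topology)
  expect_equal(cl$n_clusters, 1)
  expect_equal(as.integer(cl$sizes), 5)
})

test_that("heavy-atom linkage ignores hydrogens", {
  # two diatomics whose only close contact is H...H
  df <- data.frame(atom_id = 0:3, element = c("O", "H", "O", "H"),
                   mass = c(16, 1, 16, 1), charge = 0, lj_epsilon = 0,
                   lj_sigma = 0.3, molecule_id = c(1, 1, 2, 2),
                   molecule_type = "solute")
  topo <- topology(df)
  coords <- rbind(c(1.0, 1, 1), c(1.5, 1, 1), c(2.1, 1, 1), c(1.8, 1, 1))
  fr <- make_frame(coords, 10)
  heavy <- cluster_frame(fr, topo, cluster_criteria(0.35, "heavy"))
  any_ <- cluster_frame(fr, topo, cluster_criteria(0.35, "any"))
  expect_equal(heavy$n_clusters, 2)   # O-O distance 1.1 nm
  expect_equal(any_$n_clusters, 1)    # H-H distance 0.3 nm
})

test_that("scripted merges show up in the cluster-count series", {
  pc <- gen_planted_config(box = 14, cluster_sizes = c(4, 3), n_frames = 20,
                           merge_schedule = data.frame(frame = 10, from = 2,
                                                       to = 1),
                           seed = 3)
  cs <- cluster_count_series(pc$trajectory, pc$topology)
  expect_equal(cs$series$n_clusters, rep(c(2, 1), c(9, 11)))
  expect_true(cs$fitted)
  # static trajectory: constant counts, fit reduces to (c, 0, 0)
  pc2 <- gen_planted_config(box = 8, cluster_sizes = c(3, 2), n_frames = 5,
                            seed = 6)
  cs2 <- cluster_count_series(pc2$trajectory, pc2$topology)
  expect_equal(unname(cs2$fit), c(2, 0, 0), tolerance = 1e-9)
  # too few frames: fit skipped with flag
  cs3 <- cluster_count_series(pc2$trajectory[1:2], pc2$topology)
  expect_false(cs3$fitted)
  expect_null(cs3$fit)
})
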