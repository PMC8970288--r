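test_that("signed distance matches analytic sphere distances", {
  m <- sphere_mesh(5)
  expect_equal(signed_distance(m, c(0, 0, 0)), -5, tolerance = 0.01)
  expect_equal(signed_distance(m, c(5, 0, 0)), 0, tolerance = 0.01)
  expect_equal(signed_distance(m, c(7, 0, 0)), 2, tolerance = 0.01)
  expect_equal(signed_distance(m, c(0, -3, 0)), -2, tolerance = 0.01)
  # agrees in magnitude with the brute-force oracle at random points
  set.seed(3)
  P <- matrix(runif(60, -8, 8), ncol = 3)
  expect_equal(abs(signed_distance(m, P)), oracle_mesh_dist(m, P), tolerance = 1e-10)
})

test_that("shell membership is inclusive within the half-width", {
  m <- sphere_mesh(5)
  cfg <- shell_config(half_width = 1)
  expect_true(in_shell(m, c(5.9, 0, 0), cfg))
  expect_false(in_shell(m, c(6.5, 0, 0), cfg))
  expect_true(in_shell(m, c(4.2, 0, 0), cfg))   # 0.8 um inside
  expect_false(in_shell(m, c(0, 0, 0), cfg))    # deep inside
})

test_that("voxelized sphere shell volume is within 2% of the closed form", {
  m <- sphere_mesh(5)
  v <- shell_volume(m, shell_config(half_width = 1, voxel_pitch = 0.25))
  closed <- 4 * pi / 3 * (6^3 - 4^3)
  expect_lt(abs(v - closed) / closed, 0.02)
})

test_that("shell volume converges to its fine-pitch limit as the pitch shrinks", {
  m <- sphere_mesh(5)
  ref <- shell_volume(m, shell_config(voxel_pitch = 0.03125))
  errs <- vapply(c(0.5, 0.25, 0.125), function(p)
    abs(shell_volume(m, shell_config(voxel_pitch = p)) - ref), numeric(1))
  # voxel-centre counting oscillates within a shrinking envelope rather than
  # decreasing strictly at every halving: check the envelope, not each step
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3] / ref, 1e-3)
  expect_equal(ref, 4 * pi / 3 * (6^3 - 4^3), tolerance = 0.01)
})

test_that("ellipsoid shell volume agrees with a Monte-Carlo rejection oracle", {
  set.seed(7)
  m <- ellipsoid_mesh(c(8, 5, 4), subdiv = 2, cell_id = "e")
  t <- 1
  v <- shell_volume(m, shell_config(half_width = t, voxel_pitch = 0.25))
  # independent oracle: uniform samples in the padded box, membership by the
  # pure-R brute-force distance, with triangle-AABB prefiltering for speed
  lo <- apply(m$vertices, 2, min) - t
  hi <- apply(m$vertices, 2, max) + t
  n <- 1e6
  P <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]), runif(n, lo[3], hi[3]))
  inshell <- rep(FALSE, n)
  V <- m$vertices
  F <- m$faces
  for (tr in seq_len(nrow(F))) {
    tv <- V[F[tr, ], , drop = FALSE]
    blo <- apply(tv, 2, min) - t
    bhi <- apply(tv, 2, max) + t
    cand <- which(!inshell &
                    P[, 1] >= blo[1] & P[, 1] <= bhi[1] &
                    P[, 2] >= blo[2] & P[, 2] <= bhi[2] &
                    P[, 3] >= blo[3] & P[, 3] <= bhi[3])
    if (!length(cand)) next
    d2 <- oracle_pt_tri_dist2(P[cand, , drop = FALSE], tv[1, ], tv[2, ], tv[3, ])
    inshell[cand[d2 <= t^2]] <- TRUE
  }
  vbox <- prod(hi - lo)
  phat <- mean(inshell)
  mc <- vbox * phat
  se <- vbox * sqrt(phat * (1 - phat) / n)
  expect_lt(abs(v - mc), 3 * se)
})

test_that("translation leaves counts, shell volumes and densities unchanged", {
  set.seed(13)
  sc <- random_test_scene(4, 150)
  cfg <- shell_config()
  shift <- c(17.3, -4.2, 8.8)
  cells2 <- lapply(sc$cells, function(m)
    surface_mesh(sweep(m$vertices, 2, shift, "+"), m$faces,
                 cell_id = attr(m, "cell_id"), repair = FALSE))
  spots2 <- dplyr::mutate(sc$spots, x_um = x_um + shift[1],
                          y_um = y_um + shift[2], z_um = z_um + shift[3])
  a1 <- attribute_spots(sc$cells, sc$spots, cfg)
  a2 <- attribute_spots(cells2, spots2, cfg)
  expect_equal(a1$cell_id, a2$cell_id)
  v1 <- vapply(sc$cells, shell_volume, numeric(1), cfg = cfg)
  v2 <- vapply(cells2, shell_volume, numeric(1), cfg = cfg)
  expect_equal(v1, v2, tolerance = 1e-6)
})

test_that("rotation preserves counts exactly and volumes within voxel error", {
  set.seed(14)
  sc <- random_test_scene(3, 120)
  cfg <- shell_config()
  R <- random_rotation()
  cells2 <- lapply(sc$cells, function(m)
    surface_mesh(m$vertices %*% t(R), m$faces,
                 cell_id = attr(m, "cell_id"), repair = FALSE))
  P2 <- spot_matrix(sc$spots) %*% t(R)
  spots2 <- dplyr::mutate(sc$spots, x_um = P2[, 1], y_um = P2[, 2], z_um = P2[, 3])
  a1 <- attribute_spots(sc$cells, sc$spots, cfg)
  a2 <- attribute_spots(cells2, spots2, cfg)
  expect_equal(a1$cell_id, a2$cell_id)
  v1 <- vapply(sc$cells, shell_volume, numeric(1), cfg = cfg)
  v2 <- vapply(cells2, shell_volume, numeric(1), cfg = cfg)
  expect_equal(v1, v2, tolerance = 0.01)  # voxel grid is axis-aligned
})

test_that("attribution matches the brute-force oracle on random scenes", {
  set.seed(31)
  for (rep in 1:5) {
    sc <- random_test_scene(sample(2:6, 1), sample(80:200, 1))
    att <- attribute_spots(sc$cells, sc$spots, shell_config())
    want <- oracle_attribution(sc$cells, spot_matrix(sc$spots), 1)
    expect_identical(att$cell_id, want)
  }
})

test_that("exact distance ties go to the lexicographically smallest cell_id", {
  base <- sphere_mesh(4)
  twin_b <- surface_mesh(base$vertices, base$faces, cell_id = "b", repair = FALSE)
  twin_a <- surface_mesh(base$vertices, base$faces, cell_id = "a", repair = FALSE)
  sp <- tibble::tibble(marker = "TH", x_um = 4.5, y_um = 0, z_um = 0)
  att <- attribute_spots(list(twin_b, twin_a), sp, shell_config())
  expect_identical(att$cell_id, "a")
})

test_that("each spot is counted at most once and totals are conserved", {
  set.seed(41)
  sc <- random_test_scene(5, 300)
  scene <- ganglion_scene("S1", "G1", sc$cells, sc$spots)
  labels <- make_labels(names(scene$cells))
  d <- compute_densities(scene, labels)
  expect_lte(sum(d$count), nrow(sc$spots))
  att <- attribute_spots(sc$cells, sc$spots, shell_config())
  expect_equal(sum(d$count), sum(!is.na(att$cell_id)))
  expect_equal(d$density_per_1000um3, 1000 * d$count / d$shell_volume_um3)
})

test_that("spots nearest an excluded cell are dropped, not reassigned", {
  a <- sphere_mesh(5, c(0, 0, 0), cell_id = "a")
  b <- sphere_mesh(5, c(11, 0, 0), cell_id = "b")
  # both shells contain x in [5.0, 6.0]; 5.3 is nearer a, 5.8 nearer b
  sp <- tibble::tibble(marker = "TH", x_um = c(5.3, 5.8), y_um = 0, z_um = 0)
  scene <- ganglion_scene("S1", "G1", list(a, b), sp)
  labels <- make_labels(c("a", "b"), excluded = c(TRUE, FALSE))
  d <- compute_densities(scene, labels)
  expect_equal(unique(d$cell_id), "b")
  expect_equal(sum(d$count[d$marker == "TH"]), 1)  # only the 5.8 spot
})

test_that("density is independent of cell size at fixed true density", {
  cfg <- shell_config()
  rho <- 100 / 1000  # spots per um^3 of shell; high enough that count
                     # rounding is well under the comparison tolerance
  out <- vapply(c(5, 10), function(r) {
    m <- sphere_mesh(r, cell_id = "c")
    v <- shell_volume(m, cfg)
    n <- round(rho * v)
    set.seed(100 + r)
    P <- sample_shell_points(m, n, cfg)
    sp <- tibble::tibble(marker = "TH", x_um = P[, 1], y_um = P[, 2], z_um = P[, 3])
    d <- compute_densities(ganglion_scene("S", "G", list(m), sp), make_labels("c"), cfg)
    d$density_per_1000um3[d$marker == "TH"]
  }, numeric(1))
  expect_equal(out[1], out[2], tolerance = 0.02)
  expect_equal(out, c(100, 100), tolerance = 0.02)
})

test_that("empty cell lists and bad configs are rejected", {
  sp <- tibble::tibble(marker = "TH", x_um = 1, y_um = 1, z_um = 1)
  expect_error(attribute_spots(list(), sp), class = "perishell_scene_error")
  expect_error(shell_config(half_width = 0), class = "perishell_config_error")
  expect_error(shell_config(voxel_pitch = 0.8), class = "perishell_config_error")
})
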