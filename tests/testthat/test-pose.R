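test_that("a single atom's simulated density peaks at the atom and scales with Z", {
  c1 <- mk_points(matrix(c(0, 0, 0), 1), name = "C1", element = "C",
                  hetero = TRUE)
  m <- simulate_map(c1, resolution = 4, voxel_size = 0.5, padding = 6)
  peak <- which(m$values == max(m$values), arr.ind = TRUE)[1, ]
  peak_xyz <- m$origin + (peak - 1) * m$voxel_size
  expect_lt(max(abs(peak_xyz)), m$voxel_size / 2 + 1e-9)
  # integrated density proportional to atomic number (closed-form Gaussian)
  sigma <- 0.225 * 4
  analytic <- function(z) z * (sqrt(2 * pi) * sigma)^3
  int_c <- sum(m$values) * m$voxel_size^3
  expect_equal(int_c, analytic(6), tolerance = 0.01)
  o1 <- mk_points(matrix(c(0, 0, 0), 1), name = "O1", element = "O",
                  hetero = TRUE)
  mo <- simulate_map(o1, resolution = 4, voxel_size = 0.5, padding = 6)
  expect_equal(sum(mo$values) / sum(m$values), 8 / 6, tolerance = 1e-6)
  empty <- select_atoms(c1, selection(chains = "none"))
  expect_error(simulate_map(empty, 4), "empty")
})

test_that("self-correlation is 1 and affine intensity changes leave CC fixed", {
  b <- make_ideal_barrel(barrel_spec(residues_per_strand = 6L))
  m <- simulate_map(b, resolution = 5, voxel_size = 1.5)
  expect_equal(map_model_cc(m, b, mask_radius = 3, resolution = 5), 1,
               tolerance = 1e-6)
  m2 <- m; m2$values <- 3 * m$values + 7
  expect_equal(map_model_cc(m2, b, 3, 5),
               map_model_cc(m, b, 3, 5), tolerance = 1e-9)
})

test_that("a voxel-shuffled map decorrelates from the model", {
  b <- make_ideal_barrel(barrel_spec(residues_per_strand = 6L))
  m <- simulate_map(b, resolution = 5, voxel_size = 1.5)
  set.seed(1)
  m3 <- m; m3$values[] <- sample(m$values)
  expect_lt(abs(map_model_cc(m3, b, 3, 5)), 0.05)
})

test_that("an empty mask is rejected", {
  c1 <- mk_points(matrix(c(0, 0, 0), 1), name = "C1", hetero = TRUE)
  m <- simulate_map(c1, resolution = 3, voxel_size = 2, padding = 4)
  far <- mk_points(matrix(c(0, 0, 0), 1), name = "C1", hetero = TRUE)
  expect_error(map_model_cc(m, far, mask_radius = 0.4, resolution = 3),
               "mask")
})

test_that("MRC mode-2 maps round-trip with voxel size and origin intact", {
  b <- make_ideal_barrel(barrel_spec(residues_per_strand = 6L))
  m <- simulate_map(b, resolution = 6, voxel_size = 2)
  f <- tempfile(fileext = ".mrc")
  write_mrc(m, f)
  m2 <- read_mrc(f)
  expect_equal(dim(m2$values), dim(m$values))
  expect_equal(m2$voxel_size, m$voxel_size, tolerance = 1e-6)
  expect_equal(m2$origin, m$origin, tolerance = 1e-4)
  expect_lt(max(abs(m2$values - m$values)), 1e-5 * max(abs(m$values)))
})

test_that("Lennard-Jones and cutoff behavior match the closed forms", {
  p <- energy_params()
  at <- function(x) mk_points(matrix(c(x, 0, 0), 1), name = "X1",
                              element = "C", hetero = TRUE)
  rmin <- 2 * p$table$rmin_half[p$table$element == "C"]
  expect_equal(interaction_energy(at(0), at(rmin), p), -0.07,
               tolerance = 1e-12)
  expect_identical(interaction_energy(at(0), at(12.5), p), 0)
  # enlarging the cutoff only adds pair terms (additivity)
  p14 <- energy_params(cutoff = 14)
  lig <- mk_points(rbind(c(5, 0, 0), c(13, 0, 0)), name = c("X1", "X2"),
                   element = "C", hetero = TRUE)
  e12 <- interaction_energy(at(0), lig, p)
  e14 <- interaction_energy(at(0), lig, p14)
  far_pair <- interaction_energy(at(0), mk_points(matrix(c(13, 0, 0), 1),
                                                  name = "X2", element = "C",
                                                  hetero = TRUE), p14)
  expect_equal(e14, e12 + far_pair, tolerance = 1e-12)
})

test_that("interaction energy equals a brute-force double loop and is symmetric", {
  set.seed(9)
  xr <- matrix(rnorm(9, sd = 4), 3, 3)
  xl <- matrix(rnorm(6, sd = 4), 2, 3)
  rec <- mk_points(xr, name = paste0("X", 1:3), element = c("C", "N", "O"),
                   hetero = TRUE)
  lig <- mk_points(xl, name = c("N", "O"), element = c("N", "O"),
                   hetero = TRUE)
  p <- energy_params()
  tab <- p$table
  brute <- 0
  els_r <- c("C", "N", "O"); els_l <- c("N", "O")
  qs <- function(nm) if (nm %in% names(p$charges)) p$charges[[nm]] else 0
  q_r <- c(0, 0, 0); q_l <- c(qs("N"), qs("O"))
  for (i in 1:3) for (j in 1:2) {
    r <- sqrt(sum((xr[i, ] - xl[j, ])^2))
    if (r > p$cutoff) next
    eps <- sqrt(tab$epsilon[tab$element == els_r[i]] *
                  tab$epsilon[tab$element == els_l[j]])
    rmin <- tab$rmin_half[tab$element == els_r[i]] +
      tab$rmin_half[tab$element == els_l[j]]
    sr6 <- (rmin / r)^6
    brute <- brute + eps * (sr6^2 - 2 * sr6) +
      332.06 * q_r[i] * q_l[j] / (p$dielectric * r)
  }
  expect_equal(interaction_energy(rec, lig, p), brute, tolerance = 1e-9)
  expect_equal(interaction_energy(lig, rec, p),
               interaction_energy(rec, lig, p), tolerance = 1e-12)
})

test_that("unknown elements fall back to carbon defaults with a warning", {
  a <- mk_points(matrix(0, 1, 3), name = "Q1", element = "Q", hetero = TRUE)
  b <- mk_points(matrix(c(4, 0, 0), 1), name = "X1", element = "C",
                 hetero = TRUE)
  expect_warning(e <- interaction_energy(a, b), "carbon-like")
  expect_equal(e, -0.07, tolerance = 1e-12)
})

test_that("the eight-pose set carries the planted structure", {
  b <- make_ideal_barrel()
  rec <- open_gate(b, gate_perturbation())
  poses <- make_pose_set(rec)
  expect_identical(names(poses),
                   c("E1", "E2", "E3", "E4", "C1", "C2", "C3", "C4"))
  expect_identical(attr(poses, "ground_truth"), "E4")
  expect_identical(attr(poses, "best_energy"), "C4")
  # determinism
  poses2 <- make_pose_set(rec)
  expect_equal(coords(poses2$C4), coords(poses$C4))
})

test_that("ranking recovers the planted hydrogen-bond and energy winners", {
  b <- make_ideal_barrel()
  rec <- open_gate(b, gate_perturbation())
  poses <- make_pose_set(rec)
  sc <- rank_poses(rec, poses)
  expect_setequal(sc$rank, seq_len(8))
  best_hb <- sc$pose_id[which.max(sc$mean_hbonds)]
  expect_identical(best_hb, attr(poses, "ground_truth"))
  expect_gt(max(sc$mean_hbonds), sort(sc$mean_hbonds, decreasing = TRUE)[2])
  # without a map the primary criterion is energy: the planted pose is rank 1
  expect_identical(sc$pose_id[sc$rank == 1], attr(poses, "best_energy"))
  expect_lt(min(sc$energy), sort(sc$energy)[2])
})

test_that("a single pose gets rank 1 and map-based ranking prefers the truth", {
  b <- make_ideal_barrel()
  rec <- open_gate(b, gate_perturbation())
  poses <- make_pose_set(rec)
  one <- rank_poses(rec, poses["E4"])
  expect_equal(one$rank, 1L)
  # simulate a ground-truth map from receptor + E4 and rank two rivals by CC
  truth <- merge_structures(rec, poses$E4)
  m <- simulate_map(truth, resolution = 5, voxel_size = 2)
  sc <- rank_poses(rec, poses[c("E4", "E2")], map = m, resolution = 5,
                   mask_radius = 3)
  expect_identical(sc$pose_id[sc$rank == 1], "E4")
  expect_gt(sc$map_cc[sc$pose_id == "E4"], sc$map_cc[sc$pose_id == "E2"])
})
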