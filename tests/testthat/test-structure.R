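test_that("PDB read/write round-trips preserve coordinates and identifiers", {
  b <- make_ideal_barrel(barrel_spec(residues_per_strand = 6L))
  f <- tempfile(fileext = ".pdb")
  write_structure(b, f)
  b2 <- read_structure(f)
  expect_equal(n_atoms(b2), n_atoms(b))
  expect_lt(max(abs(coords(b2) - coords(b))), 1e-3)
  expect_identical(b2$atoms$name, b$atoms$name)
  expect_identical(b2$atoms$res_seq, b$atoms$res_seq)

  # minimal 3-atom fixture
  s3 <- mk_points(matrix(rnorm(9), 3, 3))
  f3 <- tempfile(fileext = ".pdb")
  write_structure(s3, f3)
  r3 <- read_structure(f3)
  expect_equal(n_atoms(r3), 3L)
  expect_equal(r3$n_models, 1L)

  # insertion codes survive the round trip
  a <- b$atoms[b$atoms$model_index == 1, ][1:10, ]
  a$i_code[3:4] <- "A"
  si <- new_structure(a)
  fi <- tempfile(fileext = ".pdb")
  write_structure(si, fi)
  expect_identical(read_structure(fi)$atoms$i_code, a$i_code)
})

test_that("mmCIF write is read back identically by an independent parser", {
  b <- make_ideal_barrel(barrel_spec(residues_per_strand = 6L))
  f <- tempfile(fileext = ".cif")
  write_structure(b, f)
  b2 <- suppressWarnings(read_structure(f))
  expect_equal(n_atoms(b2), n_atoms(b))
  expect_lt(max(abs(coords(b2) - coords(b))), 1e-3)
})

test_that("multi-model files round-trip with models intact", {
  b <- make_ideal_barrel(barrel_spec(residues_per_strand = 6L))
  P <- diag(5)[c(4, 4, 4, 4, 4), ]
  tr <- make_seam_trajectory(seam_chain_spec(P, n_frames = 3L), b)
  f <- tempfile(fileext = ".pdb")
  write_structure(tr, f)
  tr2 <- read_structure(f)
  expect_equal(tr2$n_models, 3L)
  expect_lt(max(abs(coords(tr2, 2) - coords(tr, 2))), 1e-3)
})

test_that("reading fails cleanly on missing or empty files", {
  expect_error(read_structure(tempfile()), "cannot read")
  f <- tempfile(fileext = ".pdb")
  writeLines("END", f)
  expect_error(suppressWarnings(read_structure(f)))
})

test_that("select_atoms filters exactly and tolerates empty results", {
  x <- matrix(seq_len(15), 5, 3)
  s <- mk_points(x)
  expect_equal(n_atoms(select_atoms(s, selection(atom_names = "CA"))), 5L)
  expect_equal(n_atoms(select_atoms(s, selection(chains = "Z"))), 0L)
  expect_error(select_atoms(s, selection(model_index = 2L)), "out of bounds")

  # residue-range selection with insertion codes vs a brute-force filter
  a <- s$atoms
  a$i_code[2] <- "A"
  a$res_seq <- c(1L, 1L, 2L, 3L, 4L)
  si <- new_structure(a)
  got <- select_atoms(si, selection(residue_ranges = list(c(1, 2))))
  expect_equal(nrow(got$atoms), sum(a$res_seq >= 1 & a$res_seq <= 2))
})

test_that("altloc handling keeps a single deterministic conformer", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA AALA A   1      11.639   6.071  -5.147  0.50  0.00           C",
    "ATOM      3  CA BALA A   1      12.639   7.071  -4.147  0.50  0.00           C",
    "END"), f)
  s <- read_structure(f)
  expect_equal(n_atoms(s), 2L)
  expect_true(all(s$atoms$alt_loc %in% c("", "A")))
})

test_that("correspondence by residue id pairs identically numbered chains", {
  x <- matrix(rnorm(30), 10, 3)
  a <- mk_points(x); b <- mk_points(x + 1)
  corr <- build_correspondence(a, b, "by_resid")
  expect_equal(nrow(corr), 10L)
  expect_error(build_correspondence(a, mk_points(x, chain = "B"), "by_resid"),
               "no shared chains")
})

test_that("alignment correspondence matches the exhaustive oracle", {
  resn <- c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS", "ILE", "LYS",
            "LEU")
  x <- matrix(rnorm(30), 10, 3)
  a <- mk_points(x, res_name = resn)
  # internal single-residue deletion
  b <- mk_points(x[-6, ], res_name = resn[-6], res_seq = 1:9)
  corr <- build_correspondence(a, b, "by_alignment")
  expect_equal(nrow(corr), 9L)
  sa <- unname(gatescope:::.aa3to1[resn])
  sb <- sa[-6]
  al <- align_global(sa, sb)
  # achieves the optimum found by exhaustive enumeration
  expect_equal(align_score_of(al, sa, sb), align_score_oracle(sa, sb))
  # tie-break determinism: repeated runs give identical pairings
  expect_identical(al, align_global(sa, sb))
})

test_that("explicit cross-species loop pairs load one-to-one from the fixture", {
  fx <- read.csv(system.file("extdata", "crossspecies_loop_pairs.csv",
                             package = "gatescope"))
  corr <- explicit_correspondence(data.frame(
    chain_a = fx$chain_a, resseq_a = fx$resseq_a,
    chain_b = fx$chain_b, resseq_b = fx$resseq_b))
  expect_equal(nrow(corr), 8L)
  l1 <- fx[fx$loop == "L1", ]
  expect_equal(l1$resseq_a, c(144L, 145L, 152L, 153L))
  expect_equal(l1$resseq_b, c(129L, 130L, 138L, 139L))
  dup <- fx; dup$resseq_b[2] <- dup$resseq_b[1]
  expect_error(explicit_correspondence(data.frame(
    chain_a = dup$chain_a, resseq_a = dup$resseq_a,
    chain_b = dup$chain_b, resseq_b = dup$resseq_b)), "one-to-one")
})

test_that("superposition of a structure onto itself is the identity", {
  b <- make_ideal_barrel(barrel_spec(residues_per_strand = 6L))
  corr <- build_correspondence(b, b, "by_resid")
  fit <- kabsch_superpose(b, b, corr)
  expect_lt(fit$rmsd, 1e-9)
  expect_lt(max(abs(fit$rotation - diag(3))), 1e-9)
})

test_that("a constructed rigid transform is recovered exactly", {
  set.seed(7)
  x <- matrix(rnorm(60, sd = 5), 20, 3)
  a <- mk_points(x)
  ang <- 30 * pi / 180
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  tv <- c(5, -2, 1)
  b <- transform_structure(a, R, tv)
  corr <- build_correspondence(a, b, "by_resid")
  fit <- kabsch_superpose(b, a, corr)   # a onto b recovers (R, tv)
  expect_lt(fit$rmsd, 1e-9)
  expect_lt(max(abs(fit$rotation - R)), 1e-9)
  expect_lt(max(abs(fit$translation - tv)), 1e-9)
  # and the inverse transform maps back
  inv <- kabsch_superpose(a, b, corr)
  expect_lt(max(abs(inv$rotation - t(R))), 1e-9)
})

test_that("superposition properties hold over random synthetic pairs", {
  set.seed(11)
  for (k in 1:100) {
    n <- sample(4:12, 1)
    xa <- matrix(rnorm(3 * n, sd = 4), n, 3)
    xb <- xa + matrix(rnorm(3 * n, sd = 0.7), n, 3)
    a <- mk_points(xa); b <- mk_points(xb)
    corr <- build_correspondence(a, b, "by_resid")
    f1 <- kabsch_superpose(a, b, corr)
    # rotations orthonormal with det +1
    expect_lt(max(abs(crossprod(f1$rotation) - diag(3))), 1e-8)
    expect_equal(det(f1$rotation), 1, tolerance = 1e-8)
    # RMSD symmetry
    f2 <- kabsch_superpose(b, a, corr)
    expect_equal(f1$rmsd, f2$rmsd, tolerance = 1e-9)
    # optimality: no worse than the identity transform
    expect_lte(f1$rmsd, sqrt(mean(rowSums((xa - xb)^2))) + 1e-12)
    # invariance under a common rigid motion
    R <- random_rotation(); tv <- rnorm(3, sd = 10)
    f3 <- kabsch_superpose(transform_structure(a, R, tv),
                           transform_structure(b, R, tv), corr)
    expect_equal(f3$rmsd, f1$rmsd, tolerance = 1e-8)
  }
})

test_that("superposition agrees with an independent reference fit", {
  set.seed(3)
  xa <- matrix(rnorm(45), 15, 3)
  xb <- xa + 0.5 * matrix(rnorm(45), 15, 3)
  a <- mk_points(xa); b <- mk_points(xb)
  fit <- kabsch_superpose(a, b, build_correspondence(a, b, "by_resid"))
  fb <- bio3d::fit.xyz(fixed = as.vector(t(xa)), mobile = as.vector(t(xb)),
                       fixed.inds = 1:45, mobile.inds = 1:45)
  ref_rmsd <- sqrt(mean(rowSums((matrix(fb, ncol = 3, byrow = TRUE) - xa)^2)))
  expect_equal(fit$rmsd, ref_rmsd, tolerance = 1e-9)
})

test_that("superposition errors and warnings trigger on degenerate input", {
  x <- matrix(rnorm(6), 2, 3)
  a <- mk_points(x); b <- mk_points(x)
  expect_error(kabsch_superpose(a, b, build_correspondence(a, b, "by_resid")),
               "insufficient pairs")
  xl <- cbind(1:5, 0, 0)  # collinear
  al <- mk_points(xl); bl <- mk_points(xl)
  expect_warning(kabsch_superpose(al, bl,
                                  build_correspondence(al, bl, "by_resid")),
                 "collinear")
})

test_that("rmsd_subset reports over one selection after fitting on another", {
  set.seed(5)
  x <- matrix(rnorm(60, sd = 5), 20, 3)
  a <- mk_points(x)
  expect_equal(rmsd_subset(a, a, build_correspondence(a, a, "by_resid"),
                           selection(atom_names = "CA")), 0)
  # displace residues 11..20 by exactly 2 A, fit on 1..10
  y <- x; y[11:20, 1] <- y[11:20, 1] + 2
  b <- mk_points(y)
  corr <- build_correspondence(a, b, "by_resid")
  r <- rmsd_subset(a, b, corr,
                   sel = selection(residue_ranges = list(c(11, 20))),
                   fit_sel = selection(residue_ranges = list(c(1, 10))))
  expect_equal(r, 2, tolerance = 1e-9)
  # symmetry of the reported RMSD
  r2 <- rmsd_subset(b, a, corr,
                    sel = selection(residue_ranges = list(c(11, 20))),
                    fit_sel = selection(residue_ranges = list(c(1, 10))))
  expect_equal(r, r2, tolerance = 1e-9)
})
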