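test_that("loop means and displayed values follow the truncate rule", {
  expect_equal(loop_mean(c(0, 0, 0, 0)), 0)
  expect_equal(loop_mean(c(14.25, 19.25, 12.13, 10.93)), 14.14)
  expect_equal(display_trunc(loop_mean(c(14.25, 19.25, 12.13, 10.93))), 14.14)
  # 44.86 / 4 = 11.215: truncation, not rounding, gives the printed 11.21
  m <- loop_mean(c(10.93, 12.99, 11.34, 9.60))
  expect_equal(m, 11.215)
  expect_equal(display_trunc(m), 11.21)
  expect_error(loop_mean(c(1, 2, 3)), "exactly 4")
  expect_error(loop_mean(c(1, 2, 3, -1)), "nonnegative")
})

test_that("percent openness uses full-precision sums", {
  expect_equal(percent_openness(c(1, 2, 3, 4), c(1, 2, 3, 4)), 100)
  p1 <- percent_openness(c(14.25, 19.25, 12.13, 10.93),
                         c(18.45, 22.27, 18.14, 15.09))
  expect_equal(display_trunc(p1), 76.48)
  p2 <- percent_openness(c(1.15, 1.11, 0.30, 0.44),
                         c(5.99, 8.36, 4.93, 3.43))
  expect_equal(display_trunc(p2), 13.21)
  # the ratio of the displayed means would NOT reproduce the printed cell
  expect_false(display_trunc(100 * 14.14 / 18.48) == display_trunc(p1))
  expect_error(percent_openness(c(1, 2, 3, 4), c(0, 0, 0, 0)), "positive")
})

test_that("percent openness is invariant under a global scale change", {
  d <- c(2.3, 4.1, 1.7, 0.9); r <- c(5.5, 6.1, 4.9, 3.3)
  expect_equal(percent_openness(3.7 * d, 3.7 * r), percent_openness(d, r),
               tolerance = 1e-12)
})

test_that("measured gate distances obey the rigid-rotation chord formula", {
  b <- make_ideal_barrel()
  sr <- b$metadata$strand_ranges
  fit_sel <- selection(residue_ranges = list(c(sr$first_res[5],
                                               sr$last_res[16])),
                       atom_names = "CA")
  loops <- synthetic_gate_loops(b$metadata$spec, c("ref", "other"))
  for (theta in c(10, 30, 60)) {
    bo <- open_gate(b, gate_perturbation(4, theta))
    corr <- build_correspondence(b, bo, "by_resid")
    d <- measure_gate_distances(b, bo, loops, corr, fit_sel = fit_sel,
                                ref_key = "ref", other_key = "other")
    h <- bo$metadata$hinge
    for (lab in c("L1", "L2")) {
      rs <- loops[[match(lab, vapply(loops, `[[`, "", "label"))]]$residues$ref
      ca <- b$atoms[b$atoms$name == "CA" & b$atoms$res_seq %in% rs$res_seq, ]
      ca <- ca[match(rs$res_seq, ca$res_seq), ]
      r <- sqrt((ca$x - h[1])^2 + (ca$y - h[2])^2)
      expect_equal(d[[lab]], 2 * r * sin(theta / 2 * pi / 180),
                   tolerance = 1e-6)
    }
  }
})

test_that("missing loop C-alpha atoms raise a named error", {
  b <- make_ideal_barrel()
  loops <- list(gate_loop("L1", list(
    ref = data.frame(chain_id = "A", res_seq = c(3, 5, 9000, 15)),
    other = data.frame(chain_id = "A", res_seq = c(3, 5, 13, 15)))))
  corr <- build_correspondence(b, b, "by_resid")
  expect_error(measure_gate_distances(b, b, loops, corr,
                                      ref_key = "ref", other_key = "other"),
               "A:9000")
})

test_that("openness is monotone in the gate angle and halves at half-angle", {
  b <- make_ideal_barrel()
  sr <- b$metadata$strand_ranges
  fit_sel <- selection(residue_ranges = list(c(sr$first_res[5],
                                               sr$last_res[16])),
                       atom_names = "CA")
  keys <- c("closed", "q1", "q2", "stalled")
  loops <- synthetic_gate_loops(b$metadata$spec, keys)
  structs <- list(closed = b,
                  q1 = open_gate(b, gate_perturbation(4, 15)),
                  q2 = open_gate(b, gate_perturbation(4, 30)),
                  stalled = open_gate(b, gate_perturbation(4, 45)))
  rep <- openness_report(structs, loops, "closed", "stalled",
                         fit_sel = fit_sel)
  df <- as.data.frame(rep)
  p <- function(pair, loop) df$percent[df$pair == pair & df$loop == loop]
  # monotone in theta
  expect_lt(p("closed-q1", "L1"), p("closed-q2", "L1"))
  expect_lt(p("closed-q2", "L1"), 100)
  # chord ratio: percent(0 <-> theta/2) relative to percent(0 <-> theta)
  pred <- 100 * sin(15 / 2 * pi / 180) / sin(30 / 2 * pi / 180)
  expect_equal(p("closed-q1", "L1") / p("closed-q2", "L1") * 100, pred,
               tolerance = 1e-6)
  # reference row is exactly 100, both loops
  expect_equal(p("closed-stalled", "L1"), 100)
  expect_equal(p("closed-stalled", "L2"), 100)
})

test_that("self-pair rows are zero and the reference row is 100 percent", {
  b <- make_ideal_barrel()
  keys <- c("closed", "copy", "stalled")
  loops <- synthetic_gate_loops(b$metadata$spec, keys)
  sr <- b$metadata$strand_ranges
  fit_sel <- selection(residue_ranges = list(c(sr$first_res[5],
                                               sr$last_res[16])),
                       atom_names = "CA")
  rep <- openness_report(list(closed = b, copy = b,
                              stalled = open_gate(b, gate_perturbation(4, 45))),
                         loops, "closed", "stalled", fit_sel = fit_sel)
  df <- as.data.frame(rep)
  self_rows <- df[df$pair == "closed-copy", ]
  expect_true(all(abs(self_rows$percent) < 1e-9))
  expect_true(all(abs(self_rows$mean) < 1e-9))
  ref_rows <- df[df$pair == "closed-stalled", ]
  expect_true(all(abs(ref_rows$percent - 100) < 1e-12))
})

test_that("the bundled per-residue fixture reproduces every printed cell", {
  tab <- openness_from_fixture()
  df <- as.data.frame(tab)
  cell <- function(pair, loop, col)
    display_trunc(df[df$pair == pair & df$loop == loop, col])
  expect_equal(cell("cl-op", "L1", "mean"), 14.14)
  expect_equal(cell("cl-daro", "L1", "mean"), 11.21)
  expect_equal(cell("op-daro", "L1", "mean"), 4.94)
  expect_equal(cell("daro-stall", "L1", "mean"), 8.27)
  expect_equal(cell("op-stall", "L1", "mean"), 4.46)
  expect_equal(cell("cl-stall", "L1", "mean"), 18.48)
  expect_equal(cell("cl-op", "L2", "mean"), 4.60)
  expect_equal(cell("cl-daro", "L2", "mean"), 4.64)
  expect_equal(cell("op-daro", "L2", "mean"), 0.75)
  expect_equal(cell("daro-stall", "L2", "mean"), 1.60)
  expect_equal(cell("op-stall", "L2", "mean"), 1.55)
  expect_equal(cell("cl-stall", "L2", "mean"), 5.67)
  expect_equal(cell("cl-op", "L1", "percent"), 76.48)
  expect_equal(cell("cl-daro", "L1", "percent"), 60.66)
  expect_equal(cell("op-daro", "L1", "percent"), 26.76)
  expect_equal(cell("daro-stall", "L1", "percent"), 44.77)
  expect_equal(cell("op-stall", "L1", "percent"), 24.16)
  expect_equal(cell("cl-stall", "L1", "percent"), 100.00)
  expect_equal(cell("cl-op", "L2", "percent"), 81.06)
  expect_equal(cell("cl-daro", "L2", "percent"), 81.85)
  expect_equal(cell("op-daro", "L2", "percent"), 13.21)
  expect_equal(cell("daro-stall", "L2", "percent"), 28.22)
  expect_equal(cell("op-stall", "L2", "percent"), 27.34)
  expect_equal(cell("cl-stall", "L2", "percent"), 100.00)
})

test_that("gate distances are stable under swapping the reference role", {
  b <- make_ideal_barrel()
  bo <- open_gate(b, gate_perturbation(4, 25))
  sr <- b$metadata$strand_ranges
  fit_sel <- selection(residue_ranges = list(c(sr$first_res[5],
                                               sr$last_res[16])),
                       atom_names = "CA")
  loops <- synthetic_gate_loops(b$metadata$spec, c("x", "y"))
  corr <- build_correspondence(b, bo, "by_resid")
  d1 <- measure_gate_distances(b, bo, loops, corr, fit_sel = fit_sel,
                               ref_key = "x", other_key = "y")
  d2 <- measure_gate_distances(bo, b, loops, corr, fit_sel = fit_sel,
                               ref_key = "y", other_key = "x")
  expect_equal(d1$L1, d2$L1, tolerance = 1e-6)
})
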