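test_that("baseline is the mean over the 30 s before addition", {
  tr <- flat_trace(100)
  expect_equal(compute_baseline(tr$time_s, tr$f, 30), 100)
  # alternating 90/110 over the window averages to 100
  f <- rep(c(90, 110), length.out = 150)
  expect_equal(compute_baseline(0:149, f, 30), 100)
  # no full baseline window before an addition at t = 10 s
  expect_error(compute_baseline(0:120, rep(1, 121), 10), "baseline window")
  # non-increasing times are malformed
  expect_error(compute_baseline(c(0, 2, 1), c(1, 1, 1), 30), "increasing")
})

test_that("deltaF/F compares the last 10 s to baseline, signed", {
  f <- c(rep(100, 30), rep(150, 120))
  m <- compute_delta_f(0:149, f, 30)
  expect_equal(m$F, 100)
  expect_equal(m$dF, 50)
  expect_equal(m$dff, 0.5)
  expect_equal(compute_delta_f(0:149, rep(77, 150), 30)$dff, 0)
  # inhibition: a drop gives a negative dF
  fneg <- c(rep(100, 30), rep(80, 120))
  expect_equal(compute_delta_f(0:149, fneg, 30)$dF, -20)
})

test_that("deltaF/F is invariant to multiplying a trace by a positive gain", {
  set.seed(1)
  f <- 500 + cumsum(rnorm(150))
  base <- compute_delta_f(0:149, f, 30)
  for (k in c(0.2, 3, 17)) {
    scaled <- compute_delta_f(0:149, k * f, 30)
    expect_equal(scaled$dff, base$dff, tolerance = 1e-12)
  }
})

test_that("positive-control normalization scales and self-normalizes", {
  expect_equal(normalize_to_positive_control(1.0, 2.0), 0.5)
  expect_error(normalize_to_positive_control(1.0, 0), "> 0")
  sim <- recovery_sim()
  meas <- process_traces(sim$traces, sim$plate_map)
  pc <- meas[meas$role == "positive_control", ]
  expect_equal(pc$dff_normalized, rep(1, nrow(pc)), tolerance = 1e-9)
})

test_that("plate-scale differences cancel after control normalization", {
  # same truth, two plates with very different transfection scales
  sim <- recovery_sim(n_bio = 2, plate_scales = c(1.0, 1.5))
  meas <- process_traces(sim$traces, sim$plate_map)
  ex <- meas[meas$role == "experimental", ]
  p1 <- ex[ex$plate_id == "P01", ]
  p2 <- ex[ex$plate_id == "P02", ]
  key <- function(d) paste(d$ligand_id, format(d$concentration))
  p2 <- p2[match(key(p1), key(p2)), ]
  expect_equal(p1$dff_normalized, p2$dff_normalized, tolerance = 1e-9)
  # raw dff also matches here because dff itself is gain-invariant
  expect_equal(p1$dff, p2$dff, tolerance = 1e-9)
})

test_that("baseline activity is the F ratio to the indicator-only control", {
  sim <- recovery_sim()
  meas <- process_traces(sim$traces, sim$plate_map)
  nc <- meas[meas$role == "negative_control", ]
  expect_equal(nc$baseline_ratio, rep(1, nrow(nc)), tolerance = 1e-9)
  # all wells share baseline_f in this simulation, so every ratio is 1
  expect_equal(meas$baseline_ratio, rep(1, nrow(meas)), tolerance = 1e-9)
})

test_that("missing controls are reported as errors naming the plate", {
  sim <- recovery_sim()
  no_pc <- sim$plate_map$role != "positive_control"
  expect_error(process_traces(sim$traces, sim$plate_map[no_pc, ]),
               "positive-control")
  no_nc <- sim$plate_map$role != "negative_control"
  expect_error(process_traces(sim$traces, sim$plate_map[no_nc, ]),
               "negative-control")
})

test_that("technical replicates average into one biological replicate", {
  wm <- data.frame(
    plate_id = "P01", receptor_id = "R", ligand_id = "x",
    concentration = 1e-5, role = "experimental",
    F = c(100, 100, 100, -5), dF = 0, dff = 0,
    dff_normalized = c(0.4, 0.6, 0.5, 9),
    baseline_ratio = 1,
    valid = c(TRUE, TRUE, TRUE, FALSE)
  )
  out <- average_technical_replicates(wm)
  expect_equal(nrow(out), 1)
  expect_equal(out$dff_normalized, 0.5)  # mean of the three valid wells
  expect_equal(out$n_technical, 3)
  # idempotence on identical replicates
  wm$valid <- TRUE
  wm$dff_normalized <- 0.7
  expect_equal(average_technical_replicates(wm)$dff_normalized, 0.7)
  # zero valid replicates: condition dropped with a warning
  wm$valid <- FALSE
  expect_error(expect_warning(average_technical_replicates(wm), "dropped"))
})

test_that("pipeline deltaF/F matches the forward model on noise-free plates", {
  sim <- recovery_sim()  # fast kinetics, no noise
  meas <- process_traces(sim$traces, sim$plate_map)
  ex <- meas[meas$role == "experimental", ]
  truth <- recovery_truth()
  for (i in seq_len(nrow(ex))) {
    p <- truth$ligands[truth$ligands$ligand_id == ex$ligand_id[i], ]
    expect_equal(ex$dff[i],
                 hill_response(ex$concentration[i], p$log_ec50, p$amplitude,
                               p$slope),
                 tolerance = 1e-3)
  }
})
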