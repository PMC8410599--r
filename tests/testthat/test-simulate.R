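test_that("simulation is deterministic under a fixed seed", {
  s1 <- recovery_sim(noise_sd = 5, seed = 21)
  s2 <- recovery_sim(noise_sd = 5, seed = 21)
  expect_identical(s1$traces, s2$traces)
  expect_identical(s1$plate_map, s2$plate_map)
  s3 <- recovery_sim(noise_sd = 5, seed = 22)
  expect_false(identical(s1$traces, s3$traces))

  p1 <- simulate_descriptor_panel(20, c(logP = 1), noise_sd = 1,
                                  n_missing = 3, seed = 5)
  p2 <- simulate_descriptor_panel(20, c(logP = 1), noise_sd = 1,
                                  n_missing = 3, seed = 5)
  expect_identical(p1, p2)
})

test_that("null-response noise-free plates are flat at the scaled baseline", {
  tr <- ground_truth("R0", data.frame(ligand_id = "x", log_ec50 = -5,
                                      amplitude = 0, slope = 1),
                     noise_sd = 0, baseline_f = 800)
  layout <- make_plate_layout("P01", "R0", "x",
                              make_dilution_series(5e-4, 3, 7),
                              positive_control = list(receptor_id = "R0",
                                                      ligand_id = "x",
                                                      concentration = 5e-4))
  sim <- simulate_plate(tr, layout, plate_scale = 1.5, seed = 3)
  expect_true(all(sim$traces$fluorescence == 800 * 1.5))
})

test_that("fast kinetics settle to the Hill response within the tail window", {
  tr <- ground_truth("R0", data.frame(ligand_id = "x", log_ec50 = -5,
                                      amplitude = 0.9, slope = 1),
                     kinetic_tau = 2, noise_sd = 0)
  conc <- make_dilution_series(5e-4, 3, 7)
  layout <- make_plate_layout("P01", "R0", "x", conc,
                              positive_control = list(receptor_id = "R0",
                                                      ligand_id = "x",
                                                      concentration = 5e-4))
  sim <- simulate_plate(tr, layout, seed = 3)
  wells <- layout[layout$role == "experimental", ]
  for (i in seq_len(nrow(wells))) {
    w <- sim$traces[sim$traces$well_id == wells$well_id[i], ]
    tail10 <- w$fluorescence[w$time_s > max(w$time_s) - 10]
    base <- mean(w$fluorescence[w$time_s < 30])
    dff <- (mean(tail10) - base) / base
    expect_equal(dff, hill_response(wells$concentration[i], -5, 0.9, 1),
                 tolerance = 1e-3)
  }
})

test_that("negative-control wells carry no ligand response", {
  tr <- recovery_truth(noise_sd = 4)
  conc <- make_dilution_series(5e-4, 3, 7)
  # many control wells across simulated plates: mean dF stays near 0
  devs <- unlist(lapply(1:30, function(b) {
    layout <- make_plate_layout(sprintf("P%02d", b), "WT",
                                "strong", conc,
                                positive_control = list(receptor_id = "WT",
                                                        ligand_id = "pc",
                                                        concentration = 5e-4))
    sim <- simulate_plate(tr, layout, seed = 100 + b)
    nc <- layout$well_id[layout$role == "negative_control"]
    sapply(nc, function(wid) {
      w <- sim$traces[sim$traces$well_id == wid, ]
      mean(w$fluorescence[w$time_s > max(w$time_s) - 10]) -
        mean(w$fluorescence[w$time_s < 30])
    })
  }))
  expect_gte(length(devs), 100)
  # sd of (mean of 10) - (mean of 30) samples of sd-4 noise
  se <- 4 * sqrt(1 / 10 + 1 / 30)
  expect_lt(abs(mean(devs)), 3 * se / sqrt(length(devs)))
})

test_that("layouts carry four technical replicates and both controls", {
  conc <- make_dilution_series(5e-4, 3, 7)
  layout <- make_plate_layout("P01", "WT", c("a", "b"), conc)
  ex <- layout[layout$role == "experimental", ]
  counts <- table(ex$ligand_id, ex$concentration)
  expect_true(all(counts == 4))
  expect_true(any(layout$role == "positive_control"))
  expect_true(any(layout$role == "negative_control"))
  expect_false(any(duplicated(layout$well_id)))
})

test_that("simulate_plate rejects layouts referencing unknown ligands", {
  tr <- ground_truth("R0", data.frame(ligand_id = "x", log_ec50 = -5,
                                      amplitude = 1, slope = 1))
  layout <- make_plate_layout("P01", "R0", "mystery",
                              make_dilution_series(5e-4, 3, 7),
                              positive_control = list(receptor_id = "R0",
                                                      ligand_id = "x",
                                                      concentration = 5e-4))
  expect_error(simulate_plate(tr, layout, seed = 1), "mystery")
})

test_that("descriptor panel plants a linear truth with controlled missingness", {
  dp <- simulate_descriptor_panel(54, c(polar_surface_area = -1),
                                  noise_sd = 0, n_missing = 6, seed = 8)
  expect_equal(nrow(dp$panel), 54)
  expect_equal(length(dp$truth$missing_ligands), 6)
  cols <- orpharm_descriptors()
  complete <- rowSums(is.na(dp$panel[cols])) == 0
  expect_equal(sum(complete), 48)
  # noiseless truth: activity is exactly linear in the planted descriptor
  d <- dp$panel[complete, ]
  expect_equal(d$activity_index, -d$polar_surface_area, tolerance = 1e-12)
  expect_error(simulate_descriptor_panel(10, c(nope = 1)), "unknown")
  expect_error(simulate_descriptor_panel(5, n_missing = 5), "n_missing")
})
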