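# shared builders for simulated assays

# truth whose positive control saturates at amplitude 1 (so normalized
# amplitudes equal true amplitudes to well under 1e-3 at the 0.5 mM top)
recovery_truth <- function(noise_sd = 0, kinetic_tau = 0.5) {
  ground_truth(
    "WT",
    data.frame(
      ligand_id = c("pc", "strong", "mid", "weak", "inhib"),
      log_ec50 = c(-7, -6, -5, -4.2, -5),
      amplitude = c(1, 1.2, 0.8, 0.6, -0.4),
      slope = c(2, 1.2, 1.0, 1.1, 1.0)
    ),
    kinetic_tau = kinetic_tau, noise_sd = noise_sd
  )
}

recovery_sim <- function(noise_sd = 0, n_bio = 2, seed = 11,
                         plate_scales = NULL) {
  tr <- recovery_truth(noise_sd)
  # "pc" serves as the plate positive control only; its EC50 sits below the
  # tested range, so it is not dosed as an experimental series
  simulate_assay(tr, ligand_ids = setdiff(tr$ligands$ligand_id, "pc"),
                 n_bio = n_bio, seed = seed,
                 plate_scales = plate_scales,
                 positive_control = list(receptor_id = "WT",
                                         ligand_id = "pc",
                                         concentration = 5e-4))
}

# a minimal single-well trace builder
flat_trace <- function(level = 100, t = 0:149) {
  data.frame(time_s = t, f = rep(level, length(t)))
}
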