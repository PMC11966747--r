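# Noiseless replicate-level 4PL data at 8 log-spaced concentrations.
noiseless_curve <- function(ic50 = 1, top = 100, bottom = 0, hill = 1,
                            n_rep = 3) {
  simulate_inhibition_curve(ic50 = ic50, top = top, bottom = bottom,
                            hill = hill, n_replicates = n_rep, noise_sd = 0)
}

fit_curve <- function(d, ...) {
  fit_fourpl(activity_percent ~ concentration_uM, d, ...)
}

# Minimal hand-built DCR record table for evaluation tests.
make_records <- function(dcr, outcome, cutoff = 1) {
  data.frame(
    compound = paste0("cpd", seq_along(dcr)),
    dose_mg_per_kg = seq_along(dcr),
    dcr = dcr,
    predicted_label = classify_dcr(dcr, cutoff),
    reported_outcome = outcome,
    cutoff = rep(cutoff, length(dcr))
  )
}
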