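# Small shared fixtures, built in code.

quiet_cfg <- function(...) {
  generator_config(noise = list(enabled = FALSE), ...)
}

# Minimal one-genotype design: n wells of `genotype` under one treatment.
mini_design <- function(cfg, genotype = "tgMOR", compound = "fentanyl",
                        dose = 40) {
  build_plate_design(
    data.frame(genotype = genotype, compound = compound, dose = dose),
    cfg
  )
}

# Hand-built single-well binned table on a regular grid.
make_binned <- function(centers, values, well_id = "W01",
                        experiment_id = "E01", genotype = "tgMOR",
                        treatment = "fentanyl_40", dose = 40,
                        state = "baseline") {
  tibble::tibble(
    experiment_id = experiment_id, well_id = well_id,
    genotype = genotype, treatment = treatment, dose = dose,
    bin_center_min = centers, mean_speed = values,
    n_samples = 60L, n_animals = 4L,
    normalization_state = state
  )
}

# Run the standard analysis chain on a tracker table without file I/O.
analyze_table <- function(tab, meta, bin_width = 60, t_apply = 10,
                          window = c(1, 30), smooth_k = 3) {
  qc <- qc_filter_wells(tab)
  b <- bin_well_means(qc$kept, bin_width, t_apply, meta)
  bn <- baseline_normalize(b)
  response_metrics(bn, window = window, smooth_k = smooth_k)
}
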