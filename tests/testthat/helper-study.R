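# Matched-cohort study machinery shared by the study-logic tests: two
# cohorts with identical target connective area fraction but branch density
# 0 vs 8. Both calibrations share a seed base, so septum-geometry noise in
# the calibration measurements largely cancels from the cohort mean
# difference; study images use disjoint seed blocks.
build_matched_cohorts <- function(seed, target = 0.40, tolerance = 0.005,
                                  n_seeds = 200L) {
  spA <- tissue_spec(branch_density = 0, seed = seed)
  spB <- tissue_spec(branch_density = 8, seed = seed)
  list(
    sparse = calibrate_area_fraction(spA, target, tolerance = tolerance,
                                     n_seeds = n_seeds),
    branched = calibrate_area_fraction(spB, target, tolerance = tolerance,
                                       n_seeds = n_seeds)
  )
}

run_matched_replicate <- function(specs, rep_seed, cfg, n_per_group = 20L) {
  sim <- simulate_cohorts(specs, n_per_group = n_per_group, seed = rep_seed)
  res <- run_study(sim$manifest, cfg)
  a <- res$anova
  list(p_area = a$p[a$feature == "area_fraction"],
       p_D = a$p[a$feature == "fractal_D"],
       band_area = classify_auc(res$roc$auc[res$roc$feature == "area_fraction"]),
       band_D = classify_auc(res$roc$auc[res$roc$feature == "fractal_D"]))
}
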