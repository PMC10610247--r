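# Shared study conditions for the simulation-based checks.

# Effect-recovery condition: a single drug with a planted odds multiplier
# of 4 on Pruritus. Exposure probabilities are kept at 0.5% so that
# co-medication leakage into the comparator arm is negligible (the
# model-implied ROR, expected_ror(), is within 1.5% of the planted 4);
# the 10% baseline keeps the exposed-with-event cell large enough for the
# Wald interval to behave. Noise processes are switched off: they are
# exercised by their own tests and do not bias the estimator.
recovery_config <- function(n_cases, seed, multiplier = 4) {
  synthetic_config(
    n_cases = n_cases, seed = seed,
    drug_catalog = data.frame(drug = paste0("drug", 1:5), p = 0.005),
    pt_catalog = data.frame(pt = c("Pruritus", "Nausea", "Headache"),
                            p0 = c(0.10, 0.45, 0.25),
                            is_pruritus = c(TRUE, FALSE, FALSE)),
    planted_effects = data.frame(drug = "drug1", pt = "Pruritus",
                                 multiplier = multiplier),
    duplicate_rate = 0, missing_date_rate = 0, missing_demo_rate = 0,
    out_of_window_rate = 0, indication_overlap_rate = 0)
}

# Three drug archetypes with disjoint elevated PT triples: the planted
# partition the profile clustering must recover.
archetype_config <- function(n_cases = 50000, seed = 1, multiplier = 6) {
  groups <- rep(1:3, each = 4)
  drugs <- sprintf("drug%02d", 1:12)
  prur_pts <- c("Pruritus", "Eye Pruritus", "Nasal Pruritus",
                "Oral Pruritus", "Tongue Pruritus", "Lip Pruritus",
                "Injection Site Pruritus", "Application Site Pruritus",
                "Rash Pruritic")
  effects <- do.call(rbind, lapply(1:12, function(i) {
    data.frame(drug = drugs[i],
               pt = prur_pts[(groups[i] - 1) * 3 + 1:3],
               multiplier = multiplier)
  }))
  cfg <- synthetic_config(
    n_cases = n_cases, seed = seed,
    drug_catalog = data.frame(drug = drugs, p = 0.08),
    pt_catalog = data.frame(
      pt = c(prur_pts, "Nausea", "Headache"),
      p0 = c(rep(0.015, 9), 0.35, 0.20),
      is_pruritus = c(rep(TRUE, 9), FALSE, FALSE)),
    planted_effects = effects,
    duplicate_rate = 0, missing_date_rate = 0, missing_demo_rate = 0,
    out_of_window_rate = 0, indication_overlap_rate = 0)
  list(config = cfg, groups = setNames(groups, drugs))
}

# Generator tables -> internal-schema tables.
normalize_tables <- function(tables) {
  lapply(setNames(names(tables), names(tables)),
         function(nm) normalize_faers(tables[[nm]], nm))
}

# Full cleaning chain on a generated dataset.
synth_cohort <- function(gen) {
  build_cohort(normalize_tables(gen$tables))
}
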