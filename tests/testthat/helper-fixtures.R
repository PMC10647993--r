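# Shared fixtures, built once per test run. Phantoms are kept small (40^3)
# so the default suite stays fast; the acceptance tests build their own
# 64^3 phantom at the sizes stated there.

local_fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(local_fixture_cache[[key]]))
    local_fixture_cache[[key]] <- builder()
  local_fixture_cache[[key]]
}

fixture_clean_phantom <- function() cached("clean40", function()
  generate_phantom_pair(phantom_config(dim = c(40, 40, 40), seed = 7,
                                       class_fractions = c(0.25, 0.25, 0.25, 0.25))))

fixture_warped_phantom <- function() cached("warp40", function()
  generate_phantom_pair(phantom_config(dim = c(40, 40, 40), seed = 11,
                                       warp_amplitude = 2)))

fixture_noiseless_cohort <- function() cached("cohort_noiseless", function()
  generate_cohort(cohort_config(n = 300L, seed = 21,
                                noise_sd_fev1_fvc = 0, noise_sd_fev1_pct = 0)))

fixture_noisy_cohort <- function() cached("cohort_noisy", function()
  generate_cohort(cohort_config(n = 300L, seed = 42)))

# Published six-row table of subjects whose model staging disagreed with
# staging from measured spirometry (normal/high-risk task); spirometry in
# fraction units, PRM percentages of whole-lung volume.
discordant_cases_table <- function() data.frame(
  fsad_pct = c(11.3, 22.8, 9.9, 13.8, 69.9, 19.2),
  emph_pct = c(3.67, 2.37, 0.57, 3.1, 4.85, 2.76),
  group_pft = c("high_risk", "high_risk", "high_risk", "normal", "normal", "normal"),
  fev1_pct = c(0.83, 0.81, 0.80, 1.11, 1.25, 1.04),
  fev1_fvc = c(0.94, 0.75, 0.87, 0.96, 0.96, 0.84),
  fev1_pct_pred = c(1.01, 0.97, 1.04, 0.88, 0.92, 0.78),
  group_model = c("normal", "normal", "normal", "high_risk", "high_risk", "high_risk"))
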