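#!/usr/bin/env Rscript
# Stage 1: build the synthetic inputs for the whole analysis.
#
# Two kinds of ground truth are generated: a paired-breath phantom whose
# per-voxel PRM classes are known by construction (for the image-side
# stages), and a screening cohort whose spirometry follows a known linear
# model in whole-lung fSAD% and Emph% (for the model-side stages).

suppressPackageStartupMessages(library(prmct))

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

# -- phantom: moderate disease burden, no degradation (reference case) -------
cfg_ph <- phantom_config(dim = c(64, 64, 64), seed = 101,
                         class_fractions = c(0.1, 0.2, 0.65, 0.05))
ph <- generate_phantom_pair(cfg_ph)
write_phantom(ph, "scratch/phantom_clean")
counts <- ph$truth$class_counts
cat("phantom lung volume:", sum(counts), "voxels;",
    "class fractions (%):", round(100 * colSums(counts) / sum(counts), 2), "\n")

# degraded variants exercised by later stages
write_phantom(generate_phantom_pair(phantom_config(dim = c(64, 64, 64), seed = 102,
                                                   class_fractions = c(0.1, 0.2, 0.65, 0.05),
                                                   noise_sd = 5)),
              "scratch/phantom_noisy")
write_phantom(generate_phantom_pair(phantom_config(dim = c(64, 64, 64), seed = 103,
                                                   warp_amplitude = 2)),
              "scratch/phantom_warped")

# -- cohort: 615 subjects at the generator's default conditions -------------
co <- generate_cohort(cohort_config(n = 615L, seed = 110))
write_cohort_csv(co, "results/cohort.csv")
prev <- table(co$group)
cat("cohort of", nrow(co), "subjects; group prevalence:\n")
print(round(prop.table(prev), 3))
cat("whole-lung fSAD% median:", round(median(co$prm_whole_fsad_pct), 1),
    "| Emph% median:", round(median(co$prm_whole_emph_pct), 2), "\n")

# a noiseless twin of the cohort for the parameter-recovery experiment
co0 <- generate_cohort(cohort_config(n = 500L, seed = 111,
                                     noise_sd_fev1_fvc = 0, noise_sd_fev1_pct = 0))
write_cohort_csv(co0, "results/cohort_noiseless.csv")
cat("wrote results/cohort.csv and results/cohort_noiseless.csv\n")
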