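#!/usr/bin/env Rscript

# Step 1: write a small demonstration session to disk in the package's
# trajectory TSV dialect (full 16-sensor recordings), so the file-based
# reading path of the pipeline can be exercised end to end. The large
# replicate studies elsewhere use the in-memory generator instead.

suppressMessages(library(oppkin))

dir.create("results/trajectories", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_participants = 1L, trials_per_task = 2L, seed = 100L)
ses <- simulate_session(cfg)

write_trials(ses$recordings, "results/trajectories/demo_trajectories.tsv")
write_manifest(ses$recordings, "results/trajectories/demo_manifest.tsv")
data.table::fwrite(ses$truth, "results/trajectories/demo_truth.tsv", sep = "\t")

cat(sprintf(
  "Simulated %d trials (%d participant, %d per task) at %g Hz, %g s each.\n",
  length(ses$recordings), cfg$n_participants, cfg$trials_per_task,
  cfg$fs, cfg$duration
))
cat("True thumb share ranges from",
    sprintf("%.2f (index distal) to %.2f (little proximal).\n",
            min(ses$truth$r), max(ses$truth$r)))
cat("Wrote trajectories, manifest and ground truth under results/trajectories/.\n")
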