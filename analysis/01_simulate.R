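#!/usr/bin/env Rscript
# Generate the synthetic study cohort: imaging sessions with planted
# response motifs, a photometry afferent recording, and rabies-tracing
# input-count tables. Everything downstream reads from results/data.

library(avoidpop)

seed <- 20260926L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_neurons = 60, n_trials = 30, n_sessions = 3,
                  frame_rate_hz = 5, p_success = 0.7, noise_sd = 1,
                  seed = seed)
cohort <- generate_cohort(cfg)
gt <- NULL
for (s in cohort) {
  write_session_bundle(s, file.path(out, s$session_id))
  gt <- rbind(gt, data.frame(session_id = s$session_id,
                             neuron_id = s$neurons$neuron_id,
                             motif = s$ground_truth$motif_name))
}
write.csv(gt, file.path(out, "ground_truth_motifs.csv"), row.names = FALSE)

message(sprintf("cohort: %d sessions x %d neurons, %d trials each",
                length(cohort), cfg$n_neurons, cfg$n_trials))
message(sprintf("success rate: %.2f",
                mean(unlist(lapply(cohort,
                                   function(s) s$events$outcome == "success")))))
print(table(gt$motif))

# the photometry afferent is regenerated by 07_encoding_glm.R from the
# same seed, so only the tabular data are materialized here

# input-count matrices for four molecularly defined subtypes
icm <- generate_input_counts(5, default_region_profiles(),
                             concentration = 60, total_cells = 2000,
                             seed = seed)
write.csv(data.frame(subject = rownames(icm$counts),
                     subtype = icm$subtype, icm$counts),
          file.path(out, "input_counts.csv"), row.names = FALSE)
message("wrote ", out)
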