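#!/usr/bin/env Rscript
# Generate the 14-group synthetic study population: LLM responses to the
# 9-item Q-matrix, group latent-class distributions concentrated on a
# planted mastery chain, two groups planted with the alternative
# data-handling-first step. Writes the dataset and the ground truth.

library(cdmtraj)

seed <- 1
out <- "results/simulation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sc <- pisa_like_scenario(seed = seed)
cat("simulated", nrow(sc$responses$scores), "persons x",
    ncol(sc$responses$scores), "items in",
    length(unique(sc$responses$group)), "groups (seed", seed, ")\n")

write_responses(sc$responses, file.path(out, "responses.csv"))
write_q_matrix(sc$q, file.path(out, "q_matrix.csv"))

truth <- do.call(rbind, lapply(names(sc$planted_chains), function(g)
  data.frame(group = g,
             chain = paste(sc$planted_chains[[g]], collapse = " -> "),
             alt_first_step = g %in% sc$config$alt_groups)))
write.csv(truth, file.path(out, "planted_chains.csv"), row.names = FALSE)
cat("\nplanted chains:\n")
print(truth, row.names = FALSE)

dists <- do.call(rbind, lapply(names(sc$group_dists), function(g) {
  d <- sc$group_dists[[g]]
  data.frame(group = g, pattern = rownames(attribute_patterns(4)),
             probability = d)
}))
write.csv(dists, file.path(out, "group_class_distributions.csv"),
          row.names = FALSE)
cat("\ntrue class distributions written to",
    file.path(out, "group_class_distributions.csv"), "\n")
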