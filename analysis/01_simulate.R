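#!/usr/bin/env Rscript
# Stage 1 — simulate the study system: a gridded landscape, a species pool
# with known niches, abundance-class occurrence records, a phylogeny, a trait
# table with gaps, and the climate scenario. Everything downstream reads the
# files written here.

suppressPackageStartupMessages(library(traitshift))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260921L

env <- generate_landscape(nrows = 32, ncols = 32, n_continuous = 4,
                          n_categorical = 2, correlation_length = 4,
                          seed = seed)
write_env_stack(env, file.path(out, "env_current"))
cat(sprintf("landscape: %d layers on a %d x %d grid\n",
            length(env$layers), nrow(env$mask), ncol(env$mask)))

delta <- scenario_delta(c(temp = 2.85, precip = -0.5))
write_scenario(delta, file.path(out, "scenario.yml"))
write_env_stack(apply_scenario(env, delta), file.path(out, "env_future"))
cat("scenario: temp +2.85, precip -0.5 (standardized layer units)\n")

species <- generate_species(env, n_species = 24, seed = seed + 1L)
occ <- sample_occurrences(species, env, n_sites = 600,
                          class_thresholds = c(0.1, 0.5), seed = seed + 2L)
write.csv(occ, file.path(out, "occurrences.csv"), row.names = FALSE)
cat(sprintf("occurrences: %d records of %d species (classes: %s)\n",
            nrow(occ), length(unique(occ$species_id)),
            paste(table(occ$abundance_class), collapse = "/")))

ids <- vapply(species, `[[`, character(1), "id")
pfg <- setNames(vapply(species, `[[`, character(1), "pfg"), ids)
tree <- simulate_phylogeny(ids, depth = 1, seed = seed + 3L)
ape::write.tree(tree, file.path(out, "tree.nwk"))

traits <- simulate_traits(tree, sigma2 = 0.25,
                          root_state = c(log(15), log(0.4), log(0.4)),
                          missing_fraction = 0.2, pfg = pfg, seed = seed + 4L)
write.csv(traits, file.path(out, "traits_raw.csv"), row.names = FALSE)
cat(sprintf("traits: %d species, %d missing continuous entries\n",
            nrow(traits), sum(is.na(traits[c("SLA", "CH", "RD")]))))
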