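#!/usr/bin/env Rscript
# Stage 3 — presence-background maximum-entropy SDMs, one per species per
# abundance class, projected onto current and scenario climates, then
# combined into weighted-average relative abundance surfaces.

suppressPackageStartupMessages(library(traitshift))

env <- read_env_stack("results/data/env_current/stack.yml")
env_fut <- read_env_stack("results/data/env_future/stack.yml")
occ <- read_occurrences("results/data/occurrences.csv")

sdms <- fit_all_sdms(occ, env, env_fut, beta = 0.1, min_presences = 5)
logl <- attr(sdms, "log")
cat(sprintf("fitted %d species-class models, skipped %d\n",
            sum(grepl("fitted", logl)), sum(grepl("skipped", logl))))

dir.create("results/abundance", showWarnings = FALSE, recursive = TRUE)
fitted <- names(sdms)[vapply(sdms, function(s) any(s$fitted), logical(1))]
for (sp in fitted) {
  cur <- weighted_abundance(sdms[[sp]]$current[[1]], sdms[[sp]]$current[[2]],
                            sdms[[sp]]$current[[3]])
  fut <- weighted_abundance(sdms[[sp]]$future[[1]], sdms[[sp]]$future[[2]],
                            sdms[[sp]]$future[[3]])
  write_grid(cur, sprintf("results/abundance/%s__current.asc", sp),
             cellsize = env$cellsize, origin = env$origin)
  write_grid(fut, sprintf("results/abundance/%s__future.asc", sp),
             cellsize = env$cellsize, origin = env$origin)
}
cat(sprintf("wrote abundance surfaces for %d species\n", length(fitted)))
writeLines(logl, "results/sdm_log.txt")
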