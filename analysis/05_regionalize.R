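#!/usr/bin/env Rscript
# Stage 5 — partition the landscape into regions of similar community change
# (k-means over per-cell species share changes) and summarize the CWMT
# change surfaces within each region.

suppressPackageStartupMessages(library(traitshift))

env <- read_env_stack("results/data/env_current/stack.yml")
traits <- read_traits("results/data/traits_imputed.csv")

abund <- function(scn) {
  files <- list.files("results/abundance", pattern = paste0("__", scn, ".asc$"))
  sp <- sub("__.*$", "", files)
  setNames(lapply(file.path("results/abundance", files), read_grid), sp)
}
ab_cur <- abund("current"); ab_fut <- abund("future")

heights <- setNames(traits$CH, traits$species_id)
forms <- setNames(ifelse(traits$pfg == "tree", "tree", "non-tree"),
                  traits$species_id)
pool <- intersect(c(layer_pool(traits, "field"), layer_pool(traits, "shrub")),
                  names(ab_cur))
sh_cur <- relative_biomass(ab_cur[pool], heights, forms)
sh_fut <- relative_biomass(ab_fut[pool], heights, forms)

change <- build_change_matrix(sh_cur, sh_fut)
K <- min(5L, nrow(unique(change$X)))
part <- kmeans_regions(change$X, K = K, n_init = 10, seed = 20260921L)
cat(sprintf("k-means: K = %d, SSE = %.4f, region sizes %s\n",
            K, part$sse, paste(table(part$labels), collapse = "/")))

rgrid <- region_grid(part, change)
write_grid(rgrid, "results/regions.asc", cellsize = env$cellsize,
           origin = env$origin)
write.csv(data.frame(region = seq_len(K), part$centers),
          "results/region_centroids.csv", row.names = FALSE)

summaries <- list()
for (f in list.files("results/cwmt", pattern = "__delta.asc$")) {
  d <- read_grid(file.path("results/cwmt", f))
  s <- regional_summary(d, rgrid)
  s$surface <- sub("__delta.asc$", "", f)
  summaries[[f]] <- s
}
summaries <- do.call(rbind, c(summaries, list(make.row.names = FALSE)))
write.csv(summaries, "results/regional_summaries.csv", row.names = FALSE)
cat("regional summaries (first rows):\n")
print(head(summaries), row.names = FALSE)
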