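#!/usr/bin/env Rscript
# Stage 2: fit the three model families to the full survey table --
# the two-stage density GAM (Tweedie encounter rate with log effective-area
# offset x lognormal group size), the binomial presence/absence GAM, and
# the screened boosted regression tree. Writes model metadata and the BRT
# leaderboard under results/.

suppressPackageStartupMessages(library(cetsdm))
segments <- read_segments_csv("results/segments.csv")

dens_spec <- make_model_spec("encounter_rate", terms = c("sst", "depth"),
                             interaction = "lon:lat")
dens <- prune_terms(fit_count_model(segments, dens_spec))
grp <- fit_group_size_model(segments)
cat("Density GAM:\n"); print(dens)

pres_spec <- make_model_spec("presence", terms = c("sst", "depth"),
                             interaction = "lon:lat")
pres <- prune_terms(fit_presence_gam(segments, pres_spec))
cat("Presence/absence GAM:\n"); print(pres)

bc <- brt_config(min_trees = 300, n_iterations = 5, cv_folds = 5,
                 seed = 20260902)
brt <- select_best_brt(segments, bc)
cat("Best BRT:\n"); print(brt)

sdm_save(dens, "results/density_gam.json")
sdm_save(grp, "results/group_size_gam.json")
sdm_save(pres, "results/presence_gam.json")
write_brt_influence_csv(brt, "results/brt_influence.csv")
write_brt_json(brt, "results/brt_model.json")
write.csv(brt$leaderboard, "results/brt_leaderboard.csv", row.names = FALSE)
saveRDS(list(dens = dens, grp = grp, pres = pres, brt = brt),
        "scratch/fits.rds") # scratch object for later stages
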