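#!/usr/bin/env Rscript
# Parcel-level group statistics on synthetic imaging-derived feature tables:
# hemisphere pooling, z-scoring against controls, covariate-adjusted GLM
# contrasts with max-statistic permutation FWE, and the multivariate
# Mahalanobis / Hotelling analyses.

library(rmfm)

out <- file.path("results", "stats")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

study <- standard_study(seed = 1, n_subjects = 20)
parc <- study$parcellation

# FA-like modality: planted 1-SD decrease in TLE limbic regions plus a
# milder somatomotor effect; GE carries a small diffuse default-network dip
ft <- generate_feature_tables(
  parc,
  effects = list(TLE = c(limbic = -1, somatomotor = -0.6),
                 GE = c(default = -0.3)),
  n_per_group = c(HC = 20, GE = 20, TLE = 20), seed = 2001)
ft <- zscore_vs_controls(flip_to_ipsilateral(ft))

for (pair in list(c("TLE", "HC"), c("GE", "HC"), c("TLE", "GE"))) {
  res <- permutation_fwe(ft, terms = c("sex", "age"), contrast = pair,
                         n_perm = 2000, seed = 77)
  write.table(res, file.path(out, paste0(pair[1], "_vs_", pair[2], ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- res$region_id[res$p_fwe < 0.05]
  nets <- parc$network[match(sig, parc$region_id)]
  message(sprintf("%s vs %s: %d regions at p_FWE < 0.05 (%s)",
                  pair[1], pair[2], length(sig),
                  if (length(sig)) paste(sort(unique(nets)), collapse = ", ")
                  else "none"))
}

# multivariate patient-vs-control dissimilarity on two diffusion-like
# features per subject (means over limbic regions of two modalities)
fa <- ft
md <- generate_feature_tables(
  parc, effects = list(TLE = c(limbic = 1)),
  n_per_group = c(HC = 20, GE = 20, TLE = 20), seed = 2002)
md <- zscore_vs_controls(flip_to_ipsilateral(md))
limbic <- parc$network == "limbic"
feat <- cbind(fa = rowMeans(fa$values[, limbic]),
              md = rowMeans(md$values[, limbic]))
grp <- fa$covariates$group
ctl <- feat[grp == "HC", ]
dists <- apply(feat, 1, mahalanobis_d, controls = ctl)
ht <- hotelling_t2(feat[grp == "TLE", ], feat[grp == "HC", ])
message(sprintf("mean Mahalanobis distance: HC %.2f, GE %.2f, TLE %.2f",
                mean(dists[grp == "HC"]), mean(dists[grp == "GE"]),
                mean(dists[grp == "TLE"])))
message(sprintf("Hotelling T2 (TLE vs HC): T2 = %.1f, F = %.1f, p = %.2g",
                ht$T2, ht$F, ht$p))
write.table(data.frame(subject_id = fa$covariates$subject_id, group = grp,
                       mahalanobis = dists),
            file.path(out, "mahalanobis.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message("statistics written to ", out)
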