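#!/usr/bin/env Rscript
# Contrast fitted regional parameters between cohorts, normalised by the
# within-network SD of the differences, and check the planted dissociation:
# TLE should show lower subcortical input and higher recurrent
# excitation-inhibition than HC in limbic/somatomotor networks, GE higher
# subcortical input with w essentially unchanged.

library(rmfm)

fits_dir <- file.path("results", "fits")
out <- file.path("results", "contrasts")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

study <- standard_study(seed = 1, n_subjects = 20)
parc <- study$parcellation

read_fit <- function(grp) {
  x <- jsonlite::read_json(file.path(fits_dir, paste0("fit_", grp, ".json")),
                           simplifyVector = TRUE)
  structure(list(params = list(G = x$G, sigma = x$sigma, w = x$w, I = x$I),
                 parcellation = parc), class = "fit_result")
}
fits <- lapply(c(HC = "HC", GE = "GE", TLE = "TLE"), read_fit)

for (pair in list(c("TLE", "HC"), c("GE", "HC"), c("TLE", "GE"))) {
  tab <- contrast_ready_params(fits[[pair[1]]], fits[[pair[2]]])
  tab$delta_w <- as.numeric(parameter_contrast(tab$w_a, tab$w_b, tab$network))
  tab$delta_I <- as.numeric(parameter_contrast(tab$I_a, tab$I_b, tab$network))
  write.table(tab, file.path(out, paste0(pair[1], "_vs_", pair[2], ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sel <- tab$network %in% c("limbic", "somatomotor")
  message(sprintf(
    "%s vs %s: limbic/somatomotor mean delta_w = %+.2f, mean delta_I = %+.2f",
    pair[1], pair[2], mean(tab$delta_w[sel]), mean(tab$delta_I[sel])))
}
message("contrast tables written to ", out)
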