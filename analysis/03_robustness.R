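#!/usr/bin/env Rscript
# Stage 3: robustness battery on the detected clusters.
#
# For each section whose cluster survived the Holm correction:
#   - a logistic regression predicting cluster membership from the coded
#     autism risk factors (composition check: is the cluster an artifact of
#     who conceives in those weeks?),
#   - logistic regressions of preterm birth and low birth weight on
#     cluster membership (outcome check).
# Then the assortative-conception sibling test (circular day-of-year
# proximity at 15/22.5/30/45 days for siblings of in-cluster cases vs
# in-cluster controls) and the gestational-age profile.

source("analysis/_common.R")

cfg <- cohort_config()
cohort <- filter_cohort(load_or_generate_cohort(), cfg$start, cfg$end)

if (!file.exists(paths$scan)) stop("run analysis/02_scan.R first")
scan <- read.csv(paths$scan, stringsAsFactors = FALSE)
sig <- scan[scan$reject_holm & !is.na(scan$cluster_start), ]
message(nrow(sig), " post-Holm significant cluster(s)")

comp_rows <- list(); out_rows <- list()
for (i in seq_len(nrow(sig))) {
  sec <- list(start = as.Date(substr(sig$section[i], 1, 10)),
              end = as.Date(substr(sig$section[i], 14, 23)))
  cl <- list(start = as.Date(sig$cluster_start[i]),
             end = as.Date(sig$cluster_end[i]))
  insec <- cohort[cohort$conception_date >= sec$start &
                    cohort$conception_date < sec$end, ]
  labels <- cluster_membership(insec, cl, sec)
  message(sprintf("section %s: %d in cluster of %d", sig$section[i],
                  sum(labels), length(labels)))
  comp <- composition_model(insec, labels)
  comp$section <- sig$section[i]
  comp_rows[[i]] <- comp
  om <- outcome_models(insec, labels)
  for (nm in names(om)) if (!is.null(om[[nm]])) {
    om[[nm]]$outcome <- nm
    om[[nm]]$section <- sig$section[i]
    out_rows[[length(out_rows) + 1L]] <- om[[nm]]
  }
}
if (length(comp_rows) > 0) {
  comp_all <- do.call(rbind, comp_rows)
  write.csv(comp_all, "results/table3_composition.csv", row.names = FALSE)
  message("composition odds ratios -> results/table3_composition.csv")
  print(comp_all[comp_all$term != "(Intercept)",
                 c("section", "term", "or", "ci_lo", "ci_hi", "p")],
        digits = 3)
}
if (length(out_rows) > 0) {
  out_all <- do.call(rbind, out_rows)
  write.csv(out_all, "results/table4_outcomes.csv", row.names = FALSE)
  message("outcome odds ratios -> results/table4_outcomes.csv")
  print(out_all[out_all$term == "membership",
                c("section", "outcome", "or", "ci_lo", "ci_hi", "p")],
        digits = 3)
}

# Assortative-conception sibling test, restricted to sibling pairs whose
# index child was conceived in a detected cluster period.
siblings <- load_or_generate_siblings(cohort)
clusters <- data.frame(start = as.Date(sig$cluster_start),
                       end = as.Date(sig$cluster_end))
pairs <- sibling_pairs(cohort, siblings, clusters)
message(sprintf("sibling pairs: %d total, %d with an in-cluster index child",
                nrow(pairs), sum(pairs$index_in_cluster)))
assort <- assortative_test(pairs)
write.csv(assort, "results/table5_assortative.csv", row.names = FALSE)
message("assortative-conception test -> results/table5_assortative.csv")
print(assort, digits = 3)

gp <- gestational_age_profile(cohort)
write.csv(gp$profile, "results/fig1_gestational_profile.csv",
          row.names = FALSE)
message(sprintf(paste0("gestational ages: %.1f%% of cases and %.1f%% of all",
                       " births preterm -> results/fig1_gestational_profile.csv"),
                100 * gp$preterm_case_frac, 100 * gp$preterm_all_frac))

write_manifest("robustness", list(
  significant_sections = nrow(sig),
  sibling_pairs_in_cluster = sum(pairs$index_in_cluster)
))
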