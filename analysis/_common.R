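# Shared plumbing for the numbered analysis drivers: master seed, file
# locations, and deterministic regeneration of the synthetic cohort so each
# script can run standalone. All randomness flows from one master seed
# through fixed per-stage offsets.

suppressPackageStartupMessages(library(seasonscan))

master_seed <- {
  a <- commandArgs(trailingOnly = TRUE)
  i <- match("--seed", a)
  if (!is.na(i) && length(a) > i) as.integer(a[i + 1]) else 20260929L
}

paths <- list(
  cohort = "scratch/cohort.csv",
  siblings = "scratch/siblings.csv",
  results = "results",
  scan = "results/table2_scan_sections.csv",
  manifest = "results/run_manifest.json"
)
dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cohort_config <- function() sim_config(seed = master_seed)

load_or_generate_cohort <- function() {
  if (file.exists(paths$cohort)) {
    message("reading cohort from ", paths$cohort)
    read_cohort(paths$cohort)
  } else {
    message("generating synthetic cohort (seed ", master_seed, ")")
    generate_cohort(cohort_config())
  }
}

load_or_generate_siblings <- function(cohort) {
  if (file.exists(paths$siblings)) {
    read_cohort(paths$siblings)
  } else {
    generate_siblings(cohort, cohort_config())
  }
}

write_manifest <- function(stage, extra = list()) {
  m <- c(list(stage = stage, master_seed = master_seed,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              r_version = R.version.string,
              seasonscan_version =
                as.character(utils::packageVersion("seasonscan"))),
         extra)
  path <- sub("\\.json$", paste0("_", stage, ".json"), paths$manifest)
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE)
  message("manifest: ", path)
}
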