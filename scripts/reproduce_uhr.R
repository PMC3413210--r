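#!/usr/bin/env Rscript
# Optional reproduction of the ultrahigh-resolution cohort audit.
#
# This is NOT part of the offline acceptance report: it downloads 18
# deposited entries from the PDB (network required) and audits them with
# the deposited-h preset, printing pooled clash and severe-clash
# frequencies per 100 residues alongside the per-structure counts.
#
# Usage: Rscript scripts/reproduce_uhr.R [--dir cache_dir]

suppressPackageStartupMessages(library(clashaudit))

ids <- c("1byz", "1dy5", "1i1w", "1m40", "1muw", "1p9g", "1ucs", "1vyr",
         "1yk4", "2b97", "2h5c", "2vb1", "2wur", "2xu3", "3a38", "3g63",
         "3ip0", "3mi4")

args <- commandArgs(trailingOnly = TRUE)
dir <- if (length(args) >= 2 && args[1] == "--dir") args[2] else "uhr_cache"
dir.create(dir, showWarnings = FALSE, recursive = TRUE)

paths <- character(0)
for (id in ids) {
  f <- file.path(dir, paste0(id, ".pdb"))
  if (!file.exists(f)) {
    url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
    ok <- tryCatch({
      utils::download.file(url, f, quiet = TRUE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) { message("could not fetch ", id); next }
  }
  paths <- c(paths, f)
}

b <- batch_audit(paths, preset = "deposited-h")
print(b$table)
cat(sprintf("pooled: %.1f clashes / %.1f severe per 100 residues (%d residues)\n",
            b$cohort$clashes_per_100, b$cohort$severe_per_100,
            b$cohort$residue_count))
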