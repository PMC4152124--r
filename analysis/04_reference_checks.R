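#!/usr/bin/env Rscript
# Stage 4: desk-scale checks against the published reference counts.
#
# The source claims database is inaccessible, but every percentage,
# partition sum and trend delta printed in the published tables is an
# arithmetic consequence of the printed counts. This stage recomputes all
# of them through the package's aggregation arithmetic and reports
# pass/fail at the printed precision (one decimal, half-away-from-zero).

suppressPackageStartupMessages(library(offlabelr))

out_dir <- "results/reference"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

checks <- reference_checks()
readr::write_csv(checks, file.path(out_dir, "reference_checks.csv"))

cat(sprintf("%d/%d reference checks reproduce the printed value\n",
            sum(checks$pass), nrow(checks)))
key <- c("pct_offlabel_R03AC02", "pct_offlabel_R03CC63",
         "pct_offlabel_class_Inhaled bronchodilative drugs",
         "total_offlabel_partition", "total_prescriptions",
         "breakdown_pct_R03AC02_Acute_bronchitis",
         "breakdown_pct_R03CC63_Acute_upper_respiratory_infections",
         "trend_relative_pct_R03AC02", "trend_relative_pct_R03BC01")
print(as.data.frame(checks[checks$check %in% key, ]))
if (!all(checks$pass)) stop("reference arithmetic mismatch")
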