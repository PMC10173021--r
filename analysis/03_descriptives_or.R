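#!/usr/bin/env Rscript
# Descriptive characteristics by SEP group and crude/adjusted odds ratios of
# survival to discharge and good neurological recovery (NHI Q1 reference).
suppressPackageStartupMessages(library(ohcapath))

comp <- binarize_sep(read_registry("results/registry_completed.csv"))
desc <- descriptive_table(comp)
utils::write.csv(desc, "results/table1_descriptives.csv", row.names = FALSE)
cat("descriptive table:", nrow(desc), "rows ->",
    "results/table1_descriptives.csv\n")

for (oc in c("surv_discharge", "good_neuro")) {
  crude <- adjusted_or_table(comp, oc, confounders = character())
  adj <- adjusted_or_table(comp, oc)
  out <- rbind(cbind(model = "crude", crude), cbind(model = "adjusted", adj))
  utils::write.csv(out, sprintf("results/or_%s.csv", oc), row.names = FALSE)
  cat(sprintf("%s: adjusted OR (MA vs NHI Q1) = %.2f (%.2f-%.2f)\n", oc,
              adj$or[adj$level == "MA"], adj$lcl[adj$level == "MA"],
              adj$ucl[adj$level == "MA"]))
}
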