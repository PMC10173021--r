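#!/usr/bin/env Rscript
# Baron-Kenny mediator screening: adjusted exposure-mediator and
# mediator-outcome associations for every candidate, in the full population
# and in the admitted-only subset (which adds CAG and TTM).
suppressPackageStartupMessages(library(ohcapath))

comp <- binarize_sep(read_registry("results/registry_completed.csv"))
full_cand <- c("public_location", "witnessed", "bystander_cpr",
               "bystander_aed", "rti_lt8", "shockable", "ed_level12")
scr <- screen_mediators(comp, full_cand)
utils::write.csv(scr, "results/mediator_screen_all.csv", row.names = FALSE)
cat("full population mediators:",
    paste(scr$mediator[scr$is_mediator], collapse = ", "), "\n")

adm <- comp[comp$surv_admission == 1L, ]
scr_adm <- screen_mediators(adm, c(full_cand, "cag", "ttm"))
utils::write.csv(scr_adm, "results/mediator_screen_admitted.csv",
                 row.names = FALSE)
cat("admitted-only mediators:",
    paste(scr_adm$mediator[scr_adm$is_mediator], collapse = ", "), "\n")
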