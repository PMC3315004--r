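#!/usr/bin/env Rscript
# Stage 5 - relate coupling estimates to age and to TMS-measured
# interhemispheric inhibition.
#
# For every intrinsic connection, regress the BMA coupling on age, classify
# the age pattern (type 1: inhibition crossing into facilitation; type 2:
# facilitation strengthening), and test the left-to-right M1 coupling
# against a 1000-shuffle permutation null. The TMS linkage is checked by
# correlating the same coupling with each subject's change in IHI.

suppressPackageStartupMessages(library(gripdcm))

meta <- jsonlite::read_json("results/cohort_meta.json", simplifyVector = TRUE)
tab <- read.table("results/bma_parameters.tsv", sep = "\t", header = TRUE,
                  check.names = FALSE)
a_cols <- grep("^A\\[", names(tab), value = TRUE)

age_cor <- do.call(rbind, lapply(a_cols, function(cn) {
  cr <- correlate(tab$age, tab[[cn]])
  data.frame(connection = cn, r2 = cr$r2, p = cr$p, slope = cr$slope,
             pattern = classify_pattern(tab[[cn]], tab$age))
}))
write.table(age_cor, "results/age_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

key <- "A[M1_R,M1_L]"
cr_age <- correlate(tab$age, tab[[key]])
null_q95 <- quantile(permutation_null_r2(tab$age, tab[[key]], 1000,
                                         seed = meta$seed), 0.95)
cr_ihi <- correlate(tab$change_ihi, tab[[key]])

cat(sprintf("%d connections tested against age (no multiplicity correction):\n",
            nrow(age_cor)))
print(age_cor, row.names = FALSE, digits = 3)
cat(sprintf("\nLM1->RM1 vs age: slope %.4g /s/yr, r2 = %.2f (perm null q95 = %.2f)\n",
            cr_age$slope, cr_age$r2, null_q95))
cat(sprintf("LM1->RM1 vs change-IHI: r2 = %.2f, p = %.3g\n",
            cr_ihi$r2, cr_ihi$p))

jsonlite::write_json(
  list(n_tests = nrow(age_cor),
       lm1_rm1_age = unclass(cr_age), perm_null_q95 = unname(null_q95),
       lm1_rm1_change_ihi = unclass(cr_ihi),
       patterns = setNames(as.list(age_cor$pattern), age_cor$connection)),
  "results/group_correlations.json", auto_unbox = TRUE, digits = NA)
cat("Report written to results/group_correlations.json\n")
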