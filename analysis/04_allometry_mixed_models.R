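#!/usr/bin/env Rscript
# Allometric adjustment and mixed-model inference: pooled log10-log10
# regressions of kype length/height on fork length (residuals = AKL/AKH),
# gonadosomatic residuals, backward-eliminated REML models with type-III
# Satterthwaite ANOVA, and Tukey-adjusted strain/SW marginal means.

library(kypemorph)

rec <- read_phenotypes("results/synthetic_cohort/phenotypes.csv")
adj <- adjusted_traits(rec)
for (tr in c("AKL", "AKH")) {
  f <- adj$fits[[tr]]
  cat(sprintf("%s regression: slope %.3f, R2 = %.3f, F(1,%d) = %.0f\n",
              tr, f$slope, f$r_squared, f$df[2], f$f_statistic))
}
write.csv(adj$table, "results/adjusted_traits.csv", row.names = FALSE)

d <- lmm_data(rec, adj = adj)
tk <- usable_model_terms(d)
for (resp in c("AKL", "AKH")) {
  sel <- backward_eliminate(build_formula(resp, tk$fixed, tk$random), d)
  cat(sprintf("\nselected model for %s: %s\n", resp,
              paste(deparse(sel$formula), collapse = " ")))
  an <- type3_anova(sel$fit)
  print(an, digits = 3)
  write.csv(an, sprintf("results/anova_%s.csv", resp), row.names = FALSE)
  write.csv(sel$trace, sprintf("results/elimination_%s.csv", resp),
            row.names = FALSE)
  for (fac in intersect(c("strain", "SW"), fixed_terms(sel$formula))) {
    em <- emmeans_tukey(sel$fit, fac)
    cat(sprintf("estimated marginal means of %s for %s:\n", resp, fac))
    print(em$emmeans, digits = 3)
    write.csv(em$emmeans, sprintf("results/emm_%s_%s.csv", resp, fac),
              row.names = FALSE)
    write.csv(em$pairs, sprintf("results/emm_pairs_%s_%s.csv", resp, fac),
              row.names = FALSE)
  }
}
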