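#!/usr/bin/env Rscript
# Stage 3: nitrification activity.
#
# From the stage-1 microcosm chemistry: net nitrification rates per soil
# and treatment, percent inhibition by acetylene, and a one-way ANOVA (on
# the per-replicate NO3- accumulations) testing the treatment effect, at
# the 5% significance level. Also reports soil C/N ratios from the
# physicochemical characterization. Outputs: results/rates.tsv,
# results/anova.tsv.

suppressPackageStartupMessages(library(nsip))

chem <- read_chem_table("results/chemistry.tsv")

rates <- do.call(rbind, c(lapply(
  split(chem, interaction(chem$soil, chem$treatment, chem$replicate,
                          drop = TRUE)),
  function(d) {
    d <- d[order(d$day), ]
    data.frame(soil = d$soil[1], treatment = d$treatment[1],
               replicate = d$replicate[1],
               delta_no3 = d$no3_mg_kg[nrow(d)] - d$no3_mg_kg[1],
               rate = net_nitrification_rate(d$no3_mg_kg[1],
                                             d$no3_mg_kg[nrow(d)],
                                             d$day[nrow(d)] - d$day[1]))
  }), make.row.names = FALSE))

anova_rows <- list()
for (soil in unique(rates$soil)) {
  r <- rates[rates$soil == soil, ]
  urea <- r$delta_no3[r$treatment == "15N-urea"]
  c2h2 <- r$delta_no3[r$treatment == "15N-urea+C2H2"]
  inhib <- inhibition_percent(mean(c2h2), mean(urea))
  aov_res <- one_way_anova(list(urea = urea, c2h2 = c2h2))
  cat(sprintf(
    "%s soil: net rate %.2f mg N/kg/d (urea), C2H2 inhibition %.1f%%, ANOVA F=%.1f p=%.2g%s\n",
    soil, mean(r$rate[r$treatment == "15N-urea"]), inhib, aov_res$f,
    aov_res$p, if (aov_res$significant) " *" else ""))
  anova_rows[[soil]] <- data.frame(
    soil = soil, inhibition_percent = inhib, f = aov_res$f, p = aov_res$p,
    df_between = aov_res$df_between, df_within = aov_res$df_within,
    significant = aov_res$significant)
}

# soil characterization: C/N from total carbon and nitrogen (g/kg)
cat(sprintf("C/N: acidic %.2f, neutral %.2f\n",
            cn_ratio(1.89, 0.16), cn_ratio(5.50, 0.30)))

write.table(rates, "results/rates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(do.call(rbind, c(anova_rows, make.row.names = FALSE)),
            "results/anova.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/rates.tsv and results/anova.tsv\n")
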