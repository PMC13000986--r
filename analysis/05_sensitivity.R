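#!/usr/bin/env Rscript

# Step 5 — sensitivity analyses.
#
# (a) Leave-one-species-out refits for the three most-studied species in
#     each role (host plant, inducing herbivore, subsequent herbivore);
# (b) the binary-outcome validation: log odds ratios for survival and
#     choice records, fitted with the same multilevel machinery;
# (c) a phylogeny-augmented overall model per response category, adding a
#     plant-taxon random intercept correlated by a (here simulated)
#     phylogeny — one phylogeny at a time.

library(seqherb)

ds <- read_dataset("results/synthetic_dataset.csv")
es <- add_derived_moderators(suppressWarnings(compute_effect_sizes(ds)))
g <- es[es$metric == "hedges_g", ]
dir.create("results/sensitivity", showWarnings = FALSE, recursive = TRUE)

rows <- list()
for (role in c("plant", "inducer", "subsequent")) {
  ranked <- rank_species_by_representation(g, role)
  cat(sprintf("Most-studied %s species: %s\n", role,
              paste(sprintf("%s (%.1f%%)", head(ranked$species, 3),
                            head(ranked$share, 3)), collapse = ", ")))
  for (sp in head(ranked$species, 3)) {
    ex <- leave_species_out(g, sp, role)
    rows[[paste(role, sp)]] <- data.frame(
      role = role, species = sp, share = ex$share_of_observations,
      estimate = unname(ex$fit$beta[1]), delta = ex$delta_vs_full,
      ci_excludes_full = ex$ci_excludes_full)
  }
}
excl <- do.call(rbind, rows)
write.table(excl, "results/sensitivity/species_exclusions.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("No exclusion shifted the pooled estimate outside its refit CI:",
    !any(excl$ci_excludes_full), "\n")

lv <- lor_validation(ds)
print(lv)
lor_tab <- do.call(rbind, lapply(names(lv$fits), function(nm) {
  f <- lv$fits[[nm]]
  data.frame(class = nm, lor = unname(f$beta[1]),
             ci_low = unname(f$ci_low[1]), ci_high = unname(f$ci_high[1]),
             k = f$k, i2 = f$i2)
}))
write.table(lor_tab, "results/sensitivity/lor_validation.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

tree <- simulate_tree(unique(g$plant_species), seed = 1)
R <- correlation_from_tree(tree)
cat("\nPhylogeny-augmented overall models (plant tree):\n")
for (cat_ in unique(g$response_category)) {
  sub <- g[g$response_category == cat_, ]
  plain <- fit_multilevel(sub$value, sub$variance, data = sub)
  ph <- fit_multilevel(sub$value, sub$variance, data = sub,
                       phylo = list(taxon = "plant_species", corr = R))
  cat(sprintf(
    "  %-22s g = %6.3f (plain %6.3f), CI width %.3f (plain %.3f), sigma2_taxon = %.3f\n",
    cat_, unname(ph$beta[1]), unname(plain$beta[1]),
    unname(ph$ci_high[1] - ph$ci_low[1]),
    unname(plain$ci_high[1] - plain$ci_low[1]),
    unname(ph$vc["sigma2_taxon"])))
}
cat("Wrote results/sensitivity/\n")
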