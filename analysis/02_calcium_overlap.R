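#!/usr/bin/env Rscript
# Calcium-imaging responder overlap on the four worked-example populations:
# dissociated gut epithelial sensory cells (ratiometric), cultured vagal
# sensory neurons (ratiometric, almost fully non-responsive), in vivo vagal
# neurons (single-channel dF/F) and coculture pairs (externally recorded
# excitatory currents).

library(gutsense)

fmt <- function(v, label) {
  data.frame(
    population = label, n_viable = v$n_viable, n_responders = v$n_responders,
    a_only = v$counts[["a_only"]], b_only = v$counts[["b_only"]],
    both = v$counts[["both"]], neither = v$counts[["neither"]],
    pct_a_only_resp = round(v$pct_of_responders[["a_only"]], 1),
    pct_b_only_resp = round(v$pct_of_responders[["b_only"]], 1),
    pct_both_resp = round(v$pct_of_responders[["both"]], 1),
    pct_a_only_viable = round(v$pct_of_viable[["a_only"]], 1),
    pct_b_only_viable = round(v$pct_of_viable[["b_only"]], 1),
    row.names = NULL)
}

# dissociated epithelial cells: 21 KCl-only / 14 / 4 / 8
epi <- gen_calcium_population(21, 14, 4, 8, 0, seed = 7)
v_epi <- venn_summary(classify_population(epi$traces), "glucose", "sucralose")

# cultured vagal neurons: 58 of 59 respond to nothing
nod <- gen_calcium_population(58, 1, 0, 0, 0, seed = 8)
v_nod <- venn_summary(classify_population(nod$traces), "glucose", "sucralose")

# in vivo vagal neurons: 22 sucrose-only, 12 sucralose-only of 54
viv <- gen_dff_population(20, 22, 12, 0, seed = 4)
v_viv <- venn_summary(classify_dff_population(viv$traces),
                      "sucrose", "sucralose")

# coculture pairs: 8 / 4 / 6 of 18 (currents recorded outside this package)
v_co <- venn_summary(
  response_calls_from_logical(rep(c(TRUE, FALSE, TRUE), c(8, 4, 6)),
                              rep(c(FALSE, TRUE, TRUE), c(8, 4, 6)),
                              "glucose", "sucralose"),
  "glucose", "sucralose")

tab <- rbind(fmt(v_epi, "epithelial_dissociated"),
             fmt(v_nod, "nodose_in_vitro"),
             fmt(v_viv, "nodose_in_vivo"),
             fmt(v_co, "coculture_pairs"))

dir.create("results", showWarnings = FALSE)
write.table(tab, "results/calcium_overlap.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

for (v in list(v_epi, v_nod, v_viv, v_co)) print(v)
cat(sprintf("nodose in vitro non-responsive: %.1f%%\n",
            100 * v_nod$counts[["neither"]] / v_nod$n_viable))
cat("wrote results/calcium_overlap.tsv\n")
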