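#!/usr/bin/env Rscript
# Stage 5: carbon and nitrogen mass-flow networks.
#
# Attaches the targeted mM quantifications to the cross-feeding edges
# (consumed amount = concentration at the first sampled time minus the
# minimum over the consumer's culture in the producer's spent medium),
# converts each exchange to element-mmol/L by multiplying by the C or N
# atom count of the molecular formula, and drops edges at or below the
# 0.1 element-mmol/L display cutoff.

library(crossfeedr)

out <- "results/analysis"
edges <- read_tsv(file.path(out, "edges.tsv"))
conc <- read_concentration_table("results/data/concentrations_mM.tsv")
db <- read_formula_db(system.file("extdata", "formula_db.tsv",
                                  package = "crossfeedr"))

edges <- quantify_edges(edges, conc)
message(sum(!is.na(edges$consumed_mM)), " of ", nrow(edges),
        " edges quantified in mM")

for (el in c("C", "N")) {
  net <- suppressWarnings(build_element_network(edges, db, el,
                                                min_flow = 0.1))
  write_tsv(net$edges, file.path(out, paste0("flows_", el, ".tsv")))
  write_tsv(net$totals, file.path(out, paste0("flow_totals_", el, ".tsv")))
  if (nrow(net$edges) > 0) {
    write_network_graphml(net$edges,
                          file.path(out, paste0("network_", el, ".graphml")))
  }
  message(sprintf("%s network: %d edges above cutoff, total flow %.1f %s-mmol/L",
                  el, nrow(net$edges), sum(net$edges$flow), el))
  tot <- net$totals[order(-net$totals$out_flow), ]
  for (i in seq_len(min(3, nrow(tot)))) {
    message(sprintf("  top provider %-20s out = %5.1f  in = %5.1f",
                    tot$species[i], tot$out_flow[i], tot$in_flow[i]))
  }
}
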