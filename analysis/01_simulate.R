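#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data.
#
# Builds a six-member gut consortium with hand-specified cross-feeding
# biology (a succinate/malate/fumarate producer, an arginine provider, a
# nucleobase provider, a promiscuous consumer, two lactic-acid-bacteria-like
# members), simulates every monoculture in fresh medium and in every other
# member's spent medium (1:1 with fresh), simulates a rich-medium dilution
# series for threshold calibration, and derives a targeted quantification
# table (mM) for a subset of cross-fed metabolites. All downstream stages
# work only from the tables written here.

library(crossfeedr)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- community_spec(
  species = c("B. caecimuris", "M. intestinale", "F. plautii",
              "C. clostridioforme", "L. reuteri", "E. faecalis"),
  growth = list(
    "B. caecimuris"      = c(A = 0.05, K = 1.8, r = 0.9, t0 = 5),
    "M. intestinale"     = c(A = 0.05, K = 1.3, r = 0.7, t0 = 6),
    "F. plautii"         = c(A = 0.05, K = 1.6, r = 1.1, t0 = 4),
    "C. clostridioforme" = c(A = 0.05, K = 1.5, r = 1.0, t0 = 5),
    "L. reuteri"         = c(A = 0.05, K = 1.1, r = 0.8, t0 = 6),
    "E. faecalis"        = c(A = 0.05, K = 1.4, r = 1.2, t0 = 4)),
  # the rich medium also contains background levels of several metabolites
  # that community members secrete, as a brain-heart-infusion-type medium
  # would; this lets fresh-medium monocultures reveal consumption of other
  # members' products
  medium = c(glucose = 2000, cysteine = 400, histidine = 300,
             leucine = 350, uracil = 150, glutamate = 500,
             succinate = 120, malate = 60, arginine = 90, xanthine = 60),
  interactions = list(
    "B. caecimuris" = list(
      consume = c(glucose = 0.9),
      secrete = c(succinate = 600, malate = 120, fumarate = 80)),
    "M. intestinale" = list(
      consume = c(glucose = 0.7, leucine = 0.6),
      secrete = c(arginine = 400, alanine = 150)),
    "F. plautii" = list(
      consume = c(glutamate = 0.8, succinate = 0.7),
      secrete = c(xanthine = 180, hypoxanthine = 150, butyrate = 200)),
    "C. clostridioforme" = list(
      consume = c(succinate = 0.85, cysteine = 0.8, glucose = 0.6,
                  histidine = 0.5, xanthine = 0.6),
      secrete = c(butyrate = 250, acetate = 300)),
    "L. reuteri" = list(
      consume = c(malate = 0.8, arginine = 0.7, glucose = 0.5,
                  uracil = 0.5),
      secrete = c(lactate = 500, ornithine = 200)),
    "E. faecalis" = list(
      consume = c(arginine = 0.6, fumarate = 0.7),
      secrete = c(acetate = 250, formate = 120))),
  noise_cv = 0.05,
  times = seq(1, 24, length.out = 10),
  replicates = 3,
  seed = 42)

sim <- simulate_consortium(spec)
write_tsv(sim$table, file.path(out, "ion_timecourses.tsv"))
write_ground_truth(sim$truth, file.path(out, "ground_truth_edges.tsv"))
message(nrow(sim$table), " sample rows for ",
        length(unique(sim$table$medium)), " media; ",
        nrow(sim$truth$edges), " true cross-feeding edges")

# rich-medium dilution series (1/dilution response + background ions)
set.seed(42)
dil <- simulate_dilution_series(
  medium_ions = setNames(runif(12, 2e3, 2e5), paste0("medium_ion", 1:12)),
  background_ions = setNames(runif(4, 200, 1500), paste0("background", 1:4)),
  dilutions = c(20, 40, 80, 160), replicates = 3, noise_cv = 0.03,
  seed = 42)
write_tsv(dil, file.path(out, "dilution_series.tsv"))

# targeted quantification (synthetic): replicate-mean intensities of the
# five LC-MS-quantified metabolites converted to mM with a single response
# factor of 0.02 mM per intensity unit
quantified <- c("succinate", "malate", "fumarate", "arginine", "xanthine")
tab <- sim$table
rows <- do.call(rbind, lapply(split(tab, list(tab$species, tab$medium),
                                    drop = TRUE), function(d) {
  agg <- aggregate(d[quantified], by = list(time_h = d$time_h), FUN = mean)
  do.call(rbind, lapply(quantified, function(m) {
    data.frame(metabolite = m, species = d$species[1], medium = d$medium[1],
               time_h = agg$time_h, conc_mM = agg[[m]] * 0.02)
  }))
}))
write_tsv(rows, file.path(out, "concentrations_mM.tsv"))
message("wrote dilution series and targeted concentrations to ", out)
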