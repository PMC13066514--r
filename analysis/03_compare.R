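#!/usr/bin/env Rscript
# Stage 3: compare genetic differentiation against geography and modelled
# dispersal. F_ST here is synthetic with a known log-linear dependence on
# the stepping-stone dispersal proportion, so the expected outcome is
# known: a clear F_ST-dispersal association, and a geography association
# only insofar as distance correlates with dispersal along the chain.
#
# Outputs (results/): fst.csv, mantel.json.

source(file.path("analysis", "common.R"))

tag <- sprintf("pld%03d", HEADLINE_PLD)
ss_pct <- read_matrix_csv(file.path(RESULTS_DIR,
                                    sprintf("stepping_stone_%s.csv", tag)))
psym <- symmetrize_max(ss_pct / 100)

# restrict to a maximal subset in which every pair is connected in at
# least one direction
conn <- largest_connected_subset(psym)
message(sprintf("%d of %d sites are pairwise connected at PLD %d d",
                length(conn), nrow(psym), HEADLINE_PLD))
psym <- psym[conn, conn]

layout <- study_layout()
fst <- generate_synthetic_fst(psym, a = 0.01, b = 0.005, sd = 0.003,
                              seed = SEED + 1L)
write_matrix_csv(fst, file.path(RESULTS_DIR, "fst.csv"))

geo <- geographic_distance(layout, subset = conn)
dd <- dispersal_to_distance(psym)

tests <- list(
  fst_vs_geography = mantel_test(fst, geo, n_perm = 10000, seed = SEED + 2L),
  fst_vs_dispersal_distance = mantel_test(fst, dd, n_perm = 10000,
                                          seed = SEED + 3L)
)

# outlier-excluded variant: drop the single largest F_ST pair
ut <- which(upper.tri(fst), arr.ind = TRUE)
worst <- ut[which.max(fst[upper.tri(fst)]), ]
worst_pair <- cbind(rownames(fst)[worst[1]], colnames(fst)[worst[2]])
tests$fst_vs_dispersal_excl_outlier <- mantel_excluding_pairs(
  fst, dd, worst_pair, n_perm = 10000, seed = SEED + 4L)

for (nm in names(tests)) {
  t <- tests[[nm]]
  message(sprintf("%s: R = %.3f, p = %.4f%s", nm, t$r, t$p,
                  if (length(t$excluded))
                    paste0(" (excluded ", t$excluded, ")") else ""))
}

jsonlite::write_json(
  lapply(tests, function(x) x[c("r", "p", "n_perm", "tail", "method",
                                "seed", "excluded")]),
  file.path(RESULTS_DIR, "mantel.json"), auto_unbox = TRUE, digits = NA)
message("wrote results/mantel.json")
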