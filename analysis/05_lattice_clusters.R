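#!/usr/bin/env Rscript
# Equilibrium lattice statistics of the cooperative binding model at the pooled
# parameters (K_D = 2.3 nM, omega = 23, n = 26 bp): the occupancy isotherm, a
# grand-canonical Monte-Carlo cross-check of the isotherm on a periodic
# lattice, and mean bound-cluster sizes from the exact transfer matrix at
# several lattice lengths with a Monte-Carlo cross-check.

suppressMessages(library(smtether))
dir.create("results", showWarnings = FALSE)
bp <- binding_params(K_D = 2.3, omega = 23, n = 26)

## isotherm across the titration range
cg <- c(0.001, 0.003, 0.01, 0.03, 0.07, 0.15, 0.3, 1, 2.3, 10)
occ <- mvh_occupancy(cg, bp)
utils::write.table(occ, "results/occupancy_isotherm.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
cat("Occupancy isotherm (n = 26, omega = 23):\n")
print(round(occ[, c("c", "theta")], 4))

## Monte-Carlo cross-check on a 2080-site ring at three concentrations
cat("\nMonte-Carlo occupancy vs isotherm (2080-site periodic lattice):\n")
for (cc in c(0.03, 0.07, 0.15)) {
  mc <- suppressWarnings(
    mean_cluster_size(cc, bp, method = "montecarlo", lattice_sites = 2080,
                      seed = 20260110L, sweeps = 400, chains = 6,
                      boundary = "circular"))
  cat(sprintf("  c = %.2f nM: MC theta %.4f +/- %.4f, isotherm %.4f\n",
              cc, mc$theta, mc$theta_se, mvh_occupancy(cc, bp)$theta))
}

## cluster sizes at c = K_D: strong lattice-length dependence
cat("\nMean bound-cluster size at c = K_D:\n")
cl <- do.call(rbind, lapply(c(78, 260, 1040, 10000), function(M) {
  r <- mean_cluster_size(2.3, bp, method = "exact", lattice_sites = M)
  data.frame(lattice_sites = M, theta = r$theta,
             mean_cluster_size = r$mean_cluster_size)
}))
print(cl, row.names = FALSE)
mc <- suppressWarnings(
  mean_cluster_size(2.3, bp, method = "montecarlo", lattice_sites = 260,
                    seed = 20260111L, sweeps = 1500, chains = 8))
cat(sprintf("Monte-Carlo cross-check at 260 sites: %.2f +/- %.2f (exact %.2f)\n",
            mc$mean_cluster_size, mc$se, cl$mean_cluster_size[cl$lattice_sites == 260]))
cat("On lattices of a few footprints the average cluster holds about two\n")
cat("proteins; in the long-lattice limit at c = K_D it grows to about four.\n")
utils::write.table(cl, "results/cluster_sizes.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

## cluster size at mid-transition occupancies
cat("\nCluster size across the transition (10000-site lattice):\n")
tr <- do.call(rbind, lapply(c(0.03, 0.07, 0.15, 0.3, 2.3), function(cc) {
  r <- mean_cluster_size(cc, bp, method = "exact", lattice_sites = 10000)
  data.frame(c_nM = cc, theta = round(r$theta, 3),
             mean_cluster_size = round(r$mean_cluster_size, 2))
}))
print(tr, row.names = FALSE)
utils::write.table(tr, "results/cluster_vs_concentration.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
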