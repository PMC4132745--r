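#!/usr/bin/env Rscript
# Generates the synthetic single-molecule datasets every downstream analysis
# consumes: optical-tweezers pulling curves (with and without protein-mediated
# loops), the three mechanical titration series, a constant-force compaction
# record, and AFM-style traced molecules with protein-site and bridge
# annotations. Everything is seeded and written in the package's TSV/JSON
# dialects under results/data/.

suppressMessages(library(smtether))
seed <- 20260101L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

wp <- wlc_params(P_ds = 50, B_ds = 0.34, S_ds = 1200)   # bare lambda DNA

## pulling curves: one protein-free, one with three HMO1-stabilized loops
bare <- simulate_fec(wp, n_bp = 48500, noise_F = 0.3, seed = seed)
write_curve(bare, file.path(out, "fec_bare.tsv"))
loops <- data.frame(size_bp = c(600, 500, 650), rupture_pN = c(6, 10, 14))
looped <- simulate_fec(wp, n_bp = 48500, loops = loops, noise_F = 0.3,
                       seed = seed + 1L, concentration = 0.3, pulling_rate = 970)
write_curve(looped, file.path(out, "fec_looped.tsv"))
utils::write.table(attr(looped, "events"),
                   file.path(out, "fec_looped_true_events.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
cat(sprintf("pulling curves: bare (%d pts) and looped (%d true ruptures)\n",
            length(bare$force), nrow(attr(looped, "events"))))

## titration series at the pooled binding parameters
bt <- binding_params(K_D = 2.3, omega = 23, n = 26)
ep <- list(P_D = 50, P_L = 8, B_D = 0.34, B_L = 0.40, F_ov_D = 62, F_ov_L = 68)
cgrid <- c(0, 0.02, 0.05, 0.2, 0.5, 1, 2, 5, 20)
tit <- simulate_titration(bt, ep, cgrid, noise_frac = 0.05, seed = seed + 2L)
for (obs in names(tit))
  utils::write.table(tit[[obs]], file.path(out, sprintf("titration_%s.tsv", obs)),
                     sep = "\t", row.names = FALSE, quote = FALSE)
cat(sprintf("titration series at %d concentrations (truth K_D = 2.3 nM, omega = 23)\n",
            length(cgrid)))

## constant-force compaction record (10 pN hold, protein flowed in at t = 0)
cmp <- simulate_compaction(k = 0.64, amplitude = 800, baseline = 15600,
                           noise = 40, seed = seed + 3L)
utils::write.table(data.frame(time_s = cmp$times, extension_nm = cmp$extensions),
                   file.path(out, "compaction.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
cat(sprintf("compaction record: %d samples, truth k = 0.64 1/s\n", length(cmp$times)))

## AFM traces: 174 protein-bound molecules at p = 39 nm with a protein-site
## kink each, plus 100 bare molecules at p = 59 nm
set.seed(seed + 4L)
bound <- lapply(1:174, function(i) {
  kink <- abs(rnorm(1, mean = 38, sd = 33)) %% 180
  tr <- simulate_chain_2d(p = 39, contour = 1483, step = 2.5,
                          kinks = data.frame(at_nm = 740, angle_deg = kink),
                          molecule_id = sprintf("bound_%03d", i), n_bp = 4361)
  # bridges are annotated, not detected: 70% bridged, two per molecule on average
  nb <- if (runif(1) < 0.7) 1 + rpois(1, 2 / 0.7 - 1) else 0
  if (nb > 0)
    tr$annotations <- rbind(tr$annotations,
                            data.frame(kind = rep("bridge", nb),
                                       start_index = 1, end_index = 2))
  tr
})
bare_tr <- lapply(1:100, function(i)
  simulate_chain_2d(p = 59, contour = 1483, step = 2.5,
                    molecule_id = sprintf("bare_%03d", i), n_bp = 4361))
write_traces(bound, file.path(out, "afm_bound.tsv"),
             file.path(out, "afm_bound_annotations.tsv"))
write_traces(bare_tr, file.path(out, "afm_bare.tsv"))
cat(sprintf("AFM traces: %d protein-bound and %d bare molecules\n",
            length(bound), length(bare_tr)))
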