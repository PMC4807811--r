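#!/usr/bin/env Rscript
# Eigenvalue-weighted overlap of the reference barrel's modes with
# idealized displacements: rigid rotation/translation of the strand barrel
# and the helix bundle, and the five per-helix motions. Low Omega_w means
# the motion is carried by soft modes (favourable).

suppressPackageStartupMessages(library(barreldyn))

src <- "results/synthetic"
out <- "results/overlaps"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

model <- read_pdb_ca(file.path(src, "reference.pdb"))
sse_tab <- utils::read.delim(file.path(src, "sse_annotation.tsv"))
sse <- sse_annotation(
  strands = as.matrix(sse_tab[sse_tab$kind == "strand", c("start", "end")]),
  helices = as.matrix(sse_tab[sse_tab$kind == "helix", c("start", "end")]))

modes <- normal_modes(build_network(model))
ov <- suppressWarnings(overlap_report(modes, model, sse))
utils::write.table(ov, file.path(out, "overlap_scores.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

grp <- ov[ov$sse %in% c("barrel", "bundle"), ]
cat("rigid-group scores (Omega_w):\n")
for (q in seq_len(nrow(grp)))
  cat(sprintf("  %-7s %-18s %8.1f\n", grp$sse[q], grp$motion[q], grp$omega_w[q]))
cat(sprintf("barrel/bundle separation: min barrel %.1f vs max bundle %.1f\n",
            min(grp$omega_w[grp$sse == "barrel"]),
            max(grp$omega_w[grp$sse == "bundle"])))

hx <- ov[ov$sse == "helix", ]
agg <- aggregate(omega_w ~ motion, hx, mean)
agg <- agg[order(agg$omega_w), ]
cat("per-helix motions, mean Omega_w over the 8 helices (soft to stiff):\n")
for (q in seq_len(nrow(agg)))
  cat(sprintf("  %-18s %8.1f\n", agg$motion[q], agg$omega_w[q]))
cat("wrote the 44-row overlap table under", out, "\n")
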