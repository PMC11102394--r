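#!/usr/bin/env Rscript
# Hierarchical clustering of the unity-normalized topic z-maps (complete
# linkage, with Ward as a cross-check), a parallel whole-brain run, and
# reconciliation of the two trees with cerebellar priority.

suppressPackageStartupMessages(library(cbparcel))

db <- read_foci_table("results/db_masked.tsv")
grid <- cerebellar_grid(4)
mask <- grid_mask(grid)
zfiles <- sprintf("results/zmaps/z_%s.nii.gz", db$topics)
zmaps <- lapply(zfiles, read_volume)
names(zmaps) <- db$topics
tm <- topic_matrix(zmaps, mask)

link_c <- hcluster(tm, "complete")
link_w <- hcluster(tm, "ward")
k <- 4
cb <- cut_model(link_c, k)
agree <- rand_index(cb$assignment, cut_model(link_w, k)$assignment)
cat(sprintf("complete vs ward at k=%d: ARI %.2f\n", k, agree$adjusted_rand))

# whole-brain run: same studies, all foci, whole-brain grid
wb_grid <- whole_brain_grid(8)
wb_mask <- array(TRUE, dim = wb_grid$shape)
wb_z <- run_topic_zmaps(db, wb_grid, mask = wb_mask, n_bins = 1000,
                        max_levels = 64)
wb_link <- hcluster(topic_matrix(wb_z, wb_mask), "complete")
rec <- reconcile(cb, wb_link, split_ratio_threshold = 0.5)
cat(sprintf("reconciled solution: %d clusters (%d reconciliation decisions)\n",
            rec$k, nrow(rec$decisions)))
if (nrow(rec$decisions))
  print(rec$decisions[, c("cb_cluster", "action", "join_height", "threshold")])

jsonlite::write_json(list(k = rec$k, assignment = as.list(rec$assignment),
                          method = "complete"),
                     "results/clusters.json", auto_unbox = TRUE, digits = NA)
heights <- data.frame(merge_step = seq_along(link_c$height),
                      complete = link_c$height, ward = link_w$height)
utils::write.table(heights, "results/dendrogram_heights.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote results/clusters.json and results/dendrogram_heights.tsv\n")
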