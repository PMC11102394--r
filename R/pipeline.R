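#' Run per-topic ALE z-maps for a database
#'
#' @param db A \code{topic_database}.
#' @param grid A \code{voxel_grid}.
#' @param kernel A \code{kernel_spec}.
#' @param mask Logical analysis mask over the grid.
#' @param n_bins,max_levels Null-distribution resolution.
#' @return Named list (topic -> z \code{volume}).
#' @export
run_topic_zmaps <- function(db, grid, kernel = kernel_spec(),
                            mask = grid_mask(grid), n_bins = 10000,
                            max_levels = 256) {
  zv <- lapply(db$topics, function(tp)
    ale_topic(db, tp, grid, kernel, mask, n_bins = n_bins,
              max_levels = max_levels)$z)
  names(zv) <- db$topics
  zv
}

#' End-to-end winner-take-all parcellation pipeline
#'
#' Runs, on a masked and screened database: per-topic ALE z-maps; unity
#' normalization into the topics-by-voxels matrix; hierarchical clustering
#' of topics (complete linkage by default) cut at \code{k}; per-cluster mean
#' score maps; winner-take-all labeling; and stochastic box-filter
#' smoothing.
#'
#' @param db A \code{topic_database}.
#' @param k Number of topic clusters.
#' @param grid Analysis grid (default 4 mm cerebellar grid; production runs
#'   use 2 mm).
#' @param kernel A \code{kernel_spec}.
#' @param mask Analysis mask (default: geometric cerebellar mask).
#' @param method Linkage ("complete" or "ward").
#' @param box,sweeps,seed Mode-filter settings (box = 5 voxels, 10 sweeps).
#' @param n_bins,max_levels Null-distribution resolution.
#' @param aggregator Cluster score aggregator ("mean" or "max").
#' @return List: \code{zmaps}, \code{tm} (topic matrix), \code{linkage},
#'   \code{model}, \code{scores}, \code{parc_raw} (unsmoothed), \code{parc}
#'   (smoothed).
#' @export
run_parcellation <- function(db, k, grid = cerebellar_grid(4),
                             kernel = kernel_spec(),
                             mask = grid_mask(grid),
                             method = "complete", box = 5, sweeps = 10,
                             seed = 1L, n_bins = 10000, max_levels = 256,
                             aggregator = "mean") {
  zmaps <- run_topic_zmaps(db, grid, kernel, mask, n_bins, max_levels)
  tm <- topic_matrix(zmaps, mask)
  linkage <- hcluster(tm, method = method)
  model <- cut_model(linkage, k)
  scores <- cluster_scores(tm, model, aggregator = aggregator)
  parc_raw <- winner_take_all(scores)
  parc <- mode_filter(parc_raw, box = box, sweeps = sweeps, seed = seed)
  list(zmaps = zmaps, tm = tm, linkage = linkage, model = model,
       scores = scores, parc_raw = parc_raw, parc = parc)
}

#' Run the reference synthetic recovery experiment
#'
#' Generates the reference scenario (four planted topic clusters, three
#' topics each, 40 studies per topic, 6 mm scatter, 10 percent background),
#' runs the full pipeline on a 4 mm grid, and scores recovery of the planted
#' structure: adjusted Rand of the topic clustering against the planted
#' topic groups, and Rand of the voxel labels against the rasterized planted
#' regions.
#'
#' @param seed Integer seed (drives both the generator and the smoothing).
#' @param grid_mm Grid spacing in mm (default 4).
#' @param n_bins Null resolution (default 2000 at this problem size).
#' @return List: \code{topic_ari}, \code{voxel_rand}, \code{voxel_ari},
#'   plus the pipeline \code{fit}, the \code{db} and the \code{truth}.
#' @export
recover_reference <- function(seed = 1L, grid_mm = 4, n_bins = 2000) {
  sc <- reference_scenario(seed = seed)
  db <- generate_database(sc$cfg, sc$truth)
  fit <- run_parcellation(db, k = 4, grid = cerebellar_grid(grid_mm),
                          seed = seed, n_bins = n_bins, max_levels = 128)
  groups <- sc$truth$topic_groups[names(fit$model$assignment)]
  topic_sim <- rand_index(fit$model$assignment, groups)
  vox <- recovery_score(fit$parc, sc$truth)
  list(topic_ari = topic_sim$adjusted_rand,
       topic_rand = topic_sim$rand,
       voxel_rand = vox$rand, voxel_ari = vox$adjusted_rand,
       fit = fit, db = db, truth = sc$truth)
}
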