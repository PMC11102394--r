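mk_tm <- function(values, spacing = 1) {
  nv <- ncol(values)
  grid <- voxel_grid(c(nv, 1, 1), spacing = spacing)
  mask <- array(TRUE, dim = grid$shape)
  structure(list(values = values, topics = rownames(values),
                 voxels = seq_len(nv), grid = grid, mask = mask),
            class = "topic_matrix")
}

mk_model <- function(assignment) {
  structure(list(assignment = assignment, k = max(assignment),
                 linkage = NULL, source = "fixture"),
            class = "cluster_model")
}

test_that("cluster scores reduce to topic rows for singleton clusters", {
  vals <- rbind(t1 = c(0.9, 0.1), t2 = c(0.2, 0.8))
  tm <- mk_tm(vals)
  sc <- cluster_scores(tm, mk_model(c(t1 = 1L, t2 = 2L)))
  expect_equal(unname(sc$values), unname(vals))
})

test_that("identical member rows average to themselves; mean and max differ
           exactly where members disagree", {
  vals <- rbind(t1 = c(0.4, 0.2, 0.6), t2 = c(0.4, 0.8, 0.6))
  tm <- mk_tm(vals)
  model <- mk_model(c(t1 = 1L, t2 = 1L))
  m_mean <- cluster_scores(tm, model, "mean")$values
  m_max <- cluster_scores(tm, model, "max")$values
  expect_equal(as.numeric(m_mean), c(0.4, 0.5, 0.6))
  expect_equal(as.numeric(m_max), c(0.4, 0.8, 0.6))
  expect_equal(which(m_mean != m_max), which(vals[1, ] != vals[2, ]))
})

test_that("empty clusters are refused", {
  tm <- mk_tm(rbind(t1 = c(1, 0)))
  expect_error(cluster_scores(tm, mk_model(c(t1 = 2L))), "surjective")
})

test_that("winner-take-all picks the top score with documented tie-breaks", {
  sc <- toy_scores(rbind(c(0.9, 0.5, 0, 0.2),
                         c(0.3, 0.5, 0, 0.1)))
  parc <- winner_take_all(sc)
  labs <- as.integer(parc$volume$values)
  expect_equal(labs, c(1L, 1L, 0L, 1L))
  expect_equal(parc$n_ties, 1)
})

test_that("WTA is invariant under strictly monotone score transforms", {
  set.seed(18)
  vals <- matrix(runif(3 * 50), 3)
  p1 <- winner_take_all(toy_scores(vals))
  p2 <- winner_take_all(toy_scores(vals^3))
  p3 <- winner_take_all(toy_scores(exp(vals) - exp(0)))
  expect_equal(p1$volume$values, p2$volume$values)
  expect_equal(p1$volume$values, p3$volume$values)
})

test_that("a uniform field is a mode-filter fixed point", {
  grid <- voxel_grid(c(7, 7, 7), spacing = 1)
  mask <- array(TRUE, dim = grid$shape)
  parc <- structure(list(volume = volume(grid, array(2L, dim = grid$shape),
                                         mask = mask),
                         legend = c("1" = "1", "2" = "2"), n_ties = 0L),
                    class = "parcellation")
  sm <- mode_filter(parc, box = 5, sweeps = 10, seed = 1)
  expect_equal(sm$volume$values, parc$volume$values)
})

test_that("a single speckle inside a uniform field is absorbed in one sweep", {
  grid <- voxel_grid(c(7, 7, 7), spacing = 1)
  mask <- array(TRUE, dim = grid$shape)
  vals <- array(1L, dim = grid$shape)
  vals[4, 4, 4] <- 2L
  parc <- structure(list(volume = volume(grid, vals, mask = mask),
                         legend = c("1" = "1", "2" = "2"), n_ties = 0L),
                    class = "parcellation")
  sm <- mode_filter(parc, box = 5, sweeps = 1, seed = 2)
  expect_equal(unique(as.integer(sm$volume$values)), 1L)
})

test_that("mode filtering is seed-deterministic and never invents labels", {
  grid <- voxel_grid(c(8, 8, 8), spacing = 1)
  mask <- array(TRUE, dim = grid$shape)
  set.seed(19)
  vals <- array(sample(0:3, 512, TRUE), dim = grid$shape)
  parc <- structure(list(volume = volume(grid, vals, mask = mask),
                         legend = structure(as.character(1:3),
                                            names = as.character(1:3)),
                         n_ties = 0L),
                    class = "parcellation")
  a <- mode_filter(parc, box = 3, sweeps = 2, seed = 7)
  b <- mode_filter(parc, box = 3, sweeps = 2, seed = 7)
  expect_identical(a$volume$values, b$volume$values)
  expect_true(all(a$volume$values %in% 0:3))
  expect_error(mode_filter(parc, box = 4), "odd")
})

test_that("smoothing moves under 5% of labeled voxels on clean planted
           data at production resolution", {
  sc <- reference_scenario(seed = 5)
  cfg <- sim_config(studies_per_topic = 40, focus_scatter_sd = 4,
                    background_rate = 0, seed = 5)
  db <- generate_database(cfg, sc$truth)
  fit <- run_parcellation(db, k = 4, grid = cerebellar_grid(2),
                          n_bins = 1000, max_levels = 64, seed = 5, box = 5)
  raw <- parcellation_labels(fit$parc_raw)
  sm <- parcellation_labels(fit$parc)
  expect_lt(mean(raw[raw > 0] != sm[raw > 0]), 0.05)
})

test_that("network merging follows the shipped map and is idempotent", {
  sc <- toy_scores(matrix(c(diag(10) * 0.5 + 0.1), 10, 10))
  parc <- winner_take_all(sc)
  nets <- load_network_config()
  merged <- merge_networks(parc, nets)
  expect_equal(length(unique(merged$legend)), 7)
  labs <- as.integer(merged$volume$values)
  expect_equal(merged$legend[as.character(labs[7])], merged$legend[as.character(labs[8])],
               ignore_attr = TRUE)
  expect_equal(unname(merged$legend[as.character(labs[5])]), "limbic")
  again <- merge_networks(merged, nets)
  expect_equal(again$volume$values, merged$volume$values)
  expect_equal(again$legend, merged$legend)

  ident <- structure(parc$legend, names = parc$legend)
  same <- merge_networks(parc, ident)
  expect_equal(same$volume$values, parc$volume$values)

  expect_error(merge_networks(parc, nets[1:3]), "unmapped")
})
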