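test_that("Rand and adjusted Rand match hand-enumerated examples", {
  r <- rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))
  expect_equal(r$rand, 2 / 6)
  expect_equal(r$adjusted_rand, -0.5)
  r2 <- rand_index(c(1, 1, 1), c(1, 1, 2))
  expect_equal(r2$rand, 1 / 3)
  ident <- rand_index(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_equal(ident$rand, 1)
  expect_equal(ident$adjusted_rand, 1)
})

test_that("rand_index equals the all-pairs oracle on random partitions", {
  set.seed(20)
  for (i in 1:60) {
    n <- sample(2:10, 1)
    l1 <- sample.int(sample(1:4, 1), n, replace = TRUE)
    l2 <- sample.int(sample(1:4, 1), n, replace = TRUE)
    got <- rand_index(l1, l2)
    want <- rand_oracle(l1, l2)
    expect_equal(got$rand, want$rand)
    expect_equal(got$adjusted_rand, want$adjusted_rand)
  }
})

test_that("adjusted Rand agrees with an independent library implementation", {
  skip_if_not_installed("mclust")
  set.seed(21)
  for (i in 1:20) {
    l1 <- sample.int(5, 30, replace = TRUE)
    l2 <- sample.int(3, 30, replace = TRUE)
    expect_equal(rand_index(l1, l2)$adjusted_rand,
                 unname(mclust::adjustedRandIndex(l1, l2)))
  }
})

test_that("ARI of independent random partitions is centred on zero", {
  set.seed(22)
  aris <- replicate(1000, rand_index(sample.int(4, 40, TRUE),
                                     sample.int(4, 40, TRUE))$adjusted_rand)
  expect_lt(abs(mean(aris)), 0.02)
})

mk_parc <- function(labels, grid = NULL, legend = NULL) {
  nv <- length(labels)
  if (is.null(grid)) grid <- voxel_grid(c(nv, 1, 1), spacing = 2)
  mask <- array(TRUE, dim = grid$shape)
  if (is.null(legend)) {
    u <- sort(unique(labels[labels > 0]))
    legend <- structure(as.character(u), names = as.character(u))
  }
  structure(list(volume = volume(grid, array(as.integer(labels),
                                             dim = grid$shape), mask = mask),
                 legend = legend, n_ties = 0L),
            class = "parcellation")
}

test_that("merging rules collapse unmapped labels into 'other'", {
  p1 <- mk_parc(c(1, 1, 2, 2, 3, 3))
  p2 <- mk_parc(c(1, 1, 2, 2, 4, 4))
  merge1 <- c("1" = "net1", "2" = "net2")
  merge2 <- c("1" = "net1", "2" = "net2")
  r <- rand_report(p1, p2, merge1, merge2)
  expect_equal(r$rand, 1)  # 3 and 4 both collapse to "other"
  expect_true("other" %in% rownames(r$contingency))
})

test_that("comparison is restricted to voxels labeled in both", {
  p1 <- mk_parc(c(1, 1, 2, 2, 0, 1))
  p2 <- mk_parc(c(1, 1, 2, 2, 2, 0))
  r <- rand_report(p1, p2)
  expect_equal(r$n, 4)
  expect_equal(r$rand, 1)
})

test_that("per-network comparison binarizes and flags degeneracy", {
  p1 <- mk_parc(c(1, 1, 2, 2))
  p2 <- mk_parc(c(1, 1, 3, 3))
  r <- per_network_rand(p1, p2, "1")
  expect_equal(r$rand, 1)  # identical voxel sets for network "1"
  oracle <- rand_oracle(c("n", "n", "o", "o"), c("n", "n", "o", "o"))
  expect_equal(r$rand, oracle$rand)
  # one displaced voxel, 4-voxel toy: oracle by pair enumeration
  p3 <- mk_parc(c(1, 1, 1, 2))
  p4 <- mk_parc(c(1, 1, 2, 2))
  r2 <- per_network_rand(p3, p4, "1")
  want <- rand_oracle(c(1, 1, 1, 2), c(1, 1, 2, 2))
  expect_equal(r2$rand, want$rand)
  absent <- per_network_rand(p1, p2, "zzz")
  expect_equal(absent$rand, 1)
  expect_true(absent$degenerate)
})

test_that("the distance-bin rule matches a one-pair-at-a-time oracle", {
  centers <- seq(6, 50, by = 4)
  set.seed(23)
  d <- c(runif(100, 0, 60), 7.9, 8, 16, 4, 52.9)
  got <- cbparcel:::dcbc_bin(d, centers)
  want <- vapply(d, bin_oracle, 1, centers = centers)
  expect_equal(got, want)
})

orthogonal_fixture <- function(jitter = 1e-3, nvox = 26) {
  grid <- voxel_grid(c(nvox, 1, 1), spacing = 2)
  mask <- array(TRUE, dim = grid$shape)
  half <- nvox / 2
  labels <- rep(1:2, each = half)
  set.seed(24)
  prof <- sapply(seq_len(nvox), function(i)
    (if (labels[i] == 1) c(1, 0, 0) else c(0, 1, 0)) + rnorm(3, 0, jitter))
  rownames(prof) <- paste0("t", 1:3)
  tm <- structure(list(values = prof, topics = rownames(prof),
                       voxels = seq_len(nvox), grid = grid, mask = mask),
                  class = "topic_matrix")
  list(parc = mk_parc(labels, grid), tm = tm, labels = labels)
}

test_that("orthogonal profiles give within ~1, between ~-0.5, dcbc ~1.5", {
  fx <- orthogonal_fixture()
  res <- dcbc(fx$parc, fx$tm)
  pop <- !is.na(res$dcbc)
  expect_true(any(pop))
  expect_true(all(abs(res$within_r[pop] - 1) < 0.05))
  expect_true(all(abs(res$between_r[pop] + 0.5) < 0.05))
  expect_true(all(abs(res$dcbc[pop] - 1.5) < 0.1))
})

test_that("dcbc is invariant to parcel relabeling and profile shifts", {
  fx <- orthogonal_fixture(jitter = 0.3)
  res1 <- dcbc(fx$parc, fx$tm)
  swapped <- mk_parc(3 - fx$labels, fx$parc$volume$grid)
  res2 <- dcbc(swapped, fx$tm)
  expect_equal(res1$dcbc, res2$dcbc)
  tm_shift <- fx$tm
  tm_shift$values <- fx$tm$values + 5
  res3 <- dcbc(fx$parc, tm_shift)
  expect_equal(res1$dcbc, res3$dcbc, tolerance = 1e-12)
})

test_that("dcbc refuses single-parcel input", {
  fx <- orthogonal_fixture()
  expect_error(dcbc(mk_parc(rep(1, 26), fx$parc$volume$grid), fx$tm),
               "two parcels")
})

test_that("dcbc subsampling approximates exact enumeration", {
  fx <- orthogonal_fixture(jitter = 0.2)
  exact <- dcbc(fx$parc, fx$tm)
  sub <- dcbc(fx$parc, fx$tm, pair_budget = 150, seed = 5)
  pop <- !is.na(exact$dcbc) & !is.na(sub$dcbc)
  expect_true(any(pop))
  expect_lt(max(abs(exact$dcbc[pop] - sub$dcbc[pop])), 0.5)
})

test_that("recovery scoring is exact for rasterized truth and floored for
           a single label", {
  sc <- reference_scenario(n_groups = 3, topics_per_group = 1)
  grid <- cerebellar_grid(8)
  tv <- rasterize_truth(sc$truth, grid)
  parc <- structure(list(volume = tv,
                         legend = structure(as.character(1:3),
                                            names = as.character(1:3)),
                         n_ties = 0L),
                    class = "parcellation")
  r <- recovery_score(parc, sc$truth)
  expect_equal(r$rand, 1)
  expect_equal(r$adjusted_rand, 1)
  flat <- parc
  flat$volume$values[flat$volume$mask] <- 1L
  r2 <- recovery_score(flat, sc$truth)
  expect_lte(r2$adjusted_rand, 0)
})
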