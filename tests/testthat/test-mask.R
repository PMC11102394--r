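test_that("printed example coordinates classify as expected", {
  expect_false(in_geometric_mask(c(0, -50, 12)))   # on the superior plane
  expect_true(in_geometric_mask(c(30, -60, -20)))
  expect_false(in_geometric_mask(c(0, -20, -30)))  # y box violation
})

test_that("plane anchor points sit exactly on their plane boundaries", {
  spec <- mask_spec()
  sup <- spec$superior; post <- spec$posterior
  for (p in list(c(0, -50, 12), c(60, -50, -30), c(-60, -50, -30)))
    expect_equal(sup$slope * abs(p[1]) + sup$intercept, p[3])
  for (p in list(c(0, -50, 12), c(0, -100, -15)))
    expect_equal(post$slope * (p[2] + post$offset) + post$intercept, p[3])
  # strict inequalities exclude the anchors themselves
  expect_false(any(in_geometric_mask(rbind(c(0, -50, 12), c(60, -50, -30),
                                           c(0, -100, -15)), spec)))
})

test_that("shrinking the box or raising a plane never adds coordinates", {
  set.seed(8)
  pts <- cbind(runif(500, -70, 70), runif(500, -110, -20),
               runif(500, -60, 15))
  base <- in_geometric_mask(pts)
  shrunk <- mask_spec(x_abs_max = 50, y_min = -90, y_max = -40, z_max = 0)
  expect_true(all(in_geometric_mask(pts, shrunk) <= base))
  lowered <- mask_spec(superior_anchors = rbind(c(0, -50, 6),
                                                c(60, -50, -36)))
  expect_true(all(in_geometric_mask(pts, lowered) <= base))
})

test_that("screening flags remove whole studies", {
  foci <- replicate(3, matrix(c(30, -60, -20), 1), simplify = FALSE)
  db <- tiny_db(c("t1", "t1", "t1"), 12, foci,
                flags = list("patients", character(), character()))
  res <- filter_database(db, excluded_flags = c("patients", "resting-state"))
  expect_equal(nrow(res$db$studies), 2)
  expect_equal(res$audit$studies_removed_screening, 1)
  expect_equal(res$audit$foci_removed_screening, 1)
})

test_that("a fully in-mask unflagged database passes unchanged", {
  foci <- replicate(2, matrix(c(30, -60, -20), 1), simplify = FALSE)
  db <- tiny_db(c("t1", "t1"), 10, foci)
  res <- filter_database(db, excluded_flags = "patients")
  expect_equal(res$db$foci, db$foci)
  expect_equal(res$audit$foci_removed_mask, 0)
})

test_that("a labeler that never labels removes every focus", {
  foci <- replicate(2, matrix(c(30, -60, -20), 1), simplify = FALSE)
  db <- tiny_db(c("t1", "t1"), 10, foci)
  expect_warning(res <- filter_database(db, labeler = function(x)
    rep(FALSE, nrow(x))), "no foci")
  expect_equal(res$audit$foci_removed_unlabeled, 2)
  expect_equal(nrow(res$db$foci), 0)
})

test_that("audit counts reconcile with the input", {
  sc <- reference_scenario(n_groups = 3, topics_per_group = 1)
  cfg <- sim_config(studies_per_topic = 10, focus_scatter_sd = 25,
                    flag_rates = c(patients = 0.3), seed = 21)
  db <- generate_database(cfg, sc$truth)
  res <- filter_database(db, excluded_flags = "patients")
  a <- res$audit
  expect_equal(a$foci_in, a$foci_out + a$foci_removed_screening +
                 a$foci_removed_mask + a$foci_removed_unlabeled)
  expect_equal(a$studies_in, a$studies_out + a$studies_removed_screening +
                 a$studies_removed_no_foci)
})

test_that("a volume labeler gates foci on cerebellar label names", {
  grid <- voxel_grid(c(40, 40, 30), spacing = 4, origin = c(-70, -110, -60))
  vals <- array(2L, dim = grid$shape)
  vals[1:10, , ] <- 1L
  lab_vol <- volume(grid, vals)
  labeler <- volume_labeler(lab_vol, c("cerebral cortex", "cerebellum lobule"))
  expect_true(labeler(matrix(c(30, -60, -20), 1)))
  expect_false(labeler(matrix(c(-60, -60, -20), 1)))
})
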