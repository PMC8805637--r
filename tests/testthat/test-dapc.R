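make_clusters <- function(n = 15, p = 50, sep = 10, seed = 1) {
  set.seed(seed)
  m <- rbind(matrix(rnorm(n * p), n), matrix(rnorm(n * p, mean = sep), n))
  list(m = m, groups = rep(c("g1", "g2"), each = n))
}

test_that("well-separated clusters are perfectly reassigned", {
  cl <- make_clusters()
  fit <- fit_dapc(cl$m, cl$groups)
  assign_nearest <- apply(fit$coordinates, 1L, function(z) {
    rownames(fit$centroids)[which.min(colSums((t(fit$centroids) - z)^2))]
  })
  expect_identical(unname(assign_nearest), cl$groups)
  # sign convention: first group's centroid is non-positive on every axis
  expect_true(all(fit$centroids["g1", ] <= 0))
})

test_that("centroids equal member means and duplication changes nothing", {
  cl <- make_clusters(seed = 2)
  fit <- fit_dapc(cl$m, cl$groups)
  for (g in c("g1", "g2")) {
    expect_equal(unname(fit$centroids[g, , drop = TRUE]),
                 unname(colMeans(fit$coordinates[cl$groups == g, ,
                                                 drop = FALSE])))
  }
  dup <- fit_dapc(rbind(cl$m, cl$m), c(cl$groups, cl$groups),
                  n_pcs = fit$retained_pcs)
  expect_equal(dup$centroids, fit$centroids, tolerance = 1e-6)
})

test_that("scores are invariant to uniform intensity scaling", {
  cl <- make_clusters(seed = 3)
  f1 <- fit_dapc(cl$m, cl$groups)
  f7 <- fit_dapc(cl$m * 7, cl$groups)
  expect_equal(f1$coordinates, f7$coordinates, tolerance = 1e-8)
})

test_that("degenerate group sizes and axis counts are rejected", {
  cl <- make_clusters()
  expect_error(fit_dapc(cl$m, c("solo", cl$groups[-1])), "fewer than 2")
  expect_error(fit_dapc(cl$m, cl$groups, n_lds = 2), "n_lds")
  expect_error(fit_dapc(cl$m, rep("g1", nrow(cl$m))), "2 groups")
})

test_that("held-out reassignment is near chance under the null", {
  acc <- vapply(1:50, function(s) {
    set.seed(s)
    train <- matrix(rnorm(40 * 30), 40)
    test <- matrix(rnorm(40 * 30), 40)
    grp <- rep(c("a", "b"), each = 20)
    fit <- fit_dapc(train, grp)
    z <- predict(fit, test)
    pred <- apply(z, 1L, function(v) {
      rownames(fit$centroids)[which.min(colSums((t(fit$centroids) - v)^2))]
    })
    mean(pred == grp)
  }, numeric(1))
  expect_lt(abs(mean(acc) - 0.5), 0.1)
})

fake_dapc <- function(ctrl_coords, trt_coords) {
  coords <- rbind(ctrl_coords, trt_coords)
  colnames(coords) <- c("LD1", "LD2")
  groups <- factor(rep(c("ctrl", "trt"),
                       c(nrow(ctrl_coords), nrow(trt_coords))))
  centroids <- rbind(ctrl = colMeans(ctrl_coords),
                     trt = colMeans(trt_coords))
  structure(list(coordinates = coords, groups = groups,
                 centroids = centroids), class = "dapc")
}

test_that("centroid distance summary matches hand computation", {
  ctrl <- matrix(0, 3, 2)
  # all treated cells at the control centroid
  expect_equal(centroid_distances(fake_dapc(ctrl, matrix(0, 2, 2)),
                                  "ctrl", "trt")$mean_distance, 0)
  # two treated cells at distances 3 and 5 from the control centroid
  trt <- matrix(c(3, 0, 0, 5), 2, byrow = TRUE)
  d <- centroid_distances(fake_dapc(ctrl, trt), "ctrl", "trt")
  expect_equal(d$mean_distance, 4)
  expect_equal(d$sd_distance, sqrt(2))
  expect_equal(d$n_cells, 2L)
  # translation invariance
  d10 <- centroid_distances(fake_dapc(ctrl + 10, trt + 10), "ctrl", "trt")
  expect_equal(d10$mean_distance, 4)
  expect_equal(d10$sd_distance, sqrt(2))
  expect_error(centroid_distances(fake_dapc(ctrl, trt), "ctrl", "nope"),
               "unknown group")
})

test_that("rank-sum separation p-values behave at both extremes", {
  set.seed(4)
  base <- matrix(rnorm(40 * 20), 40)
  grp <- rep(c("a", "b"), each = 20)
  same <- fit_dapc(base, grp)
  ident <- structure(list(
    coordinates = rbind(same$coordinates[1:20, , drop = FALSE],
                        same$coordinates[1:20, , drop = FALSE]),
    groups = factor(grp),
    centroids = same$centroids
  ), class = "dapc")
  expect_true(all(group_separation_test(ident, "a", "b") == 1))

  shifted <- ident
  shifted$coordinates[21:40, 1] <- shifted$coordinates[21:40, 1] + 100
  p <- group_separation_test(shifted, "a", "b")
  expect_lt(p[["LD1"]], 1e-6)
  expect_equal(unname(group_separation_test(shifted, "a", "b")),
               unname(group_separation_test(shifted, "b", "a")))
})

test_that("peak screen flags nothing on a copied group", {
  pop <- generate_population(population_spec(10, 0.5, seed = 5),
                             phenotype_profile("DSB", "control"))
  fp <- crop_band(pop, default_bands()$fingerprint)
  res <- peakwise_significance(fp, fp)
  expect_equal(sum(res$significant), 0L)
  expect_true(all(res$p_value > 0.9))

  # a wavenumber constant in both groups is flagged with p = 1
  a <- cbind(matrix(rnorm(30), 10), 1)
  b <- cbind(matrix(rnorm(30), 10), 1)
  res2 <- peakwise_significance(a, b)
  expect_true(res2$constant[4])
  expect_equal(res2$p_value[4], 1)
})

test_that("constructed drought signature is flagged with correct directions", {
  ctrl <- generate_population(population_spec(20, 0.5, seed = 6),
                              phenotype_profile("DSB", "control"))
  peg <- generate_population(population_spec(20, 0.5, seed = 7),
                             phenotype_profile("DSB", "PEG"))
  fp <- default_bands()$fingerprint
  res <- peakwise_significance(crop_band(ctrl, fp), crop_band(peg, fp))
  at <- function(wn) res[res$wavenumber == wn, ]
  expect_true(at(1209)$significant)
  expect_identical(at(1209)$direction, "up")
  expect_true(at(1267)$significant)
  expect_identical(at(1267)$direction, "down")
  expect_error(peakwise_significance(crop_band(ctrl, fp)$intensities[1:2, ],
                                     crop_band(peg, fp)$intensities),
               "3 cells")
})

test_that("synthetic sensitive strains separate farther than tolerant ones", {
  dist_for <- function(role, seed) {
    pops <- lapply(c("control", "PEG"), function(cond) {
      generate_population(
        population_spec(15, 1, seed = seed + (cond == "PEG")),
        phenotype_profile(role, cond))
    })
    fp <- default_bands()$fingerprint
    m <- rbind(crop_band(pops[[1]], fp)$intensities,
               crop_band(pops[[2]], fp)$intensities)
    grp <- rep(c("control", "PEG"), each = 15)
    fit <- fit_dapc(m, grp, n_lds = 1)
    centroid_distances(fit, "control", "PEG")$mean_distance
  }
  wins <- vapply(1:10, function(s) {
    dist_for("DSB", 100 + 2 * s) > dist_for("DTB", 200 + 2 * s)
  }, logical(1))
  expect_gte(sum(wins), 9L)
})
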