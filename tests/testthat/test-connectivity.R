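test_that("Fisher z transform identities", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r))
  # round trip with tanh
  z <- seq(-4, 4, by = 0.25)
  expect_equal(fisher_z(tanh(z)), z, tolerance = 1e-12)
  expect_error(fisher_z(1), "< 1")
})

test_that("seed FC maps behave under self, null and planted correlation", {
  set.seed(8)
  n <- 300
  seed_ts <- bandpass(rnorm(n), TR_s = 4)
  targets <- matrix(rnorm(5 * n), 5)
  targets[1, ] <- seed_ts
  zg <- seed_fc_map(seed_ts, targets, "glm")
  zp <- seed_fc_map(seed_ts, targets, "pearson")
  expect_equal(which.max(zg), 1L)
  expect_equal(which.max(zp), 1L)
  # both monotone in the underlying correlation
  rho <- c(0.1, 0.3, 0.5, 0.7)
  mix <- t(sapply(rho, function(r) r * scale(seed_ts) +
                    sqrt(1 - r^2) * rnorm(n)))
  expect_true(all(diff(seed_fc_map(seed_ts, mix, "glm")) > 0))
  expect_true(all(diff(seed_fc_map(seed_ts, mix, "pearson")) > 0))
  # null distribution of Fisher z approximately N(0, 1/(n-3))
  nullz <- replicate(300, seed_fc_map(rnorm(n), matrix(rnorm(n), 1),
                                      "pearson"))
  expect_lt(abs(mean(nullz)), 3 / sqrt(300 * (n - 3)))
  expect_equal(sd(nullz), 1 / sqrt(n - 3), tolerance = 0.15)
  expect_error(seed_fc_map(rep(1, n), targets), "zero variance")
})

test_that("depth FC matrices are symmetric, masked and null-calibrated", {
  set.seed(9)
  ind <- matrix(rnorm(6 * 400), 6)
  fc <- depth_fc_matrix(ind)
  expect_true(all(is.na(diag(fc$z))))
  expect_equal(fc$z, t(fc$z))
  expect_lt(max(abs(fc$z), na.rm = TRUE), 4 / sqrt(400))
  # shared signal -> large positive z everywhere
  shared <- outer(rep(1, 6), rnorm(400)) + 0.1 * matrix(rnorm(2400), 6)
  expect_gt(min(depth_fc_matrix(shared)$z, na.rm = TRUE), 2)
  # constant row masked with a warning
  bad <- ind; bad[2, ] <- 7
  expect_warning(fc2 <- depth_fc_matrix(bad), "masked")
  expect_true(all(is.na(fc2$z[2, ])))
  # averaging across columns
  fc3 <- depth_fc_matrix(list(ind, ind))
  expect_equal(fc3$z, fc$z)
})

test_that("paired condition contrast is exact under identity and BH matches hand computation", {
  set.seed(10)
  mats <- lapply(1:6, function(i) matrix(rnorm(16), 4))
  # identical conditions -> zero t everywhere, nothing significant
  ct <- condition_contrast(mats, mats)
  expect_true(all(ct$t == 0))
  expect_true(!any(ct$significant))
  # hand-computed Benjamini-Hochberg
  expect_equal(layervn:::bh_adjust(c(0.01, 0.02, 0.2)), c(0.03, 0.03, 0.2))
  # subject-order invariance
  a <- lapply(1:8, function(i) matrix(rnorm(16), 4))
  b <- lapply(1:8, function(i) matrix(rnorm(16), 4))
  perm <- sample(8)
  c1 <- condition_contrast(a, b)
  c2 <- condition_contrast(a[perm], b[perm])
  expect_equal(c1$t, c2$t)
  expect_error(condition_contrast(a[1:2], b[1:2]), "at least 3")
})

test_that("cross-layer differences are antisymmetric and detect planted effects", {
  set.seed(12)
  n_subj <- 10; n_targ <- 30
  base <- matrix(rnorm(n_subj * n_targ, sd = 0.2), n_subj)
  maps <- list(superficial = base + 0, middle = base, deep = base)
  # identical layers -> all-zero differences
  d0 <- cross_layer_difference(maps)
  expect_true(all(abs(d0$superficial_vs_middle$mean_diff) < 1e-12))
  # planted superficial-only edge at target 5
  maps$superficial[, 5] <- maps$superficial[, 5] + 1
  d <- cross_layer_difference(maps)
  sig <- d$superficial_vs_deep$significant
  expect_true(sig[5])
  expect_true(!any(sig[-5]))
  # antisymmetry
  d_rev <- cross_layer_difference(maps, pairs = list(c("deep", "superficial")))
  expect_equal(d_rev$deep_vs_superficial$mean_diff,
               -d$superficial_vs_deep$mean_diff)
})

test_that("laminar connectome recovers a planted directed laminar edge", {
  col <- default_column()
  net <- laminar_network_spec(
    rois = c("V1", "V2"),
    edges = data.frame(roi_a = "V2", layer_a = "deep", roi_b = "V1",
                       layer_b = "superficial", r = 0.6,
                       stringsAsFactors = FALSE))
  cohort <- make_subject_cohort(n_subjects = 6, seed = 44, network = net,
                                b_values = 7, n_volumes = 300)
  subj_ts <- lapply(cohort, function(s) layer_sampled_run(s$runs$b7))
  lc <- laminar_connectome(subj_ts, roi_pairs = list(c("V2", "V1")))[[1]]
  hot <- which(lc$mean_z == max(lc$mean_z), arr.ind = TRUE)
  expect_equal(rownames(lc$mean_z)[hot[1]], "deep")        # V2 side
  expect_equal(colnames(lc$mean_z)[hot[2]], "superficial") # V1 side
  expect_true(lc$significant[hot])
  # missing ROI errors by name
  broken <- subj_ts; broken[[2]]$V2 <- NULL
  expect_error(laminar_connectome(broken), "V2")
})
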