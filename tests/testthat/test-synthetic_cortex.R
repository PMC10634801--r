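test_that("block paradigm volume arithmetic", {
  expect_equal(n_volumes(block_paradigm(18, 30, 30, 4)), 270L)
  expect_equal(n_volumes(block_paradigm(1, 30, 30, 4)), 15L)
  expect_equal(n_volumes(block_paradigm(20, 30, 30, 4)), 300L)
  expect_error(block_paradigm(1, 30, 30, 7), "non-integer")
  box <- task_boxcar(block_paradigm(2, 30, 30, 4))
  expect_equal(length(box), 30)
  expect_equal(box[1:8], rep(1, 8))       # ON first
  expect_equal(box[9:15], rep(0, 7))
})

test_that("leakage operator drains deep signal upward geometrically", {
  nd <- 6
  imp <- matrix(0, nd, 3); imp[1, 1] <- 1    # unit impulse at deepest layer
  # drain 0 -> local only
  v0 <- leakage_operator(imp, 0, rep(1, nd))
  expect_equal(v0, imp)
  # drain 1, unit weights -> equal contribution at every superficial depth
  v1 <- leakage_operator(imp, 1, rep(1, nd))
  expect_equal(v1[, 1], rep(1, nd))
  # drain 0.5 -> geometric decay across depths
  v5 <- leakage_operator(imp, 0.5, rep(1, nd))
  expect_equal(v5[, 1], 0.5^(0:(nd - 1)))
  # linearity
  set.seed(1)
  x <- matrix(rnorm(nd * 4), nd); y <- matrix(rnorm(nd * 4), nd)
  expect_equal(leakage_operator(2 * x + 3 * y, 0.4, 1),
               2 * leakage_operator(x, 0.4, 1) + 3 * leakage_operator(y, 0.4, 1))
  # causal in depth: signal never propagates downward
  imp_top <- matrix(0, nd, 1); imp_top[nd, 1] <- 1
  expect_equal(leakage_operator(imp_top, 0.7, rep(1, nd))[1:(nd - 1), 1],
               rep(0, nd - 1))
  expect_error(leakage_operator(imp, 1.2, 1), "\\[0, 1\\]")
})

test_that("pial blooming term falls off as inverse square of distance", {
  col <- default_column()
  sig <- sin(seq(0, 2 * pi, length.out = 50))
  pt <- pial_extravascular_term(col, sig)
  w <- (col$pial_diameter_mm / 2 / col$pial_distance_mm)^2
  expect_equal(pt$magnitude, outer(w, sig))
  # surface voxel (distance = radius) gets full strength
  col2 <- col; col2$pial_distance_mm[col$n_depths] <- col$pial_diameter_mm / 2
  pt2 <- pial_extravascular_term(col2, sig)
  expect_equal(pt2$magnitude[col$n_depths, ], sig)
  # distance = 6 radius -> 1/36
  col2$pial_distance_mm[1] <- 6 * col$pial_diameter_mm / 2
  expect_equal(pial_extravascular_term(col2, sig)$magnitude[1, ], sig / 36)
  expect_equal(pial_extravascular_term(col, rep(0, 50))$magnitude,
               matrix(0, col$n_depths, 50))
})

test_that("task simulation reduces to the pure forward model without noise", {
  col <- default_column(drain_fraction = 0)
  p <- block_paradigm(4)
  prof <- double_peak_profile(col)
  cts <- simulate_task(col, p, activation_profile = prof, b = 0,
                       noise_sd = 0, seed = 1, amp_pial = 0, amp_artery = 0,
                       amp_vein = 0)
  resp <- attr(cts, "ground_truth")$response
  expect_equal(cts$magnitude, col$baseline + 2 * outer(prof, resp),
               tolerance = 1e-12)
  expect_equal(unname(cts$phase), matrix(0, col$n_depths, n_volumes(p)))
})

test_that("VN gradient scales the vein contribution by its attenuation factor", {
  col <- default_column()
  p <- block_paradigm(4)
  args <- list(column = col, paradigm = p, noise_sd = 0, seed = 3,
               amp_pial = 0, amp_artery = 0)
  m0 <- do.call(simulate_task, c(args, b = 0))$magnitude
  m7 <- do.call(simulate_task, c(args, b = 7))$magnitude
  comps <- canonical_compartments()
  prof <- double_peak_profile(col)
  resp <- attr(do.call(simulate_task, c(args, b = 0)), "ground_truth")$response
  tissue <- col$tissue_weight * 2 * outer(prof, resp)
  vein <- leakage_operator(2 * outer(prof, resp), col$drain_fraction,
                           col$vein_weight)
  expected_diff <- (1 - vn_attenuation(7, comps$capillary)) * tissue +
    (1 - vn_attenuation(7, comps$vein)) * vein
  expect_equal(m0 - m7, expected_diff, tolerance = 1e-10)
})

test_that("simulations are reproducible bit-for-bit under a fixed seed", {
  col <- default_column()
  a <- simulate_task(col, block_paradigm(2), seed = 9)
  b <- simulate_task(col, block_paradigm(2), seed = 9)
  expect_identical(a$magnitude, b$magnitude)
  expect_identical(a$phase, b$phase)
  r1 <- simulate_rest(seed = 9, n_volumes = 60)
  r2 <- simulate_rest(seed = 9, n_volumes = 60)
  expect_identical(r1$M1$magnitude, r2$M1$magnitude)
  expect_error(simulate_task(col, block_paradigm(2)), "seed")
  expect_error(simulate_rest(n_volumes = 60), "seed")
})

test_that("resting network edges are recovered at the generator level", {
  col <- default_column(drain_fraction = 0)
  wdw <- three_layer_windows()
  # planted edge r = 0.6, no drainage, no noise, b large (veins nulled)
  net <- laminar_network_spec(
    rois = c("A", "B"),
    edges = data.frame(roi_a = "A", layer_a = "deep", roi_b = "B",
                       layer_b = "superficial", r = 0.6,
                       stringsAsFactors = FALSE))
  runs <- simulate_rest(net, col, b = 50, noise_sd = 0, n_volumes = 300,
                        seed = 21, amp_pial = 0)
  a_deep <- sample_layers(runs$A$magnitude, runs$A$sites$depth, wdw)$deep
  b_sup <- sample_layers(runs$B$magnitude, runs$B$sites$depth, wdw)$superficial
  r_hat <- cor(a_deep, b_sup)
  # Fisher-z tolerance; band-limited samples have fewer effective dof than
  # white noise, so allow 4x the nominal SE 1/sqrt(n-3)
  expect_lt(abs(atanh(r_hat) - atanh(0.6)), 4 / sqrt(300 - 3))
  # null edge stays null
  net0 <- laminar_network_spec(rois = c("A", "B"))
  runs0 <- simulate_rest(net0, col, b = 50, noise_sd = 0, n_volumes = 300,
                         seed = 22, amp_pial = 0)
  r0 <- cor(sample_layers(runs0$A$magnitude, runs0$A$sites$depth, wdw)$deep,
            sample_layers(runs0$B$magnitude, runs0$B$sites$depth, wdw)$superficial)
  expect_lt(abs(r0), 4 / sqrt(300))
  # non-PSD network errors naming the edges
  bad <- laminar_network_spec(
    rois = c("A", "B", "C"),
    edges = data.frame(roi_a = c("A", "A", "B"),
                       layer_a = "deep",
                       roi_b = c("B", "C", "C"), layer_b = "deep",
                       r = c(0.9, 0.9, -0.9), stringsAsFactors = FALSE))
  expect_error(simulate_rest(bad, col, seed = 1, n_volumes = 20),
               "positive semi-definite")
})

test_that("drainage raises intra-column depth coupling and VN lowers it", {
  col <- default_column(drain_fraction = 0.4)
  net <- laminar_network_spec(rois = "A")
  sup <- which(col$depth > 0.7)
  mean_off <- function(runs) {
    z <- depth_fc_matrix(bandpass(runs$A$magnitude, TR_s = 4))$z[sup, sup]
    mean(z[row(z) != col(z)], na.rm = TRUE)
  }
  z_b0 <- mean_off(simulate_rest(net, col, b = 0, seed = 31))
  z_b7 <- mean_off(simulate_rest(net, col, b = 7, seed = 31))
  expect_gt(z_b0, z_b7)
  # energy ordering: vein-compartment variance shrinks under any b > 0
  r0 <- simulate_rest(net, col, b = 0, noise_sd = 0, seed = 32, amp_pial = 0)
  r7 <- simulate_rest(net, col, b = 7, noise_sd = 0, seed = 32, amp_pial = 0)
  expect_gt(sum(apply(r0$A$magnitude, 1, var)),
            sum(apply(r7$A$magnitude, 1, var)))
})

test_that("subject cohorts share neural sources across paired conditions", {
  cohort <- make_subject_cohort(n_subjects = 3, between_subject_sd = 0,
                                seed = 5, n_volumes = 80, noise_sd = 0)
  s1 <- cohort[[1]]
  expect_named(s1$runs, c("b0", "b7"))
  # with zero noise, paired runs differ only via deterministic attenuation:
  # the b0/b7 magnitude difference is exactly the attenuated vascular share
  m0 <- s1$runs$b0$M1$magnitude
  m7 <- s1$runs$b7$M1$magnitude
  expect_gt(cor(as.vector(m0 - 100), as.vector(m7 - 100)), 0.9)
  # zero between-subject SD -> identical generative parameters
  expect_equal(s1$params$drain_fraction, cohort[[2]]$params$drain_fraction)
  expect_error(make_subject_cohort(n_subjects = 1, seed = 1), ">= 2")
})
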