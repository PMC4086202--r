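test_that("a fixed seed reproduces the cohort bit for bit", {
  cfg <- small_planted_config(seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$runs, b$runs)
  expect_identical(a$events, b$events)
  expect_identical(a$surrogate_t, b$surrogate_t)
  expect_identical(a$truth$subject_params, b$truth$subject_params)

  c2 <- simulate_cohort(small_planted_config(seed = 43))
  expect_false(identical(a$runs[[1]][[1]], c2$runs[[1]][[1]]))
})

test_that("cohort geometry matches the configuration", {
  cfg <- sim_config(seed = 5)
  coh <- simulate_cohort(cfg)
  expect_equal(as.integer(table(coh$subjects$group)[c("HV", "PD")]),
               c(14L, 12L))
  expect_length(coh$runs, 26)
  expect_length(coh$runs[[1]], 4)
  expect_equal(dim(coh$runs[[1]][[1]]), c(146, 62))
  expect_equal(nrow(coh$schedule), 4 * 146)
  # every subject has surrogate t-values for the 10 subcortical ROIs
  expect_equal(nrow(coh$surrogate_t), 26 * 10)
})

test_that("a shared noise-free latent factor yields correlation 1", {
  roi <- small_roi()
  pair <- roi[roi$name %in% c("SMA1", "PreSMA1"), ]
  cfg <- sim_config(roi = pair, n_per_group = c(A = 1, B = 1), n_runs = 1,
                    frames_per_run = 60, base_coupling = 1,
                    planted_edges = no_planted_edges(),
                    activity_gain = 0, coupling_sd = 0, seed = 2)
  coh <- simulate_cohort(cfg)
  run <- coh$runs[[1]][[1]]
  expect_equal(unname(stats::cor(run[, 1], run[, 2])), 1, tolerance = 1e-12)
})

test_that("an over-budgeted covariance is rejected naming the ROI", {
  expect_error(
    sim_config(roi = small_roi(), planted_edges = tibble::tibble(
      node1 = "DLPFC1", node2 = "SOG1", coupling = 0.95,
      attenuated = TRUE, driver = "shared"
    )),
    "positive semi-definite.*DLPFC1"
  )
  # budget is checked at the coupling-scalar maximum, not just its mean
  expect_error(
    sim_config(roi = small_roi(), coupling_sd = 0.3,
               planted_edges = tibble::tibble(
                 node1 = "DLPFC1", node2 = "SOG1", coupling = 0.6,
                 attenuated = TRUE, driver = "shared")),
    "positive semi-definite"
  )
})

test_that("empirical correlations converge to the closed-form values", {
  # long single run, no coupling heterogeneity, no activity offsets:
  # cross-community planted edge -> r = b^2; same-community pair -> rho;
  # same-community planted edge -> rho + b^2
  roi <- small_roi()
  cfg <- sim_config(
    roi = roi, n_per_group = c(A = 1, B = 1), n_runs = 1,
    frames_per_run = 4000, base_coupling = 0.25,
    planted_edges = tibble::tibble(
      node1 = c("DLPFC1", "SMA1"), node2 = c("SOG1", "PreSMA1"),
      coupling = 0.55, attenuated = FALSE, driver = "shared"),
    activity_gain = 0, coupling_sd = 0, seed = 11
  )
  coh <- simulate_cohort(cfg)
  r <- stats::cor(coh$runs[[1]][[1]])
  tol <- 4 / sqrt(4000)
  expect_equal(unname(r["DLPFC1", "SOG1"]), 0.55^2, tolerance = tol)
  expect_equal(unname(r["SMA1", "PreSMA1"]), 0.25 + 0.55^2, tolerance = tol)
  expect_equal(unname(r["PMd1", "M1-1"]), 0.25, tolerance = tol)  # community
  expect_equal(unname(r["DLPFC1", "LG1"]), 0, tolerance = tol)    # cross
  # matches the truth table's implied correlations
  tr <- coh$truth$subject_couplings
  expect_equal(tr$implied_r[tr$node1 == "DLPFC1" & tr$subject == "sub01"],
               0.55^2)
})

test_that("attenuation multiplier 1 plants no group difference", {
  cfg <- sim_config(
    roi = small_roi(), n_per_group = c(A = 7, B = 6), n_runs = 1,
    frames_per_run = 300, attenuation = 1, coupling_sd = 0,
    planted_edges = tibble::tibble(
      node1 = "DLPFC1", node2 = "SOG1", coupling = 0.55,
      attenuated = TRUE, driver = "shared"),
    activity_gain = 0, seed = 7
  )
  coh <- simulate_cohort(cfg)
  cond <- cohort_condition_matrices(coh)
  corrs <- lapply(cond, correlation_matrix)
  ez <- subject_edge_z(corrs, coh$subjects,
                       tibble::tibble(node1 = "DLPFC1", node2 = "SOG1"))
  diff <- mean(ez$z[ez$group == "A"]) - mean(ez$z[ez$group == "B"])
  expect_lt(abs(diff), 0.2)
  # and the coupling itself is identical across groups
  cp <- coh$truth$subject_couplings
  expect_equal(length(unique(round(cp$coupling, 12))), 1L)
})

test_that("group-2 couplings are attenuated only on attenuated edges", {
  cfg <- small_planted_config(seed = 9)
  coh <- simulate_cohort(cfg)
  cp <- coh$truth$subject_couplings
  pars <- coh$truth$subject_params
  driver_of <- function(row) {
    p <- pars[pars$subject == row$subject, ]
    switch(row$driver, shared = p$s_shared, dlpfc = p$s_dlpfc,
           vlpfc = p$s_vlpfc)
  }
  for (i in seq_len(nrow(cp))) {
    base <- cp$coupling[i] / driver_of(cp[i, ])
    want <- 0.55 * if (cp$group[i] == "PD" && cp$attenuated[i]) 0.5 else 1
    expect_equal(base, want, tolerance = 1e-12)
  }
})

test_that("the planted-truth report tabulates every effect", {
  cfg <- sim_config(seed = 1)
  rep_ <- planted_truth_report(simulate_cohort(cfg)$truth)
  edges <- rep_[rep_$type == "edge", ]
  expect_equal(sum(edges$attenuated), 5L)
  expect_true(all(edges$effect[edges$attenuated] > 0))
  expect_equal(edges$effect[!edges$attenuated], 0)
  slopes <- rep_[rep_$type == "rt_slope", ]
  expect_lt(slopes$effect[slopes$name == "dlpfc_striatum"], 0)
  expect_gt(slopes$effect[slopes$name == "vlpfc_striatum"], 0)
  gains <- rep_[rep_$type == "activity_gain", ]
  expect_equal(nrow(gains), 10L)
  expect_true(all(gains$effect[grepl("^Thal", gains$name)] < 0))
  expect_true(all(gains$effect[!grepl("^Thal", gains$name)] > 0))

  # zero-effect configuration -> all planted effects are zero
  cfg0 <- sim_config(
    roi = small_roi(), attenuation = 1, activity_gain = 0,
    planted_edges = tibble::tibble(
      node1 = "DLPFC1", node2 = "SOG1", coupling = 0.5,
      attenuated = TRUE, driver = "shared"),
    rt_model = list(intercept_ms = 900, beta_dlpfc_ms = 0,
                    beta_vlpfc_ms = 0, sd_ms = 60))
  rep0 <- planted_truth_report(simulate_cohort(cfg0)$truth)
  expect_equal(max(abs(rep0$effect[rep0$type != "edge"])), 0)
  expect_equal(rep0$effect[rep0$type == "edge"], 0)
})

test_that("the volume fixture is deterministic and self-consistent", {
  peaks <- tibble::tibble(name = c("A", "B"), x = c(0, 30),
                          y = c(0, 0), z = c(0, 0))
  f1 <- simulate_volume_fixture(peaks, frames = 10, seed = 4)
  f2 <- simulate_volume_fixture(peaks, frames = 10, seed = 4)
  expect_identical(f1$volume, f2$volume)
  # affine maps voxel indices back to the stated mm coordinates
  v <- round(solve(f1$affine, c(0, 0, 0, 1)))[1:3]
  expect_equal(as.numeric(f1$affine[1:3, ] %*% c(v, 1)), c(0, 0, 0),
               tolerance = 1e-9)

  # noise-free fixture round-trips exactly through extraction
  f0 <- simulate_volume_fixture(peaks, frames = 6, seed = 4, noise_sd = 0)
  got <- extract_roi_timeseries(f0$volume, f0$affine, peaks)
  expect_equal(got, f0$signals, tolerance = 1e-12)

  # constant planted signal is recovered as a constant
  sig <- matrix(c(rep(5, 6), rep(2, 6)), ncol = 2)
  fc <- simulate_volume_fixture(peaks, frames = 6, seed = 1,
                                signals = sig, noise_sd = 0)
  expect_equal(unname(extract_roi_timeseries(fc$volume, fc$affine,
                                             peaks)[, 1]),
               rep(5, 6))
})

test_that("overlapping ROI cubes are rejected with the colliding pair", {
  peaks <- tibble::tibble(name = c("A", "B"), x = c(0, 4),
                          y = c(0, 0), z = c(0, 0))
  expect_error(simulate_volume_fixture(peaks, frames = 3, voxel_mm = 3),
               "overlap.*A/B")
})
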