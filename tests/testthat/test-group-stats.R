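make_edge_z <- function(z1, z2, node1 = "a", node2 = "b",
                        groups = c("HV", "PD")) {
  tibble::tibble(
    subject = c(sprintf("h%d", seq_along(z1)),
                sprintf("p%d", seq_along(z2))),
    group = rep(groups, c(length(z1), length(z2))),
    node1 = node1, node2 = node2,
    z = c(z1, z2)
  )
}

test_that("the pooled t-test matches its closed form", {
  tt <- edgewise_group_ttest(make_edge_z(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(tt$t, -1.224745, tolerance = 1e-6)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.2878641, tolerance = 1e-6)
  expect_equal(tt$direction, "PD>HV")
  expect_false(tt$significant)

  # against an independent closed-form oracle on random draws
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
    got <- edgewise_group_ttest(make_edge_z(x, y))
    want <- oracle_pooled_t(x, y)
    expect_equal(got$t, want$t)
    expect_equal(got$df, want$df)
    expect_equal(got$p, want$p)
  }
})

test_that("identical groups give t = 0 and zero variance is degenerate", {
  same <- edgewise_group_ttest(make_edge_z(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_false(same$degenerate)
  flat <- edgewise_group_ttest(make_edge_z(c(2, 2, 2), c(2, 2, 2)))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$p))
  expect_error(edgewise_group_ttest(make_edge_z(1, c(1, 2))),
               "at least 2 subjects")
})

test_that("the Welch variant is available as a sensitivity switch", {
  set.seed(3)
  x <- rnorm(5); y <- rnorm(7, sd = 3)
  pooled <- edgewise_group_ttest(make_edge_z(x, y), var_equal = TRUE)
  welch <- edgewise_group_ttest(make_edge_z(x, y), var_equal = FALSE)
  expect_equal(welch$t, unname(t.test(x, y)$statistic))
  expect_false(isTRUE(all.equal(pooled$df, welch$df)))
})

test_that("edge-activity correlations recover exact relationships", {
  set.seed(4)
  z <- rnorm(10)
  ez <- tibble::tibble(subject = sprintf("s%d", 1:10),
                       node1 = "a", node2 = "b", z = z)
  act <- tibble::tibble(subject = rep(sprintf("s%d", 1:10), 2),
                        roi = rep(c("Put1", "Thal1"), each = 10),
                        activity = c(2 * z, rep(1, 10)))
  out <- edge_activity_correlation(ez, act)
  put <- out[out$roi == "Put1", ]
  expect_equal(put$r, 1)
  expect_true(put$significant)
  tha <- out[out$roi == "Thal1", ]
  expect_true(tha$degenerate)  # constant activity
  expect_error(
    edge_activity_correlation(ez, act[act$subject != "s1", ]),
    "same subjects"
  )
})

test_that("edge-RT correlations apply FDR everywhere except the DLPFC", {
  roi <- costnet::roi_table()
  set.seed(6)
  subs <- sprintf("s%d", 1:12)
  rtv <- rnorm(12, 900, 100)
  cort <- c("DLPFC1", "SMA1", "PreSMA1", "SOG1", "VLPFC1")
  ez <- purrr::map_dfr(cort, function(cn) {
    z <- if (cn == "DLPFC1") -(rtv - 900) / 200 + rnorm(12, 0, 0.1) else rnorm(12)
    tibble::tibble(subject = subs, node1 = cn, node2 = "Put1", z = z)
  })
  rt <- tibble::tibble(subject = subs, rt_ms = rtv)
  out <- edge_rt_correlation(ez, rt, roi)
  dl <- out[out$cortical == "DLPFC1", ]
  expect_lt(dl$r, -0.9)
  expect_true(is.na(dl$p_adj))   # uncorrected by design
  expect_true(dl$significant)
  others <- out[out$cortical != "DLPFC1", ]
  expect_equal(others$p_adj, bh_fdr(others$p))
  # exact anticorrelation
  ez1 <- tibble::tibble(subject = subs, node1 = "DLPFC1", node2 = "Put1",
                        z = -(rtv - 900))
  expect_equal(edge_rt_correlation(ez1, rt, roi)$r, -1)
  # an edge with two subcortical members is a contract violation
  bad <- tibble::tibble(subject = subs, node1 = "Put1", node2 = "Thal1",
                        z = rnorm(12))
  expect_error(edge_rt_correlation(bad, rt, roi), "one cortical")
})

test_that("Benjamini-Hochberg adjustment matches the step-up closed form", {
  expect_equal(bh_fdr(c(0.005, 0.02, 0.03, 0.04)),
               c(0.02, 0.04, 0.04, 0.04))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  set.seed(8)
  p <- runif(20)
  expect_true(all(bh_fdr(p) >= p))
  o <- sample(20)
  expect_equal(bh_fdr(p)[o], bh_fdr(p[o]))  # order invariance
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("the Wilcoxon comparison matches exact enumeration", {
  pl <- tibble::tibble(
    subject = sprintf("s%d", 1:4),
    group = c("HV", "HV", "PD", "PD"),
    source = "M1-1", target = "SMA1",
    length = c(1, 2, 3, 4)
  )
  out <- pathlength_group_comparison(pl)
  expect_equal(out$p, 1 / 3, tolerance = 1e-9)
  expect_equal(out$mean_group1, 1.5)
  expect_equal(out$mean_group2, 3.5)

  # identical distributions
  pl2 <- pl; pl2$length <- c(1, 2, 1, 2)
  expect_equal(pathlength_group_comparison(pl2)$p, 1, tolerance = 1e-9)

  # agreement with exhaustive permutation enumeration (no ties)
  set.seed(9)
  for (i in 1:8) {
    x <- runif(5, 0, 100); y <- runif(4, 20, 120)
    pli <- tibble::tibble(
      subject = sprintf("s%d", 1:9),
      group = rep(c("A", "B"), c(5, 4)),
      source = "src", target = "tgt",
      length = c(x, y)
    )
    expect_equal(pathlength_group_comparison(pli)$p,
                 oracle_wilcoxon_exact(x, y), tolerance = 1e-9)
  }
})

test_that("unreachable path lengths are excluded and counted", {
  pl <- tibble::tibble(
    subject = sprintf("s%d", 1:8),
    group = rep(c("HV", "PD"), each = 4),
    source = "M1-1", target = "SMA1",
    length = c(1, 2, NA, 2, 3, 4, 3, NA)
  )
  out <- pathlength_group_comparison(pl)
  expect_equal(out$n_excluded, 2L)
  expect_equal(out$n_group1, 3L)
  expect_equal(out$n_group2, 3L)
  expect_false(out$untestable)
  # fewer than 2 finite values in a group is untestable
  pl$length[c(1, 2, 3)] <- NA
  out2 <- pathlength_group_comparison(pl)
  expect_true(out2$untestable)
  expect_true(is.na(out2$p))
})

test_that("subject path lengths flow from networks into the comparison", {
  nodes <- c("M1-1", "SMA1", "SOG1")
  chain <- make_net(nodes, rbind(c("M1-1", "SMA1"), c("SMA1", "SOG1")))
  direct <- make_net(nodes, rbind(c("M1-1", "SOG1")))
  nets <- list(s1 = chain, s2 = chain, s3 = direct, s4 = direct)
  subjects <- tibble::tibble(subject = sprintf("s%d", 1:4),
                             group = c("HV", "HV", "PD", "PD"))
  pl <- subject_path_lengths(nets, subjects, "M1-1")
  expect_equal(nrow(pl), 8L)
  expect_equal(pl$length[pl$subject == "s1" & pl$target == "SOG1"], 2)
  expect_true(is.na(pl$length[pl$subject == "s3" & pl$target == "SMA1"]))
  out <- pathlength_group_comparison(pl)
  expect_equal(out$n_excluded[out$target == "SMA1"], 2L)
  expect_error(subject_path_lengths(nets, subjects, "nope"),
               "not in the network")
})
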