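test_that("deterministic lineages settle into an exact periodic steady state", {
  lin <- steady_lineage()
  expect_s3_class(lin, "cell_lineage")
  expect_identical(lin$status, "steady")
  r <- lin$records
  expect_lt(diff(range(r$V_b)) / mean(r$V_b), 1e-3)
  expect_lt(diff(range(r$T_D)) / mean(r$T_D), 1e-3)
  ## volume continuity across division: V_b(k+1) = V_d(k) / 2
  expect_equal(r$V_b[-1], r$V_d[-nrow(r)] / 2, tolerance = 1e-9)
  ## the regulator ratio dips after birth before rising back to theta
  expect_true(all(r$t_at_min > 0.01))
  expect_true(all(r$ratio_min < r$theta_k))
})

test_that("free RNAP drops sharply at division while free ribosomes do not", {
  r <- steady_lineage()$records
  dF_n <- abs(r$F_n_d - r$F_n_b)
  dF_r <- abs(r$F_r_d - r$F_r_b)
  expect_gt(min(dF_n / pmax(dF_r, 1e-12)), 4)
})

test_that("seeded stochastic lineages replay exactly", {
  gp <- default_model()
  rule <- division_rule("ratio", theta_bar = 0.7, delta_theta = 0.1)
  a <- simulate_lineage(gp$genome, gp$params, rule, 8, seed = 5, burn_in = 3)
  b <- simulate_lineage(gp$genome, gp$params, rule, 8, seed = 5, burn_in = 3)
  expect_identical(a$records, b$records)
  expect_gt(stats::sd(a$records$theta_k), 0)
})

test_that("perturbed birth volumes relax back to the fixed point", {
  gp <- default_model()
  ti <- default_inputs()
  rule <- division_rule("ratio", theta = 0.8)
  ref <- steady_lineage()$records$V_b[1]
  for (fac in c(0.9, 1.1)) {
    lin <- simulate_lineage(gp$genome, gp$params, rule, 3, seed = 1,
                            burn_in = 3, V0 = fac * ref)
    expect_identical(lin$status, "steady")
    ## within <= 3 generations of burn-in the lineage is back on cycle
    expect_equal(lin$records$V_b[1], ref, tolerance = 0.01)
  }
})

test_that("a threshold outside the stable window never divides", {
  gp <- default_model()
  ti <- default_inputs()
  th <- critical_thresholds(ti)
  lin <- simulate_lineage(gp$genome, gp$params,
                          division_rule("ratio", theta = th[[1]] - 0.05),
                          1, seed = 1, burn_in = 0, horizon = 10)
  expect_identical(lin$status, "failed_no_division")
  expect_identical(lin$failed_generation, 1L)
})

test_that("asymmetric division partitions volume and inhibitor as configured", {
  gp <- default_model()
  rule <- division_rule("ratio", theta = 0.7, gamma = 0.4, eta = 0.45)
  lin <- simulate_lineage(gp$genome, gp$params, rule, 4, seed = 2,
                          burn_in = 10)
  expect_identical(lin$status, "steady")
  r <- lin$records
  ## the tracked daughter is the gamma fraction of the divided cell
  expect_equal(r$V_b[-1] / r$V_d[-nrow(r)], rep(0.4, nrow(r) - 1),
               tolerance = 1e-3)
})

test_that("the replication-delay variant divides T_M after the crossing", {
  gp <- default_model()
  rule <- division_rule("ratio", theta = 0.7, replication_delay = 1)
  lin <- simulate_lineage(gp$genome, gp$params, rule, 3, seed = 2,
                          burn_in = 10)
  expect_identical(lin$status, "steady")
  r <- lin$records
  expect_true(all(r$T_D > 1 + rule$t_min))
  ## steady periodic state again
  expect_lt(diff(range(r$V_b)) / mean(r$V_b), 1e-3)
  ## the ratio at division exceeds theta: growth continued for T_M after
  ## the crossing with the replicated genome
  base <- simulate_lineage(gp$genome, gp$params,
                           division_rule("ratio", theta = 0.7), 2, seed = 2,
                           burn_in = 10)
  expect_gt(mean(r$V_b), mean(base$records$V_b))
})

test_that("alternative division criteria produce stable cycles", {
  gp <- default_model(); g <- gp$genome; pp <- gp$params
  ## calibrate concentration thresholds from the ratio-rule steady state
  ref <- steady_lineage()
  st_d <- simulate_cycle(initialize_state(ref$records$V_b[1], g, pp),
                         division_rule("ratio", theta = 0.8), g, pp)
  i_act <- grep("^act", names(g$classes))
  i_inh <- grep("^inh", names(g$classes))
  c_act_d <- st_d$state_d$p[i_act] / st_d$V_d
  c_inh_d <- st_d$state_d$p[i_inh] / st_d$V_d
  lin_a <- simulate_lineage(g, pp,
                            division_rule("activator_only", theta = c_act_d),
                            3, seed = 1, burn_in = 8, V0 = ref$records$V_b[1])
  expect_identical(lin_a$status, "steady")
  expect_equal(mean(lin_a$records$V_d), st_d$V_d, tolerance = 0.1)
  lin_i <- simulate_lineage(g, pp,
                            division_rule("inhibitor_only", theta = c_inh_d),
                            3, seed = 1, burn_in = 8, V0 = ref$records$V_b[1])
  expect_identical(lin_i$status, "steady")
  expect_equal(mean(lin_i$records$V_d), st_d$V_d, tolerance = 0.1)
  lin_and <- simulate_lineage(
    g, pp, division_rule("and_logic", theta_act = c_act_d,
                         theta_inh = c_inh_d * 1.02),
    3, seed = 1, burn_in = 8, V0 = ref$records$V_b[1])
  expect_identical(lin_and$status, "steady")
})

test_that("hazard-based entry reproduces an imperfect sizer", {
  gp <- default_model()
  rule <- division_rule("hazard", hazard = make_power_hazard(200, 1))
  lin <- simulate_lineage(gp$genome, gp$params, rule, 120, seed = 3,
                          burn_in = 10, V0 = 0.25)
  expect_identical(lin$status, "steady")
  r <- lin$records
  ## the drawn division ratios vary and sit above the birth ratio
  expect_gt(stats::sd(r$theta_k), 0.005)
  ## imperfect sizer: division size now correlates with birth size
  expect_gt(binned_regression(r$V_b, r$V_d, 8)$slope, 0.15)
})

test_that("trajectory sampling exposes the within-cycle dynamics", {
  gp <- default_model()
  lin <- simulate_lineage(gp$genome, gp$params,
                          division_rule("ratio", theta = 0.8), 1, seed = 1,
                          burn_in = 6, trajectories = TRUE)
  tr <- lin$trajectories
  expect_true(all(c("t", "V", "c_act", "c_inh", "F_n", "F_r") %in%
                    names(tr)))
  last <- tr[tr$generation == max(tr$generation), ]
  ## volume grows within the cycle; the ratio ends at theta
  expect_gt(last$V[nrow(last)], last$V[1])
  expect_equal(last$c_act[nrow(last)] / last$c_inh[nrow(last)], 0.8,
               tolerance = 1e-3)
  expect_true(all(tr$F_n >= 0 & tr$F_n <= 1 & tr$F_r >= 0 & tr$F_r <= 1))
})

test_that("the nondegradable-inhibitor variant cycles in its narrow window", {
  ## with an accumulating inhibitor the ratio is orders of magnitude smaller
  ## and its rise-and-fall over the cycle leaves only a narrow viable window
  gp <- default_genome(nondegradable_inhibitor = TRUE)
  lin <- simulate_lineage(gp$genome, gp$params,
                          division_rule("ratio", theta = 0.0018), 3,
                          seed = 1, burn_in = 10, V0 = 0.3, horizon = 15)
  expect_identical(lin$status, "steady")
  expect_lt(diff(range(lin$records$V_b)) / mean(lin$records$V_b), 1e-3)
  ## just above the variant's upper critical point the curves no longer
  ## cross once the initial transient has decayed
  out <- simulate_lineage(gp$genome, gp$params,
                          division_rule("ratio", theta = 0.0019), 1,
                          seed = 1, burn_in = 6, V0 = 0.3, horizon = 15)
  expect_identical(out$status, "failed_no_division")
})
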