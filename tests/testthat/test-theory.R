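test_that("the effective promoter combination and critical window are exact", {
  expect_equal(ktilde(0.8, 12000, 4000), 5600)
  expect_equal(ktilde(4000 / 12000, 12000, 4000), 0, tolerance = 1e-9)
  ## linearity in theta
  th <- seq(0.2, 0.9, by = 0.1)
  expect_equal(diff(ktilde(th, 12000, 4000)), rep(0.1 * 12000, 7))
  expect_equal(unname(critical_thresholds(K_act = 12000, K_inh = 4000,
                                          c_n = 1e5)),
               c(1 / 3, (1e5 + 4000) / (1e5 + 12000)))
  ## equal promoters: degenerate empty window at 1
  expect_equal(unname(critical_thresholds(K_act = 5000, K_inh = 5000,
                                          c_n = 1e5)), c(1, 1))
  ## saturating nuclear RNAP pushes the upper threshold to 1
  expect_equal(unname(critical_thresholds(K_act = 12000, K_inh = 4000,
                                          c_n = 1e12))[2], 1,
               tolerance = 1e-7)
  ti <- default_inputs()
  expect_equal(unname(critical_thresholds(ti))[1], 1 / 3)
})

test_that("free fraction at division closes the division condition exactly", {
  ti <- default_inputs()
  th <- critical_thresholds(ti)
  ## ratio(F_n_d(theta)) == theta is an algebraic identity on the window
  for (theta in seq(th[1] + 1e-3, th[2] - 1e-3, length.out = 25)) {
    expect_equal(ratio_of_concentrations(
      free_fraction_at_division(theta, ti), ti), theta, tolerance = 1e-12)
  }
  expect_equal(free_fraction_at_division(th[[1]], ti), 0)
  expect_equal(free_fraction_at_division(th[[2]], ti), 1)
  expect_error(free_fraction_at_division(th[[2]] + 0.01, ti), "window")
})

test_that("the ratio of concentrations is monotone with the proper bounds", {
  ti <- default_inputs()
  th <- critical_thresholds(ti)
  Fs <- seq(0, 1, length.out = 200)
  vals <- ratio_of_concentrations(Fs, ti)
  expect_true(all(diff(vals) > 0))
  expect_equal(vals[1], th[[1]])
  expect_equal(vals[200], th[[2]])
})

test_that("birth volume rises across the window and scales with capacity", {
  ti <- default_inputs()
  th <- critical_thresholds(ti)
  grid <- seq(th[1] + 1e-4, th[2] - 1e-4, length.out = 100)
  vb <- vapply(grid, birth_volume, numeric(1), inputs = ti)
  expect_true(all(diff(vb) > 0))
  expect_equal(birth_volume(th[[1]], ti), 0)
  expect_lt(vb[1], 1e-3)
  ## doubling n_c (ploidy) doubles the volume pointwise
  ti2 <- ti; ti2$n_c <- 2 * ti$n_c
  expect_equal(vapply(grid, birth_volume, numeric(1), inputs = ti2), 2 * vb)
  expect_error(birth_volume(th[[1]] - 0.01, ti), "window")
})

test_that("theory quantities are ploidy-invariant where they should be", {
  gp <- default_model()
  g2 <- gp$genome; g2$ploidy <- 2
  ti1 <- default_inputs()
  ti2 <- theory_inputs(g2, gp$params)
  expect_equal(critical_thresholds(ti2), critical_thresholds(ti1))
  expect_equal(ti2$c_n, ti1$c_n)
  expect_equal(ti2$n_c, 2 * ti1$n_c)
  expect_equal(free_fraction_at_division(0.7, ti2),
               free_fraction_at_division(0.7, ti1))
  expect_equal(division_count_at_division(0.7, ti2),
               2 * division_count_at_division(0.7, ti1))
  expect_equal(birth_volume(0.7, ti2), 2 * birth_volume(0.7, ti1))
})

test_that("division-state counts are consistent with the birth volume", {
  ti <- default_inputs()
  gp <- default_model()
  th <- critical_thresholds(ti)
  theta <- 0.7
  ds <- division_state(theta, ti, genome = gp$genome, params = gp$params)
  ## volume implied by n_d through the RNAP concentration is twice V_b
  expect_equal(ti$a * ds$n_d / ti$c_n, 2 * birth_volume(theta, ti))
  expect_equal(ds$n_b, ds$n_d / 2)
  ## the n_d pole at theta2
  expect_equal(division_count_at_division(th[[2]], ti), Inf)
  ## mRNA vector: bulk class at its closed-form value
  mod_K <- vapply(gp$genome$classes, `[[`, numeric(1), "K_n")
  kt <- ktilde(theta, ti$K_act, ti$K_inh)
  i_b <- which(names(gp$genome$classes) == "bulk")
  cl <- gp$genome$classes[[i_b]]
  expect_equal(ds$m_d[[i_b]],
               cl$Gamma_n * cl$multiplicity * cl$tau_m * kt /
                 (kt + (1 - theta) * mod_K[[i_b]]), tolerance = 1e-12)
})

test_that("free fraction at birth matches a dense grid oracle", {
  ti <- default_inputs()
  expect_equal(free_fraction_at_birth(0, ti), 0)
  expect_equal(free_fraction_at_birth(Inf, ti), 1)
  for (nb in c(500, 5000, 20000)) {
    expect_equal(free_fraction_at_birth(nb, ti),
                 grid_fraction_oracle(nb, ti$n_c, ti$K_n, ti$c_n),
                 tolerance = 1e-6)
  }
  ## monotone in n_b
  nbs <- seq(100, 3e4, length.out = 10)
  expect_true(all(diff(vapply(nbs, free_fraction_at_birth, numeric(1),
                              inputs = ti)) > 0))
})

test_that("the amplitude vanishes at both critical thresholds and peaks once", {
  ti <- default_inputs()
  th <- critical_thresholds(ti)
  expect_identical(amplitude(th[[1]], ti), 0)
  expect_identical(amplitude(th[[2]], ti), 0)
  grid <- seq(th[1] + 1e-3, th[2] - 1e-3, length.out = 120)
  A <- vapply(grid, amplitude, numeric(1), inputs = ti)
  expect_true(all(A > 0))
  ## single interior maximum: the sign of the increment changes exactly once
  expect_equal(sum(diff(sign(diff(A))) != 0), 1)
})

test_that("stochastic moments obey the printed closed form and its limits", {
  ti <- default_inputs()
  mom0 <- stochastic_birth_moments(0.7, 0, ti)
  expect_equal(mom0$cv_V_b, 0)
  expect_equal(mom0$mean_V_b, birth_volume(0.7, ti))
  ## the closed-form CV equals the delta method applied numerically to the
  ## birth-volume curve (guards the long formula against transcription slips)
  for (tb in c(0.5, 0.6, 0.7, 0.8)) {
    h <- 1e-6
    dlogV <- (log(birth_volume(tb + h, ti)) -
                log(birth_volume(tb - h, ti))) / (2 * h)
    expect_equal(stochastic_birth_moments(tb, 0.1, ti)$cv_V_b,
                 abs(dlogV) * 0.1 / 3, tolerance = 1e-5)
  }
  ## CV falls with K_act at fixed K_inh (on the weak-promoter side of the
  ## shallow CV minimum), and rises with K_inh at fixed K_act
  cv_ka <- vapply(seq(9000, 15000, by = 1500), function(ka) {
    t2 <- ti; t2$K_act <- ka
    stochastic_birth_moments(0.7, 0.1, t2)$cv_V_b
  }, numeric(1))
  expect_true(all(diff(cv_ka) < 0))
  cv_ki <- vapply(seq(1000, 5000, by = 1000), function(ki) {
    t2 <- ti; t2$K_inh <- ki
    stochastic_birth_moments(0.7, 0.1, t2)$cv_V_b
  }, numeric(1))
  expect_true(all(diff(cv_ki) > 0))
})

test_that("the robustness condition reduces to amplitude positivity", {
  ti <- default_inputs()
  th <- critical_thresholds(ti)
  ## zero noise: viable exactly where A > 0 (strict interior)
  expect_true(robust_division_condition(0.7, 0, ti))
  expect_false(robust_division_condition(th[[2]] + 0.01, 0, ti))
  ## noise wider than half the peak amplitude kills every theta_bar
  A_max <- max(vapply(seq(th[1] + 1e-3, th[2] - 1e-3, length.out = 200),
                      amplitude, numeric(1), inputs = ti))
  dt_big <- A_max / 2 + 0.01
  grid <- seq(dt_big + 1e-3, th[2] - 1e-3, length.out = 50)
  expect_false(any(vapply(grid, robust_division_condition, logical(1),
                          delta_theta = dt_big, inputs = ti)))
  ## the band is consistent with the condition at its interior and edges
  band <- robust_theta_band(0.1, ti)
  expect_true(robust_division_condition(mean(band), 0.1, ti))
  expect_true(robust_division_condition(band[[1]] + 0.005, 0.1, ti))
  expect_false(robust_division_condition(band[[1]] - 0.005, 0.1, ti))
  expect_false(robust_division_condition(band[[2]] + 0.005, 0.1, ti))
})

test_that("birth volume is near-linear in the effective threshold midwindow", {
  ti <- default_inputs()
  th <- critical_thresholds(ti)
  W <- th[2] - th[1]
  grid <- seq(th[1] + 0.25 * W, th[2] - 0.25 * W, length.out = 50)
  kt <- ktilde(grid, ti$K_act, ti$K_inh)
  vb <- vapply(grid, birth_volume, numeric(1), inputs = ti)
  fit <- stats::lm(vb ~ kt)
  expect_gt(summary(fit)$r.squared, 0.99)
  ## where V_b is proportional to Ktilde (log-log slope near 1, around
  ## theta = 0.7 here) the birth-size CV equals the CV of the effective
  ## threshold, CV(Ktilde) = sigma * K_act / Ktilde
  for (tb in c(0.70, 0.72)) {
    cv_vb <- stochastic_birth_moments(tb, 0.1, ti)$cv_V_b
    cv_kt <- (0.1 / 3) * ti$K_act / ktilde(tb, ti$K_act, ti$K_inh)
    expect_equal(cv_vb, cv_kt, tolerance = 0.1)
  }
})
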