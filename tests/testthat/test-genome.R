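test_that("genome construction enforces the single-resource invariants", {
  expect_error(genome(list(gene_class("a", "bulk"))), "rnap")
  expect_error(
    genome(list(gene_class("n", "rnap"), gene_class("n2", "rnap"),
                gene_class("r", "ribosome"))), "rnap")
  expect_error(
    genome(list(gene_class("n", "rnap"), gene_class("n", "ribosome"))),
    "unique")
  expect_error(gene_class("x", "bulk", length = -1), "positive")
  g <- toy_genome()
  expect_s3_class(g, "genome")
  expect_identical(names(g$classes), c("rnap", "ribosome", "bulk"))
})

test_that("volume is total protein mass over density", {
  g <- toy_genome()
  pp <- toy_params()
  ## identity case: one unit of mass per unit volume
  g1 <- genome(list(
    gene_class("rnap", "rnap", length = 1, Gamma_n = 1, K_n = 1),
    gene_class("ribosome", "ribosome", length = 1, Gamma_n = 1, K_n = 1)))
  p1 <- global_params(a = 1, rho = 5, v_n = 1, v_r = 1, nc_target = 10)
  expect_equal(volume_of(c(5, 0), g1, p1), 1)
  ## hand sum: (2*3 + 3*4 + 4*2) / 8
  expect_equal(volume_of(c(2, 3, 4), g, pp), (6 + 12 + 8) / 8)
  ## linearity
  expect_equal(volume_of(2 * c(2, 3, 4), g, pp),
               2 * volume_of(c(2, 3, 4), g, pp))
  expect_error(volume_of(c(1, 2), g, pp), "match")
  expect_error(volume_of(c(0, 0, 0), g, pp), "zero")
})

test_that("genome capacity matches the hand sum and scales with ploidy", {
  ## two classes: {g = 2, Gamma*L/v_n = 4} and {g = 1, Gamma*L/v_n ~ 0}
  g <- genome(list(
    gene_class("rnap", "rnap", copy_number = 2, length = 1, Gamma_n = 4,
               K_n = 1),
    gene_class("ribosome", "ribosome", copy_number = 1, length = 1,
               Gamma_n = 1e-12, K_n = 1)))
  pp <- global_params(a = 1, rho = 1, v_n = 1, v_r = 1, nc_target = 100)
  expect_equal(total_capacity(g, pp), 11, tolerance = 1e-9)
  g$ploidy <- 2
  expect_equal(total_capacity(g, pp), 22, tolerance = 1e-9)
})

test_that("total RNAP concentration follows the steady-state formula", {
  g <- toy_genome(); pp <- toy_params()
  ## a*rho*Gamma_n g_n / sum(Gamma g L) = 2*8*10 / (30 + 28 + 6)
  expect_equal(rnap_concentration(g, pp), 2 * 8 * 5 * 2 / 64)
  ## ploidy invariance
  g2 <- g; g2$ploidy <- 2
  expect_equal(rnap_concentration(g2, pp), rnap_concentration(g, pp))
  ## genome with only the RNAP gene reduces to a*rho/L_n
  gn <- genome(list(
    gene_class("rnap", "rnap", length = 4, Gamma_n = 3, K_n = 1),
    gene_class("ribosome", "ribosome", copy_number = 1, length = 1,
               Gamma_n = 1e-14, K_n = 1)))
  expect_equal(rnap_concentration(gn, pp), 2 * 8 / 4, tolerance = 1e-9)
})

test_that("steady protein ratios are set by dosage times initiation rate", {
  g <- toy_genome(); pp <- toy_params()
  expect_equal(steady_protein_ratio(g, "rnap", pp), 1)
  expect_equal(steady_protein_ratio(g, "bulk", pp), (1 * 3) / (5 * 2))
  gd <- g
  gd$classes$bulk$tau_p <- 0.1
  expect_error(steady_protein_ratio(gd, "bulk", pp), "nondegradable")
})

test_that("model configurations round-trip through YAML and JSON", {
  gp <- default_model()
  for (ext in c("yml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_model_config(gp$genome, gp$params, path)
    back <- read_model_config(path)
    expect_equal(back$params, gp$params, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(back$genome$ploidy, gp$genome$ploidy)
    expect_equal(names(back$genome$classes), names(gp$genome$classes))
    for (nm in names(gp$genome$classes)) {
      expect_equal(back$genome$classes[[nm]], gp$genome$classes[[nm]],
                   tolerance = 1e-12)
    }
  }
})

test_that("regulator deletion and promoter swaps edit only what they should", {
  gp <- panel_model()
  g <- gp$genome
  gd <- delete_regulators(g, "act1")
  expect_false("act1" %in% names(gd$classes))
  expect_length(gd$classes, length(g$classes) - 1L)
  gs <- swap_promoters(g, "act1", "inh1")
  expect_equal(gs$classes$act1$K_n, g$classes$inh1$K_n)
  expect_equal(gs$classes$inh1$K_n, g$classes$act1$K_n)
  same <- setdiff(names(g$classes), c("act1", "inh1"))
  expect_equal(gs$classes[same], g$classes[same])
  ## cannot delete the last regulator of a kind
  gp1 <- default_model()
  expect_error(delete_regulators(gp1$genome, "act"), "last")
  ## lumped regulators lose one gene, not the class
  gl <- genome(list(
    gene_class("rnap", "rnap", length = 10, Gamma_n = 1, K_n = 1),
    gene_class("ribosome", "ribosome", length = 10, Gamma_n = 1, K_n = 1),
    gene_class("acts", "activator", multiplicity = 10, Gamma_n = 1,
               K_n = 12, tau_p = 1),
    gene_class("inhs", "inhibitor", multiplicity = 10, Gamma_n = 1, K_n = 4,
               tau_p = 1)))
  expect_equal(delete_regulators(gl, "acts")$classes$acts$multiplicity, 9)
})

test_that("the equivalent threshold maps multi-regulator rules to one pair", {
  expect_equal(equivalent_threshold(10, 10, 0.45), 0.45)
  expect_equal(equivalent_threshold(9, 10, 0.45), 0.5)
  ## equal weights cancel
  expect_equal(equivalent_threshold(4, 6, 0.3, chi_act = rep(2, 4),
                                    chi_inh = rep(2, 6)),
               equivalent_threshold(4, 6, 0.3))
  expect_error(equivalent_threshold(3, 3, 0.5, chi_act = rep(0, 3)), "zero")
})
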