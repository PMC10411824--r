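## Shared fixtures, built in code. Expensive objects are memoized so that
## several test files (and several acceptance blocks) reuse one computation.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

default_model <- function() memo("default_model", default_genome())

default_inputs <- function() {
  memo("default_inputs", {
    gp <- default_model()
    theory_inputs(gp$genome, gp$params)
  })
}

panel_model <- function() memo("panel_model", default_genome("panel"))

## A tiny hand-checkable genome: explicit rates, no calibration step.
toy_genome <- function() {
  genome(list(
    gene_class("rnap", "rnap", copy_number = 2, length = 3, Gamma_n = 5,
               K_n = 10),
    gene_class("ribosome", "ribosome", copy_number = 1, length = 4,
               Gamma_n = 7, K_n = 10),
    gene_class("bulk", "bulk", copy_number = 3, length = 2, Gamma_n = 1,
               K_n = 10)))
}

toy_params <- function() {
  global_params(a = 2, rho = 8, v_n = 1, v_r = 1, mu = 0.01, nc_target = 100)
}

## Steady deterministic lineage at theta = 0.8, shared across tests.
steady_lineage <- function() {
  memo("steady_lineage", {
    gp <- default_model()
    simulate_lineage(gp$genome, gp$params,
                     division_rule("ratio", theta = 0.8), 3,
                     seed = 1, burn_in = 10)
  })
}

## Brute-force oracle for the free-fraction balances: dense grid scan of the
## two sides of total*(1-F) = sum(w * F*conc / (F*conc + K)).
grid_fraction_oracle <- function(total, wts, K, conc, n_grid = 1e6) {
  F <- seq(0, 1, length.out = n_grid + 1)
  lhs <- total * (1 - F)
  rhs <- vapply(F, function(f) sum(wts * f * conc / (f * conc + K)),
                numeric(1))
  d <- lhs - rhs
  i <- which(d[-1] <= 0 & d[-length(d)] > 0)[1]
  if (is.na(i)) return(if (d[1] <= 0) 0 else 1)
  ## linear interpolation inside the bracketing grid cell
  F[i] + (F[i + 1] - F[i]) * d[i] / (d[i] - d[i + 1])
}
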