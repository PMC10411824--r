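## Observation grid for event monitoring within a cycle: fine early (the
## activator-to-inhibitor ratio dips within a few regulator lifetimes of
## birth), coarser later.
.obs_times <- function(t0, t1, fine_until = 1, fine_dt = 0.005,
                       coarse_dt = 0.05) {
  if (t1 <= t0) return(c(t0, t1))
  brk <- min(t1, t0 + fine_until)
  tt <- seq(t0, brk, by = fine_dt)
  if (brk < t1) tt <- c(tt, seq(brk + coarse_dt, t1, by = coarse_dt))
  unique(c(tt, t1))
}

.desolve_func <- function(mod, cache) {
  k <- length(mod$L)
  function(t, y, parms) {
    d <- .rhs(y[seq_len(k)], y[k + seq_len(k)], mod, cache)
    list(c(d$dm, d$dp))
  }
}

## Integrate one cell cycle from a birth state until the first upward
## zero-crossing of the division signal at t >= t_min (plus an optional
## replication delay). Returns the division-time state, timing, the minimum
## of the monitored ratio, and optional trajectory samples.
.cycle_impl <- function(y0, mod, mod_rep, rule, theta, horizon,
                        trajectories = FALSE, hazard_draw = NULL,
                        rtol = 1e-8, atol = 1e-8) {
  k <- length(mod$L)
  cache <- new.env(parent = emptyenv())
  func <- .desolve_func(mod, cache)
  sig <- function(y) .signal_value(y[k + seq_len(k)], mod, rule, theta)
  rootfunc <- function(t, y, parms) sig(y)
  ratio_of <- function(y) {
    s <- .regulator_sums(y[k + seq_len(k)], mod)
    if (s$inh > 0) s$act / s$inh else NA_real_
  }
  traj <- if (trajectories) list() else NULL
  keep_rows <- function(out) {
    if (trajectories) traj[[length(traj) + 1L]] <<- out
  }
  ratio_min <- ratio_of(y0); t_at_min <- 0
  scan_min <- function(out) {
    rr <- apply(out[, 1L + k + seq_len(k), drop = FALSE], 1L, function(p) {
      s <- .regulator_sums(p, mod)
      if (s$inh > 0) s$act / s$inh else NA_real_
    })
    i <- which.min(rr)
    if (length(i) && !is.na(rr[i]) && rr[i] < ratio_min) {
      ratio_min <<- rr[i]; t_at_min <<- out[i, 1L]
      ## parabolic refinement through the bracketing samples
      if (i > 1L && i < length(rr) && all(is.finite(rr[(i - 1L):(i + 1L)]))) {
        t3 <- out[(i - 1L):(i + 1L), 1L]; r3 <- rr[(i - 1L):(i + 1L)]
        d2 <- (r3[3L] - 2 * r3[2L] + r3[1L])
        if (d2 > 0) {
          s <- 0.5 * (r3[1L] - r3[3L]) / d2   # offset in grid units
          if (abs(s) <= 1) {
            ratio_min <<- r3[2L] - 0.25 * (r3[1L] - r3[3L]) * s
            t_at_min <<- t3[2L] + s * (t3[3L] - t3[2L])
          }
        }
      }
    }
  }

  ## phase 1: the minimal cycle time, no event detection
  y <- y0; t_cur <- 0
  if (rule$t_min > 0) {
    tt <- .obs_times(0, rule$t_min)
    out <- deSolve::lsoda(y, tt, func, parms = NULL, rtol = rtol, atol = atol)
    keep_rows(out); scan_min(out)
    y <- out[nrow(out), -1L]; t_cur <- rule$t_min
  }
  ## probabilistic entry samples its division ratio from the post-dip state
  ## (sig/rootfunc read `theta` lexically, so assigning it here suffices)
  if (!is.null(hazard_draw)) theta <- hazard_draw(ratio_of(y))

  ## phase 2: run with root detection; accept only upward crossings
  t_cross <- NA_real_
  repeat {
    if (t_cur >= horizon) break
    tt <- .obs_times(t_cur, horizon)
    out <- deSolve::lsodar(y, tt, func, parms = NULL, rootfunc = rootfunc,
                           rtol = rtol, atol = atol)
    keep_rows(out); scan_min(out)
    troot <- attributes(out)$troot
    y <- out[nrow(out), -1L]
    t_cur <- out[nrow(out), 1L]
    if (is.null(troot) || length(troot) == 0L) break   # horizon reached
    ## crossing direction from the flow at the root
    d <- .rhs(y[seq_len(k)], y[k + seq_len(k)], mod, cache)
    h <- 1e-7
    y2 <- y + h * c(d$dm, d$dp)
    if ((sig(y2) - sig(y)) / h > 0) { t_cross <- t_cur; break }
    ## downward crossing (the post-birth dip): nudge past the root and go on
    tt2 <- c(t_cur, t_cur + 1e-3)
    out2 <- deSolve::lsoda(y, tt2, func, parms = NULL, rtol = rtol,
                           atol = atol)
    y <- out2[nrow(out2), -1L]; t_cur <- out2[nrow(out2), 1L]
  }

  if (is.na(t_cross)) {
    return(list(status = "failed_no_division", t_d = NA_real_, y_d = y,
                theta = theta, ratio_min = ratio_min, t_at_min = t_at_min,
                traj = traj, mod_at_division = mod))
  }

  mod_d <- mod
  if (!is.null(rule$replication_delay)) {
    ## threshold crossing triggers genome replication; division T_M later
    mod_d <- mod_rep
    cache2 <- new.env(parent = emptyenv())
    func2 <- .desolve_func(mod_rep, cache2)
    tt <- .obs_times(t_cross, t_cross + rule$replication_delay)
    out <- deSolve::lsoda(y, tt, func2, parms = NULL, rtol = rtol,
                          atol = atol)
    keep_rows(out); scan_min(out)
    y <- out[nrow(out), -1L]
    t_cross <- t_cross + rule$replication_delay
  }

  list(status = "divided", t_d = t_cross, y_d = y, theta = theta,
       ratio_min = ratio_min, t_at_min = t_at_min, traj = traj,
       mod_at_division = mod_d)
}

#' Simulate one cell cycle
#'
#' Integrates the gene-expression dynamics from a birth state until the first
#' upward zero-crossing of the division signal with `t >= t_min` (the crossing
#' located by the integrator's root finder), optionally followed by the
#' replication delay `T_M` with doubled gene copy numbers.
#'
#' @param state Birth [cell_state()].
#' @param rule A [division_rule()].
#' @inheritParams volume_of
#' @param theta Threshold for this cycle; when `NULL` it is drawn from the
#'   rule ([draw_threshold()], or the hazard for `kind = "hazard"`).
#' @param horizon Give up and report `failed_no_division` after this many
#'   hours (default `10 / mu`).
#' @return List with the cycle record fields (`V_b`, `V_d`, `T_D`,
#'   `theta_k`, `ratio_min`, `status`) and `state_d`, the division-time
#'   [cell_state()] (before partitioning).
#' @export
simulate_cycle <- function(state, rule, genome, params, theta = NULL,
                           horizon = NULL) {
  mod <- .compile_model(genome, params)
  .check_calibrated(mod)
  mod_rep <- if (!is.null(rule$replication_delay)) {
    g2 <- genome; g2$ploidy <- g2$ploidy * 2
    .compile_model(g2, params)
  }
  if (is.null(horizon)) horizon <- 10 / params$mu
  hazard_draw <- NULL
  if (is.null(theta)) {
    if (rule$kind == "hazard") {
      hazard_draw <- function(ratio) hazard_sample_division(rule$hazard,
                                                            ratio)
    } else if (!is.null(rule$theta_sequence)) {
      theta <- rule$theta_sequence[1L]
    } else if (!is.null(rule$theta_bar)) {
      theta <- draw_threshold(rule$theta_bar, rule$delta_theta)
    }
  }
  y0 <- c(state$m, state$p)
  res <- .cycle_impl(y0, mod, mod_rep, rule, theta, horizon,
                     hazard_draw = hazard_draw)
  k <- length(mod$L)
  p_d <- res$y_d[k + seq_len(k)]
  list(V_b = sum(state$p * mod$L) / mod$rho,
       V_d = sum(p_d * res$mod_at_division$L) / res$mod_at_division$rho,
       T_D = res$t_d, theta_k = res$theta, ratio_min = res$ratio_min,
       status = res$status,
       state_d = cell_state(ifelse(is.na(res$t_d), 0, res$t_d),
                            pmax(res$y_d[seq_len(k)], 0), pmax(p_d, 0)))
}

#' Simulate a single-cell lineage
#'
#' Runs `burn_in + n_generations` consecutive cell cycles, tracking one
#' daughter after every division, and records per-generation birth and
#' division volumes, cycle duration, threshold, and the within-cycle minimum
#' of the activator-to-inhibitor ratio. The first `burn_in` generations are
#' discarded so the reported cycles sample the (periodic or stochastic)
#' steady state.
#'
#' @inheritParams simulate_cycle
#' @param n_generations Number of recorded generations.
#' @param seed Integer seed making all threshold draws reproducible.
#' @param burn_in Generations discarded before recording.
#' @param V0 Initial volume; defaults to the theory birth volume when the
#'   rule admits one, so burn-in is short.
#' @param trajectories If `TRUE`, keep time series of
#'   `(t, V, c_act, c_inh, F_n, F_r)` (time measured within each cycle,
#'   cycles concatenated with a generation column).
#' @return An object of class `cell_lineage` with elements `records` (a
#'   data.frame with columns `k, V_b, V_d, delta_V, T_D, theta_k, ratio_min,
#'   t_at_min, F_n_b, F_n_d, F_r_b, F_r_d, n_d`), `status` (`"steady"` or
#'   `"failed_no_division"`), `failed_generation`, `burn_in`, `seed`,
#'   `trajectories`.
#' @export
simulate_lineage <- function(genome, params, rule, n_generations,
                             seed = NULL, burn_in = 10L, V0 = NULL,
                             horizon = NULL, trajectories = FALSE) {
  stopifnot(n_generations >= 1)
  mod <- .compile_model(genome, params)
  .check_calibrated(mod)
  mod_rep <- if (!is.null(rule$replication_delay)) {
    g2 <- genome; g2$ploidy <- g2$ploidy * 2
    .compile_model(g2, params)
  }
  if (is.null(horizon)) horizon <- 10 / params$mu
  if (!is.null(seed)) set.seed(seed)
  if (is.null(V0)) V0 <- .default_V0(mod, rule)
  state <- initialize_state(V0, genome, params)
  k <- length(mod$L)
  total <- burn_in + n_generations
  rec <- vector("list", n_generations)
  trj <- if (trajectories) vector("list", total) else NULL
  status <- "steady"; failed_gen <- NA_integer_

  hazard_draw <- if (rule$kind == "hazard") {
    function(ratio) hazard_sample_division(rule$hazard, ratio)
  }
  for (g in seq_len(total)) {
    theta <- if (rule$kind == "hazard") {
      NULL                       # drawn mid-cycle from the post-dip ratio
    } else if (!is.null(rule$theta_sequence)) {
      rule$theta_sequence[(g - 1L) %% length(rule$theta_sequence) + 1L]
    } else if (!is.null(rule$theta_bar)) {
      draw_threshold(rule$theta_bar, rule$delta_theta)
    } else NA_real_
    y0 <- c(state$m, state$p)
    res <- .cycle_impl(y0, mod, mod_rep, rule, theta, horizon,
                       trajectories = trajectories,
                       hazard_draw = hazard_draw)
    theta <- res$theta
    if (trajectories) trj[[g]] <- .traj_frame(res$traj, mod, g)
    if (res$status != "divided") {
      status <- "failed_no_division"; failed_gen <- g
      break
    }
    p_d <- res$y_d[k + seq_len(k)]
    m_d <- res$y_d[seq_len(k)]
    mod_d <- res$mod_at_division
    V_b <- sum(state$p * mod$L) / mod$rho
    V_d <- sum(p_d * mod_d$L) / mod_d$rho
    if (g > burn_in) {
      F_n_b <- .solve_fraction(state$p[mod$i_n], mod$cap_n, mod$K_n,
                               mod$a * state$p[mod$i_n] / V_b)
      F_r_b <- .solve_fraction(state$p[mod$i_r],
                               pmax(state$m, 0) * mod$fac_r, mod$K_r,
                               state$p[mod$i_r] / (mod$cyto * V_b))
      F_n_d <- .solve_fraction(p_d[mod$i_n], mod_d$cap_n, mod_d$K_n,
                               mod_d$a * p_d[mod$i_n] / V_d)
      F_r_d <- .solve_fraction(p_d[mod$i_r], pmax(m_d, 0) * mod_d$fac_r,
                               mod_d$K_r, p_d[mod$i_r] / (mod_d$cyto * V_d))
      rec[[g - burn_in]] <- data.frame(
        k = g - burn_in, V_b = V_b, V_d = V_d, delta_V = V_d - V_b,
        T_D = res$t_d, theta_k = theta, ratio_min = res$ratio_min,
        t_at_min = res$t_at_min, F_n_b = F_n_b, F_n_d = F_n_d,
        F_r_b = F_r_b, F_r_d = F_r_d, n_d = p_d[mod$i_n])
    }
    ## partition; in the replication variant the copy numbers halve back, so
    ## the daughter genome is the original one
    frac_p <- rep(rule$gamma, k)
    if (!is.null(rule$eta)) frac_p[mod$i_inh] <- rule$eta
    state <- cell_state(0, m_d * rule$gamma, p_d * frac_p)
  }

  records <- if (status == "steady") do.call(rbind, rec) else {
    done <- Filter(Negate(is.null), rec)
    if (length(done)) do.call(rbind, done) else NULL
  }
  structure(list(records = records, status = status,
                 failed_generation = failed_gen, burn_in = burn_in,
                 seed = seed, rule = rule,
                 trajectories = if (trajectories) {
                   do.call(rbind, Filter(Negate(is.null), trj))
                 }),
            class = "cell_lineage")
}

.traj_frame <- function(rows, mod, generation) {
  if (is.null(rows) || length(rows) == 0L) return(NULL)
  k <- length(mod$L)
  out <- do.call(rbind, rows)
  t <- out[, 1L]
  mmat <- out[, 1L + seq_len(k), drop = FALSE]
  pmat <- out[, 1L + k + seq_len(k), drop = FALSE]
  V <- as.numeric(pmat %*% mod$L) / mod$rho
  c_act <- as.numeric(pmat[, mod$i_act, drop = FALSE] %*%
                        mod$chi[mod$i_act]) / V
  c_inh <- as.numeric(pmat[, mod$i_inh, drop = FALSE] %*%
                        mod$chi[mod$i_inh]) / V
  F_n <- F_r <- numeric(length(t))
  for (i in seq_along(t)) {
    n <- pmat[i, mod$i_n]; r <- pmat[i, mod$i_r]
    F_n[i] <- .solve_fraction(n, mod$cap_n, mod$K_n, mod$a * n / V[i])
    F_r[i] <- .solve_fraction(r, pmax(mmat[i, ], 0) * mod$fac_r, mod$K_r,
                              r / (mod$cyto * V[i]))
  }
  data.frame(generation = generation, t = t, V = V, c_act = c_act,
             c_inh = c_inh, F_n = F_n, F_r = F_r)
}

## Rough-but-adequate initial volume: the theory birth volume at the rule's
## equivalent threshold when it exists, otherwise a mid-window value.
.default_V0 <- function(mod, rule) {
  ka <- mean(mod$K_n[mod$i_act]); ki <- mean(mod$K_n[mod$i_inh])
  kb <- stats::median(mod$K_n[setdiff(seq_along(mod$K_n),
                                      c(mod$i_act, mod$i_inh))])
  c_n <- mod$c_n
  th <- NULL
  if (rule$kind %in% c("ratio", "hazard")) {
    th0 <- if (!is.null(rule$theta_sequence)) rule$theta_sequence[1L] else
      rule$theta_bar
    if (!is.null(th0)) {
      th <- sum(mod$chi[mod$i_inh] * mod$w[mod$i_inh]) /
        sum(mod$chi[mod$i_act] * mod$w[mod$i_act]) * th0
    }
  }
  th1 <- ki / ka; th2 <- (c_n + ki) / (c_n + ka)
  if (is.null(th) || !is.finite(th) || th <= th1 || th >= th2) {
    th <- (th1 + th2) / 2
  }
  kt <- th * ka - ki
  vb <- mod$a * mod$nc * (1 - th) * kt /
    (2 * ((1 - th) * c_n - kt) * ((1 - th) * kb + kt))
  if (!is.finite(vb) || vb <= 0) vb <- mod$a * mod$nc / (4 * c_n)
  vb
}

#' @export
print.cell_lineage <- function(x, ...) {
  n <- if (is.null(x$records)) 0L else nrow(x$records)
  cat(sprintf("<cell_lineage> %d recorded generations (burn-in %d), status: %s\n",
              n, x$burn_in, x$status))
  if (x$status != "steady") {
    cat(sprintf("  growth/division failed at generation %d\n",
                x$failed_generation))
  }
  if (n > 0) {
    cat(sprintf("  V_b: mean %.4g, CV %.3g; mean T_D %.3g h\n",
                mean(x$records$V_b),
                stats::sd(x$records$V_b) / mean(x$records$V_b),
                mean(x$records$T_D)))
  }
  invisible(x)
}

#' @export
summary.cell_lineage <- function(object, ...) {
  out <- list(status = object$status,
              n = if (is.null(object$records)) 0L else nrow(object$records),
              size = size_summary(object))
  class(out) <- "summary.cell_lineage"
  out
}

#' @export
print.summary.cell_lineage <- function(x, ...) {
  cat(sprintf("Lineage of %d generations (%s)\n", x$n, x$status))
  print(x$size)
  invisible(x)
}

#' @export
as.data.frame.cell_lineage <- function(x, ...) {
  x$records
}

#' @param x A `cell_lineage`.
#' @param which One of `"sizes"` (V_d, delta_V and T_D against V_b),
#'   `"series"` (V_b against generation), `"hist"` (birth-size histogram).
#' @param ... Passed to the underlying plot calls.
#' @rdname simulate_lineage
#' @export
plot.cell_lineage <- function(x, which = c("sizes", "series", "hist"), ...) {
  which <- match.arg(which)
  r <- x$records
  if (is.null(r) || nrow(r) == 0L) stop("no recorded generations to plot")
  if (which == "series") {
    graphics::plot(r$k, r$V_b, type = "l", xlab = "generation",
                   ylab = expression(V[b] ~ (mu * m^3)), ...)
  } else if (which == "hist") {
    graphics::hist(r$V_b, breaks = 30, main = "",
                   xlab = expression(V[b] ~ (mu * m^3)), ...)
  } else {
    op <- graphics::par(mfrow = c(1, 3)); on.exit(graphics::par(op))
    for (col in c("V_d", "delta_V", "T_D")) {
      graphics::plot(r$V_b, r[[col]], pch = 16, cex = 0.4,
                     xlab = expression(V[b]), ylab = col, ...)
      bf <- binned_regression(r$V_b, r[[col]], 10)
      graphics::points(bf$bin_centers, bf$bin_means, col = 2, pch = 19)
      graphics::abline(bf$intercept, bf$slope, col = 2)
    }
  }
  invisible(x)
}
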