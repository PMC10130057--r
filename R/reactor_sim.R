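# Monod-kinetics simulation of the coupled three-guild system:
# batch cycling (closed bottle) and continuous (CSTR) steady state.

#' Kinetic parameters for the three guilds
#'
#' Each guild follows multiplicative Monod kinetics on its substrates:
#' `v_g = vmax_g * prod_s C_s / (K_s + C_s)` (extent units, mmol/L/d).
#' Substrate sets come from the guild reactions: anammox uses NH4 + NO2,
#' bacterial n-DAMO uses CH4 + NO2, archaeal n-DAMO uses CH4 + NO3.
#'
#' Default half-saturation constants: bacterial n-DAMO methane 2.6 uM
#' (a literature respirometry value) and archaeal methane 26 uM, ten times
#' higher, the minimum consistent with the reported "at least one order of
#' magnitude" affinity gap.  Nitrogen-species affinities are not constrained
#' by the study design and default to 1 mg N/L each as configurable
#' placeholders; results that depend on them are simulation-only.
#'
#' @param vmax named numeric vector of maximum volumetric extent rates
#'   (mmol reaction-extent/L/d) for `anammox`, `ndamo_bacteria`,
#'   `ndamo_archaea`; all >= 0.
#' @param ks named list per guild of named substrate half-saturation
#'   constants in mmol/L (note: 2.6 uM = 0.0026 mmol/L).
#' @return object of class `"kinetic_params"`.
#' @examples
#' kinetic_params(vmax = c(anammox = 10, ndamo_bacteria = 1,
#'                         ndamo_archaea = 1))
#' @export
kinetic_params <- function(vmax = c(anammox = 0, ndamo_bacteria = 0,
                                    ndamo_archaea = 0),
                           ks = NULL) {
  guilds <- c("anammox", "ndamo_bacteria", "ndamo_archaea")
  if (is.null(names(vmax)) || !all(guilds %in% names(vmax))) {
    stop("vmax must be named with entries for: ",
         paste(guilds, collapse = ", "), call. = FALSE)
  }
  if (any(vmax < 0)) stop("vmax must be >= 0", call. = FALSE)
  ks_n <- 1 / .N_MASS  # 1 mg N/L placeholder affinity, in mmol/L
  defaults <- list(
    anammox = c(NH4 = ks_n, NO2 = ks_n),
    ndamo_bacteria = c(CH4 = 0.0026, NO2 = ks_n),
    ndamo_archaea = c(CH4 = 0.026, NO3 = ks_n)
  )
  if (!is.null(ks)) {
    for (g in intersect(names(ks), guilds)) {
      for (s in names(ks[[g]])) defaults[[g]][[s]] <- ks[[g]][[s]]
    }
  }
  if (any(unlist(defaults) <= 0)) {
    stop("half-saturation constants must be > 0", call. = FALSE)
  }
  structure(list(vmax = vmax[guilds], ks = defaults),
            class = "kinetic_params")
}

# Guild extent rates v(C) at concentrations C (named, mmol/L).
guild_rates <- function(conc, params) {
  vapply(names(params$vmax), function(g) {
    ks <- params$ks[[g]]
    monod <- vapply(names(ks), function(s) {
      cs <- max(conc[[s]], 0)
      cs / (ks[[s]] + cs)
    }, numeric(1))
    params$vmax[[g]] * prod(monod)
  }, numeric(1))
}

# Internal state layout for the batch integrator (all mmol/L):
# NH4, NO2, NO3, CH4, N2 (cumulative produced), biomassN (cumulative
# nitrogen assimilated, closing the ~0.02 mol N gap of the anammox
# equation as printed).
.SIM_SPECIES <- c("NH4", "NO2", "NO3", "CH4")

sim_derivative <- function(conc, params, S, imbalance, ch4_fixed) {
  v <- guild_rates(conc, params)
  d <- as.numeric(S %*% v)
  names(d) <- rownames(S)
  if (ch4_fixed) d[["CH4"]] <- 0
  c(d, biomassN = -sum(imbalance * v))
}

# One RK4 step; recursively halves the step when a concentration would go
# negative (Monod factors vanish at zero, so refinement restores positivity).
rk4_step <- function(y, dt, f, depth = 0) {
  k1 <- f(y)
  k2 <- f(pmax(y + dt / 2 * k1, 0))
  k3 <- f(pmax(y + dt / 2 * k2, 0))
  k4 <- f(pmax(y + dt * k3, 0))
  y1 <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (any(!is.finite(y1))) {
    stop("non-finite derivative during integration; state: ",
         paste(sprintf("%s = %.4g", names(y), y), collapse = ", "),
         call. = FALSE)
  }
  if (any(y1[.SIM_SPECIES] < -1e-9) && depth < 30) {
    half <- rk4_step(y, dt / 2, f, depth + 1)
    return(rk4_step(half, dt / 2, f, depth + 1))
  }
  pmax(y1, 0)
}

#' Simulate a batch (closed-bottle) cycling experiment
#'
#' Integrates `dC/dt = S v(C)` with multiplicative Monod kinetics using
#' fixed-step fourth-order Runge-Kutta.  Steps that would drive a
#' concentration negative are recursively halved (substrate-depletion
#' sub-stepping); the state is clamped at zero only within integration
#' tolerance.  Cumulative dinitrogen and the nitrogen assimilated into
#' biomass (the imbalance of the anammox equation as printed) are tracked so
#' total nitrogen is conserved.
#'
#' @param initial named concentrations: NH4, NO2, NO3 in mg N/L and CH4 in
#'   mmol/L (missing species default to 0).
#' @param params a [kinetic_params()].
#' @param duration_d simulated time (d), > 0.
#' @param dt_d output/macro step (d), > 0 and < `duration_d`.
#' @param methane `"closed"` (methane depletes in the bottle) or `"fixed"`
#'   (membrane-supplied, held at its initial value).
#' @param reactions guild reaction registry.
#' @return object of class `"sim_state"`: `time` (d), `conc` (time x state
#'   matrix, mmol/L, including cumulative `N2` and `biomassN`), and the
#'   call parameters.  `as.data.frame()` yields a tidy series with nitrogen
#'   species in mg N/L and CH4 in mmol/L.
#' @examples
#' p <- kinetic_params(vmax = c(anammox = 20, ndamo_bacteria = 0,
#'                              ndamo_archaea = 0))
#' s <- simulate_batch(c(NH4 = 50, NO2 = 66), p, duration_d = 0.2,
#'                     dt_d = 0.005)
#' tail(as.data.frame(s))
#' @export
simulate_batch <- function(initial, params, duration_d, dt_d,
                           methane = c("closed", "fixed"),
                           reactions = guild_reactions()) {
  methane <- match.arg(methane)
  stopifnot(inherits(params, "kinetic_params"))
  if (duration_d <= 0 || dt_d <= 0) {
    stop("duration_d and dt_d must be > 0", call. = FALSE)
  }
  if (dt_d >= duration_d) {
    stop("dt_d must be smaller than duration_d", call. = FALSE)
  }
  if (any(initial < 0)) {
    stop("initial concentrations must be >= 0", call. = FALSE)
  }
  y0 <- c(NH4 = 0, NO2 = 0, NO3 = 0, CH4 = 0, N2 = 0, biomassN = 0)
  for (sp in names(initial)) {
    if (!sp %in% .SIM_SPECIES) {
      stop("unknown species in initial state: ", sp, call. = FALSE)
    }
    y0[[sp]] <- if (sp == "CH4") initial[[sp]] else initial[[sp]] / .N_MASS
  }
  S <- build_stoich_matrix(reactions, c(.SIM_SPECIES, "N2"))
  imbalance <- vapply(reactions, nitrogen_imbalance, numeric(1))
  f <- function(y) sim_derivative(y, params, S, imbalance,
                                  ch4_fixed = (methane == "fixed"))
  times <- seq(0, duration_d, by = dt_d)
  if (times[length(times)] < duration_d) times <- c(times, duration_d)
  out <- matrix(NA_real_, nrow = length(times), ncol = length(y0),
                dimnames = list(NULL, names(y0)))
  out[1, ] <- y0
  y <- y0
  for (i in seq_along(times)[-1]) {
    y <- rk4_step(y, times[i] - times[i - 1], f)
    out[i, ] <- y
  }
  structure(list(time = times, conc = out, params = params,
                 methane = methane),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat("<sim_state> ", length(x$time), " time points over ",
      format(max(x$time)), " d (methane: ", x$methane, ")\n", sep = "")
  cat("  final state [mmol/L]: ",
      paste(sprintf("%s = %.4g", colnames(x$conc),
                    x$conc[nrow(x$conc), ]), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.sim_state <- function(x, ...) {
  sp <- c(.SIM_SPECIES, "N2")
  do.call(rbind, lapply(sp, function(s) {
    val <- x$conc[, s]
    if (s == "CH4") {
      data.frame(time_d = x$time, species = s, value = val, unit = "mmol/L")
    } else if (s == "N2") {
      data.frame(time_d = x$time, species = s, value = val * 2 * .N_MASS,
                 unit = "mg N/L (cumulative N2-N)")
    } else {
      data.frame(time_d = x$time, species = s, value = val * .N_MASS,
                 unit = "mg N/L")
    }
  }))
}

#' Total nitrogen bookkeeping of a simulated trajectory
#'
#' @param state a [simulate_batch()] result.
#' @return numeric vector (mmol N/L) of dissolved N + 2 x cumulative N2 +
#'   biomass-assimilated N at each time point; constant when nitrogen is
#'   conserved.
#' @export
total_nitrogen <- function(state) {
  stopifnot(inherits(state, "sim_state"))
  n <- default_n_atoms(.SIM_SPECIES)
  as.numeric(state$conc[, .SIM_SPECIES] %*% n) +
    2 * state$conc[, "N2"] + state$conc[, "biomassN"]
}

#' Solve the continuous (CSTR) steady state of the coupled system
#'
#' Finds effluent concentrations `C` satisfying the chemostat balance
#' `(C_in - C)/HRT + S v(C) = 0` over NH4, NO2 and NO3, with methane either
#' held at a fixed dissolved concentration (membrane-fed) or effectively
#' non-limiting.  A damped Newton iteration with backtracking line search
#' and positivity projection is used; non-convergence raises an error
#' carrying the last residual.
#'
#' @param config a [reactor_config()]; influent nitrogen species in mg N/L.
#' @param params a [kinetic_params()].
#' @param methane `"non_limiting"` (dissolved methane pinned at 1 mmol/L,
#'   far above both methane affinities) or a fixed dissolved concentration
#'   in mmol/L.
#' @param reactions guild reaction registry.
#' @param tol convergence tolerance on the balance residual, relative to the
#'   volumetric nitrogen loading.
#' @param max_iter maximum Newton iterations.
#' @return list with `effluent_mg` (mg N/L), `effluent_mmol`, `efficiency`
#'   (percent total-nitrogen removal), `partition` (the implied
#'   [partition_fluxes()] result), `residual` (mmol/L/d) and `iterations`.
#' @examples
#' cfg <- reactor_config(1, c(NH4 = 100, NO2 = 132, NO3 = 0))
#' p <- kinetic_params(vmax = c(anammox = 100, ndamo_bacteria = 50,
#'                              ndamo_archaea = 50))
#' ss <- solve_steady_state(cfg, p)
#' ss$efficiency
#' @export
solve_steady_state <- function(config, params, methane = "non_limiting",
                               reactions = guild_reactions(),
                               tol = 1e-10, max_iter = 500) {
  stopifnot(inherits(config, "reactor_config"),
            inherits(params, "kinetic_params"))
  nsp <- c("NH4", "NO2", "NO3")
  cin <- vapply(nsp, function(s) {
    v <- config$influent[s]
    if (is.na(v)) 0 else unname(v) / .N_MASS
  }, numeric(1))
  ch4 <- if (identical(methane, "non_limiting")) 1 else {
    stopifnot(is.numeric(methane), methane >= 0)
    as.numeric(methane)
  }
  S <- build_stoich_matrix(reactions, nsp)
  hrt <- config$hrt_days
  balance <- function(cN) {
    conc <- c(as.list(pmax(cN, 0)), CH4 = ch4)
    names(conc)[1:3] <- nsp
    (cin - pmax(cN, 0)) / hrt + as.numeric(S %*% guild_rates(conc, params))
  }
  scale <- max(sum(cin) / hrt, 1e-12)

  x <- pmax(cin, 1e-6)
  fx <- balance(x)
  it <- 0
  while (max(abs(fx)) > tol * scale && it < max_iter) {
    it <- it + 1
    # forward-difference Jacobian on the 3x3 system
    J <- matrix(0, 3, 3)
    h <- pmax(1e-8 * pmax(abs(x), 1e-4), 1e-12)
    for (j in 1:3) {
      xp <- x
      xp[j] <- xp[j] + h[j]
      J[, j] <- (balance(xp) - fx) / h[j]
    }
    step <- tryCatch(solve(J, -fx), error = function(e) -fx * hrt)
    lambda <- 1
    repeat {
      xn <- pmax(x + lambda * step, 0)
      fn <- balance(xn)
      if (max(abs(fn)) < max(abs(fx)) || lambda < 1e-12) break
      lambda <- lambda / 2
    }
    if (lambda < 1e-12) break
    x <- xn
    fx <- fn
  }
  if (max(abs(fx)) > tol * scale) {
    stop("steady-state solver did not converge; last residual ",
         format(max(abs(fx)), digits = 4), " mmol/L/d", call. = FALSE)
  }
  effluent_mmol <- x
  names(effluent_mmol) <- nsp
  effluent_mg <- effluent_mmol * .N_MASS
  tn_in <- sum(cin) * .N_MASS
  eff <- removal_efficiency(tn_in, sum(effluent_mg))
  conc <- c(as.list(effluent_mmol), CH4 = ch4)
  rates <- as.numeric(S %*% guild_rates(conc, params))
  names(rates) <- nsp
  part <- partition_fluxes(rate_vector(rates, "mmol"),
                           reactions = reactions, solver = "exact")
  list(effluent_mg = effluent_mg, effluent_mmol = effluent_mmol,
       efficiency = eff, partition = part,
       residual = max(abs(fx)), iterations = it)
}
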