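# Guild reaction registry, stoichiometric matrices, and flux partitioning.

#' Define a chemical reaction with signed molar stoichiometry
#'
#' A reaction is a named chemical transformation with signed molar
#' coefficients per chemical species: negative coefficients are consumed,
#' positive are produced.  On construction the reaction is checked for a
#' nitrogen-atom balance within `n_slack` mol N per unit extent.  The slack
#' default (0.05) deliberately admits the literature anammox equation, which
#' is about 0.02 mol N short per unit extent because its biomass term is
#' conventionally omitted; `n_slack = 0` enforces strict balance.
#'
#' @param id short machine name, e.g. `"anammox"`.
#' @param label human-readable name.
#' @param coefficients named numeric vector, species symbol -> signed molar
#'   coefficient.  At least one negative (substrate) and one positive
#'   (product) coefficient are required.
#' @param n_atoms named numeric vector of nitrogen atoms per formula unit;
#'   defaults to the built-in table (NH4 = 1, NO2 = 1, NO3 = 1, N2 = 2,
#'   CH4 = 0, ...).
#' @param n_slack allowed absolute nitrogen imbalance (mol N per unit
#'   extent); default 0.05.
#' @return an object of class `"reaction"`.
#' @examples
#' rxn <- reaction("anammox", "anammox",
#'   c(NH4 = -1, NO2 = -1.32, N2 = 1.02, NO3 = 0.26, H2O = 2.03))
#' nitrogen_imbalance(rxn)
#' @export
reaction <- function(id, label, coefficients,
                     n_atoms = default_n_atoms(names(coefficients)),
                     n_slack = 0.05) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
    stop("coefficients must be a named numeric vector", call. = FALSE)
  }
  if (anyDuplicated(names(coefficients))) {
    stop("duplicate species in reaction '", id, "': ",
         paste(unique(names(coefficients)[duplicated(names(coefficients))]),
               collapse = ", "), call. = FALSE)
  }
  if (!any(coefficients < 0) || !any(coefficients > 0)) {
    stop("reaction '", id,
         "' needs at least one substrate (negative) and one product ",
         "(positive) coefficient", call. = FALSE)
  }
  n_atoms <- n_atoms[names(coefficients)]
  if (anyNA(n_atoms)) {
    stop("n_atoms missing for species: ",
         paste(names(coefficients)[is.na(n_atoms)], collapse = ", "),
         call. = FALSE)
  }
  imbalance <- sum(coefficients * n_atoms)
  if (abs(imbalance) > n_slack + 1e-12) {
    stop("reaction '", id, "' violates the nitrogen-atom balance by ",
         format(imbalance, digits = 4), " mol N per unit extent (slack ",
         n_slack, ")", call. = FALSE)
  }
  structure(
    list(id = id, label = label, coefficients = coefficients,
         n_atoms = n_atoms),
    class = "reaction"
  )
}

#' @export
print.reaction <- function(x, ...) {
  co <- x$coefficients
  lhs <- co[co < 0]
  rhs <- co[co > 0]
  fmt <- function(v) paste(
    ifelse(abs(v) == 1, names(v), paste0(format(abs(v)), " ", names(v))),
    collapse = " + ")
  cat("<reaction> ", x$id, ": ", fmt(lhs), " -> ", fmt(rhs), "\n", sep = "")
  invisible(x)
}

#' Nitrogen imbalance of a reaction
#'
#' Signed sum of coefficient times nitrogen atoms over all species; zero for
#' a strictly nitrogen-balanced equation.
#'
#' @param rxn a [reaction()].
#' @return mol N per unit extent (signed).
#' @export
nitrogen_imbalance <- function(rxn) {
  stopifnot(inherits(rxn, "reaction"))
  sum(rxn$coefficients * rxn$n_atoms)
}

#' The three guild reactions of coupled anammox / n-DAMO systems
#'
#' Returns the built-in registry with exactly the three reactions, with
#' coefficients as conventionally printed:
#' \itemize{
#'   \item anammox: NH4+ + 1.32 NO2- -> 1.02 N2 + 0.26 NO3- + 2.03 H2O
#'   \item bacterial n-DAMO: 3 CH4 + 8 NO2- + 8 H+ -> 3 CO2 + 4 N2 + 10 H2O
#'   \item archaeal n-DAMO: CH4 + 4 NO3- -> CO2 + 4 NO2- + 2 H2O
#' }
#' The bacterial n-DAMO extent unit is the full 3-CH4 equation, so one unit
#' of extent consumes 8 mmol nitrite and 3 mmol methane.
#'
#' @param n_slack nitrogen-balance slack passed to [reaction()].  The
#'   anammox equation as printed is ~0.02 mol N short (biomass omitted);
#'   `n_slack = 0` therefore rejects it.
#' @return named list of three [reaction()] objects, in order
#'   `anammox`, `ndamo_bacteria`, `ndamo_archaea`.
#' @examples
#' reg <- guild_reactions()
#' build_stoich_matrix(reg, c("NH4", "NO2", "NO3"))
#' @export
guild_reactions <- function(n_slack = 0.05) {
  list(
    anammox = reaction(
      "anammox", "anammox (anaerobic ammonium oxidation)",
      c(NH4 = -1, NO2 = -1.32, N2 = 1.02, NO3 = 0.26, H2O = 2.03),
      n_slack = n_slack),
    ndamo_bacteria = reaction(
      "ndamo_bacteria", "bacterial n-DAMO (nitrite-dependent AOM)",
      c(CH4 = -3, NO2 = -8, H = -8, CO2 = 3, N2 = 4, H2O = 10),
      n_slack = n_slack),
    ndamo_archaea = reaction(
      "ndamo_archaea", "archaeal n-DAMO (nitrate-dependent AOM)",
      c(CH4 = -1, NO3 = -4, CO2 = 1, NO2 = 4, H2O = 2),
      n_slack = n_slack)
  )
}

#' Build a stoichiometric matrix (species x reactions)
#'
#' @param reactions list of [reaction()] objects (may be empty).
#' @param species_order character vector of species symbols defining row
#'   order; species absent from every reaction get zero rows.
#' @return numeric matrix with `length(species_order)` rows and one column
#'   per reaction (columns named by reaction id, input order preserved).
#' @examples
#' S <- build_stoich_matrix(guild_reactions(), c("NH4", "NO2", "NO3"))
#' S %*% c(1, 0, 0)  # net rates at unit anammox extent
#' @export
build_stoich_matrix <- function(reactions, species_order) {
  if (anyDuplicated(species_order)) {
    stop("duplicate species symbol in species_order: ",
         paste(unique(species_order[duplicated(species_order)]),
               collapse = ", "), call. = FALSE)
  }
  S <- matrix(0, nrow = length(species_order), ncol = length(reactions),
              dimnames = list(species_order,
                              vapply(reactions, function(r) r$id, "")))
  for (j in seq_along(reactions)) {
    co <- reactions[[j]]$coefficients
    hit <- intersect(names(co), species_order)
    S[hit, j] <- co[hit]
  }
  S
}

# ---------------------------------------------------------------------------
# Rate vectors and units
# ---------------------------------------------------------------------------

#' Construct a net volumetric rate vector
#'
#' Sign convention: consumption is negative, production positive (rates are
#' net concentration-change contributions).
#'
#' @param rates named numeric vector, species -> net volumetric conversion
#'   rate.  Must contain at least NH4, NO2 and NO3.
#' @param units `"mmol"` (mmol species/L/d) or `"mgN"` (mg N/L/d for
#'   nitrogen species; mg CH4/L/d for methane).
#' @return object of class `"rate_vector"`.
#' @export
rate_vector <- function(rates, units = c("mmol", "mgN")) {
  units <- match.arg(units)
  if (is.null(names(rates))) stop("rates must be named", call. = FALSE)
  if (any(!is.finite(rates))) {
    stop("non-finite rate for species: ",
         paste(names(rates)[!is.finite(rates)], collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(c("NH4", "NO2", "NO3"), names(rates))
  if (length(missing) > 0) {
    stop("rate vector must include NH4, NO2 and NO3; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(rates = rates, units = units), class = "rate_vector")
}

#' @export
print.rate_vector <- function(x, ...) {
  cat("<rate_vector> [", x$units, "/L/d]\n", sep = "")
  print(x$rates)
  invisible(x)
}

#' Convert a rate vector between mg-N and mmol bases
#'
#' Nitrogen species convert via mg N = mmol x n_atoms x 14.0067; methane via
#' mg CH4 = mmol x 16.043.  Species with no nitrogen and no methane identity
#' (e.g. CO2) are only representable on the mmol basis and raise an error.
#'
#' @param rv a [rate_vector()].
#' @param to `"mmol"` or `"mgN"`.
#' @return a [rate_vector()] on the requested basis.
#' @export
convert_rates <- function(rv, to = c("mmol", "mgN")) {
  to <- match.arg(to)
  stopifnot(inherits(rv, "rate_vector"))
  if (rv$units == to) return(rv)
  sp <- names(rv$rates)
  n <- default_n_atoms(sp)
  factor <- ifelse(sp == "CH4", .CH4_MASS, n * .N_MASS)
  bad <- sp[factor == 0 & rv$rates[sp] != 0]
  if (length(bad) > 0) {
    stop("cannot convert nitrogen-free species to/from a mg-N basis: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  factor[factor == 0] <- 1  # zero rates: factor irrelevant
  out <- if (to == "mgN") rv$rates * factor else rv$rates / factor
  rate_vector(out, units = to)
}

#' Continuous-reactor operating configuration
#'
#' @param hrt_days hydraulic retention time (d), > 0.
#' @param influent named numeric vector of influent concentrations
#'   (mg N/L for nitrogen species; mmol/L for CH4), all >= 0.
#' @param volume_l working volume (L); informational.
#' @return object of class `"reactor_config"`.
#' @export
reactor_config <- function(hrt_days, influent, volume_l = 1) {
  stopifnot(is.numeric(hrt_days), length(hrt_days) == 1)
  if (!is.finite(hrt_days) || hrt_days <= 0) {
    stop("hrt_days must be a positive number", call. = FALSE)
  }
  if (is.null(names(influent))) stop("influent must be named", call. = FALSE)
  if (any(influent < 0)) {
    stop("influent concentrations must be >= 0", call. = FALSE)
  }
  structure(list(hrt_days = hrt_days, influent = influent,
                 volume_l = volume_l),
            class = "reactor_config")
}

#' Net conversion rates from a measurement series
#'
#' For continuous steady-state operation the net volumetric conversion rate
#' of each species follows the CSTR balance
#' `rate = (mean effluent - influent) / HRT`, so consumption is negative.
#' For batch (dynamic) series the rate is the least-squares slope of
#' concentration over the time window.
#'
#' @param series data frame with columns `time_d`, `species`, `value` (and
#'   optionally `unit`); one row per sample per species.
#' @param config a [reactor_config()]; required for `mode = "steady_state"`.
#' @param mode `"steady_state"` or `"dynamic"`.
#' @param units unit tag of the concentration values (`"mgN"` or `"mmol"`),
#'   propagated to the returned [rate_vector()].
#' @return a [rate_vector()] with one rate per species in the series.
#' @export
net_rates_from_series <- function(series, config = NULL,
                                  mode = c("steady_state", "dynamic"),
                                  units = c("mgN", "mmol")) {
  mode <- match.arg(mode)
  units <- match.arg(units)
  check_columns(series, c("time_d", "species", "value"), "measurement series")
  species <- unique(series$species)
  if (mode == "steady_state") {
    if (is.null(config)) {
      stop("steady_state mode requires a reactor_config", call. = FALSE)
    }
    missing <- setdiff(names(config$influent), species)
    if (length(missing) > 0) {
      stop("series is missing species present in the influent: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    rates <- vapply(species, function(sp) {
      eff <- mean(series$value[series$species == sp])
      inf <- if (sp %in% names(config$influent)) config$influent[[sp]] else 0
      (eff - inf) / config$hrt_days
    }, numeric(1))
  } else {
    rates <- vapply(species, function(sp) {
      sub <- series[series$species == sp, , drop = FALSE]
      if (nrow(sub) < 2) {
        stop("dynamic mode needs >= 2 time points for species ", sp,
             call. = FALSE)
      }
      t <- sub$time_d
      if (is.unsorted(t, strictly = TRUE)) {
        stop("non-monotone timestamps for species ", sp, call. = FALSE)
      }
      tc <- t - mean(t)
      sum(tc * (sub$value - mean(sub$value))) / sum(tc^2)
    }, numeric(1))
  }
  names(rates) <- species
  rate_vector(rates, units = units)
}

# ---------------------------------------------------------------------------
# Flux partitioning
# ---------------------------------------------------------------------------

# Lawson-Hanson active-set non-negative least squares: min ||A x - b||, x >= 0.
nnls_lh <- function(A, b, tol = NULL) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(A, b - A %*% x)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * sum(abs(A)) * nrow(A)
  iter <- 0
  while (any(!passive & w > tol) && iter < 30 * n) {
    iter <- iter + 1
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      z[passive] <- qr.solve(A[, passive, drop = FALSE], b)
      if (all(z[passive] > tol)) break
      # step toward z until the first passive variable hits zero
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive <- passive & (x > tol)
      x[!passive] <- 0
    }
    x <- z
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Partition measured net rates into guild-specific fluxes
#'
#' Solves the linear system `S e = r` over the measured nitrogen species
#' NH4, NO2 and NO3 for the extents `e` of the three guild reactions, then
#' derives the field-standard reporting rates and the out-of-sample
#' predictions:
#' \itemize{
#'   \item `r_AN`: nitrite removal by anammox (1.32 x anammox extent),
#'   \item `r_DB`: nitrite removal by bacterial n-DAMO (8 x extent of the
#'     3-CH4 equation),
#'   \item `r_DA`: nitrate removal by archaeal n-DAMO (4 x extent),
#'   \item `predicted_ch4`: methane consumption, 3 x bacterial + 1 x
#'     archaeal extent (mmol/L/d; also reported as mg/L/d),
#'   \item `predicted_n2`: dinitrogen production, 1.02 x anammox + 4 x
#'     bacterial extent (mmol N2/L/d; N-atom basis via [predict_n2()]).
#' }
#' Methane and dinitrogen are deliberately excluded from the solve so that
#' they remain out-of-sample checks of the three-reaction model.
#'
#' @param rates a [rate_vector()] (any basis; converted to mmol internally)
#'   or a named numeric vector in mmol/L/d.
#' @param reactions reaction registry as returned by [guild_reactions()].
#' @param solver `"exact"` (LU solve of the 3x3 system; negative extents are
#'   recorded as a warning in the result) or `"nnls"` (non-negative least
#'   squares).
#' @return object of class `"flux_partition"` with fields `extents`, `r_AN`,
#'   `r_DB`, `r_DA`, `predicted_ch4` (mmol/L/d), `predicted_ch4_mg`
#'   (mg/L/d), `predicted_n2` (mmol N2/L/d), `residual` (per species,
#'   mmol/L/d), `solver` and `warnings`.
#' @examples
#' p <- partition_fluxes(c(NH4 = -1, NO2 = -1.32, NO3 = 0.26))
#' p$r_AN          # 1.32
#' p$predicted_n2  # 1.02
#' @export
partition_fluxes <- function(rates, reactions = guild_reactions(),
                             solver = c("exact", "nnls")) {
  solver <- match.arg(solver)
  if (!inherits(rates, "rate_vector")) rates <- rate_vector(rates, "mmol")
  rates <- convert_rates(rates, "mmol")
  need <- c("anammox", "ndamo_bacteria", "ndamo_archaea")
  ids <- vapply(reactions, function(r) r$id, "")
  if (!all(need %in% ids)) {
    stop("registry must contain the three guild reactions: ",
         paste(setdiff(need, ids), collapse = ", "), call. = FALSE)
  }
  reactions <- reactions[match(need, ids)]
  names(reactions) <- need
  species <- c("NH4", "NO2", "NO3")
  S <- build_stoich_matrix(reactions, species)
  r <- rates$rates[species]
  warnings <- character(0)

  if (solver == "exact") {
    e <- tryCatch(solve(S, r), error = function(err) {
      stop("singular stoichiometric system under the exact solver; ",
           "retry with solver = \"nnls\"", call. = FALSE)
    })
    if (any(e < -1e-10)) {
      warnings <- c(warnings, paste0(
        "negative extent under exact solve: ",
        paste(sprintf("%s = %.4g", need[e < -1e-10], e[e < -1e-10]),
              collapse = ", ")))
    }
  } else {
    e <- nnls_lh(S, r)
  }
  e <- as.numeric(e)
  names(e) <- need

  co <- lapply(reactions, function(x) x$coefficients)
  resid <- as.numeric(S %*% e - r)
  names(resid) <- species
  coef_of <- function(rxn_co, sp) {
    v <- unname(rxn_co[sp])
    if (length(v) == 0 || is.na(v)) 0 else v
  }
  n2 <- sum(vapply(seq_along(e), function(j) {
    coef_of(co[[j]], "N2") * e[j]
  }, numeric(1)))
  ch4 <- -sum(vapply(seq_along(e), function(j) {
    coef_of(co[[j]], "CH4") * e[j]
  }, numeric(1)))
  structure(list(
    extents = e,
    r_AN = -co$anammox[["NO2"]] * e[["anammox"]],
    r_DB = -co$ndamo_bacteria[["NO2"]] * e[["ndamo_bacteria"]],
    r_DA = -co$ndamo_archaea[["NO3"]] * e[["ndamo_archaea"]],
    predicted_ch4 = ch4,
    predicted_ch4_mg = ch4 * .CH4_MASS,
    predicted_n2 = n2,
    residual = resid,
    solver = solver,
    warnings = warnings
  ), class = "flux_partition")
}

#' @export
print.flux_partition <- function(x, ...) {
  cat("<flux_partition> (solver: ", x$solver, ")\n", sep = "")
  cat("  extents [mmol/L/d]: ",
      paste(sprintf("%s = %.4g", names(x$extents), x$extents),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  r_AN = %.4g, r_DB = %.4g, r_DA = %.4g mmol N/L/d\n",
              x$r_AN, x$r_DB, x$r_DA))
  cat(sprintf("  predicted CH4 = %.4g mmol/L/d, predicted N2 = %.4g mmol/L/d\n",
              x$predicted_ch4, x$predicted_n2))
  cat("  residual max |.| = ", format(max(abs(x$residual)), digits = 3),
      " mmol/L/d\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Predicted methane consumption of a flux partition
#'
#' @param partition a [partition_fluxes()] result.
#' @return methane consumption rate (mmol CH4/L/d): 3 x bacterial n-DAMO
#'   extent + 1 x archaeal n-DAMO extent.
#' @export
predict_methane <- function(partition) {
  stopifnot(inherits(partition, "flux_partition"))
  partition$predicted_ch4
}

#' Predicted dinitrogen-nitrogen production of a flux partition
#'
#' @param partition a [partition_fluxes()] result.
#' @return N2-N production rate (mmol N/L/d), i.e. 2 x the molecular N2 rate
#'   `partition$predicted_n2`.
#' @export
predict_n2 <- function(partition) {
  stopifnot(inherits(partition, "flux_partition"))
  2 * partition$predicted_n2
}

#' Total-nitrogen removal efficiency
#'
#' @param influent_tn influent total nitrogen (mg N/L), > 0.
#' @param effluent_tn effluent total nitrogen (mg N/L), >= 0.
#' @return percent removed, `100 * (in - out) / in`.
#' @export
removal_efficiency <- function(influent_tn, effluent_tn) {
  if (any(influent_tn <= 0)) {
    stop("influent_tn must be > 0", call. = FALSE)
  }
  if (any(effluent_tn < 0)) {
    stop("effluent_tn must be >= 0", call. = FALSE)
  }
  100 * (influent_tn - effluent_tn) / influent_tn
}

#' Maximum nitrogen removal efficiency of an anammox-type reaction
#'
#' The nitrate by-product of anammox caps the achievable total-nitrogen
#' removal: per unit extent, the nitrogen consumed (N-atom weighted over all
#' substrates) is partly re-released as nitrate.  The ceiling is
#' `100 * (N consumed - N released as nitrate) / N consumed`, which for the
#' conventional coefficients is just under 90%.
#'
#' @param rxn a [reaction()] that consumes NH4 and NO2 and produces NO3.
#' @return percent; invariant under uniform scaling of the coefficients.
#' @examples
#' anammox_max_efficiency(guild_reactions()$anammox)  # 88.79...
#' @export
anammox_max_efficiency <- function(rxn) {
  stopifnot(inherits(rxn, "reaction"))
  co <- rxn$coefficients
  ok <- !is.na(co["NH4"]) && co["NH4"] < 0 &&
    !is.na(co["NO2"]) && co["NO2"] < 0 &&
    !is.na(co["NO3"]) && co["NO3"] >= 0
  if (!ok) {
    stop("reaction must consume NH4 and NO2 and produce NO3", call. = FALSE)
  }
  n <- rxn$n_atoms
  consumed <- sum(-co[co < 0] * n[names(co)[co < 0]])
  released <- co[["NO3"]] * n[["NO3"]]
  100 * (consumed - released) / consumed
}
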