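# Shared constants and small helpers.

# Atomic/molecular masses (g/mol) used for unit conversion.
.N_MASS <- 14.0067
.CH4_MASS <- 16.043

# Nitrogen atoms per formula unit for the chemical species the package knows.
.DEFAULT_N_ATOMS <- c(
  NH4 = 1, NO2 = 1, NO3 = 1, N2 = 2,
  CH4 = 0, CO2 = 0, H2O = 0, H = 0
)

#' Nitrogen-atom content of chemical species
#'
#' @param species character vector of species symbols (e.g. `"NH4"`).
#' @return named numeric vector of nitrogen atoms per formula unit; unknown
#'   species raise an error.
#' @keywords internal
default_n_atoms <- function(species) {
  unknown <- setdiff(species, names(.DEFAULT_N_ATOMS))
  if (length(unknown) > 0) {
    stop("unknown chemical species (no nitrogen-atom entry): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  .DEFAULT_N_ATOMS[species]
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  One substream per generator call.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Stop with a consistent message when a required column is missing.
check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
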