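# Seeded generators for every input the pipeline consumes, with known
# ground truth: reactor series, expression count tables, abundance profiles.

#' Generate a steady-state reactor monitoring series from known extents
#'
#' Forward model: effluent = influent + HRT x (S e), converted to mg N/L,
#' with multiplicative Gaussian noise of coefficient of variation
#' `noise_cv` applied per sample and species.  Negative draws are clamped
#' to zero and recorded so recovery analyses can exclude them.
#'
#' @param extents named numeric vector of true guild extents
#'   (`anammox`, `ndamo_bacteria`, `ndamo_archaea`), mmol/L/d, >= 0.
#' @param config a [reactor_config()] (influent in mg N/L); the true
#'   effluent must be nonnegative, otherwise the scenario is inconsistent
#'   and an error is raised.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 for noise-free).
#' @param n_samples number of sampling days.
#' @param seed integer seed; identical inputs give identical output.
#' @param reactions guild reaction registry.
#' @return list with `series` (tidy data frame: `time_d`, `species`,
#'   `value` mg N/L, `unit`), `truth` (extents and noise-free effluent),
#'   and `n_clamped`.
#' @examples
#' cfg <- reactor_config(1, c(NH4 = 250, NO2 = 350, NO3 = 0))
#' g <- gen_reactor_series(c(anammox = 14, ndamo_bacteria = 0.8,
#'                           ndamo_archaea = 0.9), cfg, noise_cv = 0.05,
#'                         n_samples = 10, seed = 1)
#' head(g$series)
#' @export
gen_reactor_series <- function(extents, config, noise_cv = 0.05,
                               n_samples = 50, seed = 1,
                               reactions = guild_reactions()) {
  stopifnot(inherits(config, "reactor_config"), noise_cv >= 0,
            n_samples >= 1, all(extents >= 0))
  nsp <- c("NH4", "NO2", "NO3")
  ids <- vapply(reactions, function(r) r$id, "")
  e <- vapply(ids, function(id) {
    v <- extents[id]
    if (is.na(v)) 0 else unname(v)
  }, numeric(1))
  S <- build_stoich_matrix(reactions, nsp)
  rate_mmol <- as.numeric(S %*% e)
  influent <- vapply(nsp, function(s) {
    v <- config$influent[s]
    if (is.na(v)) 0 else unname(v)
  }, numeric(1))
  effluent_true <- influent + config$hrt_days * rate_mmol * .N_MASS
  if (any(effluent_true < -1e-9)) {
    stop("extents imply a negative effluent concentration for: ",
         paste(nsp[effluent_true < -1e-9], collapse = ", "),
         call. = FALSE)
  }
  effluent_true <- pmax(effluent_true, 0)
  with_seed(seed, {
    draws <- matrix(
      effluent_true, nrow = n_samples, ncol = length(nsp), byrow = TRUE) *
      (1 + noise_cv * matrix(stats::rnorm(n_samples * length(nsp)),
                             nrow = n_samples))
    n_clamped <- sum(draws < 0)
    draws[draws < 0] <- 0
    series <- data.frame(
      time_d = rep(seq_len(n_samples), times = length(nsp)),
      species = rep(nsp, each = n_samples),
      value = as.numeric(draws),
      unit = "mg N/L"
    )
    list(series = series,
         truth = list(extents = stats::setNames(e, ids),
                      effluent = stats::setNames(effluent_true, nsp)),
         n_clamped = n_clamped)
  })
}

#' Generate a per-CDS read-count table from known genome fractions
#'
#' Builds a CDS catalogue (uniform lengths 300-3000 bp, log-normal
#' within-genome transcript weights with sdlog 1), then draws
#' `total_reads` multinomially with per-CDS probability proportional to
#' genome fraction x within-genome transcript weight x CDS length, so that
#' [compute_tpm()] + [mag_expression_fraction()] recover the target
#' fractions in expectation.
#'
#' @param n_cds named integer vector: genome id -> number of CDS.
#' @param fractions named numeric vector of target transcriptome fractions
#'   per genome (same names as `n_cds`); must sum to 1.
#' @param total_reads total read count to distribute (>= 0).
#' @param seed integer seed.
#' @return list with `cds` (data frame: `cds_id`, `genome_id`,
#'   `gene_symbol`, `length`, `strand`), `counts` (named integer vector),
#'   and `truth` (the fractions).
#' @examples
#' g <- gen_expression_counts(c(G1 = 20, G2 = 30), c(G1 = 0.6, G2 = 0.4),
#'                            total_reads = 1e5, seed = 1)
#' sum(g$counts)
#' @export
gen_expression_counts <- function(n_cds, fractions, total_reads,
                                  seed = 1) {
  stopifnot(!is.null(names(n_cds)), all(n_cds >= 1), total_reads >= 0)
  if (!setequal(names(n_cds), names(fractions))) {
    stop("n_cds and fractions must cover the same genomes", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  fractions <- fractions[names(n_cds)]
  with_seed(seed, {
    cds <- do.call(rbind, lapply(names(n_cds), function(g) {
      k <- n_cds[[g]]
      data.frame(
        cds_id = sprintf("%s_cds%04d", g, seq_len(k)),
        genome_id = g,
        gene_symbol = sprintf("%s_gene%04d", g, seq_len(k)),
        length = sample(300:3000, k, replace = TRUE),
        strand = sample(c("+", "-"), k, replace = TRUE)
      )
    }))
    # transcript-abundance weights within each genome (TPM space)
    w <- stats::rlnorm(nrow(cds), meanlog = 0, sdlog = 1)
    w <- unlist(lapply(split(w, cds$genome_id)[unique(cds$genome_id)],
                       function(x) x / sum(x)), use.names = FALSE)
    prob <- fractions[cds$genome_id] * w * cds$length
    prob <- prob / sum(prob)
    counts <- if (total_reads == 0) {
      integer(nrow(cds))
    } else {
      as.integer(stats::rmultinom(1, size = total_reads, prob = prob))
    }
    list(cds = cds,
         counts = stats::setNames(counts, cds$cds_id),
         truth = list(fractions = fractions))
  })
}

#' Generate OTU abundance profiles with controlled evenness
#'
#' Per-sample community compositions are drawn from a symmetric Dirichlet
#' distribution whose concentration parameter controls evenness: large
#' concentrations approach the uniform profile (Shannon index near
#' `ln(n_categories)`), small concentrations give skewed, low-diversity
#' profiles.
#'
#' @param n_samples number of profiles.
#' @param n_categories number of OTUs/categories.
#' @param concentration symmetric Dirichlet concentration (> 0).
#' @param seed integer seed.
#' @return list with `profiles` (list of [abundance_profile()]s) and
#'   `expected_h` (Shannon index of the expected, i.e. uniform, profile:
#'   `ln(n_categories)`).
#' @export
gen_abundance_profiles <- function(n_samples, n_categories,
                                   concentration, seed = 1) {
  stopifnot(n_samples >= 1, n_categories >= 2, concentration > 0)
  with_seed(seed, {
    profiles <- lapply(seq_len(n_samples), function(i) {
      g <- stats::rgamma(n_categories, shape = concentration, rate = 1)
      if (sum(g) == 0) g[1] <- 1  # pathological tiny-concentration draw
      abundance_profile(stats::setNames(
        g, sprintf("OTU%03d", seq_len(n_categories))))
    })
    list(profiles = profiles, expected_h = log(n_categories))
  })
}
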