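# Shannon diversity and Mann-Whitney U comparison between systems.

#' Construct an abundance profile
#'
#' @param x named or unnamed numeric vector of proportions or raw counts
#'   (counts are normalised internally; no rarefaction is applied).
#' @return object of class `"abundance_profile"` with proportions summing
#'   to 1.
#' @export
abundance_profile <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("abundances must be finite and >= 0", call. = FALSE)
  }
  total <- sum(x)
  if (total == 0) stop("all-zero abundance profile", call. = FALSE)
  structure(list(p = x / total, labels = names(x), n = length(x)),
            class = "abundance_profile")
}

#' Shannon diversity index
#'
#' `H = -sum p_i ln(p_i)` with the convention `0 ln 0 = 0`.  Natural
#' logarithm by default, matching the standard ecological definition; the
#' base-2 variant is available but never the default.
#'
#' @param profile an [abundance_profile()] or a numeric vector of
#'   proportions/counts.
#' @param base logarithm base (`exp(1)` for nats).
#' @return H in nats (or the requested base).
#' @examples
#' shannon(rep(1, 4))            # ln 4
#' shannon(c(0.5, 0.25, 0.25))   # 1.0397...
#' @export
shannon <- function(profile, base = exp(1)) {
  if (!inherits(profile, "abundance_profile")) {
    profile <- abundance_profile(profile)
  }
  p <- profile$p[profile$p > 0]
  -sum(p * log(p, base = base))
}

# U-statistic of sample x against pooled midranks.
u_statistic <- function(rank_x, n_x, n_y) {
  sum(rank_x) - n_x * (n_x + 1) / 2
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midrank tie handling.  For total sample sizes
#' `n_x + n_y <= exact_max` the two-sided p-value is computed exactly by
#' full enumeration of all group assignments of the pooled (mid)ranks,
#' `p = min(1, 2 min(P(U <= u), P(U >= u)))`; larger samples use the normal
#' approximation with tie correction and continuity correction.  When every
#' pooled value is identical the variance degenerates and `p = 1` is
#' returned with a flag.
#'
#' @param x,y numeric samples (nonempty).
#' @param exact_max total sample size up to which exact enumeration is
#'   used (default 12).
#' @return list with `U` (statistic for sample `x`), `p_value`, `method`
#'   (`"exact"` or `"normal"`), and `degenerate` flag.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))       # U = 0, p = 1/3
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact_max = 12) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  n_x <- length(x)
  n_y <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- u_statistic(r[seq_len(n_x)], n_x, n_y)
  if (length(unique(pooled)) == 1) {
    return(list(U = u, p_value = 1, method = "degenerate",
                degenerate = TRUE))
  }
  n <- n_x + n_y
  if (n <= exact_max) {
    combos <- utils::combn(n, n_x)
    us <- apply(combos, 2, function(idx) u_statistic(r[idx], n_x, n_y))
    eps <- 1e-9
    p <- min(1, 2 * min(mean(us <= u + eps), mean(us >= u - eps)))
    list(U = u, p_value = p, method = "exact", degenerate = FALSE)
  } else {
    mu <- n_x * n_y / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_x * n_y / 12 * ((n + 1) - tie_term)
    z <- (u - mu)
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(U = u, p_value = p, method = "normal", degenerate = FALSE)
  }
}

#' Compare Shannon diversity between two reactor systems
#'
#' Computes the Shannon index of each sample profile in each group and
#' tests the null hypothesis of equal group medians with the two-sided
#' Mann-Whitney U test at `alpha = 0.05`.
#'
#' @param profiles_a,profiles_b lists of [abundance_profile()]s (or numeric
#'   vectors) for the two systems.
#' @param alpha significance level for the flag.
#' @return list with `h_a`, `h_b` (per-sample Shannon values), `median_a`,
#'   `median_b`, `U`, `p_value`, `significant`, and a `warnings` character
#'   vector (e.g. insufficient replication).
#' @export
compare_system_diversity <- function(profiles_a, profiles_b,
                                     alpha = 0.05) {
  as_h <- function(profiles) {
    if (!is.list(profiles)) profiles <- list(profiles)
    if (length(profiles) == 0) stop(">= 1 profile per group", call. = FALSE)
    vapply(profiles, shannon, numeric(1))
  }
  h_a <- as_h(profiles_a)
  h_b <- as_h(profiles_b)
  warnings <- character(0)
  if (length(h_a) < 2 || length(h_b) < 2) {
    warnings <- c(warnings,
                  "fewer than 2 samples in a group: test has no power")
  }
  test <- mann_whitney_u(h_a, h_b)
  list(h_a = h_a, h_b = h_b,
       median_a = stats::median(h_a), median_b = stats::median(h_b),
       U = test$U, p_value = test$p_value,
       significant = test$p_value < alpha,
       method = test$method, warnings = warnings)
}
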