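#' Rank progeny and select the top m
#'
#' Stable sort of the named breeding values, ties broken by progeny
#' identifier (lexicographic), top `m` selected. The implied selection
#' intensity is `m` over the number of candidates.
#'
#' @param values named numeric vector of per-progeny values (breeding values
#'   or index scores).
#' @param m number of progeny to select (`<= length(values)`).
#' @param direction `"maximize"` (default) or `"minimize"`.
#' @return list with `ranking` (progeny identifiers, best first), `selected`
#'   (first `m`), `values` (in ranking order), `intensity`.
#' @export
rank_and_select <- function(values, m, direction = c("maximize", "minimize")) {
  direction <- match.arg(direction)
  stopifnot(!is.null(names(values)), m >= 1, m <= length(values))
  ord <- order(if (direction == "maximize") -values else values, names(values),
               method = "radix")
  ranking <- names(values)[ord]
  list(ranking = ranking, selected = ranking[seq_len(m)],
       values = unname(values[ord]), intensity = m / length(values))
}

#' Predicted selection gain
#'
#' Gain is the mean predicted genotypic value (`u+g`) of the selected progeny
#' minus the overall mean, also expressed as a percentage of the overall
#' mean.
#'
#' @param selected_values `u+g` values of the selected progeny.
#' @param overall_mean overall trait mean (positive for the percent gain).
#' @return list with `gain_abs` (trait units) and `gain_pct`.
#' @export
gain_stats <- function(selected_values, overall_mean) {
  stopifnot(length(selected_values) >= 1)
  gain_abs <- mean(selected_values) - overall_mean
  list(gain_abs = gain_abs,
       gain_pct = if (overall_mean > 0) 100 * gain_abs / overall_mean else NA_real_)
}

#' Agreement between two rankings of the same progeny
#'
#' Spearman rank correlation between the two full breeding-value vectors,
#' with a seeded nonparametric bootstrap (progeny pairs resampled with
#' replacement, percentile interval), plus the chance-corrected coincidence
#' index of the two top-`m` sets: `(A - C) / (M - C)` with `A` the observed
#' overlap and `C = b * M` the chance overlap at selection intensity `b`
#' (`C` may be non-integer). A coincidence below zero (worse than chance) is
#' reported unclipped.
#'
#' @param values_a,values_b named per-progeny value vectors over the same
#'   progeny set.
#' @param m number of selected progeny for the coincidence index.
#' @param b_intensity selection intensity used for the chance correction
#'   (default 0.15).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level of the percentile interval.
#' @return list with `spearman_rho`, `boot_ci` (length 2), `coincidence`,
#'   `overlap` (A), `chance` (C).
#' @export
rank_agreement <- function(values_a, values_b, m, b_intensity = 0.15,
                           n_boot = 1000L, seed = 1L, conf = 0.95) {
  stopifnot(!is.null(names(values_a)), !is.null(names(values_b)),
            b_intensity > 0, b_intensity < 1, m >= 1)
  if (!setequal(names(values_a), names(values_b)) ||
      length(values_a) != length(values_b)) {
    stop("the two value vectors must cover the same progeny set", call. = FALSE)
  }
  values_b <- values_b[names(values_a)]
  n <- length(values_a)
  rho <- cor(values_a, values_b, method = "spearman")
  set.seed(as.integer(seed))
  boot_rho <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    suppressWarnings(cor(values_a[idx], values_b[idx], method = "spearman"))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boot_rho, c(alpha, 1 - alpha), na.rm = TRUE))
  top_a <- rank_and_select(values_a, m)$selected
  top_b <- rank_and_select(values_b, m)$selected
  A <- length(intersect(top_a, top_b))
  C <- b_intensity * m
  list(spearman_rho = rho, boot_ci = ci,
       coincidence = (A - C) / (m - C), overlap = A, chance = C)
}

#' Additive genetic index for simultaneous selection
#'
#' Aggregates per-trait predicted genotypic values into one score per
#' progeny. With `standardize = TRUE` (default) each trait's values are
#' divided by a per-trait scale before weighting, making the ranking
#' invariant to the measurement units of any trait:
#' `AGI_i = sum_t w_t * g_it / s_t`. With `standardize = FALSE` the raw
#' values are weighted and summed. Weights default to each trait's genotypic
#' coefficient of variation when supplied by the caller; any positive
#' weights are accepted. All traits must be oriented so that larger is
#' better.
#'
#' @param blups progeny x trait matrix of predicted genotypic values, with
#'   progeny row names.
#' @param weights positive per-trait weights (recycled names checked against
#'   the columns when named).
#' @param standardize divide each trait by `scale` before weighting.
#' @param scale per-trait scale used when standardizing; defaults to the
#'   standard deviation of each column of `blups`.
#' @return list with `agi` (named per-progeny scores) and `ranking`
#'   (descending).
#' @export
agi_scores <- function(blups, weights, standardize = TRUE,
                       scale = apply(blups, 2, sd)) {
  blups <- as.matrix(blups)
  stopifnot(!is.null(rownames(blups)), length(weights) == ncol(blups))
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  if (!is.null(names(weights)) && !is.null(colnames(blups))) {
    weights <- weights[colnames(blups)]
  }
  scores <- if (standardize) {
    stopifnot(all(scale > 0))
    as.numeric(sweep(blups, 2, scale, `/`) %*% weights)
  } else {
    as.numeric(blups %*% weights)
  }
  names(scores) <- rownames(blups)
  list(agi = scores, ranking = rank_and_select(scores, length(scores))$ranking)
}
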