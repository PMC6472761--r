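#' Derived genetic and non-genetic parameters
#'
#' From the variance components of a multi-environment progeny model with
#' `n` locations and `r` replicates per location, computes per trait:
#' plot-basis broad-sense heritability of progeny-mean performance
#' `h2 = sg2 / (sg2 + si2/n + se2/(n r))`, the GxE coefficient of
#' determination `c2_int = si2 / sphen2` with
#' `sphen2 = sg2 + si2 + se2`, and the genotypic and residual coefficients
#' of variation `cv_g = sqrt(sg2)/mean`, `cv_e = sqrt(se2)/mean`
#' (unitless, not percent).
#'
#' @param components a [covariance_set()] (single- or multi-trait) with all
#'   three components present.
#' @param grand_means per-trait trait means (positive; used for the CVs).
#' @param n_locations,n_reps number of locations and replicates per location.
#' @return data frame with one row per trait: `trait`, `sigma_g2`,
#'   `sigma_int2`, `sigma_e2`, `sigma_phen2`, `h2_prog`, `c2_int`, `cv_g`,
#'   `cv_e`.
#' @examples
#' cs <- covariance_set(128.625, 33.9228, 56.5253, traits = "DM")
#' derive_genetic_parameters(cs, grand_means = 143.45, n_locations = 2,
#'                           n_reps = 3)
#' @export
derive_genetic_parameters <- function(components, grand_means, n_locations,
                                      n_reps) {
  stopifnot(inherits(components, "covariance_set"),
            n_locations >= 1, n_reps >= 1)
  if (is.null(components$sigma_g) || is.null(components$sigma_int)) {
    stop("components must include sigma_g and sigma_int", call. = FALSE)
  }
  traits <- components$traits
  t <- length(traits)
  stopifnot(length(grand_means) == t)
  if (any(grand_means <= 0)) {
    stop("grand means must be positive for coefficient-of-variation computation",
         call. = FALSE)
  }
  sg2 <- diag(as.matrix(components$sigma_g))
  si2 <- diag(as.matrix(components$sigma_int))
  se2 <- diag(as.matrix(components$sigma_e))
  if (any(c(sg2, si2, se2) < 0)) stop("negative variance component", call. = FALSE)
  denom <- sg2 + si2 / n_locations + se2 / (n_locations * n_reps)
  sphen2 <- sg2 + si2 + se2
  if (any(denom == 0) || any(sphen2 == 0)) {
    stop("zero denominator in heritability computation", call. = FALSE)
  }
  data.frame(
    trait = traits,
    sigma_g2 = unname(sg2), sigma_int2 = unname(si2), sigma_e2 = unname(se2),
    sigma_phen2 = unname(sphen2),
    h2_prog = unname(sg2 / denom),
    c2_int = unname(si2 / sphen2),
    cv_g = unname(sqrt(sg2) / grand_means),
    cv_e = unname(sqrt(se2) / grand_means),
    stringsAsFactors = FALSE
  )
}

#' Selection accuracy from prediction error variance
#'
#' The PEV-based estimator `sqrt((sg2 - PEV) / sg2)` per progeny; the mean
#' across progeny is the reported mean progeny accuracy. A PEV exceeding the
#' genetic variance (numerically impossible for a proper fit) is clamped to
#' accuracy 0 with a warning.
#'
#' @param sigma_g_diag genetic variance of the trait (scalar).
#' @param pev vector of per-progeny prediction error variances.
#' @return vector of accuracies in `[0, 1]`.
#' @export
accuracy_pev <- function(sigma_g_diag, pev) {
  stopifnot(length(sigma_g_diag) == 1, sigma_g_diag > 0)
  bad <- pev > sigma_g_diag
  if (any(bad)) {
    warning(sum(bad), " PEV value(s) exceed sigma_g2; accuracy clamped to 0",
            call. = FALSE)
    pev[bad] <- sigma_g_diag
  }
  sqrt((sigma_g_diag - pev) / sigma_g_diag)
}

#' Selection accuracy from posterior chains of breeding values
#'
#' The posterior estimator `1 - sd / |mean|` per progeny, truncated to
#' `[0, 1]`. Progeny whose posterior mean is numerically zero (below
#' `epsilon`) have an undefined ratio; they are excluded from the reported
#' mean accuracy and their count is returned.
#'
#' @param g_mean,g_sd per-progeny posterior means and standard deviations of
#'   the breeding value (equal-length vectors).
#' @param epsilon exclusion threshold on `|mean|` (default `1e-6 * sd(g_mean)`).
#' @return list with `accuracy` (per progeny, `NA` where excluded),
#'   `mean_accuracy`, `n_excluded`.
#' @export
accuracy_posterior <- function(g_mean, g_sd, epsilon = 1e-6 * sd(g_mean)) {
  stopifnot(length(g_mean) == length(g_sd))
  excl <- abs(g_mean) < epsilon
  acc <- pmin(pmax(1 - g_sd / abs(g_mean), 0), 1)
  acc[excl] <- NA_real_
  list(accuracy = acc, mean_accuracy = mean(acc, na.rm = TRUE),
       n_excluded = sum(excl))
}

#' Genetic covariance by the sum-of-traits trick
#'
#' Given genetic variances from three single-trait analyses -- trait i,
#' trait j, and their plot-wise sum (see [make_sum_trait()]) -- the genetic
#' covariance is `(var_sum - var_i - var_j) / 2`.
#'
#' @param var_i,var_j,var_sum genetic variances of the two traits and of
#'   their sum trait.
#' @return the implied genetic covariance.
#' @export
cov_sum_trick <- function(var_i, var_j, var_sum) {
  (var_sum - var_i - var_j) / 2
}

#' Genetic correlation matrix with out-of-bounds flags
#'
#' `rho_ij = cov_ij / sqrt(var_i var_j)`. Covariances assembled from
#' single-trait sum-trick analyses need not form a PSD matrix, so `|rho| > 1`
#' can occur; such cells are returned unclipped and flagged rather than
#' silently truncated (correlations from a PSD multi-trait fit are always in
#' `[-1, 1]` and never flagged).
#'
#' @param cov_g trait x trait genetic covariance matrix (diagonal > 0).
#' @return list with `rho` (correlation matrix) and `out_of_bounds` (logical
#'   matrix flagging `|rho| > 1`).
#' @export
gen_correlation <- function(cov_g) {
  cov_g <- as.matrix(cov_g)
  d <- diag(cov_g)
  if (any(d <= 0)) stop("genetic variances must be positive", call. = FALSE)
  rho <- cov_g / sqrt(outer(d, d))
  flags <- abs(rho) > 1
  diag(flags) <- FALSE
  list(rho = rho, out_of_bounds = flags)
}
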