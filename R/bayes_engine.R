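#' Prior specification for the Bayesian mixed model
#'
#' Weakly informative conjugate priors: inverse-Wishart on each trait x trait
#' covariance matrix (multi-trait) or independent inverse-gamma on each
#' variance (single trait), and independent zero-mean normals with a large
#' variance on the fixed effects. Defaults are deliberately weak -- scale
#' `diag(1e-3)` with `df = n_traits` for the IW, shape and scale `0.001` for
#' the IG, fixed-effect prior variance `1e8` -- and every hyperparameter can
#' be overridden.
#'
#' @param n_traits number of traits in the model.
#' @param iw_scale IW scale matrix (default `diag(1e-3, n_traits)`).
#' @param iw_df IW degrees of freedom (default `n_traits`; must exceed
#'   `n_traits - 1`).
#' @param ig_shape,ig_scale inverse-gamma hyperparameters used when
#'   `n_traits == 1`.
#' @param fixed_prior_var prior variance of fixed effects.
#' @return an object of class `prior_spec` with one entry per covariance
#'   component (`sigma_g`, `sigma_int`, `sigma_e`).
#' @export
prior_spec <- function(n_traits, iw_scale = diag(1e-3, n_traits),
                       iw_df = n_traits, ig_shape = 0.001, ig_scale = 0.001,
                       fixed_prior_var = 1e8) {
  stopifnot(n_traits >= 1, fixed_prior_var > 0)
  comp <- if (n_traits == 1L) {
    if (ig_shape <= 0 || ig_scale <= 0) {
      stop("inverse-gamma shape and scale must be positive", call. = FALSE)
    }
    list(type = "ig", shape = ig_shape, scale = ig_scale)
  } else {
    iw_scale <- as.matrix(iw_scale)
    check_psd(iw_scale, "iw_scale")
    if (iw_df <= n_traits - 1) {
      stop("inverse-Wishart df must exceed n_traits - 1", call. = FALSE)
    }
    list(type = "iw", scale = iw_scale, df = iw_df)
  }
  structure(list(sigma_g = comp, sigma_int = comp, sigma_e = comp,
                 fixed_prior_var = fixed_prior_var, n_traits = n_traits),
            class = "prior_spec")
}

#' MCMC schedule
#'
#' @param n_iter total Gibbs iterations (default desk-scale 20000).
#' @param burn_in discarded initial iterations (must be `< n_iter`;
#'   default 10000).
#' @param thin sampling interval (default 5). The number of stored samples is
#'   `floor((n_iter - burn_in) / thin)`.
#' @param seed integer RNG seed.
#' @return an object of class `mcmc_opts`.
#' @export
mcmc_opts <- function(n_iter = 20000L, burn_in = 10000L, thin = 5L, seed = 1L) {
  stopifnot(burn_in < n_iter, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 n_stored = (as.integer(n_iter) - as.integer(burn_in)) %/%
                   as.integer(thin)),
            class = "mcmc_opts")
}

# inverse-Wishart draw via the Wishart of the inverse scale
riwish1 <- function(df, scale) {
  solve(rWishart(1L, df, solve(scale))[, , 1])
}

# -2 log N(y; Xb, V) with V = Z Sg Z' + W Sint W' + R, random effects
# integrated out through the random-only MME identity.
gaussian_deviance <- function(design, ctx, blue, components) {
  inc_g <- !is.null(components$sigma_g)
  inc_i <- !is.null(components$sigma_int)
  q <- ctx$q; nloc <- ctx$nloc; t <- ctx$t
  rr <- build_rinv(ctx, components$sigma_e)
  r <- design$y - as.numeric(design$X %*% blue)
  Um <- cbind(if (inc_g) design$Z, if (inc_i) design$W)
  quad <- sum(r * as.numeric(rr$Rinv %*% r))
  ldet <- rr$logdet_R
  if (!is.null(Um)) {
    UtR <- Matrix::t(Um) %*% rr$Rinv
    Mrr <- as.matrix(UtR %*% Um)
    k <- 0L
    if (inc_g) {
      idx <- seq_len(q * t)
      Mrr[idx, idx] <- Mrr[idx, idx] + kronecker(solve(components$sigma_g), diag(q))
      ldet <- ldet + q * logdet(components$sigma_g)
      k <- q * t
    }
    if (inc_i) {
      idx <- k + seq_len(q * nloc * t)
      Mrr[idx, idx] <- Mrr[idx, idx] +
        kronecker(solve(components$sigma_int), diag(q * nloc))
      ldet <- ldet + q * nloc * logdet(components$sigma_int)
    }
    ch <- chol(Mrr)
    rhs <- as.numeric(UtR %*% r)
    u <- backsolve(ch, forwardsolve(t(ch), rhs))
    quad <- quad - sum(u * rhs)
    ldet <- ldet + 2 * sum(log(diag(ch)))
  }
  ctx$n * log(2 * pi) + ldet + quad
}

#' Gibbs sampler for the Bayesian multi-environment mixed model
#'
#' Blocked Gibbs sampling with conjugate conditionals: (a) a joint
#' multivariate-normal draw of all fixed and random effects given the
#' covariance components, from the Cholesky factor of the mixed-model
#' coefficient matrix (fixed effects carry a large-variance normal prior);
#' (b) inverse-Wishart (multi-trait) or inverse-gamma (single-trait) draws of
#' `sigma_g`, `sigma_int` and `sigma_e` given the sampled effects and
#' residuals, in that fixed order. The run is deterministic given
#' `opts$seed`.
#'
#' Multi-trait sampling requires every plot to have all traits observed (the
#' conjugate residual update acts on complete plot residual vectors); the
#' single-trait sampler handles missing plots exactly by row deletion. A
#' deviance chain is stored alongside, defined conditionally on the fixed
#' effects and the covariance components with the random effects integrated
#' out of the Gaussian likelihood.
#'
#' @param design a [build_design()] result.
#' @param prior a [prior_spec()]; default weak priors for the design's trait
#'   count.
#' @param opts an [mcmc_opts()].
#' @param include named logical vector with elements `g` and `int` selecting
#'   the random terms (reduced models for DIC comparisons).
#' @return an object of class `posterior_samples`: list with
#'   `component_chains` (stored samples x parameters matrix, lower-triangle
#'   entries of each included covariance), `g_chains` (stored samples x
#'   (progeny x trait) matrix of progeny effects), `blue_chains`,
#'   `deviance_chain`, `opts_used`, `prior_used`, `traits`, `progeny`.
#' @export
run_mcmc <- function(design, prior = NULL, opts = mcmc_opts(),
                     include = c(g = TRUE, int = TRUE)) {
  stopifnot(inherits(design, "design_set"), inherits(opts, "mcmc_opts"))
  ctx <- mme_context(design)
  t <- ctx$t; q <- ctx$q; nloc <- ctx$nloc; p <- ctx$p
  traits <- design$traits
  if (t > 1L && length(ctx$partial)) {
    stop("multi-trait MCMC requires all traits observed on every plot; ",
         length(ctx$partial), " plot(s) are partially observed", call. = FALSE)
  }
  prior <- prior %||% prior_spec(t)
  if (!inherits(prior, "prior_spec")) stop("prior must be a prior_spec", call. = FALSE)
  inc_g <- isTRUE(include[["g"]]); inc_i <- isTRUE(include[["int"]])
  Tm <- cbind(design$X, if (inc_g) design$Z, if (inc_i) design$W)
  pr <- ctx$plot_rows[rowSums(!is.na(ctx$plot_rows)) == t, , drop = FALSE]
  n_plots <- nrow(pr)
  # cross-products per trait pair; rows aligned by plot
  Cab <- vector("list", t * t); Tay <- vector("list", t * t)
  for (a in seq_len(t)) for (b in seq_len(t)) {
    k <- (a - 1L) * t + b
    Cab[[k]] <- Matrix::crossprod(Tm[pr[, a], , drop = FALSE],
                                  Tm[pr[, b], , drop = FALSE])
    Tay[[k]] <- as.numeric(Matrix::crossprod(Tm[pr[, a], , drop = FALSE],
                                             design$y[pr[, b]]))
  }
  P <- ncol(Tm)
  gidx <- if (inc_g) p + seq_len(q * t) else integer(0)
  iidx <- if (inc_i) p + length(gidx) + seq_len(q * nloc * t) else integer(0)
  draw_cov <- function(hyp, S_data, n_units) {
    if (hyp$type == "ig") {
      matrix(1 / rgamma(1, shape = hyp$shape + n_units / 2,
                        rate = hyp$scale + S_data[1, 1] / 2), 1, 1)
    } else {
      riwish1(hyp$df + n_units, hyp$scale + S_data)
    }
  }
  set.seed(opts$seed)
  # start: equal split of the phenotypic covariance
  ymat <- matrix(design$y[pr], n_plots, t)
  Sp <- psd_project(cov(ymat), 1e-6)$mat
  k0 <- 1L + inc_g + inc_i
  Sg <- if (inc_g) Sp / k0
  Si <- if (inc_i) Sp / k0
  Se <- Sp / k0
  n_stored <- opts$n_stored
  par_names <- c(if (inc_g) vech_labels("sigma_g", traits),
                 if (inc_i) vech_labels("sigma_int", traits),
                 vech_labels("sigma_e", traits))
  comp_chain <- matrix(NA_real_, n_stored, length(par_names),
                       dimnames = list(NULL, par_names))
  g_chain <- if (inc_g) matrix(NA_real_, n_stored, q * t,
                               dimnames = list(NULL, paste(rep(traits, each = q),
                                                           rep(design$progeny, t),
                                                           sep = ":")))
  blue_chain <- matrix(NA_real_, n_stored, p,
                       dimnames = list(NULL, colnames(design$X)))
  dev_chain <- numeric(n_stored)
  stored <- 0L
  for (it in seq_len(opts$n_iter)) {
    Einv <- solve(Se)
    lhs <- matrix(0, P, P); rhs <- numeric(P)
    for (a in seq_len(t)) for (b in seq_len(t)) {
      k <- (a - 1L) * t + b
      if (Einv[a, b] != 0) {
        lhs <- lhs + Einv[a, b] * as.matrix(Cab[[k]])
        rhs <- rhs + Einv[a, b] * Tay[[k]]
      }
    }
    diag(lhs)[seq_len(p)] <- diag(lhs)[seq_len(p)] + 1 / prior$fixed_prior_var
    if (inc_g) lhs[gidx, gidx] <- lhs[gidx, gidx] + kronecker(solve(Sg), diag(q))
    if (inc_i) lhs[iidx, iidx] <- lhs[iidx, iidx] +
        kronecker(solve(Si), diag(q * nloc))
    ch <- tryCatch(chol(lhs), error = function(e) {
      warning("conditional coefficient matrix near-singular; jitter added",
              call. = FALSE)
      chol(lhs + diag(1e-8 * mean(diag(lhs)), P))
    })
    theta_hat <- backsolve(ch, forwardsolve(t(ch), rhs))
    theta <- theta_hat + backsolve(ch, rnorm(P))
    if (inc_g) {
      gmat <- matrix(theta[gidx], q, t)
      Sg <- draw_cov(prior$sigma_g, crossprod(gmat), q)
    }
    if (inc_i) {
      imat <- matrix(theta[iidx], q * nloc, t)
      Si <- draw_cov(prior$sigma_int, crossprod(imat), q * nloc)
    }
    resid <- design$y - as.numeric(Tm %*% theta)
    emat <- matrix(resid[pr], n_plots, t)
    Se <- draw_cov(prior$sigma_e, crossprod(emat), n_plots)
    if (it > opts$burn_in && (it - opts$burn_in) %% opts$thin == 0L) {
      stored <- stored + 1L
      comp_chain[stored, ] <- c(if (inc_g) vech(Sg), if (inc_i) vech(Si),
                                vech(Se))
      if (inc_g) g_chain[stored, ] <- theta[gidx]
      blue_chain[stored, ] <- theta[seq_len(p)]
      cs <- covariance_set(if (inc_g) Sg, if (inc_i) Si, Se, traits = traits)
      dev_chain[stored] <- gaussian_deviance(design, ctx, theta[seq_len(p)], cs)
    }
  }
  structure(list(
    component_chains = comp_chain, g_chains = g_chain,
    blue_chains = blue_chain, deviance_chain = dev_chain,
    opts_used = opts, prior_used = prior, include = c(g = inc_g, int = inc_i),
    traits = traits, progeny = design$progeny
  ), class = "posterior_samples")
}

# Reconstruct the covariance matrices of one stored draw.
draw_components <- function(samples, row) {
  t <- length(samples$traits)
  nv <- t * (t + 1) / 2
  v <- samples$component_chains[row, ]
  k <- 0L
  grab <- function() {
    m <- unvech(v[k + seq_len(nv)], t)
    k <<- k + nv
    m
  }
  Sg <- if (samples$include[["g"]]) grab()
  Si <- if (samples$include[["int"]]) grab()
  Se <- grab()
  list(sigma_g = Sg, sigma_int = Si, sigma_e = Se)
}

#' Posterior mean and standard deviation of progeny effects
#'
#' @param samples a [run_mcmc()] result with progeny effects.
#' @return list of `mean` and `sd`, each a progeny x trait matrix.
#' @export
posterior_breeding_values <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"), !is.null(samples$g_chains))
  q <- length(samples$progeny); t <- length(samples$traits)
  m <- matrix(colMeans(samples$g_chains), q, t,
              dimnames = list(samples$progeny, samples$traits))
  s <- matrix(apply(samples$g_chains, 2, sd), q, t,
              dimnames = list(samples$progeny, samples$traits))
  list(mean = m, sd = s)
}

#' Shortest (highest posterior density) credible interval
#'
#' The shortest contiguous empirical interval containing a `prob` fraction of
#' the sample. A constant chain yields a degenerate point interval.
#'
#' @param x numeric sample.
#' @param prob interval probability (default 0.95).
#' @return length-2 numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  stopifnot(length(x) >= 1, prob > 0, prob <= 1)
  xs <- sort(x)
  n <- length(xs)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(xs[1], xs[n]))
  width <- xs[(m + 1):n] - xs[1:(n - m)]
  j <- which.min(width)
  c(xs[j], xs[j + m])
}

#' Convergence diagnostics for one MCMC chain
#'
#' Geweke's z statistic comparing the mean of the first 10% of the chain
#' with the last 50%, using spectral-density estimates of the variances
#' (via the coda package), together with the highest-posterior-density
#' interval and the effective sample size. A constant chain has an undefined
#' Geweke statistic and a degenerate point HPD interval; this is flagged
#' rather than an error.
#'
#' @param chain numeric vector of at least 100 samples.
#' @param prob HPD probability (default 0.95).
#' @return list with `geweke_z`, `hpd`, `ess`, `constant` (logical flag).
#' @export
chain_diagnostics <- function(chain, prob = 0.95) {
  stopifnot(length(chain) >= 100)
  if (sd(chain) == 0) {
    return(list(geweke_z = NA_real_, hpd = c(chain[1], chain[1]),
                ess = NA_real_, constant = TRUE))
  }
  gz <- unname(coda::geweke.diag(coda::mcmc(chain), frac1 = 0.1,
                                 frac2 = 0.5)$z)
  list(geweke_z = gz, hpd = hpd_interval(chain, prob),
       ess = unname(coda::effectiveSize(coda::mcmc(chain))),
       constant = FALSE)
}

#' Deviance information criterion
#'
#' `Dbar` is the posterior mean of the stored deviance chain, `Dhat` the
#' deviance at the posterior means of the fixed effects and covariance
#' components, `pD = Dbar - Dhat` the effective number of parameters, and
#' `DIC = Dhat + 2 pD = Dbar + pD` (the identity is asserted). The deviance
#' is conditional on fixed effects and components with random effects
#' integrated out, so values are comparable between full and reduced models
#' fitted to the same design.
#'
#' @param samples a [run_mcmc()] result.
#' @param design the [build_design()] the samples were drawn from.
#' @return list with `dic`, `pD`, `Dbar`, `Dhat`.
#' @export
dic_value <- function(samples, design) {
  stopifnot(inherits(samples, "posterior_samples"), inherits(design, "design_set"))
  ctx <- mme_context(design)
  Dbar <- mean(samples$deviance_chain)
  t <- length(samples$traits)
  n_draws <- nrow(samples$component_chains)
  acc <- lapply(draw_components(samples, 1), function(m) {
    if (is.null(m)) NULL else m * 0
  })
  for (r in seq_len(n_draws)) {
    d <- draw_components(samples, r)
    for (nm in names(acc)) if (!is.null(acc[[nm]])) acc[[nm]] <- acc[[nm]] + d[[nm]]
  }
  mean_comps <- lapply(acc, function(m) {
    if (is.null(m)) NULL else psd_project(m / n_draws)$mat
  })
  cs <- covariance_set(mean_comps$sigma_g, mean_comps$sigma_int,
                       mean_comps$sigma_e, traits = samples$traits)
  Dhat <- gaussian_deviance(design, ctx, colMeans(samples$blue_chains), cs)
  pD <- Dbar - Dhat
  if (pD < 0) {
    warning("negative pD: poor mixing or non-log-concave posterior", call. = FALSE)
  }
  dic <- Dhat + 2 * pD
  stopifnot(abs(dic - (Dbar + pD)) < 1e-8 * max(1, abs(dic)))
  list(dic = dic, pD = pD, Dbar = Dbar, Dhat = Dhat)
}

#' Posterior summaries of a derived scalar parameter
#'
#' Applies `quantity` to the covariance matrices of every stored draw
#' (draw-wise transformation, e.g. plot-basis heritability), then summarizes
#' the transformed chain: kernel-density mode (Gaussian kernel, Silverman's
#' bandwidth), mean, median and HPD interval.
#'
#' @param samples a [run_mcmc()] result.
#' @param quantity function of a list with elements `sigma_g`, `sigma_int`,
#'   `sigma_e` (matrices; `NULL` when excluded) returning a scalar.
#' @param prob HPD probability.
#' @return list with `mode`, `mean`, `median`, `hpd`, and the transformed
#'   chain as `chain`.
#' @export
posterior_summary <- function(samples, quantity, prob = 0.95) {
  stopifnot(inherits(samples, "posterior_samples"), is.function(quantity))
  n_draws <- nrow(samples$component_chains)
  vals <- vapply(seq_len(n_draws),
                 function(r) quantity(draw_components(samples, r)), numeric(1))
  dd <- density(vals, bw = "nrd0")
  list(mode = dd$x[which.max(dd$y)], mean = mean(vals), median = median(vals),
       hpd = hpd_interval(vals, prob), chain = vals)
}
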