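#' Variance-covariance component set
#'
#' Holds the trait x trait covariance matrices of the mixed model: `sigma_g`
#' (progeny), `sigma_int` (progeny-by-location interaction) and `sigma_e`
#' (residual, modeled within plot across traits). Scalars are accepted for
#' single-trait models. A `NULL` `sigma_g` or `sigma_int` encodes a reduced
#' model without that random term.
#'
#' @param sigma_g,sigma_int,sigma_e symmetric PSD matrices (or scalars), all
#'   of the same dimension; `sigma_g`/`sigma_int` may be `NULL`.
#' @param traits optional trait names used for dimnames.
#' @return an object of class `covariance_set`.
#' @export
covariance_set <- function(sigma_g, sigma_int, sigma_e, traits = NULL) {
  norm <- function(m, nm) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    check_psd(m, nm)
    if (!is.null(traits)) dimnames(m) <- list(traits, traits)
    m
  }
  sigma_e <- norm(sigma_e, "sigma_e")
  t <- ncol(sigma_e)
  out <- list(sigma_g = norm(sigma_g, "sigma_g"),
              sigma_int = norm(sigma_int, "sigma_int"),
              sigma_e = sigma_e,
              traits = traits %||% colnames(sigma_e) %||% paste0("trait", seq_len(t)))
  for (nm in c("sigma_g", "sigma_int")) {
    if (!is.null(out[[nm]]) && ncol(out[[nm]]) != t) {
      stop(nm, " must have the same dimension as sigma_e", call. = FALSE)
    }
  }
  structure(out, class = "covariance_set")
}

# ---- internal machinery -----------------------------------------------------

# Precompute the plot/trait row layout of a design once per fit.
mme_context <- function(design) {
  t <- length(design$traits)
  plots <- design$plot_key
  pos <- match(design$obs_index$plot, plots)
  tri <- match(design$obs_index$trait, design$traits)
  plot_rows <- matrix(NA_integer_, length(plots), t)
  plot_rows[cbind(pos, tri)] <- seq_along(design$y)
  n_obs_traits <- rowSums(!is.na(plot_rows))
  list(t = t, q = length(design$progeny), nloc = length(design$locations),
       n = length(design$y), p = ncol(design$X),
       plot_rows = plot_rows,
       complete = which(n_obs_traits == t),
       partial = which(n_obs_traits > 0L & n_obs_traits < t),
       n_plots_used = sum(n_obs_traits > 0L))
}

# Sparse residual precision matrix plus its log-determinant contribution.
build_rinv <- function(ctx, sigma_e) {
  t <- ctx$t
  Einv <- solve(sigma_e)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  if (length(ctx$complete)) {
    pr <- ctx$plot_rows[ctx$complete, , drop = FALSE]
    for (a in seq_len(t)) for (b in seq_len(t)) {
      ii <- c(ii, pr[, a]); jj <- c(jj, pr[, b])
      xx <- c(xx, rep(Einv[a, b], nrow(pr)))
    }
  }
  ld <- length(ctx$complete) * logdet(sigma_e)
  for (pl in ctx$partial) {
    obs <- which(!is.na(ctx$plot_rows[pl, ]))
    r <- ctx$plot_rows[pl, obs]
    Eo <- solve(sigma_e[obs, obs, drop = FALSE])
    ii <- c(ii, rep(r, each = length(r))); jj <- c(jj, rep(r, length(r)))
    xx <- c(xx, as.vector(Eo))
    ld <- ld + logdet(sigma_e[obs, obs, drop = FALSE])
  }
  list(Rinv = Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                   dims = c(ctx$n, ctx$n)),
       logdet_R = ld)
}

# Assemble and solve the mixed-model equations at given components.
# Returns coefficient-matrix inverse, solutions, residuals and the restricted
# log-likelihood. `fixed_prior_var` adds a ridge on the fixed block (used by
# the Gibbs sampler); NULL means flat fixed effects (REML).
mme_solve <- function(design, components, ctx = mme_context(design),
                      fixed_prior_var = NULL) {
  t <- ctx$t; q <- ctx$q; nloc <- ctx$nloc; p <- ctx$p
  inc_g <- !is.null(components$sigma_g)
  inc_i <- !is.null(components$sigma_int)
  Tm <- cbind(design$X,
              if (inc_g) design$Z,
              if (inc_i) design$W)
  rr <- build_rinv(ctx, components$sigma_e)
  TtR <- Matrix::t(Tm) %*% rr$Rinv
  lhs <- TtR %*% Tm
  rhs <- as.numeric(TtR %*% design$y)
  nre_g <- if (inc_g) q * t else 0L
  nre_i <- if (inc_i) q * nloc * t else 0L
  gidx <- if (inc_g) p + seq_len(nre_g) else integer(0)
  iidx <- if (inc_i) p + nre_g + seq_len(nre_i) else integer(0)
  logdet_G <- 0
  lhs <- as.matrix(lhs)
  if (inc_g) {
    lhs[gidx, gidx] <- lhs[gidx, gidx] +
      kronecker(solve(components$sigma_g), diag(q))
    logdet_G <- logdet_G + q * logdet(components$sigma_g)
  }
  if (inc_i) {
    lhs[iidx, iidx] <- lhs[iidx, iidx] +
      kronecker(solve(components$sigma_int), diag(q * nloc))
    logdet_G <- logdet_G + q * nloc * logdet(components$sigma_int)
  }
  if (!is.null(fixed_prior_var)) {
    lhs[cbind(seq_len(p), seq_len(p))] <-
      lhs[cbind(seq_len(p), seq_len(p))] + 1 / fixed_prior_var
  }
  ch <- tryCatch(chol(lhs), error = function(e) {
    stop(sprintf(
      "singular mixed-model coefficient matrix (dim %d, reciprocal condition %.3g): %s",
      ncol(lhs), 1 / kappa(lhs), conditionMessage(e)), call. = FALSE)
  })
  Cinv <- chol2inv(ch)
  theta <- as.numeric(Cinv %*% rhs)
  resid <- as.numeric(design$y - Tm %*% theta)
  yRy <- sum(design$y * as.numeric(rr$Rinv %*% design$y))
  quad <- yRy - sum(theta * rhs)
  logdet_LHS <- 2 * sum(log(diag(ch)))
  logL <- -0.5 * ((ctx$n - p) * log(2 * pi) + rr$logdet_R + logdet_G +
                    logdet_LHS + quad)
  list(theta = theta, Cinv = Cinv, resid = resid, Tm = Tm, ch = ch, rhs = rhs,
       gidx = gidx, iidx = iidx, p = p, logL = logL, Rinv = rr$Rinv,
       inc_g = inc_g, inc_i = inc_i)
}

# Extract user-facing effect estimates from an mme_solve() result.
mme_effects <- function(design, components, sol, ctx) {
  t <- ctx$t; q <- ctx$q; nloc <- ctx$nloc
  traits <- design$traits
  blue <- setNames(sol$theta[seq_len(sol$p)], colnames(design$X))
  blup_g <- pev_g <- NULL
  if (sol$inc_g) {
    blup_g <- matrix(sol$theta[sol$gidx], q, t,
                     dimnames = list(design$progeny, traits))
    pev_g <- matrix(diag(sol$Cinv)[sol$gidx], q, t,
                    dimnames = list(design$progeny, traits))
  }
  blup_i <- NULL
  if (sol$inc_i) {
    cells <- paste(rep(design$locations, each = q), rep(design$progeny, nloc),
                   sep = ":")
    blup_i <- matrix(sol$theta[sol$iidx], q * nloc, t,
                     dimnames = list(cells, traits))
  }
  # per-trait intercept-level mean of the fixed part, used for u+g values
  xb <- as.numeric(design$X %*% blue)
  u <- vapply(seq_len(t), function(k) {
    rows <- which(design$obs_index$trait == traits[k])
    mean(xb[rows])
  }, numeric(1))
  names(u) <- traits
  list(blue = blue, blup_g = blup_g, pev_g = pev_g, blup_i = blup_i, u = u,
       blup_ug = if (!is.null(blup_g)) sweep(blup_g, 2, u, `+`))
}

# ---- public operations ------------------------------------------------------

#' Solve Henderson's mixed-model equations at fixed components
#'
#' Computes BLUE of fixed effects and BLUP of progeny and GxE effects for
#' given covariance components, together with the per-progeny prediction
#' error variance (PEV, the diagonal of the progeny block of the inverted
#' coefficient matrix) and the restricted log-likelihood at these components.
#'
#' @param design a [build_design()] result.
#' @param components a [covariance_set()] conformable with the design.
#' @return list with `blue`, `blup_g` (progeny deviations, progeny x trait),
#'   `blup_ug` (deviation plus the trait mean of the fixed part), `blup_i`,
#'   `pev_g`, `u` (per-trait fixed-part mean), `logL`.
#' @export
solve_mme <- function(design, components) {
  stopifnot(inherits(design, "design_set"), inherits(components, "covariance_set"))
  if (min(diag(components$sigma_e)) <= 0) {
    stop("sigma_e must be positive definite (zero residual variance is degenerate)",
         call. = FALSE)
  }
  ctx <- mme_context(design)
  sol <- mme_solve(design, components, ctx)
  c(mme_effects(design, components, sol, ctx), list(logL = sol$logL))
}

#' Restricted log-likelihood at given components
#'
#' Evaluates the REML (restricted) Gaussian log-likelihood of the design's
#' response at fixed covariance components. The additive constant convention
#' includes the `-(n - p)/2 log(2 pi)` term, where `p` is the number of fixed
#' effect columns; only differences of this quantity are comparable across
#' software.
#'
#' @inheritParams solve_mme
#' @return a single numeric value.
#' @export
reml_loglik <- function(design, components) {
  stopifnot(inherits(design, "design_set"), inherits(components, "covariance_set"))
  mme_solve(design, components, mme_context(design))$logL
}

# Moment (balanced ANOVA cross-products) starting values for EM-REML.
# Valid for complete balanced multi-location RCBD data; returns NULL when the
# layout does not support it. Strata: progeny, progeny-by-location, residual
# (after removing location and block-within-location means).
moment_start <- function(design, ctx) {
  t <- ctx$t
  if (length(ctx$partial) || length(ctx$complete) != nrow(ctx$plot_rows)) {
    return(NULL)
  }
  oi <- design$obs_index[match(seq_len(nrow(ctx$plot_rows)),
                               match(design$obs_index$plot, design$plot_key)), ]
  prog <- factor(oi$progeny, levels = design$progeny)
  loc <- factor(oi$location, levels = design$locations)
  blk <- factor(paste(oi$location, oi$block, sep = ":"))
  q <- nlevels(prog); n <- nlevels(loc)
  r <- length(unique(oi$block[oi$location == design$locations[1]]))
  if (n < 2L || r < 2L || q < 2L) return(NULL)
  if (nrow(ctx$plot_rows) != q * n * r) return(NULL)
  tab <- table(prog, paste(loc, blk))
  if (any(tab != 1L)) return(NULL)
  ymat <- matrix(design$y[ctx$plot_rows], ncol = t)
  ybar <- colMeans(ymat)
  pm <- rowsum(ymat, prog) / (n * r)
  lm_ <- rowsum(ymat, loc) / (q * r)
  cellf <- paste(as.integer(loc), as.integer(prog))
  cm <- rowsum(ymat, cellf) / r
  cm <- cm[match(paste(rep(seq_len(n), each = q), rep(seq_len(q), n)),
                 rownames(cm)), , drop = FALSE]
  lbm <- rowsum(ymat, blk) / q
  M_G <- n * r * crossprod(sweep(pm, 2, ybar)) / (q - 1)
  dev_cell <- cm - pm[rep(seq_len(q), n), , drop = FALSE] -
    lm_[rep(seq_len(n), each = q), , drop = FALSE] +
    matrix(ybar, q * n, t, byrow = TRUE)
  M_GxE <- r * crossprod(dev_cell) / ((q - 1) * (n - 1))
  resid <- ymat - cm[(as.integer(loc) - 1L) * q + as.integer(prog), , drop = FALSE] -
    lbm[as.integer(blk), , drop = FALSE] + lm_[as.integer(loc), , drop = FALSE]
  M_E <- crossprod(resid) / (n * (q - 1) * (r - 1))
  list(sigma_g = psd_project((M_G - M_GxE) / (n * r), 1e-4)$mat,
       sigma_int = psd_project((M_GxE - M_E) / r, 1e-4)$mat,
       sigma_e = psd_project(M_E, 1e-6)$mat)
}

# One EM update of all included components; returns new covariance_set.
em_update <- function(design, components, sol, ctx) {
  t <- ctx$t; q <- ctx$q; nloc <- ctx$nloc
  tr_block <- function(idx_base, m, a, b) {
    ia <- idx_base + (a - 1L) * m + seq_len(m)
    ib <- idx_base + (b - 1L) * m + seq_len(m)
    sum(sol$Cinv[cbind(ia, ib)])
  }
  new_g <- new_i <- NULL
  if (sol$inc_g) {
    gmat <- matrix(sol$theta[sol$gidx], q, t)
    new_g <- crossprod(gmat)
    for (a in seq_len(t)) for (b in seq_len(t)) {
      new_g[a, b] <- (new_g[a, b] + tr_block(sol$p, q, a, b)) / q
    }
  }
  if (sol$inc_i) {
    m <- q * nloc
    imat <- matrix(sol$theta[sol$iidx], m, t)
    new_i <- crossprod(imat)
    base <- sol$p + length(sol$gidx)
    for (a in seq_len(t)) for (b in seq_len(t)) {
      new_i[a, b] <- (new_i[a, b] + tr_block(base, m, a, b)) / m
    }
  }
  # residual update: per-plot conditional expectation of e e'
  Se <- components$sigma_e
  S <- matrix(0, t, t)
  if (length(ctx$complete)) {
    pr <- ctx$plot_rows[ctx$complete, , drop = FALSE]
    for (a in seq_len(t)) for (b in seq_len(a)) {
      ra <- pr[, a]; rb <- pr[, b]
      M <- Matrix::crossprod(sol$Tm[rb, , drop = FALSE],
                             sol$Tm[ra, , drop = FALSE])
      M <- as(as(M, "generalMatrix"), "TsparseMatrix")
      val <- sum(sol$resid[ra] * sol$resid[rb]) +
        sum(sol$Cinv[cbind(M@i + 1L, M@j + 1L)] * M@x)
      S[a, b] <- S[a, b] + val
      if (a != b) S[b, a] <- S[b, a] + val
    }
  }
  for (pl in ctx$partial) {
    obs <- which(!is.na(ctx$plot_rows[pl, ]))
    mis <- setdiff(seq_len(t), obs)
    r <- ctx$plot_rows[pl, obs]
    Tro <- sol$Tm[r, , drop = FALSE]
    Eoo <- tcrossprod(sol$resid[r]) +
      as.matrix(Tro %*% sol$Cinv %*% Matrix::t(Tro))
    Ef <- matrix(0, t, t)
    Ef[obs, obs] <- Eoo
    if (length(mis)) {
      A <- Se[mis, obs, drop = FALSE] %*% solve(Se[obs, obs, drop = FALSE])
      Ef[mis, obs] <- A %*% Eoo
      Ef[obs, mis] <- t(Ef[mis, obs])
      Ef[mis, mis] <- A %*% Eoo %*% t(A) +
        (Se[mis, mis, drop = FALSE] - A %*% Se[obs, mis, drop = FALSE])
    }
    S <- S + Ef
  }
  new_e <- S / ctx$n_plots_used
  list(sigma_g = new_g, sigma_int = new_i, sigma_e = new_e)
}

#' Fit the mixed model by EM-REML
#'
#' Estimates the covariance components by expectation-maximization on the
#' restricted likelihood. Each EM step solves Henderson's equations at the
#' current components and updates each included covariance matrix from the
#' conditional expectations of its effects; the restricted log-likelihood is
#' non-decreasing along the iteration, which is asserted and recorded in
#' `logl_trace`. An Aitken extrapolation step is attempted periodically and
#' accepted only when it does not decrease the likelihood, so monotonicity
#' survives acceleration. Updated matrices that leave the PSD cone are
#' projected back (with a warning) and still count as parameters.
#'
#' @param design a [build_design()] result.
#' @param init optional starting [covariance_set()]; default splits the
#'   phenotypic trait covariance equally among the included components.
#' @param include named logical vector with elements `g` and `int`; set one
#'   to `FALSE` to fit a reduced model without that random term.
#' @param tol relative log-likelihood change declaring convergence
#'   (default 1e-9).
#' @param max_iter iteration cap (default 5000); reaching it returns the
#'   current fit with `converged = FALSE`.
#' @param accelerate logical, attempt safeguarded Aitken extrapolation
#'   (default TRUE).
#' @param verbose print the log-likelihood trace.
#' @return an object of class `freq_fit`: list with `components`, `blue`,
#'   `blup_g`, `blup_ug`, `blup_i`, `pev_g`, `u`, `logL`, `deviance`,
#'   `n_varparams`, `converged`, `n_iter`, `logl_trace`, `aic`.
#' @export
fit_reml <- function(design, init = NULL, include = c(g = TRUE, int = TRUE),
                     tol = 1e-9, max_iter = 5000L, accelerate = TRUE,
                     verbose = FALSE) {
  stopifnot(inherits(design, "design_set"))
  inc_g <- isTRUE(include[["g"]]); inc_i <- isTRUE(include[["int"]])
  ctx <- mme_context(design)
  t <- ctx$t
  traits <- design$traits
  if (is.null(init)) {
    ms <- if (inc_g && inc_i) moment_start(design, ctx)
    if (!is.null(ms)) {
      init <- covariance_set(ms$sigma_g, ms$sigma_int, ms$sigma_e,
                             traits = traits)
    } else {
      ymat <- matrix(NA_real_, length(design$plot_key), t)
      ymat[cbind(match(design$obs_index$plot, design$plot_key),
                 match(design$obs_index$trait, traits))] <- design$y
      Sp <- cov(ymat, use = "pairwise.complete.obs")
      Sp[is.na(Sp)] <- 0
      Sp <- psd_project(Sp, 1e-6)$mat
      k <- 1L + inc_g + inc_i
      init <- covariance_set(if (inc_g) Sp / k, if (inc_i) Sp / k, Sp / k,
                             traits = traits)
    }
  }
  comps <- init
  pack <- function(cs) c(if (inc_g) vech(cs$sigma_g),
                         if (inc_i) vech(cs$sigma_int), vech(cs$sigma_e))
  unpack <- function(v) {
    nv <- t * (t + 1) / 2
    k <- 0L
    g <- NULL; i <- NULL
    if (inc_g) { g <- unvech(v[k + seq_len(nv)], t); k <- k + nv }
    if (inc_i) { i <- unvech(v[k + seq_len(nv)], t); k <- k + nv }
    e <- unvech(v[k + seq_len(nv)], t)
    pg <- lapply(list(g = g, int = i, e = e), function(m) {
      if (is.null(m)) NULL else psd_project(m)$mat
    })
    covariance_set(pg$g, pg$int, pg$e, traits = traits)
  }
  sol <- mme_solve(design, comps, ctx)
  trace <- sol$logL
  projected_warned <- FALSE
  converged <- FALSE
  iter <- 0L
  one_em <- function(comps, sol) {
    upd <- em_update(design, comps, sol, ctx)
    any_proj <- FALSE
    for (nm in names(upd)) {
      if (is.null(upd[[nm]])) next
      pj <- psd_project(upd[[nm]])
      upd[[nm]] <- pj$mat
      any_proj <- any_proj || pj$projected
    }
    if (any_proj && !projected_warned) {
      warning("EM update left the PSD cone; projected back (component pinned near boundary)",
              call. = FALSE)
      projected_warned <<- TRUE
    }
    cs <- covariance_set(upd$sigma_g, upd$sigma_int, upd$sigma_e,
                         traits = traits)
    list(comps = cs, sol = mme_solve(design, cs, ctx))
  }
  while (iter < max_iter) {
    logL_prev <- sol$logL
    if (!accelerate) {
      iter <- iter + 1L
      st <- one_em(comps, sol)
      comps <- st$comps; sol <- st$sol
      trace <- c(trace, sol$logL)
    } else {
      # SQUAREM cycle: two EM steps plus a safeguarded extrapolation that is
      # only kept when it does not decrease the restricted likelihood
      p0 <- pack(comps)
      s1 <- one_em(comps, sol)
      s2 <- one_em(s1$comps, s1$sol)
      iter <- iter + 2L
      trace <- c(trace, s1$sol$logL, s2$sol$logL)
      comps <- s2$comps; sol <- s2$sol
      rvec <- pack(s1$comps) - p0
      vvec <- (pack(s2$comps) - pack(s1$comps)) - rvec
      nv <- sqrt(sum(vvec^2))
      if (nv > 0) {
        alpha <- min(-1, -sqrt(sum(rvec^2)) / nv)
        cand <- tryCatch(unpack(p0 - 2 * alpha * rvec + alpha^2 * vvec),
                         error = function(e) NULL)
        if (!is.null(cand)) {
          sol_c <- tryCatch(mme_solve(design, cand, ctx),
                            error = function(e) NULL)
          if (!is.null(sol_c) && sol_c$logL >= sol$logL) {
            comps <- cand; sol <- sol_c
            trace <- c(trace, sol$logL)
          }
        }
      }
    }
    rel <- abs(sol$logL - logL_prev) / (abs(logL_prev) + 1)
    if (verbose) cat(sprintf("iter %4d logL %.8f\n", iter, sol$logL))
    if (rel < tol * (1 + accelerate)) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("EM-REML reached max_iter = %d without meeting tol = %g",
                    max_iter, tol), call. = FALSE)
  }
  eff <- mme_effects(design, comps, sol, ctx)
  nvp <- (1L + inc_g + inc_i) * t * (t + 1) / 2
  structure(c(eff, list(
    components = comps, logL = sol$logL, deviance = -2 * sol$logL,
    n_varparams = nvp, converged = converged, n_iter = iter,
    logl_trace = trace, include = c(g = inc_g, int = inc_i),
    aic = aic_value(-2 * sol$logL, nvp),
    n_obs = ctx$n, traits = traits
  )), class = "freq_fit")
}

#' @method print freq_fit
#' @export
print.freq_fit <- function(x, ...) {
  cat(sprintf("EM-REML fit: %d traits, %d iterations, converged: %s\n",
              length(x$traits), x$n_iter, x$converged))
  cat(sprintf("  logL = %.4f, deviance = %.4f, AIC = %.4f (p = %d)\n",
              x$logL, x$deviance, x$aic, x$n_varparams))
  cat("  sigma_g diag:", if (!is.null(x$components$sigma_g))
    signif(diag(x$components$sigma_g), 6) else "excluded", "\n")
  invisible(x)
}

#' Akaike information criterion from a deviance
#'
#' `AIC = deviance + 2 p`, where `p` counts estimated variance-covariance
#' parameters only (fixed effects excluded): 3 for a full single-trait model,
#' 2 for its reduced versions, `3 t (t + 1) / 2` for a full `t`-trait model.
#'
#' @param deviance `-2 logL` of the fit.
#' @param n_varparams number of (co)variance parameters.
#' @return the AIC value.
#' @export
aic_value <- function(deviance, n_varparams) {
  stopifnot(n_varparams >= 0)
  deviance + 2 * n_varparams
}

#' Likelihood-ratio test between nested fits
#'
#' `lambda` is the deviance difference between the reduced and the full
#' model, referred to a chi-square distribution. The default `df = 1` matches
#' dropping one variance component from a single-trait model; for multi-trait
#' comparisons pass the parameter-count difference. A slightly negative
#' lambda (numerical noise) is clamped to zero; at the boundary `lambda = 0`
#' the p-value is 1 under this convention.
#'
#' @param deviance_reduced,deviance_full deviances of the two fits.
#' @param df chi-square degrees of freedom (default 1).
#' @param tol tolerance for negative lambda before warning.
#' @return list with `lambda`, `p_value`, `df`.
#' @export
lrt <- function(deviance_reduced, deviance_full, df = 1, tol = 1e-6) {
  lambda <- deviance_reduced - deviance_full
  if (lambda < -tol) {
    warning(sprintf("reduced-model deviance below full-model deviance by %.3g; lambda clamped to 0",
                    -lambda), call. = FALSE)
  }
  lambda <- max(lambda, 0)
  list(lambda = lambda,
       p_value = if (lambda == 0) 1 else pchisq(lambda, df, lower.tail = FALSE),
       df = df)
}
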