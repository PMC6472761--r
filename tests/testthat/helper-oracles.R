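# Shared fixtures and independent oracles used across the suite.

# Small well-conditioned three-trait trial parameters (moderate correlations,
# trait scales like the soybean study but away from the PSD boundary).
toy_params3 <- function(n_progeny = 40, n_locations = 2, n_blocks = 2,
                        rho_g = 0.3, rho_i = 0.2, rho_e = 0.2,
                        missing_rate = 0) {
  cor_m <- function(rho, k = 3) { m <- matrix(rho, k, k); diag(m) <- 1; m }
  sd_g <- sqrt(c(130, 1.8, 10.5))
  sd_i <- sqrt(c(31, 0.62, 8.3))
  sd_e <- sqrt(c(56, 1.5, 36))
  trial_params(n_progeny, n_locations, n_blocks, c("A", "B", "C"),
               grand_means = c(140, 18, 21),
               sigma_g = cor_m(rho_g) * outer(sd_g, sd_g),
               sigma_int = cor_m(rho_i) * outer(sd_i, sd_i),
               sigma_e = cor_m(rho_e) * outer(sd_e, sd_e),
               missing_rate = missing_rate)
}

toy_params1 <- function(n_progeny = 20, n_locations = 2, n_blocks = 2,
                        sigma_g = 4, sigma_int = 1.5, sigma_e = 2,
                        missing_rate = 0) {
  trial_params(n_progeny, n_locations, n_blocks, "T1", grand_means = 10,
               sigma_g = sigma_g, sigma_int = sigma_int, sigma_e = sigma_e,
               missing_rate = missing_rate)
}

# Brute-force GLS oracle: BLUE/BLUP by explicit inversion of
# V = Z Sg Z' + W Si W' + R for a single-trait design.
gls_oracle <- function(design, sg2, si2, se2) {
  X <- as.matrix(design$X); Z <- as.matrix(design$Z); W <- as.matrix(design$W)
  y <- design$y
  V <- sg2 * tcrossprod(Z) + si2 * tcrossprod(W) + se2 * diag(length(y))
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  b <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% b
  list(blue = as.numeric(b),
       blup_g = as.numeric(sg2 * t(Z) %*% Vi %*% r),
       blup_i = as.numeric(si2 * t(W) %*% Vi %*% r))
}

# Direct restricted log-likelihood via V and the projection matrix P.
gls_reml_loglik <- function(design, sg2, si2, se2) {
  X <- as.matrix(design$X); Z <- as.matrix(design$Z); W <- as.matrix(design$W)
  y <- design$y; n <- length(y); p <- ncol(X)
  V <- sg2 * tcrossprod(Z) + si2 * tcrossprod(W) + se2 * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       determinant(XtViX, logarithm = TRUE)$modulus +
                       t(y) %*% P %*% y))
}

# Closed-form balanced MANOVA / ANOVA moment estimates of the three strata
# (equal to REML for balanced complete data with an interior optimum).
manova_oracle <- function(table, traits) {
  df <- as.data.frame(table)
  df$progeny <- factor(df$progeny); df$location <- factor(df$location)
  df$block <- factor(df$block)
  q <- nlevels(df$progeny); n <- nlevels(df$location)
  r <- nlevels(df$block)
  Y <- as.matrix(df[, traits, drop = FALSE])
  if (length(traits) > 1L) {
    fit <- stats::manova(Y ~ location / block + progeny + location:progeny,
                         data = df)
    ss <- summary(fit)$SS
    M_E <- ss$Residuals / fit$df.residual
    M_GxE <- ss[["location:progeny"]] / ((q - 1) * (n - 1))
    M_G <- ss[["progeny"]] / (q - 1)
  } else {
    fit <- stats::lm(Y ~ location / block + progeny + location:progeny,
                     data = df)
    a <- stats::anova(fit)
    M_E <- matrix(a["Residuals", "Mean Sq"])
    M_GxE <- matrix(a["location:progeny", "Mean Sq"])
    M_G <- matrix(a["progeny", "Mean Sq"])
  }
  list(sigma_e = M_E, sigma_int = (M_GxE - M_E) / r,
       sigma_g = (M_G - M_GxE) / (n * r),
       interior = min(eigen((M_GxE - M_E) / r)$values) > 0 &&
         min(eigen((M_G - M_GxE) / (n * r))$values) > 0)
}

expect_monotone_trace <- function(fit, tol = 1e-6) {
  expect_true(all(diff(fit$logl_trace) > -tol),
              label = "restricted log-likelihood trace is non-decreasing")
}

write_toy_file <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
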