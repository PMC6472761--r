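#' Build response vector and incidence matrices for a mixed-model fit
#'
#' Translates a phenotype table into the design of the model
#' `y = Xb + Zg + Wi + e`: `X` encodes the overall mean, locations and
#' blocks-within-locations under reference-level (treatment) coding; `Z` has
#' one column per progeny; `W` one column per progeny-by-location cell.
#' Multi-trait designs stack traits trait-major (all rows of the first trait,
#' then the second, ...), with block-diagonal `X`, `Z`, `W` so that
#' Kronecker-structured covariances index consistently. Rows for missing
#' trait cells are dropped (observed-data likelihood).
#'
#' @param table a validated [phenotype_table()].
#' @param traits traits to model, default all traits in the table.
#' @param multitrait logical; stack the traits into one design (default when
#'   more than one trait is requested). With `multitrait = FALSE` and several
#'   traits, an error is raised; fit traits one at a time instead.
#' @return an object of class `design_set`: list with `y`, sparse `X`, `Z`,
#'   `W`, `obs_index` (data frame mapping each row of `y` to trait, progeny,
#'   location, block and plot), `traits`, `progeny`, `locations`,
#'   `n_blocks_per_location`, `plot_key` (all plots present in the table) and
#'   bookkeeping of column layouts.
#' @export
build_design <- function(table, traits = trait_names(table),
                         multitrait = length(traits) > 1L) {
  stopifnot(inherits(table, "phenotype_table"))
  miss <- setdiff(traits, trait_names(table))
  if (length(miss)) stop("trait(s) not in table: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!multitrait && length(traits) > 1L) {
    stop("multitrait = FALSE requires a single trait", call. = FALSE)
  }
  df <- as.data.frame(table)
  df$location <- factor(df$location)
  df$block <- factor(df$block)
  df$progeny <- factor(df$progeny)
  progeny <- levels(df$progeny)
  locations <- levels(df$location)
  q <- length(progeny); nloc <- length(locations)
  cellf <- interaction(df$location, df$progeny, sep = ":", lex.order = TRUE)
  # fixed effects: mean + location + block within location (treatment coding)
  multi_block <- nlevels(df$block) > 1L
  X0 <- if (nloc > 1L && multi_block) {
    model.matrix(~ location + location:block, data = df)
  } else if (nloc > 1L) {
    model.matrix(~ location, data = df)
  } else if (multi_block) {
    model.matrix(~ block, data = df)
  } else {
    matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
  }
  X0 <- X0[, qr(X0)$pivot[seq_len(qr(X0)$rank)], drop = FALSE]
  Z0 <- Matrix::sparseMatrix(i = seq_len(nrow(df)), j = as.integer(df$progeny),
                             x = 1, dims = c(nrow(df), q),
                             dimnames = list(NULL, progeny))
  W0 <- Matrix::sparseMatrix(i = seq_len(nrow(df)), j = as.integer(cellf),
                             x = 1, dims = c(nrow(df), q * nloc),
                             dimnames = list(NULL, levels(cellf)))
  plot_id <- paste(df$location, df$block, df$progeny, sep = ":")
  keep <- lapply(traits, function(tr) which(!is.na(df[[tr]])))
  y <- unlist(lapply(seq_along(traits), function(k) df[[traits[k]]][keep[[k]]]),
              use.names = FALSE)
  Xs <- lapply(keep, function(r) Matrix::Matrix(X0[r, , drop = FALSE], sparse = TRUE))
  X <- Matrix::bdiag(Xs)
  Z <- Matrix::bdiag(lapply(keep, function(r) Z0[r, , drop = FALSE]))
  W <- Matrix::bdiag(lapply(keep, function(r) W0[r, , drop = FALSE]))
  obs_index <- do.call(rbind, lapply(seq_along(traits), function(k) {
    r <- keep[[k]]
    data.frame(trait = traits[k], progeny = as.character(df$progeny[r]),
               location = as.character(df$location[r]),
               block = as.character(df$block[r]), plot = plot_id[r],
               stringsAsFactors = FALSE)
  }))
  rownames(obs_index) <- NULL
  unseen <- progeny[Matrix::colSums(Z) == 0]
  if (length(unseen)) {
    warning("progeny with no observed cells kept in the design (BLUP by shrinkage): ",
            paste(unseen, collapse = ", "), call. = FALSE)
  }
  nb <- vapply(locations, function(l) length(unique(df$block[df$location == l])),
               integer(1))
  structure(list(
    y = y, X = X, Z = Z, W = W, obs_index = obs_index,
    traits = traits, progeny = progeny, locations = locations,
    n_blocks_per_location = nb, n_fixed_per_trait = ncol(X0),
    plot_key = sort(unique(plot_id)),
    rows_per_trait = lengths(keep)
  ), class = "design_set")
}

#' Add the plot-wise sum of two traits as a new trait
#'
#' Used by the sum-of-traits trick for estimating a genetic covariance from
#' three single-trait analyses: the new trait is the plot-wise sum of the two
#' components and is missing wherever either component is missing.
#'
#' @param table a [phenotype_table()].
#' @param trait_i,trait_j distinct trait names present in the table.
#' @return the table with an added trait named `sum(trait_i,trait_j)`.
#' @export
make_sum_trait <- function(table, trait_i, trait_j) {
  stopifnot(inherits(table, "phenotype_table"))
  if (identical(trait_i, trait_j)) {
    stop("trait_i and trait_j must be distinct traits", call. = FALSE)
  }
  miss <- setdiff(c(trait_i, trait_j), trait_names(table))
  if (length(miss)) stop("trait(s) not in table: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  nm <- sprintf("sum(%s,%s)", trait_i, trait_j)
  df <- as.data.frame(table)
  df[[nm]] <- df[[trait_i]] + df[[trait_j]]
  phenotype_table(df, traits = c(trait_names(table), nm))
}
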