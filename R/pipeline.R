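#' Pipeline configuration
#'
#' Collects every knob of an end-to-end evaluation run. Either `input` (a
#' delimited phenotype file read with `schema`) or `preset = "soybean"`
#' (simulation at the soybean study conditions, see
#' [soybean_trial_params()]) must be given.
#'
#' @param input optional path to a phenotype file.
#' @param schema column schema for `input` (default [default_schema()]).
#' @param preset simulation preset name, currently `"soybean"`.
#' @param sim_params optional [trial_params()] object overriding the preset
#'   (e.g. a reduced-size trial for quick runs).
#' @param traits traits to analyze (default all in the data).
#' @param methods any of `"reml"`, `"mcmc"`.
#' @param mcmc an [mcmc_opts()] schedule for the Bayesian fits.
#' @param selection list with `m` (selected progeny), `b` (intensity for the
#'   coincidence index), `n_boot`.
#' @param seed master seed; all stage seeds are derived from it.
#' @param out_dir output directory for the report tables (created).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, schema = default_schema(),
                            preset = "soybean", sim_params = NULL,
                            traits = NULL, methods = c("reml", "mcmc"),
                            mcmc = mcmc_opts(n_iter = 4000L, burn_in = 2000L,
                                             thin = 5L),
                            selection = list(m = 30L, b = 0.15, n_boot = 1000L),
                            seed = 1L, out_dir = tempfile("mtmeval_run_")) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!is.null(input) && !file.exists(input)) {
    stop("input file does not exist: ", input, call. = FALSE)
  }
  structure(list(input = input, schema = schema, preset = preset,
                 sim_params = sim_params, traits = traits, methods = methods,
                 mcmc = mcmc, selection = selection, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  write.table(format(df, digits = 10, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
}

#' Run the full evaluation pipeline
#'
#' Reads or simulates a trial, validates it, fits the four model variants
#' (frequentist and Bayesian, single- and multi-trait: FSTME, FMTME, BSTME,
#' BMTME) with their reduced versions for model comparison, derives genetic
#' parameters and correlations, performs per-trait selection with gains and
#' between-method agreement, computes the additive genetic index, and writes
#' every table plus a manifest (seed, config hash, package version) under
#' `config$out_dir`. Outputs are deterministic given the configuration.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all fitted objects and tables; the same
#'   content is written as delimited text files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(nm, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", nm, conditionMessage(e)),
           call. = FALSE)
    })
  }
  # --- data -----------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$input)) {
    table <- stage("read", read_phenotypes(config$input, config$schema))
  } else {
    params <- config$sim_params %||% soybean_trial_params()
    sim <- stage("simulate", simulate_trial(params, seed = config$seed))
    table <- sim$table
    truth <- sim$truth
  }
  traits <- config$traits %||% trait_names(table)
  report <- stage("validate", validate_table(table))
  m_sel <- config$selection$m %||% 30L
  if (m_sel > report$n_progeny) {
    stop(sprintf("selection size m = %d exceeds the %d available progeny",
                 m_sel, report$n_progeny), call. = FALSE)
  }
  n_loc <- report$n_locations
  n_rep <- max(report$n_blocks_per_location)
  grand_means <- vapply(traits, function(tr) mean(table[[tr]], na.rm = TRUE),
                        numeric(1))
  # --- fits -----------------------------------------------------------------
  fits <- list()
  comparison <- list()
  if ("reml" %in% config$methods) {
    stage("fit FSTME", for (tr in traits) {
      d <- build_design(table, traits = tr)
      full <- fit_reml(d)
      red_g <- fit_reml(d, include = c(g = FALSE, int = TRUE))
      red_i <- fit_reml(d, include = c(g = TRUE, int = FALSE))
      fits[[paste0("FSTME.", tr)]] <- full
      comparison[[paste0("FSTME.", tr)]] <- data.frame(
        model = "FSTME", trait = tr,
        deviance_full = full$deviance, aic_full = full$aic,
        deviance_no_prog = red_g$deviance, aic_no_prog = red_g$aic,
        deviance_no_int = red_i$deviance, aic_no_int = red_i$aic,
        lrt_prog = lrt(red_g$deviance, full$deviance)$lambda,
        lrt_int = lrt(red_i$deviance, full$deviance)$lambda)
    })
    if (length(traits) > 1L) {
      stage("fit FMTME", {
        d <- build_design(table, traits = traits)
        fits[["FMTME"]] <- fit_reml(d)
      })
    }
  }
  if ("mcmc" %in% config$methods) {
    dics <- function(design, seed_off) {
      out <- list()
      for (variant in c("full", "no_prog", "no_int")) {
        inc <- switch(variant,
                      full = c(g = TRUE, int = TRUE),
                      no_prog = c(g = FALSE, int = TRUE),
                      no_int = c(g = TRUE, int = FALSE))
        o <- config$mcmc
        s <- run_mcmc(design, opts = mcmc_opts(o$n_iter, o$burn_in, o$thin,
                                               seed = config$seed + seed_off),
                      include = inc)
        out[[variant]] <- s
      }
      out
    }
    stage("fit BSTME", for (k in seq_along(traits)) {
      tr <- traits[k]
      d <- build_design(table, traits = tr)
      ss <- dics(d, seed_off = 100L + k)
      fits[[paste0("BSTME.", tr)]] <- ss$full
      comparison[[paste0("BSTME.", tr)]] <- data.frame(
        model = "BSTME", trait = tr,
        dic_full = dic_value(ss$full, d)$dic,
        dic_no_prog = dic_value(ss$no_prog, d)$dic,
        dic_no_int = dic_value(ss$no_int, d)$dic)
    })
    if (length(traits) > 1L) {
      stage("fit BMTME", {
        d <- build_design(table, traits = traits)
        o <- config$mcmc
        fits[["BMTME"]] <- run_mcmc(d, opts = mcmc_opts(o$n_iter, o$burn_in,
                                                         o$thin,
                                                         seed = config$seed + 200L))
      })
    }
  }
  # --- derived parameters ---------------------------------------------------
  params_tabs <- list()
  blups <- list()   # model -> progeny x trait matrix of u+g
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (inherits(f, "freq_fit")) {
      gp <- derive_genetic_parameters(f$components,
                                      grand_means[f$traits], n_loc, n_rep)
      gp$ac_prog <- vapply(seq_along(f$traits), function(k) {
        mean(accuracy_pev(diag(f$components$sigma_g)[k], f$pev_g[, k]))
      }, numeric(1))
      gp$model <- nm
      params_tabs[[nm]] <- gp
      blups[[nm]] <- f$blup_ug
    } else if (inherits(f, "posterior_samples")) {
      t <- length(f$traits)
      post_mean <- draw_components(f, 1)
      for (el in names(post_mean)) post_mean[[el]] <- post_mean[[el]] * 0
      for (r in seq_len(nrow(f$component_chains))) {
        d <- draw_components(f, r)
        for (el in names(post_mean)) post_mean[[el]] <- post_mean[[el]] + d[[el]]
      }
      for (el in names(post_mean)) {
        post_mean[[el]] <- post_mean[[el]] / nrow(f$component_chains)
      }
      cs <- covariance_set(post_mean$sigma_g, post_mean$sigma_int,
                           post_mean$sigma_e, traits = f$traits)
      gp <- derive_genetic_parameters(cs, grand_means[f$traits], n_loc, n_rep)
      bv <- posterior_breeding_values(f)
      gp$ac_prog <- vapply(seq_len(t), function(k) {
        accuracy_posterior(bv$mean[, k], bv$sd[, k])$mean_accuracy
      }, numeric(1))
      gp$model <- nm
      params_tabs[[nm]] <- gp
      blups[[nm]] <- sweep(bv$mean, 2, grand_means[f$traits], `+`)
    }
  }
  params_tab <- do.call(rbind, params_tabs)
  # --- selection and agreement ----------------------------------------------
  sel_rows <- list()
  for (nm in names(blups)) {
    bv <- blups[[nm]]
    for (tr in colnames(bv)) {
      sel <- rank_and_select(setNames(bv[, tr], rownames(bv)), m_sel)
      gain <- gain_stats(sel$values[seq_len(m_sel)], grand_means[[tr]])
      sel_rows[[paste(nm, tr)]] <- data.frame(
        model = nm, trait = tr, mean_selected = mean(sel$values[seq_len(m_sel)]),
        overall_mean = grand_means[[tr]], gain_abs = gain$gain_abs,
        gain_pct = gain$gain_pct,
        selected = paste(sel$selected, collapse = ","))
    }
  }
  sel_tab <- do.call(rbind, sel_rows)
  agree_rows <- list()
  pairs <- list(c("FSTME", "FMTME"), c("BSTME", "BMTME"))
  for (pp in pairs) {
    mt <- blups[[pp[2]]]
    if (is.null(mt)) next
    for (tr in colnames(mt)) {
      st <- blups[[paste0(pp[1], ".", tr)]]
      if (is.null(st)) next
      ra <- rank_agreement(setNames(st[, tr], rownames(st)),
                           setNames(mt[rownames(st), tr], rownames(st)),
                           m = m_sel, b_intensity = config$selection$b %||% 0.15,
                           n_boot = config$selection$n_boot %||% 1000L,
                           seed = config$seed + 300L)
      agree_rows[[paste(pp[1], pp[2], tr)]] <- data.frame(
        model_a = pp[1], model_b = pp[2], trait = tr,
        spearman_rho = ra$spearman_rho, ci_lo = ra$boot_ci[1],
        ci_hi = ra$boot_ci[2], coincidence = ra$coincidence,
        overlap = ra$overlap)
    }
  }
  agree_tab <- if (length(agree_rows)) do.call(rbind, agree_rows)
  agi_tab <- NULL
  if (!is.null(blups[["FMTME"]]) || !is.null(blups[["BMTME"]])) {
    agi_rows <- list()
    for (nm in intersect(c("FMTME", "BMTME"), names(blups))) {
      gp <- params_tabs[[nm]]
      w <- setNames(gp$cv_g, gp$trait)
      agi <- agi_scores(blups[[nm]], weights = w[colnames(blups[[nm]])])
      agi_rows[[nm]] <- data.frame(model = nm,
                                   progeny = names(agi$agi),
                                   agi = unname(agi$agi))
    }
    agi_tab <- do.call(rbind, agi_rows)
  }
  # --- outputs --------------------------------------------------------------
  out <- list(table = table, truth = truth, validation = report, fits = fits,
              comparison = comparison, parameters = params_tab,
              selection = sel_tab, agreement = agree_tab, agi = agi_tab,
              grand_means = grand_means, config = config)
  stage("write", {
    write_phenotypes(table, file.path(config$out_dir, "phenotypes.tsv"))
    write_tsv(params_tab, file.path(config$out_dir, "parameters.tsv"))
    write_tsv(sel_tab, file.path(config$out_dir, "selection.tsv"))
    if (!is.null(agree_tab)) {
      write_tsv(agree_tab, file.path(config$out_dir, "agreement.tsv"))
    }
    if (!is.null(agi_tab)) write_tsv(agi_tab, file.path(config$out_dir, "agi.tsv"))
    comp <- comparison
    if (length(comp)) {
      freq <- do.call(rbind, Filter(function(x) "aic_full" %in% names(x), comp))
      bay <- do.call(rbind, Filter(function(x) "dic_full" %in% names(x), comp))
      if (!is.null(freq)) write_tsv(freq, file.path(config$out_dir,
                                                    "model_comparison_reml.tsv"))
      if (!is.null(bay)) write_tsv(bay, file.path(config$out_dir,
                                                  "model_comparison_mcmc.tsv"))
    }
    cfg_file <- file.path(config$out_dir, "config.yaml")
    cfg_plain <- list(
      input = config$input %||% "", preset = config$preset,
      traits = traits, methods = config$methods,
      mcmc = unclass(config$mcmc)[c("n_iter", "burn_in", "thin", "seed")],
      selection = config$selection, seed = config$seed)
    yaml::write_yaml(cfg_plain, cfg_file)
    manifest <- c(
      sprintf("package: mtmeval %s",
              as.character(utils::packageVersion("mtmeval"))),
      sprintf("seed: %d", config$seed),
      sprintf("config_hash: %s", unname(tools::md5sum(cfg_file))),
      sprintf("n_progeny: %d", report$n_progeny),
      sprintf("traits: %s", paste(traits, collapse = ",")),
      sprintf("methods: %s", paste(config$methods, collapse = ",")))
    writeLines(manifest, file.path(config$out_dir, "manifest.txt"))
  })
  invisible(out)
}
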