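#' Model registry
#'
#' Builds a model from a name and an optional parameter list, as used by
#' configuration files: `"binomial"` (`k`), `"cir"` (`a`, `sigma`,
#' `method`), `"inar1"`, `"lotka_volterra"`.
#'
#' @param name model name.
#' @param params named list of constructor arguments.
#' @return A [`pwabc_model`][models].
#' @export
model_from_name <- function(name, params = list()) {
  ctor <- switch(name,
    binomial = binomial_model,
    cir = cir_model,
    inar1 = inar1_model,
    lotka_volterra = lv_model,
    abort(sprintf("unknown model '%s' (known: binomial, cir, inar1, lotka_volterra)", name)))
  do.call(ctor, params)
}

prior_from_config <- function(cfg, model) {
  if (is.null(cfg) || identical(cfg, "default")) return(model$default_prior())
  kind <- cfg$kind %||% cfg$type
  if (kind %in% c("normal", "gaussian")) {
    prior_normal(unlist(cfg$mean), unlist(cfg$cov %||% cfg$sd^2))
  } else if (kind == "uniform") {
    prior_uniform(unlist(cfg$lower), unlist(cfg$upper))
  } else {
    abort(sprintf("unknown prior kind '%s'", kind))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Persist and reload factor samples
#'
#' Accepted draws are written as a single CSV
#' (`factor,draw,theta_...,distance`) with a JSON sidecar holding the
#' attempt counts, tolerances and seeds, so a run can later be reloaded and
#' [top_up()]ed under a smaller tolerance or larger `m`.
#'
#' @param fit a `pwabc_fit`.
#' @param dir output directory (created if needed).
#' @param model,prior,config objects to attach to the reloaded fit; must
#'   match those of the stored run.
#' @return `write_fit_samples()` the directory, invisibly;
#'   `read_fit_samples()` a `pwabc_fit`.
#' @export
write_fit_samples <- function(fit, dir) {
  stopifnot(inherits(fit, "pwabc_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- purrr::map_dfr(fit$factors, as_tibble.factor_sample)
  readr::write_csv(samples, file.path(dir, "samples.csv"))
  meta <- list(
    master_seed = fit$seed,
    epsilon = fit$config$epsilon, p = fit$config$p, m = fit$config$m,
    model = fit$model$name, param_names = fit$model$param_names,
    factors = purrr::map(fit$factors, function(f) {
      list(index = f$index, attempts = f$attempts, epsilon = f$epsilon,
           p = f$p, seed = f$seed, x_prev = as.numeric(f$x_prev),
           x_next = as.numeric(f$x_next), t_prev = f$t_prev,
           t_next = f$t_next)
    }))
  jsonlite::write_json(meta, file.path(dir, "samples_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(fit$data, file.path(dir, "series.csv"))
  invisible(dir)
}

#' @rdname write_fit_samples
#' @export
read_fit_samples <- function(dir, model, prior, config) {
  samples <- readr::read_csv(file.path(dir, "samples.csv"),
                             show_col_types = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "samples_meta.json"),
                              simplifyVector = TRUE)
  data <- readr::read_csv(file.path(dir, "series.csv"),
                          show_col_types = FALSE)
  th_cols <- setdiff(names(samples), c("factor", "draw", "distance"))
  factors <- purrr::map(seq_len(nrow(meta$factors)), function(k) {
    mf <- meta$factors[k, ]
    sub <- samples[samples$factor == mf$index, , drop = FALSE]
    cfg_k <- abc_config(epsilon = mf$epsilon, m = nrow(sub), p = mf$p,
                        max_attempts = config$max_attempts,
                        batch_size = config$batch_size)
    new_factor_sample(mf$index, as.matrix(sub[, th_cols]), sub$distance,
                      mf$attempts, cfg_k, mf$seed,
                      unlist(mf$x_prev), unlist(mf$x_next),
                      mf$t_prev, mf$t_next, th_cols)
  })
  structure(list(factors = factors, model = model, prior = prior,
                 config = config, seed = meta$master_seed,
                 data = data),
            class = "pwabc_fit")
}

#' Configuration-driven end-to-end run
#'
#' Runs the whole pipeline -- data loading or generation, per-factor
#' rejection sampling, posterior recombination, marginal likelihood -- from
#' a YAML or JSON configuration file (or an equivalent named list), writing
#' all artefacts to an output directory: the observation series, accepted
#' samples with their sidecar, posterior summaries as JSON, the posterior
#' lattice as CSV, and a plain-text log with one line per completed factor.
#' Re-running the same configuration reproduces the artefacts exactly.
#'
#' Configuration fields: `model` (`name`, optional `params`), `data`
#' (either `path` to a series CSV or `generate`: optional `theta`, `x0`,
#' `times`, `seed`), `prior` (`"default"` or `kind`/`mean`/`cov` or
#' `lower`/`upper`), `abc` (`epsilon`, `m`, optional `p`, `max_attempts`,
#' `seed`), `approx` (`"gaussian"`, `"kde"` or `"both"`), optional `q`,
#' `grid` (`resolution`, `k_sd`), `out` (directory).
#'
#' @param config path to a YAML/JSON file, or a named list.
#' @param out output directory; overrides the config's `out`.
#' @param top_up_from directory of a previous run whose samples are reused
#'   (retained under the new tolerance, topped up to the new `m`).
#' @param quiet suppress per-factor progress lines on the console (they are
#'   always written to the log file).
#' @return The `pwabc_fit`, invisibly, with posterior summaries attached as
#'   attribute `"summaries"`.
#' @export
run_pwabc <- function(config, out = NULL, top_up_from = NULL, quiet = FALSE) {
  cfg <- if (is.character(config)) {
    if (grepl("[.]json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  } else {
    config
  }
  model <- model_from_name(cfg$model$name, cfg$model$params %||% list())
  prior <- prior_from_config(cfg$prior, model)
  abc <- cfg$abc
  config_obj <- abc_config(epsilon = abc$epsilon %||% 0, m = abc$m,
                           p = abc$p %||% 2,
                           max_attempts = abc$max_attempts %||% 1e7,
                           batch_size = abc$batch_size %||% 1e4,
                           seed = abc$seed %||% 1L)
  out <- out %||% cfg$out %||% "pwabc-run"
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out, "log.txt")
  logline <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = logfile, append = TRUE, sep = "")
    if (!quiet) message(msg)
  }
  cat(sprintf("pwabc run, master seed %d\n", config_obj$seed), file = logfile)

  # -- data ------------------------------------------------------------
  if (!is.null(cfg$data$path)) {
    data <- read_series(cfg$data$path)
    logline("data: %d observations from %s", nrow(data), cfg$data$path)
  } else {
    gen <- cfg$data$generate %||% list()
    times <- gen$times
    if (is.list(times)) times <- seq(times$from, times$to, by = times$by)
    data <- generate_series(model,
                            theta = unlist(gen$theta) %||% model$default_theta,
                            x0 = unlist(gen$x0) %||% model$default_x0,
                            times = as.numeric(times %||% model$default_times),
                            seed = gen$seed %||% config_obj$seed)
    logline("data: generated %d observations (seed %d)", nrow(data),
            gen$seed %||% config_obj$seed)
  }

  # -- sampling ---------------------------------------------------------
  if (!is.null(top_up_from)) {
    old <- read_fit_samples(top_up_from, model, prior, config_obj)
    factors <- purrr::map(old$factors, function(f) {
      g <- top_up(f, model, prior, config_obj,
                  new_epsilon = config_obj$epsilon, new_m = config_obj$m,
                  seed = factor_seed(config_obj$seed, f$index))
      logline("factor %d: topped up to m = %d, M = %d (%.3g%%)",
              g$index, g$m, g$attempts, 100 * g$m / g$attempts)
      g
    })
    fit <- structure(list(factors = factors, model = model, prior = prior,
                          config = config_obj, seed = config_obj$seed,
                          data = old$data),
                     class = "pwabc_fit")
  } else {
    X <- series_states(data)
    n <- nrow(X)
    factors <- vector("list", n - 1)
    for (i in 2:n) {
      fs <- sample_factor(model, prior, X[i - 1, ], X[i, ],
                          data$t[i - 1], data$t[i], config_obj,
                          seed = factor_seed(config_obj$seed, i), index = i)
      factors[[i - 1]] <- fs
      logline("factor %d/%d: M = %d, acceptance %.3g%%", i, n,
              fs$attempts, 100 * fs$m / fs$attempts)
    }
    fit <- structure(list(factors = factors, model = model, prior = prior,
                          config = config_obj, seed = config_obj$seed,
                          data = tibble::as_tibble(data)),
                     class = "pwabc_fit")
  }
  write_fit_samples(fit, out)

  # -- posteriors -------------------------------------------------------
  approx <- cfg$approx %||% "both"
  V <- ball_normaliser(config_obj$epsilon, config_obj$p, model$state_dim,
                       model$discrete)
  summaries <- list(config = cfg, master_seed = config_obj$seed,
                    acceptance = as.list(glance(fit)),
                    log_c_hat = purrr::map_dbl(
                      fit$factors, ~ estimate_log_c(.x$m, .x$attempts, V)))
  if (approx %in% c("gaussian", "both")) {
    pg <- tryCatch(posterior_gaussian(fit), error = function(e) e)
    if (inherits(pg, "error")) {
      logline("gaussian route failed: %s", conditionMessage(pg))
    } else {
      summaries$gaussian <- list(mean = as.numeric(pg$mean),
                                 cov = as.matrix(pg$cov),
                                 log_w = pg$product$log_w,
                                 log_marginal = pg$log_marginal)
      logline("gaussian posterior mean: %s",
              paste(signif(pg$mean, 5), collapse = ", "))
    }
  }
  if (approx %in% c("kde", "both") && model$d <= 3) {
    grid_cfg <- cfg$grid %||% list()
    pk <- posterior_kde(fit, q = cfg$q,
                        k_sd = grid_cfg$k_sd %||% 6,
                        resolution = grid_cfg$resolution)
    summaries$kde <- list(mean = as.numeric(pk$mean),
                          cov = as.matrix(pk$cov),
                          q = pk$factors[[1]]$q,
                          log_marginal = pk$log_marginal,
                          quantiles = grid_quantiles(pk$density))
    readr::write_csv(as_tibble.grid_density(pk$density),
                     file.path(out, "posterior_grid.csv"))
    logline("kernel posterior mean: %s",
            paste(signif(pk$mean, 5), collapse = ", "))
  }
  jsonlite::write_json(summaries, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logline("artefacts written to %s", out)
  attr(fit, "summaries") <- summaries
  invisible(fit)
}
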