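#' Read a plot table
#'
#' CSV with mandatory columns `plot_id`, `easting`, `northing` (metres,
#' planar national-grid convention) and the response, plus covariate
#' columns; a missing `square_id` is derived by the floor-division grid
#' convention. Comma-separated, UTF-8, "." decimal, header row mandatory,
#' empty fields = missing.
#'
#' @param path CSV path
#' @param response name of the response column that must be present
#' @param grid_size square size in metres
#' @return data frame with a derived `square_id`; attributes `n_plots`,
#'   `n_squares`
#' @export
read_plot_table <- function(path, response = "richness", grid_size = 1000) {
  dat <- read.csv(path, check.names = FALSE)
  need <- c("plot_id", "easting", "northing", response)
  miss <- setdiff(need, names(dat))
  if (length(miss)) stop_("plot table is missing column(s): %s", paste(miss, collapse = ", "))
  for (cl in c("easting", "northing")) {
    v <- dat[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop_("non-numeric %s at row(s) %s", cl,
            paste(utils::head(bad, 5), collapse = ", "))
    }
    if (anyNA(v)) stop_("missing %s at row(s) %s", cl,
                        paste(utils::head(which(is.na(v)), 5), collapse = ", "))
  }
  if (is.null(dat$square_id)) {
    dat$square_id <- square_id(dat$easting, dat$northing, grid_size)
  }
  attr(dat, "n_plots") <- nrow(dat)
  attr(dat, "n_squares") <- length(unique(dat$square_id))
  dat
}

#' Write a plot table
#'
#' @param data plot table data frame
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_plot_table <- function(data, path) {
  write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run configuration
#'
#' A fully serializable description of one pipeline run: input path (or
#' preset), model spec fields, mesh options, inference options and seed.
#' Round-trips through YAML; the config hash stamped on every output ties
#' artifacts to the settings that made them.
#'
#' @param data_path plot-table CSV, or NULL when `preset` is given
#' @param preset optional preset name (`"sea04"`/`"mea10"`) simulated on the
#'   fly
#' @param covariates covariate names for the model
#' @param structure spatial error structure
#' @param response response column
#' @param method inference method
#' @param mesh_options,fit_options option lists (see [build_mesh()],
#'   [fit_model()])
#' @param seed integer seed
#' @param out_dir output directory
#' @return object of class `run_config`
#' @export
run_config <- function(data_path = NULL, preset = NULL, covariates,
                       structure = "mesh_plus_square", response = "richness",
                       method = "laplace_eb", mesh_options = list(),
                       fit_options = list(), seed = 20100429,
                       out_dir = "run") {
  if (is.null(data_path) && is.null(preset)) {
    stop_("config needs a data_path or a preset")
  }
  structure(list(data_path = data_path, preset = preset,
                 covariates = covariates, structure = structure,
                 response = response, method = method,
                 mesh_options = mesh_options, fit_options = fit_options,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML path
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config` (for writing)
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  ## small rolling hash; stable across sessions, no extra dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' prepare -> mesh -> fit -> diagnostics, writing to the configured output
#' directory: `coefficients.csv` (linear and exponentiated scales),
#' `hyperparameters.csv`, `latent_field.csv` (posterior mean/sd by node
#' coordinates), `dic.csv`, `variance_partition.csv`,
#' `partial_effects.csv`, and `metadata.json` (settings, seed, config
#' hash). Every CSV carries the config hash as a comment-free extra column.
#'
#' @param config a [run_config()]
#' @return the fit, invisibly; side effect: files under `config$out_dir`
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  hash <- config_hash(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dat <- stage("prepare", {
    if (!is.null(config$preset)) {
      sim <- simulate_preset(config$preset, seed = config$seed)
      rescale_sim(sim)
    } else {
      read_plot_table(config$data_path, response = config$response)
    }
  })
  use_mesh <- config$structure %in% c("mesh_plus_square", "mesh_only")
  mesh <- NULL
  if (use_mesh) {
    mesh <- stage("mesh", {
      mo <- modifyList(list(boundary_extension_fraction = 0.15,
                            max_edge = Inf, max_edge_outer = Inf),
                       config$mesh_options)
      build_mesh(cbind(dat$easting, dat$northing),
                 boundary_extension_fraction = mo$boundary_extension_fraction,
                 max_edge = mo$max_edge, max_edge_outer = mo$max_edge_outer)
    })
  }
  fit <- stage("fit", {
    spec <- model_spec(config$covariates, structure = config$structure,
                       response = config$response)
    fit_model(dat, spec, mesh = mesh, method = config$method,
              options = modifyList(list(seed = config$seed),
                                   config$fit_options))
  })
  stage("diagnostics", {
    co <- fit$summary
    for (qc in c("q0.025", "median", "q0.975")) {
      co[[paste0("exp_", qc)]] <- round(exp(co[[qc]]), 2)
    }
    co$config_hash <- hash
    write.csv(co, file.path(config$out_dir, "coefficients.csv"), row.names = FALSE)
    if (!is.null(fit$hyper)) {
      hy <- fit$hyper; hy$config_hash <- hash
      write.csv(hy, file.path(config$out_dir, "hyperparameters.csv"),
                row.names = FALSE)
    }
    if (use_mesh) {
      lf <- fit$latent$w; lf$config_hash <- hash
      write.csv(lf, file.path(config$out_dir, "latent_field.csv"),
                row.names = FALSE)
    }
    dv <- dic(fit, seed = config$seed)
    write.csv(data.frame(dbar = dv$dbar, dhat = dv$dhat, pd = dv$pd,
                         dic = dv$dic, config_hash = hash),
              file.path(config$out_dir, "dic.csv"), row.names = FALSE)
    if (config$structure == "mesh_plus_square") {
      vp <- variance_partition(fit)
      write.csv(data.frame(var_structured = vp$var_structured,
                           var_iid = vp$var_iid,
                           percent_structured = vp$percent_structured,
                           config_hash = hash),
                file.path(config$out_dir, "variance_partition.csv"),
                row.names = FALSE)
    }
    pe <- do.call(rbind, lapply(config$covariates, function(cv) {
      out <- partial_effect(fit, cv, seed = config$seed)
      cbind(covariate = cv, as.data.frame(out))
    }))
    pe$config_hash <- hash
    write.csv(pe, file.path(config$out_dir, "partial_effects.csv"),
              row.names = FALSE)
    meta <- list(config = unclass(config), config_hash = hash,
                 converged = fit$converged,
                 n_plots = nrow(dat),
                 mesh_nodes = if (use_mesh) mesh$n_nodes else NULL,
                 r_version = as.character(getRversion()))
    jsonlite::write_json(meta, file.path(config$out_dir, "metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
  if (!fit$converged) warning("fit flagged as not converged", call. = FALSE)
  invisible(fit)
}

#' Table of exponentiated coefficients and DIC across fitted structures
#'
#' @param fits named list of `spdepois_fit`s (names = structure labels)
#' @param covariate coefficient to report on the multiplicative scale
#' @param ... forwarded to [dic()]
#' @return data frame: structure, exponentiated 2.5/50/97.5% quantiles,
#'   DIC, and DIC difference from the first fit
#' @export
compare_structures <- function(fits, covariate, ...) {
  rows <- lapply(names(fits), function(nm) {
    e <- summarize_exp(fits[[nm]], covariate)
    d <- dic(fits[[nm]], ...)
    data.frame(structure = nm, q0.025 = e[["q0.025"]],
               median = e[["median"]], q0.975 = e[["q0.975"]], dic = d$dic)
  })
  out <- do.call(rbind, rows)
  out$delta_dic <- out$dic - out$dic[1]
  out
}
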