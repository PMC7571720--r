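# Configuration, result serialisation and the command-line interface.

.config_keys <- list(
  top = c("model", "preset", "parameters", "geometry", "protocol", "solver",
          "seed", "output"),
  parameters = c("ru", "xb"),
  ru = c("Q", "mu", "gamma", "kd_bar", "alpha_kd", "SL_kd", "koff",
         "kbasic", "kd_floor_frac"),
  xb = c("mu_fP0", "mu_fP1", "r0", "alpha", "a_XB", "k_XB"),
  geometry = c("SL0", "LA", "LM", "LH", "eps", "n_ru", "n_mh", "DM"),
  protocol = c("name", "Ca", "SL", "Ca_grid", "SL_grid", "v_grid",
               "dL_grid", "dt_step", "transient", "t_end", "dt", "mode",
               "n_ru", "Ca_levels", "stage", "targets", "ranges",
               "n_samples"),
  solver = c("rtol", "atol", "eps_den"),
  output = c("dir", "prefix", "format")
)

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop(sprintf("unknown key%s in %s: %s", if (length(bad) > 1) "s" else "",
                 where, paste(bad, collapse = ", ")), call. = FALSE)
  }
}

#' Load and validate a run configuration
#'
#' Reads a JSON run configuration, rejects unknown keys (naming them),
#' and fills defaults: the rat room-temperature preset, the standard
#' geometry, and the MF-ODE model.
#'
#' @param path path to a JSON file.
#' @return validated configuration list of class \code{"sarco_config"}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  check_keys(cfg, .config_keys$top, "configuration")
  for (sect in c("parameters", "geometry", "protocol", "solver", "output")) {
    if (!is.null(cfg[[sect]])) check_keys(cfg[[sect]], .config_keys[[sect]],
                                          sect)
  }
  if (!is.null(cfg$parameters)) {
    for (sub in c("ru", "xb")) {
      if (!is.null(cfg$parameters[[sub]])) {
        check_keys(cfg$parameters[[sub]], .config_keys[[sub]],
                   paste0("parameters$", sub))
      }
    }
  }
  if (is.null(cfg$model)) cfg$model <- "MF-ODE"
  if (!cfg$model %in% c("MF-ODE", "MF-PDE", "SE-ODE", "SE-PDE")) {
    stop("unknown model: ", cfg$model)
  }
  if (is.null(cfg$preset)) cfg$preset <- "rat_room"
  if (is.null(cfg$seed)) cfg$seed <- 1L
  class(cfg) <- "sarco_config"
  cfg
}

# build a sarcomere_model from a validated configuration
config_model <- function(cfg) {
  geom <- do.call(sarcomere_geometry, as.list(cfg$geometry %||% list()))
  family <- if (startsWith(cfg$model, "MF")) "MF" else "SE"
  p <- sarcomere_preset(cfg$preset, family)
  ru <- p$ru; xb <- p$xb
  if (!is.null(cfg$parameters$ru)) {
    args <- utils::modifyList(ru[!vapply(ru, is.null, TRUE)],
                              as.list(cfg$parameters$ru))
    ru <- do.call(ru_parameters, args[names(args) %in% .config_keys$ru])
  }
  if (!is.null(cfg$parameters$xb)) {
    args <- utils::modifyList(xb[!vapply(xb, is.null, TRUE)],
                              as.list(cfg$parameters$xb))
    xb <- do.call(xb_parameters, args[names(args) %in% .config_keys$xb])
  }
  sv <- cfg$solver %||% list()
  sarcomere_model(cfg$model, ru = ru, xb = xb, geom = geom,
                  rtol = sv$rtol, atol = sv$atol,
                  eps_den = sv$eps_den %||% 1e-12)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write protocol results to disk
#'
#' Time series and curves go to a tidy long-format CSV (columns: the
#' abscissa, \code{variable}, \code{value}); scalar metrics go to JSON.  A
#' manifest with the configuration, its MD5 hash, the seed and the package
#' version is written alongside.
#'
#' @param result list with optional components \code{series} (data.frame;
#'   first column is the abscissa) and \code{metrics} (named list of
#'   scalars).
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @param config the originating configuration (stored in the manifest).
#' @param seed the run seed.
#' @return invisibly, the paths written.
#' @export
write_results <- function(result, dir, prefix = "run", config = NULL,
                          seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(result$series)) {
    df <- result$series
    ab <- names(df)[1]
    long <- do.call(rbind, lapply(names(df)[-1], function(v) {
      data.frame(df[[1]], variable = rep_len(v, nrow(df)),
                 value = df[[v]])
    }))
    if (is.null(long)) {
      long <- data.frame(numeric(0), variable = character(0),
                         value = numeric(0))
    }
    names(long)[1] <- ab
    p <- file.path(dir, paste0(prefix, "_series.csv"))
    utils::write.csv(long, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(result$metrics)) {
    p <- file.path(dir, paste0(prefix, "_metrics.json"))
    jsonlite::write_json(result$metrics, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, p)
  }
  cfg_path <- file.path(dir, paste0(prefix, "_config.json"))
  jsonlite::write_json(config %||% list(), cfg_path, auto_unbox = TRUE,
                       pretty = TRUE)
  manifest <- list(
    config_file = basename(cfg_path),
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = seed,
    package = "sarcodyn",
    version = as.character(utils::packageVersion("sarcodyn")))
  p <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, cfg_path, p))
}

cli_parse <- function(args) {
  opts <- list(); pos <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        opts[[key]] <- TRUE; i <- i + 1L
      } else {
        opts[[key]] <- args[i + 1L]; i <- i + 2L
      }
    } else {
      pos <- c(pos, a); i <- i + 1L
    }
  }
  list(opts = opts, pos = pos)
}

cli_usage <- function() {
  cat("usage: sarcodyn <command> [--config FILE] [--out DIR] [options]\n",
      "commands:\n",
      "  presets   --name rat_room|human_body [--family SE|MF]\n",
      "  steady    --config FILE --out DIR   (isometric steady state)\n",
      "  fca       --config FILE --out DIR   (force-calcium curve)\n",
      "  fsl       --config FILE --out DIR   (force-length curve)\n",
      "  twitch    --config FILE --out DIR   (isometric twitch)\n",
      "  fv        --config FILE --out DIR   (force-velocity curve)\n",
      "  step      --config FILE --out DIR   (fast length steps)\n",
      "  simulate  --config FILE --out DIR   (free trajectory)\n",
      "  oracle    --config FILE --out DIR   (closure-error report)\n",
      sep = "")
}

#' Command-line entry point
#'
#' Thin dispatcher over the package protocols; see \code{inst/cli/sarcodyn}
#' for the executable wrapper.  Deterministic protocols are bit-reproducible
#' given (configuration, seed).
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code (0 on success), invisibly.
#' @export
sarco_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  p <- cli_parse(args)
  if (!length(p$pos)) { cli_usage(); return(invisible(1L)) }
  cmd <- p$pos[1]
  ok_cmds <- c("presets", "steady", "fca", "fsl", "twitch", "fv", "step",
               "simulate", "oracle")
  if (!cmd %in% ok_cmds) {
    message("unknown command: ", cmd); cli_usage(); return(invisible(1L))
  }
  if (cmd == "presets") {
    name <- p$opts$name %||% "rat_room"
    fam <- p$opts$family %||% "MF"
    pr <- sarcomere_preset(name, fam)
    cat(jsonlite::toJSON(list(preset = name, family = fam,
                              ru = unclass(pr$ru), xb = unclass(pr$xb),
                              geometry = unclass(sarcomere_geometry())),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA),
        "\n")
    return(invisible(0L))
  }
  if (is.null(p$opts$config)) { message("--config required"); return(invisible(1L)) }
  cfg <- load_config(p$opts$config)
  out_dir <- p$opts$out %||% "."
  model <- config_model(cfg)
  pr <- as.list(cfg$protocol %||% list())
  res <- switch(cmd,
    steady = {
      st <- run_to_steady_state(model, pr$Ca %||% 1, pr$SL %||% 2.2)
      list(metrics = list(Ta_iso = st$Ta_iso, converged = st$converged,
                          residual = st$residual))
    },
    fca = {
      grid <- pr$Ca_grid %||% exp(seq(log(0.1), log(10), length.out = 12))
      fc <- force_calcium_curve(model, grid, pr$SL %||% 2.2)
      list(series = fc$curve,
           metrics = list(Ta_max = fc$hill$Ta_max, EC50 = fc$hill$EC50,
                          nH = fc$hill$nH))
    },
    fsl = {
      grid <- pr$SL_grid %||% seq(1.4, 2.6, by = 0.1)
      list(series = force_length_curve(model, grid, pr$Ca %||% 10))
    },
    twitch = {
      tr_args <- as.list(pr$transient %||% list())
      tr <- do.call(synthetic_calcium_transient, tr_args)
      tw <- isometric_twitch(model, tr, pr$SL %||% 2.2,
                             t_end = pr$t_end %||% NULL)
      list(series = tw$trace, metrics = unclass(tw$metrics))
    },
    fv = {
      grid <- pr$v_grid %||% seq(0, 8, by = 0.5)
      fv <- force_velocity_curve(model, pr$Ca %||% 1.2, pr$SL %||% 2.2, grid)
      list(series = fv$curve,
           metrics = list(v_max = fv$v_max, Ta_iso = fv$Ta_iso))
    },
    step = {
      grid <- pr$dL_grid %||% seq(-0.008, 0.004, by = 0.002)
      list(series = fast_step_response(model, grid,
                                       dt_step = pr$dt_step %||% 2e-4,
                                       Ca = pr$Ca %||% 1.2,
                                       SL = pr$SL %||% 2.2))
    },
    simulate = {
      tt <- seq(0, pr$t_end %||% 1, by = pr$dt %||% 1e-3)
      tr <- stats::simulate(model, times = tt, Ca = pr$Ca %||% 1,
                            SL = pr$SL %||% 2.2)
      list(series = tr)
    },
    oracle = {
      n_ru <- pr$n_ru %||% 6L
      rep_df <- closure_error_report(
        n_ru, model$ru, pr$Ca_levels %||% c(0.3, 1, 3),
        geom = sarcomere_geometry(n_ru = n_ru))
      list(series = rep_df)
    })
  paths <- write_results(res, out_dir, prefix = cmd, config = unclass(cfg),
                         seed = cfg$seed)
  message("wrote: ", paste(basename(paths), collapse = ", "))
  invisible(0L)
}
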