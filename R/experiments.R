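#' Experiment configuration
#'
#' Validated description of a reproducible sweep: which model, which
#' parameter set (the packaged defaults, a named shipped config, or a YAML
#' file), the bias grid, the calcium conductances, and integrator options.
#' All algorithms in the package are deterministic; the \code{seed} field
#' exists for interface stability only.
#'
#' @param sweep one of \code{"fi"}, \code{"bifurcation"}, \code{"theory"},
#'   \code{"iterative"}, \code{"return_map"}.
#' @param model \code{"hh"} or \code{"qif"}.
#' @param mu_grid bias currents (uA/cm^2); nonempty, sorted.
#' @param gca_values calcium conductances swept (mS/cm^2).
#' @param param_set \code{"default"}, the name of a config shipped under
#'   \code{inst/configs}, or a path to a parameter YAML file.
#' @param overrides named list of parameter overrides.
#' @param duration,dt simulation settings (ms).
#' @param reset_mode QIF gating reset rule.
#' @param out_dir output directory for \code{\link{run_experiment}}.
#' @param seed unused; retained for interface stability.
#' @return A validated list of class \code{vn_config}.
#' @export
experiment_config <- function(sweep = c("fi", "bifurcation", "theory",
                                        "iterative", "return_map"),
                              model = c("qif", "hh"),
                              mu_grid,
                              gca_values = 0.2,
                              param_set = "default",
                              overrides = list(),
                              duration = 4000, dt = 0.01,
                              reset_mode = "spike_waveform",
                              out_dir = ".",
                              seed = NULL) {
  sweep <- match.arg(sweep)
  model <- match.arg(model)
  if (length(mu_grid) < 1L || is.unsorted(mu_grid)) {
    stop("config error in field 'mu_grid': need a nonempty sorted grid")
  }
  if (any(gca_values < 0)) {
    stop("config error in field 'gca_values': conductances must be >= 0")
  }
  if (!identical(param_set, "default") && !file.exists(param_set) &&
      is.na(.shipped_config_path(param_set))) {
    stop("config error in field 'param_set': '", param_set,
         "' is neither 'default', a shipped config name, nor a file")
  }
  structure(list(sweep = sweep, model = model, mu_grid = mu_grid,
                 gca_values = gca_values, param_set = param_set,
                 overrides = overrides, duration = duration, dt = dt,
                 reset_mode = reset_mode, out_dir = out_dir, seed = seed),
            class = "vn_config")
}

.shipped_config_path <- function(name) {
  f <- system.file("configs", paste0(name, ".yaml"), package = "vnboost")
  if (identical(f, "")) NA_character_ else f
}

#' Load an experiment config from YAML
#'
#' @param file path to a YAML file with the fields of
#'   \code{\link{experiment_config}}, or the name of a config shipped with
#'   the package.
#' @return A \code{vn_config}.
#' @export
read_experiment_config <- function(file) {
  if (!file.exists(file)) {
    shipped <- .shipped_config_path(file)
    if (is.na(shipped)) stop("no such config: ", file)
    file <- shipped
  }
  obj <- yaml::read_yaml(file)
  obj$mu_grid <- if (!is.null(obj$mu_grid)) as.numeric(obj$mu_grid) else
    seq(obj$mu_min, obj$mu_max, by = obj$mu_step)
  obj$mu_min <- obj$mu_max <- obj$mu_step <- NULL
  do.call(experiment_config, obj)
}

config_parameters <- function(config, gCa) {
  base <- if (identical(config$param_set, "default")) {
    default_parameters()
  } else if (file.exists(config$param_set)) {
    read_parameters(config$param_set)
  } else {
    read_parameters(.shipped_config_path(config$param_set))
  }
  ov <- c(list(gCa = gCa), config$overrides)
  ov <- ov[!duplicated(names(ov))]
  args <- utils::modifyList(
    base[setdiff(names(unclass(base)), "C_reset")], ov)
  args$C_reset <- if ("C_reset" %in% names(ov)) ov$C_reset else NULL
  do.call(model_parameters, args)
}

#' Run a configured experiment
#'
#' Executes the configured sweep for every calcium conductance in the config,
#' writes the per-sweep CSV/JSON outputs into \code{out_dir}, and writes a
#' manifest recording the config, a content hash, the package version and the
#' parameter provenance table. Identical configs produce identical outputs.
#'
#' @param config a \code{vn_config}.
#' @return Invisibly, the manifest list (with \code{files}).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "vn_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (gCa in config$gca_values) {
    p <- config_parameters(config, gCa)
    tag <- sprintf("%s_%s_gca%g", config$sweep, config$model, gCa)
    out <- file.path(config$out_dir, paste0(tag, ".csv"))
    if (config$sweep == "fi") {
      fi <- fi_curve(p, config$mu_grid, config$model,
                     duration = config$duration, dt = config$dt,
                     reset_rule = reset_rule(config$reset_mode,
                                             dx = p$dx, dC = p$dC,
                                             x_reset = p$x_reset,
                                             C_reset = p$C_reset))
      write_fi_curve(fi, out, meta = list(model = config$model, gCa = gCa,
                                          reset_mode = config$reset_mode))
    } else if (config$sweep == "bifurcation") {
      bd <- bifurcation_diagram(config$model, p, config$mu_grid,
                                simulate = TRUE,
                                duration = min(config$duration, 2000),
                                dt = config$dt)
      write_bifurcation(bd, json_file = file.path(config$out_dir,
                                                  paste0(tag, ".json")),
                        csv_file = out)
      files <- c(files, file.path(config$out_dir, paste0(tag, ".json")))
    } else if (config$sweep == "theory") {
      th <- firing_rate_theory(config$mu_grid, p)
      g <- theory_gain(th, p)
      th$G_tau <- g$G_tau; th$G_0 <- g$G_0
      th$G_minus <- g$G_minus; th$G_plus <- g$G_plus
      utils::write.csv(th, out, row.names = FALSE)
    } else if (config$sweep == "iterative") {
      rows <- lapply(config$mu_grid, function(mu) {
        it <- iterate_qif_theory(mu, p)
        data.frame(mu = mu, class = it$class, period = it$period,
                   rate_mean = it$rate_mean, rate_sd = it$rate_sd,
                   failed = it$failed)
      })
      utils::write.csv(do.call(rbind, rows), out, row.names = FALSE)
    } else if (config$sweep == "return_map") {
      rows <- lapply(config$mu_grid, function(mu) {
        tr <- if (config$model == "hh") {
          simulate_hh(p, mu, config$duration, config$dt, record = FALSE)
        } else {
          simulate_qif(p, mu, config$duration, config$dt, record = FALSE)
        }
        isis <- isi_sequence(tr$spike_times)
        if (length(isis) < 22L) return(NULL)
        kept <- isis[-seq_len(20L)]
        data.frame(mu = mu, isi_k = kept[-length(kept)], isi_k1 = kept[-1])
      })
      utils::write.csv(do.call(rbind, rows), out, row.names = FALSE)
    }
    files <- c(files, out)
  }
  manifest <- list(
    package = "vnboost",
    version = as.character(utils::packageVersion("vnboost")),
    config = unclass(config),
    config_hash = config_hash(config),
    files = basename(files),
    provenance = parameter_provenance(config_parameters(
      config, config$gca_values[1])))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Deterministic hash of an experiment config
#'
#' @param config a \code{vn_config}.
#' @return md5 hex string of the canonical JSON serialization.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Generate the packaged reference fixtures
#'
#' Writes the small reference tables the test suite and worked examples
#' consume: the burst-window ISI tables of the conductance-based model, an
#' f-I curve for the spike-waveform QIF, and an analytic theory sweep. The
#' fast tier completes in about a minute on one CPU; the full tier adds the
#' bifurcation diagrams.
#'
#' @param out_dir target directory.
#' @param tier \code{"fast"} or \code{"full"}.
#' @return Invisibly, the manifest list written alongside the fixtures.
#' @export
generate_fixtures <- function(out_dir, tier = c("fast", "full")) {
  tier <- match.arg(tier)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifests <- list()
  cfg1 <- experiment_config("return_map", "hh",
                            mu_grid = c(18, 19, 22, 22.5), gca_values = 0.6,
                            duration = 4000,
                            out_dir = file.path(out_dir, "hh_burst"))
  manifests$hh_burst <- run_experiment(cfg1)
  cfg2 <- experiment_config("theory", "qif", mu_grid = seq(1, 30, 0.5),
                            gca_values = 0.2,
                            out_dir = file.path(out_dir, "theory"))
  manifests$theory <- run_experiment(cfg2)
  if (tier == "full") {
    cfg3 <- experiment_config("bifurcation", "hh",
                              mu_grid = seq(2, 26, 1), gca_values = c(0, 0.6),
                              out_dir = file.path(out_dir, "bifurcation"))
    manifests$bifurcation <- run_experiment(cfg3)
    cfg4 <- experiment_config("fi", "qif", mu_grid = seq(2, 30, 1),
                              gca_values = c(0, 0.1, 0.2),
                              out_dir = file.path(out_dir, "qif_fi"))
    manifests$qif_fi <- run_experiment(cfg4)
  }
  jsonlite::write_json(lapply(manifests, function(m)
    m[c("config_hash", "files")]),
    file.path(out_dir, "fixtures_manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifests)
}
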