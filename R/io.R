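#' Write a simulation trace to CSV
#'
#' Flat CSV of the recorded state samples preceded by \code{#}-prefixed
#' metadata header lines (model, bias, step, integrator, spike count).
#'
#' @param trace a \code{vn_trace} with a recorded state.
#' @param file output path.
#' @param meta extra named metadata written as header lines.
#' @return \code{file}, invisibly.
#' @export
write_trace <- function(trace, file, meta = list()) {
  stopifnot(inherits(trace, "vn_trace"), !is.null(trace$states))
  con <- file(file, "w")
  on.exit(close(con))
  hdr <- c(list(model = trace$model, mu = trace$mu, dt = trace$dt,
                integrator = trace$integrator_id,
                n_spikes = length(trace$spike_times)), meta)
  for (nm in names(hdr)) {
    writeLines(sprintf("# %s: %s", nm, paste(hdr[[nm]], collapse = " ")),
               con)
  }
  utils::write.csv(data.frame(time = trace$times, trace$states,
                              check.names = FALSE),
                   con, row.names = FALSE)
  invisible(file)
}

#' Write an iteration record to CSV and JSON
#'
#' The per-iteration log (iteration, branch, resets in/out, interval) goes to
#' CSV; the summary (mean and SD of the retained rates, classification,
#' period) to JSON.
#'
#' @param it a \code{vn_iteration} from \code{\link{iterate_qif_theory}}.
#' @param csv_file,json_file output paths (either may be NULL).
#' @return Invisibly, the summary list.
#' @export
write_iteration <- function(it, csv_file = NULL, json_file = NULL) {
  stopifnot(inherits(it, "vn_iteration"))
  if (!is.null(csv_file)) {
    utils::write.csv(it$log, csv_file, row.names = FALSE)
  }
  summary <- list(mu = it$mu, class = it$class, period = it$period,
                  rate_mean = it$rate_mean, rate_sd = it$rate_sd,
                  failed = it$failed)
  if (!is.null(json_file)) {
    jsonlite::write_json(summary, json_file, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(summary)
}
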