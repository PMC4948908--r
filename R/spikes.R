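#' Interspike intervals from spike times
#'
#' @param spike_times sorted spike times (ms).
#' @return Numeric vector of ISIs (ms); empty when fewer than two spikes.
#' @export
isi_sequence <- function(spike_times) {
  if (length(spike_times) < 2L) return(numeric(0))
  diff(spike_times)
}

#' Classify the steady-state firing pattern of an ISI sequence
#'
#' Discards the first \code{n_discard} ISIs as transient, then searches for
#' the smallest period \code{N <= N_max} such that \code{isis[i + N]} matches
#' \code{isis[i]} within relative tolerance \code{rel_tol} for every retained
#' index. Periods: 1 is tonic firing, N >= 2 is an N-spike burst, no period is
#' aperiodic. Too few ISIs for the test yields \code{"quiescent"}.
#'
#' @param isis numeric ISI vector (ms).
#' @param rel_tol relative equality tolerance.
#' @param n_discard transient ISIs discarded before classification.
#' @param N_max largest period searched.
#' @return List with \code{pattern} (\code{"quiescent"}, \code{"tonic_1spk"},
#'   \code{"burst_N"}, \code{"aperiodic"}), \code{period} (NA for
#'   quiescent/aperiodic), \code{n_distinct} (distinct ISI values among the
#'   retained ones under \code{rel_tol} clustering), \code{distinct_isis}
#'   (cluster means) and \code{retained} (the ISIs used).
#' @export
classify_firing_pattern <- function(isis, rel_tol = 1e-3, n_discard = 20L,
                                    N_max = 6L) {
  if (length(isis) < n_discard + 4L) {
    return(list(pattern = "quiescent", period = NA_integer_,
                n_distinct = 0L, distinct_isis = numeric(0),
                retained = numeric(0)))
  }
  kept <- isis[-seq_len(n_discard)]
  period <- NA_integer_
  for (N in seq_len(min(N_max, length(kept) - 1L))) {
    i <- seq_len(length(kept) - N)
    if (all(abs(kept[i + N] - kept[i]) <= rel_tol * kept[i])) {
      period <- N
      break
    }
  }
  cl <- .cluster_isis(kept, rel_tol)
  pattern <- if (is.na(period)) "aperiodic"
             else if (period == 1L) "tonic_1spk"
             else paste0("burst_", period)
  list(pattern = pattern, period = period,
       n_distinct = length(cl), distinct_isis = cl, retained = kept)
}

# Greedy relative-tolerance clustering of ISI values; returns cluster means.
.cluster_isis <- function(x, rel_tol) {
  if (!length(x)) return(numeric(0))
  x <- sort(x)
  means <- x[1]
  counts <- 1L
  for (v in x[-1]) {
    k <- length(means)
    if (abs(v - means[k]) <= rel_tol * means[k]) {
      means[k] <- (means[k] * counts[k] + v) / (counts[k] + 1L)
      counts[k] <- counts[k] + 1L
    } else {
      means <- c(means, v)
      counts <- c(counts, 1L)
    }
  }
  means
}

#' Count distinct ISI values in the steady-state pattern
#'
#' Convenience wrapper: number of ISI clusters among the post-transient ISIs
#' under relative-tolerance clustering.
#'
#' @inheritParams classify_firing_pattern
#' @return Integer count (0 when too few ISIs).
#' @export
count_distinct_isis <- function(isis, rel_tol = 1e-3, n_discard = 20L) {
  if (length(isis) <= n_discard) return(0L)
  length(.cluster_isis(isis[-seq_len(n_discard)], rel_tol))
}

#' Detect the bidirectional afterhyperpolarization
#'
#' For each interspike segment of a recorded trace, counts direction reversals
#' of the (lightly smoothed) voltage between the end of the post-spike guard
#' and the next spike. A normal trajectory falls to a single minimum and rises
#' (one reversal); the bidirectional AHP falls, rises, falls again and rises
#' to threshold (at least two additional reversals beyond none). The segment
#' is flagged \code{TRUE} when at least two reversals occur.
#'
#' @param trace a \code{vn_trace} with a recorded voltage.
#' @param spike_times spike times (ms); defaults to the trace's own.
#' @param guard post-spike stretch excluded from the count (ms); covers the
#'   spike downstroke.
#' @param smooth_ms moving-average window used to suppress numerical chatter
#'   (ms).
#' @param min_amplitude ignore reversals smaller than this voltage excursion
#'   (mV).
#' @return Logical vector, one entry per interspike interval.
#' @export
detect_ahp <- function(trace, spike_times = NULL, guard = NULL,
                       smooth_ms = 0.2, min_amplitude = 0.05) {
  stopifnot(inherits(trace, "vn_trace"), !is.null(trace$states))
  if (is.null(spike_times)) spike_times <- trace$spike_times
  if (length(spike_times) < 2L) {
    stop("need at least two spikes to assess interspike segments")
  }
  if (is.null(guard)) guard <- 3  # refractory-scale downstroke exclusion
  times <- trace$times
  V <- trace$states[, "V"]
  vapply(seq_len(length(spike_times) - 1L), function(i) {
    sel <- times > spike_times[i] + guard & times < spike_times[i + 1L] - 0.1
    v <- V[sel]
    if (length(v) < 5L) return(FALSE)
    w <- max(1L, round(smooth_ms / (times[2] - times[1])))
    if (w > 1L) v <- stats::filter(v, rep(1 / w, w), sides = 2)
    v <- v[!is.na(v)]
    .count_reversals(v, min_amplitude) >= 2L
  }, logical(1))
}

# Count direction reversals of a sampled curve, ignoring excursions smaller
# than `amp` between consecutive turning points.
.count_reversals <- function(v, amp) {
  dv <- diff(v)
  dv <- dv[dv != 0]
  if (length(dv) < 2L) return(0L)
  s <- sign(dv)
  turn <- which(s[-1] != s[-length(s)])
  if (!length(turn)) return(0L)
  # amplitude filter on turning points of the raw curve
  idx <- c(1L, turn + 1L, length(v))
  vt <- v[idx]
  keep <- c(TRUE, abs(diff(vt)) >= amp)
  vt <- vt[keep]
  if (length(vt) < 3L) return(0L)
  s2 <- sign(diff(vt))
  sum(s2[-1] != s2[-length(s2)])
}

#' ISI return map
#'
#' Consecutive interspike-interval pairs \code{(ISI_k, ISI_{k+1})} plus the
#' mean ISI, the standard tool for telling periodic bursting from aperiodic
#' firing.
#'
#' @param isis numeric ISI vector (>= 2 values).
#' @return List with \code{pairs} (two-column matrix) and \code{mean_isi}.
#' @export
isi_return_map <- function(isis) {
  stopifnot(length(isis) >= 2L)
  list(pairs = cbind(isi_k = isis[-length(isis)], isi_k1 = isis[-1]),
       mean_isi = mean(isis))
}

#' f-I curve of a simulated model
#'
#' Sweeps the bias current and, for each value, simulates the model, extracts
#' ISIs, discards the transient ones, and reports the mean firing rate
#' (mean of 1/ISI, in spk/s), the distinct 1/ISI values of the steady-state
#' pattern (the burst branches), and the pattern classification. Quiescent
#' bias values report rate 0.
#'
#' @param p a \code{vn_parameters} object.
#' @param mu_grid sorted bias currents (uA/cm^2).
#' @param model \code{"hh"} or \code{"qif"}.
#' @param duration,dt simulation settings (ms).
#' @param n_discard transient ISIs discarded.
#' @param rel_tol ISI clustering tolerance.
#' @param vdetect spike-detection voltage for the HH model (mV).
#' @param reset_rule optional \code{\link{reset_rule}} for the QIF model.
#' @return A data frame of class \code{vn_fi_curve}: columns \code{mu},
#'   \code{rate_mean} (spk/s), \code{pattern}, \code{period},
#'   \code{n_distinct}, \code{n_isis}, and a list-column \code{rate_values}
#'   (distinct 1/ISI values, spk/s).
#' @export
fi_curve <- function(p, mu_grid, model = c("hh", "qif"), duration = 4000,
                     dt = 0.01, n_discard = 20L, rel_tol = 1e-3,
                     vdetect = 0, reset_rule = NULL) {
  model <- match.arg(model)
  stopifnot(!is.unsorted(mu_grid))
  rows <- lapply(mu_grid, function(mu) {
    tr <- if (model == "hh") {
      simulate_hh(p, mu, duration, dt, vdetect = vdetect, record = FALSE)
    } else {
      simulate_qif(p, mu, duration, dt, reset_rule = reset_rule,
                   record = FALSE)
    }
    isis <- isi_sequence(tr$spike_times)
    cls <- classify_firing_pattern(isis, rel_tol, n_discard)
    rate <- if (cls$pattern == "quiescent") 0
            else 1000 * mean(1 / cls$retained)
    row <- data.frame(mu = mu, rate_mean = rate, pattern = cls$pattern,
                      period = cls$period, n_distinct = cls$n_distinct,
                      n_isis = length(isis))
    row$rate_values <- list(sort(1000 / cls$distinct_isis))
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("vn_fi_curve", class(out))
  out
}

#' Write an f-I curve to CSV
#'
#' Flat CSV with the distinct per-burst rates JSON-encoded in a
#' \code{rate_values_json} column, preceded by \code{#}-prefixed metadata
#' header lines.
#'
#' @param fi a \code{vn_fi_curve}.
#' @param file output path.
#' @param meta named list written as header comment lines.
#' @return \code{file}, invisibly.
#' @export
write_fi_curve <- function(fi, file, meta = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, paste(meta[[nm]], collapse = " ")),
               con)
  }
  df <- as.data.frame(fi[, setdiff(names(fi), "rate_values")])
  df$rate_values_json <- vapply(fi$rate_values, function(v)
    as.character(jsonlite::toJSON(v, digits = NA)), character(1))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}
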