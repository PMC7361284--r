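# Post-hoc quality filter for MINFLUX localization events.
#
# MINFLUX localizations come with per-event quality scalars from the
# instrument: the background parameter p0 and the relative position
# estimate r_relative flag false-positive localizations (background
# reactions, events far outside the targeted region); very high photon
# count rates indicate groups of simultaneously active molecules rather
# than single emitters; photon number and signal-to-background bound the
# localization precision. The filter applies all five criteria and reports
# every failed criterion per event.

minflux_reason_codes <- c("P0", "R_RELATIVE", "RATE", "PHOTONS", "SBR")

minflux_columns <- c("x_nm", "y_nm", "z_nm", "photons", "count_rate_khz",
                     "p0", "r_relative_nm", "sbr")

#' Thresholds for MINFLUX event filtering
#'
#' An event is kept only if all five criteria hold:
#' `p0 < p0_max`, `r_relative_nm < r_relative_max_nm`,
#' `count_rate_khz <= count_rate_max_khz`, `photons > photons_min`, and
#' `sbr > sbr_min`. Boundary semantics are deliberate: an event at exactly
#' 100 kHz is kept (removal targets rates strictly above the bound), while
#' an event with exactly 1,000 photons, `p0 = 0.11`, `r_relative = 32` nm
#' or `sbr = 0.6` is removed (those criteria are strict).
#'
#' @param p0_max Maximum (exclusive) instrument background parameter.
#' @param r_relative_max_nm Maximum (exclusive) relative position, nm.
#' @param count_rate_max_khz Maximum (inclusive) photon count rate, kHz.
#' @param photons_min Minimum (exclusive) photon number.
#' @param sbr_min Minimum (exclusive) signal-to-background ratio.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(p0_max = 0.11, r_relative_max_nm = 32,
                          count_rate_max_khz = 100, photons_min = 1000,
                          sbr_min = 0.6) {
  for (nm in c("p0_max", "r_relative_max_nm", "count_rate_max_khz",
               "photons_min", "sbr_min")) {
    v <- get(nm)
    if (!is_scalar_num(v) || v <= 0)
      stop_bad_arg("'", nm, "' must be a positive scalar")
  }
  structure(list(p0_max = p0_max, r_relative_max_nm = r_relative_max_nm,
                 count_rate_max_khz = count_rate_max_khz,
                 photons_min = photons_min, sbr_min = sbr_min),
            class = "filter_params")
}

#' Filter MINFLUX localization events by the five quality criteria
#'
#' Partitions an event table into kept and removed events. Every failing
#' criterion of a removed event is recorded (no short-circuiting), so the
#' per-criterion counts support quality-control summaries. Events with a
#' non-finite value in any of the five quality fields are removed, the
#' affected criteria are recorded, and the event is additionally flagged
#' `malformed`; nothing is dropped silently.
#'
#' @param events Data frame with at least the columns
#'   `photons`, `count_rate_khz`, `p0`, `r_relative_nm`, `sbr`
#'   (positions `x_nm`, `y_nm`, `z_nm` are carried through untouched).
#' @param params A [filter_params()] object.
#' @return An object of class `minflux_filter_report`: list with `kept`
#'   (data frame), `removed` (data frame plus a `reasons` column of
#'   comma-separated codes and a `malformed` flag), `counts` (named vector
#'   over reason codes plus `MALFORMED`), `n_input`, and `params`.
#' @export
#' @examples
#' ev <- simulate_minflux_events(5, 5, seed = 1)
#' rep <- filter_events(ev)
#' rep$counts
filter_events <- function(events, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"), is.data.frame(events))
  need <- c("photons", "count_rate_khz", "p0", "r_relative_nm", "sbr")
  missing_cols <- setdiff(need, names(events))
  if (length(missing_cols))
    stop_bad_arg("event table lacks columns: ",
                 paste(missing_cols, collapse = ", "))
  n <- nrow(events)
  if (n == 0L) {
    counts <- stats::setNames(integer(6),
                              c(minflux_reason_codes, "MALFORMED"))
    return(structure(list(kept = events,
                          removed = cbind(events,
                                          reasons = character(0),
                                          malformed = logical(0)),
                          counts = counts, n_input = 0L, params = params),
                     class = "minflux_filter_report"))
  }

  # fail matrix: TRUE where the criterion rejects; a non-finite field
  # always rejects its criterion
  fin <- function(x) is.finite(x)
  fail <- cbind(
    P0         = !fin(events$p0) | !(events$p0 < params$p0_max),
    R_RELATIVE = !fin(events$r_relative_nm) |
      !(events$r_relative_nm < params$r_relative_max_nm),
    RATE       = !fin(events$count_rate_khz) |
      !(events$count_rate_khz <= params$count_rate_max_khz),
    PHOTONS    = !fin(events$photons) | !(events$photons > params$photons_min),
    SBR        = !fin(events$sbr) | !(events$sbr > params$sbr_min))
  malformed <- !fin(events$p0) | !fin(events$r_relative_nm) |
    !fin(events$count_rate_khz) | !fin(events$photons) | !fin(events$sbr)
  keep <- !malformed & rowSums(fail) == 0L

  removed <- events[!keep, , drop = FALSE]
  fail_rm <- fail[!keep, , drop = FALSE]
  removed$reasons <- apply(fail_rm, 1L, function(f)
    paste(minflux_reason_codes[f], collapse = ","))
  removed$malformed <- malformed[!keep]
  counts <- c(colSums(fail[!keep, , drop = FALSE]),
              MALFORMED = sum(malformed))
  structure(list(kept = events[keep, , drop = FALSE],
                 removed = removed,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 n_input = n, params = params),
            class = "minflux_filter_report")
}

#' @export
print.minflux_filter_report <- function(x, ...) {
  cat(sprintf("<minflux_filter_report> %d events: %d kept, %d removed\n",
              x$n_input, nrow(x$kept), nrow(x$removed)))
  if (nrow(x$removed)) {
    cat("  removal counts (an event may fail several criteria):\n")
    for (nm in names(x$counts))
      if (x$counts[[nm]] > 0) cat(sprintf("    %-10s %d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}

#' @export
summary.minflux_filter_report <- function(object, ...) {
  out <- list(n_input = object$n_input,
              n_kept = nrow(object$kept),
              n_removed = nrow(object$removed),
              kept_fraction = if (object$n_input > 0)
                nrow(object$kept) / object$n_input else NA_real_,
              counts = object$counts)
  class(out) <- "summary.minflux_filter_report"
  out
}

#' @export
print.summary.minflux_filter_report <- function(x, ...) {
  cat(sprintf("MINFLUX filter: kept %d / %d events (%.1f%%)\n",
              x$n_kept, x$n_input,
              100 * (x$kept_fraction %||% NA_real_)))
  print(x$counts)
  invisible(x)
}

#' Read / write MINFLUX event tables
#'
#' Plain CSV with header
#' `x_nm,y_nm,z_nm,photons,count_rate_khz,p0,r_relative_nm,sbr`; extra
#' columns (for example the simulator's ground-truth labels) are carried
#' through unchanged.
#'
#' @param path CSV file path.
#' @return `read_events`: the event data frame.
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(minflux_columns, names(ev))
  if (length(missing_cols))
    stop_bad_arg("event CSV lacks columns: ",
                 paste(missing_cols, collapse = ", "))
  ev
}

#' @rdname read_events
#' @param events Event data frame.
#' @export
write_events <- function(events, path) {
  stopifnot(is.data.frame(events))
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
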