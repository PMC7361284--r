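#' Simulate a mixture of valid and artifact MINFLUX events
#'
#' Generates a localization-event table in which `n_valid` events satisfy
#' all five quality criteria of [filter_events()] and `n_artifact` events
#' each violate at least one. Artifact failure modes cycle round-robin
#' through the five criteria (`P0`, `R_RELATIVE`, `RATE`, `PHOTONS`,
#' `SBR`), so any artifact count >= 5 exercises every filter branch. The
#' generating label is recorded per event (`valid`, `failure_mode`), and
#' the row order is shuffled deterministically by the seed.
#'
#' @param n_valid Number of events passing all criteria.
#' @param n_artifact Number of events failing at least one criterion.
#' @param seed Integer seed.
#' @param params [filter_params()] thresholds the mixture is built against.
#' @return Data frame with the standard event columns plus ground-truth
#'   `valid` (logical) and `failure_mode` (reason code, `NA` for valid
#'   events).
#' @export
#' @examples
#' ev <- simulate_minflux_events(50, 50, seed = 3)
#' table(ev$valid)
simulate_minflux_events <- function(n_valid, n_artifact, seed,
                                    params = filter_params()) {
  if (!is_count(n_valid) || !is_count(n_artifact))
    stop_bad_arg("'n_valid' and 'n_artifact' must be counts >= 0")
  stopifnot(inherits(params, "filter_params"))
  n_valid <- as.integer(n_valid); n_artifact <- as.integer(n_artifact)
  n <- n_valid + n_artifact

  with_seed(child_seed(seed, 3L), {
    draw_valid <- function(k) data.frame(
      x_nm = stats::runif(k, -500, 500),
      y_nm = stats::runif(k, -500, 500),
      z_nm = stats::runif(k, -150, 150),
      photons = floor(stats::runif(k, params$photons_min + 1, 6 * params$photons_min)),
      count_rate_khz = stats::runif(k, 0.2, 1) * params$count_rate_max_khz,
      p0 = stats::runif(k, 0.1, 0.9) * params$p0_max,
      r_relative_nm = stats::runif(k, 0.1, 0.9) * params$r_relative_max_nm,
      sbr = params$sbr_min + stats::runif(k, 0.1, 2))

    valid <- draw_valid(n_valid)
    if (n_valid) {
      valid$valid <- TRUE
      valid$failure_mode <- NA_character_
    }

    art <- draw_valid(n_artifact)
    if (n_artifact) {
      mode <- minflux_reason_codes[(seq_len(n_artifact) - 1L) %% 5L + 1L]
      for (i in seq_len(n_artifact)) {
        switch(mode[i],
          P0 = art$p0[i] <- params$p0_max + stats::runif(1, 0, 2 * params$p0_max),
          R_RELATIVE = art$r_relative_nm[i] <-
            params$r_relative_max_nm + stats::runif(1, 0, 2 * params$r_relative_max_nm),
          RATE = art$count_rate_khz[i] <-
            params$count_rate_max_khz + stats::runif(1, 0.5, 2 * params$count_rate_max_khz),
          PHOTONS = art$photons[i] <- floor(stats::runif(1, 50, params$photons_min)),
          SBR = art$sbr[i] <- stats::runif(1, 0.01, 0.95 * params$sbr_min))
      }
      art$valid <- FALSE
      art$failure_mode <- mode
    }

    events <- rbind(valid, art)
    if (n == 0L) {
      events <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                           z_nm = numeric(0), photons = numeric(0),
                           count_rate_khz = numeric(0), p0 = numeric(0),
                           r_relative_nm = numeric(0), sbr = numeric(0),
                           valid = logical(0), failure_mode = character(0))
      return(events)
    }
    events <- events[sample.int(n), , drop = FALSE]
    rownames(events) <- NULL
    events
  })
}
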