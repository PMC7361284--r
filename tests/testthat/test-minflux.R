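# Re-application of the five retention criteria, independent of
# filter_events(): the reference predicate for ground-truth checks.
passes_all <- function(ev, p = filter_params()) {
  ev$p0 < p$p0_max & ev$r_relative_nm < p$r_relative_max_nm &
    ev$count_rate_khz <= p$count_rate_max_khz &
    ev$photons > p$photons_min & ev$sbr > p$sbr_min
}

minflux_cols <- function() c("x_nm", "y_nm", "z_nm", "photons",
                             "count_rate_khz", "p0", "r_relative_nm", "sbr")

event_row <- function(photons = 1200, sbr = 0.7, count_rate_khz = 50,
                      p0 = 0.05, r_relative_nm = 10) {
  data.frame(x_nm = 0, y_nm = 0, z_nm = 0, photons = photons,
             count_rate_khz = count_rate_khz, p0 = p0,
             r_relative_nm = r_relative_nm, sbr = sbr)
}

test_that("an event satisfying all five criteria is kept", {
  rep <- filter_events(event_row())
  expect_identical(nrow(rep$kept), 1L)
  expect_identical(nrow(rep$removed), 0L)
})

test_that("boundary values follow the printed inequalities", {
  # photon threshold is strict: exactly 1,000 photons is removed
  rep <- filter_events(event_row(photons = 1000))
  expect_identical(nrow(rep$kept), 0L)
  expect_identical(rep$removed$reasons, "PHOTONS")
  # the rate criterion removes only rates strictly above 100 kHz
  expect_identical(nrow(filter_events(event_row(count_rate_khz = 100))$kept), 1L)
  rep <- filter_events(event_row(count_rate_khz = 150))
  expect_identical(rep$removed$reasons, "RATE")
  # p0, r_relative and sbr are strict at their bounds
  expect_identical(filter_events(event_row(p0 = 0.11))$removed$reasons, "P0")
  expect_identical(filter_events(event_row(r_relative_nm = 32))$removed$reasons,
                   "R_RELATIVE")
  expect_identical(filter_events(event_row(sbr = 0.6))$removed$reasons, "SBR")
  expect_identical(nrow(filter_events(event_row(p0 = 0.1099,
                                                r_relative_nm = 31.99,
                                                sbr = 0.601))$kept), 1L)
})

test_that("all failing criteria are reported, not only the first", {
  rep <- filter_events(event_row(photons = 10, sbr = 0.1, p0 = 0.5))
  expect_setequal(strsplit(rep$removed$reasons, ",")[[1]],
                  c("P0", "PHOTONS", "SBR"))
})

test_that("non-finite fields are removed with a MALFORMED flag", {
  ev <- event_row(); ev$photons <- NA_real_
  rep <- filter_events(ev)
  expect_identical(nrow(rep$kept), 0L)
  expect_true(rep$removed$malformed)
  expect_match(rep$removed$reasons, "PHOTONS")
  expect_identical(rep$counts[["MALFORMED"]], 1L)
})

test_that("an empty input yields an empty report with zero counts", {
  rep <- filter_events(event_row()[0, ])
  expect_identical(rep$n_input, 0L)
  expect_identical(nrow(rep$kept), 0L)
  expect_true(all(rep$counts == 0L))
})

test_that("kept and removed partition the input and the filter is idempotent", {
  ev <- simulate_minflux_events(200, 200, seed = 77)
  rep <- filter_events(ev)
  expect_identical(nrow(rep$kept) + nrow(rep$removed), nrow(ev))
  ids <- sort(c(rownames(rep$kept), rownames(rep$removed)))
  expect_identical(ids, sort(rownames(ev)))
  again <- filter_events(rep$kept)
  expect_identical(nrow(again$removed), 0L)
  expect_identical(again$kept[minflux_cols()], rep$kept[minflux_cols()])
})

test_that("filtering is order-independent", {
  ev <- simulate_minflux_events(100, 100, seed = 5)
  rep1 <- filter_events(ev)
  perm <- ev[rev(seq_len(nrow(ev))), ]
  rep2 <- filter_events(perm)
  expect_identical(rep1$counts, rep2$counts)
  k1 <- rep1$kept[order(rep1$kept$x_nm), minflux_cols()]
  k2 <- rep2$kept[order(rep2$kept$x_nm), minflux_cols()]
  rownames(k1) <- rownames(k2) <- NULL
  expect_identical(k1, k2)
})

test_that("relaxing any single threshold never shrinks the kept set", {
  ev <- simulate_minflux_events(150, 150, seed = 11)
  base <- filter_events(ev)
  relaxed <- list(
    filter_params(p0_max = 0.5),
    filter_params(r_relative_max_nm = 100),
    filter_params(count_rate_max_khz = 500),
    filter_params(photons_min = 100),
    filter_params(sbr_min = 0.1))
  for (fp in relaxed) {
    rep <- filter_events(ev, fp)
    expect_true(all(rownames(base$kept) %in% rownames(rep$kept)))
  }
})

test_that("simulator labels agree exactly with threshold re-application", {
  ev <- simulate_minflux_events(500, 500, seed = 99)
  expect_identical(sum(passes_all(ev)), 500L)
  expect_identical(unname(passes_all(ev)), ev$valid)
  # artifact failure modes cycle through all five criteria
  expect_setequal(unique(ev$failure_mode[!ev$valid]),
                  c("P0", "R_RELATIVE", "RATE", "PHOTONS", "SBR"))
  # and the package filter recovers the labels
  rep <- filter_events(ev)
  expect_identical(sort(as.integer(rownames(rep$kept))), which(ev$valid))
})

test_that("the event simulator is seed-deterministic and handles empties", {
  expect_identical(simulate_minflux_events(50, 50, seed = 4),
                   simulate_minflux_events(50, 50, seed = 4))
  expect_false(identical(simulate_minflux_events(50, 50, seed = 4),
                         simulate_minflux_events(50, 50, seed = 5)))
  ev <- simulate_minflux_events(0, 0, seed = 1)
  expect_identical(nrow(ev), 0L)
})
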