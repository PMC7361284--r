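test_that("CJ frequency pools counts over OM length per condition", {
  tab <- rbind(section_row("a", om = 10, n_cj = 5, id = "s1"))
  res <- cj_frequency(tab)
  expect_equal(res$pooled_rate, 0.5)

  tab <- rbind(section_row("a", om = 2, n_cj = 2, id = "s1"),
               section_row("a", om = 2, n_cj = 0, id = "s2"))
  res <- cj_frequency(tab)
  expect_equal(res$pooled_rate, 0.5)
  expect_equal(unname(attr(res, "per_section")$a), c(1.0, 0.0))

  # ratio invariance: doubling counts and lengths leaves the rate alone
  tab2 <- tab; tab2$n_cj <- tab2$n_cj * 2L; tab2$om_length_um <- tab2$om_length_um * 2
  expect_equal(cj_frequency(tab2)$pooled_rate, res$pooled_rate)
})

test_that("the pooled rate is invariant to splitting sections", {
  set.seed(8)
  tab <- simulate_morphometry(morphometry_presets()$wild_type, 30, seed = 2)
  pooled <- cj_frequency(tab)$pooled_rate
  # split every section in two with proportionally divided counts/lengths
  half <- tab
  half$om_length_um <- tab$om_length_um * 0.3
  half$n_cj <- as.integer(round(tab$n_cj * 0.3))
  other <- tab
  other$om_length_um <- tab$om_length_um * 0.7
  other$n_cj <- tab$n_cj - half$n_cj
  other$section_id <- paste0(tab$section_id, "b")
  split_tab <- rbind(half, other)
  expect_equal(cj_frequency(split_tab)$pooled_rate, pooled, tolerance = 1e-12)
})

test_that("diameter summaries use the pooled sample SD", {
  tab <- section_row("a", n_cj = 3, diam = "20;20;20")
  s <- diameter_summary(tab, "a")
  expect_equal(s$mean_nm, 20); expect_equal(s$sd_nm, 0)
  expect_identical(s$n, 3L)

  tab <- section_row("a", n_cj = 2, diam = "26;30")
  s <- diameter_summary(tab, "a")
  expect_equal(s$mean_nm, 28)
  expect_equal(s$sd_nm, sqrt(8))  # sample SD, n - 1 denominator

  s <- diameter_summary(section_row("a"), "a")
  expect_true(s$undefined)
  expect_error(diameter_summary(tab, "nope"), "no sections")
})

test_that("the one-way ANOVA matches the worked example and the SS oracle", {
  res <- anova_one_way(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$f_stat, 13.5)
  expect_identical(c(res$df_between, res$df_within), c(1L, 4L))

  set.seed(301)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(2:8, 1), mean = j))
    got <- anova_one_way(groups)
    want <- oracle_anova(groups)
    expect_equal(got$f_stat, want$f_stat, tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
    expect_identical(c(got$df_between, got$df_within),
                     as.integer(c(want$df_between, want$df_within)))
  }
})

test_that("the ANOVA flags degenerate inputs and is shift-invariant", {
  res <- anova_one_way(list(c(2, 2), c(2, 2)))
  expect_true(res$degenerate)
  expect_true(is.na(res$f_stat))
  res <- anova_one_way(list(c(1, 1), c(2, 2)))
  expect_true(res$degenerate)
  expect_identical(res$f_stat, Inf)
  expect_identical(res$p_value, 0)

  g <- list(rnorm(5), rnorm(4), rnorm(6))
  expect_equal(anova_one_way(g)$f_stat,
               anova_one_way(lapply(g, `+`, 17.3))$f_stat,
               tolerance = 1e-9)
  expect_error(anova_one_way(list(1:3)), "2 groups")
  expect_error(anova_one_way(list(1:3, 2)), "finite")
})

test_that("morphology fractions sum to one and reject unknown labels", {
  tab <- rbind(section_row("a", class = "wild_type", id = "s1"),
               section_row("a", class = "wild_type", id = "s2"),
               section_row("a", class = "wild_type", id = "s3"),
               section_row("a", class = "aberrant", id = "s4"))
  fr <- morphology_fractions(tab)
  expect_equal(fr$fraction[fr$class == "wild_type"], 0.75)
  expect_equal(fr$fraction[fr$class == "aberrant"], 0.25)
  expect_identical(unique(fr$n_sections), 4L)

  single <- morphology_fractions(section_row("a", class = "aberrant"))
  expect_equal(sum(single$fraction), 1)

  shuffled <- morphology_fractions(tab[c(3, 1, 4, 2), ])
  expect_identical(shuffled, fr)

  tab$morphology_class[2] <- "weird"
  expect_error(morphology_fractions(tab), "weird")

  set.seed(2)
  sim <- simulate_morphometry(morphometry_presets()$mic60_ko, 40, seed = 3)
  fr <- morphology_fractions(sim)
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-12)
})

test_that("junction/septum accounting follows the stated arithmetic", {
  # identical proportions: no decrease
  res <- junction_septa_from_rates(0.5, 0.2, 0.5, 0.2)
  expect_equal(res$relative_decrease, 0)
  # prevalences 0.60/0.36 with septum fractions 0.15/0.50: cristae-CJ
  # prevalences 0.51 and 0.18, a relative decrease of ~0.647
  res <- junction_septa_from_rates(0.60, 0.15, 0.36, 0.50)
  expect_equal(res$cristae_cj_prevalence_ctrl, 0.51)
  expect_equal(res$cristae_cj_prevalence_test, 0.18)
  expect_equal(res$relative_decrease, 1 - 0.18 / 0.51, tolerance = 1e-12)
  # zero test prevalence: complete loss
  res <- junction_septa_from_rates(0.6, 0.15, 0, 0)
  expect_equal(res$relative_decrease, 1.0)
  # zero control cristae-CJ prevalence: undefined, flagged
  res <- junction_septa_from_rates(0.5, 1, 0.3, 0.2)
  expect_true(res$undefined)
  expect_true(is.na(res$relative_decrease))
})

test_that("section-level accounting recovers the generating proportions", {
  ctrl <- rbind(
    do.call(rbind, lapply(1:51, function(i)
      section_row("c", n_cj = 1, id = paste0("c", i)))),
    do.call(rbind, lapply(1:9, function(i)
      section_row("c", n_cj = 0, septum = TRUE, n_sept = 1,
                  id = paste0("cs", i)))),
    do.call(rbind, lapply(1:40, function(i)
      section_row("c", n_cj = 0, id = paste0("c0", i)))))
  test <- rbind(
    do.call(rbind, lapply(1:18, function(i)
      section_row("t", n_cj = 1, id = paste0("t", i)))),
    do.call(rbind, lapply(1:18, function(i)
      section_row("t", n_cj = 0, septum = TRUE, n_sept = 1,
                  id = paste0("ts", i)))),
    do.call(rbind, lapply(1:64, function(i)
      section_row("t", n_cj = 0, id = paste0("t0", i)))))
  res <- junction_septa_accounting(ctrl, test)
  expect_equal(res$prevalence_ctrl, 0.60)
  expect_equal(res$septum_frac_ctrl, 0.15)
  expect_equal(res$prevalence_test, 0.36)
  expect_equal(res$septum_frac_test, 0.50)
  expect_equal(res$relative_decrease, 1 - 0.18 / 0.51, tolerance = 1e-12)

  # dimensionless: replicating every section leaves all outputs unchanged
  res3 <- junction_septa_accounting(ctrl[rep(seq_len(nrow(ctrl)), 3), ],
                                    test[rep(seq_len(nrow(test)), 3), ])
  expect_equal(res3$relative_decrease, res$relative_decrease)
})
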