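# Statistics over per-section EM morphometry annotations.

#' Crista-junction frequency per micrometre of outer membrane
#'
#' For each condition, the CJ count is normalized to the OM length. Two
#' summaries are returned: the pooled rate (total CJs over total OM
#' length, the headline number) and the per-section rates with their mean
#' and standard error.
#'
#' @param sections Morphometry data frame (see [read_sections()]).
#' @return Object of class `cj_frequency`: a data frame with one row per
#'   condition (`condition`, `pooled_rate`, `mean_rate`, `sem`,
#'   `n_sections`, `total_cj`, `total_om_um`) and the per-section rates in
#'   `attr(, "per_section")`.
#' @export
#' @examples
#' tab <- simulate_morphometry(morphometry_presets()$wild_type, 50, seed = 1)
#' cj_frequency(tab)
cj_frequency <- function(sections) {
  check_sections(sections)
  per <- split(sections, sections$condition)
  rows <- lapply(per, function(s) {
    if (any(s$om_length_um <= 0))
      stop_bad_arg("non-positive OM length in condition ", s$condition[1L])
    rates <- s$n_cj / s$om_length_um
    data.frame(condition = s$condition[1L],
               pooled_rate = sum(s$n_cj) / sum(s$om_length_um),
               mean_rate = mean(rates),
               sem = if (length(rates) > 1L)
                 stats::sd(rates) / sqrt(length(rates)) else NA_real_,
               n_sections = nrow(s),
               total_cj = sum(s$n_cj),
               total_om_um = sum(s$om_length_um),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_section") <- lapply(per, function(s)
    stats::setNames(s$n_cj / s$om_length_um, s$section_id))
  class(out) <- c("cj_frequency", "data.frame")
  out
}

#' @export
print.cj_frequency <- function(x, ...) {
  cat("CJ frequency (per um outer membrane):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Pooled crista-junction diameter summary for one condition
#'
#' Pools every measured diameter of the condition and reports mean, sample
#' standard deviation (n - 1 denominator) and count.
#'
#' @param sections Morphometry data frame.
#' @param condition Condition label to summarize.
#' @return List with `mean_nm`, `sd_nm`, `n`, and `undefined` (`TRUE` when
#'   the condition has no measured diameter; the numeric fields are then
#'   `NA`).
#' @export
diameter_summary <- function(sections, condition) {
  check_sections(sections)
  s <- sections[sections$condition == condition, , drop = FALSE]
  if (!nrow(s)) stop_bad_arg("no sections with condition '", condition, "'")
  d <- unlist(parse_diameters(s$cj_diameters_nm), use.names = FALSE)
  if (!length(d))
    return(list(mean_nm = NA_real_, sd_nm = NA_real_, n = 0L,
                undefined = TRUE))
  list(mean_nm = mean(d),
       sd_nm = if (length(d) > 1L) stats::sd(d) else 0,
       n = length(d), undefined = FALSE)
}

#' Classical one-way fixed-effects ANOVA
#'
#' Omnibus comparison of group means: `F = (SSB/df_b) / (SSW/df_w)` with a
#' p-value from the F distribution. The math is delegated to
#' [stats::oneway.test()] with equal variances assumed (the classical
#' ANOVA, no Welch correction), matching how group comparisons of CJ
#' frequencies, diameters, and clustered fractions are tested.
#'
#' Degenerate inputs are flagged rather than failing: if all groups are
#' the same constant the F statistic is undefined (0/0) and returned as
#' `NA`; if the within-group variance is zero but group means differ the F
#' statistic is infinite and the p-value is reported at the distribution
#' limit 0.
#'
#' @param groups List of numeric vectors, >= 2 groups with >= 2 finite
#'   values each.
#' @return Object of class `anova_result`: list with `f_stat`,
#'   `df_between`, `df_within`, `p_value`, `degenerate`.
#' @export
#' @examples
#' anova_one_way(list(c(1, 2, 3), c(4, 5, 6)))  # F = 13.5, df (1, 4)
anova_one_way <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_bad_arg("need at least 2 groups")
  for (g in groups) {
    if (!is.numeric(g) || length(g) < 2L || !all(is.finite(g)))
      stop_bad_arg("every group needs >= 2 finite numeric values")
  }
  y <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), lengths(groups)))
  df_b <- length(groups) - 1L
  df_w <- length(y) - length(groups)

  ssw <- sum(unlist(lapply(groups, function(g) sum((g - mean(g))^2))))
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 0) - mean(y))^2)

  if (ssw == 0 && ssb == 0) {
    res <- list(f_stat = NA_real_, df_between = df_b, df_within = df_w,
                p_value = NA_real_, degenerate = TRUE)
  } else if (ssw == 0) {
    res <- list(f_stat = Inf, df_between = df_b, df_within = df_w,
                p_value = 0, degenerate = TRUE)
  } else {
    ow <- stats::oneway.test(y ~ grp, var.equal = TRUE)
    res <- list(f_stat = unname(ow$statistic),
                df_between = df_b, df_within = df_w,
                p_value = unname(ow$p.value), degenerate = FALSE)
  }
  class(res) <- "anova_result"
  res
}

#' @export
print.anova_result <- function(x, ...) {
  if (x$degenerate && is.na(x$f_stat)) {
    cat("one-way ANOVA: degenerate (all observations identical), F undefined\n")
  } else {
    cat(sprintf("one-way ANOVA: F(%g, %g) = %.4g, p = %.4g%s\n",
                x$df_between, x$df_within, x$f_stat, x$p_value,
                if (x$degenerate) " [degenerate: zero within-group variance]"
                else ""))
  }
  invisible(x)
}

#' Significance tier of a p-value
#'
#' The star convention used alongside the group comparisons:
#' `***` for p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05,
#' `ns` otherwise.
#'
#' @param p P-value(s).
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi <= 0.001) "***" else if (pi <= 0.01) "**"
    else if (pi <= 0.05) "*" else "ns"
  }, character(1))
}

#' Morphology-class fractions per condition
#'
#' @param sections Morphometry data frame.
#' @param class_set Declared class vocabulary (see
#'   [morphology_classes()]); an observed label outside it is an error.
#' @return Data frame with one row per condition x class: `condition`,
#'   `class`, `count`, `fraction`, `n_sections`. Fractions sum to 1 within
#'   each condition.
#' @export
morphology_fractions <- function(sections, class_set = morphology_classes("two")) {
  check_sections(sections)
  bad <- setdiff(unique(sections$morphology_class), class_set)
  if (length(bad))
    stop_bad_arg("unknown morphology class label(s): ",
                 paste(bad, collapse = ", "))
  per <- split(sections, sections$condition)
  out <- do.call(rbind, lapply(per, function(s) {
    counts <- table(factor(s$morphology_class, levels = class_set))
    data.frame(condition = s$condition[1L],
               class = class_set,
               count = as.integer(counts),
               fraction = as.numeric(counts) / nrow(s),
               n_sections = nrow(s),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Junction and septum accounting between two conditions
#'
#' On 2D EM sections a septum's connection to the inner boundary membrane
#' is easily mistaken for a crista junction, so raw junction prevalence
#' overstates true CJ prevalence where septa are common. This accounting
#' separates the two: `prevalence` is the fraction of sections bearing at
#' least one junction of any kind, `septum_frac` the fraction of
#' junction-bearing sections whose junctions are septum-associated, and
#' `cristae_cj_prevalence = prevalence * (1 - septum_frac)` the prevalence
#' attributable to genuine cristae CJs. `relative_decrease` is
#' `1 - cristae_cj_prevalence_test / cristae_cj_prevalence_ctrl`.
#'
#' By default a junction-bearing section counts as septum-associated from
#' its `has_septum` flag (section-level accounting); `mode = "junction"`
#' instead weights by the per-junction counts
#' (`n_septum_junctions / (n_cj + n_septum_junctions)`).
#'
#' @param sections_ctrl,sections_test Morphometry data frames for the
#'   control and test condition.
#' @param mode `"section"` (default) or `"junction"`.
#' @return Object of class `junction_accounting`; see
#'   [junction_septa_from_rates()] for the fields.
#' @export
junction_septa_accounting <- function(sections_ctrl, sections_test,
                                      mode = c("section", "junction")) {
  mode <- match.arg(mode)
  check_sections(sections_ctrl); check_sections(sections_test)
  if (!nrow(sections_ctrl) || !nrow(sections_test))
    stop_bad_arg("both section tables must be nonempty")
  one <- function(s) {
    n_j <- s$n_cj + s$n_septum_junctions
    bearing <- n_j > 0L
    prevalence <- mean(bearing)
    septum_frac <- if (!any(bearing)) 0 else if (mode == "section")
      mean(s$has_septum[bearing] | s$n_septum_junctions[bearing] > 0L)
    else
      mean(s$n_septum_junctions[bearing] / n_j[bearing])
    c(prevalence = prevalence, septum_frac = septum_frac)
  }
  a <- one(sections_ctrl); b <- one(sections_test)
  junction_septa_from_rates(a[["prevalence"]], a[["septum_frac"]],
                            b[["prevalence"]], b[["septum_frac"]])
}

#' Junction/septum accounting from summary proportions
#'
#' The arithmetic core of [junction_septa_accounting()], usable directly
#' on published summary proportions. For example, junction prevalences of
#' 0.60 (control) and 0.36 (test) with septum fractions 0.15 and 0.50 give
#' cristae-CJ prevalences 0.51 and 0.18 and a relative decrease of about
#' 0.647.
#'
#' @param prevalence_ctrl,prevalence_test Fraction of sections bearing at
#'   least one junction.
#' @param septum_frac_ctrl,septum_frac_test Fraction of junction-bearing
#'   sections that are septum-associated.
#' @return Object of class `junction_accounting`: list with the four
#'   inputs, `cristae_cj_prevalence_ctrl`, `cristae_cj_prevalence_test`,
#'   `relative_decrease`, and `undefined` (`TRUE` with
#'   `relative_decrease = NA` when the control cristae-CJ prevalence is
#'   zero).
#' @export
junction_septa_from_rates <- function(prevalence_ctrl, septum_frac_ctrl,
                                      prevalence_test, septum_frac_test) {
  for (p in list(prevalence_ctrl, septum_frac_ctrl,
                 prevalence_test, septum_frac_test))
    if (!is_scalar_num(p) || p < 0 || p > 1)
      stop_bad_arg("all proportions must lie in [0, 1]")
  cc <- prevalence_ctrl * (1 - septum_frac_ctrl)
  ct <- prevalence_test * (1 - septum_frac_test)
  undefined <- cc == 0
  res <- list(prevalence_ctrl = prevalence_ctrl,
              prevalence_test = prevalence_test,
              septum_frac_ctrl = septum_frac_ctrl,
              septum_frac_test = septum_frac_test,
              cristae_cj_prevalence_ctrl = cc,
              cristae_cj_prevalence_test = ct,
              relative_decrease = if (undefined) NA_real_ else 1 - ct / cc,
              undefined = undefined)
  class(res) <- "junction_accounting"
  res
}

#' @export
print.junction_accounting <- function(x, ...) {
  cat(sprintf("junction prevalence: ctrl %.3f, test %.3f\n",
              x$prevalence_ctrl, x$prevalence_test))
  cat(sprintf("septum-associated fraction: ctrl %.3f, test %.3f\n",
              x$septum_frac_ctrl, x$septum_frac_test))
  cat(sprintf("cristae-CJ prevalence: ctrl %.3f, test %.3f\n",
              x$cristae_cj_prevalence_ctrl, x$cristae_cj_prevalence_test))
  if (x$undefined)
    cat("relative decrease: undefined (control cristae-CJ prevalence is 0)\n")
  else
    cat(sprintf("relative decrease of cristae CJs: %.3f\n",
                x$relative_decrease))
  invisible(x)
}

check_sections <- function(sections) {
  if (!is.data.frame(sections))
    stop_bad_arg("'sections' must be a data frame")
  need <- c("condition", "om_length_um", "n_cj", "cj_diameters_nm",
            "morphology_class", "has_septum", "n_septum_junctions")
  missing_cols <- setdiff(need, names(sections))
  if (length(missing_cols))
    stop_bad_arg("section table lacks columns: ",
                 paste(missing_cols, collapse = ", "))
  invisible(sections)
}
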