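# Generator for per-section EM morphometry tables.

morphology_two_way <- c("wild_type", "aberrant")

# The detailed (eight-way) crista-morphology vocabulary used by the
# two-tier classification. The fine classes are package-chosen descriptive
# labels for phenotypes commonly distinguished on EM sections; callers may
# declare their own class set in morphology_fractions().
morphology_eight_way <- c("lamellar_ordered", "lamellar_disordered",
                          "tubular", "onion_like", "septate",
                          "vesicular", "cristae_free", "mixed")

#' Declared crista-morphology class sets
#'
#' @param set `"two"` for the coarse \{wild_type, aberrant\} split or
#'   `"eight"` for the detailed phenotype vocabulary.
#' @return Character vector of class labels.
#' @export
morphology_classes <- function(set = c("two", "eight")) {
  switch(match.arg(set), two = morphology_two_way,
         eight = morphology_eight_way)
}

#' Generative preset for one experimental condition's EM morphometry
#'
#' Bundles the distributional parameters from which
#' [simulate_morphometry()] draws per-section annotations: the
#' crista-junction (CJ) rate per micrometre of outer membrane (OM), the CJ
#' diameter distribution, and the junction/septum probabilities.
#'
#' `p_section_has_junction` is optional. When `NA` (default) junction
#' presence is implied by the Poisson CJ counts, and the pooled CJ rate of
#' the simulated table converges to `cj_per_um`. When set, the fraction of
#' junction-bearing sections is controlled explicitly (used to emulate
#' prevalence scenarios) and `cj_per_um` only shapes counts within
#' junction-bearing sections.
#'
#' @param condition_label Condition name written into the table.
#' @param cj_per_um Mean CJ count per micrometre OM (>= 0).
#' @param diameter_mean_nm,diameter_sd_nm CJ diameter distribution
#'   (normal, truncated at 0 by resampling), nanometres.
#' @param p_section_has_junction Probability that a section bears at least
#'   one junction of any kind, or `NA` (see above).
#' @param p_septum_given_junction Probability that a junction-bearing
#'   section's junctions are septum-associated.
#' @param p_aberrant Probability of the `"aberrant"` morphology class.
#' @return An object of class `morphometry_preset`.
#' @export
morphometry_preset <- function(condition_label, cj_per_um,
                               diameter_mean_nm, diameter_sd_nm,
                               p_section_has_junction = NA_real_,
                               p_septum_given_junction = 0.15,
                               p_aberrant = 0.5) {
  stopifnot(is.character(condition_label), length(condition_label) == 1L)
  if (!is_scalar_num(cj_per_um) || cj_per_um < 0)
    stop_bad_arg("'cj_per_um' must be >= 0")
  if (!is_scalar_num(diameter_mean_nm) || diameter_mean_nm <= 0)
    stop_bad_arg("'diameter_mean_nm' must be > 0")
  if (!is_scalar_num(diameter_sd_nm) || diameter_sd_nm < 0)
    stop_bad_arg("'diameter_sd_nm' must be >= 0")
  for (p in list(p_septum_given_junction, p_aberrant))
    if (!is_scalar_num(p) || p < 0 || p > 1)
      stop_bad_arg("probabilities must lie in [0, 1]")
  if (!is.na(p_section_has_junction) &&
      (p_section_has_junction < 0 || p_section_has_junction > 1))
    stop_bad_arg("'p_section_has_junction' must lie in [0, 1] or be NA")
  structure(list(condition_label = condition_label, cj_per_um = cj_per_um,
                 diameter_mean_nm = diameter_mean_nm,
                 diameter_sd_nm = diameter_sd_nm,
                 p_section_has_junction = p_section_has_junction,
                 p_septum_given_junction = p_septum_given_junction,
                 p_aberrant = p_aberrant),
            class = "morphometry_preset")
}

#' Built-in condition presets
#'
#' Presets whose diameter means and junction/septum probabilities follow
#' the condition phenotypes reported for MICOS-knockout HeLa lines: CJ
#' diameters around 20 nm in wild type, enlarged to about 28 nm without
#' Mic10 and about 32 nm without Mic60; junction prevalences of roughly
#' 60% vs 36% of sections and septum association of roughly 15% vs 50% in
#' Mic10-KO cells with and without OPA1. CJ rates and diameter spreads are
#' not reported per condition and are package defaults.
#'
#' @return Named list of [morphometry_preset()] objects: `wild_type`,
#'   `mic10_ko`, `mic60_ko`, `mic10_ko_ctrl`, `mic10_ko_opa1_kd`.
#' @export
morphometry_presets <- function() {
  list(
    wild_type = morphometry_preset("wild_type", cj_per_um = 1.2,
                                   diameter_mean_nm = 20, diameter_sd_nm = 4,
                                   p_septum_given_junction = 0.05,
                                   p_aberrant = 0.1),
    mic10_ko = morphometry_preset("mic10_ko", cj_per_um = 0.35,
                                  diameter_mean_nm = 28, diameter_sd_nm = 6,
                                  p_septum_given_junction = 0.15,
                                  p_aberrant = 0.9),
    mic60_ko = morphometry_preset("mic60_ko", cj_per_um = 0.05,
                                  diameter_mean_nm = 32, diameter_sd_nm = 8,
                                  p_septum_given_junction = 0.3,
                                  p_aberrant = 0.95),
    mic10_ko_ctrl = morphometry_preset("mic10_ko_ctrl", cj_per_um = 0.35,
                                       diameter_mean_nm = 28,
                                       diameter_sd_nm = 6,
                                       p_section_has_junction = 0.60,
                                       p_septum_given_junction = 0.15,
                                       p_aberrant = 0.9),
    mic10_ko_opa1_kd = morphometry_preset("mic10_ko_opa1_kd",
                                          cj_per_um = 0.35,
                                          diameter_mean_nm = 28,
                                          diameter_sd_nm = 6,
                                          p_section_has_junction = 0.36,
                                          p_septum_given_junction = 0.50,
                                          p_aberrant = 0.9))
}

# Normal truncated at 0 by resampling (not clipping), so the recovered
# mean is unbiased for mean >> sd.
rnorm_trunc0 <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate per-section EM morphometry annotations
#'
#' Per section: the OM length is drawn log-normal (default median 3 um);
#' the CJ count is Poisson with mean `cj_per_um * om_length`; CJ diameters
#' are normal, truncated at 0 by resampling; the septum flag is Bernoulli
#' for junction-bearing sections; the morphology class is Bernoulli over
#' \{wild_type, aberrant\}. See [morphometry_preset()] for the
#' junction-prevalence variant used when `p_section_has_junction` is set.
#'
#' @param preset A [morphometry_preset()].
#' @param n_sections Number of sections (> 0).
#' @param seed Integer seed.
#' @param om_meanlog,om_sdlog Log-normal parameters of the OM length in
#'   micrometres (defaults give median 3 um).
#' @return Data frame with columns `section_id`, `condition`,
#'   `om_length_um`, `n_cj`, `cj_diameters_nm` (semicolon-separated),
#'   `morphology_class`, `has_septum`, `n_septum_junctions`.
#' @export
#' @examples
#' tab <- simulate_morphometry(morphometry_presets()$mic10_ko, 20, seed = 4)
#' head(tab)
simulate_morphometry <- function(preset, n_sections, seed,
                                 om_meanlog = log(3), om_sdlog = 0.4) {
  stopifnot(inherits(preset, "morphometry_preset"))
  if (!is_count(n_sections) || n_sections < 1)
    stop_bad_arg("'n_sections' must be a count > 0")
  n_sections <- as.integer(n_sections)

  with_seed(child_seed(seed, 4L), {
    om <- stats::rlnorm(n_sections, om_meanlog, om_sdlog)
    p_has <- preset$p_section_has_junction

    if (is.na(p_has)) {
      # plain Poisson CJ counts; septum junctions are drawn on top so the
      # pooled n_cj / om ratio stays an unbiased estimate of cj_per_um
      n_cj <- stats::rpois(n_sections, preset$cj_per_um * om)
      bearing <- n_cj > 0L
      septum <- bearing & stats::runif(n_sections) < preset$p_septum_given_junction
      n_sept <- ifelse(septum, pmax(1L, stats::rbinom(n_sections, 2L, 0.5)), 0L)
    } else {
      bearing <- stats::runif(n_sections) < p_has
      septum <- bearing & stats::runif(n_sections) < preset$p_septum_given_junction
      n_cj <- integer(n_sections)
      n_sept <- integer(n_sections)
      lam <- preset$cj_per_um * om
      draw <- stats::rpois(n_sections, lam)
      n_cj[bearing & !septum] <- pmax(1L, draw[bearing & !septum])
      n_sept[septum] <- pmax(1L, stats::rbinom(n_sections, 2L, 0.5))[septum]
      n_cj[septum] <- draw[septum] # may be zero: a purely septate section
    }

    diam <- vapply(seq_len(n_sections), function(i) {
      paste(formatC(rnorm_trunc0(n_cj[i], preset$diameter_mean_nm,
                                 preset$diameter_sd_nm),
                    digits = 6, format = "fg"), collapse = ";")
    }, character(1))
    cls <- ifelse(stats::runif(n_sections) < preset$p_aberrant,
                  "aberrant", "wild_type")

    data.frame(section_id = sprintf("%s_%04d", preset$condition_label,
                                    seq_len(n_sections)),
               condition = preset$condition_label,
               om_length_um = om,
               n_cj = as.integer(n_cj),
               cj_diameters_nm = diam,
               morphology_class = cls,
               has_septum = as.logical(septum),
               n_septum_junctions = as.integer(n_sept),
               stringsAsFactors = FALSE)
  })
}

#' Parse the semicolon-separated diameter column
#'
#' @param x Character vector as stored in the `cj_diameters_nm` column.
#' @return List of numeric vectors (empty where no diameter was measured).
#' @export
parse_diameters <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(v) {
    v <- v[nzchar(v)]
    as.numeric(v)
  })
}

#' Read / write per-section morphometry tables
#'
#' CSV with header `section_id,condition,om_length_um,n_cj,
#' cj_diameters_nm,morphology_class,has_septum,n_septum_junctions`, the
#' diameter list semicolon-separated within its field.
#'
#' @param path CSV file path.
#' @return `read_sections`: the section data frame.
#' @export
read_sections <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(cj_diameters_nm = "character"))
  need <- c("section_id", "condition", "om_length_um", "n_cj",
            "cj_diameters_nm", "morphology_class", "has_septum",
            "n_septum_junctions")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop_bad_arg("section CSV lacks columns: ",
                 paste(missing_cols, collapse = ", "))
  tab$has_septum <- as.logical(tab$has_septum)
  tab$cj_diameters_nm[is.na(tab$cj_diameters_nm)] <- ""
  tab
}

#' @rdname read_sections
#' @param sections Section data frame.
#' @export
write_sections <- function(sections, path) {
  stopifnot(is.data.frame(sections))
  utils::write.csv(sections, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
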