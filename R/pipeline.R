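# Configuration, provenance, and the pipeline driver behind the CLI.

pipeline_commands <- c("simulate-image", "simulate-minflux",
                       "simulate-morphometry", "cluster-metric",
                       "minflux-filter", "morphometry", "line-profile")

cq_error <- function(class, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

config_error <- function(...) cq_error("cq_config_error", ...)
input_error <- function(...) cq_error("cq_input_error", ...)

#' Assemble a pipeline run configuration
#'
#' @param command One of `simulate-image`, `simulate-minflux`,
#'   `simulate-morphometry`, `cluster-metric`, `minflux-filter`,
#'   `morphometry`, `line-profile`.
#' @param params Named list of command-specific parameters (validated by
#'   [run_pipeline()]).
#' @param seed Root seed for every random draw of the run.
#' @param output_dir Directory for all artifacts (created if needed).
#' @param log_level `"quiet"`, `"info"`, or `"debug"`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(command, params = list(), seed = 1L,
                       output_dir = "cristaequant-out",
                       log_level = c("info", "quiet", "debug")) {
  if (!is.character(command) || length(command) != 1L ||
      !command %in% pipeline_commands)
    config_error("unknown command '", command, "'; expected one of: ",
                 paste(pipeline_commands, collapse = ", "))
  if (!is.list(params)) config_error("'params' must be a named list")
  if (length(params) && (is.null(names(params)) || any(!nzchar(names(params)))))
    config_error("'params' entries must all be named")
  if (!is_scalar_num(seed)) config_error("'seed' must be a finite scalar")
  log_level <- match.arg(log_level)
  structure(list(command = command, params = params,
                 seed = as.integer(seed), output_dir = output_dir,
                 log_level = log_level),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The YAML file has top-level keys `command`, `seed`, `output_dir`,
#' `log_level`, and `params`; unknown top-level keys are rejected so that
#' typos fail loudly instead of being ignored. Writing then reading a
#' config reproduces it exactly.
#'
#' @param path YAML file path.
#' @return `read_run_config`: a [run_config()] object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) input_error("no such config file: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("command", "params", "seed", "output_dir", "log_level")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    config_error("unknown config key(s): ", paste(extra, collapse = ", "))
  if (is.null(raw$command)) config_error("config lacks 'command'")
  run_config(command = raw$command,
             params = raw$params %||% list(),
             seed = raw$seed %||% 1L,
             output_dir = raw$output_dir %||% "cristaequant-out",
             log_level = raw$log_level %||% "info")
}

#' @rdname read_run_config
#' @param config A [run_config()] object.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

pipe_log <- function(config, level, ...) {
  levels <- c(quiet = 0L, info = 1L, debug = 2L)
  if (levels[[config$log_level]] >= levels[[level]])
    message("[cristaequant] ", ...)
}

#' Execute one pipeline command
#'
#' Dispatches on `config$command`, runs
#' simulate / analyze / summarize as appropriate, and writes all
#' artifacts plus a `provenance.json` (command, parameters, seed, config
#' checksum, package and R versions) into `config$output_dir`. With a
#' fixed seed the run is idempotent: re-running overwrites the artifacts
#' with byte-identical content.
#'
#' Parameter validation problems raise a condition of class
#' `cq_config_error`; missing input files raise `cq_input_error`. The
#' command-line wrapper maps these to distinct exit codes (2 and 3).
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  out <- function(f) file.path(config$output_dir, f)
  pipe_log(config, "info", "running ", config$command,
           " (seed ", config$seed, ")")

  artifacts <- switch(config$command,
    "simulate-image" = {
      check_params(p, character(0),
                   setdiff(names(formals(scene_params)), "seed"))
      sp <- do.call(scene_params, c(p, list(seed = config$seed)))
      truth <- simulate_scene(sp)
      img <- render_image(truth)
      write_image(img, out("image.tif"))
      utils::write.csv(truth$emitters, out("emitters.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(truth$centers, out("centers.csv"),
                       row.names = FALSE, quote = FALSE)
      c(image = out("image.tif"), emitters = out("emitters.csv"),
        centers = out("centers.csv"))
    },
    "simulate-minflux" = {
      check_params(p, c("n_valid", "n_artifact"),
                   c("p0_max", "r_relative_max_nm", "count_rate_max_khz",
                     "photons_min", "sbr_min"))
      fp_args <- p[intersect(names(p),
                             c("p0_max", "r_relative_max_nm",
                               "count_rate_max_khz", "photons_min",
                               "sbr_min"))]
      ev <- simulate_minflux_events(p$n_valid, p$n_artifact,
                                    seed = config$seed,
                                    params = do.call(filter_params, fp_args))
      write_events(ev, out("events.csv"))
      c(events = out("events.csv"))
    },
    "simulate-morphometry" = {
      check_params(p, "n_sections",
                   c("preset", "condition_label", "cj_per_um",
                     "diameter_mean_nm", "diameter_sd_nm",
                     "p_section_has_junction", "p_septum_given_junction",
                     "p_aberrant", "om_meanlog", "om_sdlog"))
      preset <- if (!is.null(p$preset)) {
        pr <- morphometry_presets()[[p$preset]]
        if (is.null(pr)) config_error("unknown preset '", p$preset, "'")
        pr
      } else {
        do.call(morphometry_preset,
                p[intersect(names(p),
                            c("condition_label", "cj_per_um",
                              "diameter_mean_nm", "diameter_sd_nm",
                              "p_section_has_junction",
                              "p_septum_given_junction", "p_aberrant"))])
      }
      tab <- simulate_morphometry(preset, p$n_sections, seed = config$seed,
                                  om_meanlog = p$om_meanlog %||% log(3),
                                  om_sdlog = p$om_sdlog %||% 0.4)
      write_sections(tab, out("sections.csv"))
      c(sections = out("sections.csv"))
    },
    "cluster-metric" = {
      check_params(p, "input",
                   c("pixel_size_nm", "log_fwhm_nm", "threshold_fraction",
                     "single_cluster_area_cutoff_um2", "write_label_map"))
      cmp_args <- p[intersect(names(p),
                              c("log_fwhm_nm", "threshold_fraction",
                                "single_cluster_area_cutoff_um2"))]
      cmp <- do.call(cluster_metric_params, cmp_args)
      rows <- lapply(unlist(p$input), function(path) {
        if (!file.exists(path)) input_error("no such image: ", path)
        img <- read_image(path, pixel_size_nm = p$pixel_size_nm)
        res <- cluster_metric(img, cmp)
        if (isTRUE(p$write_label_map)) {
          seg <- attr(res, "segmentation")
          lab <- image2d(seg$label_map + 0, pixel_size_nm = seg$pixel_size_nm)
          write_image(lab, out(paste0(tools::file_path_sans_ext(basename(path)),
                                      "_labels.tif")))
        }
        data.frame(image_id = basename(path),
                   n_segments = res$n_segments,
                   n_single = res$n_single_clusters,
                   area_single_um2 = res$area_single_um2,
                   area_total_um2 = res$area_total_um2,
                   clustered_fraction = res$clustered_fraction)
      })
      utils::write.csv(do.call(rbind, rows), out("cluster_metric.csv"),
                       row.names = FALSE, quote = FALSE)
      c(cluster_metric = out("cluster_metric.csv"))
    },
    "minflux-filter" = {
      check_params(p, "input",
                   c("p0_max", "r_relative_max_nm", "count_rate_max_khz",
                     "photons_min", "sbr_min"))
      if (!file.exists(p$input)) input_error("no such event table: ", p$input)
      fp <- do.call(filter_params,
                    p[intersect(names(p),
                                c("p0_max", "r_relative_max_nm",
                                  "count_rate_max_khz", "photons_min",
                                  "sbr_min"))])
      rep <- filter_events(read_events(p$input), fp)
      write_events(rep$kept, out("kept.csv"))
      write_events(rep$removed, out("removed.csv"))
      jsonlite::write_json(list(n_input = rep$n_input,
                                n_kept = nrow(rep$kept),
                                n_removed = nrow(rep$removed),
                                counts = as.list(rep$counts),
                                params = unclass(fp)),
                           out("summary.json"), auto_unbox = TRUE,
                           digits = NA)
      c(kept = out("kept.csv"), removed = out("removed.csv"),
        summary = out("summary.json"))
    },
    "morphometry" = {
      check_params(p, "input", c("classes", "condition_ctrl",
                                 "condition_test"))
      if (!file.exists(p$input)) input_error("no such section table: ", p$input)
      tab <- read_sections(p$input)
      class_set <- morphology_classes(p$classes %||% "two")
      freq <- cj_frequency(tab)
      frac <- morphology_fractions(tab, class_set)
      utils::write.csv(as.data.frame(freq), out("cj_frequency.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(frac, out("morphology_fractions.csv"),
                       row.names = FALSE, quote = FALSE)
      conds <- unique(tab$condition)
      diam <- lapply(conds, function(cc) {
        s <- diameter_summary(tab, cc)
        s[c("mean_nm", "sd_nm", "n")]
      })
      names(diam) <- conds
      summ <- list(diameters = diam)
      if (!is.null(p$condition_ctrl) && !is.null(p$condition_test)) {
        acc <- junction_septa_accounting(
          tab[tab$condition == p$condition_ctrl, , drop = FALSE],
          tab[tab$condition == p$condition_test, , drop = FALSE])
        summ$junction_accounting <- unclass(acc)
      }
      jsonlite::write_json(summ, out("morphometry_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      c(cj_frequency = out("cj_frequency.csv"),
        morphology_fractions = out("morphology_fractions.csv"),
        summary = out("morphometry_summary.json"))
    },
    "line-profile" = {
      check_params(p, c("input", "lines"),
                   c("pixel_size_nm", "n_samples", "normalization"))
      if (!file.exists(p$input)) input_error("no such image: ", p$input)
      img <- read_image(p$input, pixel_size_nm = p$pixel_size_nm)
      pr <- mean_line_profile(img, p$lines,
                              n_samples = p$n_samples %||% 100L,
                              normalization = p$normalization %||% "minmax")
      utils::write.csv(data.frame(position_nm = pr$position_nm,
                                  mean = pr$mean, sd = pr$sd),
                       out("line_profile.csv"), row.names = FALSE,
                       quote = FALSE)
      c(line_profile = out("line_profile.csv"))
    })

  cfg_path <- out("config.yaml")
  write_run_config(config, cfg_path)
  jsonlite::write_json(
    list(command = config$command, seed = config$seed,
         config_md5 = unname(tools::md5sum(cfg_path)),
         package = "cristaequant",
         package_version = as.character(utils::packageVersion("cristaequant")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         artifacts = as.list(artifacts)),
    out("provenance.json"), auto_unbox = TRUE, digits = NA)
  pipe_log(config, "info", "wrote ", length(artifacts),
           " artifact(s) to ", config$output_dir)
  invisible(c(artifacts, config = cfg_path, provenance = out("provenance.json")))
}

check_params <- function(p, required, optional) {
  miss <- setdiff(required, names(p))
  if (length(miss))
    config_error("missing required parameter(s): ",
                 paste(miss, collapse = ", "))
  extra <- setdiff(names(p), c(required, optional))
  if (length(extra))
    config_error("unknown parameter(s): ", paste(extra, collapse = ", "))
  invisible(p)
}
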