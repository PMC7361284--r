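#' Parameters for a synthetic labeling scene on a mitochondrial tubule
#'
#' Describes a point pattern of fluorophore emitters on the surface of a
#' cylinder (the mitochondrial tubule) that is then orthographically
#' projected onto the image plane. Four spatial models cover the
#' arrangements seen for MICOS proteins in super-resolution recordings:
#'
#' * `"scattered_puncta"` — compact clusters placed uniformly over the
#'   tubule surface (the scattered-cluster phenotype).
#' * `"stripe_pattern"` — cluster centers confined to circumferential rings
#'   spaced `stripe_period_nm` along the axis, giving the stripe pattern
#'   perpendicular to the tubule axis typical of wild-type cells.
#' * `"opposite_bands"` — cluster centers confined to two diametrically
#'   opposed longitudinal strips, the two-sided distribution seen when the
#'   Mic10 subcomplex is absent. A strip is defined in projection: the
#'   absolute transverse offset of a cluster center lies within
#'   `band_halfwidth_nm` of the tubule edge (`tubule_radius_nm`).
#' * `"extended_assemblies"` — contiguous circumferential arcs of emitters
#'   spanning `assembly_arc_deg`, emulating extended ring- and rib-like
#'   assemblies.
#'
#' @param model One of `"scattered_puncta"`, `"stripe_pattern"`,
#'   `"opposite_bands"`, `"extended_assemblies"`.
#' @param tubule_length_um Tubule length in micrometres (> 0).
#' @param tubule_radius_nm Tubule radius in nanometres (> 0).
#' @param n_clusters Number of clusters (or arcs), >= 0.
#' @param assembly_arc_deg Arc extent in degrees for
#'   `"extended_assemblies"`.
#' @param band_halfwidth_nm Strip half-width in nanometres for
#'   `"opposite_bands"`.
#' @param stripe_period_nm Ring spacing in nanometres for
#'   `"stripe_pattern"`.
#' @param psf_fwhm_nm Effective point-spread-function FWHM of the simulated
#'   microscope in nanometres (>= pixel size; ~50-70 nm for 2D STED).
#' @param pixel_size_nm Physical pixel size in nanometres, in \[5, 50\]
#'   (STED recordings use 15-25 nm).
#' @param photons_per_emitter Mean photons contributed by one emitter.
#' @param background_rate Mean background counts per pixel.
#' @param emitters_per_cluster Mean number of emitters per punctate cluster
#'   (Poisson, at least one emitter is always placed).
#' @param cluster_sigma_nm Spread (s.d., on-surface) of emitters around a
#'   punctate cluster center, nanometres.
#' @param assembly_spacing_nm Arc-length spacing of emitters along an
#'   extended assembly, nanometres.
#' @param seed Integer seed; with fixed parameters it makes every
#'   downstream draw reproducible.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(model = c("scattered_puncta", "stripe_pattern",
                                   "opposite_bands", "extended_assemblies"),
                         tubule_length_um = 3,
                         tubule_radius_nm = 150,
                         n_clusters = 30,
                         assembly_arc_deg = 180,
                         band_halfwidth_nm = 50,
                         stripe_period_nm = 150,
                         psf_fwhm_nm = 60,
                         pixel_size_nm = 20,
                         photons_per_emitter = 500,
                         background_rate = 2,
                         emitters_per_cluster = 8,
                         cluster_sigma_nm = 15,
                         assembly_spacing_nm = 5,
                         seed = 1L) {
  model <- match.arg(model)
  for (nm in c("tubule_length_um", "tubule_radius_nm", "psf_fwhm_nm",
               "pixel_size_nm", "photons_per_emitter",
               "emitters_per_cluster", "cluster_sigma_nm",
               "assembly_spacing_nm")) {
    v <- get(nm)
    if (!is_scalar_num(v) || v <= 0)
      stop_bad_arg("'", nm, "' must be a positive scalar")
  }
  if (!is_count(n_clusters)) stop_bad_arg("'n_clusters' must be a count >= 0")
  if (!is_scalar_num(background_rate) || background_rate < 0)
    stop_bad_arg("'background_rate' must be >= 0")
  if (pixel_size_nm < 5 || pixel_size_nm > 50)
    stop_bad_arg("'pixel_size_nm' must lie in [5, 50] nm")
  if (psf_fwhm_nm < pixel_size_nm)
    stop_bad_arg("'psf_fwhm_nm' must be at least one pixel (",
                 pixel_size_nm, " nm)")
  if (!is_scalar_num(seed)) stop_bad_arg("'seed' must be a finite scalar")
  structure(list(model = model,
                 tubule_length_um = tubule_length_um,
                 tubule_radius_nm = tubule_radius_nm,
                 n_clusters = as.integer(n_clusters),
                 assembly_arc_deg = assembly_arc_deg,
                 band_halfwidth_nm = band_halfwidth_nm,
                 stripe_period_nm = stripe_period_nm,
                 psf_fwhm_nm = psf_fwhm_nm,
                 pixel_size_nm = pixel_size_nm,
                 photons_per_emitter = photons_per_emitter,
                 background_rate = background_rate,
                 emitters_per_cluster = emitters_per_cluster,
                 cluster_sigma_nm = cluster_sigma_nm,
                 assembly_spacing_nm = assembly_spacing_nm,
                 seed = as.integer(seed)),
            class = "scene_params")
}

#' @export
print.scene_params <- function(x, ...) {
  cat(sprintf("<scene_params> model=%s, %g um x r=%g nm, %d clusters, seed=%d\n",
              x$model, x$tubule_length_um, x$tubule_radius_nm,
              x$n_clusters, x$seed))
  invisible(x)
}

# Margin of free image around the tubule footprint, so that no PSF tail is
# clipped at the border.
scene_margin_nm <- function(params) 3 * params$psf_fwhm_nm

scene_image_size_nm <- function(params) {
  c(width_nm  = params$tubule_length_um * 1000 + 2 * scene_margin_nm(params),
    height_nm = 2 * params$tubule_radius_nm + 2 * scene_margin_nm(params))
}

#' Simulate emitter positions on a tubule surface
#'
#' Places cluster centers on the cylinder surface according to the spatial
#' model in `params`, scatters emitters around each center, and
#' orthographically projects everything onto the image plane (the cylinder
#' axis lies along image x; the projected transverse offset of a surface
#' point at azimuth theta is `tubule_radius_nm * sin(theta)`; no depth
#' attenuation is applied). Positions are returned in image-frame
#' nanometres (origin at the top-left image corner); the tubule axis sits
#' at `margin + radius` from the top.
#'
#' @param params A [scene_params()] object.
#' @return An object of class `scene_truth`: a list with `emitters`
#'   (data frame `x_nm`, `y_nm`, `cluster_id`), `centers` (cluster centers,
#'   with signed transverse offset `y_offset_nm` in the tubule frame),
#'   `params`, and the image extent `image_nm`.
#' @export
#' @examples
#' truth <- simulate_scene(scene_params("opposite_bands", seed = 7))
#' range(abs(truth$centers$y_offset_nm))
simulate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  if (params$model == "extended_assemblies" && params$assembly_arc_deg <= 0)
    stop_bad_arg("'assembly_arc_deg' must be > 0 for extended_assemblies")
  if (params$model == "stripe_pattern" && params$stripe_period_nm <= 0)
    stop_bad_arg("'stripe_period_nm' must be > 0 for stripe_pattern")
  if (params$model == "opposite_bands" &&
      (params$band_halfwidth_nm <= 0 ||
       params$band_halfwidth_nm > params$tubule_radius_nm))
    stop_bad_arg("'band_halfwidth_nm' must lie in (0, tubule_radius_nm]")

  L <- params$tubule_length_um * 1000
  r <- params$tubule_radius_nm
  margin <- scene_margin_nm(params)
  nc <- params$n_clusters

  empty <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      cluster_id = integer(0))
  if (nc == 0L) {
    return(structure(list(emitters = empty,
                          centers = data.frame(x_nm = numeric(0),
                                               y_offset_nm = numeric(0),
                                               cluster_id = integer(0)),
                          params = params,
                          margin_nm = margin,
                          image_nm = scene_image_size_nm(params)),
                     class = "scene_truth"))
  }

  with_seed(child_seed(params$seed, 1L), {
    centers <- switch(params$model,
      scattered_puncta = data.frame(
        x_nm = stats::runif(nc, 0, L),
        theta = stats::runif(nc, -pi, pi)),
      stripe_pattern = {
        p <- params$stripe_period_nm
        rings <- seq(p / 2, L, by = p)
        if (!length(rings)) rings <- L / 2
        data.frame(x_nm = sample(rings, nc, replace = TRUE),
                   theta = stats::runif(nc, -pi, pi))
      },
      opposite_bands = {
        hw <- params$band_halfwidth_nm
        # strips in projection: |r sin(theta)| in [r - hw, r]
        y <- stats::runif(nc, r - hw, r) * sample(c(-1, 1), nc, replace = TRUE)
        data.frame(x_nm = stats::runif(nc, 0, L), theta = asin(y / r))
      },
      extended_assemblies = data.frame(
        x_nm = stats::runif(nc, 0, L),
        theta = stats::runif(nc, -pi, pi)))
    centers$cluster_id <- seq_len(nc)

    if (params$model == "extended_assemblies") {
      half_arc <- params$assembly_arc_deg / 2 * pi / 180
      em <- do.call(rbind, lapply(seq_len(nc), function(i) {
        s <- seq(-half_arc, half_arc,
                 by = params$assembly_spacing_nm / r)
        th <- centers$theta[i] + s
        # rib-like: small axial spread gives the arc a physical width
        x <- centers$x_nm[i] + stats::rnorm(length(s), 0, 20)
        data.frame(x_nm = pmin(pmax(x, 0), L),
                   theta = th, cluster_id = i)
      }))
    } else {
      n_per <- pmax(1L, stats::rpois(nc, params$emitters_per_cluster))
      id <- rep(seq_len(nc), n_per)
      # scatter on the surface: axial and arc-length displacements
      x <- centers$x_nm[id] + stats::rnorm(length(id), 0, params$cluster_sigma_nm)
      th <- centers$theta[id] +
        stats::rnorm(length(id), 0, params$cluster_sigma_nm / r)
      em <- data.frame(x_nm = pmin(pmax(x, 0), L), theta = th,
                       cluster_id = id)
    }

    emitters <- data.frame(
      x_nm = em$x_nm + margin,
      y_nm = r * sin(em$theta) + r + margin,
      cluster_id = em$cluster_id)
    structure(list(emitters = emitters,
                   centers = data.frame(x_nm = centers$x_nm,
                                        y_offset_nm = r * sin(centers$theta),
                                        cluster_id = centers$cluster_id),
                   params = params,
                   margin_nm = margin,
                   image_nm = scene_image_size_nm(params)),
              class = "scene_truth")
  })
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %s: %d emitters in %d clusters, image %g x %g nm\n",
              x$params$model, nrow(x$emitters),
              length(unique(x$emitters$cluster_id)),
              x$image_nm[["width_nm"]], x$image_nm[["height_nm"]]))
  invisible(x)
}
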