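# Shared in-code fixtures.

gaussian_blob_image <- function(nr, nc, centers_px, fwhm_nm, px_nm,
                                amplitude = 100) {
  sigma <- fwhm_to_sigma(fwhm_nm) / px_nm
  m <- matrix(0, nr, nc)
  for (ctr in centers_px) {
    m <- m + amplitude * outer(
      exp(-((seq_len(nr) - ctr[1])^2) / (2 * sigma^2)),
      exp(-((seq_len(nc) - ctr[2])^2) / (2 * sigma^2)))
  }
  image2d(m, pixel_size_nm = px_nm)
}

section_row <- function(condition = "c", om = 1, n_cj = 0, diam = "",
                        class = "wild_type", septum = FALSE, n_sept = 0L,
                        id = "s1") {
  data.frame(section_id = id, condition = condition, om_length_um = om,
             n_cj = as.integer(n_cj), cj_diameters_nm = diam,
             morphology_class = class, has_septum = septum,
             n_septum_junctions = as.integer(n_sept),
             stringsAsFactors = FALSE)
}
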