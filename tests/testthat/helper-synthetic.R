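# In-code fixtures: analytic radial profiles and small cohorts built from
# the forward model, so tests need no stored data.

# roi_profile following the point-source surface model on the standard
# 0.0006 m offset grid (31 offsets spans a = 0 .. 0.018 m).
make_profile <- function(d, q, Te = 22, h0 = 8.77, pixel_size = 6e-4,
                         n_offsets = 31L, noise_sd = 0, background = Te,
                         label = "unknown", id = NULL) {
  offs <- (seq_len(n_offsets) - 1L) * pixel_size
  temp <- background + q / (4 * pi * h0 * (d^2 + offs^2))
  if (noise_sd > 0) temp <- temp + stats::rnorm(n_offsets, 0, noise_sd)
  structure(list(offsets = offs, mean_temp = temp,
                 n_directions = rep(4L, n_offsets), Tmax = temp[1L],
                 hotspot = list(row = 0L, col = 0L), Te = Te,
                 pixel_size = pixel_size, id = id, label = label),
            class = "roi_profile")
}

# fast labeled profile cohort with class-disjoint (d, q): deep/weak
# normals, shallow/strong abnormals (peak elevation above background)
make_profile_cohort <- function(n_normal, n_abnormal, seed,
                                noise_sd = 0.04, Te = 22, h0 = 8.77) {
  set.seed(seed)
  labels <- rep(c("normal", "abnormal"), c(n_normal, n_abnormal))
  lapply(seq_along(labels), function(i) {
    ab <- labels[i] == "abnormal"
    d <- runif(1, if (ab) 0.003 else 0.010, if (ab) 0.008 else 0.016)
    peak <- runif(1, if (ab) 3 else 0.6, if (ab) 8 else 1.5)
    q <- 4 * pi * h0 * d^2 * peak
    make_profile(d, q, Te = Te, h0 = h0, noise_sd = noise_sd,
                 background = runif(1, 30, 34), label = labels[i],
                 id = sprintf("p%03d", i))
  })
}
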