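# Shared fixture builders. Everything is generated in code at test time;
# populations use the package's own simulator at the default calibrated
# brightness and noise unless a test needs otherwise.

quiet_pentamer_params <- function(n = 100, noise = 0, ...) {
  simulation_params(multiple_weights = 1, n_complexes = n,
                    noise_sd_pe = noise, ...)
}

# A multi-acquisition track table from a mixture of oligomer multiples.
mixture_track_table <- function(n_acq = 6, n_per_acq = 50,
                                weights = c(0.6, 0.3, 0.1),
                                config = acquisition_config(), ...) {
  do.call(rbind, lapply(seq_len(n_acq), function(a) {
    pop <- simulate_population(
      simulation_params(multiple_weights = weights, n_complexes = n_per_acq,
                        ...),
      config)
    do.call(rbind, lapply(seq_along(pop$traces), function(i) {
      tr <- pop$traces[[i]]
      data.frame(acquisition = a, track_id = i,
                 frame = seq_along(tr) - 1L, intensity = tr)
    }))
  }))
}

# Independent enumeration of aperture pixel offsets (the test-side oracle
# for disc/annulus membership; intentionally not the package's code path).
enumerate_aperture <- function(radius_in, radius_out) {
  g <- expand.grid(dr = -radius_out:radius_out, dc = -radius_out:radius_out)
  d2 <- g$dr^2 + g$dc^2
  list(disc = g[d2 <= radius_in^2, ],
       annulus = g[d2 > radius_in^2 & d2 <= radius_out^2, ])
}
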