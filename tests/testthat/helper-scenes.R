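# shared fixtures: all scenes are generated in code, never stored

# a noiseless intensity model: deterministic class values, no pixel noise
exact_intensity <- function() {
  intensity_model(noise_sd = 0, dapi = c(0.5, 0), neg = c(0.2, 0),
                  pos = c(0.4, 0))
}

# small colony used by most image tests (~167 nuclei at default density)
small_spec <- function(seed = 1, colony_radius = 120, ...) {
  scene_spec(colony_radius = colony_radius, seed = seed, ...)
}

# three-ring germ-layer colony at full size
three_ring_spec <- function(central, seed = 1, middle = 220, outer = Inf) {
  scene_spec(seed = seed, channel_models = list(
    SOX2 = chan_central_disc(central),
    BRA = chan_ring(central, middle),
    CDX2 = chan_ring(middle, outer)))
}

# run the nuclear pipeline and classify one marker
classified_cells <- function(image, channel) {
  tab <- segment_colony_cells(image)
  tab <- normalize_to_dapi(tab, channel)
  classify_positive(tab, channel,
                    fit_binary_threshold(tab[[paste0("norm_", channel)]]))
}

# nearest-neighbour match of estimated points to truth points (um)
match_dist <- function(est, truth) {
  vapply(seq_len(nrow(est)), function(i)
    sqrt(min((truth[, 1] - est[i, 1])^2 + (truth[, 2] - est[i, 2])^2)),
    numeric(1))
}
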