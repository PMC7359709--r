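# Small phantoms shared across tests; kept short so the suite stays fast.
# Length 6 mm at the default 0.1171875 mm spacing is ~51 slices.

small_phantom <- function(mode = "lumen_opaque", length = 6, baseline = 0,
                          amplitude = 0, noise_sigma = 0, seed = 1, ...) {
  generate_phantom(phantom_spec(
    contrast_mode = mode, length = length,
    thrombus = list(baseline = baseline, amplitude = amplitude, period = 9),
    noise_sigma = noise_sigma, rng_seed = seed, ...))
}

mode_contrast <- function(mode) {
  lv <- default_intensities(mode)
  switch(mode,
    lumen_opaque = min(lv["lumen"] - lv["wall"], lv["lumen"] - lv["thrombus"]),
    thrombus_opaque = min(lv["thrombus"] - lv["wall"], lv["thrombus"] - lv["lumen"]),
    four_material = min(lv["thrombus"] - lv["wall"], lv["wall"] - lv["shrink"],
                        lv["wall"] - lv["lumen"], lv["shrink"] - lv["background"]))
}
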