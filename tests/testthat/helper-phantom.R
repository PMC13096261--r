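# Compact 48^3 abdomen used by the unit tests: one kidney (pelvis +
# extraparenchymal cyst), liver with one lesion. Same kinetics and imaging
# model as the default phantom, just smaller.
mini_spec <- function(seed = 1L, ...) {
  grid <- voxel_grid(c(48, 48, 48), 4)
  organs <- list(
    phantom_organ("liver",               c(130, 70, 100), c(40, 32, 36)),
    phantom_organ("lesion_1",            c(138, 64, 112), 12),
    phantom_organ("kidney_parenchyma_R", c(60, 120, 96),  c(28, 24, 40)),
    phantom_organ("renal_pelvis_R",      c(72, 120, 96),  c(13, 11, 20)),
    phantom_organ("cyst_extra_R",        c(40, 132, 120), 9)
  )
  phantom_spec(grid, organs, seed = seed, ...)
}

# built once per test run; anatomy/series are deterministic (noise off)
mini_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- mini_spec()
      anat <- build_anatomy(spec)
      cache <<- list(spec = spec, anatomy = anat,
                     series = make_activity_series(anat, spec))
    }
    cache
  }
})
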