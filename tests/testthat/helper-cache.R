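# Heavy fixtures (phantoms, full segmentations) are generated once per test
# run and shared across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

ph_default <- function() cached("ph_default", generate_phantom(phantom_spec()))
ph_fused <- function() cached("ph_fused",
                              generate_phantom(phantom_spec(fused = TRUE)))
ph_notch <- function() cached("ph_notch",
                              generate_phantom(phantom_spec(pleural_notch = TRUE)))
seg_default <- function() cached("seg_default", segment_lungs(ph_default()$volume))
seg_fused <- function() cached("seg_fused", segment_lungs(ph_fused()$volume))
seg_notch <- function() cached("seg_notch", segment_lungs(ph_notch()$volume))

# 100 standardized nodule-centred training patches, strong contrast, no noise
patch_dataset <- function() cached("patches", {
  phs <- generate_dataset(10, phantom_spec(),
                          diameter_sampler = function(k) runif(k, 8, 25),
                          seed = 7)
  patches <- list()
  for (p in phs) {
    st <- volume_stats(p$volume)
    vz <- standardize_intensity(p$volume, st$mean, st$std)
    rec <- p$truth$records
    ctr <- round(as.numeric(world_to_voxel(
      p$volume, c(rec$coordZ[1], rec$coordY[1], rec$coordX[1]))))
    lab <- array(as.numeric(p$truth$nodule_mask), dim(p$truth$nodule_mask))
    set.seed(1000 + length(patches))
    for (j in 1:10) {
      jit <- pmin(pmax(ctr + sample(-4:4, 3, replace = TRUE), 0),
                  dim(vz$voxels) - 1)
      patches[[length(patches) + 1]] <-
        extract_patch(vz, jit, label = lab,
                      pad_value = (-1000 - st$mean) / st$std)
    }
  }
  patches
})

# tiny single-slice patches for cheap 2-D training smoke tests
tiny_patch_set <- function(n = 20, size = 16, seed = 3) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    vox <- array(rnorm(size * size, -0.5, 0.2), c(1, size, size))
    cy <- sample(5:(size - 4), 1); cx <- sample(5:(size - 4), 1)
    g <- expand.grid(y = 1:size, x = 1:size)
    blob <- matrix((g$y - cy)^2 + (g$x - cx)^2 <= 9, size, size)
    vox[1, , ][blob] <- vox[1, , ][blob] + 2
    list(voxels = vox, label = array(blob * 1, c(1, size, size)))
  })
}
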