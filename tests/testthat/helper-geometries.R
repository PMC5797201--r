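# Toy scanner geometries used across the suite.

toy_geom <- function(n_rings = 8L, n_blocks_tx = 7L, crystals_per_block = 4L,
                     gaps_per_block = 0L, n_radial_bins = 20L,
                     max_ring_diff = n_rings - 1L, ring_diameter = 200,
                     ring_pitch = 4, ...) {
  build_geometry(list(n_rings = n_rings, ring_pitch = ring_pitch,
                      ring_diameter = ring_diameter, n_blocks_tx = n_blocks_tx,
                      crystals_per_block = crystals_per_block,
                      gaps_per_block = gaps_per_block,
                      n_radial_bins = n_radial_bins,
                      max_ring_diff = max_ring_diff, span = 1L, ...))
}

# 4-ring geometry small enough for brute-force comparisons
tiny_geom <- function(...) {
  toy_geom(n_rings = 4L, n_blocks_tx = 4L, crystals_per_block = 4L,
           n_radial_bins = 14L, max_ring_diff = 3L, ring_diameter = 180, ...)
}
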