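# Shared fixtures: phantoms are generated in code, never stored.

# sub-voxel lattice offset: avoids the measure-zero grid-aligned placement
# whose voxelization errors are systematically worst
ph_off <- function(sp) c(0.37, -0.21, 0.43) * sp

ph_spec <- function(r0 = 10, d0 = 13, g = d0 / 6, sp = 1, ...) {
  phantom_spec(r0_mm = r0, d0_gy = d0, g_gy_per_mm = g, spacing_mm = sp,
               center_mm = ph_off(sp), ...)
}

uniform_grid <- function(value, n = 8, sp = 1) {
  dose_grid(array(value, dim = rep(n, 3)), spacing = rep(sp, 3))
}

# square ROI: side mm x side mm centred at (cx, cy) on the given planes
square_roi <- function(side, planes, cx = 0, cy = 0, name = "Square") {
  h <- side / 2
  contours <- lapply(planes, function(z) {
    list(z = z, xy = cbind(cx + c(-h, h, h, -h), cy + c(-h, -h, h, h)))
  })
  structure(list(name = name, number = 1L, contours = contours),
            class = "roi")
}

# dose grid from a radial profile function d(r), centred off-lattice
radial_grid <- function(dose_of_r, extent, sp) {
  ctr <- ph_off(sp)
  n <- floor(extent / sp) + 1L
  ax <- lapply(1:3, function(a) (seq_len(n) - (n + 1) / 2) * sp)
  r <- sqrt(outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, `+`),
                  (ax[[3]] - ctr[3])^2, `+`))
  dose_grid(array(dose_of_r(r), dim = rep(n, 3)), spacing = rep(sp, 3),
            origin = c(ax[[1]][1], ax[[2]][1], ax[[3]][1]))
}
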