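# shared fixtures: small grids and closed-form oracles

small_grid <- function(n = 48, vs = 4.42) grid_spec(n, vs)

# closed-form value at distance d from the center of a uniform unit ball of
# radius R convolved with an isotropic Gaussian of sd sigma
blurred_ball <- function(d, R, sigma) {
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  d <- pmax(d, 1e-9)
  0.5 * (erf((R - d) / (sqrt(2) * sigma)) + erf((R + d) / (sqrt(2) * sigma))) -
    sigma / (d * sqrt(2 * pi)) *
      (exp(-(R - d)^2 / (2 * sigma^2)) - exp(-(R + d)^2 / (2 * sigma^2)))
}

# expected VOI-mean recovery of a hot sphere over a warm background, from
# the blurred-ball closed form evaluated at the voxel centers of the mask
oracle_sphere_recovery <- function(grid, center, R, sigma, bg, hot) {
  cx <- grid$origin[1] + (seq_len(grid$dim[1]) - 0.5) * grid$voxel_size[1]
  cy <- grid$origin[2] + (seq_len(grid$dim[2]) - 0.5) * grid$voxel_size[2]
  cz <- grid$origin[3] + (seq_len(grid$dim[3]) - 0.5) * grid$voxel_size[3]
  pts <- expand.grid(x = cx, y = cy, z = cz)
  d <- sqrt((pts$x - center[1])^2 + (pts$y - center[2])^2 +
              (pts$z - center[3])^2)
  inside <- d <= R
  f <- blurred_ball(d[inside], R, sigma)
  (bg + (hot - bg) * mean(f)) / hot
}

# a tiny Jaszczak-like phantom: four spheres in a small warm cylinder
mini_jaszczak <- function(bg = 25.9, ratio = 9.9) {
  mk <- function(v, ctr) {
    compartment_spec(sprintf("s%g", v), "sphere", center = ctr,
                     nominal_volume = v,
                     activity_concentration = bg * ratio)
  }
  phantom_spec(
    background = compartment_spec("bg", "cylinder",
                                  dimensions = list(diameter = 180,
                                                    height = 150),
                                  activity_concentration = bg),
    compartments = list(mk(1, c(45, 0, 0)), mk(2, c(0, 45, 0)),
                        mk(4, c(-45, 0, 0)), mk(8, c(0, -45, 0)),
                        mk(16, c(0, 0, 45))),
    insert_to_background_ratio = ratio
  )
}

uniform_image <- function(value, grid, units = "kBq/ml") {
  voxel_image(array(value, grid$dim), grid$voxel_size, grid$origin, units)
}
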