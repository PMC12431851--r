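# shared fixtures, built in code

# the 900 Pa/um step substrate: 4/40 kPa stripes, 40 um transition
step_pattern <- function(extent = c(1140, 400)) {
  substrate_pattern("step_stripes", E_soft = 4000, E_stiff = 40000,
                    stripe_width_stiff = 100, stripe_width_soft = 200,
                    transition_width = 40, extent = extent)
}

# the 36 Pa/um shallow gradient: 4-40 kPa over 1000 um
shallow_pattern <- function(extent = c(1000, 1000)) {
  substrate_pattern("linear_gradient", E_soft = 4000, E_stiff = 40000,
                    transition_width = 1000, extent = extent)
}

# equal stripe widths so that uniform seeding gives index 1
equal_stripe_pattern <- function(extent = c(760, 400)) {
  substrate_pattern("step_stripes", E_soft = 4000, E_stiff = 40000,
                    stripe_width_stiff = 150, stripe_width_soft = 150,
                    transition_width = 40, extent = extent)
}

uniform_map <- function(E = 4000, n = 9, pitch = 5) {
  stiffness_map(matrix(E, n, n), pitch = pitch)
}

# single straight monotone track along a given direction
straight_track <- function(id = "s1", n = 10, dt = 60, ux = 1, uy = 0) {
  data.frame(track_id = id, t = (0:(n - 1)) * dt,
             x = (0:(n - 1)) * ux, y = (0:(n - 1)) * uy)
}

rotate_tracks <- function(tracks, deg) {
  th <- deg * pi / 180
  out <- tracks
  out$x <- tracks$x * cos(th) - tracks$y * sin(th)
  out$y <- tracks$x * sin(th) + tracks$y * cos(th)
  out
}
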