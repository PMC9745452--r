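# Shared fixtures: all synthetic, built in code at test time.

DESIGN_40_TIMES <- c(10, 20, 30, 40, 50, 60)
DESIGN_50_TIMES <- c(5, 10, 20, 30, 40, 50, 60)

one_phase_mean <- function(t, ymax, k) ymax * (1 - exp(-k * t))

# noiseless endpoint values on a grid, n replicates per time
noiseless_points <- function(times, ymax, k, n = 1) {
  tt <- rep(times, each = n)
  list(times = tt, values = one_phase_mean(tt, ymax, k))
}

# one valid records row, with overridable fields
make_record <- function(power_w = 40, cf_g = 10, time_s = 30,
                        li_drop_ohm = 20, depth_a_mm = 4, diam_b_mm = 7,
                        depth_c_mm = 2, surf_d_mm = 6, steam_pop = 0,
                        replicate = 1) {
  data.frame(power_w = power_w, cf_g = cf_g, time_s = time_s,
             li_drop_ohm = li_drop_ohm, depth_a_mm = depth_a_mm,
             diam_b_mm = diam_b_mm, depth_c_mm = depth_c_mm,
             surf_d_mm = surf_d_mm, steam_pop = steam_pop,
             replicate = replicate)
}

# small single-setting config for fast pipeline tests
mini_config <- function(noiseless = TRUE, n_per_cell = 3) {
  experiment_config(times = list(`40` = DESIGN_40_TIMES),
                    forces = c(10), n_per_cell = n_per_cell,
                    noiseless = noiseless)
}
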