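# Shared fixtures built in code.

# Park parameters with moderate step sizes, suited to kinetic round trips.
kinetic_params <- function() park_params(A_L = 1, b_L = 10, k_H = 2.5,
                                         k_a = 0.05, n = 4)

# Strongly clustering parameters (hand-evaluation example set).
cluster_params <- function() park_params(A_L = 1, b_L = 10, k_H = 5,
                                         k_a = 0.5, n = 4)

# A 5-bin mesopore distribution spanning 4-32 nm with its matching
# isothermal step program (bin edges on consecutive hold temperatures).
mesopore_fixture <- function(fracs = c(10, 15, 20, 25, 10),
                             free = 100 - sum(fracs),
                             total_mg = 4) {
  edges <- exp(seq(log(4e-9), log(32e-9), length.out = length(fracs) + 1))
  Tm <- melting_temperature_for_diameter(edges)
  list(
    dist = pore_size_distribution(
      data.frame(d_low_m = edges[-length(edges)], d_high_m = edges[-1],
                 water_fraction_pct = fracs),
      free_water_fraction_pct = free,
      total_freezing_water_mg = total_mg),
    program = step_program(temp_C = c(-30, Tm - 273.15, 2),
                           duration_s = 600),
    edges = edges)
}

# Quantified sections at a programmed wall level.
quantified_sections <- function(level, n, seed0, noise_sd = 5) {
  lapply(seq_len(n), function(i)
    quantify_stack(gen_image_stack(
      target_levels = c(wall = level, background = 0),
      noise_sd = noise_sd, seed = seed0 + i)))
}
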