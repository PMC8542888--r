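# Shared fixtures: all data built in code at test time.

# Homogeneous single-layer sand column with round numbers:
# depth 0.2 m, porosity 0.4, pore velocity 1e-3 m/s, bulk density 1.6 kg/L.
# With dispersivity 0.005 m, D = 5.001e-6 m^2/s (column Peclet = 40).
hom_column <- function(alpha = 0.005, conditioning_time = 0) {
  filter_column(
    list(column_layer("sand", mass = 3.2, bulk_density = 1.6,
                      porosity = 0.4, f_sand = 1)),
    diameter = sqrt(4 * 0.01 / pi),  # A = 0.01 m^2
    flow_rate = 0.24,                # q_D = 4e-4 m/s, v = 1e-3 m/s
    dispersivity = alpha,
    conditioning_time = conditioning_time
  )
}

hom_v <- 1e-3
hom_L <- 0.2
hom_D <- 0.005 * 1e-3 + 1e-9

# K_s that produces retardation R in the homogeneous column
# (rho_b/theta = 4 L/kg^-1 => K_s = (R-1)/4)
hom_ks_for_R <- function(R) (R - 1) * 0.4 / 1.6

# A complete batch dataset covering every compound-sorbent pair at one
# loading (10 mg in 50 mL = 200 mg/L), with deterministic ce values.
full_grid_dataset <- function(compounds = paste0("c", 1:3),
                              sorbents = paste0("s", 1:4),
                              replicates = 2) {
  grid <- expand.grid(compound = compounds, sorbent = sorbents,
                      rep = seq_len(replicates), stringsAsFactors = FALSE)
  ce <- 0.2 + 0.5 * (seq_len(nrow(grid)) %% 5) / 10
  batch_dataset(grid$compound, grid$sorbent, c0 = 1, ce = ce,
                volume = 0.05, mass = 1e-5)
}

write_batch_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# interpolate a curve's relative concentration at given volumes
curve_at <- function(curve, volumes) {
  stats::approx(curve$cum_volume, curve$c_over_cin, xout = volumes,
                rule = 2)$y
}
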