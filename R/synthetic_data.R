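#' Ground truth for a synthetic batch sorption experiment
#'
#' Defaults mirror the screening design: 50 mL of solution at 1 mg/L
#' per compound, sorbent masses 5, 10, 25, 50, 100 and 250 mg,
#' triplicates, and multiplicative lognormal noise with a 5\%
#' coefficient of variation on the equilibrium concentration.
#'
#' @param isotherm an [isotherm_model()] describing the true
#'   equilibrium relation.
#' @param c0 initial aqueous concentration (mg/L).
#' @param volume solution volume (L).
#' @param masses sorbent masses (kg).
#' @param noise_cv relative SD of the multiplicative noise on `Ce`.
#' @param replicates replicate vials per mass.
#' @param seed integer seed.
#' @return a `batch_truth` list.
#' @export
batch_truth <- function(isotherm, c0 = 1, volume = 0.05,
                        masses = c(5, 10, 25, 50, 100, 250) * 1e-6,
                        noise_cv = 0.05, replicates = 3L, seed = 1L) {
  stopifnot(inherits(isotherm, "isotherm_model"),
            c0 > 0, volume > 0, all(masses > 0), noise_cv >= 0,
            replicates >= 1L)
  structure(list(isotherm = isotherm, c0 = c0, volume = volume,
                 masses = masses, noise_cv = noise_cv,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "batch_truth")
}

# lognormal multiplier with mean 1 and coefficient of variation cv
lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic batch sorption dataset
#'
#' For each sorbent mass and replicate, the implicit equilibrium mass
#' balance `C0*V = Ce*V + q(Ce)*m` is solved for `Ce` by bisection on
#' the monotone isotherm, and multiplicative lognormal measurement
#' noise is applied to `Ce` (truncated at the physical bounds 0 and
#' `C0`). A pure function of `(truth, seed)`: the same truth always
#' yields the same dataset.
#'
#' @param truth a [batch_truth()].
#' @param compound,sorbent identifiers stamped on the records.
#' @return a `batch_dataset` (see [batch_dataset()]).
#' @export
generate_batch <- function(truth, compound = "CPD", sorbent = "BC") {
  stopifnot(inherits(truth, "batch_truth"))
  model <- truth$isotherm
  c0 <- truth$c0; V <- truth$volume
  upper0 <- c0
  if (model$kind == "bet") {
    cs <- model$parameters$c_s
    upper0 <- min(c0, cs * (1 - 1e-9))
  }
  ce_true <- vapply(truth$masses, function(m) {
    f <- function(ce) ce * V + eval_isotherm(model, ce) * m - c0 * V
    if (f(upper0) < 0) {
      if (upper0 < c0)
        stop("no equilibrium in (0, C0]: isotherm diverges below C0 ",
             "but cannot hold the supplied mass balance", call. = FALSE)
      return(upper0)  # q(C0) <= 0 only when no sorption at all
    }
    stats::uniroot(f, c(0, upper0), tol = 1e-14)$root
  }, numeric(1L))
  n <- length(truth$masses) * truth$replicates
  noise <- withr::with_seed(truth$seed, lognormal_noise(n, truth$noise_cv))
  ce_obs <- pmin(pmax(rep(ce_true, each = truth$replicates) * noise, 0), c0)
  batch_dataset(
    compound = rep(compound, n), sorbent = rep(sorbent, n),
    c0 = rep(c0, n), ce = ce_obs,
    volume = rep(V, n), mass = rep(truth$masses, each = truth$replicates)
  )
}

#' Generate a synthetic salinity series
#'
#' Produces a K_bc series over NaCl molarities in which the
#' coefficient changes by a fixed factor per decade of molarity.
#' A factor below 1 emulates the ion-competition decline seen for the
#' tetracyclines and enrofloxacin; a factor above 1 emulates the
#' salting-out increase of the more hydrophobic compounds. The 0 M
#' level, which has no decade position, is placed one decade below the
#' lowest positive level; `base_kbc` is the value at the lowest
#' positive level.
#'
#' @param base_kbc K_bc (L/kg) at the lowest positive molarity.
#' @param factor_per_decade multiplicative change per tenfold molarity
#'   increase (> 0).
#' @param levels NaCl molarities (mol/L), strictly increasing; default
#'   `c(0, 0.01, 0.1, 1)`.
#' @param noise_cv relative SD of multiplicative noise; default 0.
#' @param seed integer seed.
#' @param compound,sorbent identifiers.
#' @return a `salinity_series` list: `compound`, `sorbent`, `levels`,
#'   `kbc`, `trend` (from [classify_salinity_trend()]).
#' @export
generate_salinity_series <- function(base_kbc, factor_per_decade,
                                     levels = c(0, 0.01, 0.1, 1),
                                     noise_cv = 0, seed = 1L,
                                     compound = "CPD", sorbent = "BC") {
  if (base_kbc <= 0) stop("base_kbc must be positive", call. = FALSE)
  if (factor_per_decade <= 0)
    stop("factor_per_decade must be positive", call. = FALSE)
  if (any(diff(levels) <= 0))
    stop("levels must be strictly increasing", call. = FALSE)
  ref <- min(levels[levels > 0])
  decades <- ifelse(levels > 0, log10(levels / ref), -1)
  kbc <- base_kbc * factor_per_decade^decades
  noise <- withr::with_seed(seed, lognormal_noise(length(kbc), noise_cv))
  kbc <- kbc * noise
  series <- list(compound = compound, sorbent = sorbent,
                 levels = levels, kbc = kbc)
  series$trend <- classify_salinity_trend(series)
  structure(series, class = "salinity_series")
}

#' Generate a K_bc matrix with planted sorbent blocks
#'
#' Builds a compounds-by-sorbents coefficient matrix in which the
#' sorbents fall into blocks of distinct overall sorption strength
#' (e.g. strong 2000 L/kg vs weak 200 L/kg), each cell further
#' multiplied by a shared per-compound affinity profile and lognormal
#' noise. Used to verify that profile clustering recovers known
#' structure.
#'
#' @param n_compounds,n_sorbents matrix dimensions (defaults 7 and 10,
#'   the screening design).
#' @param block_means mean K_bc (L/kg) per sorbent block; its length
#'   sets the number of blocks (default `c(2000, 200)`).
#' @param block_sizes sorbents per block; default splits evenly.
#' @param compound_spread SD (log10 units) of the per-compound
#'   affinity multipliers; default 0.3.
#' @param noise_cv per-cell lognormal noise CV; default 0.1.
#' @param seed integer seed.
#' @return a `kbc_matrix` with an extra `truth` attribute giving the
#'   planted block label of each sorbent.
#' @export
generate_planted_kbc <- function(n_compounds = 7L, n_sorbents = 10L,
                                 block_means = c(2000, 200),
                                 block_sizes = NULL, compound_spread = 0.3,
                                 noise_cv = 0.1, seed = 1L) {
  n_blocks <- length(block_means)
  if (is.null(block_sizes)) {
    base <- n_sorbents %/% n_blocks
    block_sizes <- rep(base, n_blocks)
    block_sizes[1L] <- block_sizes[1L] + n_sorbents - sum(block_sizes)
  }
  stopifnot(sum(block_sizes) == n_sorbents, all(block_means > 0))
  labels <- rep(seq_len(n_blocks), block_sizes)
  compounds <- sprintf("compound%02d", seq_len(n_compounds))
  sorbents <- sprintf("sorbent%02d", seq_len(n_sorbents))
  values <- withr::with_seed(seed, {
    profile <- 10^stats::rnorm(n_compounds, 0, compound_spread)
    base <- outer(profile, block_means[labels])
    noise <- matrix(lognormal_noise(n_compounds * n_sorbents, noise_cv),
                    n_compounds, n_sorbents)
    base * noise
  })
  dimnames(values) <- list(compounds, sorbents)
  structure(list(values = values,
                 sd = matrix(NA_real_, n_compounds, n_sorbents,
                             dimnames = dimnames(values)),
                 n = matrix(1L, n_compounds, n_sorbents,
                            dimnames = dimnames(values)),
                 censored = matrix(FALSE, n_compounds, n_sorbents,
                                   dimnames = dimnames(values)),
                 loading = 200, loq = 0.001,
                 truth = stats::setNames(labels, sorbents)),
            class = "kbc_matrix")
}

#' Ground truth for a synthetic filtration experiment
#'
#' Defaults mirror the pilot design: the layered bucket filter (see
#' [default_filter_column()]), 1 L/min flow and 24 one-litre grab
#' samples.
#'
#' @param params true [solute_transport_params()].
#' @param column the filter; default [default_filter_column()].
#' @param sample_volumes cumulative volumes (L) of the grab samples.
#' @param noise_cv relative SD of multiplicative noise on sample
#'   concentrations; default 0.05.
#' @param seed integer seed.
#' @return a `column_truth` list.
#' @export
column_truth <- function(params, column = default_filter_column(),
                         sample_volumes = 1:24, noise_cv = 0.05,
                         seed = 1L) {
  stopifnot(inherits(params, "solute_transport_params"),
            inherits(column, "filter_column"))
  structure(list(params = params, column = column,
                 sample_volumes = sample_volumes,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "column_truth")
}

#' Generate a synthetic observed breakthrough curve
#'
#' Simulates the truth with [simulate_breakthrough()], integrates the
#' effluent over each inter-sample interval to mimic composite grab
#' samples of finite volume, and applies multiplicative lognormal
#' noise. A pure function of `(truth, seed)`.
#'
#' @param truth a [column_truth()].
#' @param c_in influent concentration (mg/L); default 1. Zero influent
#'   yields an identically zero curve.
#' @param n_cells,courant solver resolution.
#' @return an observed-style [breakthrough_curve()] with
#'   `sampling = "composite"`.
#' @export
generate_breakthrough <- function(truth, c_in = 1, n_cells = 200L,
                                  courant = 0.9) {
  stopifnot(inherits(truth, "column_truth"))
  if (c_in == 0) {
    return(breakthrough_curve(truth$sample_volumes,
                              rep(0, length(truth$sample_volumes)),
                              provenance = "observed",
                              sampling = "composite"))
  }
  sim <- simulate_breakthrough(truth$column, truth$params, c_in = c_in,
                               target_volume = max(truth$sample_volumes),
                               n_cells = n_cells, courant = courant)
  rel <- resample_effluent(sim, truth$sample_volumes,
                           truth$column$flow_rate, c_in, "composite")
  noise <- withr::with_seed(truth$seed,
                            lognormal_noise(length(rel), truth$noise_cv))
  breakthrough_curve(truth$sample_volumes, pmax(rel * noise, 0),
                     provenance = "observed", sampling = "composite")
}
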