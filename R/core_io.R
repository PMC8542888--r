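#' Read a batch sorption table
#'
#' Reads a CSV of batch equilibrium sorption observations and validates
#' it into a `batch_dataset`. Mandatory columns are `compound`,
#' `sorbent`, `c0_mg_L`, `ce_mg_L`, `volume_L` and `mass_kg`; optional
#' columns `nacl_M` (default 0), `ph` (default `NA`) and `contact_h`
#' (default 24, the contact time at which equilibrium was judged
#' reached) are filled with defaults when absent.
#'
#' Each record represents one vial: a sorbent mass `m` (kg) shaken in a
#' volume `V` (L) of solution spiked at `c0` (mg/L), with equilibrium
#' aqueous concentration `ce` (mg/L). Records where `ce` exceeds
#' `c0 * (1 + ce_tolerance)` violate mass balance beyond analytical
#' scatter and are rejected with the offending row index.
#'
#' @param path path to a CSV file (comma-separated, `.` decimal, header
#'   row mandatory).
#' @param ce_tolerance relative tolerance for `ce <= c0`; default 0.05
#'   absorbs triplicate quantification scatter near zero removal.
#' @return a `batch_dataset`: a `data.frame` with columns `compound`,
#'   `sorbent`, `c0`, `ce`, `volume`, `mass`, `nacl`, `ph`, `contact`
#'   and the derived `loading` (sorbent loading, mg/L).
#' @seealso [batch_dataset()], [write_batch_table()], [sorption_point()]
#' @export
read_batch_table <- function(path, ce_tolerance = 0.05) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("compound", "sorbent", "c0_mg_L", "ce_mg_L", "volume_L", "mass_kg")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("batch table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num_cols <- c("c0_mg_L", "ce_mg_L", "volume_L", "mass_kg")
  opt_cols <- intersect(c("nacl_M", "ph", "contact_h"), names(df))
  for (col in c(num_cols, opt_cols)) {
    v <- df[[col]]
    coerced <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(coerced))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                   v[bad[1L]], col, bad[1L]), call. = FALSE)
    }
    df[[col]] <- coerced
  }
  if (nrow(df) == 0L) {
    warning("batch table '", path, "' has a valid header but no records",
            call. = FALSE)
  }
  batch_dataset(
    compound = as.character(df$compound),
    sorbent  = as.character(df$sorbent),
    c0       = df$c0_mg_L,
    ce       = df$ce_mg_L,
    volume   = df$volume_L,
    mass     = df$mass_kg,
    nacl     = if ("nacl_M" %in% names(df)) df$nacl_M else NULL,
    ph       = if ("ph" %in% names(df)) df$ph else NULL,
    contact  = if ("contact_h" %in% names(df)) df$contact_h else NULL,
    ce_tolerance = ce_tolerance
  )
}

#' Construct a validated batch sorption dataset
#'
#' Programmatic constructor behind [read_batch_table()]. Vectors are
#' recycled to the length of `compound`. Internal units: concentrations
#' mg/L, volumes L, masses kg, so K values derived downstream are L/kg.
#'
#' @param compound,sorbent identifiers.
#' @param c0,ce initial and equilibrium aqueous concentrations (mg/L).
#' @param volume solution volume (L). @param mass sorbent mass (kg).
#' @param nacl NaCl molarity (mol/L); `NULL` or `NA` becomes 0.
#' @param ph initial pH; optional.
#' @param contact contact time (h); `NULL` or `NA` becomes 24.
#' @param ce_tolerance relative tolerance for `ce <= c0`.
#' @return a `batch_dataset` data frame (see [read_batch_table()]).
#' @export
batch_dataset <- function(compound, sorbent, c0, ce, volume, mass,
                          nacl = NULL, ph = NULL, contact = NULL,
                          ce_tolerance = 0.05) {
  n <- length(compound)
  if (is.null(nacl)) nacl <- rep(0, n)
  if (is.null(ph)) ph <- rep(NA_real_, n)
  if (is.null(contact)) contact <- rep(24, n)
  nacl[is.na(nacl)] <- 0
  contact[is.na(contact)] <- 24
  df <- data.frame(
    compound = as.character(compound), sorbent = as.character(sorbent),
    c0 = as.numeric(c0), ce = as.numeric(ce),
    volume = as.numeric(volume), mass = as.numeric(mass),
    nacl = as.numeric(nacl), ph = as.numeric(ph),
    contact = as.numeric(contact),
    stringsAsFactors = FALSE
  )
  if (nrow(df) > 0L) {
    check_pos <- function(x, nm) {
      bad <- which(!is.finite(df[[x]]) | df[[x]] <= 0)
      if (length(bad) > 0L)
        stop(sprintf("%s must be positive and finite (row %d)", nm, bad[1L]),
             call. = FALSE)
    }
    check_pos("volume", "solution volume")
    check_pos("mass", "sorbent mass")
    bad <- which(!is.finite(df$c0) | df$c0 < 0 | !is.finite(df$ce) | df$ce < 0)
    if (length(bad) > 0L)
      stop(sprintf("concentrations must be non-negative (row %d)", bad[1L]),
           call. = FALSE)
    bad <- which(df$ce > df$c0 * (1 + ce_tolerance))
    if (length(bad) > 0L)
      stop(sprintf(
        "equilibrium concentration exceeds initial concentration beyond the %g%% tolerance (row %d: ce=%g > c0=%g)",
        100 * ce_tolerance, bad[1L], df$ce[bad[1L]], df$c0[bad[1L]]),
        call. = FALSE)
    bad <- which(!is.finite(df$nacl) | df$nacl < 0)
    if (length(bad) > 0L)
      stop(sprintf("NaCl molarity must be non-negative (row %d)", bad[1L]),
           call. = FALSE)
    bad <- which(!is.na(df$ph) & (df$ph < 0 | df$ph > 14))
    if (length(bad) > 0L)
      stop(sprintf("pH out of [0, 14] (row %d)", bad[1L]), call. = FALSE)
  }
  df$loading <- df$mass / df$volume * 1e6
  class(df) <- c("batch_dataset", "data.frame")
  df
}

#' Write a batch dataset back to CSV
#'
#' Inverse of [read_batch_table()]; a write-then-read round trip
#' reproduces all numeric fields to full precision.
#'
#' @param dataset a `batch_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_batch_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "batch_dataset"))
  out <- data.frame(
    compound = dataset$compound, sorbent = dataset$sorbent,
    c0_mg_L = dataset$c0, ce_mg_L = dataset$ce,
    volume_L = dataset$volume, mass_kg = dataset$mass,
    nacl_M = dataset$nacl, ph = dataset$ph, contact_h = dataset$contact,
    stringsAsFactors = FALSE
  )
  utils::write.csv(format(out, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a breakthrough curve
#'
#' A breakthrough curve records relative effluent concentration
#' `C/C_in` against cumulative effluent volume for one filter.
#'
#' @param cum_volume cumulative effluent volume (L), strictly increasing.
#' @param c_over_cin relative concentration, `>= 0`.
#' @param provenance one of `"observed"`, `"simulated-equilibrium"`,
#'   `"simulated-kinetic"`, `"analytic"`.
#' @param filter_id optional identifier.
#' @param unit concentration unit of the raw measurements (informative).
#' @param sampling `"point"` or `"composite"`; composite marks per-sample
#'   volume-averaged concentrations (grab samples of finite volume).
#' @return a `breakthrough_curve` data frame with columns `cum_volume`
#'   and `c_over_cin`.
#' @export
breakthrough_curve <- function(cum_volume, c_over_cin,
                               provenance = "observed", filter_id = NA_character_,
                               unit = "mg/L", sampling = "point") {
  cum_volume <- as.numeric(cum_volume)
  c_over_cin <- as.numeric(c_over_cin)
  stopifnot(length(cum_volume) == length(c_over_cin))
  if (any(!is.finite(cum_volume) | cum_volume < 0))
    stop("cumulative volumes must be non-negative and finite", call. = FALSE)
  if (any(diff(cum_volume) <= 0))
    stop("cumulative volume must be strictly increasing within a curve",
         call. = FALSE)
  if (any(!is.finite(c_over_cin) | c_over_cin < 0))
    stop("relative concentrations must be non-negative", call. = FALSE)
  provenance <- match.arg(provenance, c("observed", "simulated-equilibrium",
                                        "simulated-kinetic", "analytic"))
  df <- data.frame(cum_volume = cum_volume, c_over_cin = c_over_cin)
  attr(df, "provenance") <- provenance
  attr(df, "filter_id") <- filter_id
  attr(df, "unit") <- unit
  attr(df, "sampling") <- sampling
  class(df) <- c("breakthrough_curve", "data.frame")
  df
}

#' Read observed breakthrough curves from CSV
#'
#' Expects columns `filter_id`, `cum_volume_L`, `c_out`, `c_in` and
#' `unit`; one curve is returned per `filter_id`, points sorted by
#' cumulative volume. Duplicate volumes within a filter series or mixed
#' concentration units within a series are validation errors.
#'
#' @param path path to a CSV file.
#' @return a named list of `breakthrough_curve` objects.
#' @export
read_breakthrough_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("filter_id", "cum_volume_L", "c_out", "c_in", "unit")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("breakthrough table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in c("cum_volume_L", "c_out", "c_in")) {
    coerced <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(coerced) & !is.na(df[[col]]))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric value in column '%s', row %d", col, bad[1L]),
           call. = FALSE)
    df[[col]] <- coerced
  }
  if (any(df$c_in <= 0))
    stop("influent concentration c_in must be positive", call. = FALSE)
  out <- lapply(split(df, df$filter_id), function(sub) {
    if (length(unique(sub$unit)) > 1L)
      stop(sprintf("mixed concentration units within filter '%s'",
                   sub$filter_id[1L]), call. = FALSE)
    sub <- sub[order(sub$cum_volume_L), , drop = FALSE]
    if (anyDuplicated(sub$cum_volume_L))
      stop(sprintf("duplicate cumulative volume in filter '%s'",
                   sub$filter_id[1L]), call. = FALSE)
    breakthrough_curve(sub$cum_volume_L, sub$c_out / sub$c_in,
                       provenance = "observed",
                       filter_id = sub$filter_id[1L], unit = sub$unit[1L])
  })
  out
}

#' Read a run configuration from YAML
#'
#' Loads solver, fitting and geometry settings, merging them over
#' package defaults, and validates tolerances. The returned object
#' carries the seed and a content hash so every output artifact can
#' record its provenance.
#'
#' @param path path to a YAML file; `NULL` returns the defaults.
#' @return a `run_config` list with elements `solver` (`n_cells`,
#'   `courant`, `mass_balance_tol`), `fitting` (`n_starts`,
#'   `rel_tol`), `seed`, and `provenance` (`config_hash`).
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    solver = list(n_cells = 200L, courant = 0.9, mass_balance_tol = 0.005),
    fitting = list(n_starts = 5L, rel_tol = 1e-8),
    seed = 1L
  )
  cfg <- defaults
  raw <- ""
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    raw <- paste(readLines(path, warn = FALSE), collapse = "\n")
    cfg <- utils::modifyList(defaults, user)
  }
  if (cfg$solver$n_cells < 2L) stop("n_cells must be >= 2", call. = FALSE)
  if (cfg$solver$courant <= 0 || cfg$solver$courant > 1)
    stop("courant must lie in (0, 1]", call. = FALSE)
  if (cfg$solver$mass_balance_tol <= 0 || cfg$fitting$rel_tol <= 0)
    stop("all tolerances must be positive", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  bytes <- as.numeric(utf8ToInt(raw))
  cfg$provenance <- list(
    config_hash = sprintf("%08x",
                          sum(bytes * (seq_along(bytes) %% 9973)) %% 2^31),
    seed = cfg$seed
  )
  class(cfg) <- "run_config"
  cfg
}

#' Packaged compound properties
#'
#' Physicochemical properties of the seven screened micropollutants:
#' molecular mass (g/mol), pKa (a single value, a range, `"multiple"`
#' for polyprotic tetracyclines, or `"n/a"`) and logP.
#'
#' @return a data frame with columns `name`, `abbreviation`,
#'   `molecular_mass`, `pka`, `logp`.
#' @export
load_compound_properties <- function() {
  path <- system.file("extdata", "compound_properties.csv",
                      package = "sorbfate", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(df$molecular_mass > 0), !anyDuplicated(df$name))
  df
}

#' Packaged field-versus-batch partitioning coefficients
#'
#' Linear sand-water (`sand` rows) and apparent biochar-water
#' partitioning coefficients (L/kg) fitted from the pilot filtration
#' trial, alongside the corresponding batch screening values. Field
#' values below the quantifiable range are recorded as left-censored
#' strings (`"<0.1"`).
#'
#' @return a data frame with columns `compound`, `sorbent`
#'   (`sand`, `CH`, `CHCHI`), `k_field` (character; may be censored)
#'   and `k_batch` (numeric; `NA` for sand, which has no batch screen).
#' @seealso [ratio_table()]
#' @export
load_field_coefficients <- function() {
  path <- system.file("extdata", "field_batch_coefficients.csv",
                      package = "sorbfate", mustWork = TRUE)
  utils::read.csv(path, colClasses = c(k_field = "character"),
                  stringsAsFactors = FALSE)
}
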