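#' Sorbed concentration, K_bc and removal by mass balance
#'
#' Computes, for every record of a batch dataset, the sorbed-phase
#' concentration `q = (C0 - Ce) * V / m` (mg/kg), the single-point
#' linear sorption coefficient `kbc = q / Ce` (L/kg) and the removal
#' percentage `100 * (C0 - Ce) / C0`. Records with complete removal
#' (`Ce = 0`) carry no finite K: they are flagged and reported as a
#' lower bound `K >= C0 * V / (m * loq)`, i.e. the coefficient that
#' would put the equilibrium concentration right at the limit of
#' quantification.
#'
#' Mass conservation `C0*V = Ce*V + q*m` holds to machine precision by
#' construction and is asserted on every point. Negative removals
#' allowed by the intake tolerance are clipped to `q = 0`.
#'
#' @param dataset a `batch_dataset` (see [read_batch_table()]).
#' @param loq limit of quantification (mg/L) used for censored lower
#'   bounds; default 0.001.
#' @return a `sorption_points` data frame: `compound`, `sorbent`,
#'   `loading` (mg/L), `nacl`, `ce`, `q`, `kbc` (`NA` when censored),
#'   `removal`, `complete_removal` (logical) and `kbc_lower_bound`
#'   (`NA` unless censored).
#' @export
sorption_point <- function(dataset, loq = 0.001) {
  stopifnot(inherits(dataset, "batch_dataset"))
  if (loq <= 0) stop("loq must be positive", call. = FALSE)
  ce <- dataset$ce
  q <- (dataset$c0 - ce) * dataset$volume / dataset$mass
  q[q < 0] <- 0  # intake tolerance permits ce marginally above c0
  removal <- ifelse(dataset$c0 > 0, 100 * (dataset$c0 - ce) / dataset$c0, 0)
  removal <- pmin(pmax(removal, 0), 100)
  complete <- ce == 0
  kbc <- ifelse(complete, NA_real_, q / ce)
  bound <- ifelse(complete,
                  dataset$c0 * dataset$volume / (dataset$mass * loq),
                  NA_real_)
  # mass-balance audit (only meaningful where q was not clipped)
  lhs <- dataset$c0 * dataset$volume
  rhs <- ce * dataset$volume + q * dataset$mass
  ok <- abs(lhs - rhs) <= 1e-12 * pmax(lhs, 1) | q == 0
  if (!all(ok)) stop("internal mass-balance violation", call. = FALSE)
  out <- data.frame(
    compound = dataset$compound, sorbent = dataset$sorbent,
    loading = dataset$loading, nacl = dataset$nacl,
    ce = ce, q = q, kbc = kbc, removal = removal,
    complete_removal = complete, kbc_lower_bound = bound,
    stringsAsFactors = FALSE
  )
  class(out) <- c("sorption_points", "data.frame")
  out
}

#' Assemble a compounds-by-sorbents K_bc matrix
#'
#' Selects records at a stated sorbent loading (within a relative
#' tolerance), averages replicate single-point K_bc values per
#' compound-sorbent cell and returns the matrix used for similarity
#' clustering. Cells whose replicates all show complete removal carry
#' no finite mean; they are reported censored, with the mean
#' lower bound in place of a value, and excluded from clustering by
#' default downstream.
#'
#' @param dataset a `batch_dataset`.
#' @param loading target sorbent loading (mg/L), e.g. 200 for a
#'   10 mg / 50 mL screening vial.
#' @param loading_tol relative tolerance on the loading match
#'   (default 0.02).
#' @param loq limit of quantification passed to [sorption_point()].
#' @return a `kbc_matrix`: list with `values` (compounds x sorbents,
#'   L/kg; censored cells hold the lower bound), `sd`, `n`, `censored`
#'   (logical matrix), `loading`, `loq`.
#' @export
build_kbc_matrix <- function(dataset, loading, loading_tol = 0.02,
                             loq = 0.001) {
  stopifnot(inherits(dataset, "batch_dataset"), loading > 0)
  pts <- sorption_point(dataset, loq = loq)
  at <- abs(pts$loading / loading - 1) <= loading_tol
  compounds <- sort(unique(pts$compound))
  sorbents <- sort(unique(pts$sorbent))
  pairs_all <- unique(pts[, c("compound", "sorbent")])
  sel <- pts[at, , drop = FALSE]
  pairs_at <- unique(sel[, c("compound", "sorbent")])
  key <- function(d) paste(d$compound, d$sorbent, sep = "\r")
  absent <- setdiff(key(pairs_all), key(pairs_at))
  if (length(absent) > 0L) {
    stop("no record at loading ", loading, " mg/L for pair(s): ",
         paste(gsub("\r", "/", absent), collapse = ", "), call. = FALSE)
  }
  shape <- function(fill) matrix(fill, length(compounds), length(sorbents),
                                 dimnames = list(compounds, sorbents))
  values <- shape(NA_real_); sds <- shape(NA_real_)
  ns <- shape(0L); cens <- shape(FALSE)
  for (grp in split(sel, key(sel))) {
    i <- grp$compound[1L]; j <- grp$sorbent[1L]
    finite <- !grp$complete_removal
    ns[i, j] <- nrow(grp)
    if (any(finite)) {
      values[i, j] <- mean(grp$kbc[finite])
      sds[i, j] <- stats::sd(grp$kbc[finite])
    } else {
      # all replicates at complete removal: censored lower bound
      values[i, j] <- mean(grp$kbc_lower_bound)
      cens[i, j] <- TRUE
    }
  }
  structure(list(values = values, sd = sds, n = ns, censored = cens,
                 loading = loading, loq = loq),
            class = "kbc_matrix")
}

#' @export
print.kbc_matrix <- function(x, ...) {
  cat(sprintf("K_bc matrix (%d compounds x %d sorbents) at %g mg/L loading\n",
              nrow(x$values), ncol(x$values), x$loading))
  if (any(x$censored))
    cat(sprintf("  %d censored cell(s) (complete removal; values are lower bounds at LOQ %g mg/L)\n",
                sum(x$censored), x$loq))
  print(round(x$values, 1))
  invisible(x)
}

#' Write a K_bc matrix to CSV
#'
#' First column `compound`, remaining columns sorbents; a leading
#' comment line records the loading and the censoring rule.
#'
#' @param x a `kbc_matrix`. @param path output path.
#' @return `path`, invisibly.
#' @export
write_kbc_matrix <- function(x, path) {
  stopifnot(inherits(x, "kbc_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# loading_mg_L=%g; censored cells are lower bounds K>=C0*V/(m*LOQ) at LOQ=%g mg/L",
    x$loading, x$loq), con)
  df <- data.frame(compound = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Classify the trend of sorption with salinity
#'
#' Labels the direction of a K_bc series measured over increasing NaCl
#' molarities, using a relative dead band `delta` on successive ratios:
#' `"decrease"` if every ratio `kbc[i+1]/kbc[i] <= 1 - delta`,
#' `"increase"` if every ratio `>= 1 + delta`, `"flat"` if every ratio
#' lies inside the dead band, else `"non-monotone"`. A decrease is the
#' ion-competition signature seen for tetracyclines and enrofloxacin;
#' an increase matches the salting-out direction of the more
#' hydrophobic compounds.
#'
#' @param series a `salinity_series` (see [generate_salinity_series()])
#'   or a list with numeric `levels` (mol/L, strictly increasing) and
#'   `kbc` (L/kg).
#' @param delta relative dead band, default 0.05.
#' @return one of `"increase"`, `"decrease"`, `"flat"`, `"non-monotone"`.
#' @export
classify_salinity_trend <- function(series, delta = 0.05) {
  levels <- series$levels; kbc <- series$kbc
  if (length(levels) != length(kbc))
    stop("levels and kbc must have equal length", call. = FALSE)
  if (length(kbc) < 3L)
    stop("insufficient data: at least 3 salinity levels are required",
         call. = FALSE)
  if (any(diff(levels) <= 0))
    stop("salinity levels must be strictly increasing", call. = FALSE)
  if (any(kbc <= 0)) stop("kbc values must be positive", call. = FALSE)
  r <- kbc[-1L] / kbc[-length(kbc)]
  if (all(r <= 1 - delta)) return("decrease")
  if (all(r >= 1 + delta)) return("increase")
  if (all(r > 1 - delta & r < 1 + delta)) return("flat")
  "non-monotone"
}
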