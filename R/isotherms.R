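#' Construct an adsorption isotherm model
#'
#' Supported equilibrium relations between the aqueous concentration
#' `Ce` (mg/L) and sorbed concentration `q` (mg/kg):
#' \describe{
#'   \item{linear}{`q = K * Ce`, `K` in L/kg.}
#'   \item{freundlich}{`q = K_F * Ce^(1/n)`; the exponent is supplied as
#'     `one_over_n`. Exponents above 1 indicate favourable/multilayer
#'     sorption.}
#'   \item{langmuir}{`q = q_max * b * Ce / (1 + b * Ce)`, monolayer
#'     saturation at `q_max` (mg/kg), affinity `b` (L/mg).}
#'   \item{bet}{aqueous-phase BET multilayer form
#'     `q = q_m * K_B * Ce / ((C_s - Ce) * (1 + (K_B - 1) * Ce / C_s))`
#'     with monolayer capacity `q_m` (mg/kg), dimensionless energy
#'     constant `K_B` and aqueous saturation concentration `c_s` (mg/L)
#'     taking the role vapour pressure plays for gas adsorption. Defined
#'     for `Ce < c_s`, diverging as `Ce` approaches `c_s`.}
#' }
#'
#' @param kind one of `"linear"`, `"freundlich"`, `"langmuir"`, `"bet"`.
#' @param ... named positive parameters as listed above.
#' @return an `isotherm_model` object.
#' @examples
#' eval_isotherm(isotherm_model("freundlich", K_F = 3, one_over_n = 1.2), 0.5)
#' @export
isotherm_model <- function(kind = c("linear", "freundlich", "langmuir", "bet"),
                           ...) {
  kind <- match.arg(kind)
  pars <- list(...)
  needed <- isotherm_par_names(kind)
  missing <- setdiff(needed, names(pars))
  if (length(missing) > 0L)
    stop(kind, " isotherm needs parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  pars <- pars[needed]
  bad <- vapply(pars, function(p) !is.numeric(p) || length(p) != 1L ||
                  !is.finite(p) || p <= 0, logical(1L))
  if (any(bad))
    stop("isotherm parameters must be positive finite scalars: ",
         paste(needed[bad], collapse = ", "), call. = FALSE)
  structure(list(kind = kind, parameters = pars), class = "isotherm_model")
}

isotherm_par_names <- function(kind) {
  switch(kind,
         linear = "K",
         freundlich = c("K_F", "one_over_n"),
         langmuir = c("q_max", "b"),
         bet = c("q_m", "K_B", "c_s"))
}

#' Evaluate an isotherm
#'
#' @param model an `isotherm_model`.
#' @param ce aqueous concentrations (mg/L), non-negative; for the BET
#'   form every `ce` must lie strictly below the saturation
#'   concentration `c_s`.
#' @return sorbed concentrations `q` (mg/kg); `q(0) = 0` for all forms.
#' @export
eval_isotherm <- function(model, ce) {
  stopifnot(inherits(model, "isotherm_model"))
  ce <- as.numeric(ce)
  if (any(!is.finite(ce) | ce < 0))
    stop("ce must be non-negative and finite", call. = FALSE)
  p <- model$parameters
  switch(model$kind,
         linear = p$K * ce,
         freundlich = p$K_F * ce^p$one_over_n,
         langmuir = p$q_max * p$b * ce / (1 + p$b * ce),
         bet = {
           if (any(ce >= p$c_s))
             stop("BET isotherm is undefined for ce >= c_s", call. = FALSE)
           p$q_m * p$K_B * ce / ((p$c_s - ce) * (1 + (p$K_B - 1) * ce / p$c_s))
         })
}

#' Check isotherm-fitting eligibility
#'
#' A batch series qualifies for isotherm fitting only if, after
#' excluding complete-removal points (`Ce = 0`), at least five points
#' remain and they span at least a factor of five in aqueous
#' concentration.
#'
#' @param ce equilibrium aqueous concentrations (mg/L), or a
#'   `sorption_points` data frame.
#' @param min_points,min_span the rule's thresholds (defaults 5 and 5).
#' @return a list with `eligible` (logical), `reason` (character;
#'   `NA` when eligible), `n_points` and `span`.
#' @export
check_eligibility <- function(ce, min_points = 5L, min_span = 5) {
  if (is.data.frame(ce)) ce <- ce$ce
  ce <- as.numeric(ce)
  excluded <- sum(ce == 0)
  ce <- ce[ce > 0]
  note <- if (excluded > 0)
    sprintf(" (%d complete-removal point(s) excluded)", excluded) else ""
  n <- length(ce)
  if (n < min_points) {
    return(list(eligible = FALSE,
                reason = sprintf("fewer than %d data points (%d)%s",
                                 min_points, n, note),
                n_points = n, span = if (n > 0) max(ce) / min(ce) else NA_real_))
  }
  span <- max(ce) / min(ce)
  if (span < min_span) {
    return(list(eligible = FALSE,
                reason = sprintf("concentration span %.3g < %g%s",
                                 span, min_span, note),
                n_points = n, span = span))
  }
  list(eligible = TRUE, reason = NA_character_, n_points = n, span = span)
}

# Deterministic multiplicative start grids around data-driven initial
# guesses; fitting is in natural (untransformed) space so the error
# structure of q is respected, with positivity kept by box constraints.
isotherm_starts <- function(kind, ce, q, fixed = list()) {
  eps <- 1e-10
  loglog <- stats::coef(stats::lm(log(q + eps) ~ log(ce)))
  kf0 <- exp(loglog[[1]]); n0 <- max(min(loglog[[2]], 5), 0.1)
  k0 <- stats::median(q / ce)
  starts <- switch(kind,
    linear = lapply(c(0.5, 1, 2), function(f) list(K = k0 * f)),
    freundlich = {
      grid <- expand.grid(f = c(0.5, 1, 2), g = c(0.7, 1, 1.4))
      lapply(seq_len(nrow(grid)), function(i)
        list(K_F = kf0 * grid$f[i], one_over_n = n0 * grid$g[i]))
    },
    langmuir = {
      qm0 <- 1.2 * max(q)
      grid <- expand.grid(f = c(1, 2, 5), g = c(0.2, 1, 5))
      lapply(seq_len(nrow(grid)), function(i)
        list(q_max = qm0 * grid$f[i],
             b = max(k0 / qm0, eps) * grid$g[i]))
    },
    bet = {
      cs0 <- if ("c_s" %in% names(fixed)) fixed$c_s else 2 * max(ce)
      grid <- expand.grid(f = c(0.3, 1, 3), g = c(2, 20, 200),
                          h = if ("c_s" %in% names(fixed)) 1 else c(1.05, 2, 10))
      lapply(seq_len(nrow(grid)), function(i)
        list(q_m = 0.5 * max(q) * grid$f[i], K_B = grid$g[i],
             c_s = cs0 * grid$h[i]))
    })
  lapply(starts, function(s) s[setdiff(names(s), names(fixed))])
}

isotherm_bounds <- function(kind, ce, names_free) {
  lower <- c(K = 1e-12, K_F = 1e-12, one_over_n = 1e-3, q_max = 1e-12,
             b = 1e-12, q_m = 1e-12, K_B = 1e-9,
             c_s = max(ce) * (1 + 1e-6))
  upper <- c(K = Inf, K_F = Inf, one_over_n = 10, q_max = Inf,
             b = Inf, q_m = Inf, K_B = Inf, c_s = Inf)
  list(lower = lower[names_free], upper = upper[names_free])
}

#' Fit an isotherm by nonlinear least squares
#'
#' Fits one of the four isotherm forms to `(Ce, q)` pairs by
#' Levenberg-Marquardt least squares in natural space, with a
#' deterministic multiplicative multi-start grid around data-driven
#' initial guesses (no randomness; repeated calls give identical
#' results). Parameter standard errors come from the Jacobian at the
#' optimum; `r_squared = 1 - RSS/TSS` on `q`; small-sample AICc is
#' reported for model ranking. The multilayer flag is raised for a
#' Freundlich fit with exponent above 1, and for a BET fit whose
#' `r_squared` is at least `bet_fit_threshold`.
#'
#' @param points a `sorption_points` data frame (columns `ce`, `q`) or a
#'   list/data frame with numeric `ce` and `q`.
#' @param kind model kind (see [isotherm_model()]).
#' @param fixed named list of parameters to hold fixed (typically
#'   `c_s` for BET, when the aqueous solubility is known).
#' @param force fit even when the eligibility rule fails; the result is
#'   then marked ineligible.
#' @param bet_fit_threshold `r_squared` above which a BET fit counts as
#'   acceptable for the multilayer flag (default 0.9).
#' @return an `isotherm_fit`: list with `model` (an [isotherm_model()]),
#'   `std_errors`, `r_squared`, `rss`, `aicc`, `n_points`, `eligible`,
#'   `eligibility_reason`, `multilayer_flag`, `clipped` (parameters that
#'   ended on a bound), `convergence`.
#' @export
fit_isotherm <- function(points, kind = c("linear", "freundlich",
                                          "langmuir", "bet"),
                         fixed = list(), force = FALSE,
                         bet_fit_threshold = 0.9) {
  kind <- match.arg(kind)
  ce_all <- as.numeric(points$ce); q <- as.numeric(points$q)
  keep <- ce_all > 0
  ce <- ce_all[keep]; q <- q[keep]
  elig <- check_eligibility(ce_all)
  if (!elig$eligible && !force)
    stop("series is not eligible for isotherm fitting: ", elig$reason,
         " (use force = TRUE to override)", call. = FALSE)
  par_names <- isotherm_par_names(kind)
  free <- setdiff(par_names, names(fixed))
  if (length(free) == 0L) stop("no free parameters to fit", call. = FALSE)
  bounds <- isotherm_bounds(kind, ce, free)
  resid_fn <- function(p) {
    full <- c(as.list(p), fixed)[par_names]
    m <- do.call(isotherm_model, c(list(kind = kind), full))
    # guard BET domain during search
    if (kind == "bet" && full$c_s <= max(ce)) return(rep(1e6, length(ce)))
    q - eval_isotherm(m, ce)
  }
  best <- NULL
  for (start in isotherm_starts(kind, ce, q, fixed)) {
    p0 <- pmin(pmax(unlist(start[free]), bounds$lower), 1e12)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = bounds$lower,
                         upper = pmin(bounds$upper, 1e15),
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15 * max(best$rss, 1))
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("isotherm fit failed to converge from every start (kind=", kind,
         ", n=", length(ce), ")", call. = FALSE)
  fit <- best$fit
  est <- fit$par
  clipped <- names(est)[est <= bounds$lower * (1 + 1e-9) |
                          est >= pmin(bounds$upper, 1e15) * (1 - 1e-9)]
  full <- c(as.list(est), fixed)[par_names]
  model <- do.call(isotherm_model, c(list(kind = kind), full))
  n <- length(ce); p <- length(free)
  rss <- best$rss
  tss <- sum((q - mean(q))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  se <- rep(NA_real_, p); names(se) <- free
  if (n > p) {
    sigma2 <- rss / (n - p)
    cov <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
    if (!is.null(cov) && all(diag(cov) >= 0)) se <- sqrt(diag(cov))
  }
  aicc <- if (n - p - 1 > 0)
    n * log(max(rss, 1e-300) / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
  else NA_real_
  multilayer <- (kind == "freundlich" && full$one_over_n > 1) ||
    (kind == "bet" && !is.na(r2) && r2 >= bet_fit_threshold)
  structure(list(model = model, std_errors = se, r_squared = r2, rss = rss,
                 aicc = aicc, n_points = n, eligible = elig$eligible,
                 eligibility_reason = elig$reason,
                 multilayer_flag = multilayer, clipped = clipped,
                 convergence = fit$info),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  p <- unlist(x$model$parameters)
  cat(sprintf("%s isotherm fit (n=%d%s)\n", x$model$kind, x$n_points,
              if (x$eligible) "" else ", INELIGIBLE series"))
  for (nm in names(p)) {
    se <- x$std_errors[nm]
    cat(sprintf("  %-10s %.6g%s\n", nm, p[[nm]],
                if (!is.na(se)) sprintf(" (SE %.3g)", se) else " (fixed)"))
  }
  cat(sprintf("  RSS %.4g  R^2 %.4f  AICc %.4g%s\n", x$rss, x$r_squared,
              x$aicc, if (x$multilayer_flag) "  [multilayer]" else ""))
  invisible(x)
}

#' Fit and rank all isotherm models on one series
#'
#' Fits each requested model and ranks them by small-sample AICc
#' (RSS penalised by parameter count); models within `delta_tie` AICc
#' units of the best are reported as a tie set rather than a single
#' winner.
#'
#' @inheritParams fit_isotherm
#' @param kinds models to fit.
#' @param delta_tie AICc tie width (default 2).
#' @return a list with `fits` (named list of `isotherm_fit`), `table`
#'   (one row per model: parameters, SEs, RSS, AICc, flags) and
#'   `best` (character vector of the tied best kinds).
#' @export
fit_isotherms <- function(points, kinds = c("linear", "freundlich",
                                            "langmuir", "bet"),
                          fixed = list(), force = FALSE, delta_tie = 2) {
  fits <- list()
  for (k in kinds) {
    fx <- if (k == "bet") fixed else fixed[setdiff(names(fixed), "c_s")]
    fits[[k]] <- tryCatch(fit_isotherm(points, k, fixed = fx, force = force),
                          error = function(e) e)
  }
  ok <- !vapply(fits, inherits, logical(1L), "error")
  if (!any(ok)) stop("no isotherm model could be fitted", call. = FALSE)
  tab <- do.call(rbind, lapply(names(fits)[ok], function(k) {
    f <- fits[[k]]
    data.frame(kind = k,
               parameters = paste(sprintf("%s=%.5g",
                                          names(f$model$parameters),
                                          unlist(f$model$parameters)),
                                  collapse = "; "),
               rss = f$rss, r_squared = f$r_squared, aicc = f$aicc,
               multilayer_flag = f$multilayer_flag,
               eligible = f$eligible, stringsAsFactors = FALSE)
  }))
  aicc <- tab$aicc
  best <- tab$kind[aicc <= min(aicc, na.rm = TRUE) + delta_tie]
  list(fits = fits[ok], table = tab, best = best[!is.na(best)])
}
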