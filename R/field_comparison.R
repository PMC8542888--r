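#' Parse a possibly censored coefficient
#'
#' Coefficients reported only as below a quantification bound are
#' written `"<x"`; they parse to the bound with a left-censoring flag.
#'
#' @param x character or numeric vector.
#' @return data frame with columns `value` and `censored` (logical,
#'   `TRUE` for left-censored entries).
#' @export
parse_coefficient <- function(x) {
  x <- trimws(as.character(x))
  censored <- startsWith(x, "<")
  value <- suppressWarnings(as.numeric(sub("^<", "", x)))
  if (any(is.na(value) & !is.na(x) & x != "" & x != "NA"))
    stop("unparseable coefficient value: ",
         x[which(is.na(value))[1L]], call. = FALSE)
  data.frame(value = value, censored = censored)
}

#' Batch-versus-field sorption coefficient ratios
#'
#' For each compound-sorbent pair with a batch-screening coefficient
#' and a field-fitted coefficient, computes the ratio
#' `batch / field`. A left-censored field value `"<x"` yields a
#' right-censored ratio `> batch / x`; censored ratios are listed but
#' excluded from the min/max summary. This quantifies how much weaker
#' sorption is under real-world filtration (matrix effects, fouling,
#' non-ideal flow) than in clean laboratory batch systems.
#'
#' @param pairs a data frame with columns `compound`, `sorbent`,
#'   `kbc_batch` (numeric, L/kg) and `kbc_field` (numeric or character,
#'   possibly `"<x"`); rows with `NA` batch values (e.g. sand, which
#'   has no batch screen) are dropped with a notice in the summary.
#' @return a `ratio_table` list: `table` (per-pair ratios with
#'   `ratio_censored` flags), `summary` (list: `min`, `max` over
#'   finite ratios, `n_finite`, `n_censored`, `excluded` describing
#'   every dropped or censored entry).
#' @examples
#' t2 <- load_field_coefficients()
#' rt <- ratio_table(data.frame(compound = t2$compound, sorbent = t2$sorbent,
#'                              kbc_batch = t2$k_batch, kbc_field = t2$k_field))
#' rt$summary$min  # ~ 11.9
#' @export
ratio_table <- function(pairs) {
  required <- c("compound", "sorbent", "kbc_batch", "kbc_field")
  missing <- setdiff(required, names(pairs))
  if (length(missing) > 0L)
    stop("pairs is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  field <- parse_coefficient(pairs$kbc_field)
  batch <- as.numeric(pairs$kbc_batch)
  no_batch <- is.na(batch)
  excluded <- character(0)
  if (any(no_batch)) {
    excluded <- c(excluded, sprintf("%s/%s: no batch coefficient",
                                    pairs$compound[no_batch],
                                    pairs$sorbent[no_batch]))
  }
  keep <- !no_batch
  tab <- data.frame(
    compound = pairs$compound[keep], sorbent = pairs$sorbent[keep],
    kbc_batch = batch[keep], kbc_field = field$value[keep],
    field_censored = field$censored[keep], stringsAsFactors = FALSE
  )
  if (any(!is.finite(tab$kbc_batch) | tab$kbc_batch <= 0 |
            !is.finite(tab$kbc_field) | tab$kbc_field <= 0))
    stop("coefficients must be positive", call. = FALSE)
  tab$ratio <- tab$kbc_batch / tab$kbc_field
  tab$ratio_censored <- tab$field_censored  # "<x" field => "> batch/x" ratio
  finite <- !tab$ratio_censored
  if (!any(finite))
    stop("no pair with finite batch and field values", call. = FALSE)
  if (any(tab$ratio_censored)) {
    excluded <- c(excluded, sprintf(
      "%s/%s: field value < %g, ratio reported as > %.4g",
      tab$compound[tab$ratio_censored], tab$sorbent[tab$ratio_censored],
      tab$kbc_field[tab$ratio_censored], tab$ratio[tab$ratio_censored]))
  }
  summary <- list(min = min(tab$ratio[finite]), max = max(tab$ratio[finite]),
                  n_finite = sum(finite), n_censored = sum(!finite),
                  excluded = excluded)
  structure(list(table = tab, summary = summary), class = "ratio_table")
}

#' @export
print.ratio_table <- function(x, ...) {
  tab <- x$table
  shown <- data.frame(
    compound = tab$compound, sorbent = tab$sorbent,
    batch = tab$kbc_batch,
    field = ifelse(tab$field_censored, sprintf("<%g", tab$kbc_field),
                   sprintf("%g", tab$kbc_field)),
    ratio = ifelse(tab$ratio_censored, sprintf(">%.4g", tab$ratio),
                   sprintf("%.4g", tab$ratio)))
  print(shown, row.names = FALSE)
  cat(sprintf("finite ratios: %d, range %.4g to %.4g; censored: %d\n",
              x$summary$n_finite, x$summary$min, x$summary$max,
              x$summary$n_censored))
  invisible(x)
}

#' Compare the packaged batch and field coefficients
#'
#' Convenience wrapper: loads the packaged coefficient table (see
#' [load_field_coefficients()]), keeps the biochar sorbents (sand rows
#' carry no batch value) and returns the [ratio_table()].
#'
#' @return a `ratio_table`.
#' @export
compare_batch_field <- function() {
  t2 <- load_field_coefficients()
  ratio_table(data.frame(compound = t2$compound, sorbent = t2$sorbent,
                         kbc_batch = t2$k_batch, kbc_field = t2$k_field,
                         stringsAsFactors = FALSE))
}

#' Check a ratio summary against an order-of-magnitude band
#'
#' Operationalises a qualitative "about `lower` to `upper` times
#' lower" statement: the finite-ratio minimum must be at least
#' `lower` and the maximum at most `upper`.
#'
#' @param summary the `summary` element of a [ratio_table()].
#' @param lower,upper band limits (defaults 10 and 510, allowing 2\%
#'   rounding slack at the top).
#' @return logical.
#' @export
ratio_range_consistent <- function(summary, lower = 10, upper = 510) {
  summary$min >= lower && summary$max <= upper
}
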