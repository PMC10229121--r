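#' Exclude hook-affected points from a binding series
#'
#' In bead-proximity (Alpha) assays the signal can decline at high query
#' concentration because query exceeds bead saturation (the "hook" effect);
#' such points misrepresent binding and are excluded before fitting. Rule:
#' let `q*` be the concentration of maximal mean signal; a concentration
#' `Q > q*` is excluded iff its mean signal falls below
#' `(1 - hook_frac) * max` (default `hook_frac` 0.1, i.e. a >10 percent
#' drop).
#'
#' @param series data.frame with `query_nM` and `counts` (replicates as
#'   extra rows).
#' @param hook_frac fractional signal drop that triggers exclusion.
#' @return list with `series` (reduced data.frame) and `excluded`
#'   (row indices of `series` input that were dropped).
#' @export
exclude_hook <- function(series, hook_frac = 0.1) {
  stopifnot(is.data.frame(series),
            all(c("query_nM", "counts") %in% names(series)))
  if (length(unique(series$query_nM)) < 3L)
    stop("need >= 3 distinct concentrations", call. = FALSE)
  m <- stats::aggregate(counts ~ query_nM, series, mean)
  q_star <- m$query_nM[which.max(m$counts)]
  y_max <- max(m$counts)
  bad_q <- m$query_nM[m$query_nM > q_star &
                        m$counts < (1 - hook_frac) * y_max]
  excluded <- which(series$query_nM %in% bad_q)
  keep <- series[setdiff(seq_len(nrow(series)), excluded), , drop = FALSE]
  if (!nrow(keep)) stop("all points excluded by the hook rule", call. = FALSE)
  list(series = keep, excluded = excluded)
}

#' Fit a four-parameter logistic binding curve
#'
#' Least-squares fit of `y = bottom + (top - bottom) / (1 + (EC50/Q)^H)` on
#' a hook-excluded series. Replicate points are all retained in the
#' residuals. Flat series (signal range at or below `noise_floor`) are
#' refused and flagged as no-binding rather than fitted, mirroring targets
#' with minimal interaction. The EC50 reported is the relative EC50: the
#' inflection concentration between the two fitted (unconstrained) plateaus.
#'
#' @param series data.frame with `query_nM`, `counts`.
#' @param hook_frac passed to [exclude_hook()]; `NULL` disables hook
#'   exclusion.
#' @param noise_floor flat-data threshold on the range of per-concentration
#'   mean signal (default 0: only exactly constant data are refused).
#' @param fix_bottom optional value to fix the bottom plateau at (e.g. a
#'   no-target background mean); default unconstrained.
#' @return Object of class `dose_response_fit`: `bottom`, `top`, `ec50_rel`
#'   (nM), `hillslope`, `se` (named), `r2`, `rss`, `df`, `excluded`,
#'   `no_binding` (logical). For a no-binding series only `no_binding` and
#'   `excluded` are meaningful.
#' @export
fit_4pl <- function(series, hook_frac = 0.1, noise_floor = 0,
                    fix_bottom = NULL) {
  stopifnot(is.data.frame(series),
            all(c("query_nM", "counts") %in% names(series)))
  excluded <- integer()
  if (!is.null(hook_frac)) {
    hx <- exclude_hook(series, hook_frac)
    series <- hx$series
    excluded <- hx$excluded
  }
  if (length(unique(series$query_nM[series$query_nM > 0])) < 5L)
    stop("need >= 5 distinct non-zero query concentrations", call. = FALSE)
  m <- stats::aggregate(counts ~ query_nM, series, mean)
  if (diff(range(m$counts)) <= noise_floor)
    return(structure(list(no_binding = TRUE, excluded = excluded),
                     class = "dose_response_fit"))
  dat <- data.frame(Q = series$query_nM, y = series$counts)
  y <- dat$y
  bottom0 <- min(m$counts); top0 <- max(m$counts)
  half <- (bottom0 + top0) / 2
  mo <- m[order(m$query_nM), ]
  ec0 <- tryCatch(
    stats::approx(mo$counts, mo$query_nM, xout = half, ties = mean)$y,
    error = function(e) NA_real_)
  if (!is.finite(ec0) || ec0 <= 0)
    ec0 <- stats::median(mo$query_nM[mo$query_nM > 0])
  if (is.null(fix_bottom)) {
    fit <- .fit_multistart(
      y ~ bottom + (top - bottom) / (1 + (ec50 / Q)^H), dat,
      list(bottom = bottom0, top = top0, ec50 = ec0, H = 1),
      c(bottom = -Inf, top = -Inf, ec50 = 1e-12, H = 1e-3))
  } else {
    dat$bottom_fixed <- fix_bottom
    fit <- .fit_multistart(
      y ~ bottom_fixed + (top - bottom_fixed) / (1 + (ec50 / Q)^H), dat,
      list(top = top0, ec50 = ec0, H = 1),
      c(top = -Inf, ec50 = 1e-12, H = 1e-3))
  }
  s <- .fit_summary(fit, y)
  co <- s$coef
  bottom <- if (is.null(fix_bottom)) unname(co[["bottom"]]) else fix_bottom
  structure(list(
    no_binding = FALSE, bottom = bottom, top = unname(co[["top"]]),
    ec50_rel = unname(co[["ec50"]]), hillslope = unname(co[["H"]]),
    se = s$se, r2 = s$r2, rss = s$rss, df = s$df, excluded = excluded),
    class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (isTRUE(x$no_binding)) {
    cat("<dose_response_fit> no binding (flat series; fit refused)\n")
  } else {
    cat(sprintf(
      paste0("<dose_response_fit> EC50rel = %.4g nM, H = %.3g, bottom = ",
             "%.4g, top = %.4g, R^2 = %.4f (%d points excluded as hook)\n"),
      x$ec50_rel, x$hillslope, x$bottom, x$top, x$r2, length(x$excluded)))
  }
  invisible(x)
}

#' Generalized relative effective concentration EC_F
#'
#' Concentration producing F percent of the fitted maximal response:
#' `EC_F = (F / (100 - F))^(1/H) * EC50rel`. `ec_f_rel(fit, 50)` is the
#' EC50rel itself; F = 80 is the usual probing concentration for discovery
#' screens (robust signal without saturation).
#'
#' @param fit an accepted `dose_response_fit`.
#' @param F response percentage, strictly between 0 and 100 (default 80).
#' @return Concentration in nM.
#' @export
ec_f_rel <- function(fit, F = 80) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (isTRUE(fit$no_binding))
    stop("no-binding fit has no EC values", call. = FALSE)
  if (F <= 0 || F >= 100)
    stop("F must be strictly between 0 and 100", call. = FALSE)
  (F / (100 - F))^(1 / fit$hillslope) * fit$ec50_rel
}

#' Fold difference in relative EC50 between two targets
#'
#' Ratio `EC50rel(A) / EC50rel(B)` with first-order (delta-method)
#' propagation of the two fit standard errors.
#'
#' @param fit_a,fit_b accepted `dose_response_fit` objects.
#' @return list with `fold`, `se`, or an incomparable marker
#'   (`fold = NA`, `reason`) when either fit is flagged no-binding.
#' @export
compare_targets <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "dose_response_fit"),
            inherits(fit_b, "dose_response_fit"))
  if (isTRUE(fit_a$no_binding) || isTRUE(fit_b$no_binding))
    return(list(fold = NA_real_, se = NA_real_,
                reason = "incomparable: no-binding fit"))
  fold <- fit_a$ec50_rel / fit_b$ec50_rel
  rel <- sqrt((fit_a$se[["ec50"]] / fit_a$ec50_rel)^2 +
                (fit_b$se[["ec50"]] / fit_b$ec50_rel)^2)
  list(fold = fold, se = fold * rel)
}
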