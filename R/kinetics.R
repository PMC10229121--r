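#' Serial-dilution substrate titration
#'
#' Builds the concentration series of an n-point serial dilution from `top`,
#' reported to 3 significant figures (as concentrations are pipetted and
#' printed), with a zero-substrate point appended. An 8-point 1.5-fold
#' series from 400 nM gives 400, 267, 178, 119, 79.0, 52.7, 35.1, 23.4, 0.
#'
#' @param top highest concentration (> 0), nM.
#' @param fold dilution factor (> 1).
#' @param n_points number of non-zero points (>= 2).
#' @return Numeric vector, descending, ending in 0.
#' @export
make_titration <- function(top, fold, n_points) {
  if (top <= 0) stop("top must be > 0", call. = FALSE)
  if (fold <= 1) stop("fold must be > 1", call. = FALSE)
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  c(signif(top / fold^(0:(n_points - 1)), 3), 0)
}

# single nls attempt with Levenberg-Marquardt; returns fit or NULL
.try_nls <- function(formula, data, start, lower) {
  tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start, lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
}

# multistart wrapper: jittered restarts on non-convergence
.fit_multistart <- function(formula, data, start, lower, n_restarts = 5L) {
  fit <- .try_nls(formula, data, start, lower)
  if (!is.null(fit)) return(fit)
  for (i in seq_len(n_restarts)) {
    jit <- lapply(start, function(x) x * stats::runif(1, 0.5, 2))
    fit <- .try_nls(formula, data, jit, lower)
    if (!is.null(fit)) return(fit)
  }
  stop("fit-failure: nonlinear least squares did not converge after ",
       n_restarts, " jittered restarts", call. = FALSE)
}

.fit_summary <- function(fit, v) {
  rss <- sum(stats::resid(fit)^2)
  ss_tot <- sum((v - mean(v))^2)
  co <- summary(fit)$coefficients
  list(coef = stats::coef(fit), se = co[, "Std. Error"], rss = rss,
       df = length(v) - nrow(co), r2 = 1 - rss / ss_tot)
}

#' Fit steady-state kinetics: Michaelis-Menten vs Hill
#'
#' Pools all replicate points and fits both the Hill model
#' `v = Vmax * S^h / (K05^h + S^h)` and its h = 1 restriction
#' (Michaelis-Menten) by unweighted Levenberg-Marquardt least squares, then
#' compares them with the extra sum-of-squares F-test:
#' `F = ((SS_MM - SS_Hill) / (df_MM - df_Hill)) / (SS_Hill / df_Hill)`,
#' p from the F distribution; the Hill model is preferred when p < alpha
#' (evidence of cooperativity, h > 1, or negative cooperativity, h < 1).
#' Substrate is entered in nM; K_0.5 is reported in uM. `kcat = Vmax / E`.
#'
#' Starting values: `Vmax0 = max(v)`, `K0` = substrate at half-max
#' (interpolated), `h0 = 1`, with 5 jittered restarts on non-convergence.
#' When the Michaelis-Menten model already fits to within numerical noise
#' (RSS below 1e-14 of the response sum of squares, e.g. noise-free h = 1
#' data) the F statistic is set to 0 and p to 1: a perfectly fitting
#' restricted model cannot be improved upon.
#'
#' @param ds data.frame with columns `substrate_nM` and `v` (velocity in
#'   concentration per minute, same concentration unit as `E_nM`), plus an
#'   optional `replicate` column; rates may also come from raw counts via
#'   `convert`.
#' @param E_nM enzyme concentration in nM.
#' @param alpha significance level of the model comparison (default 0.05).
#' @param convert optional `list(factor =, time_min =)` converting a raw
#'   signal column `counts` to rates: `v = counts * factor / time_min`.
#' @return Object of class `kinetic_fit_set`: `mm` and `hill` fits (each
#'   with `K05_uM`, `kcat`, `h`, `se`, `r2`, `rss`, `df`), `comparison`
#'   (`F`, `df1`, `df2`, `p`, `preferred`), `E_nM`.
#' @export
fit_kinetics <- function(ds, E_nM = 4, alpha = 0.05, convert = NULL) {
  stopifnot(is.data.frame(ds), "substrate_nM" %in% names(ds))
  if (!is.null(convert))
    ds$v <- ds$counts * convert$factor / convert$time_min
  if (!"v" %in% names(ds))
    stop("ds needs a 'v' column (or 'counts' plus a convert spec)",
         call. = FALSE)
  if (length(unique(ds$substrate_nM[ds$substrate_nM > 0])) < 5L)
    stop("insufficient-design: need >= 5 distinct non-zero substrate ",
         "concentrations", call. = FALSE)
  dat <- data.frame(S = ds$substrate_nM / 1000, v = ds$v)   # fit in uM
  v <- dat$v
  vmax0 <- max(v)
  ord <- order(dat$S)
  k0 <- tryCatch(
    stats::approx(v[ord], dat$S[ord], xout = vmax0 / 2, ties = mean)$y,
    error = function(e) NA_real_)
  if (!is.finite(k0) || k0 <= 0) k0 <- stats::median(dat$S[dat$S > 0])
  lowest <- c(Vmax = 0, K05 = 1e-9, h = 1e-3)
  hill <- .fit_multistart(v ~ Vmax * S^h / (K05^h + S^h), dat,
                          list(Vmax = vmax0, K05 = k0, h = 1), lowest)
  mm <- .fit_multistart(v ~ Vmax * S / (K05 + S), dat,
                        list(Vmax = vmax0, K05 = k0), lowest[1:2])
  sh <- .fit_summary(hill, v)
  sm <- .fit_summary(mm, v)
  ss_scale <- sum(v^2)
  if (sm$rss <= 1e-14 * ss_scale) {       # restricted model already perfect
    Fstat <- 0; p <- 1
  } else {
    Fstat <- max(0, ((sm$rss - sh$rss) / (sm$df - sh$df)) /
                   (sh$rss / sh$df))
    p <- stats::pf(Fstat, sm$df - sh$df, sh$df, lower.tail = FALSE)
  }
  pack <- function(s, model) {
    co <- s$coef
    list(model = model, K05_uM = unname(co[["K05"]]),
         kcat = unname(co[["Vmax"]]) / E_nM,
         Vmax = unname(co[["Vmax"]]),
         h = if (model == "Hill") unname(co[["h"]]) else 1,
         se = s$se, r2 = s$r2, rss = s$rss, df = s$df)
  }
  structure(list(
    mm = pack(sm, "MM"), hill = pack(sh, "Hill"),
    comparison = list(F = Fstat, df1 = sm$df - sh$df, df2 = sh$df, p = p,
                      preferred = if (p < alpha) "Hill" else "MM"),
    E_nM = E_nM, alpha = alpha), class = "kinetic_fit_set")
}

#' @export
print.kinetic_fit_set <- function(x, ...) {
  f <- function(ft) sprintf(
    "  %-4s K_0.5 = %.3g uM, k_cat = %.3g min^-1, h = %.3g, R^2 = %.4f",
    ft$model, ft$K05_uM, ft$kcat, ft$h, ft$r2)
  cat("<kinetic_fit_set>\n", f(x$mm), "\n", f(x$hill), "\n", sep = "")
  cat(sprintf("  extra sum-of-squares F(%d,%d) = %.4g, p = %.4g -> %s\n",
              x$comparison$df1, x$comparison$df2, x$comparison$F,
              x$comparison$p, x$comparison$preferred))
  invisible(x)
}

#' Screen a kinetic dataset for non-determinable (n.d.) parameters
#'
#' Mirrors the reporting convention where substrates whose methylation
#' signal is indistinguishable from background get "n.d." in place of
#' kinetic parameters. A dataset is n.d. when the one-sided t-test of the
#' top-concentration signal against background is non-significant, or when
#' the fitted Vmax confidence interval includes 0.
#'
#' @param ds kinetic data.frame (`substrate_nM`, `v`).
#' @param background numeric vector of background (blank) signals, or NULL.
#' @param alpha significance level (default 0.05).
#' @param E_nM enzyme concentration, passed to the screening fit.
#' @return list with `nd` (logical) and `reason` (string).
#' @export
nd_screen <- function(ds, background = NULL, alpha = 0.05, E_nM = 4) {
  top_v <- ds$v[ds$substrate_nM == max(ds$substrate_nM)]
  if (!is.null(background) && length(background) >= 2L &&
      length(top_v) >= 2L) {
    ht <- stats::t.test(top_v, background, alternative = "greater")
    if (ht$p.value >= alpha)
      return(list(nd = TRUE, reason = sprintf(
        "top-concentration signal indistinguishable from background (one-sided p = %.3g)",
        ht$p.value)))
  }
  ci_ok <- tryCatch({
    fit <- fit_kinetics(ds, E_nM = E_nM)
    lo <- fit$hill$Vmax - stats::qt(1 - alpha / 2, fit$hill$df) *
      fit$hill$se[["Vmax"]]
    lo > 0
  }, error = function(e) NA)
  if (is.na(ci_ok)) {
    if (is.null(background))
      stop("no background provided and no Vmax confidence interval ",
           "computable", call. = FALSE)
    return(list(nd = FALSE,
                reason = "signal above background; CI not computable"))
  }
  if (!ci_ok)
    return(list(nd = TRUE,
                reason = "fitted Vmax confidence interval includes 0"))
  list(nd = FALSE, reason = "signal distinguishable from background")
}

#' Pairwise endpoint comparison of methylation signals
#'
#' Two-tailed two-sample t-tests between replicate groups of an endpoint
#' assay (Student pooled-variance by default, Welch optional).
#'
#' @param groups named list of numeric replicate vectors (each n >= 2).
#' @param pairs optional 2-column character matrix of group names to
#'   compare; default all pairs.
#' @param var.equal pooled (TRUE, default) or Welch (FALSE).
#' @return data.frame with `group_a`, `group_b`, `t`, `df`, `p`.
#' @export
endpoint_compare <- function(groups, pairs = NULL, var.equal = TRUE) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (is.null(pairs))
    pairs <- t(utils::combn(names(groups), 2L))
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- .pooled_t(groups[[pairs[i, 1]]], groups[[pairs[i, 2]]],
                   var.equal = var.equal)
    data.frame(group_a = pairs[i, 1], group_b = pairs[i, 2],
               t = r$t, df = r$df, p = r$p)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
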