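#' Acetyl-state selection window
#'
#' Everything needed to pick the MS2 scans of one acetyl degree out of a run:
#' the retention-time interval (half-open, minutes) and the four allowed
#' precursor m/z — the theoretical [M+9H]9+ of the degree's K4 me0-me3
#' proteoforms. Note the precursor filter is a coarse confirmation only: at
#' 9+ the me3-vs-ac mass difference shrinks to 0.004 Th, far below any
#' practical tolerance, so retention time is the primary classifier of the
#' acetyl state and the precursor check merely rejects grossly wrong
#' isolations.
#'
#' @param degree acetyl degree, 0-5.
#' @param rt `c(start, end)` minutes; defaults to the degree's entry in
#'   [DEFAULT_RT_WINDOWS].
#' @param prec_tol precursor match tolerance in Th (default 0.05).
#' @param frag_tol fragment match tolerance in Th (default 0.3, ion-trap
#'   resolution).
#' @return Object of class `acetyl_state_window`.
#' @export
acetyl_state_window <- function(degree,
                                rt = DEFAULT_RT_WINDOWS[[as.character(degree)]],
                                prec_tol = 0.05, frag_tol = 0.3) {
  stopifnot(degree %in% 0:5, length(rt) == 2L, rt[1] < rt[2])
  if (prec_tol <= 0 || frag_tol <= 0)
    stop("tolerances must be > 0", call. = FALSE)
  structure(list(degree = as.integer(degree), rt = as.numeric(rt),
                 precursors = .precursors_for_degree(degree),
                 prec_tol = prec_tol, frag_tol = frag_tol),
            class = "acetyl_state_window")
}

.empty_window_error <- function(degree, n_rt, n_prec, n_snr) {
  stop(structure(class = c("empty_window_error", "error", "condition"),
                 list(message = sprintf(
                   paste0("no MS2 scans survive for acetyl degree %d ",
                          "(in RT window: %d, after precursor filter: %d, ",
                          "after SNR filter: %d)"), degree, n_rt, n_prec,
                   n_snr),
                   call = NULL, degree = degree,
                   counts = c(rt = n_rt, precursor = n_prec, snr = n_snr))))
}

#' Select and average the MS2 scans of one acetyl state
#'
#' Keeps MS2 scans whose retention time falls in the window (half-open) and
#' whose precursor lies within tolerance of one of the four allowed targets,
#' then applies a deterministic signal-to-noise rule standing in for manual
#' curation: a scan is dropped when its summed intensity at the four C4+1
#' fragment targets is below `snr_min` times the median intensity of its
#' off-target peaks. Survivors are averaged on a fixed m/z bin grid.
#'
#' @param run an `ms_run` (from [simulate_run()] or [read_run_json()]).
#' @param window an [acetyl_state_window].
#' @param snr_min signal-to-noise threshold (default 3).
#' @param bin_width m/z bin width in Th (default 0.1).
#' @param grid_range m/z range of the bin grid; default the narrow MS2 range.
#' @return Object of class `averaged_spectrum`: `degree`, `mz` (bin
#'   centers), `intensity` (mean binned intensity), `n_scans`.
#' @seealso [extract_stoichiometry()]
#' @export
select_and_average <- function(run, window, snr_min = 3, bin_width = 0.1,
                               grid_range = DEFAULT_MS2_RANGE) {
  stopifnot(inherits(run, "ms_run"), inherits(window, "acetyl_state_window"))
  ms2 <- Filter(function(s) s$level == 2L, run$scans)
  if (!length(ms2)) stop("run contains no MS2 scans", call. = FALSE)
  rt <- vapply(ms2, `[[`, 0, "rt")
  in_rt <- ms2[rt >= window$rt[1] & rt < window$rt[2]]
  in_prec <- Filter(function(s) {
    !is.na(s$precursor_mz) &&
      min(abs(s$precursor_mz - window$precursors)) <= window$prec_tol
  }, in_rt)
  targets <- unname(c4_targets())
  keep <- Filter(function(s) {
    on <- sum(vapply(targets, function(tg) {
      sel <- abs(s$mz - tg) <= window$frag_tol
      if (any(sel)) max(s$intensity[sel]) else 0
    }, 0))
    off_sel <- vapply(s$mz, function(m) all(abs(m - targets) > window$frag_tol),
                      NA)
    if (!any(off_sel)) return(TRUE)   # nothing off-target: keep
    on >= snr_min * stats::median(s$intensity[off_sel])
  }, in_prec)
  if (!length(keep))
    .empty_window_error(window$degree, length(in_rt), length(in_prec), 0L)
  breaks <- seq(grid_range[1], grid_range[2], by = bin_width)
  centers <- breaks[-length(breaks)] + bin_width / 2
  acc <- numeric(length(centers))
  for (s in keep) {
    idx <- findInterval(s$mz, breaks, rightmost.closed = TRUE)
    ok <- idx >= 1L & idx <= length(centers)
    if (any(ok)) {
      binned <- numeric(length(centers))
      sums <- tapply(s$intensity[ok], idx[ok], sum)
      binned[as.integer(names(sums))] <- sums
      acc <- acc + binned
    }
  }
  structure(list(degree = window$degree, mz = centers,
                 intensity = acc / length(keep), n_scans = length(keep)),
            class = "averaged_spectrum")
}

#' K4 methyl stoichiometry from an averaged spectrum
#'
#' Reads the intensity at each of the four C4+1 targets (maximum binned
#' intensity within the fragment tolerance; robust to the bin grid) and
#' normalizes the four values to percentages summing to 100. The same four
#' target m/z apply to every acetyl degree, since acetylation sits beyond
#' residue 4 and cannot shift the c4 ion.
#'
#' @param spec an `averaged_spectrum`.
#' @param targets the four C4+1 m/z, strictly increasing; default
#'   [c4_targets()].
#' @param frag_tol match tolerance in Th; must be below half the minimum
#'   target spacing (~7 Th).
#' @param method `"max"` (default) or `"sum"`: take the maximum or the sum
#'   of binned intensity within tolerance.
#' @return Named numeric `c(me0, me1, me2, me3)` in percent, summing to 100.
#' @export
extract_stoichiometry <- function(spec, targets = c4_targets(),
                                  frag_tol = 0.3,
                                  method = c("max", "sum")) {
  stopifnot(inherits(spec, "averaged_spectrum"), length(targets) == 4L)
  method <- match.arg(method)
  if (any(diff(targets) <= 0))
    stop("targets must be strictly increasing", call. = FALSE)
  if (frag_tol >= min(diff(targets)) / 2)
    stop("frag_tol must be below half the minimum target spacing",
         call. = FALSE)
  inten <- vapply(targets, function(tg) {
    sel <- abs(spec$mz - tg) <= frag_tol
    if (!any(sel)) return(0)
    if (method == "max") max(spec$intensity[sel]) else sum(spec$intensity[sel])
  }, 0)
  if (all(inten == 0))
    stop(structure(class = c("undefined_stoichiometry_error", "error",
                             "condition"),
                   list(message = paste("all four C4+1 intensities are zero;",
                                        "stoichiometry undefined"),
                        call = NULL)))
  stats::setNames(100 * inten / sum(inten), c("me0", "me1", "me2", "me3"))
}

#' Quantify K4 stoichiometry per acetyl degree in one run
#'
#' Runs [select_and_average()] + [extract_stoichiometry()] for each degree.
#' Degrees whose window yields no usable scans are reported as missing (NA
#' percentages), never as zeros.
#'
#' @param run an `ms_run`.
#' @param windows list of [acetyl_state_window()]; default all six degrees.
#' @param snr_min,bin_width passed to [select_and_average()].
#' @param method passed to [extract_stoichiometry()].
#' @return data.frame: one row per degree with the run's metadata columns
#'   (`condition`, `time_min`, `bio`, `tech` when present), `acetyl_degree`,
#'   `me0`..`me3` (percent) and `n_scans`.
#' @export
quantify_run <- function(run, windows = lapply(0:5, acetyl_state_window),
                         snr_min = 3, bin_width = 0.1,
                         method = c("max", "sum")) {
  method <- match.arg(method)
  meta <- run$metadata[intersect(c("condition", "time_min", "bio", "tech"),
                                 names(run$metadata))]
  rows <- lapply(windows, function(w) {
    stoich <- tryCatch({
      sp <- select_and_average(run, w, snr_min = snr_min,
                               bin_width = bin_width)
      c(extract_stoichiometry(sp, frag_tol = w$frag_tol, method = method),
        n_scans = sp$n_scans)
    }, empty_window_error = function(e) {
      c(me0 = NA_real_, me1 = NA_real_, me2 = NA_real_, me3 = NA_real_,
        n_scans = 0)
    })
    row <- data.frame(acetyl_degree = w$degree, me0 = stoich[["me0"]],
                      me1 = stoich[["me1"]], me2 = stoich[["me2"]],
                      me3 = stoich[["me3"]], n_scans = stoich[["n_scans"]])
    if (length(meta)) row <- cbind(as.data.frame(meta), row)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate per-run stoichiometries across a tech-within-bio design
#'
#' Technical replicates are averaged within each biological replicate first;
#' the mean and the standard error of the mean are then taken across
#' biological replicates, so `n` counts biological replicates. Missing cells
#' propagate as NA. With a single biological replicate the SEM is reported
#' as NA (not computable), mirroring the "not available" convention.
#'
#' @param per_run data.frame as returned by [quantify_run()] (rows from
#'   several runs bound together), containing at least `acetyl_degree`,
#'   `bio`, `me0`..`me3`, and optionally `condition`, `time_min`, `tech`.
#' @return Object of class `stoich_table`: list with
#'   `table` — tidy data.frame (`condition`, `time_min`, `acetyl_degree`,
#'   `me_state`, `mean_pct`, `sem`, `n`) — and `bio`, the per-biological-
#'   replicate means the table was computed from (used by
#'   [compare_conditions()]).
#' @export
aggregate_replicates <- function(per_run) {
  stopifnot(is.data.frame(per_run), "bio" %in% names(per_run))
  if (!"condition" %in% names(per_run)) per_run$condition <- "all"
  if (!"time_min" %in% names(per_run)) per_run$time_min <- NA_real_
  me <- c("me0", "me1", "me2", "me3")
  # aggregate() drops NA grouping levels; keep a missing time point as a
  # real group via a sentinel key and restore NA afterwards
  tm_na <- is.na(per_run$time_min)
  if (any(tm_na)) per_run$time_min[tm_na] <- -Inf
  key_bio <- c("condition", "time_min", "acetyl_degree", "bio")
  bio <- stats::aggregate(per_run[me], per_run[key_bio],
                          FUN = mean, na.rm = FALSE)
  key <- c("condition", "time_min", "acetyl_degree")
  agg <- stats::aggregate(bio[me], bio[key], FUN = function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    c(mean = if (n) mean(x) else NA_real_,
      sem = if (n > 1L) stats::sd(x) / sqrt(n) else NA_real_,
      n = n)
  })
  rows <- lapply(me, function(m) {
    cbind(agg[key],
          data.frame(me_state = m, mean_pct = agg[[m]][, "mean"],
                     sem = agg[[m]][, "sem"], n = as.integer(agg[[m]][, "n"])))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$condition, tab$time_min, tab$acetyl_degree,
                   match(tab$me_state, me)), ]
  rownames(tab) <- NULL
  tab$time_min[is.infinite(tab$time_min)] <- NA_real_
  bio$time_min[is.infinite(bio$time_min)] <- NA_real_
  structure(list(table = tab, bio = bio), class = "stoich_table")
}

#' @export
print.stoich_table <- function(x, ...) {
  print(x$table, ...)
  invisible(x)
}

.pooled_t <- function(x, y, var.equal = TRUE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L)
    stop("both groups need n >= 2 biological replicates", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = nx + ny - 2, p = 1))
    stop("degenerate-variance: both groups constant with unequal means",
         call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = var.equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Compare one stoichiometry cell between two conditions
#'
#' Two-sample two-tailed t-test on the biological-replicate values of the
#' selected cell (one acetyl degree x one K4 methyl state). The default is
#' the Student pooled-variance test; `var.equal = FALSE` gives Welch. No
#' multiple-testing correction is applied here; see
#' [compare_all_conditions()] for tabulated comparisons with optional
#' Benjamini-Hochberg adjustment.
#'
#' @param a,b `stoich_table` objects (from [aggregate_replicates()]).
#' @param degree acetyl degree (0-5).
#' @param me_state one of `"me0".."me3"`.
#' @param time_min optional time point selector (NA matches NA).
#' @param var.equal pooled variance (TRUE, default) or Welch (FALSE).
#' @return list with `t`, `df`, `p`, and the two group vectors.
#' @export
compare_conditions <- function(a, b, degree, me_state, time_min = NULL,
                               var.equal = TRUE) {
  stopifnot(inherits(a, "stoich_table"), inherits(b, "stoich_table"))
  pick <- function(st) {
    d <- st$bio
    sel <- d$acetyl_degree == degree
    if (!is.null(time_min))
      sel <- sel & (is.na(time_min) & is.na(d$time_min) |
                      !is.na(d$time_min) & d$time_min %in% time_min)
    v <- d[[me_state]][sel]
    v[!is.na(v)]
  }
  x <- pick(a); y <- pick(b)
  res <- .pooled_t(x, y, var.equal = var.equal)
  c(res, list(group_a = x, group_b = y))
}

#' All-cell condition comparison
#'
#' Runs [compare_conditions()] for every (degree, me state) cell present in
#' both tables and returns a tidy p-value table; raw p-values by default,
#' Benjamini-Hochberg adjusted values added on request.
#'
#' @param a,b `stoich_table` objects.
#' @param time_min optional time point selector.
#' @param var.equal pooled (TRUE) vs Welch (FALSE).
#' @param p_adjust add a `p_bh` column of Benjamini-Hochberg adjusted
#'   p-values (default FALSE: raw p-values are reported).
#' @return data.frame (`acetyl_degree`, `me_state`, `t`, `df`, `p`
#'   [, `p_bh`]); cells whose test is not computable (missing data, n < 2)
#'   carry NA.
#' @export
compare_all_conditions <- function(a, b, time_min = NULL, var.equal = TRUE,
                                   p_adjust = FALSE) {
  me <- c("me0", "me1", "me2", "me3")
  grid <- expand.grid(acetyl_degree = 0:5, me_state = me,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    tryCatch({
      r <- compare_conditions(a, b, grid$acetyl_degree[i], grid$me_state[i],
                              time_min = time_min, var.equal = var.equal)
      data.frame(t = r$t, df = r$df, p = r$p)
    }, error = function(e) data.frame(t = NA_real_, df = NA_real_,
                                      p = NA_real_))
  })
  out <- cbind(grid, do.call(rbind, res))
  if (p_adjust) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}
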