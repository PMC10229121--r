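#' Mixture specification: ground truth for a synthetic run
#'
#' Describes the proteoform population of one sample: per acetyl degree
#' (0ac-5ac) an abundance (arbitrary intensity units) and the K4 methyl
#' stoichiometry vector (me0, me1, me2, me3) that sums to 1.
#'
#' @param abundance numeric length 6 (degrees 0..5), all >= 0, at least one
#'   > 0.
#' @param pi 6 x 4 matrix of K4 methyl fractions; row a+1 is the (me0..me3)
#'   stoichiometry within degree a. Each row must be non-negative and sum to
#'   1 (rows of zero-abundance degrees may be anything non-negative summing
#'   to 1).
#' @return Object of class `mixture_spec`.
#' @examples
#' pi <- matrix(rep(c(0.7, 0.2, 0.08, 0.02), 6), 6, 4, byrow = TRUE)
#' mixture_spec(abundance = c(40, 25, 15, 10, 6, 4), pi = pi)
#' @export
mixture_spec <- function(abundance, pi) {
  abundance <- as.numeric(abundance)
  pi <- as.matrix(pi)
  if (length(abundance) != 6L || any(abundance < 0) || all(abundance == 0))
    stop("abundance must be 6 non-negative values with at least one > 0",
         call. = FALSE)
  if (!all(dim(pi) == c(6L, 4L)) || any(pi < 0))
    stop("pi must be a non-negative 6 x 4 matrix", call. = FALSE)
  if (any(abs(rowSums(pi) - 1) > 1e-12))
    stop("each row of pi must sum to 1 (within 1e-12)", call. = FALSE)
  dimnames(pi) <- list(degree = as.character(0:5),
                       me = c("me0", "me1", "me2", "me3"))
  names(abundance) <- as.character(0:5)
  structure(list(abundance = abundance, pi = pi), class = "mixture_spec")
}

#' Acquisition configuration for the synthetic instrument
#'
#' Holds the targeted acquisition scheme: per-degree retention-time windows
#' (half-open, minutes), MS1 and narrow MS2 scan ranges, the scan cadence,
#' chromatographic peak shape, and the noise model (multiplicative lognormal
#' on peak intensities, parameterized by a coefficient of variation, plus a
#' uniform additive baseline that also populates off-target background
#' peaks).
#'
#' @param rt_windows named list `"0"`..`"5"` of `c(start, end)` minutes;
#'   default [DEFAULT_RT_WINDOWS].
#' @param ms1_range,ms2_range numeric length-2 scan ranges in Th.
#' @param scan_interval seconds between scans of one level; default 2.
#' @param peak_width chromatographic bell standard deviation in minutes.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   intensity noise; 0 disables it.
#' @param baseline upper bound of the uniform additive baseline (intensity
#'   units); 0 disables baseline and background peaks.
#' @param n_background number of random off-target background peaks per MS2
#'   scan when `baseline > 0`.
#' @param include_ms1 also emit MS1 scans (default TRUE).
#' @param isotope_envelope emit a simple binomial-carbon isotope envelope per
#'   stick instead of a single monoisotopic peak (default FALSE).
#' @return Object of class `acquisition_config`.
#' @export
acquisition_config <- function(rt_windows = DEFAULT_RT_WINDOWS,
                               ms1_range = DEFAULT_MS1_RANGE,
                               ms2_range = DEFAULT_MS2_RANGE,
                               scan_interval = 2,
                               peak_width = 1,
                               noise_cv = 0,
                               baseline = 0,
                               n_background = 20,
                               include_ms1 = TRUE,
                               isotope_envelope = FALSE) {
  stopifnot(length(ms1_range) == 2L, length(ms2_range) == 2L)
  if (ms1_range[1] <= 0 || diff(ms1_range) <= 0 ||
      ms2_range[1] <= 0 || diff(ms2_range) <= 0)
    stop("scan ranges must be positive and ordered", call. = FALSE)
  if (!setequal(names(rt_windows), as.character(0:5)))
    stop("rt_windows must be named '0'..'5'", call. = FALSE)
  for (k in names(rt_windows)) {
    w <- rt_windows[[k]]
    if (length(w) != 2L || !is.numeric(w) || w[1] >= w[2])
      stop("malformed RT window for degree ", k, ": start must be < end",
           call. = FALSE)
  }
  iv <- do.call(rbind, rt_windows[as.character(0:5)])
  if (any(iv[-1, 1] < iv[-6, 2]))
    stop("RT windows must not overlap (shared boundaries allowed)",
         call. = FALSE)
  if (scan_interval <= 0 || peak_width <= 0)
    stop("scan_interval and peak_width must be > 0", call. = FALSE)
  if (noise_cv < 0 || baseline < 0)
    stop("noise_cv and baseline must be >= 0", call. = FALSE)
  structure(list(rt_windows = rt_windows[as.character(0:5)],
                 ms1_range = ms1_range, ms2_range = ms2_range,
                 scan_interval = scan_interval, peak_width = peak_width,
                 noise_cv = noise_cv, baseline = baseline,
                 n_background = as.integer(n_background),
                 include_ms1 = isTRUE(include_ms1),
                 isotope_envelope = isTRUE(isotope_envelope)),
            class = "acquisition_config")
}

# lognormal multiplicative noise with unit mean; cv = 0 -> exactly 1
.noise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

# binomial-carbon isotope envelope: each stick spread over +0..+3 neutrons
.isotopize <- function(mz, intensity, charge, n_carbon) {
  p13 <- 0.0107
  k <- 0:3
  frac <- stats::dbinom(k, n_carbon, p13)
  frac <- frac / sum(frac)
  list(mz = as.vector(outer(1.003355 * k / charge, mz, `+`)),
       intensity = as.vector(outer(frac, intensity, `*`)))
}

# theoretical [M+9H]9+ precursor m/z for acetyl degree a, K4 states me0..me3
.precursors_for_degree <- function(degree, charge = 9L) {
  base <- proteoform_mass(proteoform(H3_1_50)) +
    degree * mass_constants$ptm_deltas[["ac"]]
  me <- c(0, mass_constants$ptm_deltas[c("me1", "me2", "me3")])
  stats::setNames((base + me + charge * mass_constants$proton) / charge,
                  c("me0", "me1", "me2", "me3"))
}

#' Simulate one targeted middle-down MS run
#'
#' Emits a run whose MS2 scans appear only inside the retention-time windows
#' of acetyl degrees with non-zero abundance. Every MS2 scan carries the four
#' C4+1 sticks at their theoretical m/z, with expected intensities
#' proportional to `abundance[a] * pi[a, ]` modulated by a symmetric
#' chromatographic bell, the lognormal noise and the additive baseline. The
#' precursor isolation target cycles through the four theoretical [M+9H]9+
#' m/z of the degree's K4 methyl states. With `noise_cv = 0` and
#' `baseline = 0` intensities are exactly proportional to the ground truth.
#'
#' @param mix a [mixture_spec]: the ground truth.
#' @param cfg an [acquisition_config].
#' @param seed integer seed; identical seed and inputs give an identical run.
#' @param metadata named list attached to the run (replicate id, condition,
#'   time point, ...).
#' @return Object of class `ms_run`: list with `scans` (each: `level`, `rt`,
#'   `precursor_mz`, `mz`, `intensity`), `metadata`, and `ground_truth`
#'   (a copy of `mix`).
#' @export
simulate_run <- function(mix, cfg = acquisition_config(), seed = 1L,
                         metadata = list()) {
  stopifnot(inherits(mix, "mixture_spec"), inherits(cfg, "acquisition_config"))
  set.seed(as.integer(seed))
  c4 <- unname(c4_targets())
  scans <- list()
  for (a in 0:5) {
    ab <- mix$abundance[[as.character(a)]]
    if (ab == 0) next
    w <- cfg$rt_windows[[as.character(a)]]
    times <- seq(w[1], w[2] - 1e-9, by = cfg$scan_interval / 60)
    mid <- mean(w)
    prec <- .precursors_for_degree(a)
    piv <- mix$pi[a + 1L, ]
    for (i in seq_along(times)) {
      t <- times[i]
      bell <- exp(-0.5 * ((t - mid) / cfg$peak_width)^2)
      expected <- ab * piv * bell
      if (cfg$include_ms1) {
        int1 <- expected * .noise_factor(4L, cfg$noise_cv) +
          stats::runif(4L, 0, cfg$baseline)
        mz1 <- unname(prec)
        if (cfg$isotope_envelope) {
          env <- .isotopize(mz1, int1, 9L, n_carbon = 238L)
          mz1 <- env$mz; int1 <- env$intensity
        }
        o <- order(mz1)
        scans[[length(scans) + 1L]] <- list(
          level = 1L, rt = t, precursor_mz = NA_real_,
          scan_range = cfg$ms1_range, mz = mz1[o],
          intensity = unname(int1[o]))
      }
      int2 <- expected * .noise_factor(4L, cfg$noise_cv) +
        stats::runif(4L, 0, cfg$baseline)
      mz2 <- c4
      if (cfg$isotope_envelope) {
        env <- .isotopize(mz2, int2, 1L, n_carbon = 20L)
        mz2 <- env$mz; int2 <- env$intensity
      }
      if (cfg$baseline > 0 && cfg$n_background > 0L) {
        mz2 <- c(mz2, stats::runif(cfg$n_background,
                                   cfg$ms2_range[1], cfg$ms2_range[2]))
        int2 <- c(int2, stats::runif(cfg$n_background, 0, cfg$baseline))
      }
      o <- order(mz2)
      scans[[length(scans) + 1L]] <- list(
        level = 2L, rt = t,
        precursor_mz = unname(prec[(i - 1L) %% 4L + 1L]),
        scan_range = cfg$ms2_range, mz = mz2[o],
        intensity = unname(int2[o]))
    }
  }
  rt <- vapply(scans, `[[`, 0, "rt")
  lvl <- vapply(scans, `[[`, 0L, "level")
  structure(list(scans = scans[order(rt, lvl)], metadata = metadata,
                 ground_truth = mix), class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  lvl <- vapply(x$scans, `[[`, 0L, "level")
  cat(sprintf("<ms_run> %d scans (%d MS1, %d MS2)\n",
              length(x$scans), sum(lvl == 1L), sum(lvl == 2L)))
  invisible(x)
}

# perturb a mixture at the biological-replicate level: lognormal jitter on
# abundances and on stoichiometry entries, rows renormalized
.perturb_mixture <- function(mix, bio_cv) {
  if (bio_cv == 0) return(mix)
  ab <- mix$abundance * .noise_factor(6L, bio_cv)
  if (all(ab == 0)) ab <- mix$abundance
  pi <- mix$pi * matrix(.noise_factor(24L, bio_cv), 6L, 4L)
  zero <- rowSums(pi) == 0
  pi[zero, ] <- mix$pi[zero, ]
  mixture_spec(ab, pi / rowSums(pi))
}

#' Simulate a replicated treatment time course
#'
#' For each time point the mixture is resampled per biological replicate
#' (lognormal perturbation of abundances and stoichiometries, controlled by
#' `bio_cv`), and each technical replicate re-acquires the same biological
#' sample with fresh acquisition noise only. The default design mirrors a
#' KDAC-inhibition experiment: biological triplicate, two technical
#' replicates per biological replicate.
#'
#' @param trajectory list of `list(time_min =, mix =)` entries; `mix` a
#'   [mixture_spec].
#' @param cfg an [acquisition_config].
#' @param n_bio,n_tech replicate counts (>= 1).
#' @param bio_cv biological between-replicate coefficient of variation.
#' @param condition condition label stored in each run's metadata.
#' @param seed integer master seed; per-run seeds are derived from it.
#' @return List of [simulate_run()] outputs, each with metadata fields
#'   `condition`, `time_min`, `bio`, `tech`.
#' @export
simulate_timecourse <- function(trajectory, cfg = acquisition_config(),
                                n_bio = 3L, n_tech = 2L, bio_cv = 0,
                                condition = "treated", seed = 1L) {
  if (!length(trajectory)) stop("empty trajectory", call. = FALSE)
  stopifnot(n_bio >= 1L, n_tech >= 1L)
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L,
                          length(trajectory) * n_bio * (n_tech + 1L))
  runs <- list()
  k <- 0L
  for (tp in trajectory) {
    for (b in seq_len(n_bio)) {
      k <- k + 1L
      set.seed(sub_seeds[k])
      bio_mix <- .perturb_mixture(tp$mix, bio_cv)
      for (te in seq_len(n_tech)) {
        k <- k + 1L
        runs[[length(runs) + 1L]] <- simulate_run(
          bio_mix, cfg, seed = sub_seeds[k],
          metadata = list(condition = condition, time_min = tp$time_min,
                          bio = b, tech = te))
      }
    }
  }
  runs
}

#' Simulate a steady-state enzyme-velocity titration
#'
#' Hill kinetics: `v(S) = kcat * E * S^h / (K05^h + S^h)` plus additive
#' Gaussian noise. With `h = 1` this is the Michaelis-Menten form.
#' Concentration units cancel as long as `K05` and `S` share one.
#'
#' @param K05 half-saturation constant (> 0), same unit as `S`.
#' @param kcat turnover number (min^-1).
#' @param h Hill coefficient (> 0).
#' @param E enzyme concentration, same unit as velocity normalization.
#' @param S substrate concentrations (>= 0), e.g. from [make_titration()].
#' @param noise_sd additive Gaussian noise SD on velocities.
#' @param n_rep replicates per concentration.
#' @param seed integer seed.
#' @return data.frame with columns `substrate_nM`, `v`, `replicate`.
#' @export
simulate_kinetics <- function(K05, kcat, h = 1, E = 4, S, noise_sd = 0,
                              n_rep = 1L, seed = 1L) {
  if (K05 <= 0 || h <= 0) stop("K05 and h must be > 0", call. = FALSE)
  if (kcat < 0 || E <= 0) stop("kcat must be >= 0 and E > 0", call. = FALSE)
  if (any(S < 0)) stop("substrate concentrations must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  out <- do.call(rbind, lapply(seq_len(n_rep), function(r) {
    v <- kcat * E * S^h / (K05^h + S^h)
    data.frame(substrate_nM = S,
               v = v + stats::rnorm(length(S), 0, noise_sd),
               replicate = r)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a bead-proximity binding series
#'
#' Four-parameter-logistic signal
#' `y(Q) = bottom + (top - bottom) / (1 + (ec50/Q)^hillslope)` with
#' multiplicative lognormal noise, and an optional hook effect: beyond
#' `hook$onset` the signal is suppressed by `(Q / onset)^(-hook$strength)`,
#' emulating query exceeding bead saturation.
#'
#' @param bottom,top plateau signals (counts), `top > bottom` for a binder.
#' @param ec50 relative EC50 (> 0), same unit as `Q`.
#' @param hillslope Hill slope (> 0).
#' @param Q query concentrations (>= 0, nM).
#' @param noise_cv multiplicative lognormal CV on counts.
#' @param hook `NULL` (default, off) or `list(onset =, strength =)`.
#' @param n_rep replicates per concentration (assays are typically run in
#'   duplicate).
#' @param seed integer seed.
#' @return data.frame with columns `query_nM`, `counts`, `replicate`.
#' @export
simulate_binding <- function(bottom, top, ec50, hillslope = 1, Q,
                             noise_cv = 0, hook = NULL, n_rep = 2L,
                             seed = 1L) {
  if (ec50 <= 0 || hillslope <= 0)
    stop("ec50 and hillslope must be > 0", call. = FALSE)
  if (any(Q < 0)) stop("query concentrations must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  y <- bottom + (top - bottom) / (1 + (ec50 / Q)^hillslope)
  y[Q == 0] <- bottom
  if (!is.null(hook)) {
    over <- Q > hook$onset
    y[over] <- y[over] * (Q[over] / hook$onset)^(-hook$strength)
  }
  out <- do.call(rbind, lapply(seq_len(n_rep), function(r) {
    data.frame(query_nM = Q,
               counts = y * .noise_factor(length(Q), noise_cv),
               replicate = r)
  }))
  rownames(out) <- NULL
  out
}
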