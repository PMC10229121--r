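test_that("mixture_spec validates its invariants", {
  pi_ok <- matrix(0.25, 6, 4)
  expect_s3_class(mixture_spec(c(1, 0, 0, 0, 0, 0), pi_ok), "mixture_spec")
  expect_error(mixture_spec(rep(0, 6), pi_ok), "at least one")
  expect_error(mixture_spec(c(-1, rep(1, 5)), pi_ok), "non-negative")
  bad <- pi_ok; bad[2, 1] <- 0.3
  expect_error(mixture_spec(rep(1, 6), bad), "sum to 1")
})

test_that("acquisition_config rejects malformed windows and ranges", {
  expect_error(acquisition_config(rt_windows = modifyList(
    DEFAULT_RT_WINDOWS, list("3" = c(68, 62)))), "malformed")
  w <- DEFAULT_RT_WINDOWS; w[["1"]] <- c(45, 57)   # overlaps 2ac
  expect_error(acquisition_config(rt_windows = w), "overlap")
  expect_error(acquisition_config(ms1_range = c(640, 585)), "ordered")
  expect_error(acquisition_config(noise_cv = -0.1), ">= 0")
})

test_that("identical seed and inputs give a bit-identical run", {
  cfg <- fast_cfg(noise_cv = 0.2, baseline = 5)
  r1 <- simulate_run(test_mixture(), cfg, seed = 7)
  r2 <- simulate_run(test_mixture(), cfg, seed = 7)
  expect_identical(r1, r2)
  r3 <- simulate_run(test_mixture(), cfg, seed = 8)
  expect_false(identical(r1$scans, r3$scans))
})

test_that("noise-free stoichiometry survives the full round trip to 1e-9", {
  mix <- test_mixture()
  run <- simulate_run(mix, fast_cfg(), seed = 1)
  rec <- quantify_run(run)
  rel_err <- stoich_abs_error(rec, mix) / (100 * mix$pi)
  expect_lt(max(rel_err), 1e-9)
})

test_that("zero-abundance degrees yield no MS2 scans in their window", {
  mix <- test_mixture(abundance = c(40, 25, 15, 10, 6, 0))
  run <- simulate_run(mix, fast_cfg(), seed = 3)
  rts <- vapply(Filter(function(s) s$level == 2L, run$scans), `[[`, 0, "rt")
  expect_false(any(rts >= 74 & rts < 78))
  expect_error(simulate_run(
    mixture_spec(rep(0, 6), matrix(0.25, 6, 4)), fast_cfg()),
    "at least one")
})

test_that("all simulated MS1 peaks fall inside the 585-640 window", {
  run <- simulate_run(test_mixture(),
                      acquisition_config(scan_interval = 30), seed = 2)
  ms1 <- Filter(function(s) s$level == 1L, run$scans)
  expect_gt(length(ms1), 0)
  mzs <- unlist(lapply(ms1, `[[`, "mz"))
  expect_true(all(mzs >= 585 & mzs <= 640))
})

test_that("timecourse emits n_bio x n_tech runs per time point", {
  mix <- test_mixture()
  traj <- lapply(c(0, 10, 20, 30, 60, 120),
                 function(t) list(time_min = t, mix = mix))
  runs <- simulate_timecourse(traj, fast_cfg(), n_bio = 3, n_tech = 2,
                              seed = 5)
  expect_length(runs, 36)
  meta <- do.call(rbind, lapply(runs, function(r)
    as.data.frame(r$metadata)))
  expect_identical(nrow(unique(meta[c("time_min", "bio", "tech")])), 36L)
  expect_error(simulate_timecourse(list(), fast_cfg()), "empty")
})

test_that("with zero noise all replicates recover identical stoichiometry", {
  traj <- list(list(time_min = 0, mix = test_mixture()))
  runs <- simulate_timecourse(traj, fast_cfg(), n_bio = 2, n_tech = 2,
                              bio_cv = 0, seed = 9)
  recs <- lapply(runs, function(r) quantify_run(r)[c("me0", "me1", "me2",
                                                     "me3")])
  for (i in 2:4) expect_equal(recs[[1]], recs[[i]], tolerance = 1e-12)
})

test_that("a monotone me3-within-5ac trajectory is recovered monotone", {
  me3 <- c(0.05, 0.15, 0.30, 0.50)
  traj <- lapply(seq_along(me3), function(i) {
    pi <- test_mixture()$pi
    pi[6, ] <- c(1 - me3[i] - 0.2, 0.1, 0.1, me3[i])
    list(time_min = (i - 1) * 10,
         mix = mixture_spec(test_mixture()$abundance, pi))
  })
  runs <- simulate_timecourse(traj, fast_cfg(), n_bio = 1, n_tech = 1,
                              seed = 13)
  rec <- vapply(runs, function(r) {
    q <- quantify_run(r)
    q$me3[q$acetyl_degree == 5]
  }, 0)
  expect_true(all(diff(rec) > 0))
})

test_that("kinetic generator obeys the half-saturation identity", {
  for (h in c(0.7, 1, 2.3)) {
    v <- simulate_kinetics(K05 = 140, kcat = 0.03, h = h, E = 4,
                           S = 140, noise_sd = 0)$v
    expect_equal(v, 0.03 * 4 / 2, tolerance = 1e-12)
  }
  S <- make_titration(400, 1.5, 8)
  mm <- 0.03 * 4 * S / (140 + S)
  expect_equal(simulate_kinetics(140, 0.03, h = 1, E = 4, S = S)$v, mm,
               tolerance = 1e-12)
  expect_error(simulate_kinetics(-1, 0.03, 1, 4, S), "K05")
  expect_error(simulate_kinetics(140, 0.03, 0, 4, S), "h")
})

test_that("hook-free 4PL series is strictly increasing when top > bottom", {
  Q <- sort(c(0.5, 1.5, 5, 15, 50, 150, 500))
  y <- simulate_binding(100, 10100, ec50 = 10, hillslope = 1.2, Q = Q,
                        noise_cv = 0, n_rep = 1)$counts
  expect_true(all(diff(y) > 0))
  # enabling the hook suppresses the high-concentration tail
  yh <- simulate_binding(100, 10100, 10, 1.2, Q = Q, noise_cv = 0,
                         hook = list(onset = 50, strength = 2),
                         n_rep = 1)$counts
  expect_true(all(yh[Q > 50] < y[Q > 50]))
  expect_identical(yh[Q <= 50], y[Q <= 50])
})
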