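# hand-built run: MS2 scans at given RTs/precursor with chosen C4 intensities
manual_run <- function(rts, precursor, intensities,
                       mz = unname(c4_targets())) {
  scans <- lapply(seq_along(rts), function(i) list(
    level = 2L, rt = rts[i], precursor_mz = precursor,
    scan_range = DEFAULT_MS2_RANGE, mz = mz,
    intensity = intensities[[i]]))
  structure(list(scans = scans, metadata = list(), ground_truth = NULL),
            class = "ms_run")
}

test_that("scan selection respects the RT window and precursor filter", {
  w3 <- acetyl_state_window(3)
  w5 <- acetyl_state_window(5)
  run <- manual_run(c(63, 64, 65), w3$precursors[["me0"]],
                    rep(list(c(100, 50, 25, 10)), 3))
  avg <- select_and_average(run, w3)
  expect_identical(avg$n_scans, 3L)
  expect_error(select_and_average(run, w5),
               class = "empty_window_error")
  # a scan with an off-window precursor is rejected even at the right RT
  run2 <- manual_run(63, w5$precursors[["me0"]],
                     list(c(100, 50, 25, 10)))
  expect_error(select_and_average(run2, w3),
               class = "empty_window_error")
})

test_that("averaging is the arithmetic mean on the bin grid", {
  w3 <- acetyl_state_window(3)
  run <- manual_run(c(63, 64), w3$precursors[["me0"]],
                    list(c(100, 0, 0, 0), c(300, 0, 0, 0)))
  avg <- select_and_average(run, w3)
  at474 <- avg$intensity[abs(avg$mz - 474.31) < 0.06]
  expect_equal(max(at474), 200)
})

test_that("the SNR rule drops scans dominated by off-target noise", {
  w3 <- acetyl_state_window(3)
  good <- list(level = 2L, rt = 63, precursor_mz = w3$precursors[["me0"]],
               scan_range = DEFAULT_MS2_RANGE,
               mz = c(unname(c4_targets()), 480, 490, 510),
               intensity = c(100, 50, 25, 10, 1, 1, 1))
  noisy <- good
  noisy$rt <- 64
  noisy$intensity <- c(1, 1, 1, 1, 500, 600, 700)
  run <- structure(list(scans = list(good, noisy), metadata = list(),
                        ground_truth = NULL), class = "ms_run")
  avg <- select_and_average(run, w3, snr_min = 3)
  expect_identical(avg$n_scans, 1L)
})

test_that("stoichiometry extraction normalizes the C4 quartet to 100", {
  w3 <- acetyl_state_window(3)
  run <- manual_run(63, w3$precursors[["me0"]], list(c(100, 0, 0, 0)))
  st <- extract_stoichiometry(select_and_average(run, w3))
  expect_equal(unname(st), c(100, 0, 0, 0))
  run_eq <- manual_run(63, w3$precursors[["me0"]], list(c(7, 7, 7, 7)))
  st_eq <- extract_stoichiometry(select_and_average(run_eq, w3))
  expect_equal(unname(st_eq), rep(25, 4))
  expect_equal(sum(st_eq), 100)
  run0 <- manual_run(63, w3$precursors[["me0"]], list(c(0, 0, 0, 0)))
  expect_error(extract_stoichiometry(select_and_average(run0, w3)),
               class = "undefined_stoichiometry_error")
  expect_error(extract_stoichiometry(select_and_average(run, w3),
                                     frag_tol = 8),
               "half the minimum target spacing")
})

test_that("noise-free simulated stoichiometry is recovered to 1e-9", {
  pi <- matrix(rep(c(0.70, 0.20, 0.08, 0.02), 6), 6, 4, byrow = TRUE)
  mix <- mixture_spec(rep(10, 6), pi)
  run <- simulate_run(mix, fast_cfg(), seed = 21)
  rec <- quantify_run(run)
  for (d in 0:5)
    expect_equal(unlist(rec[rec$acetyl_degree == d,
                            c("me0", "me1", "me2", "me3")]),
                 c(me0 = 70, me1 = 20, me2 = 8, me3 = 2),
                 tolerance = 1e-9)
})

test_that("every recovered stoichiometry row sums to 100 even under noise", {
  mix <- test_mixture()
  for (seed in 1:5) {
    run <- simulate_run(mix, fast_cfg(noise_cv = 0.3, baseline = 2),
                        seed = seed)
    rec <- quantify_run(run)
    sums <- rowSums(rec[c("me0", "me1", "me2", "me3")])
    expect_equal(sums, rep(100, 6), tolerance = 1e-9)
  }
})

test_that("extraction uses the same four targets for every acetyl degree", {
  # the windows differ in RT and precursors, never in fragment targets
  windows <- lapply(0:5, acetyl_state_window)
  prec <- t(vapply(windows, `[[`, numeric(4), "precursors"))
  expect_identical(nrow(unique(prec)), 6L)        # precursors per degree
  run <- simulate_run(test_mixture(), fast_cfg(), seed = 30)
  tops <- lapply(0:5, function(d) {
    avg <- select_and_average(run, windows[[d + 1]])
    sort(avg$mz[order(avg$intensity, decreasing = TRUE)[1:4]])
  })
  for (d in 1:5) expect_identical(tops[[d + 1]], tops[[1]])
})

test_that("missing windows propagate as NA cells, not zeros", {
  mix <- test_mixture(abundance = c(40, 25, 15, 10, 6, 0))
  run <- simulate_run(mix, fast_cfg(), seed = 4,
                      metadata = list(bio = 1L))
  rec <- quantify_run(run)
  expect_true(all(is.na(rec[rec$acetyl_degree == 5,
                            c("me0", "me1", "me2", "me3")])))
  expect_false(anyNA(rec[rec$acetyl_degree < 5, c("me0", "me3")]))
})

test_that("technical replicates average within biological replicates", {
  per_run <- data.frame(
    condition = "a", time_min = 0, acetyl_degree = 0,
    bio = c(1, 1, 2, 2, 3, 3), tech = rep(1:2, 3),
    me0 = c(8, 12, 18, 22, 28, 32), me1 = 50, me2 = 30,
    me3 = c(12, 8, 2, -2, -8, -12) + 10, n_scans = 5)
  st <- aggregate_replicates(per_run)
  cell <- st$table[st$table$me_state == "me0", ]
  expect_equal(cell$mean_pct, 20)            # bio means 10, 20, 30
  expect_equal(cell$sem, 10 / sqrt(3))       # = 5.7735
  expect_equal(cell$sem, 5.7735, tolerance = 1e-4)
  expect_identical(cell$n, 3L)
})

test_that("degenerate replicate designs are handled explicitly", {
  one <- data.frame(condition = "a", time_min = 0, acetyl_degree = 0,
                    bio = 1, tech = 1, me0 = 25, me1 = 25, me2 = 25,
                    me3 = 25, n_scans = 3)
  st <- aggregate_replicates(one)
  expect_true(all(is.na(st$table$sem)))
  expect_identical(unique(st$table$n), 1L)
  same <- do.call(rbind, lapply(1:3, function(b)
    transform(one, bio = b)))
  st2 <- aggregate_replicates(same)
  expect_equal(unique(st2$table$sem), 0)
})

test_that("condition comparison matches the closed-form pooled t-test", {
  mk <- function(vals) {
    per_run <- data.frame(condition = "x", time_min = 0, acetyl_degree = 2,
                          bio = seq_along(vals), tech = 1, me0 = vals,
                          me1 = 0, me2 = 0, me3 = 100 - vals, n_scans = 1)
    aggregate_replicates(per_run)
  }
  a <- mk(c(1, 2, 3)); b <- mk(c(11, 12, 13))
  res <- compare_conditions(a, b, degree = 2, me_state = "me0")
  # textbook pooled two-sample t
  sp2 <- (2 * stats::var(c(1, 2, 3)) + 2 * stats::var(c(11, 12, 13))) / 4
  t_oracle <- (mean(c(1, 2, 3)) - mean(c(11, 12, 13))) /
    sqrt(sp2 * (1 / 3 + 1 / 3))
  p_oracle <- 2 * stats::pt(abs(t_oracle), df = 4, lower.tail = FALSE)
  expect_equal(res$t, t_oracle, tolerance = 1e-10)
  expect_equal(res$p, p_oracle, tolerance = 1e-10)
  expect_equal(res$df, 4)
  # identical groups: p = 1 by convention
  expect_equal(compare_conditions(a, a, 2, "me0")$p, 1)
  # degenerate variance with unequal means
  expect_error(compare_conditions(mk(c(5, 5, 5)), mk(c(7, 7, 7)), 2, "me0"),
               "degenerate-variance")
  # single biological replicate
  expect_error(compare_conditions(mk(3), b, 2, "me0"), "n >= 2")
})

test_that("noisy recovery stays within 3 SEM of truth (seeded)", {
  mix <- test_mixture()
  traj <- list(list(time_min = 0, mix = mix))
  runs <- simulate_timecourse(traj, fast_cfg(noise_cv = 0.2), n_bio = 3,
                              n_tech = 2, seed = 1)
  per_run <- do.call(rbind, lapply(runs, quantify_run))
  st <- aggregate_replicates(per_run)
  tab <- st$table
  truth <- 100 * mix$pi
  tr <- truth[cbind(tab$acetyl_degree + 1,
                    match(tab$me_state, c("me0", "me1", "me2", "me3")))]
  ratio <- abs(tab$mean_pct - tr) / tab$sem
  # with n = 3 biological replicates the error/SEM ratio is t_2-distributed
  # (heavy tails), so coverage is checked across the 24 cells rather than
  # demanded of every single cell
  expect_gte(mean(ratio <= 3), 0.75)
  expect_lt(max(abs(tab$mean_pct - tr)), 3)   # no cell off by >3 points
})

test_that("all-cell comparison returns a tidy p-value table", {
  mix <- test_mixture()
  traj <- list(list(time_min = 0, mix = mix))
  mk <- function(seed) {
    runs <- simulate_timecourse(traj, fast_cfg(noise_cv = 0.1), n_bio = 3,
                                n_tech = 1, seed = seed)
    aggregate_replicates(do.call(rbind, lapply(runs, quantify_run)))
  }
  res <- compare_all_conditions(mk(1), mk(2), p_adjust = TRUE)
  expect_identical(nrow(res), 24L)
  expect_true(all(res$p >= 0 & res$p <= 1, na.rm = TRUE))
  expect_true(all(res$p_bh >= res$p, na.rm = TRUE))
})
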