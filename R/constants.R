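#' Monoisotopic mass constants
#'
#' Residue (amino-acid) monoisotopic masses in Da, small-molecule masses, and
#' the mass deltas of the post-translational modifications handled by the
#' package. The near-isobaric pair trimethyl (42.046950 Da) vs acetyl
#' (42.010565 Da) differs by 0.036385 Da and must remain distinguishable, so
#' all constants carry six decimal places.
#'
#' @format A named list with elements `residues` (named numeric vector of the
#'   20 standard amino acids), `water`, `proton`, `nh3`, and `ptm_deltas`
#'   (named numeric: `me1`, `me2`, `me3`, `ac`).
#' @export
mass_constants <- list(
  residues = c(
    G = 57.0214637230,  A = 71.0371137868,  S = 87.0320284089,
    P = 97.0527638506,  V = 99.0684139144,  T = 101.0476784727,
    C = 103.0091844768, L = 113.0840639782, I = 113.0840639782,
    N = 114.0429274460, D = 115.0269430310, Q = 128.0585775098,
    K = 128.0949630153, E = 129.0425930948, M = 131.0404846044,
    H = 137.0589118610, F = 147.0684139144, R = 156.1011110257,
    Y = 163.0633285365, W = 186.0793129515
  ),
  water = 18.010565,
  proton = 1.007276,
  nh3 = 17.026549,
  ptm_deltas = c(
    me1 = 14.015650,
    me2 = 28.031300,
    me3 = 42.046950,
    ac  = 42.010565
  )
)

#' Histone H3.1 Glu-C N-terminal peptide, residues 1-50
#'
#' Glu-C cleaves C-terminal to glutamate; the first Glu of human H3.1 is E50,
#' so middle-down analysis of the H3 tail works on this 50-residue peptide.
#' Its 9+ charge state falls inside the 585-640 m/z MS1 acquisition window.
#'
#' @export
H3_1_50 <- "ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPGTVALRE"

#' Acetylatable lysines quantified alongside K4
#'
#' The five H3-tail lysines whose acetylation defines the 0ac-5ac degrees.
#' K4 itself is excluded: the assay reads K4 methylation within each degree.
#'
#' @export
H3_ACETYL_SITES <- c(9L, 14L, 18L, 23L, 27L)

#' Default retention-time windows per acetyl degree (minutes)
#'
#' Acetylation lowers the tail's net charge, so higher acetyl degrees elute
#' later on reversed phase; the degrees are chromatographically separable and
#' each is assigned a retention-time window. Windows are half-open
#' `[start, end)`; a scan at exactly 55 min belongs to 2ac, not 1ac.
#'
#' @format Named list `"0"`..`"5"`, each `c(start, end)` in minutes.
#' @export
DEFAULT_RT_WINDOWS <- list(
  "0" = c(35, 40), "1" = c(45, 55), "2" = c(55, 60),
  "3" = c(62, 68), "4" = c(69, 73), "5" = c(74, 78)
)

#' Default MS1 scan range (m/z), covering the H3 tail 9+ charge state
#' @export
DEFAULT_MS1_RANGE <- c(585, 640)

#' Default narrow ion-trap MS2 scan range (m/z), bracketing the C4+1 series
#' @export
DEFAULT_MS2_RANGE <- c(470, 530)

#' Round half away from zero
#'
#' Rounding convention used when comparing computed m/z to printed integer
#' values (base `round` rounds half to even).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
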