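#' Construct a proteoform
#'
#' A proteoform is a peptide sequence plus a site-resolved set of PTMs. The
#' package models the Glu-C H3 N-terminal peptide (residues 1-50,
#' [H3_1_50]) decorated with lysine methylation (me1/me2/me3) and
#' acetylation (ac).
#'
#' @param sequence one-letter amino-acid string (non-empty, standard 20
#'   residues only).
#' @param ptms named character vector or list mapping 1-based residue
#'   positions to PTM kinds, e.g. `c("4" = "me3", "9" = "ac")`. May be empty.
#' @return An object of class `proteoform`: list with `sequence` and `ptms`
#'   (named character vector, names = positions, sorted by position).
#' @examples
#' p <- proteoform(H3_1_50, c("4" = "me3", "9" = "ac", "14" = "ac"))
#' proteoform_mass(p)
#' @export
proteoform <- function(sequence, ptms = character()) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("invalid-input: sequence must be a non-empty string", call. = FALSE)
  res <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(res, names(mass_constants$residues))
  if (length(unknown))
    stop("invalid-input: unknown residue letter(s): ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  ptms <- unlist(ptms)
  if (length(ptms)) {
    if (is.null(names(ptms)) || any(!nzchar(names(ptms))))
      stop("invalid-PTM: ptms must be named by residue position", call. = FALSE)
    pos <- suppressWarnings(as.integer(names(ptms)))
    kind <- as.character(ptms)
    if (anyNA(pos) || any(pos < 1L) || any(pos > length(res)))
      stop("invalid-PTM: position out of range", call. = FALSE)
    if (anyDuplicated(pos))
      stop("invalid-PTM: at most one PTM per position", call. = FALSE)
    bad <- setdiff(kind, names(mass_constants$ptm_deltas))
    if (length(bad))
      stop("invalid-PTM: unknown PTM kind(s): ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    if (any(res[pos] != "K"))
      stop("invalid-PTM: methylation/acetylation only allowed on K residues",
           call. = FALSE)
    o <- order(pos)
    ptms <- stats::setNames(kind[o], pos[o])
  } else {
    ptms <- stats::setNames(character(), character())
  }
  structure(list(sequence = sequence, ptms = ptms), class = "proteoform")
}

#' @export
print.proteoform <- function(x, ...) {
  cat(format_proteoform(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of a proteoform
#'
#' Residue masses plus one water plus the PTM mass deltas; modifications are
#' strictly additive so the near-isobaric me3/ac pair (delta 0.036385 Da)
#' stays distinct.
#'
#' @param p a [proteoform].
#' @return Monoisotopic mass in Da.
#' @export
proteoform_mass <- function(p) {
  stopifnot(inherits(p, "proteoform"))
  res <- strsplit(p$sequence, "")[[1]]
  sum(mass_constants$residues[res]) + mass_constants$water +
    sum(mass_constants$ptm_deltas[p$ptms])
}

#' m/z of a c-series fragment or precursor ion
#'
#' ETD cleaves the backbone N-Calpha bond giving N-terminal c-ions that
#' retain side-chain PTMs; the c4 ion of the H3 tail (A-R-T-K) reads out the
#' K4 methylation state directly. A c-ion is the first `index` residues plus
#' NH3; the precursor is the intact proteoform. Both are protonated to the
#' requested charge.
#'
#' @param p a [proteoform].
#' @param series `"c"` or `"precursor"`.
#' @param index residue count for c-ions (1 <= index < nchar(sequence));
#'   ignored for precursors.
#' @param charge positive integer charge state.
#' @return m/z in Th.
#' @examples
#' ion_mz(proteoform(H3_1_50), "c", 4, 1)          # ~474.31
#' ion_mz(proteoform(H3_1_50), "precursor", charge = 9)  # ~594.13
#' @export
ion_mz <- function(p, series = c("c", "precursor"), index = NULL, charge = 1L) {
  stopifnot(inherits(p, "proteoform"))
  series <- match.arg(series)
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != as.integer(charge))
    stop("charge must be a positive integer", call. = FALSE)
  if (series == "precursor")
    return((proteoform_mass(p) + charge * mass_constants$proton) / charge)
  n <- nchar(p$sequence)
  if (is.null(index) || index < 1L || index >= n)
    stop("c-ion index must satisfy 1 <= index < sequence length",
         call. = FALSE)
  res <- strsplit(p$sequence, "")[[1]][seq_len(index)]
  pos <- as.integer(names(p$ptms))
  deltas <- sum(mass_constants$ptm_deltas[p$ptms[pos <= index]])
  (sum(mass_constants$residues[res]) + deltas + mass_constants$nh3 +
      charge * mass_constants$proton) / charge
}

#' The four targeted C4+1 m/z values (K4 me0, me1, me2, me3)
#'
#' The K4 methyl-state readout ions; they round to the printed 474, 488, 502
#' and 516 and all fall inside the 470-530 narrow MS2 window regardless of
#' the proteoform's acetyl state (acetylation sits beyond residue 4).
#'
#' @return Named numeric vector `c(me0=, me1=, me2=, me3=)` in Th.
#' @export
c4_targets <- function() {
  base <- ion_mz(proteoform(H3_1_50), "c", 4, 1)
  c(me0 = base,
    me1 = base + mass_constants$ptm_deltas[["me1"]],
    me2 = base + mass_constants$ptm_deltas[["me2"]],
    me3 = base + mass_constants$ptm_deltas[["me3"]])
}

#' Enumerate H3 tail proteoforms over K4 methyl states and acetyl degrees
#'
#' Builds the quantification space: every combination of a K4 methyl state
#' with `d` acetyl marks placed on the acetylatable lysines, for each degree
#' `d` in `degrees`. K4 acetylation is excluded from this space (the assay
#' quantifies K4 methyl occupancy), as is N-terminal protein acetylation.
#'
#' @param k4_states subset of `c("me0","me1","me2","me3")`.
#' @param acetyl_sites K positions available for acetylation (distinct from
#'   4); default [H3_ACETYL_SITES].
#' @param degrees integer vector of acetyl degrees, each between 0 and
#'   `length(acetyl_sites)`.
#' @return List of [proteoform] objects, no duplicates; length
#'   `length(k4_states) * sum(choose(length(acetyl_sites), degrees))`.
#' @export
enumerate_h3_proteoforms <- function(k4_states = c("me0", "me1", "me2", "me3"),
                                     acetyl_sites = H3_ACETYL_SITES,
                                     degrees = 0:5) {
  k4_states <- match.arg(k4_states, several.ok = TRUE)
  acetyl_sites <- as.integer(acetyl_sites)
  seq_res <- strsplit(H3_1_50, "")[[1]]
  if (any(acetyl_sites == 4L) || any(seq_res[acetyl_sites] != "K"))
    stop("acetyl_sites must be K positions distinct from K4", call. = FALSE)
  if (anyDuplicated(acetyl_sites))
    stop("acetyl_sites must be distinct", call. = FALSE)
  if (any(degrees < 0L) || any(degrees > length(acetyl_sites)))
    stop("degree exceeds the number of acetylatable sites", call. = FALSE)
  out <- list()
  for (k4 in k4_states) {
    k4_ptm <- if (k4 == "me0") character() else stats::setNames(k4, "4")
    for (d in degrees) {
      combos <- if (d == 0L) list(integer()) else
        utils::combn(acetyl_sites, d, simplify = FALSE)
      for (sites in combos) {
        ptms <- c(k4_ptm, stats::setNames(rep("ac", length(sites)), sites))
        out[[length(out) + 1L]] <- proteoform(H3_1_50, ptms)
      }
    }
  }
  out
}

#' Serialize a proteoform to text notation
#'
#' Notation used in configs and reports, e.g.
#' `"H3(1-50) K4me3 K9ac K14ac K18ac"`; an unmodified peptide is
#' `"H3(1-50)"`. [parse_proteoform()] inverts it.
#'
#' @param p a [proteoform] (sequence must be the H3 1-50 peptide).
#' @return Single string.
#' @export
format_proteoform <- function(p) {
  stopifnot(inherits(p, "proteoform"))
  head <- if (identical(p$sequence, H3_1_50)) "H3(1-50)" else
    paste0("seq:", p$sequence)
  if (!length(p$ptms)) return(head)
  res <- strsplit(p$sequence, "")[[1]]
  pos <- as.integer(names(p$ptms))
  paste(c(head, paste0(res[pos], pos, unname(p$ptms))), collapse = " ")
}

#' Parse proteoform text notation
#'
#' @param x string such as `"H3(1-50) K4me3 K9ac"`.
#' @return A [proteoform].
#' @export
parse_proteoform <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  parts <- strsplit(trimws(x), "\\s+")[[1]]
  if (!length(parts)) stop("empty proteoform notation", call. = FALSE)
  seq <- if (parts[1] == "H3(1-50)") H3_1_50
         else if (startsWith(parts[1], "seq:")) sub("^seq:", "", parts[1])
         else stop("unrecognized proteoform header: ", parts[1], call. = FALSE)
  ptm_parts <- parts[-1]
  ptms <- character()
  if (length(ptm_parts)) {
    m <- regmatches(ptm_parts,
                    regexec("^([A-Z])([0-9]+)(me1|me2|me3|ac)$", ptm_parts))
    bad <- vapply(m, length, 1L) != 4L
    if (any(bad))
      stop("unparseable PTM token(s): ",
           paste(ptm_parts[bad], collapse = ", "), call. = FALSE)
    ptms <- stats::setNames(vapply(m, `[`, "", 4L),
                            vapply(m, `[`, "", 3L))
  }
  proteoform(seq, ptms)
}
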