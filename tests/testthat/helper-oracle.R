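# Independent brute-force mass oracle: sums atom counts per residue and
# multiplies by element monoisotopic masses. Shares no code or residue
# table with the package implementation.

.ORACLE_ELEMENTS <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
                      O = 15.9949146221, S = 31.97207069)

# per-residue atom counts: C, H, N, O, S
.ORACLE_ATOMS <- rbind(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))
colnames(.ORACLE_ATOMS) <- c("C", "H", "N", "O", "S")

# neutral peptide mass: residue atoms + H2O, PTMs as elemental formulas
# (each methyl adds CH2; acetyl adds C2H2O)
oracle_peptide_mass <- function(sequence, n_me = 0, n_ac = 0) {
  res <- strsplit(sequence, "")[[1]]
  atoms <- colSums(.ORACLE_ATOMS[res, , drop = FALSE])
  atoms["H"] <- atoms["H"] + 2 + 2 * n_me + 2 * n_ac
  atoms["O"] <- atoms["O"] + 1 + n_ac
  atoms["C"] <- atoms["C"] + n_me + 2 * n_ac
  sum(atoms * .ORACLE_ELEMENTS[colnames(.ORACLE_ATOMS)])
}

# c-ion m/z: first `index` residues + NH3, protonated
oracle_cion_mz <- function(sequence, index, n_me = 0, n_ac = 0, charge = 1) {
  res <- strsplit(sequence, "")[[1]][seq_len(index)]
  atoms <- colSums(.ORACLE_ATOMS[res, , drop = FALSE])
  atoms["N"] <- atoms["N"] + 1
  atoms["H"] <- atoms["H"] + 3 + 2 * n_me + 2 * n_ac
  atoms["O"] <- atoms["O"] + n_ac
  atoms["C"] <- atoms["C"] + n_me + 2 * n_ac
  m <- sum(atoms * .ORACLE_ELEMENTS[colnames(.ORACLE_ATOMS)])
  (m + charge * 1.00727646688) / charge
}

# random proteoform: random sequence, random methyl/acetyl marks on lysines
random_proteoform <- function(min_len = 5, max_len = 50) {
  len <- sample(min_len:max_len, 1)
  seq <- paste(sample(rownames(.ORACLE_ATOMS), len, replace = TRUE),
               collapse = "")
  ks <- which(strsplit(seq, "")[[1]] == "K")
  ptms <- character()
  if (length(ks)) {
    n_mod <- sample.int(length(ks) + 1L, 1L) - 1L
    if (n_mod > 0) {
      pos <- ks[sample.int(length(ks), n_mod)]
      ptms <- stats::setNames(
        sample(c("me1", "me2", "me3", "ac"), n_mod, replace = TRUE), pos)
    }
  }
  proteoform(seq, ptms)
}

# PTM counts of a proteoform, for feeding the oracle
ptm_counts <- function(p) {
  kinds <- unname(p$ptms)
  c(n_me = sum(kinds == "me1") + 2 * sum(kinds == "me2") +
      3 * sum(kinds == "me3"),
    n_ac = sum(kinds == "ac"))
}
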