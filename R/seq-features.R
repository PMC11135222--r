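# Per-CDR physicochemical features: net charge (Henderson-Hasselbalch),
# isoelectric point (bisection), average hydrophilicity.

.PKA_TABLES <- list(
  # EMBOSS (iep) ionization constants
  emboss = c(Nterm = 8.6, Cterm = 3.6,
             C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1),
  # classic biochemistry-textbook (Lehninger) free-amino-acid values
  lehninger = c(Nterm = 9.69, Cterm = 2.34,
                C = 8.33, D = 3.86, E = 4.25, H = 6.0, K = 10.53, R = 12.48,
                Y = 10.07)
)

.HYDRO_SCALES <- list(
  # Hopp & Woods hydrophilicity values (window-free, per residue)
  hopp_woods = c(A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0, Q = 0.2,
                 E = 3.0, G = 0.0, H = -0.5, I = -1.8, L = -1.8, K = 3.0,
                 M = -1.3, F = -2.5, P = 0.0, S = 0.3, T = -0.4, W = -3.4,
                 Y = -2.3, V = -1.5)
)

#' pKa constants for peptide charge calculations
#'
#' Named sets of ionization constants for the peptide termini and the seven
#' ionizable side chains (D, E, C, Y, H, K, R). The default `"emboss"` set is
#' the one used by the EMBOSS `iep` tool; `"lehninger"` gives the classic
#' textbook free-amino-acid values. A custom named vector with the same
#' names is also accepted everywhere a pKa table is.
#'
#' @param name `"emboss"` or `"lehninger"`.
#' @return Named numeric vector (pH units) with names `Nterm`, `Cterm`,
#'   `C`, `D`, `E`, `H`, `K`, `R`, `Y`.
#' @export
#' @examples pkaTable("emboss")
pkaTable <- function(name = c("emboss", "lehninger")) {
  name <- match.arg(name)
  tab <- .PKA_TABLES[[name]]
  stopifnot(all(tab > 0 & tab < 14))
  tab
}

#' Per-residue hydrophilicity scale
#'
#' @param name Scale name; `"hopp_woods"` (the Hopp-Woods hydrophilicity
#'   values) is the default and currently the only built-in.
#' @return Named numeric vector covering the 20 standard residues.
#' @export
#' @examples hydroScale()[["R"]]
hydroScale <- function(name = "hopp_woods") {
  name <- match.arg(name, names(.HYDRO_SCALES))
  .HYDRO_SCALES[[name]]
}

.checkPka <- function(pka) {
  need <- c("Nterm", "Cterm", "C", "D", "E", "H", "K", "R", "Y")
  if (!all(need %in% names(pka)))
    stop("pKa table must name: ", paste(need, collapse = ", "))
  invisible(pka)
}

.checkSeqs <- function(seq, alphabet = aminoAcids()) {
  seq <- toupper(as.character(seq))
  ok <- .validSeq(seq, alphabet)
  if (!all(ok))
    stop("invalid or empty sequence(s): ",
         paste(head(seq[!ok]), collapse = ", "))
  seq
}

# residue counts of the ionizable groups, rows = sequences
.ionizableCounts <- function(seq) {
  groups <- c("C", "D", "E", "H", "K", "R", "Y")
  counts <- vapply(groups, function(g) {
    lengths(regmatches(seq, gregexpr(g, seq, fixed = TRUE)))
  }, integer(length(seq)))
  matrix(counts, nrow = length(seq), dimnames = list(NULL, groups))
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over the ionizable groups: the N-terminus and
#' the H, K, R side chains contribute `+1 / (1 + 10^(pH - pKa))` each; the
#' C-terminus and the D, E, C, Y side chains contribute
#' `-1 / (1 + 10^(pKa - pH))` each.
#'
#' @param seq Character vector of peptide sequences (20-letter alphabet).
#' @param pH pH at which to evaluate the charge (default 7.0, "neutral pH").
#' @param pka A [pkaTable()].
#' @return Numeric vector of net charges (elementary charge units).
#' @export
#' @examples
#' netCharge("KKKK")  # positive: lysine pKa > 7
#' netCharge("DDDD")  # negative
netCharge <- function(seq, pH = 7.0, pka = pkaTable()) {
  seq <- .checkSeqs(seq)
  .checkPka(pka)
  stopifnot(length(pH) == 1L, is.finite(pH))
  counts <- .ionizableCounts(seq)
  pos <- 1 / (1 + 10^(pH - pka[["Nterm"]])) +
    counts[, "H"] / (1 + 10^(pH - pka[["H"]])) +
    counts[, "K"] / (1 + 10^(pH - pka[["K"]])) +
    counts[, "R"] / (1 + 10^(pH - pka[["R"]]))
  neg <- 1 / (1 + 10^(pka[["Cterm"]] - pH)) +
    counts[, "D"] / (1 + 10^(pka[["D"]] - pH)) +
    counts[, "E"] / (1 + 10^(pka[["E"]] - pH)) +
    counts[, "C"] / (1 + 10^(pka[["C"]] - pH)) +
    counts[, "Y"] / (1 + 10^(pka[["Y"]] - pH))
  unname(pos - neg)
}

#' Isoelectric point of a peptide
#'
#' The pH at which [netCharge()] is zero, located by bisection on `[0, 14]`.
#' The net charge is strictly decreasing in pH and the free termini
#' guarantee a sign change, so the root exists and is unique.
#'
#' @inheritParams netCharge
#' @param tol Charge tolerance: bisection continues until `|netCharge|`
#'   falls below `tol` *and* the bracketing pH interval is below 1e-6, so
#'   the returned pH is accurate even where the titration curve is flat.
#' @return Numeric vector of pI values (pH units).
#' @export
#' @examples
#' isoelectricPoint("KKKK") > isoelectricPoint("DDDD")
isoelectricPoint <- function(seq, pka = pkaTable(), tol = 1e-4) {
  seq <- .checkSeqs(seq)
  .checkPka(pka)
  vapply(seq, function(s) {
    lo <- 0
    hi <- 14
    mid <- 7
    for (iter in seq_len(60L)) {
      mid <- (lo + hi) / 2
      ch <- netCharge(s, mid, pka)
      if (abs(ch) < tol && (hi - lo) < 1e-6) break
      if (ch > 0) lo <- mid else hi <- mid
    }
    mid
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Average hydrophilicity of a peptide
#'
#' Arithmetic mean of the per-residue scale values.
#'
#' @inheritParams netCharge
#' @param scale A [hydroScale()].
#' @return Numeric vector (scale units).
#' @export
#' @examples
#' avgHydrophilicity("RD")  # midpoint of the R and D values
avgHydrophilicity <- function(seq, scale = hydroScale()) {
  seq <- .checkSeqs(seq)
  if (!all(aminoAcids() %in% names(scale)))
    stop("hydrophilicity scale must cover the 20 standard residues")
  vapply(seq, function(s) {
    mean(scale[strsplit(s, "")[[1L]]])
  }, numeric(1L), USE.NAMES = FALSE)
}

#' The 12-component physicochemical feature vector of an antibody
#'
#' Hydrophilicity and isoelectric point for each of the six CDRs, in the
#' pair table's column order: (hydrophilicity, pI) for L CDR1..3, then
#' H CDR1..3.
#'
#' @param antibody An [AntibodyCdrSet-class].
#' @param pka A [pkaTable()].
#' @param scale A [hydroScale()].
#' @param tol pI bisection tolerance.
#' @return Named numeric vector of length 12 (names are the feature column
#'   names, `hyd_l_cdr1`, `pi_l_cdr1`, ...).
#' @export
featurize <- function(antibody, pka = pkaTable(), scale = hydroScale(),
                      tol = 1e-4) {
  stopifnot(is(antibody, "AntibodyCdrSet"))
  cc <- cdrs(antibody)
  out <- numeric(0)
  for (chain_cdr in c("l_cdr1", "l_cdr2", "l_cdr3",
                      "h_cdr1", "h_cdr2", "h_cdr3")) {
    s <- cc[[chain_cdr]]
    out <- c(out,
             setNames(avgHydrophilicity(s, scale), paste0("hyd_", chain_cdr)),
             setNames(isoelectricPoint(s, pka, tol), paste0("pi_", chain_cdr)))
  }
  out
}

#' Fill the feature columns of a pair table
#'
#' Recomputes the 12 hydrophilicity/pI columns from the CDR sequences,
#' deduplicating repeated CDR strings.
#'
#' @param table A [PairTable-class].
#' @inheritParams featurize
#' @return The table with all 12 feature columns populated.
#' @export
featurizeTable <- function(table, pka = pkaTable(), scale = hydroScale(),
                           tol = 1e-4) {
  stopifnot(is(table, "PairTable"))
  rec <- records(table)
  for (cc in .CDR_COLS) {
    seqs <- rec[[cc]]
    u <- unique(seqs)
    hyd <- avgHydrophilicity(u, scale)[match(seqs, u)]
    pi_ <- isoelectricPoint(u, pka, tol)[match(seqs, u)]
    rec[[paste0("hyd_", cc)]] <- hyd
    rec[[paste0("pi_", cc)]] <- pi_
  }
  initialize(table, records = rec)
}
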