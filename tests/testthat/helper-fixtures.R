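# Shared fixtures and independent oracles, built in code.

AA <- aminoAcids()

rand_pep <- function(len) paste(sample(AA, len, replace = TRUE), collapse = "")

rand_peps <- function(n, min_len = 5, max_len = 20) {
  vapply(seq_len(n), function(i) rand_pep(sample(min_len:max_len, 1)), "")
}

# a small hand-built pair table; cdrs: list of character(6) per record
toy_table <- function(cdrs, antigen, label, score = NA_real_) {
  stopifnot(length(cdrs) == length(antigen), length(antigen) == length(label))
  df <- do.call(rbind, lapply(cdrs, function(x) {
    as.data.frame(as.list(setNames(x, c("h_cdr1", "h_cdr2", "h_cdr3",
                                        "l_cdr1", "l_cdr2", "l_cdr3"))),
                  stringsAsFactors = FALSE)
  }))
  df$antigen <- antigen
  df$label <- label
  df$docking_score <- rep_len(score, length(antigen))
  PairTable(df)
}

base_cdrs <- c("GYTFTSYW", "IYPGDSDT", "ARWGGDGFYA",
               "QSLLNSRTRKNY", "WASTRES", "KQSYNLYT")

# substitute position `pos` of cdr `which` with residue `to`
mutate_cdr <- function(cdrs, which, pos, to) {
  s <- strsplit(cdrs[[which]], "")[[1]]
  s[pos] <- to
  cdrs[[which]] <- paste(s, collapse = "")
  cdrs
}

# independent dense pH-grid oracle for the isoelectric point; reimplements
# the Henderson-Hasselbalch sum directly from residue counts
grid_pi_oracle <- function(seq, pka = pkaTable(), step = 1e-4) {
  cnt <- vapply(c("C", "D", "E", "H", "K", "R", "Y"), function(g)
    lengths(regmatches(seq, gregexpr(g, seq, fixed = TRUE))), integer(1))
  ph <- seq(0, 14, by = step)
  ch <- 1 / (1 + 10^(ph - pka[["Nterm"]])) +
    cnt[["H"]] / (1 + 10^(ph - pka[["H"]])) +
    cnt[["K"]] / (1 + 10^(ph - pka[["K"]])) +
    cnt[["R"]] / (1 + 10^(ph - pka[["R"]])) -
    1 / (1 + 10^(pka[["Cterm"]] - ph)) -
    cnt[["D"]] / (1 + 10^(pka[["D"]] - ph)) -
    cnt[["E"]] / (1 + 10^(pka[["E"]] - ph)) -
    cnt[["C"]] / (1 + 10^(pka[["C"]] - ph)) -
    cnt[["Y"]] / (1 + 10^(pka[["Y"]] - ph))
  ph[which.min(abs(ch))]
}

# exhaustive minimal-edit-script enumeration (compiled plain recursion)
brute_edit <- function(a, b, model) {
  CDRknn:::brute_edit_dist_cpp(a, b, costMatrix(model), indelCost(model),
                               paste(rownames(costMatrix(model)),
                                     collapse = ""))
}

# all strings over `alphabet` of length 0..max_len
all_strings <- function(alphabet, max_len) {
  out <- ""
  for (l in seq_len(max_len))
    out <- c(out, do.call(paste0, expand.grid(rep(list(alphabet), l),
                                              stringsAsFactors = FALSE)))
  out
}
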