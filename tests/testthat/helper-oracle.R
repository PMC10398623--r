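# Independent brute-force oracle for formula enumeration: full nested
# grid over every element INCLUDING hydrogen, no mass-based pruning or
# hydrogen solving. Returns the sorted set of candidate formula strings.
oracle_enumerate <- function(mz, tol_ppm, bounds) {
  m <- element_masses()
  proton <- m[["H"]] - 0.00054857990907
  syms <- names(bounds)
  ranges <- lapply(syms, function(s) {
    if (s == "C") seq_len(bounds[[s]]) else 0:bounds[[s]]
  })
  names(ranges) <- syms
  g <- do.call(expand.grid, c(ranges, KEEP.OUT.ATTRS = FALSE))
  mass <- as.numeric(as.matrix(g) %*% m[syms])
  mz_theo <- mass - proton
  ppm <- (mz - mz_theo) / mz_theo * 1e6
  cnt <- function(s) if (s %in% names(g)) g[[s]] else 0
  rd <- cnt("C") - (cnt("H") + cnt("Cl") + cnt("F")) / 2 +
    (cnt("N") + cnt("P")) / 2 + 1
  keep <- abs(ppm) <= tol_ppm & cnt("H") >= 1 &
    rd >= 0 & abs(rd - round(rd)) < 1e-9 &
    cnt("H") / cnt("C") <= 3 & cnt("O") / cnt("C") <= 3
  if (!any(keep)) return(character(0))
  g <- g[keep, , drop = FALSE]
  sort(vapply(seq_len(nrow(g)), function(i) {
    format_formula(as_molform(unlist(g[i, , drop = TRUE])))
  }, character(1)))
}

# small bounds keep the full grid desk-sized in the oracle comparisons
oracle_bounds <- c(C = 25, H = 50, N = 2, O = 12, S = 2)

# random valid formula over the full supported element set (13C included)
random_formula <- function() {
  m <- element_masses()
  syms <- sample(names(m), sample(2:6, 1))
  if (!any(c("C", "H", "O") %in% syms)) syms <- c(syms, "C")
  counts <- stats::setNames(sample(1:12, length(syms), replace = TRUE),
                            syms)
  as_molform(counts)
}

# scrambled, non-canonical rendering of a formula (free element order,
# explicit 1s sometimes split into repeated tokens)
scramble_formula <- function(f) {
  sym <- names(f)
  sym_out <- ifelse(sym == "13C", "[13C]", sym)
  n <- unclass(f)
  o <- sample(length(sym))
  paste0(sym_out[o], ifelse(n[o] == 1 & stats::runif(length(o)) < 0.5,
                            "", as.character(n[o])), collapse = "")
}

table2_features <- function() {
  read_feature_table(system.file("extdata", "belukha_suspects.csv",
                                 package = "icescreen"))
}

table2_standards <- function() {
  read_standards(system.file("extdata", "belukha_standards.csv",
                             package = "icescreen"))
}
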