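#' Construct an MS/MS spectrum
#'
#' @param mz Fragment m/z values.
#' @param intensity Non-negative intensities (same length).
#' @param precursor_mz Optional precursor m/z.
#' @param name Optional compound name.
#' @return A `spectrum` object (peaks stored sorted by m/z).
#' @export
spectrum <- function(mz, intensity, precursor_mz = NA_real_,
                     name = NA_character_) {
  stopifnot(is.numeric(mz), is.numeric(intensity),
            length(mz) == length(intensity))
  if (length(mz) == 0) stop("spectrum has no peaks", call. = FALSE)
  if (any(intensity < 0)) stop("negative intensity", call. = FALSE)
  o <- order(mz)
  structure(list(mz = mz[o], intensity = intensity[o],
                 precursor_mz = precursor_mz, name = name),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum>", if (!is.na(x$name)) x$name else "",
      sprintf("(%d peaks%s)\n", length(x$mz),
              if (!is.na(x$precursor_mz))
                sprintf(", precursor %.4f", x$precursor_mz) else ""))
  invisible(x)
}

#' Normalize spectrum intensities to base peak = 100
#' @param s A `spectrum`.
#' @return A `spectrum` with maximum intensity 100.
#' @export
normalize_spectrum <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  m <- max(s$intensity)
  if (m == 0) stop("all-zero intensities", call. = FALSE)
  s$intensity <- s$intensity / m * 100
  s
}

#' Spectral similarity score (square-root cosine, 0-100)
#'
#' Surrogate for proprietary library "best match" scores: fragment peaks
#' of the two spectra are aligned greedily by nearest m/z within
#' `frag_tol`, intensities are square-root transformed, and the cosine
#' of the aligned vectors (unmatched peaks paired with zero) is scaled
#' to 0-100. Symmetric, invariant under uniform intensity scaling,
#' 100 for identical spectra and 0 for disjoint fragment sets.
#'
#' @param a,b `spectrum` objects (non-empty).
#' @param frag_tol Fragment matching tolerance in u (default 0.005).
#' @return Score in [0, 100].
#' @export
#' @examples
#' s1 <- spectrum(c(100, 150), c(100, 50))
#' s2 <- spectrum(100, 100)
#' spectral_similarity(s1, s2)  # 81.6
spectral_similarity <- function(a, b, frag_tol = 0.005) {
  stopifnot(inherits(a, "spectrum"), inherits(b, "spectrum"))
  if (length(a$mz) == 0 || length(b$mz) == 0) {
    stop("empty spectrum", call. = FALSE)
  }
  # greedy nearest-pair matching within tolerance
  pairs <- expand.grid(i = seq_along(a$mz), j = seq_along(b$mz))
  pairs$d <- abs(a$mz[pairs$i] - b$mz[pairs$j])
  pairs <- pairs[pairs$d <= frag_tol, , drop = FALSE]
  pairs <- pairs[order(pairs$d), , drop = FALSE]
  used_i <- logical(length(a$mz))
  used_j <- logical(length(b$mz))
  mi <- integer(0); mj <- integer(0)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (!used_i[i] && !used_j[j]) {
      used_i[i] <- TRUE; used_j[j] <- TRUE
      mi <- c(mi, i); mj <- c(mj, j)
    }
  }
  x <- c(sqrt(a$intensity[mi]), sqrt(a$intensity[!used_i]),
         rep(0, sum(!used_j)))
  y <- c(sqrt(b$intensity[mj]), rep(0, sum(!used_i)),
         sqrt(b$intensity[!used_j]))
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  100 * sum(x * y) / (nx * ny)
}

#' Read spectra from an MSP-like text file
#'
#' Blocks of the form `Name: ...`, optional `PrecursorMZ: ...`,
#' `Num Peaks: n`, followed by n `m/z intensity` lines; blocks separated
#' by blank lines.
#'
#' @param path Path to the MSP file.
#' @return Named list of `spectrum` objects.
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    name <- NA_character_; prec <- NA_real_; npk <- NA_integer_
    while (i <= length(lines) && grepl(":", lines[i], fixed = TRUE)) {
      kv <- strsplit(lines[i], ":", fixed = TRUE)[[1]]
      key <- tolower(trimws(kv[1]))
      val <- trimws(paste(kv[-1], collapse = ":"))
      if (key == "name") name <- val
      if (key %in% c("precursormz", "precursor_mz")) prec <- as.numeric(val)
      if (key %in% c("num peaks", "numpeaks")) npk <- as.integer(val)
      i <- i + 1L
    }
    if (is.na(npk)) stop("MSP block without 'Num Peaks' near line ", i,
                         call. = FALSE)
    pk <- lines[i:(i + npk - 1L)]
    i <- i + npk
    vals <- lapply(strsplit(trimws(pk), "[ \t]+"), as.numeric)
    mzv <- vapply(vals, `[`, numeric(1), 1L)
    iv <- vapply(vals, `[`, numeric(1), 2L)
    if (anyNA(mzv) || anyNA(iv)) {
      stop("malformed peak line in MSP block '", name, "'", call. = FALSE)
    }
    out[[if (is.na(name)) paste0("spectrum_", length(out) + 1L)
         else name]] <- spectrum(mzv, iv, prec, name)
  }
  out
}

#' Write spectra to an MSP-like text file
#'
#' @param spectra Named list of `spectrum` objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_msp <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(spectra)) {
    s <- spectra[[nm]]
    writeLines(sprintf("Name: %s", if (is.na(s$name)) nm else s$name), con)
    if (!is.na(s$precursor_mz)) {
      writeLines(sprintf("PrecursorMZ: %.5f", s$precursor_mz), con)
    }
    writeLines(sprintf("Num Peaks: %d", length(s$mz)), con)
    writeLines(sprintf("%.5f %.1f", s$mz, s$intensity), con)
    writeLines("", con)
  }
  invisible(path)
}
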