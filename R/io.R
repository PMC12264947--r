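# Scattering curves and secondary-structure label series: constructors and
# plain-text readers/writers.

DSSP_ALPHABET <- c("H", "G", "I", "E", "B", "T", "S", "P", "~")

#' Construct a scattering curve
#'
#' A `scatter_curve` is a tibble with columns `q` (scattering vector,
#' 1/Angstrom, strictly increasing), `intensity` (arbitrary units) and
#' optionally `sigma` (per-point uncertainty). An extrapolated zero-angle
#' intensity may be attached as the `i0` attribute (set by [guinier_rg()]).
#'
#' @param q Strictly increasing positive scattering vector values.
#' @param intensity Intensities, finite, same length as `q`.
#' @param sigma Optional positive uncertainties.
#' @param i0 Optional zero-angle intensity.
#' @return A tibble of class `scatter_curve`.
#' @export
scatter_curve <- function(q, intensity, sigma = NULL, i0 = NULL) {
  if (length(q) == 0L) {
    abort_ed("A scattering curve needs at least one point.", "empty_input")
  }
  check_finite(q, "q")
  check_finite(intensity, "intensity")
  if (any(q <= 0)) abort_ed("`q` must be positive.", "format")
  if (is.unsorted(q, strictly = TRUE)) {
    abort_ed("`q` must be strictly increasing.", "format")
  }
  if (length(intensity) != length(q)) {
    abort_ed("`q` and `intensity` lengths differ.", "format")
  }
  if (!is.null(sigma)) {
    check_finite(sigma, "sigma")
    if (any(sigma <= 0)) abort_ed("`sigma` must be positive.", "format")
  }
  out <- tibble::tibble(q = as.numeric(q), intensity = as.numeric(intensity))
  if (!is.null(sigma)) out$sigma <- as.numeric(sigma)
  structure(out, class = c("scatter_curve", class(out)), i0 = i0)
}

curve_i0 <- function(curve) attr(curve, "i0")

#' Read a 2- or 3-column ASCII scattering curve
#'
#' Columns are q (1/Angstrom), intensity, and optionally sigma. Lines
#' beginning with `#` are skipped. A non-monotone q grid is sorted with a
#' warning.
#'
#' @param path Path to the ASCII file.
#' @return A [scatter_curve()].
#' @export
read_scatter_curve <- function(path) {
  if (!file.exists(path)) abort_ed(sprintf("File not found: %s", path), "io")
  tab <- tryCatch(
    utils::read.table(path, comment.char = "#"),
    error = function(e) abort_ed(sprintf("Cannot parse %s as a numeric table: %s", path, conditionMessage(e)), "format")
  )
  if (nrow(tab) == 0L) abort_ed("Empty scattering file.", "format")
  if (ncol(tab) < 2L) abort_ed("Scattering file needs at least 2 columns (q, I).", "format")
  if (!all(vapply(tab[, 1:min(3L, ncol(tab))], is.numeric, TRUE))) {
    abort_ed("Scattering file columns must be numeric.", "format")
  }
  q <- tab[[1]]
  if (is.unsorted(q, strictly = TRUE)) {
    warn("q values were not strictly increasing; sorting the curve.")
    ord <- order(q)
    tab <- tab[ord, , drop = FALSE]
    q <- tab[[1]]
  }
  scatter_curve(q, tab[[2]], sigma = if (ncol(tab) >= 3L) tab[[3]] else NULL)
}

#' Write a scattering curve as 2/3-column ASCII
#' @param curve A [scatter_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scatter_curve <- function(curve, path) {
  df <- as.data.frame(curve)
  utils::write.table(
    df, path,
    sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Construct a secondary-structure label series
#'
#' Labels use the DSSP alphabet `H G I E B T S P ~` (alpha-helix, 3-10
#' helix, pi-helix, beta-ladder, beta-bridge, turn, bend, PPII helix,
#' unassigned). Stored as an `n_frames x n_residues` character matrix of
#' class `ss_series`.
#'
#' @param labels Character matrix (frames x residues) or a character vector
#'   of per-frame strings, one character per residue.
#' @return An `ss_series` matrix.
#' @export
ss_series <- function(labels) {
  if (is.character(labels) && !is.matrix(labels)) {
    widths <- nchar(labels)
    if (length(unique(widths)) != 1L) {
      abort_ed("Ragged label lines: all frames must have the same residue count.", "format")
    }
    labels <- do.call(rbind, strsplit(labels, ""))
  }
  if (!is.matrix(labels) || !is.character(labels)) {
    abort_ed("`labels` must be a character matrix or vector of strings.", "format")
  }
  bad <- setdiff(unique(as.vector(labels)), DSSP_ALPHABET)
  if (length(bad) > 0L) {
    abort_ed(
      sprintf("Illegal secondary-structure symbol(s): %s", paste(sQuote(bad), collapse = ", ")),
      "format"
    )
  }
  structure(labels, class = c("ss_series", "matrix"), alphabet = DSSP_ALPHABET)
}

#' Read a plain-text secondary-structure label matrix
#'
#' One line per frame, one character per residue.
#'
#' @param path Path to the label file.
#' @return An [ss_series()] matrix.
#' @export
read_ss_labels <- function(path) {
  if (!file.exists(path)) abort_ed(sprintf("File not found: %s", path), "io")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort_ed("Empty label file.", "format")
  ss_series(lines)
}

#' Write a secondary-structure label matrix as plain text
#' @param labels An [ss_series()] matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ss_labels <- function(labels, path) {
  writeLines(apply(unclass(labels), 1L, paste, collapse = ""), path)
  invisible(path)
}

#' Read a single amino-acid sequence from FASTA or a raw string
#'
#' @param x Path to a FASTA file, or a raw one-letter sequence string.
#' @return A one-letter uppercase sequence string.
#' @export
read_sequence <- function(x) {
  if (file.exists(x)) {
    seqs <- seqinr::read.fasta(x, seqtype = "AA", as.string = TRUE)
    if (length(seqs) == 0L) abort_ed("No sequences in FASTA file.", "format")
    return(toupper(as.character(seqs[[1]])))
  }
  toupper(gsub("[[:space:]]", "", x))
}
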