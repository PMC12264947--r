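# Sequence-level parameters: charge patterning (kappa), FCR/NCPR,
# hydropathy, disorder-promoting fraction, sliding-window scale profiles.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Kyte-Doolittle hydropathy (native -4.5 .. +4.5 scale)
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Zhao & London trans-membrane tendency scale
TRANSMEMBRANE_TENDENCY <- c(
  A = 0.38, R = -2.57, N = -1.62, D = -3.27, C = -0.30, Q = -1.84,
  E = -2.90, G = -0.19, H = -1.44, I = 1.97, L = 1.82, K = -3.46,
  M = 1.40, F = 1.98, P = -1.44, S = -0.53, T = -0.32, W = 1.53,
  Y = 0.49, V = 1.46
)

DISORDER_PROMOTING <- c("T", "A", "G", "R", "D", "H", "Q", "K", "S", "E", "P")

#' Histatin 1 wild-type sequence
#'
#' The 38-residue human Histatin 1 sequence used as the package's worked
#' example (net charge +1 with histidines neutral).
#' @export
HST1_SEQUENCE <- "DSHEKRHHGYRRKFHEKHHSHREFPFYGDYGSNYLYDN"

check_sequence <- function(sequence) {
  sequence <- read_sequence(sequence)
  if (nchar(sequence) == 0L) abort_ed("Empty sequence.", "empty_input")
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0L) {
    abort_ed(
      sprintf("Non-standard amino-acid letter(s): %s.", paste(sQuote(bad), collapse = ", ")),
      "alphabet"
    )
  }
  chars
}

#' Per-residue formal charges
#'
#' K, R are +1; D, E are -1; histidine is neutral by default (it can be
#' flagged charged for low-pH conventions); all other residues 0. Termini
#' are ignored, following the sequence-level charge-patterning convention.
#'
#' @param sequence One-letter sequence string (or FASTA path).
#' @param histidine_charged Treat H as +1 (default `FALSE`).
#' @return Integer vector of per-residue charges.
#' @export
charge_assign <- function(sequence, histidine_charged = FALSE) {
  chars <- check_sequence(sequence)
  pos <- c("K", "R", if (histidine_charged) "H")
  ifelse(chars %in% pos, 1L, ifelse(chars %in% c("D", "E"), -1L, 0L))
}

#' Fraction of charged residues and net charge per residue
#'
#' FCR = (n+ + n-)/L and NCPR = (n+ - n-)/L, so |NCPR| <= FCR always.
#'
#' @inheritParams charge_assign
#' @return A one-row tibble with columns `fcr` and `ncpr`.
#' @export
fcr_ncpr <- function(sequence, histidine_charged = FALSE) {
  ch <- charge_assign(sequence, histidine_charged)
  tibble::tibble(fcr = mean(ch != 0L), ncpr = mean(ch))
}

# local charge asymmetry of a charge vector
charge_asymmetry <- function(ch) {
  fp <- mean(ch > 0L)
  fm <- mean(ch < 0L)
  if (fp + fm == 0) 0 else (fp - fm)^2 / (fp + fm)
}

# mean squared deviation of blob asymmetry from the whole-sequence value
delta_blob <- function(ch, g) {
  n_blob <- length(ch) - g + 1L
  sg <- charge_asymmetry(ch)
  blob <- vapply(seq_len(n_blob), function(i) charge_asymmetry(ch[i:(i + g - 1L)]), 0)
  mean((blob - sg)^2)
}

# Maximal delta over the same composition: the maximizing arrangement keeps
# each charge sign in one contiguous block, but the blocks float freely in
# the neutral background (they are not anchored at the termini, and for
# net-charged sequences the optimum often sits in the interior). Both sign
# orders and all O(L^2) placements of the two blocks are scanned.
delta_max_blob <- function(ch, g) {
  np <- sum(ch > 0L)
  nm <- sum(ch < 0L)
  len <- length(ch)
  best <- 0
  pos_starts <- if (np > 0L) seq_len(len - np + 1L) else NA_integer_
  neg_starts <- if (nm > 0L) seq_len(len - nm + 1L) else NA_integer_
  for (i in pos_starts) {
    p_span <- if (np > 0L) i:(i + np - 1L) else integer(0)
    for (j in neg_starts) {
      m_span <- if (nm > 0L) j:(j + nm - 1L) else integer(0)
      if (length(p_span) && length(m_span) &&
        max(p_span) >= min(m_span) && max(m_span) >= min(p_span)) {
        next # overlapping blocks
      }
      cand <- integer(len)
      cand[p_span] <- 1L
      cand[m_span] <- -1L
      d <- delta_blob(cand, g)
      if (d > best) best <- d
    }
  }
  best
}

#' Charge-patterning parameter kappa
#'
#' The blob-based patterning measure of charge mixing: the local charge
#' asymmetry \eqn{\sigma = (f_+ - f_-)^2 / (f_+ + f_-)} is computed in
#' sliding blobs of width 5 and 6; \eqn{\delta} is the mean squared
#' deviation of the blob values from the whole-sequence asymmetry, and
#' each blob size is normalized by \eqn{\delta_{max}} of the maximally
#' segregated rearrangement of the same composition. Kappa is the mean of
#' the two blob-size values: near 0 for well-mixed charges, 1 for fully
#' segregated blocks.
#'
#' @inheritParams charge_assign
#' @param blob_widths Blob sizes to average (default `c(5, 6)`).
#' @return Kappa in `[0, 1]`.
#' @export
kappa <- function(sequence, histidine_charged = FALSE, blob_widths = c(5, 6)) {
  ch <- charge_assign(sequence, histidine_charged)
  if (sum(ch != 0L) == 0L) {
    abort_ed("Kappa is undefined for a sequence with no charged residues.", "undefined_kappa")
  }
  vals <- vapply(blob_widths, function(g) {
    if (g > length(ch)) abort_ed("Blob width exceeds the sequence length.", "parameter")
    dmax <- delta_max_blob(ch, g)
    if (dmax == 0) {
      abort_ed(
        "Kappa is undefined: no arrangement of this composition shows charge patterning.",
        "undefined_kappa"
      )
    }
    delta_blob(ch, g) / dmax
  }, 0)
  mean(vals)
}

#' Mean rescaled Kyte-Doolittle hydropathy
#'
#' Mean over residues of (Kyte-Doolittle value + 4.5), mapping the native
#' -4.5..+4.5 scale onto 0..9.
#'
#' @inheritParams charge_assign
#' @return Mean hydropathy in `[0, 9]`.
#' @export
mean_hydropathy <- function(sequence) {
  chars <- check_sequence(sequence)
  mean(KYTE_DOOLITTLE[chars] + 4.5)
}

#' Fraction of disorder-promoting residues
#'
#' The fraction of residues in the disorder-promoting set
#' T, A, G, R, D, H, Q, K, S, E, P.
#'
#' @inheritParams charge_assign
#' @return Fraction in `[0, 1]`.
#' @export
disorder_promoting_fraction <- function(sequence) {
  chars <- check_sequence(sequence)
  mean(chars %in% DISORDER_PROMOTING)
}

#' Sliding-window scale profile
#'
#' Unweighted mean of a per-residue scale over each window of odd width;
#' the profile has `length - window + 1` positions, reported at window
#' centers.
#'
#' @inheritParams charge_assign
#' @param scale `"kyte_doolittle"`, `"transmembrane_tendency"`, or a named
#'   numeric vector over the 20 amino acids.
#' @param window Odd window width, at most the sequence length.
#' @return A tibble with columns `position` (center residue) and `value`.
#' @export
window_profile <- function(sequence, scale = "kyte_doolittle", window = 9) {
  chars <- check_sequence(sequence)
  if (window %% 2 == 0) abort_ed("`window` must be odd.", "parameter")
  if (window > length(chars)) abort_ed("`window` exceeds the sequence length.", "parameter")
  if (is.character(scale)) {
    scale <- switch(scale,
      kyte_doolittle = KYTE_DOOLITTLE,
      transmembrane_tendency = TRANSMEMBRANE_TENDENCY,
      abort_ed(sprintf("Unknown scale '%s'.", scale), "parameter")
    )
  }
  if (!all(chars %in% names(scale))) {
    abort_ed("The scale is missing values for some residues.", "parameter")
  }
  vals <- as.numeric(scale[chars])
  csum <- cumsum(c(0, vals))
  n_win <- length(chars) - window + 1L
  means <- (csum[(window + 1L):(length(chars) + 1L)] - csum[seq_len(n_win)]) / window
  half <- (window - 1L) %/% 2L
  tibble::tibble(position = seq_len(n_win) + half, value = means)
}

#' Full sequence-parameter table
#'
#' One row with length, kappa, FCR, NCPR, mean hydropathy and the
#' disorder-promoting fraction, in that order.
#'
#' @inheritParams charge_assign
#' @return A one-row tibble.
#' @export
sequence_params <- function(sequence, histidine_charged = FALSE) {
  chars <- check_sequence(sequence)
  fn <- fcr_ncpr(sequence, histidine_charged)
  tibble::tibble(
    length = length(chars),
    kappa = kappa(sequence, histidine_charged),
    fcr = fn$fcr,
    ncpr = fn$ncpr,
    hydropathy = mean_hydropathy(sequence),
    disorder_promoting = disorder_promoting_fraction(sequence)
  )
}
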