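# 2-D Wold texture model: a channel is split into three mutually orthogonal
# fields with disjoint frequency support — harmonic (isolated spectral peaks,
# perceived periodicity), generalized evanescent (spectral lines found by a
# Hough transform, perceived directionality) and stochastic (the remaining
# spectrum, perceived randomness). The structural component is harmonic +
# evanescent. Fields decompose the mean-subtracted plane; the channel mean is
# kept alongside so the three fields plus the mean reconstruct the input.

#' DFT spectrum of a channel plane
#'
#' Computes the 2-D DFT of the mean-subtracted plane. Amplitudes are reported
#' on sinusoid units, `2|F|/Npix`, so a cosine of amplitude A shows amplitude
#' A at its frequency pair; the paper's amplitude threshold of 10 is read on
#' this scale (10 intensity units on an 8-bit channel).
#'
#' @param plane Numeric matrix.
#' @return List of class `texture_spectrum` with complex matrix `F`, matrix
#'   `amplitude`, the plane `mean` and `dim`.
#' @export
texture_spectrum <- function(plane) {
  stopifnot(is.matrix(plane), min(dim(plane)) >= 2)
  m <- mean(plane)
  F <- fft(plane - m)
  npix <- length(plane)
  amp <- 2 * Mod(F) / npix
  amp[1, 1] <- 0 # DC carried by `mean`
  structure(list(F = F, amplitude = amp, mean = m, dim = dim(plane)),
            class = "texture_spectrum")
}

# signed frequency index for 1-based bin i of an n-point DFT
signed_freq <- function(i, n) ifelse(i - 1 < n / 2, i - 1, i - 1 - n)

# 1-based bin of the conjugate frequency
conj_bin <- function(i, n) ifelse(i == 1, 1L, n - i + 2L)

# toroidal 8-neighbourhood local maxima of a matrix
local_maxima <- function(amp) {
  nr <- nrow(amp); nc <- ncol(amp)
  res <- matrix(TRUE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    shifted <- amp[((seq_len(nr) - 1 + di) %% nr) + 1,
                   ((seq_len(nc) - 1 + dj) %% nc) + 1, drop = FALSE]
    res <- res & (amp >= shifted)
  }
  res
}

#' Locate harmonic peaks in a spectrum
#'
#' A harmonic peak is an isolated spectral maximum: its amplitude exceeds
#' `amplitude_threshold` and it is a local maximum over the toroidal
#' 8-neighbourhood of the magnitude matrix. Accepted peaks are kept at least
#' `min_separation` bins apart (greedy, by descending amplitude); the DC bin
#' is excluded and conjugate partners are returned together.
#'
#' @param spectrum A `texture_spectrum`.
#' @param amplitude_threshold Amplitude cut-off (default 10).
#' @param min_separation Minimum Chebyshev bin distance between accepted
#'   peaks (default 2).
#' @return Tibble with columns `i`, `j` (1-based bins), `u`, `v` (signed
#'   frequencies), `amplitude`, `phase`; zero rows when nothing clears the
#'   threshold.
#' @export
detect_harmonic_peaks <- function(spectrum, amplitude_threshold = 10,
                                  min_separation = 2) {
  amp <- spectrum$amplitude
  nr <- nrow(amp); nc <- ncol(amp)
  cand <- which(amp > amplitude_threshold & local_maxima(amp), arr.ind = TRUE)
  cand <- cand[!(cand[, 1] == 1 & cand[, 2] == 1), , drop = FALSE]
  if (!nrow(cand)) return(peak_tibble(integer(0), integer(0), spectrum))
  ord <- order(amp[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  acc_i <- integer(0); acc_j <- integer(0)
  tor_dist <- function(a, b, n) pmin(abs(a - b), n - abs(a - b))
  for (r in seq_len(nrow(cand))) {
    ci <- cand[r, 1]; cj <- cand[r, 2]
    if (length(acc_i)) {
      d <- pmax(tor_dist(acc_i, ci, nr), tor_dist(acc_j, cj, nc))
      if (any(d < min_separation)) next
    }
    acc_i <- c(acc_i, ci, conj_bin(ci, nr))
    acc_j <- c(acc_j, cj, conj_bin(cj, nc))
  }
  keep <- !duplicated(cbind(acc_i, acc_j))
  peak_tibble(acc_i[keep], acc_j[keep], spectrum)
}

peak_tibble <- function(i, j, spectrum) {
  nr <- spectrum$dim[1]; nc <- spectrum$dim[2]
  tibble(
    i = as.integer(i), j = as.integer(j),
    u = as.integer(signed_freq(i, nr)), v = as.integer(signed_freq(j, nc)),
    amplitude = if (length(i)) spectrum$amplitude[cbind(i, j)] else numeric(0),
    phase = if (length(i)) Arg(spectrum$F[cbind(i, j)]) else numeric(0)
  )
}

#' Reconstruct the harmonic field from detected peaks
#'
#' Inverse-transforms the spectrum restricted to the peak bins. The returned
#' parameters record frequency, amplitude and phase per peak.
#'
#' @param spectrum A `texture_spectrum`.
#' @param peaks Tibble from [detect_harmonic_peaks()].
#' @return List with spatial matrix `field` and tibble `params`.
#' @export
extract_harmonic_field <- function(spectrum, peaks) {
  Fh <- matrix(0 + 0i, spectrum$dim[1], spectrum$dim[2])
  if (nrow(peaks)) Fh[cbind(peaks$i, peaks$j)] <- spectrum$F[cbind(peaks$i, peaks$j)]
  field <- Re(fft(Fh, inverse = TRUE)) / length(Fh)
  list(field = field, params = peaks)
}

#' Detect generalized evanescent lines in a residual spectrum
#'
#' Runs a Hough transform over the thresholded magnitude of the spectrum with
#' harmonic bins removed, in centred frequency coordinates (1 degree angular,
#' 1-bin radial resolution). Up to `max_lines` highest-voted lines are
#' returned; bins within one bin of a line (and their conjugates) form that
#' line's support.
#'
#' @param spectrum A `texture_spectrum`.
#' @param exclude Optional tibble of bins (columns `i`, `j`) already assigned
#'   to the harmonic component.
#' @param amplitude_threshold Magnitude floor for Hough voting (default 5).
#' @param max_lines Maximum number of lines (default 4).
#' @param min_votes Minimum supporting bins per line (default 3).
#' @return List with `lines` (tibble: `line`, `theta_deg`, `rho`, `n_bins`)
#'   and `bins` (tibble: `line`, `i`, `j`, `amplitude`, `phase`).
#' @export
detect_evanescent_lines <- function(spectrum, exclude = NULL,
                                    amplitude_threshold = 5, max_lines = 4,
                                    min_votes = 3) {
  amp <- spectrum$amplitude
  nr <- nrow(amp); nc <- ncol(amp)
  sel <- amp > amplitude_threshold
  sel[1, 1] <- FALSE
  if (!is.null(exclude) && nrow(exclude)) sel[cbind(exclude$i, exclude$j)] <- FALSE
  idx <- which(sel, arr.ind = TRUE)
  empty <- list(
    lines = tibble(line = integer(0), theta_deg = numeric(0), rho = numeric(0),
                   n_bins = integer(0)),
    bins = tibble(line = integer(0), i = integer(0), j = integer(0),
                  amplitude = numeric(0), phase = numeric(0))
  )
  if (!nrow(idx)) return(empty)
  u <- signed_freq(idx[, 1], nr); v <- signed_freq(idx[, 2], nc)
  thetas <- seq(0, 179) * pi / 180
  lines <- list(); bins <- list(); line_no <- 0L
  remaining <- rep(TRUE, length(u))
  while (line_no < max_lines && any(remaining)) {
    ru <- u[remaining]; rv <- v[remaining]
    # accumulator over (theta, rho) for the remaining candidate bins
    rho <- round(outer(ru, cos(thetas)) + outer(rv, sin(thetas)))
    votes <- table(paste(rep(seq_along(thetas), each = length(ru))[TRUE],
                         as.vector(rho), sep = ":"))
    # rebuild as matrix-free argmax
    best <- names(votes)[which.max(votes)]
    nb <- max(votes)
    if (nb < min_votes) break
    parts <- as.numeric(strsplit(best, ":", fixed = TRUE)[[1]])
    th <- thetas[parts[1]]; rh <- parts[2]
    on_line_rem <- abs(ru * cos(th) + rv * sin(th) - rh) <= 1
    members <- which(remaining)[on_line_rem]
    line_no <- line_no + 1L
    # include conjugates to keep the spatial field real-valued
    mi <- c(idx[members, 1], conj_bin(idx[members, 1], nr))
    mj <- c(idx[members, 2], conj_bin(idx[members, 2], nc))
    dup <- duplicated(cbind(mi, mj))
    mi <- mi[dup == FALSE]; mj <- mj[dup == FALSE]
    lines[[line_no]] <- tibble(line = line_no, theta_deg = th * 180 / pi,
                               rho = rh, n_bins = length(members))
    bins[[line_no]] <- tibble(line = line_no, i = as.integer(mi),
                              j = as.integer(mj),
                              amplitude = amp[cbind(mi, mj)],
                              phase = Arg(spectrum$F[cbind(mi, mj)]))
    # drop all bins now claimed by this line (incl. conjugates present in idx)
    claimed <- paste(mi, mj)
    remaining[paste(idx[, 1], idx[, 2]) %in% claimed] <- FALSE
  }
  if (!line_no) return(empty)
  list(lines = bind_rows(lines), bins = bind_rows(bins))
}

#' Decompose a channel into harmonic, evanescent and stochastic fields
#'
#' Full 2-D Wold split: harmonic peaks are detected and removed first, the
#' residual spectrum is scanned for up to four evanescent lines, and whatever
#' frequency support remains forms the stochastic field. The three fields
#' have disjoint frequency support and, together with the stored channel
#' mean, sum back to the input plane.
#'
#' @param plane Numeric matrix with side length at least 8.
#' @param amplitude_threshold Harmonic amplitude threshold (default 10).
#' @param evanescent_threshold Hough voting floor (default 5).
#' @param max_lines Maximum evanescent lines (default 4).
#' @return Object of class `wold_fields`: matrices `harmonic`, `evanescent`,
#'   `stochastic`, scalar `mean`, tibbles `harmonic_params`,
#'   `evanescent_lines`, `evanescent_bins`.
#' @export
wold_decompose <- function(plane, amplitude_threshold = 10,
                           evanescent_threshold = 5, max_lines = 4) {
  stopifnot(min(dim(plane)) >= 8)
  spec <- texture_spectrum(plane)
  peaks <- detect_harmonic_peaks(spec, amplitude_threshold)
  harm <- extract_harmonic_field(spec, peaks)
  ev <- detect_evanescent_lines(spec, exclude = peaks,
                                amplitude_threshold = evanescent_threshold,
                                max_lines = max_lines)
  Fe <- matrix(0 + 0i, nrow(plane), ncol(plane))
  if (nrow(ev$bins)) Fe[cbind(ev$bins$i, ev$bins$j)] <- spec$F[cbind(ev$bins$i, ev$bins$j)]
  evan <- Re(fft(Fe, inverse = TRUE)) / length(plane)
  # stochastic = spectral complement, so supports are disjoint by construction
  Fs <- spec$F
  if (nrow(peaks)) Fs[cbind(peaks$i, peaks$j)] <- 0
  if (nrow(ev$bins)) Fs[cbind(ev$bins$i, ev$bins$j)] <- 0
  stoch <- Re(fft(Fs, inverse = TRUE)) / length(plane)
  structure(list(harmonic = harm$field, evanescent = evan, stochastic = stoch,
                 mean = spec$mean, harmonic_params = peaks,
                 evanescent_lines = ev$lines, evanescent_bins = ev$bins),
            class = "wold_fields")
}

#' @export
print.wold_fields <- function(x, ...) {
  cat("Wold texture fields:", nrow(x$harmonic_params), "harmonic peak bins,",
      nrow(x$evanescent_lines), "evanescent lines\n")
  invisible(x)
}

#' Structural component of a Wold decomposition
#' @param fields A `wold_fields` object.
#' @return Matrix `harmonic + evanescent`.
#' @export
structural_field <- function(fields) fields$harmonic + fields$evanescent
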