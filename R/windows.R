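## Blur vectors act on digestion offsets in [-15, +15]: half the footprint of a
## yeast ribosome in either direction.
BLUR_HALF <- 15L
BLUR_OFFSETS <- -15L:15L

## Default profile window: positions are 0-based nt offsets relative to the
## first base of the start codon, spanning [-L_UP, L_down).
L_UP_DEFAULT <- 24L

#' Shift a vector with zero fill
#'
#' `shift_profile(v, k)[i] == v[i - k]`: positive `k` moves content to the
#' right (downstream), negative to the left. Entries shifted outside the
#' window are dropped and the vacated cells are zero-filled.
#'
#' @param v numeric vector.
#' @param k integer shift.
#' @return numeric vector of the same length as `v`.
#' @export
shift_profile <- function(v, k) {
  n <- length(v)
  k <- as.integer(k)
  if (k == 0L || n == 0L) return(v)
  out <- numeric(n)
  if (abs(k) >= n) return(out)
  if (k > 0L) out[(k + 1L):n] <- v[1L:(n - k)]
  else out[1L:(n + k)] <- v[(1L - k):n]
  out
}

#' Convolve a position signal with a blur vector
#'
#' `out[i] = sum_j blur[j] * signal[i - j]` over offsets `j` in \[-15, 15\],
#' with zero padding outside the window. Interior mass is conserved when the
#' blur weights sum to 1 and no mass sits within 15 cells of the borders.
#'
#' @param signal numeric vector.
#' @param weights numeric vector of 31 blur weights for offsets -15..15.
#' @return numeric vector, same length as `signal`.
#' @export
convolve_blur <- function(signal, weights) {
  stopifnot(length(weights) == length(BLUR_OFFSETS))
  out <- numeric(length(signal))
  for (idx in seq_along(BLUR_OFFSETS)) {
    w <- weights[idx]
    if (w != 0) out <- out + w * shift_profile(signal, BLUR_OFFSETS[idx])
  }
  out
}

## Sparse banded convolution matrix C with C[i, i - j] = weights[j], so that
## C %*% s == convolve_blur(s, weights).
conv_matrix <- function(weights, n) {
  stopifnot(length(weights) == length(BLUR_OFFSETS))
  keep <- which(weights != 0 & abs(BLUR_OFFSETS) < n)
  if (length(keep) == 0L) return(Matrix::Diagonal(n, x = 0))
  ks <- -BLUR_OFFSETS[keep]
  diags <- lapply(seq_along(keep),
                  function(ii) rep(weights[keep[ii]], n - abs(ks[ii])))
  Matrix::bandSparse(n, n, k = ks, diagonals = diags)
}

## The alignment shift placing a length-l profile on the length-28 coordinate
## frame. The 3-nt periodicity of length-l 5' ends starts at -l+16, i.e. the
## observation frame is the consensus shifted by s_l = -(l - 28) = -k_l.
k_shift <- function(read_length) as.integer(read_length) - 28L

obs_shift <- function(read_length) -k_shift(read_length)

## frame of a transcript position (0-based, relative to start codon)
frame_of_pos <- function(p) ((p %% 3L) + 3L) %% 3L

## positions covered by a window of length n starting at `start`
window_positions <- function(start, n) seq.int(start, length.out = n)

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}
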