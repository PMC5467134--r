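## ---- meta-profiles and blur-vector estimation ---------------------------

new_blur_vector <- function(read_length, weights) {
  stopifnot(length(weights) == length(BLUR_OFFSETS), all(weights >= 0))
  structure(list(read_length = as.integer(read_length),
                 weights = as.numeric(weights)),
            class = "blur_vector")
}

#' @export
print.blur_vector <- function(x, ...) {
  mode <- BLUR_OFFSETS[which.max(x$weights)]
  cat(sprintf("<blur_vector> l=%d  mode_offset=%+d  mass(sum)=%.4f\n",
              x$read_length, mode, sum(x$weights)))
  invisible(x)
}

#' Build the start-codon-anchored meta-profile for one read length
#'
#' Sums 5'-end counts at each position relative to the start codon over all
#' transcripts longer than `min_tx_length` nt, on the window
#' \[-l_up, downstream\). Positions holding the top `mask_rate` fraction of
#' values (by count, `ceiling(n * mask_rate)` positions) are flagged as
#' outliers. The last 15 positions (one blur half-width) of the truncated
#' window are additionally flagged as boundary cells: reads there are
#' convolved in from consensus positions beyond the window, which the
#' zero-padded model cannot represent. Both kinds are ignored by all fitting
#' (`mask`); the outlier component alone is kept in `outlier_mask`.
#'
#' @param profiles nested list as from [build_length_profiles()] (unfiltered).
#' @param read_length the read length to accumulate.
#' @param annotations annotation data.frame.
#' @param min_tx_length only transcripts strictly longer than this contribute
#'   (reduces convolution boundary effects), default 350.
#' @param downstream number of positions kept downstream of the start codon,
#'   default 350.
#' @param l_up upstream window extent, default 24.
#' @param mask_rate fraction of positions masked as outliers, default 0.0165
#'   (top 5% of in-frame reads, i.e. 5% of one third of positions).
#' @return a `meta_profile` object with fields read_length, start, values,
#'   mask, alpha.
#' @export
build_meta_profile <- function(profiles, read_length, annotations,
                               min_tx_length = 350L, downstream = 350L,
                               l_up = L_UP_DEFAULT, mask_rate = 0.0165) {
  annotations <- validate_annotations(annotations)
  start <- -as.integer(l_up)
  n <- l_up + downstream
  values <- numeric(n)
  used <- 0L
  for (tid in names(profiles)) {
    if (annotations[tid, "length"] <= min_tx_length) next
    p <- profiles[[tid]][[as.character(read_length)]]
    if (is.null(p)) next
    used <- used + 1L
    m <- min(length(p$counts), n)   # both windows start at -l_up
    values[1:m] <- values[1:m] + p$counts[1:m]
  }
  if (used == 0L)
    stop("no transcript longer than ", min_tx_length,
         " nt contributes reads of length ", read_length)
  n_mask <- ceiling(n * mask_rate)
  outlier <- rep(FALSE, n)
  outlier[order(values, decreasing = TRUE)[seq_len(n_mask)]] <- TRUE
  boundary <- rep(FALSE, n)
  boundary[seq.int(n - BLUR_HALF + 1L, n)] <- TRUE
  structure(list(read_length = as.integer(read_length), start = start,
                 values = values, mask = outlier | boundary,
                 outlier_mask = outlier, alpha = sum(values)),
            class = "meta_profile")
}

#' Fit a blur vector by non-negative least squares
#'
#' Finds the non-negative 31-weight minimizer of
#' `|| shift_j(M_true_shifted) %*% b - M_obs ||^2` over unmasked positions,
#' where column j of the design is `M_true_shifted` shifted by offset j
#' (zero-padded), then normalizes the weights to sum 1 (the blur is a
#' relocation probability).
#'
#' @param m_true_shifted numeric vector: the consensus meta-signal already
#'   shifted into the coordinate frame of `m_obs`'s read length.
#' @param m_obs a `meta_profile` (its `mask` is honored).
#' @return a `blur_vector`.
#' @export
fit_blur <- function(m_true_shifted, m_obs) {
  if (all(m_true_shifted == 0)) stop("all-zero consensus meta-signal")
  keep <- !m_obs$mask
  X <- vapply(BLUR_OFFSETS, function(j) shift_profile(m_true_shifted, j)[keep],
              numeric(sum(keep)))
  w <- nnls_fit(X, m_obs$values[keep])$x
  s <- sum(w)
  if (s == 0) stop("NNLS returned the zero blur; degenerate meta-profile")
  new_blur_vector(m_obs$read_length, w / s)
}

#' Estimate all blur vectors from meta-profiles (EM-like)
#'
#' Initializes the meta-consensus from the in-frame values of the length-28
#' meta-profile, then iterates: (1) refit each blur vector by NNLS, (2) ridge
#' M-step for the per-length deviations, (3) consensus E-step with clipping
#' and renormalization, until the relative objective change drops below `tol`.
#'
#' @param metas list of `meta_profile` objects (must include length 28).
#' @param tol relative objective-change convergence threshold, default 0.01.
#' @param max_iter maximum EM rounds, default 100.
#' @return list with `blurs` (named list of `blur_vector` by read length),
#'   `consensus` (the fitted meta-consensus, sums to 1), `trace` (objective
#'   per EM round) and `converged`.
#' @export
estimate_all_blurs <- function(metas, tol = 0.01, max_iter = 100L) {
  lens <- vapply(metas, function(m) m$read_length, 0L)
  names(metas) <- as.character(lens)
  if (!"28" %in% names(metas))
    stop("meta-profiles must include read length 28 (the anchor)")
  n <- length(metas[["28"]]$values)
  stopifnot(all(vapply(metas, function(m) length(m$values), 0L) == n))
  norm <- lapply(metas, function(m) {
    if (m$alpha <= 0) stop("empty meta-profile for length ", m$read_length)
    m$values <- m$values / sum(m$values); m
  })
  alphas <- vapply(metas, function(m) m$alpha, 0)
  masks <- lapply(metas, function(m) m$mask)
  shifts <- setNames(vapply(lens, obs_shift, 0L), names(metas))

  start <- metas[["28"]]$start
  consensus <- inframe_init(norm[["28"]]$values, start)

  blurs <- NULL
  res <- em_loop(
    profiles = lapply(norm, `[[`, "values"),
    alphas = alphas, shifts = shifts, masks = masks,
    consensus = consensus, tol = tol, max_iter = max_iter,
    refit_blurs = function(cons) {
      lapply(names(norm), function(nm) {
        m <- norm[[nm]]
        fit_blur(shift_profile(cons, shifts[[nm]]), m)$weights
      }) |> setNames(names(norm))
    })
  blurs <- lapply(names(res$blur_weights), function(nm)
    new_blur_vector(as.integer(nm), res$blur_weights[[nm]]))
  names(blurs) <- names(res$blur_weights)
  if (!res$converged)
    warning("blur estimation did not converge within ", max_iter, " rounds")
  list(blurs = blurs, consensus = res$consensus, start = start,
       trace = res$trace, converged = res$converged)
}

## keep in-frame (position = 0 mod 3) cells, zero elsewhere, renormalize
inframe_init <- function(values, start) {
  pos <- window_positions(start, length(values))
  v <- ifelse(frame_of_pos(pos) == 0L, values, 0)
  s <- sum(v)
  if (s <= 0) stop("no in-frame mass to initialize the consensus")
  v / s
}
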