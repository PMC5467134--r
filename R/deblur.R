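## ---- EM-like ridge-regularized total-least-squares deconvolution --------
##
## Coordinate conventions. The consensus signal lives on the length-28 5'-end
## frame. The 3-nt periodicity of length-l 5' ends starts at -l+16, i.e. the
## length-l observation frame is the consensus shifted by s_l = -(l - 28)
## (= -k_l, where k_l = l - 28 aligns a length-l profile back onto length 28
## by shifting it k_l to the right). All per-length deviations are stored in
## the observation frame of their read length.

#' Initialize the consensus from a length-28 profile
#'
#' The initial consensus is the in-frame values (positions that are multiples
#' of 3 relative to the start codon) of the observed length-28 pileup,
#' renormalized to sum 1. Length-28 reads match the typical yeast footprint,
#' so their boundaries are the most likely to be digestion-exact.
#'
#' @param p28 a `length_profile` with read length 28.
#' @return numeric consensus vector (sums to 1), with the window start in
#'   attribute `start`.
#' @export
init_consensus <- function(p28) {
  if (p28$read_length != 28L) stop("initialization requires read length 28")
  v <- inframe_init(p28$counts / sum(p28$counts), p28$start)
  attr(v, "start") <- p28$start
  v
}

#' Ridge M-step: per-length deviation update
#'
#' With the consensus fixed, the deviation for one read length minimizes
#' `||b * eps - (b * consensus_shifted - p_obs)||^2 + ||eps||^2`
#' (a damped least-squares problem with damping parameter 1), where
#' `consensus_shifted` is the consensus moved into the read length's
#' observation frame and `*` is convolution. Solved exactly through the
#' banded normal equations `(A'A + I) eps = A' r`.
#'
#' @param consensus numeric consensus vector (length-28 frame).
#' @param p normalized `length_profile` (counts sum to 1).
#' @param b a `blur_vector` for `p`'s read length.
#' @param mask optional logical vector; `TRUE` positions are excluded from the
#'   residual (used by meta-profile fitting).
#' @return numeric deviation vector in the observation frame.
#' @export
m_step <- function(consensus, p, b, mask = NULL) {
  n <- length(p$counts)
  if (length(consensus) != n) stop("dimension mismatch: consensus vs profile")
  cs <- shift_profile(consensus, obs_shift(p$read_length))
  m_step_vec(cs, p$counts, b$weights, mask)
}

## core solver on plain vectors; cs is already in the observation frame
m_step_vec <- function(cs, p_obs, weights, mask = NULL) {
  n <- length(p_obs)
  A <- conv_matrix(weights, n)
  r <- as.numeric(A %*% cs) - p_obs
  if (!is.null(mask)) {
    keep <- as.numeric(!mask)
    A <- Matrix::Diagonal(n, x = keep) %*% A
    r <- keep * r
  }
  M <- Matrix::crossprod(A) + Matrix::Diagonal(n)
  as.numeric(Matrix::solve(M, Matrix::crossprod(A, r)))
}

#' E-step: consensus update from weighted deviations
#'
#' The updated consensus is the read-count-weighted average of the per-length
#' signals: `P'[i] = P[i] - sum_l alpha_l eps_l[i'] / sum_l alpha_l`, where
#' `i'` is position `i` carried into length l's observation frame. At window
#' borders the average runs over the lengths whose shifted window covers the
#' position (the exact minimizer of the objective; identical to the plain
#' weighted average in the interior). Negative entries are clipped to zero
#' and the vector renormalized to sum 1.
#'
#' @param consensus numeric consensus vector.
#' @param deviations named list (by read length) of deviation vectors in the
#'   observation frame.
#' @param alphas named numeric vector of per-length read totals.
#' @return the updated consensus (sums to 1); the pre-clipping vector is
#'   available in attribute `pre_clip`.
#' @export
e_step <- function(consensus, deviations, alphas) {
  pre <- e_step_preclip(consensus, deviations, alphas)
  out <- pmax(pre, 0)
  s <- sum(out)
  if (s <= 0) stop("signal annihilated: consensus is zero after clipping")
  out <- out / s
  attr(out, "pre_clip") <- pre
  out
}

e_step_preclip <- function(consensus, deviations, alphas) {
  n <- length(consensus)
  stopifnot(sum(alphas) > 0)
  num <- numeric(n)
  den <- numeric(n)
  for (nm in names(deviations)) {
    s_l <- obs_shift(as.integer(nm))
    ## consensus index i maps to observation index j = i + s_l
    i_idx <- seq_len(n)
    j_idx <- i_idx + s_l
    ok <- j_idx >= 1L & j_idx <= n
    num[i_idx[ok]] <- num[i_idx[ok]] + alphas[[nm]] * deviations[[nm]][j_idx[ok]]
    den[i_idx[ok]] <- den[i_idx[ok]] + alphas[[nm]]
  }
  upd <- ifelse(den > 0, num / pmax(den, .Machine$double.xmin), 0)
  as.numeric(consensus) - upd
}

#' Deblur objective
#'
#' `sum_l alpha_l [ ||p_obs(l) - b(l) * (consensus_shifted - eps_l)||^2
#'                  + ||eps_l||^2 ]`, with masked positions (if any) excluded
#' from the residual term.
#'
#' @param consensus numeric consensus vector.
#' @param deviations named list of deviation vectors (observation frame).
#' @param profiles named list of normalized observed count vectors.
#' @param blurs named list of 31-weight blur vectors.
#' @param alphas named numeric vector of read totals.
#' @param masks optional named list of logical masks.
#' @return non-negative scalar.
#' @export
deblur_objective <- function(consensus, deviations, profiles, blurs, alphas,
                             masks = NULL) {
  total <- 0
  for (nm in names(profiles)) {
    cs <- shift_profile(as.numeric(consensus), obs_shift(as.integer(nm)))
    resid <- profiles[[nm]] - convolve_blur(cs - deviations[[nm]], blurs[[nm]])
    if (!is.null(masks)) resid[masks[[nm]]] <- 0
    total <- total + alphas[[nm]] * (sum(resid^2) + sum(deviations[[nm]]^2))
  }
  total
}

## Shared EM loop used by both per-transcript deblurring (fixed blurs) and
## meta-profile blur estimation (refit_blurs provided).
##
## Stage objectives recorded per round:
##   before        objective entering the round
##   after_m       after the exact ridge M-step (must not increase)
##   after_e_pre   after the pre-clipping E-step with re-based deviations
##                 (must not increase; P_true(l) is held fixed)
##   end           after clipping + renormalization (may tick up slightly)
em_loop <- function(profiles, alphas, shifts, consensus, blurs = NULL,
                    masks = NULL, tol = 0.01, max_iter = 100L,
                    refit_blurs = NULL) {
  nms <- names(profiles)
  deviations <- lapply(profiles, function(p) numeric(length(p)))
  names(deviations) <- nms
  trace <- data.frame(iter = integer(), before = numeric(),
                      after_m = numeric(), after_e_pre = numeric(),
                      end = numeric())
  converged <- FALSE
  obj_prev <- NA_real_
  blur_w <- blurs
  for (it in seq_len(max_iter)) {
    if (!is.null(refit_blurs)) blur_w <- refit_blurs(consensus)
    obj_before <- deblur_objective(consensus, deviations, profiles, blur_w,
                                   alphas, masks)
    for (nm in nms) {
      cs <- shift_profile(as.numeric(consensus), shifts[[nm]])
      deviations[[nm]] <- m_step_vec(cs, profiles[[nm]], blur_w[[nm]],
                                     if (is.null(masks)) NULL else masks[[nm]])
    }
    obj_m <- deblur_objective(consensus, deviations, profiles, blur_w,
                              alphas, masks)
    pre <- e_step_preclip(consensus, deviations, alphas)
    ## re-base deviations so each P_true(l) is unchanged by the E-step
    delta <- pre - as.numeric(consensus)
    dev_pre <- deviations
    for (nm in nms)
      dev_pre[[nm]] <- deviations[[nm]] + shift_profile(delta, shifts[[nm]])
    obj_e <- deblur_objective(pre, dev_pre, profiles, blur_w, alphas, masks)
    new_cons <- pmax(pre, 0)
    s <- sum(new_cons)
    if (s <= 0) stop("signal annihilated: consensus is zero after clipping")
    new_cons <- new_cons / s
    delta2 <- new_cons - pre
    for (nm in nms)
      dev_pre[[nm]] <- dev_pre[[nm]] + shift_profile(delta2, shifts[[nm]])
    deviations <- dev_pre
    obj_end <- deblur_objective(new_cons, deviations, profiles, blur_w,
                                alphas, masks)
    trace <- rbind(trace, data.frame(iter = it, before = obj_before,
                                     after_m = obj_m, after_e_pre = obj_e,
                                     end = obj_end))
    consensus <- new_cons
    ## relative change below tol, or an (effectively) exactly solved problem
    ## where the relative test is ill-defined
    if (obj_end < 1e-15 ||
        (!is.na(obj_prev) && obj_prev > 0 &&
         abs(obj_end - obj_prev) / obj_prev < tol)) {
      converged <- TRUE
      obj_prev <- obj_end
      break
    }
    obj_prev <- obj_end
  }
  list(consensus = consensus, deviations = deviations, trace = trace,
       converged = converged, blur_weights = blur_w)
}

#' Deblur one transcript
#'
#' Runs the EM-like procedure: initialize the consensus from the in-frame
#' length-28 pileup, then alternate the ridge M-step (per-length deviations)
#' and the clipped E-step (consensus) until the relative change of the
#' objective is below `tol`. Observed profiles are normalized to sum 1 per
#' length; raw totals `alpha(l)` act as weights.
#'
#' @param ps a `profile_set` (see [filter_profiles()]).
#' @param blurs named list of `blur_vector` objects covering `ps`'s lengths.
#' @param tol relative objective-change threshold, default 0.01.
#' @param max_iter maximum EM rounds, default 100.
#' @return a `deblur_result`: consensus (sums to 1), per-length recovered
#'   signals (`p_true`, observation frame, negatives clipped), shifts `k`,
#'   weights `alpha`, the objective trace, and a convergence flag.
#' @export
deblur_transcript <- function(ps, blurs, tol = 0.01, max_iter = 100L) {
  stopifnot(inherits(ps, "profile_set"))
  lens <- names(ps$profiles)
  missing_b <- setdiff(lens, names(blurs))
  if (length(missing_b))
    stop("no blur vector for read length(s): ",
         paste(missing_b, collapse = ", "))
  alphas <- vapply(ps$profiles, function(p) p$alpha, 0)
  keep <- alphas > 0
  lens <- lens[keep]
  profs <- lapply(ps$profiles[lens], normalize_profile)
  alphas <- alphas[lens]
  start <- profs[[1]]$start
  n <- length(profs[[1]]$counts)

  if ("28" %in% lens) {
    consensus <- init_consensus(profs[["28"]])
  } else {
    ## fallback: the canonical anchor length 28 can be lost to filtering;
    ## seed from the most abundant length, aligned back to the consensus
    ## frame (shift by k_l).
    l_star <- lens[which.max(alphas)]
    p <- profs[[l_star]]
    aligned <- shift_profile(p$counts, k_shift(p$read_length))
    consensus <- inframe_init(aligned / sum(aligned), start)
    message("length 28 absent for ", ps$transcript_id,
            "; initialized from length ", l_star)
  }
  shifts <- setNames(lapply(lens, function(nm) obs_shift(as.integer(nm))), lens)
  res <- em_loop(profiles = lapply(profs, `[[`, "counts"),
                 alphas = alphas, shifts = shifts,
                 consensus = as.numeric(consensus),
                 blurs = setNames(lapply(lens, function(nm) blurs[[nm]]$weights),
                                  lens),
                 tol = tol, max_iter = max_iter)
  per_length <- lapply(lens, function(nm) {
    cs <- shift_profile(res$consensus, shifts[[nm]])
    list(read_length = as.integer(nm),
         p_true = pmax(cs - res$deviations[[nm]], 0),
         k = k_shift(as.integer(nm)),
         alpha = alphas[[nm]],
         deviation = res$deviations[[nm]])
  })
  names(per_length) <- lens
  structure(list(transcript_id = ps$transcript_id,
                 start = start,
                 consensus = res$consensus,
                 per_length = per_length,
                 objective_trace = res$trace,
                 converged = res$converged,
                 in_frame = ps$in_frame,
                 cds_start = ps$cds_start,
                 cds_end = ps$cds_end),
            class = "deblur_result")
}

#' @export
print.deblur_result <- function(x, ...) {
  cat(sprintf(
    "<deblur_result> %s  lengths={%s}  iters=%d  converged=%s\n",
    x$transcript_id, paste(names(x$per_length), collapse = ","),
    nrow(x$objective_trace), x$converged))
  invisible(x)
}
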