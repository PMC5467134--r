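## ---- A-site profiles, frame statistics, synthetic frameshifts -----------

new_asite_profile <- function(transcript_id, start, values,
                              cds_start = NA_integer_, cds_end = NA_integer_) {
  structure(list(transcript_id = transcript_id, start = as.integer(start),
                 values = as.numeric(values),
                 cds_start = cds_start, cds_end = cds_end),
            class = "asite_profile")
}

#' @export
print.asite_profile <- function(x, ...) {
  cat(sprintf("<asite_profile> %s  window=[%d,%d)  total=%.1f\n",
              x$transcript_id, x$start, x$start + length(x$values),
              sum(x$values)))
  invisible(x)
}

#' Merge deblurred length-specific signals into the A-site profile
#'
#' The A-site profile is the read-count-weighted sum of the recovered
#' length-specific signals, each carried from its 5'-end observation frame to
#' the decoded codon: the A-site offset of a length-l read is l - 13
#' (equivalently, align to the length-28 frame by k_l = l - 28 and shift
#' right by 15, the classic offset of 28-nt footprints). Out-of-window
#' positions contribute nothing.
#'
#' @param result a `deblur_result`.
#' @return an `asite_profile` on the same window (positions relative to the
#'   first base of the start codon); total mass equals `sum(alpha)` up to
#'   mass clipped at the window borders.
#' @export
merge_asite <- function(result) {
  stopifnot(inherits(result, "deblur_result"))
  n <- length(result$consensus)
  values <- numeric(n)
  for (pl in result$per_length) {
    offset <- pl$read_length - 13L   # == pl$k + 15
    values <- values + pl$alpha * shift_profile(pl$p_true, offset)
  }
  new_asite_profile(result$transcript_id, result$start, values,
                    result$cds_start, result$cds_end)
}

#' Frame fractions of a profile
#'
#' Fraction of total mass in each residue class modulo 3 relative to the
#' start codon.
#'
#' @param profile an `asite_profile` or `length_profile` (or any list with
#'   numeric `values`/`counts` and integer `start`).
#' @return numeric vector c(f0, f1, f2), summing to 1.
#' @export
frame_fractions <- function(profile) {
  v <- if (!is.null(profile$values)) profile$values else profile$counts
  pos <- window_positions(profile$start, length(v))
  tot <- sum(v)
  if (tot <= 0) stop("zero total mass; frame fractions undefined")
  vapply(0:2, function(f) sum(v[frame_of_pos(pos) == f]) / tot, 0)
}

#' Simulate a single-insertion frameshift in observed profiles
#'
#' Picks a uniformly random in-CDS frame-0 nt position (the frameshift point)
#' and moves every read-start count at positions strictly after it one nt to
#' the right, emulating a 1-nt insertion. Counts shifted past the window end
#' are dropped (the windows built here keep a downstream margin, so in
#' practice nothing is lost).
#'
#' @param ps a `profile_set`.
#' @param seed integer seed for the position draw.
#' @param shift_position optional fixed frameshift point (frame-0, in-CDS);
#'   when supplied no RNG is used.
#' @return list with the modified `profile_set` and `shift_position`.
#' @export
simulate_frameshift <- function(ps, seed = NULL, shift_position = NULL) {
  stopifnot(inherits(ps, "profile_set"))
  cds_len <- ps$cds_end - ps$cds_start
  if (cds_len < 60L) stop("CDS too short (< 60 nt) to plant a frameshift")
  if (is.null(shift_position)) {
    if (!is.null(seed)) set.seed(seed)
    candidates <- seq.int(0L, cds_len - 3L, by = 3L)
    shift_position <- candidates[sample.int(length(candidates), 1L)]
  }
  if (shift_position %% 3L != 0L)
    stop("frameshift point must be a frame-0 position")
  out <- ps
  out$profiles <- lapply(ps$profiles, function(p) {
    idx <- which(window_positions(p$start, length(p$counts)) > shift_position)
    if (length(idx)) {
      seg <- p$counts[idx]
      p$counts[idx] <- c(0, seg[-length(seg)])
    }
    p$alpha <- sum(p$counts)
    p
  })
  list(profiles = out, shift_position = as.integer(shift_position))
}

## exact inverse of the +1 nt shift (for round-trip checks)
unshift_frameshift <- function(ps, shift_position) {
  out <- ps
  out$profiles <- lapply(ps$profiles, function(p) {
    idx <- which(window_positions(p$start, length(p$counts)) > shift_position)
    if (length(idx)) {
      seg <- p$counts[idx]
      p$counts[idx] <- c(seg[-1], 0)
    }
    p$alpha <- sum(p$counts)
    p
  })
  out
}

#' Frame skewness around a frameshift point
#'
#' Frame-0 fraction over CDS positions at or before the frameshift point and
#' frame-1 fraction over CDS positions strictly after it. An empty or
#' massless segment yields `NA` for that fraction.
#'
#' @param asite an `asite_profile` (or any list with `values` and `start`).
#' @param shift_position the frameshift point (nt, frame 0, in-CDS).
#' @return named numeric c(f0_before, f1_after).
#' @export
frameshift_skewness <- function(asite, shift_position) {
  v <- asite$values
  pos <- window_positions(asite$start, length(v))
  cds_len <- if (!is.na(asite$cds_end)) asite$cds_end - asite$cds_start
             else max(pos) + 1L
  in_cds <- pos >= 0 & pos < cds_len
  before <- in_cds & pos <= shift_position
  after <- in_cds & pos > shift_position
  frac <- function(sel, f) {
    tot <- sum(v[sel])
    if (tot <= 0) return(NA_real_)
    sum(v[sel & frame_of_pos(pos) == f]) / tot
  }
  c(f0_before = frac(before, 0L), f1_after = frac(after, 1L))
}

#' Write A-site profiles to TSV
#'
#' @param asites list of `asite_profile` objects.
#' @param path output TSV (transcript_id, position, value; nonzero cells).
#' @export
write_asite <- function(asites, path) {
  rows <- lapply(asites, function(a) {
    nz <- which(a$values != 0)
    data.table::data.table(transcript_id = a$transcript_id,
                           position = a$start + nz - 1L,
                           value = a$values[nz])
  })
  dt <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(transcript_id = character(),
                           position = integer(), value = numeric())
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read A-site profiles from TSV
#'
#' @param path TSV written by [write_asite()].
#' @param annotations annotation data.frame.
#' @param l_up upstream window extent, default 24.
#' @return named list of `asite_profile` objects.
#' @export
read_asite <- function(path, annotations, l_up = L_UP_DEFAULT) {
  annotations <- validate_annotations(annotations)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  out <- list()
  for (tid in unique(dt$transcript_id)) {
    ann <- annotations[tid, , drop = FALSE]
    win <- profile_window(ann, l_up)
    sub <- dt[dt$transcript_id == tid, ]
    values <- numeric(win["n"])
    idx <- sub$position - win["start"] + 1L
    ok <- idx >= 1L & idx <= win["n"]
    values[idx[ok]] <- sub$value[ok]
    out[[tid]] <- new_asite_profile(tid, win["start"], values,
                                    ann$cds_start, ann$cds_end)
  }
  out
}
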