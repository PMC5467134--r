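## ---- length-stratified observed 5'-end profiles -------------------------
##
## A length_profile holds, for one transcript and one read length, the vector
## of 5'-end counts on the window [-l_up, l_down) relative to the first base
## of the start codon, plus alpha = the total raw read count for that length.

new_length_profile <- function(transcript_id, read_length, start, counts,
                               alpha = sum(counts)) {
  stopifnot(all(counts >= 0), alpha >= 0)
  structure(list(transcript_id = transcript_id,
                 read_length = as.integer(read_length),
                 start = as.integer(start),
                 counts = as.numeric(counts),
                 alpha = as.numeric(alpha)),
            class = "length_profile")
}

#' @export
print.length_profile <- function(x, ...) {
  cat(sprintf("<length_profile> %s  l=%d  window=[%d,%d)  alpha=%g\n",
              x$transcript_id, x$read_length, x$start,
              x$start + length(x$counts), x$alpha))
  invisible(x)
}

#' Build length-stratified 5'-end profiles from transcriptome alignments
#'
#' Counts, per transcript and read length, the 5'-most aligned base of every
#' uniquely mapped read (SAM `POS`; 5' soft-clipped bases are already excluded
#' by the aligner convention), at positions relative to the first base of the
#' start codon. The effective read length is the reference span of the
#' alignment. Reads that are unmapped, secondary, supplementary,
#' reverse-strand, multi-mapping (NH > 1, or MAPQ below `min_mapq` when NH is
#' absent), outside `length_range`, aligned to an unannotated reference, or
#' whose 5' end falls outside the profile window are dropped.
#'
#' @param path SAM or BAM file in transcriptome coordinates.
#' @param annotations annotation data.frame (see [read_annotations()]).
#' @param length_range integer vector c(min, max) of retained read lengths.
#' @param l_up upstream extent of the profile window (nt), default 24.
#' @param min_mapq MAPQ threshold used only when the NH tag is missing.
#' @return named list (by transcript) of lists (by read length, as character)
#'   of `length_profile` objects.
#' @export
build_length_profiles <- function(path, annotations,
                                  length_range = c(18L, 33L),
                                  l_up = L_UP_DEFAULT, min_mapq = 10L) {
  annotations <- validate_annotations(annotations)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "cigar", "flag", "mapq"), tag = "NH")
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(rec$pos)
  if (n == 0L) return(list())
  flag <- rec$flag
  keep <- !bitwAnd(flag, 4L) & !bitwAnd(flag, 256L) &
    !bitwAnd(flag, 2048L) & !bitwAnd(flag, 16L) & !is.na(rec$pos)
  nh <- rec$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, n)
  unique_ok <- ifelse(is.na(nh),
                      !is.na(rec$mapq) & rec$mapq >= min_mapq,
                      nh == 1L)
  keep <- keep & unique_ok
  rname <- as.character(rec$rname)
  known <- rname %in% annotations$transcript_id
  if (any(keep & !known)) {
    warning(sum(keep & !known),
            " read(s) aligned to reference(s) absent from the annotation; ",
            "dropped")
    keep <- keep & known
  }
  if (!any(keep)) return(list())
  rlen <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar[keep])
  rname <- rname[keep]
  pos0 <- rec$pos[keep] - 1L
  inr <- rlen >= length_range[1] & rlen <= length_range[2]
  rname <- rname[inr]; pos0 <- pos0[inr]; rlen <- rlen[inr]

  out <- list()
  for (tid in unique(rname)) {
    ann <- annotations[tid, , drop = FALSE]
    win <- profile_window(ann, l_up)
    sel <- rname == tid
    rel <- pos0[sel] - ann$cds_start
    ll <- rlen[sel]
    inw <- rel >= win["start"] & rel < win["start"] + win["n"]
    rel <- rel[inw]; ll <- ll[inw]
    profs <- list()
    for (l in sort(unique(ll))) {
      idx <- rel[ll == l] - win["start"] + 1L
      counts <- tabulate(idx, nbins = win["n"])
      profs[[as.character(l)]] <-
        new_length_profile(tid, l, win["start"], counts)
    }
    if (length(profs)) out[[tid]] <- profs
  }
  out
}

#' In-frame of a set of length profiles
#'
#' The frame (0, 1 or 2, relative to the start codon) with the highest total
#' read count, summed over all read lengths; ties break toward the smallest
#' frame index.
#'
#' @param profiles list of `length_profile` objects for one transcript, or a
#'   `profile_set`.
#' @return integer frame in 0:2.
#' @export
in_frame_of <- function(profiles) {
  if (inherits(profiles, "profile_set")) profiles <- profiles$profiles
  if (inherits(profiles, "length_profile")) profiles <- list(profiles)
  totals <- c(0, 0, 0)
  for (p in profiles) {
    pos <- window_positions(p$start, length(p$counts))
    fr <- frame_of_pos(pos)
    for (f in 0:2) totals[f + 1L] <- totals[f + 1L] + sum(p$counts[fr == f])
  }
  if (all(totals == 0)) stop("no reads: all profiles are zero")
  as.integer(which.max(totals) - 1L)
}

#' Normalize a length profile to sum 1
#'
#' Counts are divided by their sum; `alpha` (the raw total) is unchanged.
#'
#' @param p a `length_profile`.
#' @return the normalized `length_profile`.
#' @export
normalize_profile <- function(p) {
  s <- sum(p$counts)
  if (p$alpha <= 0 || s <= 0) stop("cannot normalize an empty profile")
  p$counts <- p$counts / s
  p
}

new_profile_set <- function(transcript_id, profiles, in_frame, annotation) {
  structure(list(transcript_id = transcript_id,
                 profiles = profiles,
                 in_frame = as.integer(in_frame),
                 cds_start = annotation$cds_start,
                 cds_end = annotation$cds_end,
                 tx_length = annotation$length),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("<profile_set> %s  lengths={%s}  in_frame=%d  cds=%d nt\n",
              x$transcript_id,
              paste(names(x$profiles), collapse = ","),
              x$in_frame, x$cds_end - x$cds_start))
  invisible(x)
}

#' Coverage-filter profiles and assemble per-transcript profile sets
#'
#' A length profile is retained iff strictly more than `min_coverage` of the
#' in-frame loci within the CDS have nonzero counts (the in-frame is the
#' frame with the highest total count across all lengths of the transcript).
#' A transcript is retained iff at least two read lengths survive.
#'
#' @param profiles output of [build_length_profiles()] (or the same nested
#'   list shape).
#' @param annotations annotation data.frame.
#' @param min_coverage fraction threshold, default 0.5 (strict inequality).
#' @return named list of `profile_set` objects.
#' @export
filter_profiles <- function(profiles, annotations, min_coverage = 0.5) {
  annotations <- validate_annotations(annotations)
  out <- list()
  for (tid in names(profiles)) {
    ann <- annotations[tid, , drop = FALSE]
    cds_len <- ann$cds_end - ann$cds_start
    profs <- profiles[[tid]]
    tot <- vapply(profs, function(p) sum(p$counts), 0)
    if (all(tot == 0)) next
    f <- in_frame_of(profs)
    kept <- list()
    for (nm in names(profs)) {
      p <- profs[[nm]]
      pos <- window_positions(p$start, length(p$counts))
      loci <- pos >= 0 & pos < cds_len & frame_of_pos(pos) == f
      n_loci <- sum(loci)
      if (n_loci == 0) next
      if (sum(p$counts[loci] > 0) > min_coverage * n_loci)
        kept[[nm]] <- p
    }
    if (length(kept) >= 2L)
      out[[tid]] <- new_profile_set(tid, kept, f, ann)
  }
  out
}

## ---- TSV round trip ------------------------------------------------------

#' Write profiles to a sparse TSV
#'
#' One row per nonzero cell: transcript_id, read_length, position, count.
#' @param profiles nested list as from [build_length_profiles()].
#' @param path output file.
#' @export
write_profiles <- function(profiles, path) {
  rows <- list()
  for (tid in names(profiles)) for (p in profiles[[tid]]) {
    nz <- which(p$counts != 0)
    if (!length(nz)) next
    rows[[length(rows) + 1L]] <- data.table::data.table(
      transcript_id = tid, read_length = p$read_length,
      position = p$start + nz - 1L, count = p$counts[nz])
  }
  dt <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(transcript_id = character(),
                           read_length = integer(),
                           position = integer(), count = numeric())
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read profiles from a TSV written by [write_profiles()]
#'
#' @param path TSV file.
#' @param annotations annotation data.frame (defines the windows).
#' @param l_up upstream window extent, must match the value used when building.
#' @return nested list as from [build_length_profiles()].
#' @export
read_profiles <- function(path, annotations, l_up = L_UP_DEFAULT) {
  annotations <- validate_annotations(annotations)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  out <- list()
  for (tid in unique(dt$transcript_id)) {
    if (!tid %in% annotations$transcript_id)
      stop("profile references unknown transcript: ", tid)
    ann <- annotations[tid, , drop = FALSE]
    win <- profile_window(ann, l_up)
    sub <- dt[dt$transcript_id == tid, ]
    profs <- list()
    for (l in sort(unique(sub$read_length))) {
      s2 <- sub[sub$read_length == l, ]
      counts <- numeric(win["n"])
      idx <- s2$position - win["start"] + 1L
      ok <- idx >= 1L & idx <= win["n"]
      counts[idx[ok]] <- s2$count[ok]
      profs[[as.character(l)]] <- new_length_profile(tid, l, win["start"], counts)
    }
    out[[tid]] <- profs
  }
  out
}
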