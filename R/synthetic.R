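## ---- synthetic ground-truth generator -----------------------------------
##
## The generator states a world matching the model's assumptions: a sparse,
## frame-0-concentrated consensus position signal per transcript; per-length
## signals equal to the consensus shifted into each read length's observation
## frame with small multiplicative perturbations; unimodal per-length blur
## vectors on offsets [-15, 15]; and multinomial read sampling from the
## blurred expectations. Slow codons are slow through stochastic pausing:
## codon values are drawn LN(0, s_k) with s_k^2 = s0^2 + 2 log(m_k), so the
## mean dwell is exp(s0^2/2) * m_k and both the mean and the lognormal
## skewness increase with the planted multiplier m_k.

#' Specification of a synthetic ribosome profiling data set
#'
#' Defaults describe a deep yeast-like experiment: 50 transcripts, CDSs of
#' 150-300 codons (transcripts > 350 nt, as meta-profile building requires),
#' five read lengths with length 28 carrying just under half of the reads,
#' 10,000 footprints per transcript, and digestion blur whose spread grows
#' away from the canonical 28-mer.
#'
#' @param n_transcripts number of transcripts.
#' @param cds_codons integer range c(min, max) of CDS lengths in codons
#'   (stop codon included).
#' @param read_lengths integer vector of read lengths.
#' @param mixture_weights read-length mixture, sums to 1.
#' @param depth total reads per transcript.
#' @param blur_modes per-length blur mode offsets (recycled).
#' @param blur_spreads per-length blur spreads (sd of the discretized
#'   Gaussian kernel; 0 gives a delta). Default `0.5 + 0.35 * |l - 28|`.
#' @param perturb_sigma sdlog of the multiplicative per-length perturbation
#'   of the true signal, default 0.05.
#' @param base_sigma baseline sdlog of per-codon signal values, default 0.6.
#' @param ramp_amp,ramp_tau amplitude and decay length (codons) of the shared
#'   5' translational ramp multiplying codon values,
#'   `1 + ramp_amp * exp(-c / ramp_tau)`; defaults 1.5 and 20. The ramp is
#'   the reproducible positional structure of real start-codon-anchored
#'   meta-profiles; without it the meta-consensus averages out to a
#'   3-periodic-flat signal on which within-frame blur offsets are nearly
#'   unidentifiable.
#' @param dwell optional named per-codon multiplier vector (values >= 1).
#' @param frameshift logical: plant a 1-nt insertion frameshift per
#'   transcript.
#' @param utr5,utr3 UTR lengths in nt.
#' @param seed integer seed driving all draws.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_transcripts = 50L,
                           cds_codons = c(150L, 300L),
                           read_lengths = c(26L, 27L, 28L, 29L, 30L),
                           mixture_weights = c(0.12, 0.17, 0.42, 0.17, 0.12),
                           depth = 10000L,
                           blur_modes = 0L,
                           blur_spreads = NULL,
                           perturb_sigma = 0.05,
                           base_sigma = 0.6,
                           ramp_amp = 1.5,
                           ramp_tau = 20,
                           dwell = NULL,
                           frameshift = FALSE,
                           utr5 = 24L, utr3 = 40L,
                           seed = 1L) {
  if (is.null(blur_spreads))
    blur_spreads <- 0.5 + 0.35 * abs(read_lengths - 28L)
  blur_modes <- rep_len(blur_modes, length(read_lengths))
  blur_spreads <- rep_len(blur_spreads, length(read_lengths))
  spec <- list(n_transcripts = as.integer(n_transcripts),
               cds_codons = as.integer(cds_codons),
               read_lengths = as.integer(read_lengths),
               mixture_weights = mixture_weights,
               depth = as.numeric(depth),
               blur_modes = blur_modes,
               blur_spreads = blur_spreads,
               perturb_sigma = perturb_sigma,
               base_sigma = base_sigma,
               ramp_amp = ramp_amp,
               ramp_tau = ramp_tau,
               dwell = dwell,
               frameshift = isTRUE(frameshift),
               utr5 = as.integer(utr5), utr3 = as.integer(utr3),
               seed = as.integer(seed))
  problems <- character()
  if (abs(sum(spec$mixture_weights) - 1) > 1e-8)
    problems <- c(problems, "mixture_weights must sum to 1")
  if (length(spec$mixture_weights) != length(spec$read_lengths))
    problems <- c(problems, "one mixture weight per read length")
  if (spec$depth <= 0) problems <- c(problems, "depth must be positive")
  if (any(spec$cds_codons < 21L))
    problems <- c(problems, "cds_codons must be >= 21")
  if (!is.null(spec$dwell) && any(spec$dwell < 1))
    problems <- c(problems, "dwell multipliers must be >= 1")
  if (length(problems)) stop("invalid spec: ", paste(problems, collapse = "; "))
  class(spec) <- "synthetic_spec"
  spec
}

## discretized unimodal (Gaussian) blur kernel on offsets -15..15
blur_kernel <- function(mode, spread) {
  if (spread <= 0) {
    w <- as.numeric(BLUR_OFFSETS == mode)
  } else {
    w <- exp(-((BLUR_OFFSETS - mode)^2) / (2 * spread^2))
  }
  w / sum(w)
}

#' Generate ground truth for a synthetic spec
#'
#' @param spec a `synthetic_spec`.
#' @return a `synthetic_truth` list: `annotations`, `cds_seqs`, per-length
#'   `blurs` (shared across transcripts), `dwell`, and per-transcript
#'   `transcripts` entries holding the consensus signal, per-length true
#'   signals (observation frame) and any planted frameshift position.
#' @export
generate_truth <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  lens <- spec$read_lengths
  blurs <- setNames(lapply(seq_along(lens), function(i)
    new_blur_vector(lens[i],
                    blur_kernel(spec$blur_modes[i], spec$blur_spreads[i]))),
    as.character(lens))
  dwell <- spec$dwell
  if (is.null(dwell)) dwell <- setNames(rep(1, length(SENSE_CODONS)),
                                        SENSE_CODONS)
  s_codon <- sqrt(spec$base_sigma^2 + 2 * log(dwell))

  ann <- list(); seqs <- character(); txs <- list()
  for (t in seq_len(spec$n_transcripts)) {
    tid <- sprintf("TX%04d", t)
    n_cod <- if (spec$cds_codons[1] == spec$cds_codons[2]) spec$cds_codons[1]
             else sample(spec$cds_codons[1]:spec$cds_codons[2], 1L)
    body <- sample(SENSE_CODONS, n_cod - 2L, replace = TRUE)
    codons <- c("AUG", body, "UAA")
    cds_len <- 3L * n_cod
    a <- data.frame(transcript_id = tid, cds_start = spec$utr5,
                    cds_end = spec$utr5 + cds_len,
                    length = spec$utr5 + cds_len + spec$utr3)
    win <- profile_window(a)
    pos <- window_positions(win["start"], win["n"])
    consensus <- numeric(win["n"])
    ## A-site at codon c sits at nt 3c; its length-28 5' end at 3c - 15
    svals <- s_codon[codons]
    svals[is.na(svals)] <- spec$base_sigma   # stop codon: baseline dispersion
    ramp <- 1 + spec$ramp_amp * exp(-(seq_len(n_cod) - 1L) / spec$ramp_tau)
    vals <- ramp * rlnorm(n_cod, meanlog = 0, sdlog = svals)
    p5 <- 3L * (seq_len(n_cod) - 1L) - 15L
    consensus[match(p5, pos)] <- vals
    consensus <- consensus / sum(consensus)
    per_length <- setNames(lapply(lens, function(l) {
      v <- shift_profile(consensus, obs_shift(l)) *
        rlnorm(win["n"], 0, spec$perturb_sigma)
      v / sum(v)
    }), as.character(lens))
    fs <- NA_integer_
    if (spec$frameshift) {
      cand <- seq.int(30L, cds_len - 33L, by = 3L)
      fs <- as.integer(cand[sample.int(length(cand), 1L)])
    }
    ann[[t]] <- a
    seqs[tid] <- paste(codons, collapse = "")
    txs[[tid]] <- list(transcript_id = tid, start = win[["start"]],
                       consensus = consensus, per_length = per_length,
                       codons = codons, shift_position = fs)
  }
  structure(list(spec = spec,
                 annotations = validate_annotations(do.call(rbind, ann)),
                 cds_seqs = seqs, blurs = blurs, dwell = dwell,
                 transcripts = txs),
            class = "synthetic_truth")
}

#' Sample observed profiles from a synthetic truth
#'
#' For each transcript and read length, the expected observed profile is the
#' blur convolved with the true length-specific signal; counts are drawn
#' multinomially with total `round(depth * mixture_weight)`. With
#' `exact = TRUE` the expectations themselves (scaled to the same totals) are
#' returned - the infinite-depth limit. Planted frameshifts are applied to
#' the sampled read starts.
#'
#' @param truth a `synthetic_truth`.
#' @param exact logical; skip multinomial sampling.
#' @param seed seed for the sampling stage; defaults to `spec$seed + 1`.
#' @return named list (transcript) of named lists (read length) of
#'   `length_profile` objects.
#' @export
sample_reads <- function(truth, exact = FALSE, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  spec <- truth$spec
  if (is.null(seed)) seed <- spec$seed + 1L
  set.seed(seed)
  out <- list()
  for (tid in names(truth$transcripts)) {
    tx <- truth$transcripts[[tid]]
    profs <- list()
    for (i in seq_along(spec$read_lengths)) {
      l <- spec$read_lengths[i]
      size <- round(spec$depth * spec$mixture_weights[i])
      if (size <= 0) next
      e <- convolve_blur(tx$per_length[[as.character(l)]],
                         truth$blurs[[as.character(l)]]$weights)
      e <- pmax(e, 0)
      if (sum(e) <= 0) next
      counts <- if (exact) size * e / sum(e)
                else as.numeric(rmultinom(1L, size, e))
      profs[[as.character(l)]] <-
        new_length_profile(tid, l, tx$start, counts)
    }
    if (!is.na(tx$shift_position) && length(profs)) {
      fake_ps <- new_profile_set(tid, profs, 0L,
                                 truth$annotations[tid, , drop = FALSE])
      profs <- simulate_frameshift(fake_ps,
                                   shift_position = tx$shift_position)$profiles$profiles
    }
    if (length(profs)) out[[tid]] <- profs
  }
  out
}

#' Write a self-describing synthetic fixture bundle to disk
#'
#' Writes profiles.tsv, truth_consensus.tsv, blur.tsv, annotation.tsv,
#' cds.fa, spec.json and optionally reads.sam, sufficient to exercise every
#' pipeline stage without regeneration.
#'
#' @param spec a `synthetic_spec`.
#' @param dir output directory (created if needed).
#' @param sam logical; also emit a SAM file of the sampled reads.
#' @return (invisibly) a list with the truth, the sampled profiles and the
#'   file paths.
#' @export
make_fixture <- function(spec, dir, sam = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- generate_truth(spec)
  profiles <- sample_reads(truth)
  paths <- list(
    profiles = file.path(dir, "profiles.tsv"),
    truth = file.path(dir, "truth_consensus.tsv"),
    blur = file.path(dir, "blur.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    cds = file.path(dir, "cds.fa"),
    spec = file.path(dir, "spec.json"))
  write_profiles(profiles, paths$profiles)
  data.table::fwrite(truth$annotations, paths$annotation, sep = "\t")
  tr <- data.table::rbindlist(lapply(truth$transcripts, function(tx) {
    nz <- which(tx$consensus != 0)
    data.table::data.table(transcript_id = tx$transcript_id,
                           position = tx$start + nz - 1L,
                           value = tx$consensus[nz],
                           shift_position = tx$shift_position)
  }))
  data.table::fwrite(tr, paths$truth, sep = "\t")
  write_blurs(truth$blurs, paths$blur)
  writeLines(unlist(lapply(names(truth$cds_seqs), function(tid)
    c(paste0(">", tid), chartr("U", "T", truth$cds_seqs[[tid]])))),
    paths$cds)
  sp <- truth$spec; class(sp) <- NULL
  jsonlite::write_json(sp, paths$spec, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (sam) {
    paths$sam <- file.path(dir, "reads.sam")
    write_sam(profiles, truth$annotations, paths$sam)
  }
  invisible(list(truth = truth, profiles = profiles, paths = paths))
}

#' Write blur vectors to TSV
#' @param blurs named list of `blur_vector` objects.
#' @param path output file (read_length, offset, weight).
#' @export
write_blurs <- function(blurs, path) {
  dt <- data.table::rbindlist(lapply(blurs, function(b)
    data.table::data.table(read_length = b$read_length,
                           offset = BLUR_OFFSETS, weight = b$weights)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read blur vectors from TSV
#' @param path file written by [write_blurs()].
#' @return named list of `blur_vector` objects.
#' @export
read_blurs <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  out <- list()
  for (l in sort(unique(dt$read_length))) {
    sub <- dt[dt$read_length == l, ]
    w <- numeric(length(BLUR_OFFSETS))
    w[match(sub$offset, BLUR_OFFSETS)] <- sub$weight
    out[[as.character(l)]] <- new_blur_vector(l, w)
  }
  out
}

## Emit sampled profiles as minimal single-end SAM records (sense strand,
## full-match CIGAR, NH:i:1), for end-to-end tests of the alignment reader.
write_sam <- function(profiles, annotations, path) {
  annotations <- validate_annotations(annotations)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (tid in annotations$transcript_id)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", tid,
                       annotations[tid, "length"]), con)
  ri <- 0L
  for (tid in names(profiles)) {
    cds_start <- annotations[tid, "cds_start"]
    tx_len <- annotations[tid, "length"]
    for (p in profiles[[tid]]) {
      nz <- which(p$counts > 0)
      if (!length(nz)) next
      reps <- round(p$counts[nz])
      pos1 <- rep(p$start + nz - 1L + cds_start + 1L, reps)  # 1-based SAM POS
      pos1 <- pos1[pos1 >= 1L & pos1 + p$read_length - 1L <= tx_len]
      if (!length(pos1)) next
      ids <- sprintf("read%07d", ri + seq_along(pos1))
      ri <- ri + length(pos1)
      writeLines(sprintf(
        "%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNH:i:1",
        ids, tid, pos1, p$read_length,
        strrep("N", p$read_length)), con)
    }
  }
  invisible(path)
}
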