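## ---- codon decoding time (CDT) analysis ---------------------------------

STOP_CODONS <- c("UAA", "UAG", "UGA")

SENSE_CODONS <- {
  b <- c("U", "C", "A", "G")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(sort(all3), STOP_CODONS)
}

to_rna <- function(seq) chartr("Tt", "Uu", toupper(seq))

#' Per-codon normalized A-site counts for one transcript
#'
#' The raw count of codon position `c` is the A-site profile value at nt
#' `3c` (frame 0). Positions with raw count < 1 are excluded; surviving
#' counts are divided by the transcript's mean raw count over the included
#' positions; the first and last 20 codon positions are always excluded.
#' Transcripts shorter than 41 codons are skipped with a warning.
#'
#' @param asite an `asite_profile` covering the CDS.
#' @param cds_seq CDS nucleotide sequence (DNA or RNA alphabet; length must
#'   be a multiple of 3 and match the annotated CDS).
#' @param trim number of codon positions trimmed from each CDS end,
#'   default 20.
#' @param min_raw raw-count inclusion threshold, default 1.
#' @return data.frame with columns codon, position (codon index) and
#'   normalized_count; zero rows if the transcript is skipped.
#' @export
codon_counts <- function(asite, cds_seq, trim = 20L, min_raw = 1) {
  cds_seq <- to_rna(as.character(cds_seq))
  if (nchar(cds_seq) %% 3L != 0L) stop("CDS length not divisible by 3")
  n_cod <- nchar(cds_seq) %/% 3L
  empty <- data.frame(codon = character(), position = integer(),
                      normalized_count = numeric())
  if (n_cod < 2L * trim + 1L) {
    warning(asite$transcript_id, ": CDS shorter than ", 2L * trim + 1L,
            " codons; skipped")
    return(empty)
  }
  pos <- window_positions(asite$start, length(asite$values))
  raw <- vapply(0:(n_cod - 1L), function(c0) {
    i <- match(3L * c0, pos)
    if (is.na(i)) 0 else asite$values[i]
  }, 0)
  cand <- seq.int(trim, n_cod - trim - 1L)            # 0-based codon indices
  included <- cand[raw[cand + 1L] >= min_raw]
  if (!length(included)) return(empty)
  mean_raw <- mean(raw[included + 1L])
  codons <- substring(cds_seq, 3L * included + 1L, 3L * included + 3L)
  data.frame(codon = codons, position = included,
             normalized_count = raw[included + 1L] / mean_raw)
}

#' Lognormal fit and skewness of a codon count distribution
#'
#' `mu` and `sigma` are the maximum-likelihood (1/n) mean and standard
#' deviation of the natural-log counts; the skewness of the fitted lognormal,
#' `(exp(sigma^2) + 2) * sqrt(exp(sigma^2) - 1)`, is the CDT estimate.
#'
#' @param x strictly positive normalized counts.
#' @param n_min minimum number of observations, default 20.
#' @return named numeric c(mu, sigma, skewness), or NULL if fewer than
#'   `n_min` observations.
#' @export
fit_lognormal_skewness <- function(x, n_min = 20L) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) < n_min) return(NULL)
  lx <- log(x)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  c(mu = mu, sigma = sigma, skewness = lognormal_skewness(sigma))
}

#' Closed-form lognormal skewness
#' @param sigma lognormal scale parameter (>= 0).
#' @return `(exp(sigma^2) + 2) * sqrt(exp(sigma^2) - 1)`.
#' @export
lognormal_skewness <- function(sigma) {
  e <- exp(sigma^2)
  (e + 2) * sqrt(pmax(e - 1, 0))
}

#' Build the per-codon decoding-time table
#'
#' Pools codon observations across transcripts, fits each sense codon's
#' normalized count distribution with a lognormal, and reports the fitted
#' parameters and skewness (the CDT estimate). Stop codons and codons with
#' fewer than `n_min` observations are absent from the table.
#'
#' @param asites named list of `asite_profile` objects.
#' @param cds_seqs named character vector (or `Biostrings::DNAStringSet`) of
#'   CDS sequences; names must match transcript ids.
#' @param n_min minimum observations per codon fit, default 20.
#' @param trim,min_raw passed to [codon_counts()].
#' @return `cdt_table`: data.frame with columns codon, n_obs, mu, sigma,
#'   skewness.
#' @export
build_cdt_table <- function(asites, cds_seqs, n_min = 20L, trim = 20L,
                            min_raw = 1) {
  cds_seqs <- setNames(as.character(cds_seqs), names(cds_seqs))
  obs <- list()
  for (a in asites) {
    seq <- cds_seqs[[a$transcript_id]]
    if (is.null(seq)) {
      warning("no CDS sequence for ", a$transcript_id, "; skipped")
      next
    }
    obs[[length(obs) + 1L]] <- codon_counts(a, seq, trim, min_raw)
  }
  all_obs <- do.call(rbind, obs)
  rows <- list()
  if (!is.null(all_obs) && nrow(all_obs)) {
    for (cod in sort(unique(all_obs$codon))) {
      if (cod %in% STOP_CODONS) next
      fit <- fit_lognormal_skewness(
        all_obs$normalized_count[all_obs$codon == cod], n_min)
      if (is.null(fit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        codon = cod, n_obs = sum(all_obs$codon == cod),
        mu = fit[["mu"]], sigma = fit[["sigma"]],
        skewness = fit[["skewness"]])
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(codon = character(), n_obs = integer(), mu = numeric(),
               sigma = numeric(), skewness = numeric())
  rownames(tab) <- tab$codon
  class(tab) <- c("cdt_table", "data.frame")
  tab
}

#' Default same-tRNA wobble codon pairs (yeast)
#'
#' Three anticodon classes of same-tRNA codon pairs differing only at the
#' third base: U:A (Watson-Crick) vs U:G (wobble); G:C (Watson-Crick) vs G:U
#' (wobble); inosine I:C (stronger wobble) vs I:U (weaker wobble). Compiled
#' from the standard yeast tRNA wobble-decoding rules; approximate defaults,
#' overridable with a user TSV of the same shape.
#'
#' @param path optional TSV with columns class, codon_wc, codon_wb.
#' @return data.frame with columns class, codon_wc, codon_wb (RNA alphabet).
#' @export
wobble_pairs <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "wobble_pairs_yeast.tsv",
                        package = "riboclear", mustWork = TRUE)
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  df$codon_wc <- to_rna(df$codon_wc)
  df$codon_wb <- to_rna(df$codon_wb)
  df
}

#' Relative decoding-time difference for a wobble pair
#'
#' `delta_t = (t_wobble - t_wc) / t_wc`, with the CDT skewness as the time
#' estimate. For the inosine class the `codon_wc` slot holds the
#' stronger-wobble I:C codon.
#'
#' @param table a `cdt_table`.
#' @param codon_wc,codon_wb the Watson-Crick (or stronger-wobble) and wobble
#'   codons (RNA or DNA alphabet).
#' @return the relative difference, or `NA` if either codon is missing or
#'   the reference skewness is zero.
#' @export
wobble_delta <- function(table, codon_wc, codon_wb) {
  codon_wc <- to_rna(codon_wc); codon_wb <- to_rna(codon_wb)
  if (!codon_wc %in% table$codon || !codon_wb %in% table$codon)
    return(NA_real_)
  t_wc <- table[codon_wc, "skewness"]
  t_wb <- table[codon_wb, "skewness"]
  if (t_wc == 0) return(NA_real_)
  (t_wb - t_wc) / t_wc
}

#' Wobble-pair decoding-time differences for a pair table
#'
#' @param table a `cdt_table`.
#' @param pairs data.frame as from [wobble_pairs()].
#' @return the pair table with a `delta_t` column appended.
#' @export
wobble_deltas <- function(table, pairs = wobble_pairs()) {
  pairs$delta_t <- mapply(function(wc, wb) wobble_delta(table, wc, wb),
                          pairs$codon_wc, pairs$codon_wb)
  pairs
}

#' Spearman rank correlation of CDT with a per-codon covariate
#'
#' @param table a `cdt_table`.
#' @param covariate named numeric vector (names = codons, RNA or DNA
#'   alphabet), e.g. tAI values or codon usage frequencies.
#' @param min_codons minimum overlap, default 10.
#' @return list with `rho` and `p` (`NA` for constant input).
#' @export
rank_correlation <- function(table, covariate, min_codons = 10L) {
  names(covariate) <- to_rna(names(covariate))
  common <- intersect(table$codon, names(covariate))
  if (length(common) < min_codons)
    stop("fewer than ", min_codons, " codons shared with the covariate")
  x <- table[common, "skewness"]
  y <- covariate[common]
  if (sd(x) == 0 || sd(y) == 0) return(list(rho = NA_real_, p = NA_real_))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Write a CDT table to TSV
#' @param table a `cdt_table`.
#' @param path output file.
#' @export
write_cdt <- function(table, path) {
  data.table::fwrite(as.data.frame(table), path, sep = "\t")
  invisible(path)
}
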