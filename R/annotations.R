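#' Read transcript CDS annotations
#'
#' The annotation table gives, per transcript, the 0-based offset of the first
#' start-codon base (`cds_start`), the 0-based exclusive end of the stop codon
#' (`cds_end`) and the transcript length in nt. Invariants
#' `0 <= cds_start < cds_end <= length` and `(cds_end - cds_start) %% 3 == 0`
#' are enforced.
#'
#' @param path TSV file with columns transcript_id, cds_start, cds_end, length.
#' @return data.frame of validated annotations.
#' @export
read_annotations <- function(path) {
  ann <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  validate_annotations(ann)
}

#' Validate an annotation table
#'
#' @param ann data.frame with columns transcript_id, cds_start, cds_end, length.
#' @return the validated data.frame (invisibly the same object).
#' @export
validate_annotations <- function(ann) {
  need <- c("transcript_id", "cds_start", "cds_end", "length")
  if (!all(need %in% names(ann)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  ann$transcript_id <- as.character(ann$transcript_id)
  for (col in c("cds_start", "cds_end", "length"))
    ann[[col]] <- as.integer(ann[[col]])
  bad <- with(ann, cds_start < 0 | cds_start >= cds_end | cds_end > length)
  if (any(bad))
    stop("invalid CDS coordinates for: ",
         paste(ann$transcript_id[bad], collapse = ", "))
  off <- with(ann, (cds_end - cds_start) %% 3L != 0L)
  if (any(off))
    stop("CDS length not divisible by 3 for: ",
         paste(ann$transcript_id[off], collapse = ", "))
  if (anyDuplicated(ann$transcript_id))
    stop("duplicated transcript_id in annotation table")
  rownames(ann) <- ann$transcript_id
  ann
}

## Profile window for one transcript: positions [-l_up, l_down) relative to
## cds_start, where l_down = min(space downstream of the start codon,
## CDS length + l_up). Returns c(start, length).
profile_window <- function(ann_row, l_up = L_UP_DEFAULT) {
  cds_len <- ann_row$cds_end - ann_row$cds_start
  l_down <- min(ann_row$length - ann_row$cds_start, cds_len + l_up)
  c(start = -as.integer(l_up), n = as.integer(l_up + l_down))
}
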