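# Shared synthetic fixtures, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# one mid-sized world shared by module-level tests
module_world <- function() {
  cached("module_world", function() {
    spec <- synthetic_spec(n_transcripts = 20L, cds_codons = c(130L, 200L),
                           depth = 8000L, seed = 101L)
    truth <- generate_truth(spec)
    profiles <- sample_reads(truth)
    list(spec = spec, truth = truth, profiles = profiles,
         ann = truth$annotations)
  })
}

module_blurfit <- function() {
  cached("module_blurfit", function() {
    w <- module_world()
    metas <- lapply(w$spec$read_lengths, function(l)
      build_meta_profile(w$profiles, l, w$ann))
    fit <- estimate_all_blurs(metas)
    list(metas = metas, fit = fit)
  })
}

# a tiny hand-made profile_set on a small window
toy_profile_set <- function(counts28 = c(0, 0, 4, 1, 1, 2, 0, 0, 6, 0, 0, 3),
                            start = -3L) {
  n <- length(counts28)
  ann <- data.frame(transcript_id = "T1", cds_start = 24L,
                    cds_end = 24L + 66L, length = 150L)
  p28 <- riboclear:::new_length_profile("T1", 28L, start, counts28)
  p29 <- riboclear:::new_length_profile("T1", 29L, start,
                                        shift_profile(counts28, -1L))
  riboclear:::new_profile_set("T1", list("28" = p28, "29" = p29), 0L, ann)
}

delta_blur <- function(read_length, offset = 0L) {
  w <- as.numeric(riboclear:::BLUR_OFFSETS == offset)
  riboclear:::new_blur_vector(read_length, w)
}

# naive A-site baseline: every read's A-site at 5' end + 15
naive_asite <- function(ps) {
  agg <- Reduce(`+`, lapply(ps$profiles,
                            function(p) shift_profile(p$counts, 15L)))
  structure(list(transcript_id = ps$transcript_id,
                 values = agg, start = ps$profiles[[1]]$start,
                 cds_start = ps$cds_start, cds_end = ps$cds_end),
            class = "asite_profile")
}
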