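write_test_sam <- function(path, records,
                           refs = c(T1 = 200L, T2 = 150L)) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs))
  writeLines(c(hdr, records), path)
  path
}

test_ann <- data.frame(transcript_id = "T1", cds_start = 30L,
                       cds_end = 30L + 90L, length = 200L)

sam_rec <- function(rname, pos, cigar, flag = 0L, mapq = 255L, nh = 1L) {
  sprintf("r%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*\tNH:i:%d",
          paste0(rname, pos, cigar, flag), flag, rname, pos, mapq, cigar, nh)
}

test_that("build_length_profiles counts 5' ends and filters reads", {
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam, c(
    sam_rec("T1", 19L, "28M"),          # 5' end at cds_start - 12
    sam_rec("T1", 19L, "28M"),
    sam_rec("T1", 22L, "28M"),          # 5' end at cds_start - 9
    sam_rec("T1", 40L, "2S26M"),        # soft clip: 5' at first aligned base
    sam_rec("T1", 50L, "28M", nh = 2L), # multimapper, dropped
    sam_rec("T1", 50L, "28M", flag = 256L),  # secondary, dropped
    sam_rec("T1", 50L, "28M", flag = 16L),   # reverse strand, dropped
    sam_rec("T1", 60L, "40M"),          # length outside [18, 33], dropped
    sam_rec("T2", 10L, "28M")           # unknown reference, warned + dropped
  ))
  expect_warning(
    profs <- build_length_profiles(sam, test_ann),
    "absent from the annotation")
  expect_named(profs, "T1")
  p28 <- profs$T1[["28"]]
  pos <- riboclear:::window_positions(p28$start, length(p28$counts))
  expect_equal(p28$counts[pos == -12], 2)
  expect_equal(p28$counts[pos == -9], 1)
  expect_equal(p28$alpha, 3)
  # soft-clipped read: effective length = aligned span = 26, 5' at POS
  p26 <- profs$T1[["26"]]
  expect_equal(p26$counts[pos == (40 - 1 - 30)], 1)
  expect_equal(p26$alpha, 1)
  expect_null(profs$T1[["40"]])
})

test_that("empty alignment input yields an empty profile set", {
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam, character())
  expect_identical(build_length_profiles(sam, test_ann), list())
})

test_that("in_frame_of takes the argmax frame with smallest-index ties", {
  mk <- function(counts, start = 0L)
    riboclear:::new_length_profile("T", 28L, start, counts)
  # frame totals (10, 30, 5) -> frame 1
  expect_equal(in_frame_of(list(mk(c(10, 30, 5)))), 1L)
  # tie (10, 10, 5) -> smallest index
  expect_equal(in_frame_of(list(mk(c(10, 10, 5)))), 0L)
  # concentrated on multiples of 3 -> frame 0
  expect_equal(in_frame_of(list(mk(c(7, 0, 0, 9, 0, 0)))), 0L)
  # invariant under uniform scaling
  set.seed(3)
  v <- runif(30)
  expect_equal(in_frame_of(list(mk(v))), in_frame_of(list(mk(100 * v))))
  expect_error(in_frame_of(list(mk(numeric(6)))), "no reads")
})

test_that("normalize_profile divides by the sum and keeps alpha", {
  p <- riboclear:::new_length_profile("T", 28L, 0L, c(2, 0, 2))
  n1 <- normalize_profile(p)
  expect_equal(n1$counts, c(0.5, 0, 0.5))
  expect_equal(n1$alpha, 4)
  expect_equal(normalize_profile(n1)$counts, n1$counts)  # idempotent
  p4 <- riboclear:::new_length_profile("T", 28L, 0L, rep(1, 4))
  expect_equal(normalize_profile(p4)$counts, rep(0.25, 4))
  expect_equal(normalize_profile(p4)$alpha, 4)
  p0 <- riboclear:::new_length_profile("T", 28L, 0L, numeric(3))
  expect_error(normalize_profile(p0), "empty")
})

test_that("filter_profiles enforces >50% in-frame coverage and >=2 lengths", {
  ncod <- 100L
  ann <- data.frame(transcript_id = "T1", cds_start = 24L,
                    cds_end = 24L + 3L * ncod, length = 400L)
  win <- riboclear:::profile_window(ann)
  pos <- riboclear:::window_positions(win["start"], win["n"])
  mk <- function(n_nonzero, l) {
    counts <- numeric(win["n"])
    loci <- which(pos >= 0 & pos < 3 * ncod & pos %% 3 == 0)
    counts[loci[seq_len(n_nonzero)]] <- 5
    riboclear:::new_length_profile("T1", l, win["start"], counts)
  }
  # exactly 50% of the 100 in-frame loci: not strictly more -> dropped
  out <- filter_profiles(list(T1 = list("28" = mk(50L, 28L),
                                        "27" = mk(60L, 27L))), ann)
  expect_length(out, 0)   # only one length survives -> transcript dropped
  out2 <- filter_profiles(list(T1 = list("28" = mk(60L, 28L),
                                         "27" = mk(60L, 27L))), ann)
  expect_named(out2, "T1")
  expect_setequal(names(out2$T1$profiles), c("27", "28"))
  expect_equal(out2$T1$in_frame, 0L)
})

test_that("filter_profiles is monotone under added reads", {
  w <- module_world()
  kept_before <- filter_profiles(w$profiles, w$ann)
  more <- w$profiles
  set.seed(5)
  for (tid in names(more)) for (nm in names(more[[tid]])) {
    p <- more[[tid]][[nm]]
    extra <- rmultinom(1, 200, rep(1, length(p$counts)))
    p$counts <- p$counts + as.numeric(extra)
    p$alpha <- p$alpha + 200
    more[[tid]][[nm]] <- p
  }
  kept_after <- filter_profiles(more, w$ann)
  for (tid in names(kept_before)) {
    expect_true(tid %in% names(kept_after))
    expect_true(all(names(kept_before[[tid]]$profiles) %in%
                    names(kept_after[[tid]]$profiles)))
  }
})

test_that("profile TSV round-trips and SAM alpha accounting is exact", {
  w <- module_world()
  tsv <- tempfile(fileext = ".tsv")
  write_profiles(w$profiles, tsv)
  back <- read_profiles(tsv, w$ann)
  tid <- names(w$profiles)[1]
  for (nm in names(w$profiles[[tid]])) {
    expect_equal(back[[tid]][[nm]]$counts, w$profiles[[tid]][[nm]]$counts)
    expect_equal(back[[tid]][[nm]]$alpha, w$profiles[[tid]][[nm]]$alpha)
  }
  # SAM round trip on a small world: total alpha equals emitted reads
  spec <- synthetic_spec(n_transcripts = 3L, cds_codons = c(130L, 150L),
                         depth = 500L, seed = 77L)
  fx <- make_fixture(spec, tempfile("fx"), sam = TRUE)
  profs <- build_length_profiles(fx$paths$sam, fx$truth$annotations)
  for (tid in names(fx$profiles)) {
    expect_equal(
      sum(vapply(profs[[tid]], function(p) p$alpha, 0)),
      sum(vapply(fx$profiles[[tid]], function(p) sum(round(p$counts)), 0)))
    for (nm in names(fx$profiles[[tid]]))
      expect_equal(profs[[tid]][[nm]]$counts,
                   round(fx$profiles[[tid]][[nm]]$counts))
  }
})
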