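# shared fixtures: the documented example sheet and a zero-mismatch config
example_sheet <- function() {
  parse_sample_sheet("NNNATGCNN\nNNNATTANNN:sample_2\nNNNGCGGN,NNAA:sample_3,NNNTT")
}
strict_cfg <- function(...) demux_config(m5 = 0L, m3 = 0L, quality_threshold = 0L,
                                         min_length = 0L, ...)

test_that("5' detection slices barcode, UMI and remainder correctly", {
  sheet <- example_sheet()
  cfg <- strict_cfg()
  idx <- build_indexes(sheet, cfg)
  read <- make_read("r1", "GGGATGCAATTTTGGGGCCCC")
  d5 <- detect_5prime(read, idx$five, sheet)
  expect_equal(d5$outcome$status, "unique")
  expect_equal(d5$outcome$entry_id, 1L)
  expect_equal(d5$umi5, "GGGAA")
  expect_equal(d5$remainder$seq, substring(read$seq, 10L))
  expect_equal(nchar(d5$remainder$qual), nchar(d5$remainder$seq))

  # reads shorter than the barcode region are never matched
  short <- detect_5prime(make_read("r2", "GGGAT"), idx$five, sheet)
  expect_equal(short$outcome$status, "none")
  expect_equal(short$remainder$seq, "GGGAT")
})

test_that("ambiguous 5' candidates are rejected", {
  sheet <- parse_sample_sheet("NNAAAA\nNNAAAT")
  cfg <- demux_config(m5 = 1L)
  idx <- build_indexes(sheet, cfg)
  d5 <- detect_5prime(make_read("r", "GGAAAGTTTTTTTT"), idx$five, sheet)
  expect_equal(d5$outcome$status, "ambiguous")
  out <- process_read(make_read("r", "GGAAAGTTTTTTTT"), sheet, idx, cfg)
  expect_equal(out$category, "no_match")
})

test_that("adapter trimming follows the suffix-overlap rules", {
  cfg <- demux_config()
  a <- "AGATCGGAAGAGC"
  full <- trim_adapter(paste0("ACGTACGT", a), const_qual(paste0("ACGTACGT", a)),
                       a, cfg)
  expect_equal(full$seq, "ACGTACGT")
  expect_equal(full$bases_removed, 13L)

  part <- trim_adapter("ACGTACGTAGA", const_qual("ACGTACGTAGA"), a, cfg)
  expect_equal(part$seq, "ACGTACGT")
  expect_equal(part$bases_removed, 3L)

  below <- trim_adapter("ACGTACGTAG", const_qual("ACGTACGTAG"), a, cfg)
  expect_equal(below$seq, "ACGTACGTAG")
  expect_equal(below$bases_removed, 0L)

  # one mismatch in a full occurrence is within the 10% error budget
  mism <- trim_adapter(paste0("ACGT", "AGATCGGAACAGC"),
                       const_qual(paste0("ACGT", "AGATCGGAACAGC")), a, cfg)
  expect_equal(mism$seq, "ACGT")
  expect_equal(mism$bases_removed, 13L)
  expect_equal(nchar(mism$qual), nchar(mism$seq))
})

test_that("quality trimming applies the running-sum rule", {
  # threshold 0 is the identity
  q0 <- quality_trim("ACGTAC", "IIII##", 0L)
  expect_equal(q0$seq, "ACGTAC")

  # phred 40,40,40,40,2,2 at threshold 20: last two bases fall
  q20 <- quality_trim("ACGTAC", "IIII##", 20L)
  expect_equal(q20$seq, "ACGT")
  expect_equal(q20$qual, "IIII")

  # everything below threshold: full trim
  all_low <- quality_trim("ACGT", "####", 20L)
  expect_equal(all_low$seq, "")

  # a high-quality base behind a dip is kept (sum is minimised, not first-dip)
  dip <- quality_trim("ACGTA", "II#II", 20L)
  expect_equal(dip$seq, "ACGTA")
})

test_that("3' assignment is gated on detected adapter bases", {
  sheet <- example_sheet()
  cfg <- strict_cfg()
  idx <- build_indexes(sheet, cfg)
  i3 <- idx$three[[3]]
  rem <- make_read("r", "ACGTACGTACGTGGAA")  # ends with instantiated NNAA

  gate0 <- detect_3prime_single_end(rem, i3, 0L, cfg)
  expect_equal(gate0$outcome$status, "none")
  expect_equal(gate0$final$seq, rem$seq)

  gate2 <- detect_3prime_single_end(rem, i3, 2L, cfg)
  expect_equal(gate2$outcome$status, "none")

  # the boundary is inclusive: exactly three adapter bases suffice
  gate3 <- detect_3prime_single_end(rem, i3, 3L, cfg)
  expect_equal(gate3$outcome$status, "unique")
  expect_equal(gate3$outcome$entry_id, 1L)
  expect_equal(gate3$umi3, "GG")
  expect_equal(gate3$final$seq, "ACGTACGTACGT")

  full <- detect_3prime_single_end(make_read("r", "ACGTACGTACGTGGGTT"), i3, 13L, cfg)
  expect_equal(full$outcome$entry_id, 2L)  # NNNTT
  expect_equal(full$umi3, "GGG")
  expect_equal(full$final$seq, "ACGTACGTACGT")

  tiny <- detect_3prime_single_end(make_read("r", "GA"), i3, 13L, cfg)
  expect_equal(tiny$outcome$status, "none")
})

test_that("paired 3' detection reads the mate prefix in reverse complement", {
  sheet <- example_sheet()
  idx <- build_indexes(sheet, strict_cfg())
  i3 <- idx$three[[3]]
  # forward-strand 3' pattern instantiation "CGAA" (NNAA with UMI CG);
  # the mate therefore begins with its reverse complement "TTCG"
  mate <- make_read("m", paste0("TTCG", "ACGTACGTAC"))
  d3 <- detect_3prime_paired(mate, i3, strict_cfg())
  expect_equal(d3$outcome$status, "unique")
  expect_equal(d3$outcome$entry_id, 1L)
  expect_equal(d3$umi3, "CG")  # forward-strand orientation
  expect_equal(d3$mate$seq, "ACGTACGTAC")

  # one core mismatch rescued when m3 = 1: forward core "AG" is at distance
  # 1 from "AA" but 2 from "TT", so the hit is unique
  loose <- demux_config(m3 = 1L)
  i3m <- build_indexes(sheet, loose)$three[[3]]
  mm <- detect_3prime_paired(make_read("m", paste0("CTCG", "ACGTACGTAC")),
                             i3m, loose)
  expect_equal(mm$outcome$status, "unique")
  expect_equal(mm$outcome$mismatches, 1L)

  empty <- detect_3prime_paired(make_read("m", ""), i3, strict_cfg())
  expect_equal(empty$outcome$status, "none")
})

test_that("a synthetic read round-trips through the full pipeline", {
  sheet <- example_sheet()
  cfg <- strict_cfg()
  idx <- build_indexes(sheet, cfg)
  insert <- "ACGTACGTACGTACGTAGCT"
  # [5'UMI+bc GCGG][insert][3'bc CGAA][adapter]
  seq <- paste0("TCA", "GCGG", "T", insert, "CG", "AA", "AGATCGGAAGAGC")
  out <- process_read(make_read("r", seq), sheet, idx, cfg)
  expect_equal(out$category, "assigned")
  expect_equal(out$sample_name, "sample_3")
  expect_equal(out$umi, paste0("TCA", "T", "CG"))
  expect_equal(out$output_record$seq, insert)
  expect_equal(out$output_record$id, "r_rbc:TCATCG")
  expect_equal(out$adapter_bases_removed, 13L)

  # no adapter read-through: the same read minus adapter+3'bc stays 5'-only
  seq2 <- paste0("TCA", "GCGG", "T", insert)
  out2 <- process_read(make_read("r2", seq2), sheet, idx, cfg)
  expect_equal(out2$category, "five_only_awaiting_3bc")
  expect_equal(out2$sample_name, "5bc_GCGG_no3bc")
  expect_equal(out2$umi, "TCAT")

  # unmatchable 5' prefix
  out3 <- process_read(make_read("r3", paste0("TCA", "TTTT", "T", insert)),
                       sheet, idx, cfg)
  expect_equal(out3$category, "no_match")

  # post-trim length below the minimum
  cfg_min <- strict_cfg()
  cfg_min$min_length <- 30L
  out4 <- process_read(make_read("r4", seq), sheet, idx, cfg_min)
  expect_equal(out4$category, "too_short")
  expect_true(is.na(out4$sample_name))

  expect_error(process_read(read_record("bad", "ACGT", "II"), sheet, idx, cfg),
               "malformed")
})

test_that("UMI in the header always equals the concatenated randomer slices", {
  set.seed(41)
  sheet <- parse_sample_sheet("NNAACCGN\nNNCCGGTN,NNTA,NGC")
  cfg <- strict_cfg()
  idx <- build_indexes(sheet, cfg)
  spec <- lane_spec(sheet, reads_per_sample = 60, seed = 42,
                    fraction_no_adapter = 0.3)
  lane <- generate_lane(spec)
  for (i in seq_len(nrow(lane$reads))) {
    out <- process_read(with(lane$reads[i, ], read_record(id, seq, qual)),
                        sheet, idx, cfg)
    tr <- lane$truth[i, ]
    expect_equal(out$category, tr$expect_category)
    header_umi <- sub("^.*_rbc:", "", out$output_record$id)
    expect_equal(header_umi, if (tr$expect_category == "assigned") tr$umi
                             else substr(tr$umi, 1L, nchar(header_umi)))
    # barcode cores never leak into the output sequence header UMI
    expect_false(grepl("AACCG|CCGGT", header_umi))
  }
})

test_that("paired processing assigns by forward 5' and mate 3' barcodes", {
  sheet <- parse_sample_sheet("NNAACCGN\nNNCCGGTN,NNTA,NGC")
  cfg <- strict_cfg()
  idx <- build_indexes(sheet, cfg)
  spec <- lane_spec(sheet, reads_per_sample = 50, seed = 5)
  lane <- generate_lane(spec, paired = TRUE)
  for (i in seq_len(nrow(lane$reads))) {
    out <- process_pair(with(lane$reads[i, ], read_record(id, seq, qual)),
                        with(lane$mates[i, ], read_record(id, seq, qual)),
                        sheet, idx, cfg)
    tr <- lane$truth[i, ]
    expect_equal(out$category, "assigned")
    expect_equal(out$sample_name, tr$expect_route)
    expect_equal(out$umi, tr$umi)
    expect_equal(sub("^.*_rbc:", "", out$mate_record$id), tr$umi)
  }
})

test_that("every read falls in exactly one category and counts conserve", {
  sheet <- example_sheet()
  cfg <- demux_config(min_length = 15L)
  idx <- build_indexes(sheet, cfg)
  spec <- lane_spec(sheet, reads_per_sample = 80, seed = 9,
                    fraction_no_adapter = 0.25,
                    error_rates = c(five_core = 0.1, three_core = 0.1,
                                    insert = 0.01))
  lane <- generate_lane(spec)
  cats <- vapply(seq_len(nrow(lane$reads)), function(i)
    process_read(with(lane$reads[i, ], read_record(id, seq, qual)),
                 sheet, idx, cfg)$category, "")
  expect_true(all(cats %in% c("assigned", "five_only_awaiting_3bc",
                              "no_match", "too_short")))
  expect_equal(length(cats), nrow(lane$reads))
})
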