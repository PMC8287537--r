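# Per-read processing: 5' barcode detection -> UMI extraction -> adapter
# trim -> quality trim -> optional 3' barcode detection -> minimum-length
# filter. Single reads and read pairs share the same 5' logic; in paired
# mode the 3' barcode is read from the start of the reverse mate instead of
# the end of the forward read, and no adapter-detection gate applies.

#' Construct a FASTQ read record
#'
#' @param id Header line without the leading `@`.
#' @param seq Base sequence.
#' @param qual Phred+33 quality string, same length as `seq`.
#' @return A `read_record` list.
#' @export
read_record <- function(id, seq, qual) {
  structure(list(id = id, seq = seq, qual = qual), class = "read_record")
}

#' @export
print.read_record <- function(x, ...) {
  cat(sprintf("<read_record> @%s\n  %s\n  %s\n", x$id, x$seq, x$qual))
  invisible(x)
}

#' Trimming and matching configuration
#'
#' Holds every tunable of the read pipeline. Defaults follow common Illumina
#' practice: the universal adapter, a Phred-20 quality cutoff, a 3-base
#' minimum adapter overlap both for trimming and for trusting a 3' barcode,
#' a 10% adapter error rate, and a 20-base minimum output length. `m5`/`m3`
#' are the mismatch budgets for 5' and 3' barcode assignment.
#'
#' @param adapter_fwd 3' sequencing adapter of the forward read.
#' @param adapter_rev Adapter trimmed from the reverse read (paired mode).
#' @param quality_threshold Minimum Phred score for 3' quality trimming;
#'   0 disables trimming.
#' @param min_overlap_trim Minimum adapter/read overlap for trimming.
#' @param min_overlap_for_3bc Minimum number of trimmed adapter bases
#'   required before a 3' barcode may be assigned on single-end data (the
#'   read-through gate); the comparison is inclusive.
#' @param max_adapter_error_rate Maximum mismatch fraction per adapter
#'   occurrence.
#' @param min_length Minimum post-trim read length written out.
#' @param m5,m3 Allowed barcode-base mismatches for 5' and 3' detection.
#' @return A `demux_config` list.
#' @export
demux_config <- function(adapter_fwd = "AGATCGGAAGAGC",
                         adapter_rev = "AGATCGGAAGAGC",
                         quality_threshold = 20L,
                         min_overlap_trim = 3L,
                         min_overlap_for_3bc = 3L,
                         max_adapter_error_rate = 0.1,
                         min_length = 20L,
                         m5 = 1L, m3 = 0L) {
  stopifnot(is.character(adapter_fwd), nzchar(adapter_fwd),
            is.character(adapter_rev), nzchar(adapter_rev),
            is_count(quality_threshold), is_count(min_overlap_trim),
            is_count(min_overlap_for_3bc), is_count(min_length),
            is_count(m5), is_count(m3),
            is.numeric(max_adapter_error_rate),
            max_adapter_error_rate >= 0, max_adapter_error_rate < 1)
  structure(list(adapter_fwd = toupper(adapter_fwd),
                 adapter_rev = toupper(adapter_rev),
                 quality_threshold = as.integer(quality_threshold),
                 min_overlap_trim = as.integer(min_overlap_trim),
                 min_overlap_for_3bc = as.integer(min_overlap_for_3bc),
                 max_adapter_error_rate = max_adapter_error_rate,
                 min_length = as.integer(min_length),
                 m5 = as.integer(m5), m3 = as.integer(m3)),
            class = "demux_config")
}

#' Build the lookup indexes for a sample sheet
#'
#' One prefix-anchored index over all 5' patterns, plus one end-anchored
#' index per entry that has linked 3' patterns.
#'
#' @param sheet A [parse_sample_sheet()] result.
#' @param cfg A [demux_config()] (supplies the `m5`/`m3` budgets).
#' @return List with elements `five` (a `match_index`) and `three` (list
#'   parallel to `sheet$entries`; `NULL` where an entry has no 3' barcodes).
#' @export
build_indexes <- function(sheet, cfg = demux_config()) {
  stopifnot(inherits(sheet, "sample_sheet"), inherits(cfg, "demux_config"))
  five <- build_index(lapply(sheet$entries, `[[`, "five"), cfg$m5, "prefix")
  three <- lapply(sheet$entries, function(e) {
    if (length(e$three)) build_index(e$three, cfg$m3, "suffix") else NULL
  })
  list(five = five, three = three)
}

.no_outcome <- structure(
  list(status = "none", entry_id = NA_integer_, mismatches = NA_integer_),
  class = "match_outcome")

#' Detect the 5' barcode of a read
#'
#' Slices the barcode bases from the read prefix at the sheet's shared 5'
#' offsets and looks them up in the precomputed index. On a unique match the
#' UMI bases of the matched pattern are extracted and the whole pattern
#' length is removed from the read.
#'
#' @param read A [read_record()].
#' @param index The 5' `match_index` from [build_indexes()].
#' @param sheet The [parse_sample_sheet()] result.
#' @return List with `outcome` (a `match_outcome`), `umi5` and `remainder`
#'   (the read after barcode removal; unchanged unless unique).
#' @export
detect_5prime <- function(read, index, sheet) {
  n <- nchar(read$seq)
  need <- max(index$offsets) + 1L
  if (n < need)
    return(list(outcome = .no_outcome, umi5 = "", remainder = read))
  key <- chars_at(read$seq, index$offsets + 1L)
  hit <- index_lookup(index, key)
  if (hit$status != "unique")
    return(list(outcome = structure(list(status = hit$status,
                                         entry_id = hit$entry,
                                         mismatches = hit$mismatches),
                                    class = "match_outcome"),
                umi5 = "", remainder = read))
  pat <- sheet$entries[[hit$entry]]$five
  plen <- nchar(pat$raw)
  if (n < plen)
    return(list(outcome = .no_outcome, umi5 = "", remainder = read))
  umi5 <- if (length(pat$umi_positions)) chars_at(read$seq, pat$umi_positions + 1L) else ""
  list(outcome = structure(list(status = "unique", entry_id = hit$entry,
                                mismatches = hit$mismatches),
                           class = "match_outcome"),
       umi5 = umi5,
       remainder = read_record(read$id,
                               substring(read$seq, plen + 1L),
                               substring(read$qual, plen + 1L)))
}

#' Trim the 3' sequencing adapter from a read
#'
#' Semi-global (suffix-overlap) search, substitutions only: the adapter may
#' occur fully inside the read or overhang its 3' end as a prefix. The
#' leftmost occurrence with overlap of at least `min_overlap_trim` bases and
#' mismatch fraction at most `max_adapter_error_rate` wins; everything from
#' its start to the read end is removed.
#'
#' @param seq,qual Sequence and quality strings.
#' @param adapter Adapter sequence.
#' @param cfg A [demux_config()].
#' @return List with `seq`, `qual` and `bases_removed` (0 when no
#'   occurrence was found).
#' @export
trim_adapter <- function(seq, qual, adapter, cfg = demux_config()) {
  stopifnot(nzchar(adapter))
  start <- .adapter_match_start(seq, adapter, cfg$max_adapter_error_rate,
                                cfg$min_overlap_trim)
  if (start < 0L)
    return(list(seq = seq, qual = qual, bases_removed = 0L))
  list(seq = substr(seq, 1L, start), qual = substr(qual, 1L, start),
       bases_removed = nchar(seq) - start)
}

#' Trim low-quality bases from the 3' end
#'
#' Running-sum rule: scanning from the 3' end, accumulate
#' `threshold - phred`; the read is cut where the accumulated sum is
#' maximal (equivalently, where the running quality sum is minimal). A
#' threshold of 0 leaves every read unchanged.
#'
#' @param seq,qual Sequence and Phred+33 quality strings.
#' @param threshold Minimum Phred score.
#' @return List with trimmed `seq` and `qual`.
#' @export
quality_trim <- function(seq, qual, threshold) {
  stopifnot(is_count(threshold))
  keep <- .quality_keep_length(qual, as.integer(threshold))
  list(seq = substr(seq, 1L, keep), qual = substr(qual, 1L, keep))
}

# shared tail-anchored 3' lookup on a forward-orientation string
match_3prime_tail <- function(seq, entry_index) {
  n <- nchar(seq)
  if (n < max(entry_index$offsets)) return(NULL)
  key <- chars_at(seq, n - entry_index$offsets + 1L)
  hit <- index_lookup(entry_index, key)
  if (hit$status != "unique") return(NULL)
  plen <- entry_index$pattern_lengths[hit$entry]
  if (n < plen) return(NULL)
  pat <- entry_index$patterns[[hit$entry]]
  umi3 <- if (length(pat$umi_positions))
    chars_at(seq, n - plen + pat$umi_positions + 1L) else ""
  list(hit = hit, plen = plen, umi3 = umi3)
}

#' Detect a 3' barcode at the end of a single-end read
#'
#' Only attempted when at least `min_overlap_for_3bc` adapter bases were
#' trimmed from the read: detecting the adapter certifies that the read end
#' is the true insert end and therefore carries the 3' barcode. Reads that
#' fail the gate keep their 5'-only identity.
#'
#' @param remainder Read after 5' barcode removal, adapter and quality
#'   trimming.
#' @param entry_index The owning entry's end-anchored `match_index`.
#' @param adapter_bases_removed From [trim_adapter()].
#' @param cfg A [demux_config()].
#' @return List with `outcome`, `umi3` and `final` (the read minus the
#'   matched 3' pattern; unchanged unless unique).
#' @export
detect_3prime_single_end <- function(remainder, entry_index,
                                     adapter_bases_removed, cfg = demux_config()) {
  if (adapter_bases_removed < cfg$min_overlap_for_3bc)
    return(list(outcome = .no_outcome, umi3 = "", final = remainder))
  m <- match_3prime_tail(remainder$seq, entry_index)
  if (is.null(m))
    return(list(outcome = .no_outcome, umi3 = "", final = remainder))
  n <- nchar(remainder$seq)
  list(outcome = structure(list(status = "unique", entry_id = m$hit$entry,
                                mismatches = m$hit$mismatches),
                           class = "match_outcome"),
       umi3 = m$umi3,
       final = read_record(remainder$id,
                           substr(remainder$seq, 1L, n - m$plen),
                           substr(remainder$qual, 1L, n - m$plen)))
}

#' Detect a 3' barcode at the start of a reverse mate
#'
#' In paired-end mode the 3' barcode sits at the 5' end of the reverse read,
#' in reverse-complement orientation. The mate prefix is reverse-complemented
#' back to forward-strand orientation, matched against the same end-anchored
#' index used for single-end data, and on success removed from the mate; the
#' reported UMI is in forward-strand orientation.
#'
#' @param mate Reverse-read [read_record()].
#' @param entry_index The owning entry's end-anchored `match_index`.
#' @param cfg A [demux_config()].
#' @return List with `outcome`, `umi3` and `mate` (prefix removed on
#'   success).
#' @export
detect_3prime_paired <- function(mate, entry_index, cfg = demux_config()) {
  lmax <- max(entry_index$pattern_lengths)
  if (nchar(mate$seq) < lmax)
    return(list(outcome = .no_outcome, umi3 = "", mate = mate))
  tail_fwd <- reverse_complement(substr(mate$seq, 1L, lmax))
  m <- match_3prime_tail(tail_fwd, entry_index)
  if (is.null(m))
    return(list(outcome = .no_outcome, umi3 = "", mate = mate))
  list(outcome = structure(list(status = "unique", entry_id = m$hit$entry,
                                mismatches = m$hit$mismatches),
                           class = "match_outcome"),
       umi3 = m$umi3,
       mate = read_record(mate$id,
                          substring(mate$seq, m$plen + 1L),
                          substring(mate$qual, m$plen + 1L)))
}

# append "_rbc:<umi>" to the identifier, before the first whitespace, so
# downstream UMI deduplicators that split on the last underscore find it
append_umi <- function(id, umi) {
  if (!nzchar(umi)) return(id)
  sp <- regexpr("[ \t]", id)
  if (sp < 0L) return(paste0(id, "_rbc:", umi))
  paste0(substr(id, 1L, sp - 1L), "_rbc:", umi, substring(id, sp))
}

finish_outcome <- function(category, sample, umi, id, final, removed, cfg,
                           mate = NULL) {
  if (category %in% c("assigned", "five_only_awaiting_3bc") &&
      nchar(final$seq) < cfg$min_length) {
    category <- "too_short"
    sample <- NA_character_
  }
  structure(list(category = category,
                 sample_name = sample,
                 umi = umi,
                 output_record = read_record(append_umi(id, umi),
                                             final$seq, final$qual),
                 adapter_bases_removed = removed,
                 mate_record = mate),
            class = "demux_outcome")
}

#' Process one single-end read through the full pipeline
#'
#' Composes [detect_5prime()], [trim_adapter()], [quality_trim()] and — for
#' entries with linked 3' barcodes — [detect_3prime_single_end()], then the
#' minimum-length filter. Every read lands in exactly one category:
#' `assigned` (demultiplexed to a sample), `five_only_awaiting_3bc` (5'
#' barcode found but the expected 3' barcode was not; routed to the entry's
#' recovery file), `no_match`, or `too_short`.
#'
#' @param read A [read_record()].
#' @param sheet A [parse_sample_sheet()] result.
#' @param indexes [build_indexes()] output for `sheet`.
#' @param cfg A [demux_config()].
#' @return A `demux_outcome`: `category`, `sample_name`, `umi` (5' UMI
#'   followed by the 3' UMI when one was assigned), `output_record` (trimmed,
#'   UMI in header) and `adapter_bases_removed`.
#' @export
process_read <- function(read, sheet, indexes, cfg = demux_config()) {
  if (nchar(read$seq) != nchar(read$qual))
    stop("malformed record: sequence and quality lengths differ")
  d5 <- detect_5prime(read, indexes$five, sheet)
  if (d5$outcome$status != "unique")
    return(structure(list(category = "no_match", sample_name = NA_character_,
                          umi = "", output_record = read,
                          adapter_bases_removed = 0L, mate_record = NULL),
                     class = "demux_outcome"))
  e <- d5$outcome$entry_id
  ta <- trim_adapter(d5$remainder$seq, d5$remainder$qual, cfg$adapter_fwd, cfg)
  qt <- quality_trim(ta$seq, ta$qual, cfg$quality_threshold)
  entry <- sheet$entries[[e]]
  if (length(entry$three)) {
    rem <- read_record(read$id, qt$seq, qt$qual)
    d3 <- detect_3prime_single_end(rem, indexes$three[[e]],
                                   ta$bases_removed, cfg)
    if (d3$outcome$status == "unique")
      finish_outcome("assigned", entry$names[d3$outcome$entry_id],
                     paste0(d5$umi5, d3$umi3), read$id, d3$final,
                     ta$bases_removed, cfg)
    else
      finish_outcome("five_only_awaiting_3bc", entry$no3bc_name, d5$umi5,
                     read$id, rem, ta$bases_removed, cfg)
  } else {
    finish_outcome("assigned", entry$names[1L], d5$umi5, read$id,
                   read_record(read$id, qt$seq, qt$qual), ta$bases_removed, cfg)
  }
}

#' Process one read pair through the full pipeline
#'
#' The forward read provides the 5' barcode, the reverse read the 3'
#' barcode; no adapter gate applies because the mate start is always the
#' fragment end. Both mates are adapter- and quality-trimmed; the
#' minimum-length filter is applied to the forward insert. The UMI is
#' written into both mates' headers.
#'
#' @inheritParams process_read
#' @param mate The reverse-read [read_record()].
#' @return A `demux_outcome` whose `mate_record` holds the processed mate.
#' @export
process_pair <- function(read, mate, sheet, indexes, cfg = demux_config()) {
  if (nchar(read$seq) != nchar(read$qual) || nchar(mate$seq) != nchar(mate$qual))
    stop("malformed record: sequence and quality lengths differ")
  d5 <- detect_5prime(read, indexes$five, sheet)
  if (d5$outcome$status != "unique")
    return(structure(list(category = "no_match", sample_name = NA_character_,
                          umi = "", output_record = read,
                          adapter_bases_removed = 0L, mate_record = mate),
                     class = "demux_outcome"))
  e <- d5$outcome$entry_id
  ta <- trim_adapter(d5$remainder$seq, d5$remainder$qual, cfg$adapter_fwd, cfg)
  qt <- quality_trim(ta$seq, ta$qual, cfg$quality_threshold)
  entry <- sheet$entries[[e]]

  category <- "assigned"
  sample <- entry$names[1L]
  umi <- d5$umi5
  mate_now <- mate
  if (length(entry$three)) {
    d3 <- detect_3prime_paired(mate, indexes$three[[e]], cfg)
    if (d3$outcome$status == "unique") {
      sample <- entry$names[d3$outcome$entry_id]
      umi <- paste0(d5$umi5, d3$umi3)
      mate_now <- d3$mate
    } else {
      category <- "five_only_awaiting_3bc"
      sample <- entry$no3bc_name
    }
  }
  mta <- trim_adapter(mate_now$seq, mate_now$qual, cfg$adapter_rev, cfg)
  mqt <- quality_trim(mta$seq, mta$qual, cfg$quality_threshold)
  out_mate <- read_record(append_umi(mate$id, umi), mqt$seq, mqt$qual)
  finish_outcome(category, sample, umi, read$id,
                 read_record(read$id, qt$seq, qt$qual),
                 ta$bases_removed, cfg, mate = out_mate)
}

#' @export
print.demux_outcome <- function(x, ...) {
  cat(sprintf("<demux_outcome> %s%s%s\n", x$category,
              if (!is.na(x$sample_name)) paste0(" -> ", x$sample_name) else "",
              if (nzchar(x$umi)) paste0(" (UMI ", x$umi, ")") else ""))
  invisible(x)
}
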