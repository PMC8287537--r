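# Synthetic lane generator with ground truth. Each simulated read has the
# anatomy of a typical iCLIP/ribo-seq library molecule:
#
#   [5' UMI+barcode] [cDNA insert] [3' barcode+UMI, combinatorial samples]
#   [sequencing adapter] [random tail]  -- truncated to the read length.
#
# A configurable fraction of reads per sample carries an insert too long to
# read through into the adapter; those reads end inside the insert, so no
# adapter (and on single-end data no 3' barcode) can be detected. Errors are
# independent base substitutions at per-region rates; there are no indels,
# matching the positional error model of the matcher, so ground truth stays
# exactly recoverable.

random_bases <- function(n) {
  if (n <= 0L) return("")
  paste(sample(.DNA_BASES, n, replace = TRUE), collapse = "")
}

# instantiate a pattern: random bases at N positions, substitution errors at
# rate `err` on the barcode bases; returns the sequence and the UMI drawn
instantiate_pattern <- function(pattern, err) {
  ch <- strsplit(pattern$raw, "", fixed = TRUE)[[1]]
  umi <- sample(.DNA_BASES, length(pattern$umi_positions), replace = TRUE)
  ch[pattern$umi_positions + 1L] <- umi
  if (err > 0 && length(pattern$barcode_positions)) {
    flip <- runif(length(pattern$barcode_positions)) < err
    for (i in which(flip)) {
      pos <- pattern$barcode_positions[i] + 1L
      ch[pos] <- sample(setdiff(.DNA_BASES, ch[pos]), 1L)
    }
  }
  list(seq = paste(ch, collapse = ""), umi = paste(umi, collapse = ""))
}

substitute_bases <- function(seq, err) {
  if (err <= 0 || !nzchar(seq)) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  flip <- runif(length(ch)) < err
  for (i in which(flip)) ch[i] <- sample(setdiff(.DNA_BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Specify a synthetic sequencing lane
#'
#' @param sheet A [parse_sample_sheet()] result (or sheet text); one batch
#'   of reads is generated per sample.
#' @param reads_per_sample Reads generated for each sample.
#' @param insert_length_range Inclusive range of cDNA insert lengths for
#'   read-through reads.
#' @param adapter 3' sequencing adapter appended after the insert.
#' @param error_rates Named numeric vector with per-base substitution rates
#'   for regions `five_core`, `three_core` and `insert`.
#' @param fraction_no_adapter Fraction of reads whose insert is too long to
#'   read through into the adapter.
#' @param read_length Sequencer read length; reads are truncated to it.
#' @param seed RNG seed; lanes are deterministic given the seed.
#' @return A `lane_spec` object for [generate_lane()].
#' @export
lane_spec <- function(sheet, reads_per_sample = 1000L,
                      insert_length_range = c(20L, 40L),
                      adapter = "AGATCGGAAGAGC",
                      error_rates = c(five_core = 0, three_core = 0, insert = 0),
                      fraction_no_adapter = 0,
                      read_length = 100L, seed = 1L) {
  if (is.character(sheet)) sheet <- parse_sample_sheet(sheet)
  stopifnot(inherits(sheet, "sample_sheet"),
            is_count(reads_per_sample, 1L),
            length(insert_length_range) == 2L,
            insert_length_range[1L] >= 1L,
            insert_length_range[1L] <= insert_length_range[2L],
            nzchar(adapter),
            all(c("five_core", "three_core", "insert") %in% names(error_rates)),
            all(error_rates >= 0 & error_rates <= 1),
            fraction_no_adapter >= 0, fraction_no_adapter <= 1,
            is_count(read_length, 1L), is_count(seed))
  max5 <- max(vapply(sheet$entries, function(e) nchar(e$five$raw), 0L))
  max3 <- max(c(0L, unlist(lapply(sheet$entries, function(e)
    vapply(e$three, function(p) nchar(p$raw), 0L)))))
  # read-through reads must retain >= 3 adapter bases after truncation
  if (max5 + insert_length_range[2L] + max3 + 3L > read_length)
    stop(sprintf(paste0("insert length range incompatible with read length: ",
                        "barcodes + %d-base insert + 3 adapter bases exceed %d cycles"),
                 insert_length_range[2L], read_length))
  structure(list(sheet = sheet,
                 reads_per_sample = as.integer(reads_per_sample),
                 insert_length_range = as.integer(insert_length_range),
                 adapter = toupper(adapter),
                 error_rates = error_rates,
                 fraction_no_adapter = fraction_no_adapter,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "lane_spec")
}

# TRUE when `seq` contains an acceptable adapter occurrence (>= 3-base
# suffix overlap, <= 10% mismatches) -- used to make "no read-through"
# reads genuinely adapter-free
has_adapter_hit <- function(seq, adapter) {
  .adapter_match_start(seq, adapter, 0.1, 3L) >= 0L
}

#' Generate a synthetic lane with ground truth
#'
#' Builds `reads_per_sample` reads for every sample of the sheet, shuffles
#' them, and returns both the FASTQ records and a per-read truth table. In
#' paired mode the mate is the reverse complement of the fragment read from
#' its 3' end, so it begins with the reverse complement of the 3' barcode.
#' Reads flagged as "no adapter read-through" are resampled until their
#' sequence contains no acceptable adapter occurrence at all, so that for
#' them ground truth and adapter detection cannot disagree.
#'
#' @param spec A [lane_spec()].
#' @param paired Also emit reverse mates.
#' @return List with `reads` (data.frame `id`, `seq`, `qual`), `mates`
#'   (paired mode only) and `truth` (data.frame `id`, `sample`,
#'   `expect_category`, `expect_route`, `umi`, `insert`).
#' @export
generate_lane <- function(spec, paired = FALSE) {
  stopifnot(inherits(spec, "lane_spec"))
  set.seed(spec$seed)
  sheet <- spec$sheet
  er <- spec$error_rates
  rl <- spec$read_length

  slots <- list()
  for (e in seq_along(sheet$entries)) {
    entry <- sheet$entries[[e]]
    if (length(entry$three))
      for (j in seq_along(entry$three))
        slots[[length(slots) + 1L]] <- list(entry = e, slot = j,
                                            name = entry$names[j])
    else
      slots[[length(slots) + 1L]] <- list(entry = e, slot = 0L,
                                          name = entry$names[1L])
  }
  n_total <- spec$reads_per_sample * length(slots)

  id <- character(n_total); seqs <- character(n_total)
  mseqs <- character(n_total)
  sample_nm <- character(n_total); category <- character(n_total)
  route <- character(n_total); umi <- character(n_total)
  insert_seq <- character(n_total)

  k <- 0L
  for (s in slots) {
    entry <- sheet$entries[[s$entry]]
    combinatorial <- s$slot > 0L
    for (r in seq_len(spec$reads_per_sample)) {
      k <- k + 1L
      p5 <- instantiate_pattern(entry$five, er[["five_core"]])
      no_adapter <- runif(1L) < spec$fraction_no_adapter
      if (no_adapter) {
        # insert fills the read: no adapter, no 3' barcode visible
        repeat {
          body <- substitute_bases(random_bases(rl), er[["insert"]])
          read <- substr(paste0(p5$seq, body), 1L, rl)
          if (!has_adapter_hit(substring(read, nchar(p5$seq) + 1L), spec$adapter))
            break
        }
        frag <- read
        ins <- substring(read, nchar(p5$seq) + 1L)
        if (combinatorial) {
          category[k] <- "five_only_awaiting_3bc"
          route[k] <- entry$no3bc_name
        } else {
          category[k] <- "assigned"
          route[k] <- s$name
        }
        umi[k] <- p5$umi
      } else {
        ilen <- sample(spec$insert_length_range[1L]:spec$insert_length_range[2L], 1L)
        p3 <- if (combinatorial)
          instantiate_pattern(entry$three[[s$slot]], er[["three_core"]])
        else list(seq = "", umi = "")
        # resample inserts that coincidentally contain an acceptable adapter
        # occurrence before the real one: such reads are indistinguishable
        # from shorter genuine read-throughs, so no truth label fits them
        repeat {
          ins <- substitute_bases(random_bases(ilen), er[["insert"]])
          frag <- paste0(p5$seq, ins, p3$seq)
          read <- paste0(frag, spec$adapter)
          if (nchar(read) < rl) read <- paste0(read, random_bases(rl - nchar(read)))
          read <- substr(read, 1L, rl)
          first_hit <- .adapter_match_start(substring(read, nchar(p5$seq) + 1L),
                                            spec$adapter, 0.1, 3L)
          if (first_hit == nchar(ins) + nchar(p3$seq)) break
        }
        category[k] <- "assigned"
        route[k] <- s$name
        umi[k] <- paste0(p5$umi, p3$umi)
      }
      id[k] <- sprintf("read_%06d", k)
      seqs[k] <- read
      sample_nm[k] <- s$name
      insert_seq[k] <- ins
      if (paired) {
        m <- reverse_complement(frag)
        m <- paste0(m, spec$adapter)
        if (nchar(m) < rl) m <- paste0(m, random_bases(rl - nchar(m)))
        mseqs[k] <- substr(m, 1L, rl)
      }
    }
  }

  ord <- sample.int(n_total)
  qual <- vapply(nchar(seqs[ord]), function(n) strrep("I", n), "")
  reads <- data.frame(id = id[ord], seq = seqs[ord], qual = qual,
                      stringsAsFactors = FALSE)
  truth <- data.frame(id = id[ord], sample = sample_nm[ord],
                      expect_category = category[ord],
                      expect_route = route[ord],
                      umi = umi[ord], insert = insert_seq[ord],
                      stringsAsFactors = FALSE)
  out <- list(reads = reads, truth = truth)
  if (paired)
    out$mates <- data.frame(id = id[ord], seq = mseqs[ord],
                            qual = vapply(nchar(mseqs[ord]),
                                          function(n) strrep("I", n), ""),
                            stringsAsFactors = FALSE)
  out
}

#' Write a generated lane to disk
#'
#' @param lane A [generate_lane()] result.
#' @param dir Target directory (created if missing).
#' @param name Basename for the lane files.
#' @return Named list of written paths (`fastq`, `truth`, and `fastq2` in
#'   paired mode).
#' @export
write_lane <- function(lane, dir, name = "lane") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fq <- file.path(dir, paste0(name, ".fastq.gz"))
  write_fastq(lane$reads, fq)
  paths <- list(fastq = fq)
  if (!is.null(lane$mates)) {
    fq2 <- file.path(dir, paste0(name, "_2.fastq.gz"))
    write_fastq(lane$mates, fq2)
    paths$fastq2 <- fq2
  }
  truth <- file.path(dir, paste0(name, "_truth.tsv"))
  write.table(lane$truth, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$truth <- truth
  paths
}
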