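# Streaming demultiplexing over gzip FASTQ: read fixed-size chunks, process
# them (optionally on parallel workers), and write results back strictly in
# input order so that output files are byte-identical for every thread
# count. All per-sample files, the no-match file and the per-entry
# "5' found, no 3' barcode" recovery files stay open for the whole run.

#' Read a FASTQ file into a data.frame
#'
#' Small-file convenience used by tests and the truth-checking helpers; the
#' demultiplexer itself streams in chunks and never loads a lane at once.
#'
#' @param path FASTQ file, plain or gzip-compressed.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L)
    stop(sprintf("'%s' is not valid 4-line FASTQ (%d lines)", path, length(lines)))
  n <- length(lines) %/% 4L
  if (!n) return(data.frame(id = character(0), seq = character(0),
                            qual = character(0), stringsAsFactors = FALSE))
  data.frame(id = sub("^@", "", lines[seq(1L, by = 4L, length.out = n)]),
             seq = lines[seq(2L, by = 4L, length.out = n)],
             qual = lines[seq(4L, by = 4L, length.out = n)],
             stringsAsFactors = FALSE)
}

#' Write FASTQ records
#'
#' @param records data.frame with columns `id`, `seq`, `qual`.
#' @param path Output path; `.gz` suffix selects gzip compression.
#' @param compression gzip level used for `.gz` paths.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path, compression = 5L) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb", compression = compression)
         else file(path, "wb")
  on.exit(close(con))
  if (nrow(records))
    writeLines(as.vector(rbind(paste0("@", records$id), records$seq,
                               "+", records$qual)), con)
  invisible(path)
}

#' Path of a demultiplexed output file
#'
#' `<output_dir>/<prefix>_<sample_name>.fastq.gz`, with a `_Fwd`/`_Rev`
#' suffix before the extension in paired mode.
#'
#' @param sample_name Sample (or routing-category) name.
#' @param prefix Output filename prefix.
#' @param output_dir Output directory.
#' @param mate `NULL` (single-end), `"Fwd"` or `"Rev"`.
#' @return The file path.
#' @examples
#' output_path("sample_2", "run1", "out")
#' @export
output_path <- function(sample_name, prefix, output_dir, mate = NULL) {
  stopifnot(is.character(sample_name), nzchar(sample_name))
  suffix <- if (is.null(mate)) "" else paste0("_", match.arg(mate, c("Fwd", "Rev")))
  file.path(output_dir, paste0(prefix, "_", sample_name, suffix, ".fastq.gz"))
}

# process a parsed chunk, splitting across workers; returns flat vectors
process_chunk <- function(ids, seqs, quals, mate_ids, mate_seqs, mate_quals,
                          sheet, indexes, cfg, threads) {
  n <- length(ids)
  paired <- !is.null(mate_seqs)
  worker <- function(ii) {
    category <- character(length(ii)); sample <- character(length(ii))
    oid <- character(length(ii)); oseq <- character(length(ii))
    oqual <- character(length(ii))
    mid <- character(length(ii)); mseq <- character(length(ii))
    mqual <- character(length(ii))
    for (j in seq_along(ii)) {
      i <- ii[j]
      o <- if (paired)
        process_pair(read_record(ids[i], seqs[i], quals[i]),
                     read_record(mate_ids[i], mate_seqs[i], mate_quals[i]),
                     sheet, indexes, cfg)
      else
        process_read(read_record(ids[i], seqs[i], quals[i]), sheet, indexes, cfg)
      category[j] <- o$category
      sample[j] <- if (is.na(o$sample_name)) "" else o$sample_name
      oid[j] <- o$output_record$id
      oseq[j] <- o$output_record$seq
      oqual[j] <- o$output_record$qual
      if (paired) {
        mid[j] <- o$mate_record$id
        mseq[j] <- o$mate_record$seq
        mqual[j] <- o$mate_record$qual
      }
    }
    list(category = category, sample = sample, id = oid, seq = oseq,
         qual = oqual, mid = mid, mseq = mseq, mqual = mqual)
  }
  groups <- if (threads > 1L && n > 1L)
    split(seq_len(n), cut(seq_len(n), min(threads, n), labels = FALSE))
  else list(seq_len(n))
  parts <- if (length(groups) > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(groups, worker, mc.cores = threads, mc.preschedule = TRUE)
  else lapply(groups, worker)
  lapply(stats::setNames(nm = names(parts[[1L]])), function(f)
    unlist(lapply(parts, `[[`, f), use.names = FALSE))
}

open_sink <- function(path, ultra, compression) {
  if (ultra) file(paste0(path, ".tmp"), "wb")
  else gzfile(path, "wb", compression = compression)
}

write_records <- function(con, ids, seqs, quals) {
  if (length(ids))
    writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), con)
}

# recompress an ultra-mode plain temporary into its final .gz
compress_temp <- function(path, compression, block = 160000L) {
  tmp <- paste0(path, ".tmp")
  rcon <- file(tmp, "rt")
  wcon <- gzfile(path, "wb", compression = compression)
  repeat {
    lines <- readLines(rcon, n = block)
    if (!length(lines)) break
    writeLines(lines, wcon)
  }
  close(rcon); close(wcon)
  unlink(tmp)
}

#' Demultiplex one or two FASTQ files
#'
#' Streams the lane in chunks, runs every read (or pair) through
#' [process_read()]/[process_pair()], and routes it to its per-sample gzip
#' FASTQ file. Reads whose 5' entry expects a 3' barcode that was not found
#' go to that entry's `_no3bc` recovery file; unassignable reads go to the
#' no-match file (unless suppressed); too-short reads are counted but not
#' written. Chunks are written back in input order, so output bytes are
#' identical for every `threads` value.
#'
#' @param input Forward FASTQ path (plain or gzip).
#' @param sheet A [parse_sample_sheet()] result, or sheet text/path.
#' @param output_dir Output directory (created if missing).
#' @param cfg A [demux_config()].
#' @param threads Worker count for per-chunk processing.
#' @param input2 Reverse FASTQ path; supplying it enables paired mode.
#' @param prefix Output filename prefix.
#' @param ignore_no_match Suppress the no-match output file (reads are still
#'   counted).
#' @param ultra Write uncompressed temporaries and compress after the run;
#'   final bytes are identical to the streaming default.
#' @param chunk_size Records per work unit.
#' @param compression gzip level for output files.
#' @return A `demux_run` object: `total_reads`, `per_sample_counts`,
#'   `no_match`, `too_short`, `awaiting_3bc` (per entry), `malformed`, plus
#'   the output paths. A tab-separated summary is written to
#'   `<prefix>_stats.tsv`.
#' @export
run_demux <- function(input, sheet, output_dir = ".", cfg = demux_config(),
                      threads = 1L, input2 = NULL, prefix = "demux",
                      ignore_no_match = FALSE, ultra = FALSE,
                      chunk_size = 40000L, compression = 5L) {
  if (is.character(sheet)) sheet <- parse_sample_sheet(sheet)
  stopifnot(inherits(sheet, "sample_sheet"), inherits(cfg, "demux_config"),
            is_count(threads, 1L), is_count(chunk_size, 1L))
  if (!file.exists(input)) stop(sprintf("input file '%s' does not exist", input))
  paired <- !is.null(input2)
  if (paired && !file.exists(input2))
    stop(sprintf("input file '%s' does not exist", input2))
  if (!dir.exists(output_dir) &&
      !dir.create(output_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", output_dir))
  if (file.access(output_dir, 2L) != 0L)
    stop(sprintf("output directory '%s' is not writable", output_dir))

  indexes <- build_indexes(sheet, cfg)

  route_names <- c(sheet$samples,
                   stats::na.omit(vapply(sheet$entries, `[[`, "", "no3bc_name")))
  if (!ignore_no_match) route_names <- c(route_names, "no_match")
  mates <- if (paired) c("Fwd", "Rev") else list(NULL)
  sinks <- list(); paths <- character(0)
  for (nm in route_names)
    for (mt in mates) {
      p <- output_path(nm, prefix, output_dir, mt)
      key <- paste0(nm, if (is.null(mt)) "" else paste0("/", mt))
      sinks[[key]] <- open_sink(p, ultra, compression)
      paths[key] <- p
    }
  on.exit(for (con in sinks) try(close(con), silent = TRUE), add = TRUE)

  counts <- stats::setNames(integer(length(sheet$samples)), sheet$samples)
  awaiting <- stats::setNames(
    integer(sum(!is.na(vapply(sheet$entries, `[[`, "", "no3bc_name")))),
    stats::na.omit(vapply(sheet$entries, `[[`, "", "no3bc_name")))
  total <- 0L; no_match <- 0L; too_short <- 0L; malformed <- 0L

  con_in <- gzfile(input, "rt")
  on.exit(close(con_in), add = TRUE)
  con_in2 <- NULL
  if (paired) {
    con_in2 <- gzfile(input2, "rt")
    on.exit(close(con_in2), add = TRUE)
  }

  repeat {
    lines <- readLines(con_in, n = 4L * chunk_size)
    lines2 <- if (paired) readLines(con_in2, n = 4L * chunk_size) else NULL
    if (!length(lines) && (!paired || !length(lines2))) break
    nrec <- length(lines) %/% 4L
    if (length(lines) %% 4L) {
      warning("truncated final FASTQ record skipped")
      malformed <- malformed + 1L
    }
    if (paired) {
      nrec2 <- length(lines2) %/% 4L
      if (length(lines2) %% 4L) {
        warning("truncated final FASTQ record skipped (reverse file)")
        malformed <- malformed + 1L
      }
      if (nrec2 != nrec) {
        warning("forward and reverse files differ in length; extra reads skipped")
        malformed <- malformed + abs(nrec2 - nrec)
        nrec <- min(nrec, nrec2)
      }
    }
    if (!nrec) break
    take <- function(l, off) l[seq(off, by = 4L, length.out = nrec)]
    ids <- sub("^@", "", take(lines, 1L))
    seqs <- toupper(take(lines, 2L)); quals <- take(lines, 4L)
    mate_ids <- mate_seqs <- mate_quals <- NULL
    if (paired) {
      mate_ids <- sub("^@", "", take(lines2, 1L))
      mate_seqs <- toupper(take(lines2, 2L)); mate_quals <- take(lines2, 4L)
    }
    bad <- nchar(seqs) != nchar(quals)
    if (paired) bad <- bad | (nchar(mate_seqs) != nchar(mate_quals))
    if (any(bad)) {
      warning(sprintf("%d malformed record(s) skipped", sum(bad)))
      malformed <- malformed + sum(bad)
      keep <- !bad
      ids <- ids[keep]; seqs <- seqs[keep]; quals <- quals[keep]
      if (paired) {
        mate_ids <- mate_ids[keep]; mate_seqs <- mate_seqs[keep]
        mate_quals <- mate_quals[keep]
      }
    }
    total <- total + length(ids)
    if (!length(ids)) next
    res <- process_chunk(ids, seqs, quals, mate_ids, mate_seqs, mate_quals,
                         sheet, indexes, cfg, threads)

    assigned <- res$category == "assigned"
    if (any(assigned)) {
      tab <- table(res$sample[assigned])
      counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    }
    wait <- res$category == "five_only_awaiting_3bc"
    if (any(wait)) {
      tab <- table(res$sample[wait])
      awaiting[names(tab)] <- awaiting[names(tab)] + as.integer(tab)
    }
    no_match <- no_match + sum(res$category == "no_match")
    too_short <- too_short + sum(res$category == "too_short")

    for (nm in route_names) {
      sel <- if (nm == "no_match") res$category == "no_match" else res$sample == nm
      sel <- sel & res$category != "too_short"
      if (!any(sel)) next
      if (paired) {
        write_records(sinks[[paste0(nm, "/Fwd")]], res$id[sel], res$seq[sel],
                      res$qual[sel])
        write_records(sinks[[paste0(nm, "/Rev")]], res$mid[sel], res$mseq[sel],
                      res$mqual[sel])
      } else {
        write_records(sinks[[nm]], res$id[sel], res$seq[sel], res$qual[sel])
      }
    }
  }

  for (key in names(sinks)) close(sinks[[key]])
  sinks <- list()
  if (ultra) for (p in paths) compress_temp(p, compression)

  stats <- structure(
    list(total_reads = total,
         per_sample_counts = counts,
         no_match = no_match,
         too_short = too_short,
         awaiting_3bc = awaiting,
         malformed = malformed,
         paired = paired,
         output_paths = paths,
         stats_path = file.path(output_dir, paste0(prefix, "_stats.tsv"))),
    class = "demux_run")
  stats_df <- data.frame(
    category = c(rep("assigned", length(counts)),
                 rep("awaiting_3bc", length(awaiting)),
                 "no_match", "too_short", "malformed", "total"),
    name = c(names(counts), names(awaiting), "", "", "", ""),
    reads = c(counts, awaiting, no_match, too_short, malformed, total),
    stringsAsFactors = FALSE)
  write.table(stats_df, stats$stats_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  message(sprintf("demultiplexed %d read%s: %d assigned, %d awaiting 3' barcode, %d no match, %d too short",
                  total, if (total == 1L) "" else "s", sum(counts),
                  sum(awaiting), no_match, too_short))
  stats
}

#' @export
print.demux_run <- function(x, ...) {
  cat(sprintf("<demux_run> %d reads%s\n", x$total_reads,
              if (x$paired) " (paired)" else ""))
  for (nm in names(x$per_sample_counts))
    cat(sprintf("  %-30s %d\n", nm, x$per_sample_counts[[nm]]))
  for (nm in names(x$awaiting_3bc))
    cat(sprintf("  %-30s %d (no 3' barcode)\n", nm, x$awaiting_3bc[[nm]]))
  cat(sprintf("  %-30s %d\n  %-30s %d\n", "no_match", x$no_match,
              "too_short", x$too_short))
  if (x$malformed) cat(sprintf("  %-30s %d\n", "malformed (skipped)", x$malformed))
  invisible(x)
}
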