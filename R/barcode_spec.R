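# Barcode pattern and sample-sheet parsing/validation.
#
# A pattern is a string over {A,C,G,T,N}: defined bases are the barcode
# proper ("b" bases), N positions are randomers used as UMIs. 5' patterns
# are anchored at the read start; 3' patterns at the read end (the last
# pattern character aligns with the last retained base of the read).

#' Parse a single barcode pattern
#'
#' A barcode pattern mixes defined bases (the barcode itself, used for sample
#' assignment) with `N` positions (randomers, extracted as UMI bases). For
#' example `"NNNATGCNN"` is the 4-base barcode `ATGC` flanked by a 3-base and
#' a 2-base UMI stretch.
#'
#' @param text Pattern string over `A,C,G,T,N` (case-insensitive).
#' @param side `"five_prime"` (anchored at the read start) or
#'   `"three_prime"` (anchored at the read end).
#' @return An object of class `barcode_pattern` with elements `raw`, `side`,
#'   `barcode_positions` and `umi_positions` (0-based offsets into `raw`,
#'   which they partition), and `core` (the defined bases, in order).
#' @examples
#' parse_pattern("NNNATGCNN", "five_prime")
#' @export
parse_pattern <- function(text, side = c("five_prime", "three_prime")) {
  side <- match.arg(side)
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("barcode pattern must be a single nonempty string")
  raw <- toupper(trimws(text))
  ch <- strsplit(raw, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% .DNA_ALPHABET)
  if (length(bad))
    stop(sprintf("invalid character '%s' at position %d of barcode pattern '%s'",
                 ch[bad[1L]], bad[1L], raw))
  is_core <- ch != "N"
  if (!any(is_core))
    stop(sprintf("pattern '%s' has no barcode bases (all N)", raw))
  structure(
    list(raw = raw,
         side = side,
         barcode_positions = which(is_core) - 1L,
         umi_positions = which(!is_core) - 1L,
         core = paste(ch[is_core], collapse = "")),
    class = "barcode_pattern")
}

#' Render a barcode pattern back to its string form
#'
#' Inverse of [parse_pattern()]: `parse_pattern(render_pattern(p), p$side)`
#' reproduces `p`.
#'
#' @param pattern A `barcode_pattern`.
#' @return The pattern string.
#' @export
render_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "barcode_pattern"))
  pattern$raw
}

#' @export
print.barcode_pattern <- function(x, ...) {
  cat(sprintf("<barcode_pattern %s> %s: core %s (%d b bases), %d UMI bases\n",
              x$side, x$raw, x$core, length(x$barcode_positions),
              length(x$umi_positions)))
  invisible(x)
}

# barcode-base offsets of a 3' pattern measured from the read end:
# distance 1 = last retained base. Returned in raw order (descending).
end_distances <- function(pattern) {
  nchar(pattern$raw) - pattern$barcode_positions
}

auto_name_5 <- function(core5) paste0("5bc_", core5)
auto_name_53 <- function(core5, core3) paste0("5bc_", core5, "_3bc_", core3)

# one CSV field: "PATTERN" or "PATTERN:name"
split_field <- function(field) {
  field <- trimws(field)
  colon <- regexpr(":", field, fixed = TRUE)
  if (colon < 0L) return(list(pattern = field, name = NA_character_))
  nm <- trimws(substring(field, colon + 1L))
  if (!nzchar(nm)) stop(sprintf("empty sample name in field '%s'", field))
  list(pattern = trimws(substring(field, 1L, colon - 1L)), name = nm)
}

#' Parse a barcode sample sheet
#'
#' The sheet is a small CSV: one line per 5' barcode, whose first field is
#' the 5' pattern and whose further comma-separated fields are 3' patterns
#' linked to that 5' barcode (combinatorial demultiplexing). Any field may
#' carry a sample name after a colon, except a 5' pattern that has linked 3'
#' patterns (its reads are identified only by the combination, so a name
#' there would be ambiguous). Unnamed samples get deterministic names:
#' `5bc_<core>` for 5'-only entries, `5bc_<core5>_3bc_<core3>` for
#' combinatorial ones.
#'
#' Compatibility rules enforced: every 5' pattern must place its barcode
#' bases at the same offsets from the read start; within one entry every 3'
#' pattern must place its barcode bases at the same distances from the read
#' end (3' patterns of *different* entries are free to differ); all 5' cores
#' are distinct, as are the 3' cores within an entry. UMI stretches may
#' differ in length between patterns.
#'
#' @param text Sheet content as a single string (or vector of lines), or the
#'   path of a file holding it.
#' @return An object of class `sample_sheet`: `entries` (each with `five`,
#'   `three`, `names`, `no3bc_name`), `samples` (all sample names, in sheet
#'   order), `five_offsets` (shared 0-based barcode offsets) and
#'   `five_core_length`.
#' @examples
#' sheet <- parse_sample_sheet("NNNATGCNN\nNNNATTANNN:sample_2\nNNNGCGGN,NNAA:sample_3,NNNTT")
#' sheet$samples
#' @export
parse_sample_sheet <- function(text) {
  if (!is.character(text) || !length(text) || all(is.na(text)))
    stop("sample sheet must be a nonempty string or file path")
  if (length(text) == 1L && !grepl("[,\n]", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  lines <- strsplit(gsub("\r\n?", "\n", paste(text, collapse = "\n")), "\n",
                    fixed = TRUE)[[1]]
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stop("sample sheet contains no barcode lines")

  entries <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    fields <- strsplit(lines[ln], ",", fixed = TRUE)[[1]]
    parsed <- lapply(fields, split_field)
    five <- parse_pattern(parsed[[1L]]$pattern, "five_prime")
    three <- lapply(parsed[-1L], function(f) parse_pattern(f$pattern, "three_prime"))
    if (length(three)) {
      if (!is.na(parsed[[1L]]$name))
        stop(sprintf(paste0("line %d: 5' barcode '%s' has linked 3' barcodes and ",
                            "cannot itself carry a sample name"), ln, five$raw))
      dists <- lapply(three, end_distances)
      for (j in seq_along(three)[-1L])
        if (!identical(dists[[j]], dists[[1L]]))
          stop(sprintf(paste0("line %d: incompatible 3' barcodes '%s' and '%s' ",
                              "(barcode bases at different distances from the read end)"),
                       ln, three[[1L]]$raw, three[[j]]$raw))
      cores3 <- vapply(three, `[[`, "", "core")
      if (anyDuplicated(cores3))
        stop(sprintf("line %d: duplicate 3' barcode core '%s'",
                     ln, cores3[duplicated(cores3)][1L]))
      nms <- vapply(seq_along(three), function(j) {
        if (is.na(parsed[[j + 1L]]$name)) auto_name_53(five$core, cores3[j])
        else parsed[[j + 1L]]$name
      }, "")
      no3bc <- paste0(auto_name_5(five$core), "_no3bc")
    } else {
      nms <- if (is.na(parsed[[1L]]$name)) auto_name_5(five$core) else parsed[[1L]]$name
      no3bc <- NA_character_
    }
    entries[[k]] <- list(five = five, three = three, names = nms,
                         no3bc_name = no3bc, line = ln)
  }

  offs <- lapply(entries, function(e) e$five$barcode_positions)
  for (k in seq_along(entries)[-1L])
    if (!identical(offs[[k]], offs[[1L]]))
      stop(sprintf(paste0("incompatible 5' barcodes: '%s' (line %d) and '%s' (line %d) ",
                          "place barcode bases at different offsets"),
                   entries[[1L]]$five$raw, entries[[1L]]$line,
                   entries[[k]]$five$raw, entries[[k]]$line))
  cores5 <- vapply(entries, function(e) e$five$core, "")
  if (anyDuplicated(cores5))
    stop(sprintf("duplicate 5' barcode core '%s'", cores5[duplicated(cores5)][1L]))

  samples <- unlist(lapply(entries, `[[`, "names"), use.names = FALSE)
  routing <- c(samples, stats::na.omit(vapply(entries, `[[`, "", "no3bc_name")))
  if (anyDuplicated(routing))
    stop(sprintf("duplicate sample name '%s': output files would collide",
                 routing[duplicated(routing)][1L]))

  structure(
    list(entries = entries,
         samples = samples,
         five_offsets = offs[[1L]],
         five_core_length = length(offs[[1L]])),
    class = "sample_sheet")
}

#' @export
print.sample_sheet <- function(x, ...) {
  n3 <- sum(vapply(x$entries, function(e) length(e$three), 0L))
  cat(sprintf("<sample_sheet> %d 5' barcode(s), %d sample(s) (%d combinatorial)\n",
              length(x$entries), length(x$samples), n3))
  for (e in x$entries) {
    if (length(e$three))
      cat(sprintf("  %s + {%s} -> %s\n", e$five$raw,
                  paste(vapply(e$three, `[[`, "", "raw"), collapse = ", "),
                  paste(e$names, collapse = ", ")))
    else
      cat(sprintf("  %s -> %s\n", e$five$raw, e$names))
  }
  invisible(x)
}
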