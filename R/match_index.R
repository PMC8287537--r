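# Precomputed mismatch-tolerant barcode lookup.
#
# Rather than comparing every read against every barcode, all candidate
# barcode-length sequences over {A,C,G,T,N} are enumerated up front and each
# is assigned its best-matching barcode (or "ambiguous"/"none"). Per-read
# assignment is then a single table lookup: the candidate slice is ranked in
# base 5 and indexed into flat status/entry/mismatch vectors, giving O(1)
# work per read. The comparison metric is the Hamming distance evaluated at
# barcode ("b") positions only; UMI positions never count. An N in the read
# at a barcode position mismatches every defined base, but N-containing
# candidates are enumerated so such reads can still be rescued within the
# mismatch budget.

.CANDIDATE_CAP <- 8L  # 5^8 = 390,625 table rows; longer cores use the memo map

#' Enumerate all candidate barcode sequences of a given length
#'
#' Generates every string of the given length over the five-letter alphabet
#' `{A,C,G,T,N}` — the candidate space a lookup table covers. There are
#' `5^length` of them (3,125 for the typical 5-base barcode).
#'
#' @param length Candidate length (barcode bases, UMIs excluded), between 1
#'   and 8.
#' @return Character vector of all `5^length` candidates, each exactly once,
#'   in base-5 rank order (`A` low, `N` high).
#' @examples
#' enumerate_candidates(1)
#' length(enumerate_candidates(5))  # 3125
#' @export
enumerate_candidates <- function(length) {
  if (!is_count(length, min = 1L))
    stop("length must be a positive integer")
  L <- as.integer(length)
  if (L > .CANDIDATE_CAP)
    stop(sprintf("candidate space 5^%d is too large to enumerate (cap %d)",
                 L, .CANDIDATE_CAP))
  grid <- expand.grid(rep(list(.DNA_ALPHABET), L), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  # reverse columns so the last position varies fastest: row i is the
  # candidate with base-5 rank i
  do.call(paste0, grid[, L:1, drop = FALSE])
}

#' Count barcode-position mismatches between a candidate and a pattern
#'
#' Positional (Hamming-style) comparison restricted to the pattern's barcode
#' positions; UMI (`N`) positions of the pattern are ignored. Any candidate
#' character other than the pattern's defined base — including `N` — counts
#' as one mismatch.
#'
#' @param candidate String of the same length as the pattern.
#' @param pattern A [parse_pattern()] result.
#' @return Integer mismatch count.
#' @export
count_mismatches <- function(candidate, pattern) {
  stopifnot(inherits(pattern, "barcode_pattern"))
  if (!is.character(candidate) || length(candidate) != 1L ||
      nchar(candidate) != nchar(pattern$raw))
    stop("candidate must be a single string of the same length as the pattern")
  got <- charToRaw(toupper(candidate))[pattern$barcode_positions + 1L]
  want <- charToRaw(pattern$core)
  sum(got != want)
}

# best match over core strings (candidate already sliced to barcode bases)
core_best_match <- function(core_candidate, cores, max_mismatches) {
  want <- lapply(cores, charToRaw)
  got <- charToRaw(core_candidate)
  d <- vapply(want, function(w) sum(w != got), 0L)
  m <- min(d)
  hits <- which(d == m)
  if (m > max_mismatches)
    list(status = "none", entry_id = NA_integer_, mismatches = NA_integer_)
  else if (length(hits) > 1L)
    list(status = "ambiguous", entry_id = NA_integer_, mismatches = m)
  else
    list(status = "unique", entry_id = hits, mismatches = m)
}

#' Find the best-matching barcode for one candidate sequence
#'
#' Compares the candidate against every pattern at the (shared) barcode
#' positions. The outcome is `unique` when exactly one pattern attains the
#' minimal mismatch count and that count is within budget, `ambiguous` when
#' two or more patterns tie at a minimal count within budget (such reads are
#' discarded downstream), and `none` otherwise.
#'
#' @param candidate String of the patterns' length.
#' @param patterns List of [parse_pattern()] results sharing barcode offsets.
#' @param max_mismatches Mismatch budget (>= 0).
#' @return A `match_outcome`: list with `status`, `entry_id` (index into
#'   `patterns`, only when unique) and `mismatches`.
#' @export
best_match <- function(candidate, patterns, max_mismatches) {
  if (!length(patterns)) stop("empty pattern list")
  stopifnot(is_count(max_mismatches))
  d <- vapply(patterns, function(p) count_mismatches(candidate, p), 0L)
  m <- min(d)
  hits <- which(d == m)
  out <- if (m > max_mismatches)
    list(status = "none", entry_id = NA_integer_, mismatches = NA_integer_)
  else if (length(hits) > 1L)
    list(status = "ambiguous", entry_id = NA_integer_, mismatches = m)
  else
    list(status = "unique", entry_id = hits, mismatches = m)
  structure(out, class = "match_outcome")
}

#' Build a precomputed best-match index over a barcode family
#'
#' Enumerates every core-length candidate over `{A,C,G,T,N}` and stores its
#' [best_match()] outcome, so that reads are assigned by a single indexed
#' lookup. One index serves the 5' barcode set; each entry with linked 3'
#' barcodes gets its own end-anchored index. Core lengths beyond 8 switch to
#' a memoized on-demand map with identical semantics.
#'
#' @param patterns List of mutually compatible `barcode_pattern`s (identical
#'   barcode offsets — from the start for 5' patterns, from the end for 3'
#'   patterns).
#' @param max_mismatches Mismatch budget applied at lookup time.
#' @param anchor `"prefix"` (5'-anchored) or `"suffix"` (3'-end-anchored);
#'   defaults to the patterns' side.
#' @return A `match_index` object; query it with [index_lookup()].
#' @export
build_index <- function(patterns, max_mismatches,
                        anchor = c("auto", "prefix", "suffix")) {
  if (!length(patterns)) stop("empty pattern list")
  stopifnot(all(vapply(patterns, inherits, TRUE, "barcode_pattern")),
            is_count(max_mismatches))
  anchor <- match.arg(anchor)
  if (anchor == "auto")
    anchor <- if (patterns[[1L]]$side == "three_prime") "suffix" else "prefix"

  offs <- if (anchor == "prefix") lapply(patterns, `[[`, "barcode_positions")
          else lapply(patterns, end_distances)
  for (j in seq_along(patterns)[-1L])
    if (!identical(offs[[j]], offs[[1L]]))
      stop("patterns do not share barcode offsets; they cannot share an index")
  cores <- vapply(patterns, `[[`, "", "core")
  if (anyDuplicated(cores)) stop("duplicate barcode cores in one index")
  k <- nchar(cores[1L])

  idx <- structure(
    list(core_length = k,
         anchor = anchor,
         offsets = offs[[1L]],       # prefix: 0-based positions; suffix: distances from end
         cores = cores,
         pattern_lengths = vapply(patterns, function(p) nchar(p$raw), 0L),
         patterns = patterns,
         max_mismatches = as.integer(max_mismatches),
         table = NULL, memo = NULL),
    class = "match_index")

  if (k <= .CANDIDATE_CAP) {
    n <- 5L^k
    P <- length(cores)
    core_digits <- lapply(cores, function(co) .DIGIT[as.integer(charToRaw(co)) + 1L])
    pow <- 5^((k - 1L):0)
    M <- matrix(0L, n, P)
    cand <- seq_len(n) - 1L
    for (j in seq_len(k)) {
      dj <- (cand %/% pow[j]) %% 5L
      for (p in seq_len(P)) M[, p] <- M[, p] + (dj != core_digits[[p]][j])
    }
    minm <- M[, 1L]
    for (p in seq_len(P)[-1L]) minm <- pmin(minm, M[, p])
    nmin <- rowSums(M == minm)
    status <- ifelse(minm > max_mismatches, 0L, ifelse(nmin > 1L, 2L, 1L))
    entry <- max.col(-M, ties.method = "first")
    entry[status != 1L] <- NA_integer_
    mism <- ifelse(status == 0L, NA_integer_, minm)
    idx$table <- list(status = as.integer(status), entry = as.integer(entry),
                      mism = as.integer(mism))
  } else {
    idx$memo <- new.env(parent = emptyenv())
  }
  idx
}

.STATUS_LEVELS <- c("none", "unique", "ambiguous")

#' Look up candidate core sequences in a match index
#'
#' @param index A [build_index()] result.
#' @param keys Character vector of core-length candidate strings (the bases
#'   at the index's barcode offsets, in pattern order).
#' @return A data.frame with one row per key: `status`
#'   (`unique`/`ambiguous`/`none`), `entry` (pattern index, NA unless
#'   unique) and `mismatches`.
#' @export
index_lookup <- function(index, keys) {
  stopifnot(inherits(index, "match_index"), is.character(keys))
  k <- index$core_length
  n <- length(keys)
  status <- integer(n); entry <- rep(NA_integer_, n); mism <- rep(NA_integer_, n)
  ok <- !is.na(keys) & nchar(keys) == k
  if (any(ok)) {
    if (!is.null(index$table)) {
      ranks <- encode_base5(keys[ok], k)
      valid <- !is.na(ranks)
      rows <- ranks[valid]
      si <- integer(sum(ok)); ei <- rep(NA_integer_, sum(ok)); mi <- rep(NA_integer_, sum(ok))
      si[valid] <- index$table$status[rows]
      ei[valid] <- index$table$entry[rows]
      mi[valid] <- index$table$mism[rows]
      status[ok] <- si; entry[ok] <- ei; mism[ok] <- mi
    } else {
      for (i in which(ok)) {
        key <- keys[i]
        hit <- index$memo[[key]]
        if (is.null(hit)) {
          if (anyNA(.DIGIT[as.integer(charToRaw(key)) + 1L])) {
            hit <- list(status = "none", entry_id = NA_integer_,
                        mismatches = NA_integer_)
          } else {
            hit <- core_best_match(key, index$cores, index$max_mismatches)
          }
          index$memo[[key]] <- hit
        }
        status[i] <- match(hit$status, .STATUS_LEVELS) - 1L
        entry[i] <- hit$entry_id
        mism[i] <- hit$mismatches
      }
    }
  }
  data.frame(status = .STATUS_LEVELS[status + 1L], entry = entry,
             mismatches = mism, stringsAsFactors = FALSE)
}

#' @export
print.match_index <- function(x, ...) {
  cat(sprintf("<match_index %s> %d pattern(s), core length %d, max %d mismatch(es), %s\n",
              x$anchor, length(x$cores), x$core_length, x$max_mismatches,
              if (is.null(x$table)) "memoized on-demand" else
                sprintf("%d precomputed entries", 5L^x$core_length)))
  invisible(x)
}
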