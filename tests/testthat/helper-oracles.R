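# Independent brute-force oracles and small random-case generators. These
# deliberately use naive character-vector comparisons, not the package's
# byte/base-5 machinery.

# Hamming distance between equal-length strings via character vectors
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# brute-force best match of a core-length candidate against barcode cores
oracle_best <- function(candidate, cores, max_mismatches) {
  d <- vapply(cores, function(co) oracle_hamming(candidate, co), 0)
  m <- min(d)
  if (m > max_mismatches) list(status = "none", entry = NA_integer_)
  else if (sum(d == m) > 1L) list(status = "ambiguous", entry = NA_integer_)
  else list(status = "unique", entry = which.min(d), mismatches = m)
}

# all 5^L strings over {A,C,G,T,N}, built independently via recursion
oracle_enumerate <- function(L) {
  if (L == 1L) return(c("A", "C", "G", "T", "N"))
  shorter <- oracle_enumerate(L - 1L)
  as.vector(vapply(c("A", "C", "G", "T", "N"),
                   function(b) paste0(shorter, b), character(length(shorter))))
}

random_core <- function(k) paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                                 collapse = "")

# a random set of distinct barcode cores of one length
random_core_set <- function(k, n) {
  cores <- unique(replicate(4L * n, random_core(k)))
  head(cores, n)
}

# random valid 5' pattern with the given core and UMI arm lengths
pattern_string <- function(core, umi_left, umi_right) {
  paste0(strrep("N", umi_left), core, strrep("N", umi_right))
}

const_qual <- function(seq) strrep("I", nchar(seq))

make_read <- function(id, seq) read_record(id, seq, const_qual(seq))

# brute-force best-match sweep over a whole candidate set, vectorised over
# candidates but still by plain character comparison
oracle_sweep <- function(cands, cores, max_mismatches) {
  k <- nchar(cores[1L])
  mat <- matrix(unlist(strsplit(cands, "", fixed = TRUE)), nrow = k)
  D <- vapply(cores, function(co)
    colSums(mat != strsplit(co, "", fixed = TRUE)[[1]]), numeric(ncol(mat)))
  D <- matrix(D, ncol = length(cores))
  minm <- apply(D, 1L, min)
  nmin <- rowSums(D == minm)
  status <- ifelse(minm > max_mismatches, "none",
                   ifelse(nmin > 1L, "ambiguous", "unique"))
  entry <- apply(D, 1L, which.min)
  entry[status != "unique"] <- NA_integer_
  list(status = status, entry = as.integer(entry),
       mismatches = ifelse(status == "none", NA_integer_, as.integer(minm)))
}

# a sheet mixing four 5'-only and two combinatorial entries (ten samples),
# with 5-base 5' barcode cores and per-entry 3' barcode styles
ten_sample_sheet <- function() {
  parse_sample_sheet(paste(
    c("NNNAACCGNN",
      "NNNCCGGTNN:ribo_1",
      "NNNGGTTANN",
      "NNNTTAACNN:ribo_2",
      "NNNGATCANN,NNAG:clip_1,NNCT,NNGA",
      "NNNCTAGTNN,NNNTAC,NNNGCA,NNNATG:clip_2"),
    collapse = "\n"))
}
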