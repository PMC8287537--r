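# Byte-level helpers shared across modules. All coordinates handed around
# between modules are 0-based half-open; 1-based indexing appears only
# transiently inside substr()/raw subsetting.

.DNA_BASES <- c("A", "C", "G", "T")
.DNA_ALPHABET <- c("A", "C", "G", "T", "N")

# byte -> base-5 digit (A=0, C=1, G=2, T=3, N=4), NA for anything else
.DIGIT <- local({
  d <- rep(NA_integer_, 256L)
  d[utf8ToInt("A") + 1L] <- 0L
  d[utf8ToInt("C") + 1L] <- 1L
  d[utf8ToInt("G") + 1L] <- 2L
  d[utf8ToInt("T") + 1L] <- 3L
  d[utf8ToInt("N") + 1L] <- 4L
  d
})

# byte-level complement table; non-DNA bytes map to themselves
.COMP <- local({
  co <- as.raw(0:255)
  swap <- function(a, b) {
    co[utf8ToInt(a) + 1L] <<- charToRaw(b)
    co[utf8ToInt(b) + 1L] <<- charToRaw(a)
  }
  swap("A", "T")
  swap("C", "G")
  co
})

# characters of `s` at 1-based positions `pos`, concatenated
chars_at <- function(s, pos) {
  rawToChar(charToRaw(s)[pos])
}

reverse_complement <- function(s) {
  vapply(s, function(x) rawToChar(rev(.COMP[as.integer(charToRaw(x)) + 1L])),
         character(1), USE.NAMES = FALSE)
}

# base-5 ranks (1-based) of equal-width strings over {A,C,G,T,N}; NA where a
# string contains any other character
encode_base5 <- function(keys, width) {
  if (!length(keys)) return(integer(0))
  digits <- .DIGIT[as.integer(charToRaw(paste0(keys, collapse = ""))) + 1L]
  m <- matrix(digits, nrow = width)
  as.integer(colSums(m * 5^((width - 1L):0)) + 1L)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == as.integer(x)
}
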