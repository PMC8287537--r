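Package: fastqdemux
Title: Fast Combinatorial Demultiplexing of FASTQ Files with UMI Handling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Splits raw gzip-compressed FASTQ files into per-sample files
    using 5'-only or combinatorial 5' plus 3' experimental barcodes, as
    produced by iCLIP, ribosome profiling and related protocols. Unique
    molecular identifier (UMI) bases are moved into the read header,
    sequencing adaptors and low-quality 3' bases are trimmed, and all
    processing happens in a single read-write pass. Barcode assignment is
    mismatch tolerant and runs in constant time per read via a precomputed
    best-match table over all candidate barcode sequences. Includes a
    synthetic-lane generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    parallel,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
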