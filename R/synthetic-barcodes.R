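#' Generate a dictionary of AxBy DNA barcodes
#'
#' Builds `n` double-stranded AxBy barcode definitions, each consisting of an
#' A 25-mer and a B 25-mer plus a UMI length. Sequences are drawn by rejection
#' sampling so that within the A set (and, independently, within the B set)
#' every pair of sequences differs at `min_hamming` or more positions. A
#' minimum distance of 5 guarantees that single-mismatch decoding of either
#' region is unambiguous.
#'
#' @param n Number of barcodes.
#' @param length Length of each of the A and B oligo regions, in nt.
#' @param umi_length Length of the unique molecular identifier, in nt.
#' @param min_hamming Minimum pairwise Hamming distance enforced within the A
#'   set and within the B set.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param max_attempts Rejection-sampling attempt budget per sequence set.
#'   When exhausted, a capacity error (class `pmhc_capacity_error`) is raised
#'   rather than silently returning fewer barcodes.
#' @return A `data.frame` with columns `barcode_id`, `seq_a`, `seq_b`,
#'   `umi_length`.
#' @examples
#' dict <- generate_barcode_dictionary(10, seed = 1)
#' nchar(dict$seq_a[1])
#' @export
generate_barcode_dictionary <- function(n, length = 25, umi_length = 6,
                                        min_hamming = 5, seed = 1,
                                        max_attempts = 200L * n + 1000L) {
  if (n < 1) abort_config("n must be >= 1")
  if (min_hamming > length) abort_config("min_hamming cannot exceed sequence length")
  with_seed(derive_seed(seed, "barcode_dictionary"), {
    gen_set <- function() {
      acc <- matrix(integer(0), nrow = 0, ncol = length)
      attempts <- 0L
      while (nrow(acc) < n) {
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          abort_capacity(sprintf(
            "could not place %d sequences of length %d at pairwise Hamming >= %d within %d attempts",
            n, length, min_hamming, max_attempts
          ))
        }
        cand <- sample.int(4L, length, replace = TRUE)
        if (nrow(acc) == 0L ||
            min(rowSums(acc != matrix(cand, nrow(acc), length, byrow = TRUE))) >= min_hamming) {
          acc <- rbind(acc, cand)
        }
      }
      acc
    }
    a <- gen_set()
    b <- gen_set()
    to_seq <- function(m) paste_rows(matrix(DNA_BASES[m], nrow = nrow(m)))
    data.frame(
      barcode_id = sprintf("BC%04d", seq_len(n)),
      seq_a = to_seq(a),
      seq_b = to_seq(b),
      umi_length = as.integer(umi_length),
      stringsAsFactors = FALSE
    )
  })
}
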