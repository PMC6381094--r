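DNA_BASES <- c("A", "C", "G", "T")

## Condition helpers: the pipeline distinguishes configuration errors,
## capacity (rejection-sampling budget) errors, validation errors on user
## inputs, data-integrity errors (pipeline bug signals) and I/O errors.
abort_config <- function(msg) {
  stop(errorCondition(msg, class = "pmhc_config_error"))
}
abort_capacity <- function(msg) {
  stop(errorCondition(msg, class = "pmhc_capacity_error"))
}
abort_validation <- function(msg) {
  stop(errorCondition(msg, class = "pmhc_validation_error"))
}
abort_integrity <- function(msg) {
  stop(errorCondition(msg, class = "pmhc_integrity_error"))
}
abort_io <- function(msg) {
  stop(errorCondition(msg, class = "pmhc_io_error"))
}

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' Per-sample random streams are derived by stable hashing of
#' `(seed, label)`, so adding a sample to a simulation never perturbs the
#' reads of any other sample. The hash is a plain polynomial string hash
#' modulo 2^31 - 1, computed exactly in double precision, hence identical
#' across platforms.
#'
#' @param seed Integer master seed.
#' @param label Character scalar naming the stream (e.g. a sample id).
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, label) {
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(as.character(label))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

## Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## n x len matrix of random DNA characters
random_dna_matrix <- function(n, len) {
  matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n, ncol = len)
}

## Collapse a character matrix to one string per row.
paste_rows <- function(m) {
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

## Random UMI strings (uniform over 4^len sequences).
random_umis <- function(n, len) {
  if (n == 0L) return(character(0))
  paste_rows(random_dna_matrix(n, len))
}

## Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

## Split a ";"-collapsed HLA genotype string into an allele vector.
#' Split collapsed HLA genotype strings
#'
#' Donor tables store HLA class I genotypes as a single `;`-separated string
#' (TSV-friendly); this expands them back into character vectors.
#'
#' @param x Character vector of collapsed genotypes.
#' @return A list of character vectors, one per element of `x`.
#' @export
split_alleles <- function(x) {
  strsplit(as.character(x), ";", fixed = TRUE)
}

geometric_mean <- function(x) exp(mean(log(x)))
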