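#' Construct a barcode x sample count table
#'
#' Container for the output of barcode processing: per (barcode, sample) the
#' raw assigned read count and the clonally reduced count (number of distinct
#' UMIs), plus per-sample QC totals.
#'
#' @param raw,clonal Barcode x sample integer matrices with identical
#'   dimnames; `clonal <= raw` elementwise.
#' @param qc Optional per-sample QC `data.frame` with columns `sample_id`,
#'   `total_reads`, `assigned`, `unassigned`, `unparseable`.
#' @return An object of class `count_table`.
#' @export
count_table <- function(raw, clonal, qc = NULL) {
  raw <- as.matrix(raw)
  clonal <- as.matrix(clonal)
  if (!identical(dim(raw), dim(clonal)) ||
      !identical(dimnames(raw), dimnames(clonal))) {
    abort_config("raw and clonal matrices must have identical dimnames")
  }
  if (any(raw < 0) || any(clonal < 0)) abort_config("counts must be >= 0")
  if (any(clonal > raw)) abort_config("clonal counts cannot exceed raw counts")
  structure(
    list(
      raw = raw, clonal = clonal, qc = qc,
      samples = colnames(raw), barcode_ids = rownames(raw)
    ),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d barcodes x %d samples\n",
              nrow(x$raw), ncol(x$raw)))
  cat(sprintf("  total raw reads: %s; total clonal reads: %s\n",
              format(sum(x$raw), big.mark = ","),
              format(sum(x$clonal), big.mark = ",")))
  if (!is.null(x$qc)) {
    cat(sprintf("  unassigned: %s; unparseable: %s\n",
                format(sum(x$qc$unassigned), big.mark = ","),
                format(sum(x$qc$unparseable), big.mark = ",")))
  }
  invisible(x)
}

#' @export
as.data.frame.count_table <- function(x, ...) {
  data.frame(
    sample_id = rep(x$samples, each = nrow(x$raw)),
    barcode_id = rep(x$barcode_ids, times = ncol(x$raw)),
    raw_reads = as.vector(x$raw),
    clonal_reads = as.vector(x$clonal),
    stringsAsFactors = FALSE
  )
}

#' Parse fixed-layout barcode amplicon reads from a FASTQ file
#'
#' Under the default layout a read is `seq_a (25 nt) + UMI (6 nt) + seq_b
#' (25 nt)` at fixed offsets; reads shorter than the layout are counted as
#' unparseable rather than raising an error.
#'
#' @param fastq Path to a FASTQ file.
#' @param a_length,umi_length,b_length Region lengths in nt.
#' @return A list with `reads` (a `data.frame` of `seq_a_region`, `umi`,
#'   `seq_b_region`), `n_total` and `n_unparseable`.
#' @export
parse_reads <- function(fastq, a_length = 25, umi_length = 6, b_length = 25) {
  reads <- tryCatch(
    Biostrings::readDNAStringSet(fastq, format = "fastq"),
    error = function(e) abort_io(sprintf("malformed FASTQ '%s': %s",
                                         fastq, conditionMessage(e)))
  )
  min_len <- a_length + umi_length + b_length
  w <- Biostrings::width(reads)
  ok <- w >= min_len
  s <- as.character(reads[ok])
  list(
    reads = data.frame(
      seq_a_region = substr(s, 1L, a_length),
      umi = substr(s, a_length + 1L, a_length + umi_length),
      seq_b_region = substr(s, a_length + umi_length + 1L, min_len),
      stringsAsFactors = FALSE
    ),
    n_total = length(reads),
    n_unparseable = sum(!ok)
  )
}

## Lookup table mapping every sequence within `max_mismatch` (0 or 1) of a
## dictionary sequence to its barcode index; keys reachable from two
## different barcodes (possible only if the dictionary violates its
## min-Hamming invariant) map to NA so that ties stay unassigned.
mismatch_lookup <- function(seqs, max_mismatch) {
  keys <- seqs
  idx <- seq_along(seqs)
  if (max_mismatch >= 1L) {
    L <- nchar(seqs[1])
    for (p in seq_len(L)) {
      for (b in DNA_BASES) {
        v <- seqs
        substr(v, p, p) <- b
        keys <- c(keys, v)
        idx <- c(idx, seq_along(seqs))
      }
    }
  }
  dt <- data.table::data.table(variant = keys, idx = idx)
  dt[, .(idx = if (data.table::uniqueN(idx) == 1L) idx[1L]
         else NA_integer_), by = "variant"]
}

#' Assign reads to dictionary barcodes by Hamming-tolerant matching
#'
#' A read is assigned iff both its A and B regions lie within `max_mismatch`
#' substitutions of the same barcode's `seq_a` and `seq_b`, and that barcode
#' is the unique such minimum; ties yield `NA` (unassigned). For
#' `max_mismatch <= 1` matching uses exact lookup over the 1-mismatch
#' neighborhood (unambiguous whenever the dictionary's minimum pairwise
#' Hamming distance is at least 3); larger tolerances fall back to an
#' exhaustive Hamming scan.
#'
#' @param a_region,b_region Character vectors of read regions (equal length).
#' @param dictionary Barcode dictionary.
#' @param max_mismatch Per-region mismatch tolerance (default 1).
#' @return Character vector of `barcode_id` or `NA` per read.
#' @export
assign_barcodes <- function(a_region, b_region, dictionary, max_mismatch = 1) {
  if (length(a_region) != length(b_region)) {
    abort_config("a_region and b_region must have equal length")
  }
  n <- length(a_region)
  if (n == 0L) return(character(0))
  mm_fast <- min(max_mismatch, 1L)
  lka <- mismatch_lookup(dictionary$seq_a, mm_fast)
  lkb <- mismatch_lookup(dictionary$seq_b, mm_fast)
  ia <- lka$idx[match(a_region, lka$variant)]
  ib <- lkb$idx[match(b_region, lkb$variant)]
  res <- ifelse(!is.na(ia) & !is.na(ib) & ia == ib,
                dictionary$barcode_id[ia], NA_character_)
  if (max_mismatch > 1L) {
    ## exhaustive scan for reads not resolved within one mismatch
    todo <- which(is.na(res))
    if (length(todo)) {
      to_int <- function(x) t(vapply(strsplit(x, ""), function(ch)
        match(ch, DNA_BASES), integer(nchar(x[1]))))
      da_m <- to_int(dictionary$seq_a)
      db_m <- to_int(dictionary$seq_b)
      for (i in todo) {
        ca <- match(strsplit(a_region[i], "")[[1]], DNA_BASES)
        cb <- match(strsplit(b_region[i], "")[[1]], DNA_BASES)
        da <- rowSums(da_m != matrix(ca, nrow(da_m), length(ca), byrow = TRUE))
        db <- rowSums(db_m != matrix(cb, nrow(db_m), length(cb), byrow = TRUE))
        feas <- which(da <= max_mismatch & db <= max_mismatch)
        if (length(feas)) {
          tot <- da[feas] + db[feas]
          best <- feas[tot == min(tot)]
          if (length(best) == 1L) res[i] <- dictionary$barcode_id[best]
        }
      }
    }
  }
  res
}

#' Collapse assigned reads to raw and clonally reduced counts
#'
#' Per (barcode, sample), `raw_reads` is the number of assigned reads and
#' `clonal_reads` the number of distinct UMI sequences, collapsing PCR
#' duplicates of the same oligo molecule. UMI collapse is exact-match only.
#'
#' @param assigned A `data.frame` with columns `sample_id`, `barcode_id`,
#'   `umi` (one row per assigned read).
#' @param barcode_ids Full barcode universe for the row set (zero-filled).
#' @param sample_ids Ordered sample ids for the column set; defaults to the
#'   samples present.
#' @param qc Optional QC `data.frame` forwarded to [count_table()].
#' @return A [count_table()].
#' @export
clonal_reduce <- function(assigned, barcode_ids,
                          sample_ids = unique(assigned$sample_id), qc = NULL) {
  dt <- data.table::as.data.table(assigned)
  agg <- dt[, .(raw_reads = .N,
                clonal_reads = data.table::uniqueN(umi)),
            by = .(sample_id, barcode_id)]
  raw <- matrix(0L, nrow = length(barcode_ids), ncol = length(sample_ids),
                dimnames = list(barcode_ids, sample_ids))
  clonal <- raw
  i <- match(agg$barcode_id, barcode_ids)
  j <- match(agg$sample_id, sample_ids)
  if (anyNA(i)) abort_integrity("assigned reads carry barcodes outside the dictionary")
  if (anyNA(j)) abort_integrity("assigned reads carry unknown sample ids")
  raw[cbind(i, j)] <- agg$raw_reads
  clonal[cbind(i, j)] <- agg$clonal_reads
  count_table(raw = raw, clonal = clonal, qc = qc)
}

#' Process per-sample FASTQ files into a count table
#'
#' Front end of the pipeline: parses each sample's FASTQ (one file per
#' sample; file-level demultiplexing), assigns reads to barcodes, and
#' collapses UMIs into clonally reduced counts. Per sample,
#' `assigned + unassigned + unparseable = total reads`.
#'
#' @param fastq_files Character vector of FASTQ paths named by sample id.
#' @param dictionary Barcode dictionary.
#' @param max_mismatch Per-region mismatch tolerance for assignment.
#' @return A [count_table()] whose `qc` component holds per-sample totals.
#' @export
process_samples <- function(fastq_files, dictionary, max_mismatch = 1) {
  if (is.null(names(fastq_files)) || any(names(fastq_files) == "")) {
    abort_config("fastq_files must be named by sample id")
  }
  missing <- fastq_files[!file.exists(fastq_files)]
  if (length(missing)) {
    abort_config(sprintf("missing FASTQ file: %s", missing[1]))
  }
  assigned_all <- vector("list", length(fastq_files))
  qc <- data.frame(
    sample_id = names(fastq_files), total_reads = 0L, assigned = 0L,
    unassigned = 0L, unparseable = 0L, stringsAsFactors = FALSE
  )
  for (k in seq_along(fastq_files)) {
    p <- parse_reads(fastq_files[k],
                     umi_length = dictionary$umi_length[1])
    bc <- assign_barcodes(p$reads$seq_a_region, p$reads$seq_b_region,
                          dictionary, max_mismatch)
    ok <- !is.na(bc)
    qc$total_reads[k] <- p$n_total
    qc$unparseable[k] <- p$n_unparseable
    qc$assigned[k] <- sum(ok)
    qc$unassigned[k] <- p$n_total - p$n_unparseable - sum(ok)
    if (any(ok)) {
      assigned_all[[k]] <- data.frame(
        sample_id = names(fastq_files)[k],
        barcode_id = bc[ok],
        umi = p$reads$umi[ok],
        stringsAsFactors = FALSE
      )
    }
  }
  assigned <- do.call(rbind, assigned_all)
  if (is.null(assigned)) {
    assigned <- data.frame(sample_id = character(0), barcode_id = character(0),
                           umi = character(0), stringsAsFactors = FALSE)
  }
  clonal_reduce(assigned, barcode_ids = dictionary$barcode_id,
                sample_ids = names(fastq_files), qc = qc)
}

#' Write / read a count table as long-format TSV
#'
#' @param x A [count_table()].
#' @param counts_path Path for the long-format counts TSV (`sample_id`,
#'   `barcode_id`, `raw_reads`, `clonal_reads`).
#' @param qc_path Optional path for the per-sample QC TSV.
#' @return `write_count_table` returns the path invisibly;
#'   `read_count_table` returns a [count_table()].
#' @export
write_count_table <- function(x, counts_path, qc_path = NULL) {
  data.table::fwrite(as.data.frame(x), counts_path, sep = "\t")
  if (!is.null(qc_path) && !is.null(x$qc)) {
    data.table::fwrite(x$qc, qc_path, sep = "\t")
  }
  invisible(counts_path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(counts_path, qc_path = NULL) {
  long <- data.table::fread(counts_path, sep = "\t", data.table = FALSE)
  samples <- unique(long$sample_id)
  barcodes <- unique(long$barcode_id)
  raw <- matrix(0L, length(barcodes), length(samples),
                dimnames = list(barcodes, samples))
  clonal <- raw
  i <- match(long$barcode_id, barcodes)
  j <- match(long$sample_id, samples)
  raw[cbind(i, j)] <- long$raw_reads
  clonal[cbind(i, j)] <- long$clonal_reads
  qc <- if (!is.null(qc_path) && file.exists(qc_path)) {
    data.table::fread(qc_path, sep = "\t", data.table = FALSE)
  }
  count_table(raw = raw, clonal = clonal, qc = qc)
}
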