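#' Simulate a binding-prediction table
#'
#' Emulates the upstream MHC class I binding predictions consumed by the
#' library builder: 9-11-mer peptides from the seven hypocretin-neuron
#' proteins scored against the eight-allele panel with a percentile rank
#' (%Rank). `n_binders` records receive %Rank <= 2 (binders), allocated
#' across protein x HLA cells proportionally to protein length with
#' log-normal jitter (so some cells can be empty, as observed for real
#' predictions); an equal number of non-binders receive %Rank > 2.
#'
#' @param proteins Named integer vector of protein lengths (aa); defaults to
#'   [protein_lengths()].
#' @param hlas HLA alleles to score against; defaults to [hla_panel()].
#' @param n_binders Total number of binder records (default 1183, the size
#'   of the screened library).
#' @param seed Integer seed.
#' @return A `data.frame` with columns `peptide`, `protein`, `start_pos`
#'   (1-based), `hla`, `rank_score`.
#' @export
simulate_prediction_table <- function(proteins = protein_lengths(),
                                      hlas = hla_panel(),
                                      n_binders = 1183, seed = 1) {
  if (n_binders < 1) abort_config("n_binders must be >= 1")
  with_seed(derive_seed(seed, "prediction_table"), {
    cells <- expand.grid(protein = names(proteins), hla = hlas,
                         stringsAsFactors = FALSE)
    w <- proteins[cells$protein] * 10^rnorm(nrow(cells), 0, 0.35)
    alloc <- as.vector(rmultinom(1, n_binders, w / sum(w)))
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    make_records <- function(n, protein, hla, binder) {
      if (n == 0L) return(NULL)
      len <- sample(9:11, n, replace = TRUE)
      data.frame(
        peptide = vapply(len, function(l) paste(sample(aa, l, replace = TRUE),
                                                collapse = ""), character(1)),
        protein = protein,
        start_pos = vapply(len, function(l)
          sample.int(proteins[[protein]] - l + 1L, 1), integer(1)),
        hla = hla,
        rank_score = if (binder) round(runif(n, 0.01, 2), 3)
                     else round(runif(n, 2.01, 50), 3),
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, c(
      lapply(seq_len(nrow(cells)), function(i)
        make_records(alloc[i], cells$protein[i], cells$hla[i], TRUE)),
      lapply(seq_len(nrow(cells)), function(i)
        make_records(alloc[i], cells$protein[i], cells$hla[i], FALSE))
    ))
    ## keep (peptide, hla) unique so the binder count is exact
    out <- out[!duplicated(out[, c("peptide", "hla")]), ]
    rownames(out) <- NULL
    out
  })
}

#' Filter binding predictions to binders
#'
#' Keeps records with `%Rank <= threshold` (inclusive: a score of exactly 2
#' is a binder under the default) and collapses duplicate `(peptide, hla)`
#' pairs -- e.g. the same peptide predicted from several isoforms -- keeping
#' the best (lowest) score.
#'
#' @param predictions Prediction table with at least `peptide`, `hla`,
#'   `rank_score`.
#' @param threshold %Rank cutoff (> 0; default 2).
#' @return The filtered, deduplicated prediction table.
#' @export
filter_binders <- function(predictions, threshold = 2) {
  if (threshold <= 0) abort_config("threshold must be > 0")
  keep <- predictions[predictions$rank_score <= threshold, , drop = FALSE]
  keep <- keep[order(keep$rank_score), , drop = FALSE]
  keep <- keep[!duplicated(keep[, c("peptide", "hla")]), , drop = FALSE]
  keep <- keep[order(keep$protein, keep$hla, keep$start_pos, keep$peptide), ,
               drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Assemble the barcode-labeled pMHC reagent library
#'
#' Pairs each binder with a barcode from the dictionary, one reagent per
#' unique `(peptide, hla)`.
#'
#' @param predictions Prediction table (filtered with [filter_binders()]
#'   internally using `threshold`).
#' @param dictionary Barcode dictionary; must contain at least as many
#'   barcodes as there are binders.
#' @param threshold %Rank cutoff passed to [filter_binders()].
#' @return A `data.frame` with columns `pmhc_id`, `peptide`, `protein`,
#'   `start_pos`, `hla`, `barcode_id`.
#' @export
build_library <- function(predictions, dictionary, threshold = 2) {
  binders <- filter_binders(predictions, threshold)
  if (nrow(binders) > nrow(dictionary)) {
    abort_config(sprintf("dictionary has %d barcodes but %d reagents are needed",
                         nrow(dictionary), nrow(binders)))
  }
  data.frame(
    pmhc_id = sprintf("pMHC%04d", seq_len(nrow(binders))),
    peptide = binders$peptide,
    protein = binders$protein,
    start_pos = binders$start_pos,
    hla = binders$hla,
    barcode_id = dictionary$barcode_id[seq_len(nrow(binders))],
    stringsAsFactors = FALSE
  )
}

#' Build the HLA-matched reagent panel for one donor
#'
#' Donors are screened only with the fraction of the library restricted to
#' the HLA alleles they carry; the panel size is the denominator of the
#' donor's recognition percentage.
#'
#' @param donor One-row donor record.
#' @param library Reagent library from [build_library()].
#' @return A list of class `donor_panel` with `donor_id`, `reagents`
#'   (pMHC ids), `panel` (the library subset) and `panel_size`. A donor
#'   sharing no allele with the library yields an empty panel with a warning.
#' @export
build_donor_panel <- function(donor, library) {
  if (nrow(library) == 0) abort_config("library must be non-empty")
  alleles <- split_alleles(donor$hla_class_I)[[1]]
  panel <- library[library$hla %in% alleles, , drop = FALSE]
  if (nrow(panel) == 0) {
    warning(sprintf("donor %s shares no HLA allele with the library; empty panel",
                    donor$donor_id))
  }
  structure(
    list(
      donor_id = donor$donor_id,
      reagents = panel$pmhc_id,
      panel = panel,
      panel_size = nrow(panel)
    ),
    class = "donor_panel"
  )
}

#' Summarize library composition as a protein x HLA table
#'
#' @param library Reagent library.
#' @param proteins,hlas Row/column level sets; default to the values present,
#'   but passing full sets exposes empty cells (protein-HLA combinations with
#'   no predicted binder).
#' @return A list with `table` (counts with protein rows and HLA columns),
#'   `row_totals`, `col_totals`, `total` and `zero_cells` (data.frame of
#'   empty combinations).
#' @export
library_summary <- function(library,
                            proteins = sort(unique(library$protein)),
                            hlas = sort(unique(library$hla))) {
  tab <- table(
    factor(library$protein, levels = proteins),
    factor(library$hla, levels = hlas)
  )
  tab <- matrix(as.integer(tab), nrow = length(proteins),
                dimnames = list(proteins, hlas))
  zero <- which(tab == 0L, arr.ind = TRUE)
  list(
    table = tab,
    row_totals = rowSums(tab),
    col_totals = colSums(tab),
    total = sum(tab),
    zero_cells = data.frame(
      protein = proteins[zero[, 1]],
      hla = hlas[zero[, 2]],
      stringsAsFactors = FALSE
    )
  )
}

#' Map immunogenic hotspots on protein coordinates
#'
#' A hotspot is a maximal protein interval in which recognized peptides of
#' at least `min_hlas` distinct HLA restrictions mutually overlap by one or
#' more residues. Operationally: residues covered by peptides of >=
#' `min_hlas` distinct HLAs seed a hotspot, whose reported interval is the
#' union (1-based, closed) of all peptides covering those residues;
#' overlapping seeded intervals are merged.
#'
#' @param recognized Recognized reagents: a `data.frame` with `protein`,
#'   `start_pos`, `peptide`, `hla`.
#' @param protein_lengths Named vector of protein lengths (aa); peptides
#'   exceeding their protein's bounds raise a validation error.
#' @param min_hlas Minimum number of distinct HLA restrictions (default 2).
#' @return A `data.frame` with columns `protein`, `start`, `end`,
#'   `n_peptides`, `n_hlas`.
#' @export
hotspot_map <- function(recognized, protein_lengths, min_hlas = 2) {
  cols <- c("protein", "start_pos", "peptide", "hla")
  if (!all(cols %in% names(recognized))) {
    abort_config("recognized must have columns protein, start_pos, peptide, hla")
  }
  empty <- data.frame(protein = character(0), start = integer(0),
                      end = integer(0), n_peptides = integer(0),
                      n_hlas = integer(0), stringsAsFactors = FALSE)
  if (nrow(recognized) == 0) return(empty)
  ends <- recognized$start_pos + nchar(recognized$peptide) - 1L
  lens <- protein_lengths[recognized$protein]
  if (anyNA(lens)) abort_validation("recognized protein missing from protein_lengths")
  bad <- which(ends > lens | recognized$start_pos < 1L)
  if (length(bad)) {
    abort_validation(sprintf(
      "peptide %s (%s at %d) exceeds protein bounds",
      recognized$peptide[bad[1]], recognized$protein[bad[1]],
      recognized$start_pos[bad[1]]
    ))
  }
  out <- empty
  for (prot in sort(unique(recognized$protein))) {
    sel <- recognized[recognized$protein == prot, , drop = FALSE]
    s <- sel$start_pos
    e <- s + nchar(sel$peptide) - 1L
    L <- protein_lengths[[prot]]
    ## distinct-HLA coverage per residue
    n_hla_at <- vapply(seq_len(L), function(r) {
      length(unique(sel$hla[s <= r & e >= r]))
    }, integer(1))
    seeds <- which(n_hla_at >= min_hlas)
    if (!length(seeds)) next
    ## union interval of peptides covering each seed residue, then merge
    ivs <- t(vapply(seeds, function(r) {
      cov <- s <= r & e >= r
      c(min(s[cov]), max(e[cov]))
    }, integer(2)))
    ivs <- ivs[order(ivs[, 1], ivs[, 2]), , drop = FALSE]
    merged <- list()
    cur <- ivs[1, ]
    for (i in seq_len(nrow(ivs))[-1]) {
      if (ivs[i, 1] <= cur[2]) {
        cur[2] <- max(cur[2], ivs[i, 2])
      } else {
        merged[[length(merged) + 1]] <- cur
        cur <- ivs[i, ]
      }
    }
    merged[[length(merged) + 1]] <- cur
    for (iv in merged) {
      member <- s <= iv[2] & e >= iv[1]
      out <- rbind(out, data.frame(
        protein = prot, start = iv[1], end = iv[2],
        n_peptides = sum(member),
        n_hlas = length(unique(sel$hla[member])),
        stringsAsFactors = FALSE
      ))
    }
  }
  rownames(out) <- NULL
  out
}
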