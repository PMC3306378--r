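#' Demultiplex barcoded GBS reads
#'
#' Assigns genotyping-by-sequencing reads to inbred lines by inline
#' barcode. A read is kept iff it begins with an exact barcode immediately
#' followed by the ApeKI cut-site remnant `GC[A/T]GC`; the barcode is
#' removed and the cut site retained. All other reads are discarded (and
#' counted). Barcodes must be unique and prefix-free: with perfect-match
#' parsing a barcode that is a prefix of another would be ambiguous.
#'
#' @param reads A tibble with columns `read_id` and `sequence`
#'   (over A, C, G, T, N).
#' @param barcodes A tibble with columns `barcode` and `line_id`.
#' @param keep_cut_site Keep the 5-bp cut-site remnant on the trimmed read
#'   (default TRUE).
#' @return A tibble `read_id`, `line_id`, `trimmed` of assigned reads, with
#'   attribute `n_discarded`.
#' @examples
#' reads <- tibble::tibble(read_id = "r1", sequence = "ACGTGCAGCTTTT")
#' bcs <- tibble::tibble(barcode = "ACGT", line_id = "L1")
#' demultiplex(reads, bcs)
#' @export
demultiplex <- function(reads, barcodes, keep_cut_site = TRUE) {
  assert_cols(reads, c("read_id", "sequence"), "reads")
  assert_cols(barcodes, c("barcode", "line_id"), "barcodes")
  bc <- barcodes$barcode
  if (anyDuplicated(bc)) abort("Barcodes must be unique.")
  for (i in seq_along(bc)) {
    pref <- startsWith(bc, bc[i])
    pref[i] <- FALSE
    if (any(pref)) {
      abort(sprintf("Barcode %s is a prefix of %s: barcode set must be prefix-free.",
                    bc[i], bc[pref][1]))
    }
  }
  # prefix-free => at most one barcode matches any read
  pattern <- paste0("^(", paste(bc, collapse = "|"), ")(GC[AT]GC)")
  m <- stringr::str_match(reads$sequence, pattern)
  hit <- !is.na(m[, 1])
  matched_bc <- m[hit, 2]
  trimmed <- substring(reads$sequence[hit], nchar(matched_bc) + 1L)
  if (!keep_cut_site) trimmed <- substring(trimmed, 6L)
  out <- tibble(
    read_id = reads$read_id[hit],
    line_id = barcodes$line_id[match(matched_bc, bc)],
    trimmed = trimmed
  )
  attr(out, "n_discarded") <- sum(!hit)
  out
}

#' Call a GBS genotype under the 70% majority rule
#'
#' At a GBS site a single nucleotide is called iff it is supported by at
#' least `min_frac` (default 70%) of the reads; otherwise the call is
#' missing. With the threshold above 50% at most one nucleotide can
#' qualify. Zero coverage yields missing.
#'
#' @param counts Length-4 numeric vector (A, C, G, T) or 4-column matrix.
#' @param min_frac Minimum supporting read fraction, inclusive
#'   (default 0.70).
#' @return Character vector of calls (nucleotide or NA), one per row.
#' @examples
#' call_gbs_genotype(c(7, 3, 0, 0))  # "A": 70% exactly
#' call_gbs_genotype(c(6, 4, 0, 0))  # NA
#' @export
call_gbs_genotype <- function(counts, min_frac = 0.70) {
  if (is.null(dim(counts))) counts <- matrix(as.numeric(counts), nrow = 1)
  if (ncol(counts) != 4L) abort("`counts` must have four columns (A, C, G, T).")
  if (anyNA(counts) || any(counts < 0)) abort("Base counts must be nonnegative.")
  total <- rowSums(counts)
  frac <- counts / ifelse(total == 0, NA_real_, total)
  best <- max.col(counts, "first")
  best_frac <- frac[cbind(seq_len(nrow(counts)), best)]
  ifelse(!is.na(best_frac) & best_frac >= min_frac, NUCLEOTIDES[best],
         NA_character_)
}

#' Genotype matrix from a GBS count table
#'
#' Applies [call_gbs_genotype()] to every record of a GBS per-site count
#' table (same layout as a base-count table) and returns calls in the wide
#' layout used by [discover_snps()], suitable for concordance analysis.
#'
#' @param gbs_counts A count table (see [read_basecount_table()]).
#' @param lines Ordered line ids for the columns; defaults to those present.
#' @param min_frac Majority-rule threshold (default 0.70).
#' @return A wide tibble `chrom`, `pos`, then one call column per line.
#' @export
gbs_genotype_matrix <- function(gbs_counts, lines = NULL, min_frac = 0.70) {
  bc <- validate_basecount_table(gbs_counts)
  lines <- lines %||% sort(unique(bc$line_id))
  bc$allele <- call_gbs_genotype(count_matrix(bc), min_frac)
  wide <- bc |>
    select("line_id", "chrom", "pos", "allele") |>
    tidyr::pivot_wider(names_from = "line_id", values_from = "allele")
  for (l in setdiff(lines, names(wide))) wide[[l]] <- NA_character_
  out <- wide |>
    select("chrom", "pos", dplyr::all_of(lines)) |>
    arrange(.data$chrom, .data$pos)
  attr(out, "lines") <- lines
  out
}
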