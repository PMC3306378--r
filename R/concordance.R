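#' Concordance of genotype calls with a reference sequence
#'
#' Compares non-missing calls (one data point per position-by-line) against
#' reference nucleotides. Positions absent from the reference are excluded
#' from the rate and counted separately.
#'
#' @param calls A tibble `chrom`, `pos`, `line_id`, `allele` of non-missing
#'   calls.
#' @param reference A tibble `chrom`, `pos`, `ref`.
#' @return A one-row tibble: `n_compared`, `n_matching`, `rate`,
#'   `n_absent_from_reference`. An empty comparison set is an error, since
#'   the rate would be undefined.
#' @export
reference_concordance <- function(calls, reference) {
  assert_cols(calls, c("chrom", "pos", "line_id", "allele"), "calls")
  assert_cols(reference, c("chrom", "pos", "ref"), "reference")
  if (anyNA(calls$allele)) {
    abort("`calls` must contain non-missing alleles only.")
  }
  joined <- calls |>
    left_join(reference, by = c("chrom", "pos"))
  n_absent <- sum(is.na(joined$ref))
  joined <- joined |> filter(!is.na(.data$ref))
  if (nrow(joined) == 0L) {
    abort("No call positions present in the reference: concordance undefined.")
  }
  tibble(
    n_compared = nrow(joined),
    n_matching = sum(joined$allele == joined$ref),
    rate = sum(joined$allele == joined$ref) / nrow(joined),
    n_absent_from_reference = n_absent
  )
}

#' Concordance between two genotype call sets
#'
#' Compares two wide call matrices (e.g. RNA-seq derived vs. GBS derived)
#' over the data points — (position, line) pairs — that are non-missing in
#' both. Also reports "contradiction positions": positions at which more
#' than `max_discordant_lines` lines disagree between the methods.
#'
#' @param a,b Wide call tibbles (`chrom`, `pos`, then line columns) sharing
#'   line and coordinate vocabularies, e.g. from [discover_snps()] and
#'   [gbs_genotype_matrix()].
#' @param max_discordant_lines Threshold above which a position is flagged
#'   as contradictory (default 2).
#' @return A one-row tibble: `n_shared_points`, `n_concordant`, `rate`,
#'   `n_positions`, `n_contradiction_positions`, and a list-column
#'   `contradiction_positions` (tibble `chrom`, `pos`, `n_discordant`).
#'   Symmetric in `a` and `b`.
#' @export
cross_method_concordance <- function(a, b, max_discordant_lines = 2) {
  lines <- intersect(gm_lines(a), gm_lines(b))
  if (length(lines) == 0L) abort("`a` and `b` share no line columns.")
  long <- function(x) {
    as_tibble(x)[, c("chrom", "pos", lines)] |>
      tidyr::pivot_longer(dplyr::all_of(lines), names_to = "line_id",
                          values_to = "allele") |>
      filter(!is.na(.data$allele))
  }
  shared <- dplyr::inner_join(long(a), long(b),
                              by = c("chrom", "pos", "line_id"),
                              suffix = c("_a", "_b"))
  n_shared <- nrow(shared)
  concordant <- shared$allele_a == shared$allele_b
  by_pos <- shared |>
    group_by(.data$chrom, .data$pos) |>
    summarise(n_discordant = sum(.data$allele_a != .data$allele_b),
              .groups = "drop")
  contradictions <- by_pos |>
    filter(.data$n_discordant > max_discordant_lines)
  tibble(
    n_shared_points = n_shared,
    n_concordant = sum(concordant),
    rate = if (n_shared == 0) NA_real_ else sum(concordant) / n_shared,
    n_positions = nrow(by_pos),
    n_contradiction_positions = nrow(contradictions),
    contradiction_positions = list(contradictions)
  )
}
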