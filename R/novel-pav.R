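#' Select the representative transcript per assembly locus
#'
#' At each de novo assembly locus the representative transcript is the
#' longest one; ties are broken lexicographically by transcript id. All
#' transcripts must meet the assembly's minimum length (default 500 bp).
#'
#' @param transcripts A tibble `locus_id`, `transcript_id`, `length`.
#' @param min_length Minimum transcript length; shorter entries are a
#'   validation error (default 500).
#' @return A tibble with one row per locus.
#' @export
select_representative <- function(transcripts, min_length = 500) {
  assert_cols(transcripts, c("locus_id", "transcript_id", "length"))
  if (any(transcripts$length < min_length)) {
    abort(sprintf("All transcripts must be at least %d bp long.", min_length))
  }
  transcripts |>
    group_by(.data$locus_id) |>
    arrange(dplyr::desc(.data$length), .data$transcript_id,
            .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
}

#' Filter assembled transcripts for novelty against a reference
#'
#' A transcript is removed (judged an allele or close paralog of reference
#' sequence) iff it aligns with coverage strictly greater than `cov_cut`
#' AND identity strictly greater than `id_cut` (defaults 0.85). Retained
#' transcripts are the complement: those with no alignment at all, plus
#' those whose best alignment is below the coverage and/or identity cutoff.
#'
#' @param summaries An alignment-summary tibble
#'   (see [read_alignment_summary()]); one best alignment per transcript.
#' @param cov_cut,id_cut Strict removal thresholds.
#' @return The input tibble with a `status` column
#'   (`"unaligned"`, `"below_cutoff"`, `"removed"`) and a `retained`
#'   logical; the three statuses partition the input.
#' @export
filter_novel <- function(summaries, cov_cut = 0.85, id_cut = 0.85) {
  summaries <- validate_alignment_summary(summaries)
  summaries |>
    mutate(
      status = dplyr::case_when(
        !.data$aligned ~ "unaligned",
        .data$coverage > cov_cut & .data$identity > id_cut ~ "removed",
        TRUE ~ "below_cutoff"
      ),
      retained = .data$status != "removed"
    )
}

#' Removed-transcript counts over a grid of cutoffs
#'
#' Re-applies the novelty filter at every combination of coverage and
#' identity cutoffs, reporting how many transcripts would be removed. The
#' count is non-increasing in each cutoff.
#'
#' @param summaries An alignment-summary tibble.
#' @param cov_grid,id_grid Cutoff values (defaults 0.70 to 0.95 in steps
#'   of 0.05).
#' @return A tibble `cov_cut`, `id_cut`, `n_removed` covering the full
#'   grid.
#' @export
cutoff_sweep <- function(summaries,
                         cov_grid = seq(0.70, 0.95, by = 0.05),
                         id_grid = seq(0.70, 0.95, by = 0.05)) {
  summaries <- validate_alignment_summary(summaries)
  tidyr::expand_grid(cov_cut = cov_grid, id_cut = id_grid) |>
    mutate(n_removed = purrr::map2_int(
      .data$cov_cut, .data$id_cut,
      function(cc, ic) {
        sum(summaries$aligned & summaries$coverage > cc &
              summaries$identity > ic, na.rm = TRUE)
      }
    ))
}

#' Classify transcript presence/absence from read support
#'
#' In `unique` mode a line supports a transcript iff at least one read maps
#' uniquely to it (the stringent criterion); in `multi` mode any read —
#' unique or multi-mapped — counts, which additionally rescues transcripts
#' resembling paralogous copies. Transcripts are then categorised by the
#' number of supporting lines: `CORE` (all lines), `DISPENSABLE` (some but
#' not all) and `NO_SUPPORT` (none).
#'
#' @param support A read-support tibble (`transcript_id`, `line_id`,
#'   `unique_reads`, `multi_reads`); absent cells count as zero.
#' @param n_lines Total number of lines in the panel.
#' @param mode `"unique"` (default) or `"multi"`.
#' @return A tibble `transcript_id`, `n_lines_supported`, `category`.
#' @export
classify_support <- function(support, n_lines, mode = c("unique", "multi")) {
  mode <- match.arg(mode)
  assert_cols(support, c("transcript_id", "line_id", "unique_reads",
                         "multi_reads"))
  assert_scalar_number(n_lines, "n_lines", min = 1)
  support |>
    mutate(supported = if (mode == "unique") .data$unique_reads >= 1
           else .data$unique_reads + .data$multi_reads >= 1) |>
    group_by(.data$transcript_id) |>
    summarise(n_lines_supported = sum(.data$supported), .groups = "drop") |>
    mutate(category = dplyr::case_when(
      .data$n_lines_supported == n_lines ~ "CORE",
      .data$n_lines_supported == 0 ~ "NO_SUPPORT",
      TRUE ~ "DISPENSABLE"
    ))
}

#' Group-specific transcript sets
#'
#' In `all_groups` mode a transcript is specific to a pedigree group iff it
#' is present in at least one line of exactly one group and absent from
#' every line of every other group. In `pairwise` mode the line set is
#' first restricted to the two named groups (e.g. the SSS and NSS heterotic
#' groups) and the same rule applied; transcripts present in at least one
#' line of each group are shared.
#'
#' @param presence A tibble `transcript_id`, `line_id`, `present`
#'   (logical). For novel transcripts presence is usually unique-read
#'   support; for annotated genes, the expression call.
#' @param groups A line-group tibble (`line_id`, `group`).
#' @param comparison `"all_groups"` (default) or `"pairwise"`.
#' @param pair For `pairwise`, the two group labels to compare.
#' @return A tibble `transcript_id`, `status` where `status` is a group
#'   label (specific), `"shared"`, or `"absent"`. Group-specific sets for
#'   different groups are disjoint by construction.
#' @export
group_specific_sets <- function(presence, groups,
                                comparison = c("all_groups", "pairwise"),
                                pair = NULL) {
  comparison <- match.arg(comparison)
  assert_cols(presence, c("transcript_id", "line_id", "present"))
  groups <- validate_line_groups(groups)
  if (comparison == "pairwise") {
    if (is.null(pair) || length(pair) != 2L) {
      abort("`pair` must name exactly two groups for a pairwise comparison.")
    }
    groups <- groups |> filter(.data$group %in% pair)
  }
  ungrouped <- setdiff(unique(presence$line_id), groups$line_id)
  if (comparison == "all_groups" && length(ungrouped) > 0L) {
    abort(sprintf("Line(s) without a group assignment: %s.",
                  paste(ungrouped, collapse = ", ")))
  }
  presence |>
    dplyr::inner_join(groups, by = "line_id") |>
    group_by(.data$transcript_id) |>
    summarise(
      groups_present = list(sort(unique(.data$group[.data$present]))),
      .groups = "drop"
    ) |>
    mutate(status = purrr::map_chr(.data$groups_present, function(g) {
      if (length(g) == 0L) "absent"
      else if (length(g) == 1L) g
      else "shared"
    })) |>
    select("transcript_id", "status")
}
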