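#' Expression call from an FPKM confidence interval
#'
#' A gene is considered expressed in a line iff the lower bound of its 95%
#' FPKM confidence interval is strictly greater than zero. The comparison
#' is exact (no epsilon): upstream quantification emits literal zeros for
#' genes not detected as expressed.
#'
#' @param conf_lo Numeric vector of CI lower bounds.
#' @return Logical vector.
#' @export
expression_call <- function(conf_lo) {
  if (any(conf_lo < 0, na.rm = TRUE)) abort("`conf_lo` must be nonnegative.")
  conf_lo > 0
}

#' Semi-quantitative expression category
#'
#' Bins each gene-by-line FPKM record into NONE / LOW / MEDIUM / HIGH:
#' NONE when the CI lower bound equals zero; otherwise LOW for FPKM below
#' 5, MEDIUM for FPKM from 5 to 200 (both boundaries inclusive), and HIGH
#' above 200.
#'
#' @param fpkm Numeric vector of FPKM values.
#' @param conf_lo Numeric vector of CI lower bounds.
#' @param low_cut,high_cut Bin boundaries (defaults 5 and 200; values equal
#'   to either boundary are MEDIUM).
#' @return Factor with levels NONE, LOW, MEDIUM, HIGH.
#' @export
semiquant_category <- function(fpkm, conf_lo, low_cut = 5, high_cut = 200) {
  if (length(fpkm) != length(conf_lo)) {
    abort("`fpkm` and `conf_lo` must have equal length.")
  }
  expressed <- expression_call(conf_lo)
  cat <- dplyr::case_when(
    !expressed ~ "NONE",
    fpkm < low_cut ~ "LOW",
    fpkm <= high_cut ~ "MEDIUM",
    TRUE ~ "HIGH"
  )
  factor(cat, levels = c("NONE", "LOW", "MEDIUM", "HIGH"))
}

#' Classify FPKM records
#'
#' Adds `expressed` and `category` columns to an FPKM record table.
#'
#' @param records An FPKM tibble (see [read_fpkm_table()]).
#' @inheritParams semiquant_category
#' @return The input tibble with `expressed` (logical) and `category`
#'   (factor) columns appended.
#' @export
classify_expression <- function(records, low_cut = 5, high_cut = 200) {
  records <- validate_fpkm_table(records)
  records |>
    mutate(
      expressed = expression_call(.data$conf_lo),
      category = semiquant_category(.data$fpkm, .data$conf_lo,
                                    low_cut, high_cut)
    )
}

#' Densify an FPKM table to a complete gene-by-line grid
#'
#' Core/dispensable accounting needs a record for every gene in every line.
#' Genes absent from a line's quantification are filled in as
#' `(fpkm = 0, conf_lo = 0, conf_hi = 0)` — i.e. not expressed — with a
#' warning.
#'
#' @param records An FPKM tibble.
#' @param genes Optional character vector of all annotated gene ids (the
#'   denominator of per-line percentages); defaults to the genes present.
#' @param lines Optional character vector of all line ids.
#' @return A complete FPKM tibble.
#' @export
densify_fpkm <- function(records, genes = NULL, lines = NULL) {
  records <- validate_fpkm_table(records)
  genes <- genes %||% sort(unique(records$gene_id))
  lines <- lines %||% sort(unique(records$line_id))
  full <- tidyr::expand_grid(gene_id = genes, line_id = lines)
  out <- full |>
    left_join(records, by = c("gene_id", "line_id"))
  n_filled <- sum(is.na(out$fpkm))
  if (n_filled > 0L) {
    warn(sprintf("Filled %d missing gene-by-line cell(s) with (0, 0, 0).",
                 n_filled))
    out <- out |>
      mutate(across(c("fpkm", "conf_lo", "conf_hi"),
                    ~ tidyr::replace_na(.x, 0)))
  }
  out
}

check_complete <- function(records) {
  n_genes <- n_distinct(records$gene_id)
  n_lines <- n_distinct(records$line_id)
  if (nrow(distinct(records, .data$gene_id, .data$line_id)) !=
      n_genes * n_lines || nrow(records) != n_genes * n_lines) {
    abort(paste0("Every gene needs exactly one record per line; ",
                 "use densify_fpkm() to fill absent cells."))
  }
  invisible(records)
}

#' Core/dispensable transcriptome histogram
#'
#' Counts, for each possible number of lines `0..N`, how many genes are
#' expressed (CI lower bound > 0) in exactly that many lines. Genes in the
#' `N` bucket form the core transcriptome, buckets `1..N-1` the dispensable
#' (variable) transcriptome, and bucket 0 the genes never detected as
#' expressed.
#'
#' @param records A complete FPKM tibble (every gene x line cell present;
#'   see [densify_fpkm()]).
#' @return A tibble `n_lines_expressed` (0..N), `n_genes`; the counts sum
#'   to the number of genes. Attributes `n_lines` and `n_genes_total`.
#' @export
core_dispensable_histogram <- function(records) {
  records <- validate_fpkm_table(records)
  check_complete(records)
  n_lines <- n_distinct(records$line_id)
  per_gene <- records |>
    group_by(.data$gene_id) |>
    summarise(n_expr = sum(expression_call(.data$conf_lo)), .groups = "drop")
  out <- per_gene |>
    count(n_lines_expressed = .data$n_expr, name = "n_genes") |>
    tidyr::complete(n_lines_expressed = 0:n_lines,
                    fill = list(n_genes = 0L)) |>
    arrange(.data$n_lines_expressed)
  attr(out, "n_lines") <- n_lines
  attr(out, "n_genes_total") <- nrow(per_gene)
  out
}

#' Summarise a core/dispensable histogram
#'
#' @param histogram Output of [core_dispensable_histogram()].
#' @return One-row tibble with core / dispensable / never-expressed counts
#'   and percentages (0-100 scale).
#' @export
core_dispensable_summary <- function(histogram) {
  n_lines <- attr(histogram, "n_lines")
  total <- sum(histogram$n_genes)
  n_core <- histogram$n_genes[histogram$n_lines_expressed == n_lines]
  n_never <- histogram$n_genes[histogram$n_lines_expressed == 0]
  n_disp <- total - n_core - n_never
  tibble(
    n_genes = total,
    n_core = n_core, pct_core = 100 * n_core / total,
    n_dispensable = n_disp, pct_dispensable = 100 * n_disp / total,
    n_never = n_never, pct_never = 100 * n_never / total
  )
}

#' Constitutive vs. variable expression partition
#'
#' A gene is constitutive when all lines fall in a single semi-quantitative
#' category (including all-NONE); otherwise it is variable. The partition
#' is exhaustive: constitutive counts per category plus the variable count
#' equal the total number of genes.
#'
#' @param records A complete FPKM tibble.
#' @inheritParams semiquant_category
#' @return A tibble with one row per category (NONE, LOW, MEDIUM, HIGH)
#'   giving `n_constitutive`, plus a row `VARIABLE`; attribute `n_genes`.
#' @export
constitutive_variable_partition <- function(records, low_cut = 5,
                                            high_cut = 200) {
  cls <- classify_expression(records, low_cut, high_cut)
  check_complete(cls)
  per_gene <- cls |>
    group_by(.data$gene_id) |>
    summarise(
      cat = if (n_distinct(.data$category) == 1L)
        as.character(.data$category[1]) else "VARIABLE",
      .groups = "drop"
    )
  out <- per_gene |>
    count(.data$cat, name = "n_genes") |>
    tidyr::complete(cat = c("NONE", "LOW", "MEDIUM", "HIGH", "VARIABLE"),
                    fill = list(n_genes = 0L)) |>
    mutate(cat = factor(.data$cat,
                        levels = c("NONE", "LOW", "MEDIUM", "HIGH", "VARIABLE"))) |>
    arrange(.data$cat) |>
    rename(category = "cat")
  attr(out, "n_genes") <- nrow(per_gene)
  out
}

#' Per-line expression summary
#'
#' For each line: the number and percentage of annotated genes expressed,
#' the maximum FPKM value, and the gene attaining it (ties broken by
#' gene id order).
#'
#' @param records A complete FPKM tibble (see [densify_fpkm()]).
#' @return A tibble `line_id`, `n_expressed`, `pct_expressed` (0-100 over
#'   all genes), `max_fpkm`, `max_fpkm_gene`.
#' @export
per_line_summary <- function(records) {
  records <- validate_fpkm_table(records)
  check_complete(records)
  n_genes <- n_distinct(records$gene_id)
  records |>
    arrange(.data$line_id, .data$gene_id) |>
    group_by(.data$line_id) |>
    summarise(
      n_expressed = sum(expression_call(.data$conf_lo)),
      pct_expressed = 100 * .data$n_expressed / n_genes,
      max_fpkm = max(.data$fpkm),
      max_fpkm_gene = .data$gene_id[which.max(.data$fpkm)],
      .groups = "drop"
    )
}
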