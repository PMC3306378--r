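# internal validation helpers

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  if (!is.data.frame(df)) {
    abort(sprintf("`%s` must be a data frame.", what))
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

assert_scalar_number <- function(x, what, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", what, min, max))
  }
  invisible(x)
}

assert_nucleotides <- function(x, what, allow_na = TRUE) {
  bad <- !(x %in% NUCLEOTIDES) & !(allow_na & is.na(x))
  if (any(bad)) {
    abort(sprintf(
      "`%s` contains value(s) outside {A,C,G,T}: %s.",
      what, paste(unique(x[bad]), collapse = ", ")
    ))
  }
  invisible(x)
}

# counts matrix from a base-count table, columns ordered A,C,G,T
count_matrix <- function(tbl) {
  m <- as.matrix(tbl[, c("count_A", "count_C", "count_G", "count_T")])
  storage.mode(m) <- "double"
  colnames(m) <- NUCLEOTIDES
  m
}

# line columns of a wide genotype matrix
gm_lines <- function(gm) {
  attr(gm, "lines") %||%
    setdiff(names(gm), c("chrom", "pos", "confirmed_alleles"))
}
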