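## Likelihood-ratio-test plumbing for branch-specific positive-selection
## scans.  The codon-model fits that produce the per-gene log-likelihoods
## are an external prerequisite; this module turns pairs of nested fits
## into test statistics, p-values and a ranked gene table.

#' Likelihood-ratio test from two nested log-likelihoods
#'
#' Computes `stat = 2 * (lnl_alt - lnl_null)` and its upper-tail
#' chi-square p-value.  Negative raw differences (numerical noise from
#' the optimizers) are clamped to 0 with a warning and flagged.  The
#' degrees of freedom must be supplied explicitly — they depend on which
#' pair of nested codon models was fitted.
#'
#' @param lnl_null,lnl_alt finite log-likelihoods of the null and
#'   alternative model (vectorized).
#' @param df degrees of freedom (positive integer).
#' @param mixture use the 50:50 mixture of a point mass at 0 and
#'   chi-square(df) appropriate when the alternative constrains a
#'   parameter to the boundary; default plain chi-square.
#' @return data.frame with `lnl_null`, `lnl_alt`, `df`, `stat`,
#'   `p_value`, `clamped`.
#' @export
lrt <- function(lnl_null, lnl_alt, df, mixture = FALSE) {
  if (any(!is.finite(lnl_null)) || any(!is.finite(lnl_alt))) {
    stop("log-likelihoods must be finite")
  }
  stopifnot(length(df) == 1L, df >= 1)
  raw <- 2 * (lnl_alt - lnl_null)
  clamped <- raw < 0
  if (any(clamped)) {
    warning(sum(clamped), " negative statistic(s) clamped to 0 ",
            "(alternative fit worse than null)")
  }
  stat <- pmax(0, raw)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  if (mixture) p <- ifelse(stat <= 0, 1, 0.5 * p)
  data.frame(lnl_null = lnl_null, lnl_alt = lnl_alt, df = df,
             stat = stat, p_value = ifelse(stat <= 0, 1, p),
             clamped = clamped)
}

#' Ranked likelihood-ratio tests for a gene table
#'
#' @param table data.frame (or TSV path) with columns `gene_id`,
#'   `lnl_null`, `lnl_alt`.
#' @param df degrees of freedom passed to [lrt()].
#' @param alpha significance level for the `significant` column
#'   (default 0.05).
#' @param mixture see [lrt()].
#' @return data.frame sorted by ascending p-value (ties by gene id) with
#'   a `significant` column.
#' @export
batch_lrt <- function(table, df, alpha = 0.05, mixture = FALSE) {
  if (is.character(table) && length(table) == 1L) {
    table <- utils::read.delim(table, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  }
  need <- c("gene_id", "lnl_null", "lnl_alt")
  if (!all(need %in% names(table))) {
    stop("table must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(table) == 0L) {
    out <- data.frame(gene_id = character(), lnl_null = numeric(),
                      lnl_alt = numeric(), df = numeric(), stat = numeric(),
                      p_value = numeric(), clamped = logical(),
                      significant = logical())
    return(out)
  }
  if (anyDuplicated(table$gene_id)) {
    stop("duplicate gene_id: ",
         paste(unique(table$gene_id[duplicated(table$gene_id)]), collapse = ", "))
  }
  res <- lrt(table$lnl_null, table$lnl_alt, df, mixture)
  res <- cbind(gene_id = table$gene_id, res)
  res$significant <- res$p_value < alpha
  res <- res[order(res$p_value, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
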