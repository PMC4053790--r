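## Synonymous/non-synonymous site and substitution counting on pairwise
## in-frame codon alignments.  Equal-weight pathway counting in the
## Nei-Gojobori tradition: sites apportion each codon position by the
## fraction of its three single-base mutants that are synonymous (changes
## to stop codons are non-synonymous); substitutions between codons
## differing at several positions are averaged over all orderings of
## single-base steps, excluding orderings that pass through a stop codon.

#' Synonymous and non-synonymous site counts for sense codons
#'
#' Apportions the 3 positions of each codon into synonymous and
#' non-synonymous "sites": each position contributes the fraction of its
#' three alternative bases whose substitution leaves the amino acid
#' unchanged.  Mutations to stop codons count as non-synonymous, so for
#' every sense codon `syn_sites + nonsyn_sites == 3`.
#'
#' @param codon character vector of codons over A/C/G/T (case-insensitive).
#' @return data.frame with columns `codon`, `syn_sites`, `nonsyn_sites`.
#' @examples
#' count_sites("TTT")  # 1/3 synonymous, 8/3 non-synonymous
#' count_sites("TGG")  # Trp: every mutant changes the protein
#' @export
count_sites <- function(codon) {
  codon <- toupper(as.character(codon))
  tabs <- codon_tables()
  bad <- !grepl("^[ACGT]{3}$", codon)
  if (any(bad)) {
    stop("not an unambiguous codon: ", paste(unique(codon[bad]), collapse = ", "))
  }
  if (any(tabs$aa[codon] == "*")) {
    stop("stop codon has no site decomposition: ",
         paste(unique(codon[tabs$aa[codon] == "*"]), collapse = ", "))
  }
  data.frame(codon = codon,
             syn_sites = unname(tabs$syn_sites[codon]),
             nonsyn_sites = unname(tabs$nonsyn_sites[codon]))
}

#' Pathway-averaged substitution counts between two sense codons
#'
#' For codon pairs differing at d positions, the d! orderings of
#' single-base steps are enumerated; each step is synonymous when it
#' preserves the amino acid.  Orderings whose intermediate codons are
#' stops are excluded from the average (if every ordering passes through
#' a stop, all are used, with steps touching a stop classed
#' non-synonymous).  `syn_subs + nonsyn_subs` equals the number of
#' differing positions.
#'
#' @param codon_a,codon_b character vectors of sense codons (recycled to
#'   a common length).
#' @return data.frame with columns `codon_a`, `codon_b`, `syn_subs`,
#'   `nonsyn_subs`.
#' @examples
#' count_substitutions("TTT", "TTC")  # Phe -> Phe: one synonymous change
#' count_substitutions("TTT", "GTA")  # two pathways averaged: 0.5 / 1.5
#' @export
count_substitutions <- function(codon_a, codon_b) {
  codon_a <- toupper(as.character(codon_a))
  codon_b <- toupper(as.character(codon_b))
  n <- max(length(codon_a), length(codon_b))
  codon_a <- rep_len(codon_a, n)
  codon_b <- rep_len(codon_b, n)
  ok <- .is_sense(codon_a) & .is_sense(codon_b)
  if (any(!ok)) {
    stop("non-sense or ambiguous codon in pair: ",
         paste(unique(paste(codon_a[!ok], codon_b[!ok])), collapse = "; "))
  }
  tabs <- codon_tables()
  data.frame(codon_a = codon_a, codon_b = codon_b,
             syn_subs = tabs$sub_syn[cbind(codon_a, codon_b)],
             nonsyn_subs = tabs$sub_nonsyn[cbind(codon_a, codon_b)])
}

#' Construct a pairwise codon alignment object
#'
#' @param gene_id single gene identifier.
#' @param seq_a,seq_b aligned nucleotide strings of equal length, a
#'   multiple of 3, over A/C/G/T/N/`-`.  Gaps must fill whole codons.
#' @return object of class `codon_alignment`.
#' @export
codon_alignment <- function(gene_id, seq_a, seq_b) {
  seq_a <- toupper(as.character(seq_a))
  seq_b <- toupper(as.character(seq_b))
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("gene ", gene_id, ": aligned sequences differ in length")
  }
  if (nchar(seq_a) %% 3L != 0L) {
    stop("gene ", gene_id, ": alignment length not a multiple of 3")
  }
  if (grepl("[^ACGTN-]", seq_a) || grepl("[^ACGTN-]", seq_b)) {
    stop("gene ", gene_id, ": alphabet must be A,C,G,T,N,-")
  }
  for (s in c(seq_a, seq_b)) {
    cod <- .split_codons(s)
    partial <- grepl("-", cod) & cod != "---"
    if (any(partial)) {
      stop("gene ", gene_id, ": gap does not fill a whole codon (codon ",
           which(partial)[1], ")")
    }
  }
  structure(list(gene_id = as.character(gene_id), seq_a = seq_a, seq_b = seq_b),
            class = "codon_alignment")
}

.split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Per-gene substitution and site counts from a codon alignment
#'
#' Codon columns containing a gap, an ambiguous base, or a stop codon in
#' either sequence are skipped and excluded from `codons_used`.  Site
#' counts are averaged over the two sequences; substitution counts are
#' pathway-averaged per column and summed.
#'
#' @param alignment a [codon_alignment()] object.
#' @return one-row data.frame with columns `gene_id`, `a` (non-synonymous
#'   substitutions), `A` (non-synonymous sites), `s`, `S`, `codons_used`,
#'   `usable`.  A gene with zero retained codons has `usable = FALSE` and
#'   `NA` counts.
#' @export
count_gene <- function(alignment) {
  stopifnot(inherits(alignment, "codon_alignment"))
  tabs <- codon_tables()
  ca <- .split_codons(alignment$seq_a)
  cb <- .split_codons(alignment$seq_b)
  keep <- .is_sense(ca) & .is_sense(cb)
  used <- sum(keep)
  if (used == 0L) {
    return(data.frame(gene_id = alignment$gene_id, a = NA_real_, A = NA_real_,
                      s = NA_real_, S = NA_real_, codons_used = 0L,
                      usable = FALSE))
  }
  ca <- ca[keep]; cb <- cb[keep]
  a <- sum(tabs$sub_nonsyn[cbind(ca, cb)])
  s <- sum(tabs$sub_syn[cbind(ca, cb)])
  S <- sum(tabs$syn_sites[ca] + tabs$syn_sites[cb]) / 2
  A <- 3 * used - S
  data.frame(gene_id = alignment$gene_id, a = a, A = A, s = s, S = S,
              codons_used = used, usable = TRUE)
}

#' Count a collection of codon alignments
#'
#' @param alignments list of [codon_alignment()] objects.
#' @param drop_unusable drop genes with zero retained codons (with a
#'   message) instead of keeping their `NA` rows.
#' @return data.frame of per-gene counts (one row per gene), with the
#'   derived rates added by [gene_rates()].
#' @export
count_alignments <- function(alignments, drop_unusable = TRUE) {
  rows <- lapply(alignments, count_gene)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (drop_unusable && any(!out$usable)) {
    message(sum(!out$usable), " gene(s) with zero usable codons dropped: ",
            paste(utils::head(out$gene_id[!out$usable], 5), collapse = ", "))
    out <- out[out$usable, , drop = FALSE]
  }
  gene_rates(out)
}

#' Per-gene Ka, Ks and their ratio
#'
#' Adds `ka = a/A`, `ks = s/S` and `ka_ks` to a counts table.  `ka_ks` is
#' `NA` (with `ks_zero = TRUE`) for genes without observed synonymous
#' substitutions; these raw proportions are what the category statistic
#' consumes (see [jukes_cantor()] for a corrected per-gene distance).
#'
#' @param counts data.frame with columns `gene_id`, `a`, `A`, `s`, `S`.
#' @return the input with `ka`, `ks`, `ka_ks`, `ks_zero` columns added.
#' @export
gene_rates <- function(counts) {
  counts$ka <- counts$a / counts$A
  counts$ks <- counts$s / counts$S
  counts$ks_zero <- !is.na(counts$ks) & counts$ks == 0
  counts$ka_ks <- ifelse(counts$ks_zero, NA_real_, counts$ka / counts$ks)
  counts
}

#' Jukes-Cantor correction for multiple hits
#'
#' Converts an observed proportion of substitutions per site into an
#' expected number of substitutions per site under the one-parameter
#' substitution model: `-(3/4) * log(1 - 4p/3)`.
#'
#' @param p numeric vector of observed proportions, `0 <= p < 3/4`.
#' @return corrected distances.
#' @export
jukes_cantor <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 0.75)) {
    stop("proportion must satisfy 0 <= p < 3/4")
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Read paired codon alignments from aligned FASTA
#'
#' Accepts a multi-FASTA in which each gene appears as two records named
#' `geneID|speciesA` and `geneID|speciesB`, or a file of exactly two
#' records (one gene; names taken verbatim as `gene|species` or the first
#' record's name as gene id).
#'
#' @param path FASTA file of aligned coding sequences.
#' @return named list of [codon_alignment()] objects.
#' @export
read_codon_alignments <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- names(seqs)
  nm <- sub("\\s.*$", "", nm)
  if (length(seqs) == 0L) stop("no sequences in ", path)
  has_pipe <- grepl("|", nm, fixed = TRUE)
  if (all(has_pipe)) {
    gene <- sub("\\|.*$", "", nm)
  } else if (length(seqs) == 2L) {
    gene <- rep(nm[1], 2)
  } else {
    stop("record names must follow 'geneID|species' in multi-gene FASTA: ", path)
  }
  split_idx <- split(seq_along(seqs), gene)
  out <- lapply(names(split_idx), function(g) {
    idx <- split_idx[[g]]
    if (length(idx) != 2L) {
      stop("gene ", g, " has ", length(idx), " records (need exactly 2) in ", path)
    }
    codon_alignment(g, as.character(seqs[[idx[1]]]), as.character(seqs[[idx[2]]]))
  })
  names(out) <- names(split_idx)
  out[unique(gene)]
}

#' Read a per-gene substitution-count table
#'
#' Imports externally estimated counts (for example from a codon
#' maximum-likelihood run) as the per-gene `(a, A, s, S)` quantities the
#' category statistic consumes.
#'
#' @param path TSV with header columns `gene_id`, `a`, `A`, `s`, `S`
#'   (extra columns ignored).
#' @return data.frame of validated counts with rates added; rows
#'   violating the invariants (negative counts, non-positive sites,
#'   duplicated gene ids) are rejected with a per-row diagnostic.
#' @export
read_counts_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "a", "A", "s", "S")
  if (nrow(df) == 0L) {
    warning("empty counts table: ", path)
    empty <- data.frame(gene_id = character(), a = numeric(), A = numeric(),
                        s = numeric(), S = numeric())
    return(gene_rates(empty))
  }
  if (!all(need %in% names(df))) {
    stop("counts table must have header columns ", paste(need, collapse = ", "))
  }
  for (col in c("a", "A", "s", "S")) df[[col]] <- as.numeric(df[[col]])
  bad <- !is.finite(df$a) | !is.finite(df$s) | !is.finite(df$A) | !is.finite(df$S) |
    df$a < 0 | df$s < 0 | df$A <= 0 | df$S <= 0 | duplicated(df$gene_id)
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected (negative counts, non-positive sites, ",
            "or duplicate gene ids): rows ",
            paste(utils::head(which(bad), 10), collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  gene_rates(df[need])
}

#' Write a per-gene counts table
#'
#' @param counts data.frame from [count_alignments()] or
#'   [read_counts_table()].
#' @param path output TSV path.
#' @export
write_counts_table <- function(counts, path) {
  keep <- intersect(c("gene_id", "a", "A", "s", "S", "ka", "ks", "ka_ks",
                      "codons_used"), names(counts))
  out <- counts[keep]
  # 17 significant digits so the written doubles read back bit-identical
  for (col in keep) {
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
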