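## Codon-level simulator for genome-scale ortholog sets with plantable
## category effects.  Each gene pair descends from a uniform-random
## sense-codon ancestor; the two lineages evolve independently by
## single-base proposals (transitions weighted kappa : 1 over
## transversions).  Synonymous proposals are always accepted,
## non-synonymous proposals with probability min(1, omega), and
## proposals creating stop codons are rejected, so sequences stay
## coding.  Each lineage stops after a Poisson(dS_target * S_ancestor)
## number of accepted synonymous substitutions, which targets the
## requested synonymous divergence per synonymous site per lineage.

#' Simulation configuration for a synthetic ortholog set
#'
#' Defaults describe a songbird-scale pairwise comparison: coding genes
#' of 100-500 codons, per-lineage synonymous divergence 0.1
#' substitutions per synonymous site, genome-background omega 0.15, and
#' transition/transversion rate ratio 2.
#'
#' @param n_genes number of ortholog gene pairs.
#' @param length_range inclusive range (codons) from which gene lengths
#'   are drawn uniformly.
#' @param dS_target expected synonymous substitutions per synonymous
#'   site per lineage (must be < 0.75).
#' @param omega0 baseline non-synonymous/synonymous rate ratio.
#' @param kappa transition/transversion rate ratio of the proposal
#'   process.
#' @param categories data.frame with columns `term_id`, `n_genes`,
#'   `multiplier` describing planted annotation categories; a gene in a
#'   category evolves with omega multiplied by the category's
#'   multiplier (product over categories for overlapping membership).
#' @param n_unannotated number of extra genes carrying no annotation
#'   (they stay in the permutation universe with empty term sets).
#' @param disjoint draw category memberships disjointly (default) or
#'   independently, allowing overlap.
#' @param seed RNG seed recorded in the config and applied by
#'   [simulate_dataset()].
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 1000L,
                              length_range = c(100L, 500L),
                              dS_target = 0.1, omega0 = 0.15, kappa = 2,
                              categories = NULL, n_unannotated = 0L,
                              disjoint = TRUE, seed = 1L) {
  stopifnot(n_genes >= 1, dS_target >= 0, dS_target < 0.75, omega0 >= 0,
            kappa > 0, length(length_range) == 2L,
            length_range[1] >= 1, length_range[2] >= length_range[1])
  if (!is.null(categories)) {
    stopifnot(all(c("term_id", "n_genes", "multiplier") %in% names(categories)),
              all(categories$multiplier > 0),
              all(categories$n_genes <= n_genes))
    if (disjoint && sum(categories$n_genes) > n_genes) {
      stop("disjoint categories need sum(n_genes) <= n_genes")
    }
  }
  structure(list(n_genes = as.integer(n_genes),
                 length_range = as.integer(length_range),
                 dS_target = dS_target, omega0 = omega0, kappa = kappa,
                 categories = categories,
                 n_unannotated = as.integer(n_unannotated),
                 disjoint = isTRUE(disjoint), seed = as.integer(seed)),
            class = "simulation_config")
}

## Evolve one lineage: codon-index vector -> codon-index vector.
.evolve_lineage <- function(cod, n_syn_target, omega, kappa, tabs) {
  if (n_syn_target <= 0L) return(cod)
  accept_nonsyn <- min(1, omega)
  s_done <- 0L
  L <- length(cod)
  repeat {
    i <- sample.int(L, 1L)
    pos <- sample.int(3L, 1L)
    cols <- (pos - 1L) * 3L + 1:3
    w <- ifelse(tabs$nb_ts[cod[i], cols], kappa, 1)
    j <- cols[sample.int(3L, 1L, prob = w)]
    if (tabs$nb_stop[cod[i], j]) next
    if (tabs$nb_syn[cod[i], j]) {
      cod[i] <- tabs$nb_codon[cod[i], j]
      s_done <- s_done + 1L
      if (s_done >= n_syn_target) break
    } else if (accept_nonsyn > 0 && stats::runif(1) < accept_nonsyn) {
      cod[i] <- tabs$nb_codon[cod[i], j]
    }
  }
  cod
}

#' Simulate one pairwise codon alignment
#'
#' See the module description for the generative scheme.  Randomness
#' comes from R's global RNG; seed with [set.seed()] (or use
#' [simulate_dataset()], which seeds from its config).
#'
#' @param length gene length in codons.
#' @param omega non-synonymous acceptance ratio (effective value is
#'   `min(1, omega)`).
#' @param dS_target expected synonymous substitutions per synonymous
#'   site per lineage.
#' @param kappa transition/transversion rate ratio.
#' @param gene_id identifier for the returned alignment.
#' @return a [codon_alignment()] object (ungapped by construction).
#' @export
simulate_gene_pair <- function(length, omega, dS_target, kappa = 2,
                               gene_id = "gene") {
  stopifnot(length >= 1, omega >= 0, dS_target >= 0, dS_target < 0.75,
            kappa > 0)
  tabs <- codon_tables()
  sense_idx <- unname(tabs$codon_index[tabs$sense])
  anc <- sample(sense_idx, length, replace = TRUE)
  S_anc <- sum(tabs$syn_sites[anc])
  seqs <- lapply(1:2, function(k) {
    n_syn <- stats::rpois(1L, dS_target * S_anc)
    .evolve_lineage(anc, n_syn, omega, kappa, tabs)
  })
  codon_alignment(gene_id,
                  paste(tabs$codons[seqs[[1]]], collapse = ""),
                  paste(tabs$codons[seqs[[2]]], collapse = ""))
}

#' Simulate a full synthetic ortholog dataset
#'
#' Draws gene lengths, assigns planted category memberships, evolves
#' every gene pair at `omega0` times the product of its categories'
#' multipliers, and returns the alignments together with the annotation
#' and a truth table.  Fully reproducible from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with elements `alignments` (named list of
#'   [codon_alignment()]), `annotation` ([go_annotation()] over all
#'   genes, planted plus unannotated), `truth` (list of data.frames
#'   `genes` — gene_id, length, omega — and `categories` — term_id,
#'   n_genes, multiplier, direction rapid/slow/null), and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_total <- config$n_genes + config$n_unannotated
  gene_ids <- sprintf("g%05d", seq_len(n_total))
  lens <- sample(config$length_range[1]:config$length_range[2], n_total,
                 replace = TRUE)

  sets <- stats::setNames(rep(list(character()), n_total), gene_ids)
  omega <- rep(config$omega0, n_total)
  truth_cat <- NULL
  if (!is.null(config$categories)) {
    cats <- config$categories
    annotatable <- gene_ids[seq_len(config$n_genes)]
    pool <- sample(annotatable)
    for (k in seq_len(nrow(cats))) {
      size <- cats$n_genes[k]
      members <- if (config$disjoint) {
        picked <- pool[seq_len(size)]
        pool <- pool[-seq_len(size)]
        picked
      } else {
        sample(annotatable, size)
      }
      for (g in members) sets[[g]] <- c(sets[[g]], cats$term_id[k])
      omega[match(members, gene_ids)] <-
        omega[match(members, gene_ids)] * cats$multiplier[k]
    }
    truth_cat <- data.frame(
      term_id = cats$term_id, n_genes = cats$n_genes,
      multiplier = cats$multiplier,
      direction = ifelse(cats$multiplier > 1, "rapid",
                         ifelse(cats$multiplier < 1, "slow", "null")))
  }

  alignments <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    alignments[[i]] <- simulate_gene_pair(lens[i], omega[i], config$dS_target,
                                          config$kappa, gene_ids[i])
  }
  names(alignments) <- gene_ids

  list(alignments = alignments,
       annotation = go_annotation(sets, gene_ids),
       truth = list(genes = data.frame(gene_id = gene_ids, length = lens,
                                       omega = omega),
                    categories = truth_cat),
       config = config)
}

#' Write a simulated dataset to pipeline input files
#'
#' Emits the aligned multi-FASTA (`alignments.fasta`, records
#' `geneID|spA` / `geneID|spB`), the annotation TSV
#' (`annotation.tsv`), truth tables (`truth_genes.tsv`,
#' `truth_categories.tsv`) and a JSON config snapshot
#' (`sim_config.json`).
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- unlist(lapply(unname(dataset$alignments), function(al) {
    stats::setNames(c(al$seq_a, al$seq_b),
                    paste0(al$gene_id, c("|spA", "|spB")))
  }))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs),
                              file.path(dir, "alignments.fasta"))
  ann <- dataset$annotation
  gene <- rep(names(ann$sets), lengths(ann$sets))
  term <- unlist(ann$sets, use.names = FALSE)
  writeLines(if (length(gene) > 0) paste(gene, term, sep = "\t") else character(),
             file.path(dir, "annotation.tsv"))
  utils::write.table(dataset$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$truth$categories)) {
    utils::write.table(dataset$truth$categories,
                       file.path(dir, "truth_categories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- dataset$config
  jsonlite::write_json(cfg[setdiff(names(cfg), "categories")],
                       file.path(dir, "sim_config.json"), auto_unbox = TRUE)
  invisible(dir)
}
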