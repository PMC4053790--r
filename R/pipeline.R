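## End-to-end orchestration: read (or take) alignments and annotation,
## count, test every category, run the permutation null, and write the
## result bundle with reproducible run metadata.

#' Validate pipeline input files
#'
#' Schema-checks each supplied file and returns a findings table; fatal
#' findings mean the pipeline would refuse the file.
#'
#' @param alignments optional aligned FASTA path.
#' @param counts optional per-gene counts TSV path.
#' @param annotation optional annotation TSV path.
#' @param mappings optional transcript-mapping TSV path.
#' @return data.frame with columns `file`, `level` (`"fatal"` or
#'   `"warning"`), `message`; zero rows when everything validates.
#' @export
validate_inputs <- function(alignments = NULL, counts = NULL,
                            annotation = NULL, mappings = NULL) {
  findings <- list()
  note <- function(file, level, msg) {
    findings[[length(findings) + 1L]] <<- data.frame(file = file, level = level,
                                                     message = msg)
  }
  check_file <- function(path, what, reader) {
    if (!file.exists(path)) {
      note(path, "fatal", paste(what, "file does not exist"))
      return()
    }
    res <- tryCatch(withCallingHandlers(
      reader(path),
      warning = function(w) {
        note(path, "warning", conditionMessage(w))
        invokeRestart("muffleWarning")
      }), error = function(e) e)
    if (inherits(res, "error")) note(path, "fatal", conditionMessage(res))
  }
  if (!is.null(alignments)) {
    check_file(alignments, "alignment FASTA", read_codon_alignments)
  }
  if (!is.null(counts)) check_file(counts, "counts TSV", read_counts_table)
  if (!is.null(annotation)) {
    check_file(annotation, "annotation TSV", function(p) {
      suppressMessages(read_go_annotation(p, universe = unique(
        vapply(strsplit(readLines(p), "\t"), `[[`, character(1), 1L))))
    })
  }
  if (!is.null(mappings)) check_file(mappings, "mappings TSV", read_mappings)
  if (length(findings) == 0L) {
    return(data.frame(file = character(), level = character(),
                      message = character()))
  }
  do.call(rbind, findings)
}

#' Run the full category divergence analysis
#'
#' Counts substitutions on the alignments (or imports a precomputed
#' counts table), reads and size-filters the annotation, computes the
#' genome-wide rates and per-category binomial tails, scans the outlier
#' thresholds, runs the annotation-permutation null, and writes the
#' result bundle to `out_dir`:
#' `counts.tsv`, `category_results.tsv`, `permutation_summary.tsv`,
#' `report.txt` and `run_metadata.json`.
#'
#' @param alignments aligned FASTA path, or a list of
#'   [codon_alignment()] objects; ignored when `counts` is given.
#' @param annotation annotation TSV path or a [go_annotation()] object.
#' @param out_dir output directory (created).
#' @param counts optional precomputed counts: TSV path or data.frame.
#' @param thresholds outlier thresholds to scan.
#' @param n_permutations permutations for the null (default 10000).
#' @param min_genes minimum category size (default 20).
#' @param seed RNG seed for the permutation null (required).
#' @param namespace optional annotation namespace filter (third TSV
#'   column), e.g. `"molecular_function"`.
#' @return list with `counts`, `rates`, `results`, `summary` (all also
#'   written to `out_dir`), invisibly.
#' @export
run_pipeline <- function(alignments = NULL, annotation, out_dir,
                         counts = NULL,
                         thresholds = c(0.05, 0.01, 0.001, 0.0001),
                         n_permutations = 10000L, min_genes = 20L, seed,
                         namespace = NULL) {
  if (missing(seed)) stop("stage config: an explicit seed is required")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  counts_df <- stage("count", {
    if (!is.null(counts)) {
      if (is.character(counts)) read_counts_table(counts) else gene_rates(counts)
    } else if (is.character(alignments)) {
      count_alignments(read_codon_alignments(alignments))
    } else if (is.list(alignments)) {
      count_alignments(alignments)
    } else {
      stop("either alignments or counts must be supplied")
    }
  })

  ann <- stage("annotation", {
    if (inherits(annotation, "go_annotation")) {
      annotation
    } else {
      read_go_annotation(annotation, universe = counts_df$gene_id,
                         namespace = namespace)
    }
  })

  rates <- stage("rates", genome_rates(counts_df))
  categories <- stage("categories", build_categories(ann, min_genes))
  results <- stage("test", test_categories(counts_df, categories, rates))
  summary_df <- stage("permute",
                      permutation_null(counts_df, ann, thresholds,
                                       n_permutations, seed, min_genes))

  stage("write", {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_counts_table(counts_df, file.path(out_dir, "counts.tsv"))
    res_out <- results[order(results$p_rapid), ]
    utils::write.table(format(res_out, digits = 15, scientific = NA,
                              trim = TRUE),
                       file.path(out_dir, "category_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(summary_df),
                       file.path(out_dir, "permutation_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(format_report(rates, results, summary_df),
               file.path(out_dir, "report.txt"))
    jsonlite::write_json(
      list(seed = seed, n_permutations = n_permutations,
           thresholds = thresholds, min_genes = min_genes,
           n_genes = nrow(counts_df), n_categories = nrow(results),
           genome_ka = rates$ka, genome_ks = rates$ks,
           counts_digest = .digest_table(counts_df)),
      file.path(out_dir, "run_metadata.json"),
      auto_unbox = TRUE, digits = NA)
  })

  invisible(list(counts = counts_df, rates = rates, results = results,
                 summary = summary_df))
}

## Small stable digest for provenance (sum-based; not cryptographic).
.digest_table <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  sprintf("%dx%d:%.10g", nrow(df), ncol(df),
          sum(vapply(df[num], sum, numeric(1))))
}

#' Human-readable observed-vs-expected report
#'
#' @param rates [genome_rates()] object.
#' @param results per-category results from [test_categories()].
#' @param summary a [permutation_null()] summary.
#' @return character vector of report lines.
#' @export
format_report <- function(rates, results, summary) {
  lines <- c(
    sprintf("Genome-wide rates over %d genes: ka = %.5g, ks = %.5g, ka/ks = %.4g",
            rates$n_genes, rates$ka, rates$ks, rates$ka_ks),
    sprintf("%d categories tested", nrow(results)),
    "")
  for (k in seq_len(nrow(summary))) {
    r <- summary[k, ]
    lines <- c(lines, sprintf(
      "%-5s P < %-7g: %d categories observed, %.2f expected by permutation (global P %s %.4g)",
      r$direction, r$threshold, r$observed, r$expected,
      if (r$global_p_raw == 0) "<" else "=",
      if (r$global_p_raw == 0) 1 / r$n_permutations else r$global_p_raw))
  }
  lines
}
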