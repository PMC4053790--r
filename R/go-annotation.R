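## Gene -> GO-term annotation handling: parsing, the minimum-size
## category filter, and the term-set-atomic permutation used for the
## null distribution of outlier category counts.

#' Construct a gene annotation object
#'
#' Stores, for every gene in the ortholog universe, its full
#' (deduplicated) set of annotation terms.  Genes without annotations are
#' carried explicitly with empty sets, so they participate in the
#' annotation permutation.
#'
#' @param sets named list mapping gene id to a character vector of term
#'   ids; genes in `universe` absent from `sets` get empty sets.
#' @param universe character vector of gene ids (the ortholog set T).
#' @return object of class `go_annotation`.
#' @export
go_annotation <- function(sets, universe = names(sets)) {
  universe <- unique(as.character(universe))
  full <- stats::setNames(vector("list", length(universe)), universe)
  for (g in universe) {
    full[[g]] <- if (g %in% names(sets)) sort(unique(as.character(sets[[g]]))) else character()
  }
  structure(list(sets = full, universe = universe), class = "go_annotation")
}

#' @exportS3Method base::print
print.go_annotation <- function(x, ...) {
  n_ann <- sum(lengths(x$sets) > 0)
  cat("go_annotation: ", length(x$universe), " genes in universe, ",
      n_ann, " annotated, ",
      length(unique(unlist(x$sets))), " distinct terms\n", sep = "")
  invisible(x)
}

#' Read a gene -> term annotation table
#'
#' Expects a headerless two- or three-column TSV: `gene_id`, `term_id`,
#' and optionally `namespace` (e.g. `molecular_function`) used for
#' filtering.  Terms are assumed already propagated to ancestors
#' upstream; duplicates are removed; genes outside the universe are
#' dropped with a message.
#'
#' @param path annotation TSV.
#' @param universe gene ids of the ortholog set; the mapping is
#'   restricted to it.
#' @param namespace optional value the third column must equal.
#' @return a [go_annotation()] object over `universe`.
#' @export
read_go_annotation <- function(path, universe, namespace = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty annotation file: ", path)
    return(go_annotation(list(), universe))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2L)
  if (length(bad) > 0L) {
    stop("malformed annotation line ", bad[1], " in ", path,
         " (need at least 2 tab-separated fields)")
  }
  gene <- vapply(parts, `[[`, character(1), 1L)
  term <- vapply(parts, `[[`, character(1), 2L)
  if (!is.null(namespace)) {
    ns <- vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else NA_character_,
                 character(1))
    keep <- !is.na(ns) & ns == namespace
    gene <- gene[keep]; term <- term[keep]
  }
  inside <- gene %in% universe
  if (any(!inside)) {
    message(length(unique(gene[!inside])),
            " annotated gene(s) outside the ortholog universe dropped")
  }
  gene <- gene[inside]; term <- term[inside]
  go_annotation(split(term, gene), universe)
}

#' Build minimum-size GO categories from an annotation
#'
#' One category per term annotated to at least `min_genes` genes of the
#' universe; smaller terms are dropped.
#'
#' @param annotation a [go_annotation()] object.
#' @param min_genes minimum category size (default 20).
#' @return object of class `go_categories`: a named list of member gene
#'   id vectors, with `min_genes` stored as an attribute.
#' @export
build_categories <- function(annotation, min_genes = 20L) {
  stopifnot(inherits(annotation, "go_annotation"))
  g <- rep(names(annotation$sets), lengths(annotation$sets))
  t <- unlist(annotation$sets, use.names = FALSE)
  members <- if (length(t) > 0L) split(g, t) else list()
  members <- members[lengths(members) >= min_genes]
  members <- lapply(members, sort)
  structure(members, class = "go_categories", min_genes = as.integer(min_genes))
}

#' @exportS3Method base::print
print.go_categories <- function(x, ...) {
  cat("go_categories: ", length(x), " categories of >= ",
      attr(x, "min_genes"), " genes\n", sep = "")
  invisible(x)
}

#' Summarise categories as a data.frame
#'
#' @param x a `go_categories` object.
#' @param row.names,optional,... passed over from the generic (unused).
#' @return data.frame with `term_id`, `n_genes`, `gene_ids`
#'   (comma-joined).
#' @exportS3Method base::as.data.frame
as.data.frame.go_categories <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(term_id = names(x), n_genes = lengths(x),
             gene_ids = vapply(x, paste, character(1), collapse = ","),
             row.names = row.names)
}

#' Permute an annotation, keeping per-gene term sets together
#'
#' Reassigns whole per-gene term sets to genes by a uniform random
#' permutation of the universe.  Because sets move atomically, every
#' term's gene count — and therefore the identity of the categories
#' passing the size filter — is invariant; only memberships change.
#' Randomness comes from R's global RNG: seed with [set.seed()] for
#' reproducibility.
#'
#' @param annotation a [go_annotation()] object.
#' @return a permuted `go_annotation` over the same universe.
#' @export
permute_annotation <- function(annotation) {
  stopifnot(inherits(annotation, "go_annotation"))
  n <- length(annotation$universe)
  sets <- annotation$sets[sample.int(n)]
  names(sets) <- annotation$universe
  structure(list(sets = sets, universe = annotation$universe),
            class = "go_annotation")
}

#' Write category memberships to TSV
#'
#' @param categories a `go_categories` object.
#' @param path output TSV path.
#' @export
write_categories <- function(categories, path) {
  utils::write.table(as.data.frame(categories), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
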