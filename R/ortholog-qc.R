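## Ortholog coding-sequence quality control: the four mapping filters
## (coverage, low-quality fraction, frameshift compensation, premature
## stop / splice conservation), longest-transcript selection and the
## required-species check.

#' Cluster indels for frameshift-compensation checking
#'
#' Indels whose start positions lie within `window` bases of the next
#' indel are merged transitively into clusters; each cluster carries the
#' sum of its signed lengths.  A cluster whose net length is a multiple
#' of 3 restores the reading frame and is treated as compensated.
#'
#' @param positions 0-based CDS offsets of the indels.
#' @param lengths signed indel lengths (+insertion / -deletion).
#' @param window maximum start-to-start distance joining two indels into
#'   one cluster (default 15 bases).
#' @return data.frame with one row per cluster: `start`, `end`,
#'   `n_indels`, `net_length`, `in_frame` (net a multiple of 3).
#' @export
cluster_indels <- function(positions, lengths, window = 15L) {
  stopifnot(length(positions) == length(lengths))
  if (length(positions) == 0L) {
    return(data.frame(start = integer(), end = integer(), n_indels = integer(),
                      net_length = integer(), in_frame = logical()))
  }
  ord <- order(positions)
  positions <- positions[ord]; lengths <- lengths[ord]
  new_cluster <- c(TRUE, diff(positions) > window)
  id <- cumsum(new_cluster)
  out <- data.frame(
    start = as.vector(tapply(positions, id, min)),
    end = as.vector(tapply(positions, id, max)),
    n_indels = as.vector(tapply(positions, id, length)),
    net_length = as.vector(tapply(lengths, id, sum)))
  out$in_frame <- out$net_length %% 3L == 0L
  out
}

.parse_indels <- function(spec) {
  if (is.na(spec) || spec == "" || spec == ".") {
    return(data.frame(position = integer(), length = integer()))
  }
  parts <- strsplit(strsplit(spec, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("malformed indel spec: ", spec)
  data.frame(position = as.integer(vapply(parts, `[[`, character(1), 1L)),
             length = as.integer(vapply(parts, `[[`, character(1), 2L)))
}

#' Apply the four ortholog mapping filters
#'
#' A transcript mapping passes when (a) the mapped regions cover at
#' least `min_coverage` of the coding region, (b) at most `max_lowqual`
#' of the coding region is in sequence gaps or low-quality sequence,
#' (c) it has no frameshift indels except those compensated within
#' `window` bases (every indel cluster's net length is a multiple of 3),
#' and (d) it has no in-frame stop codon and all splice sites are
#' conserved.  Both boundaries are inclusive.  Criteria are evaluated
#' independently and all failures recorded.
#'
#' @param mappings data.frame of transcript mappings with columns
#'   `transcript_id`, `gene_id`, `coding_length`, `coverage_fraction`,
#'   `lowqual_fraction`, `indels` (comma-joined `pos:len`, empty or `.`
#'   for none), `in_frame_stop`, `splice_sites_conserved`.
#' @param min_coverage criterion (a) bound, default 0.80.
#' @param max_lowqual criterion (b) bound, default 0.10.
#' @param window criterion (c) compensation window in bases, default 15.
#' @return the input with `passed` (logical) and `failed_criteria`
#'   (comma-joined subset of `a,b,c,d`, empty when passed) appended.
#' @export
check_mapping <- function(mappings, min_coverage = 0.80, max_lowqual = 0.10,
                          window = 15L) {
  need <- c("transcript_id", "gene_id", "coding_length", "coverage_fraction",
            "lowqual_fraction", "indels", "in_frame_stop",
            "splice_sites_conserved")
  if (!all(need %in% names(mappings))) {
    stop("mappings must have columns ", paste(need, collapse = ", "))
  }
  stopifnot(all(mappings$coding_length > 0),
            all(mappings$coverage_fraction >= 0 & mappings$coverage_fraction <= 1),
            all(mappings$lowqual_fraction >= 0 & mappings$lowqual_fraction <= 1))
  fails <- vapply(seq_len(nrow(mappings)), function(i) {
    m <- mappings[i, ]
    f <- character()
    if (m$coverage_fraction < min_coverage) f <- c(f, "a")
    if (m$lowqual_fraction > max_lowqual) f <- c(f, "b")
    ind <- .parse_indels(m$indels)
    if (any(ind$position < 0 | ind$position >= m$coding_length)) {
      stop("indel position outside coding region for ", m$transcript_id)
    }
    cl <- cluster_indels(ind$position, ind$length, window)
    if (nrow(cl) > 0L && any(!cl$in_frame)) f <- c(f, "c")
    if (isTRUE(as.logical(m$in_frame_stop)) ||
        !isTRUE(as.logical(m$splice_sites_conserved))) f <- c(f, "d")
    paste(f, collapse = ",")
  }, character(1))
  mappings$failed_criteria <- fails
  mappings$passed <- fails == ""
  mappings
}

#' Select the longest passing transcript per gene
#'
#' @param mappings data.frame of QC-passing mappings (rows with a
#'   `passed` column are filtered to `passed == TRUE` first).
#' @return one row per gene: maximum `coding_length`, ties broken by the
#'   lexicographically smallest `transcript_id`.
#' @export
select_longest_transcript <- function(mappings) {
  if ("passed" %in% names(mappings)) {
    mappings <- mappings[mappings$passed, , drop = FALSE]
  }
  if (nrow(mappings) == 0L) return(mappings)
  ord <- order(mappings$gene_id, -mappings$coding_length, mappings$transcript_id)
  mappings <- mappings[ord, , drop = FALSE]
  out <- mappings[!duplicated(mappings$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Does an ortholog record contain all required species?
#'
#' @param species character vector of species present in the record.
#' @param required character vector of species that must be present
#'   (e.g. the two focal species of the pairwise comparison).
#' @return single logical.
#' @export
require_species <- function(species, required) {
  all(required %in% species)
}

#' Read a transcript-mapping table
#'
#' @param path TSV with the columns documented in [check_mapping()]
#'   (header required; `in_frame_stop` and `splice_sites_conserved` as
#'   TRUE/FALSE).
#' @return validated data.frame.
#' @export
read_mappings <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(indels = "character"))
  df$in_frame_stop <- as.logical(df$in_frame_stop)
  df$splice_sites_conserved <- as.logical(df$splice_sites_conserved)
  if (any(is.na(df$in_frame_stop)) || any(is.na(df$splice_sites_conserved))) {
    stop("in_frame_stop / splice_sites_conserved must be TRUE or FALSE")
  }
  df$indels[is.na(df$indels)] <- ""
  df
}
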