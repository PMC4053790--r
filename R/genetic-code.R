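## Precomputed lookup tables over the standard genetic code.
##
## All codon arithmetic in the package goes through the tables built here:
## per-codon synonymous/non-synonymous site fractions, pathway-averaged
## substitution counts for every ordered codon pair, and the single-base
## neighbourhood used by the sequence simulator.  Tables are built once per
## session from Biostrings::GENETIC_CODE and cached.

.gokaks_env <- new.env(parent = emptyenv())

.BASES <- c("T", "C", "A", "G")

## Orderings of 1, 2 or 3 differing codon positions; used to enumerate
## minimal single-step mutational pathways between codons.
.PERMS <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

## A<->G and C<->T are transitions; everything else is a transversion.
.is_transition <- function(b1, b2) {
  purine <- c("A", "G")
  (b1 %in% purine) == (b2 %in% purine) & b1 != b2
}

## Average (syn, nonsyn) substitution counts over all minimal pathways
## between two codons.  Pathways whose intermediate codons are stops are
## excluded; if every pathway is excluded, all pathways are used with
## steps into or out of a stop classed non-synonymous.
.pathway_counts <- function(c1, c2, aa) {
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(b1 != b2)
  nd <- length(diff_pos)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  step_class <- function(from, to) {
    # stop codons never encode; any step touching one changes the protein
    if (aa[from] == "*" || aa[to] == "*") return(c(0, 1))
    if (aa[from] == aa[to]) c(1, 0) else c(0, 1)
  }
  paths <- lapply(.PERMS[[nd]], function(ord) {
    cur <- b1
    syn <- 0; nonsyn <- 0; via_stop <- FALSE
    for (k in seq_len(nd)) {
      p <- diff_pos[ord[k]]
      nxt <- cur
      nxt[p] <- b2[p]
      from <- paste(cur, collapse = "")
      to <- paste(nxt, collapse = "")
      cls <- step_class(from, to)
      syn <- syn + cls[1]; nonsyn <- nonsyn + cls[2]
      if (k < nd && aa[to] == "*") via_stop <- TRUE
      cur <- nxt
    }
    list(syn = syn, nonsyn = nonsyn, via_stop = via_stop)
  })
  ok <- !vapply(paths, `[[`, logical(1), "via_stop")
  use <- if (any(ok)) paths[ok] else paths
  c(syn = mean(vapply(use, `[[`, numeric(1), "syn")),
    nonsyn = mean(vapply(use, `[[`, numeric(1), "nonsyn")))
}

## Build (or fetch cached) lookup tables.
codon_tables <- function() {
  if (!is.null(.gokaks_env$tables)) return(.gokaks_env$tables)

  codons <- as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0))
  codons <- sort(codons)
  aa <- as.character(Biostrings::GENETIC_CODE[codons])
  names(aa) <- codons
  sense <- codons[aa != "*"]
  stopifnot(length(sense) == 61L)

  n <- length(codons)
  codon_index <- seq_len(n)
  names(codon_index) <- codons

  ## Per-codon site fractions: each position contributes
  ## (# synonymous single-base changes among its 3 alternatives) / 3.
  syn_sites <- rep(NA_real_, n)
  names(syn_sites) <- codons
  ## Single-base neighbourhood: 9 mutants per codon, columns
  ## (pos - 1) * 3 + k over the 3 alternative bases at each position.
  nb_codon <- matrix(NA_integer_, n, 9L)
  nb_syn <- matrix(NA, n, 9L)
  nb_stop <- matrix(NA, n, 9L)
  nb_ts <- matrix(NA, n, 9L)
  for (i in codon_index) {
    b <- strsplit(codons[i], "")[[1]]
    syn_here <- 0
    col <- 0L
    for (pos in 1:3) {
      alts <- setdiff(.BASES, b[pos])
      for (a in alts) {
        col <- col + 1L
        nb <- b
        nb[pos] <- a
        mut <- paste(nb, collapse = "")
        j <- codon_index[[mut]]
        nb_codon[i, col] <- j
        nb_stop[i, col] <- aa[mut] == "*"
        nb_syn[i, col] <- aa[mut] != "*" && aa[mut] == aa[codons[i]]
        nb_ts[i, col] <- .is_transition(b[pos], a)
        if (aa[codons[i]] != "*" && nb_syn[i, col]) syn_here <- syn_here + 1
      }
    }
    if (aa[codons[i]] != "*") syn_sites[i] <- syn_here / 3
  }

  ## Pathway-averaged substitution counts for every ordered sense pair.
  sub_syn <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  sub_nonsyn <- sub_syn
  for (c1 in sense) {
    for (c2 in sense) {
      cts <- .pathway_counts(c1, c2, aa)
      sub_syn[c1, c2] <- cts["syn"]
      sub_nonsyn[c1, c2] <- cts["nonsyn"]
    }
  }

  tabs <- list(
    codons = codons, aa = aa, sense = sense, codon_index = codon_index,
    syn_sites = syn_sites, nonsyn_sites = ifelse(is.na(syn_sites), NA, 3 - syn_sites),
    sub_syn = sub_syn, sub_nonsyn = sub_nonsyn,
    nb_codon = nb_codon, nb_syn = nb_syn, nb_stop = nb_stop, nb_ts = nb_ts
  )
  .gokaks_env$tables <- tabs
  tabs
}

.is_sense <- function(codon) {
  tabs <- codon_tables()
  ok <- grepl("^[ACGT]{3}$", codon)
  ok[ok] <- tabs$aa[codon[ok]] != "*"
  ok
}
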