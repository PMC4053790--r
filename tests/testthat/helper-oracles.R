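# Independent oracles used to check the package's counting and tail
# machinery.  Deliberately written as plain brute force against
# Biostrings::GENETIC_CODE, sharing no code with the implementation.

# All sense codons in a fixed order.
sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  cods <- as.vector(outer(outer(b, b, paste0), b, paste0))
  cods[Biostrings::GENETIC_CODE[cods] != "*"]
}

# Recursive enumeration of every minimal single-step pathway between two
# codons; returns the average (syn, nonsyn) step counts over pathways
# that avoid stop-codon intermediates (all pathways if none avoid them).
oracle_pathway_counts <- function(c1, c2) {
  GC <- Biostrings::GENETIC_CODE
  b2 <- strsplit(c2, "")[[1]]
  walk <- function(cur) {
    bc <- strsplit(cur, "")[[1]]
    dpos <- which(bc != b2)
    if (length(dpos) == 0L) return(list(c(syn = 0, nonsyn = 0, stop = 0)))
    out <- list()
    for (p in dpos) {
      nb <- bc
      nb[p] <- b2[p]
      nxt <- paste(nb, collapse = "")
      syn_step <- GC[[cur]] != "*" && GC[[nxt]] != "*" && GC[[cur]] == GC[[nxt]]
      via_stop <- nxt != c2 && GC[[nxt]] == "*"
      for (tail in walk(nxt)) {
        out[[length(out) + 1L]] <- c(
          syn = tail[["syn"]] + as.numeric(syn_step),
          nonsyn = tail[["nonsyn"]] + as.numeric(!syn_step),
          stop = max(tail[["stop"]], as.numeric(via_stop)))
      }
    }
    out
  }
  paths <- walk(c1)
  stop_flag <- vapply(paths, `[[`, numeric(1), "stop")
  use <- if (any(stop_flag == 0)) paths[stop_flag == 0] else paths
  c(syn = mean(vapply(use, `[[`, numeric(1), "syn")),
    nonsyn = mean(vapply(use, `[[`, numeric(1), "nonsyn")))
}

# Direct binomial tail summation in log space (integer counts only).
oracle_binom_tail <- function(a, s, p, direction) {
  n <- a + s
  js <- if (direction == "rapid") a:n else 0:a
  sum(exp(lchoose(n, js) + js * log(p) + (n - js) * log1p(-p)))
}

# Tiny counts table with known integer sums, for exhaustive-permutation
# and category-arithmetic checks.
tiny_counts <- function() {
  data.frame(gene_id = c("g1", "g2", "g3"),
             a = c(5, 0, 2), A = c(100, 80, 120),
             s = c(1, 6, 2), S = c(50, 40, 60))
}
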