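## The category-level divergence statistic: genome-wide Ka and Ks by
## ratio of sums, the expected non-synonymous proportion P_A per
## category, binomial tail probabilities in both directions (continuous
## in the counts via the regularized incomplete beta), threshold
## scanning, and the annotation-permutation null for the expected number
## of outlier categories.

#' Genome-wide Ka and Ks by ratio of sums
#'
#' `ka = sum(a_i) / sum(A_i)` and `ks = sum(s_i) / sum(S_i)` over all
#' genes of the ortholog universe — equivalent to counting on the
#' concatenated gene set, not a mean of per-gene ratios.
#'
#' @param counts per-gene counts data.frame (`gene_id`, `a`, `A`, `s`,
#'   `S`).
#' @return object of class `genome_rates` with fields `ka`, `ks`,
#'   `ka_ks`, `n_genes` and the four sums.
#' @export
genome_rates <- function(counts) {
  stopifnot(nrow(counts) > 0)
  sums <- colSums(counts[c("a", "A", "s", "S")])
  if (!all(is.finite(sums))) stop("non-finite counts in rates input")
  if (sums["S"] <= 0 || sums["A"] <= 0) {
    stop("genome-wide site totals must be positive")
  }
  ks <- unname(sums["s"] / sums["S"])
  if (ks == 0) stop("genome-wide ks is zero; divergence statistic undefined")
  ka <- unname(sums["a"] / sums["A"])
  structure(list(ka = ka, ks = ks, ka_ks = ka / ks,
                 n_genes = nrow(counts),
                 sum_a = unname(sums["a"]), sum_A = unname(sums["A"]),
                 sum_s = unname(sums["s"]), sum_S = unname(sums["S"])),
            class = "genome_rates")
}

#' @exportS3Method base::print
print.genome_rates <- function(x, ...) {
  cat(sprintf("genome_rates over %d genes: ka = %.5g, ks = %.5g, ka/ks = %.4g\n",
              x$n_genes, x$ka, x$ks, x$ka_ks))
  invisible(x)
}

#' Expected non-synonymous proportion of a category
#'
#' Under genome-average rates, a category with `sum_A` non-synonymous and
#' `sum_S` synonymous sites is expected to accumulate non-synonymous
#' substitutions in proportion
#' `P_A = ka * sum_A / (ka * sum_A + ks * sum_S)`.
#'
#' @param sum_A,sum_S per-category site totals (vectorized).
#' @param rates a [genome_rates()] object.
#' @return numeric vector of expected proportions in `[0, 1]`.
#' @export
expected_nonsyn_proportion <- function(sum_A, sum_S, rates) {
  stopifnot(inherits(rates, "genome_rates"))
  denom <- rates$ka * sum_A + rates$ks * sum_S
  ifelse(denom > 0, rates$ka * sum_A / denom, NA_real_)
}

#' Binomial tail probability of a category's substitution split
#'
#' With `n = a + s` substitutions and expected non-synonymous proportion
#' `p`, the rapid tail is `P(j >= a)` and the slow tail `P(j <= a)` for
#' `j ~ Binomial(n, p)`; both tails include the observed value.
#' Evaluation goes through the regularized incomplete beta function
#' (`pbeta`), which coincides with the direct binomial summation at
#' integer counts and extends it continuously to the fractional counts
#' produced by pathway averaging.
#'
#' @param a,s non-synonymous and synonymous substitution counts
#'   (non-negative, possibly fractional; vectorized).
#' @param p expected non-synonymous proportion.
#' @param direction `"rapid"` (upper tail) or `"slow"` (lower tail).
#' @return tail probabilities in `[0, 1]`.
#' @export
tail_probability <- function(a, s, p, direction = c("rapid", "slow")) {
  direction <- match.arg(direction)
  n <- max(length(a), length(s), length(p))
  a <- rep_len(a, n); s <- rep_len(s, n); p <- rep_len(p, n)
  if (any(a < 0 | s < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (any(a + s <= 0, na.rm = TRUE)) stop("a + s must be positive")
  degen <- !is.na(p) & (p <= 0 | p >= 1)
  if (any(degen)) {
    warning("degenerate expected proportion (0 or 1); tails are 0/1")
  }
  out <- rep(NA_real_, n)
  if (direction == "rapid") {
    reg <- !degen & !is.na(p)
    out[reg] <- ifelse(a[reg] <= 0, 1, stats::pbeta(p[reg], a[reg], s[reg] + 1))
    out[degen] <- ifelse(p[degen] <= 0, as.numeric(a[degen] <= 0), 1)
  } else {
    reg <- !degen & !is.na(p)
    out[reg] <- ifelse(s[reg] <= 0, 1, stats::pbeta(1 - p[reg], s[reg], a[reg] + 1))
    out[degen] <- ifelse(p[degen] >= 1, as.numeric(s[degen] <= 0), 1)
  }
  out
}

#' Test every category against the genome-wide expectation
#'
#' Sums each category's member-gene counts, computes its expected
#' non-synonymous proportion from the genome-wide rates, and evaluates
#' both binomial tails.  Member genes without a counts record are
#' dropped (with a message) and the category re-checked against the size
#' filter.
#'
#' @param counts per-gene counts data.frame.
#' @param categories a `go_categories` object from [build_categories()].
#' @param rates optional [genome_rates()]; computed from `counts` when
#'   `NULL`.
#' @return data.frame with one row per surviving category: `term_id`,
#'   `n_genes`, `a_C`, `s_C`, `sum_A`, `sum_S`, `ka`, `ks`, `ka_ks`,
#'   `p_a`, `p_rapid`, `p_slow`.
#' @export
test_categories <- function(counts, categories, rates = NULL) {
  stopifnot(inherits(categories, "go_categories"))
  if (is.null(rates)) rates <- genome_rates(counts)
  min_genes <- attr(categories, "min_genes")
  idx <- stats::setNames(seq_len(nrow(counts)), counts$gene_id)

  missing_total <- 0L
  rows <- lapply(names(categories), function(term) {
    members <- categories[[term]]
    have <- members %in% names(idx)
    missing_total <<- missing_total + sum(!have)
    members <- members[have]
    if (length(members) < min_genes) return(NULL)
    m <- idx[members]
    a_C <- sum(counts$a[m]); s_C <- sum(counts$s[m])
    sum_A <- sum(counts$A[m]); sum_S <- sum(counts$S[m])
    data.frame(term_id = term, n_genes = length(members),
               a_C = a_C, s_C = s_C, sum_A = sum_A, sum_S = sum_S)
  })
  if (missing_total > 0L) {
    message(missing_total,
            " category member(s) without a counts record dropped")
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(term_id = character(), n_genes = integer(),
                      a_C = numeric(), s_C = numeric(), sum_A = numeric(),
                      sum_S = numeric(), ka = numeric(), ks = numeric(),
                      ka_ks = numeric(), p_a = numeric(), p_rapid = numeric(),
                      p_slow = numeric()))
  }
  out <- do.call(rbind, rows)
  out$ka <- out$a_C / out$sum_A
  out$ks <- out$s_C / out$sum_S
  out$ka_ks <- ifelse(out$ks > 0, out$ka / out$ks, NA_real_)
  out$p_a <- expected_nonsyn_proportion(out$sum_A, out$sum_S, rates)
  out$p_rapid <- tail_probability(out$a_C, out$s_C, out$p_a, "rapid")
  out$p_slow <- tail_probability(out$a_C, out$s_C, out$p_a, "slow")
  rownames(out) <- NULL
  out
}

#' Count outlier categories below a threshold
#'
#' @param results data.frame from [test_categories()].
#' @param threshold tail-probability threshold in (0, 1); strict
#'   inequality.
#' @param direction `"rapid"` or `"slow"`.
#' @return integer count.
#' @export
count_outliers <- function(results, threshold, direction = c("rapid", "slow")) {
  direction <- match.arg(direction)
  stopifnot(threshold > 0, threshold < 1)
  if (nrow(results) == 0L) return(0L)
  p <- if (direction == "rapid") results$p_rapid else results$p_slow
  sum(p < threshold, na.rm = TRUE)
}

## All permutations of 1..n (for the exhaustive null on tiny universes).
.all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (p in sub) {
      k <- k + 1L
      rest <- seq_len(n)[-i]
      out[[k]] <- c(i, rest[p])
    }
  }
  out
}

#' Permutation null for outlier category counts
#'
#' Repeats the whole category test on annotations permuted by
#' [permute_annotation()] (per-gene term sets moved atomically), holding
#' the genome-wide rates fixed — they are sums over all genes and hence
#' permutation-invariant.  For each direction and threshold it reports
#' the observed outlier count, the mean count over permutations (the
#' expected number of false positives), and a global p-value for the
#' null that the observed count is no larger than expected:
#' `global_p = (1 + #\{count_perm >= count_obs\}) / (1 + n_permutations)`
#' (the add-one estimator; the plain proportion is reported alongside as
#' `global_p_raw`).
#'
#' Genes in the universe without a usable counts record are removed from
#' the universe before permuting, so category sizes stay fixed across
#' permutations; a sparse membership matrix then reduces each permuted
#' test to one matrix product.
#'
#' @param counts per-gene counts data.frame.
#' @param annotation a [go_annotation()] object.
#' @param thresholds tail-probability thresholds to scan (default the
#'   standard scan 0.05, 0.01, 0.001, 0.0001).
#' @param n_permutations number of annotation permutations (default
#'   10000).
#' @param seed RNG seed; required, so every run is reproducible.
#' @param min_genes minimum category size (default 20).
#' @param exhaustive enumerate all `n!` assignments instead of sampling
#'   (universes of at most 8 genes); `n_permutations` is ignored.
#' @return data.frame of class `permutation_summary` with one row per
#'   (direction, threshold): `observed`, `expected`, `global_p`,
#'   `global_p_raw`, `n_permutations`, `seed`.  The per-permutation
#'   outlier counts are attached as attribute `perm_counts` (a matrix,
#'   permutations x summary rows).
#' @export
permutation_null <- function(counts, annotation,
                             thresholds = c(0.05, 0.01, 0.001, 0.0001),
                             n_permutations = 10000L, seed,
                             min_genes = 20L, exhaustive = FALSE) {
  stopifnot(inherits(annotation, "go_annotation"))
  if (!exhaustive) {
    if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
    n_permutations <- as.integer(n_permutations)
    if (n_permutations < 1L) stop("n_permutations must be >= 1")
    set.seed(seed)
  } else {
    seed <- NA_integer_
  }
  stopifnot(all(thresholds > 0 & thresholds < 1))

  usable <- annotation$universe %in% counts$gene_id
  if (any(!usable)) {
    message(sum(!usable), " universe gene(s) without counts removed before permutation")
    annotation <- go_annotation(annotation$sets[annotation$universe[usable]],
                                annotation$universe[usable])
  }
  universe <- annotation$universe
  n_genes <- length(universe)
  rates <- genome_rates(counts[match(universe, counts$gene_id), , drop = FALSE])

  categories <- build_categories(annotation, min_genes)
  observed <- test_categories(counts, categories, rates)

  ## Sparse membership matrix over the universe; category sums under a
  ## permutation perm are M %*% X[perm, ] because each gene's term set
  ## moves to exactly one other gene.
  X <- as.matrix(counts[match(universe, counts$gene_id), c("a", "s", "A", "S")])
  n_cat <- length(categories)
  grid <- expand.grid(direction = c("rapid", "slow"), threshold = thresholds,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$direction, -grid$threshold), ]
  rownames(grid) <- NULL
  obs_counts <- mapply(function(d, t) count_outliers(observed, t, d),
                       grid$direction, grid$threshold)

  perms <- if (exhaustive) {
    if (n_genes > 8L) stop("exhaustive enumeration limited to 8 genes")
    .all_perms(n_genes)
  } else {
    replicate(n_permutations, sample.int(n_genes), simplify = FALSE)
  }
  n_rep <- length(perms)

  perm_counts <- matrix(0L, n_rep, nrow(grid))
  if (n_cat > 0L) {
    gi <- stats::setNames(seq_len(n_genes), universe)
    M <- Matrix::sparseMatrix(
      i = rep(seq_len(n_cat), lengths(categories)),
      j = unname(gi[unlist(categories, use.names = FALSE)]),
      x = 1, dims = c(n_cat, n_genes))
    for (r in seq_len(n_rep)) {
      ## permute_annotation gives gene i the term set of gene perm[i], so
      ## category C's permuted members are {i : perm[i] in C} and its sums
      ## take counts through the inverse permutation.
      inv <- integer(n_genes)
      inv[perms[[r]]] <- seq_len(n_genes)
      Y <- as.matrix(M %*% X[inv, , drop = FALSE])
      p_a <- expected_nonsyn_proportion(Y[, 3], Y[, 4], rates)
      p_rapid <- tail_probability(Y[, 1], Y[, 2], p_a, "rapid")
      p_slow <- tail_probability(Y[, 1], Y[, 2], p_a, "slow")
      for (k in seq_len(nrow(grid))) {
        p <- if (grid$direction[k] == "rapid") p_rapid else p_slow
        perm_counts[r, k] <- sum(p < grid$threshold[k], na.rm = TRUE)
      }
    }
  }

  out <- data.frame(
    direction = grid$direction, threshold = grid$threshold,
    observed = as.integer(obs_counts),
    expected = colMeans(perm_counts),
    global_p = (1 + colSums(perm_counts >= rep(obs_counts, each = n_rep))) /
      (1 + n_rep),
    global_p_raw = colMeans(perm_counts >= rep(obs_counts, each = n_rep)),
    n_permutations = n_rep, seed = seed)
  attr(out, "perm_counts") <- perm_counts
  attr(out, "observed_results") <- observed
  class(out) <- c("permutation_summary", "data.frame")
  out
}
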