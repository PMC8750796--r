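# Permutation overlap testing between a query region set and a feature
# set: observed overlap count vs a null built by re-placing the query
# regions uniformly at random, with a z-score and a moment-based
# null-normality gate.

#' Randomize a region set over the genome
#'
#' Each region is re-placed independently: a chromosome is drawn with
#' probability proportional to its length among chromosomes long enough
#' to hold the region, then a start is drawn uniformly so the region
#' lies fully inside. Region lengths are preserved; strand is ignored.
#' With `per_chromosome = TRUE` each region keeps its chromosome and
#' only the start is redrawn.
#'
#' @param regions `GRanges`.
#' @param genome_sizes named vector of chromosome lengths.
#' @param seed optional integer seed (the caller's RNG state is
#'   restored afterwards).
#' @param per_chromosome keep chromosome assignment fixed.
#' @return `GRanges` of randomized regions (strand `*`).
#' @export
randomize_regions <- function(regions, genome_sizes, seed = NULL,
                              per_chromosome = FALSE) {
  w <- width(regions)
  if (any(w > max(genome_sizes))) {
    stopf("randomize_regions: a region is longer than every chromosome")
  }
  with_seed(seed, {
    n <- length(regions)
    if (per_chromosome) {
      chr <- as.character(seqnames(regions))
      if (any(w > genome_sizes[chr])) {
        stopf("randomize_regions: region longer than its chromosome")
      }
    } else {
      chr <- character(n)
      # sample per distinct width so the eligible-chromosome set is right
      for (uw in unique(w)) {
        ok <- genome_sizes >= uw
        idx <- which(w == uw)
        chr[idx] <- sample(names(genome_sizes)[ok], length(idx),
                           replace = TRUE, prob = genome_sizes[ok])
      }
    }
    max_start <- genome_sizes[chr] - w + 1
    starts <- floor(runif(n, min = 1, max = max_start + 1))
    starts <- pmin(starts, max_start)  # guard the runif upper edge
    GRanges(chr, IRanges(starts, width = w))
  })
}

#' Permutation test for region-set overlap
#'
#' The statistic is the number of query regions overlapping at least
#' one feature by >= 1 bp. The null distribution is built by
#' randomizing the query set `n` times with [randomize_regions()].
#' `z = (observed - null mean) / null sd`; the empirical p-value uses
#' the plus-one correction `(#(null >= observed) + 1) / (n + 1)` for
#' enrichment (mirrored for depletion). The null sample is additionally
#' checked for approximate normality with a D'Agostino-Pearson
#' skewness/kurtosis omnibus test at alpha = 0.05; the z-score is
#' reported regardless but flagged unusable when the gate fails.
#'
#' @param query,features `GRanges`.
#' @param genome_sizes named chromosome lengths.
#' @param n number of permutations (>= 100).
#' @param seed integer seed.
#' @param alternative `"enrichment"` or `"depletion"`.
#' @param per_chromosome passed to [randomize_regions()].
#' @return list of class `permutation_result`: `observed_overlaps`,
#'   `null_mean`, `null_sd`, `z_score` (NA when the null is
#'   degenerate), `empirical_p`, `alternative`, `n_permutations`,
#'   `normality_ok`, `null_sample`.
#' @export
permutation_overlap_test <- function(query, features, genome_sizes,
                                     n = 1000, seed = NULL,
                                     alternative = c("enrichment",
                                                     "depletion"),
                                     per_chromosome = FALSE) {
  alternative <- match.arg(alternative)
  if (length(query) == 0) stopf("permutation_overlap_test: empty query")
  if (n < 100) stopf("permutation_overlap_test: need n >= 100 permutations")
  observed <- sum(overlapsAny(query, features, ignore.strand = TRUE))
  w <- width(query)
  if (any(w > max(genome_sizes))) {
    stopf("permutation_overlap_test: a query region is longer than every chromosome")
  }
  # merged features per chromosome: with disjoint sorted intervals, a
  # region [s, e] overlaps one iff the last feature starting at or
  # before e ends at or after s -- an O(log f) lookup that lets the
  # whole null (n permutations x m regions) be drawn and scored in a
  # handful of vectorized calls instead of n GRanges round-trips.
  fr <- reduce(granges(features), ignore.strand = TRUE)
  fs <- lapply(split(seq_along(fr), as.character(seqnames(fr))),
               function(i) list(s = start(fr)[i][order(start(fr)[i])],
                                e = sort(end(fr)[i])))
  m <- length(query)
  null_sample <- with_seed(seed, {
    N <- n * m
    wrep <- rep(w, times = n)
    if (per_chromosome) {
      chr <- rep(as.character(seqnames(query)), times = n)
      if (any(wrep > genome_sizes[chr])) {
        stopf("permutation_overlap_test: region longer than its chromosome")
      }
    } else {
      chr <- character(N)
      for (uw in unique(w)) {
        ok <- genome_sizes >= uw
        idx <- which(wrep == uw)
        chr[idx] <- sample(names(genome_sizes)[ok], length(idx),
                           replace = TRUE, prob = genome_sizes[ok])
      }
    }
    max_start <- genome_sizes[chr] - wrep + 1
    st <- pmin(floor(runif(N, min = 1, max = max_start + 1)), max_start)
    en <- st + wrep - 1
    hit <- logical(N)
    for (ch in names(fs)) {
      ii <- which(chr == ch)
      if (!length(ii)) next
      pos <- findInterval(en[ii], fs[[ch]]$s)
      hit[ii] <- pos >= 1 & fs[[ch]]$e[pmax(pos, 1)] >= st[ii]
    }
    as.numeric(tabulate(rep(seq_len(n), each = m)[hit], nbins = n))
  })
  mu <- mean(null_sample)
  sdv <- sd(null_sample)
  z <- if (sdv > 0) (observed - mu) / sdv else NA_real_
  p <- if (alternative == "enrichment") {
    (sum(null_sample >= observed) + 1) / (n + 1)
  } else {
    (sum(null_sample <= observed) + 1) / (n + 1)
  }
  structure(list(observed_overlaps = observed,
                 null_mean = mu,
                 null_sd = sdv,
                 z_score = z,
                 empirical_p = p,
                 alternative = alternative,
                 n_permutations = n,
                 normality_ok = dagostino_normality(null_sample)$ok,
                 null_sample = null_sample),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation overlap test (%s, n = %d)\n  observed = %d, null = %.2f +/- %.2f, z = %s, p = %.4g%s\n",
    x$alternative, x$n_permutations, x$observed_overlaps, x$null_mean,
    x$null_sd, ifelse(is.na(x$z_score), "NA", sprintf("%.2f", x$z_score)),
    x$empirical_p,
    if (!x$normality_ok) " [null not ~normal: z unusable]" else ""))
  invisible(x)
}

# D'Agostino-Pearson K^2 omnibus normality test: transformed sample
# skewness (D'Agostino 1970) and kurtosis (Anscombe-Glynn 1983) z
# statistics, K2 = z1^2 + z2^2 ~ chi^2(2) under normality.
dagostino_normality <- function(x, alpha = 0.05) {
  n <- length(x)
  if (n < 20 || sd(x) == 0) {
    return(list(ok = FALSE, statistic = NA_real_, p.value = NA_real_))
  }
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha_s <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / alpha_s + sqrt((Y / alpha_s)^2 + 1))
  # kurtosis
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- z1^2 + z2^2
  p <- pchisq(K2, df = 2, lower.tail = FALSE)
  if (!is.finite(p)) return(list(ok = FALSE, statistic = K2, p.value = p))
  list(ok = p > alpha, statistic = K2, p.value = p)
}

#' Run a battery of overlap tests and tabulate the results
#'
#' Convenience wrapper producing one row per query-set x feature-set
#' pair, the shape of the TSV this module exports.
#'
#' @param query_sets named list of `GRanges`.
#' @param feature_sets named list of `GRanges`.
#' @param genome_sizes named chromosome lengths.
#' @param n,seed,alternative passed to [permutation_overlap_test()];
#'   seeds are derived per pair for independence.
#' @return data.frame: query, features, observed, null_mean, null_sd,
#'   z, p, normality_ok.
#' @export
association_table <- function(query_sets, feature_sets, genome_sizes,
                              n = 1000, seed = 1,
                              alternative = "enrichment") {
  rows <- list()
  k <- 0
  for (qn in names(query_sets)) {
    for (fn in names(feature_sets)) {
      k <- k + 1
      res <- permutation_overlap_test(query_sets[[qn]], feature_sets[[fn]],
                                      genome_sizes, n = n,
                                      seed = seed + k,
                                      alternative = alternative)
      rows[[k]] <- data.frame(query = qn, features = fn,
                              observed = res$observed_overlaps,
                              null_mean = res$null_mean,
                              null_sd = res$null_sd,
                              z = res$z_score,
                              p = res$empirical_p,
                              normality_ok = res$normality_ok,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
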