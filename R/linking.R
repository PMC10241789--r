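# Linking super-enhancers to promoters through capture interactions, and
# the interaction-profile utilities built on the same tables: relative
# log2 fold changes, k-means row clustering, virtual 4C viewpoints, and the
# quantile-normalised interaction-change statistic between genotypes.

#' Mean interaction score between a gene's bait and a region
#'
#' Arithmetic mean of the score over all recorded interactions from the
#' gene's bait to restriction fragments overlapping the region -- including
#' sub-threshold ones; significance gates link existence, not this mean.
#'
#' @param gene_id Bait gene.
#' @param region A single `GRanges` region (the SE span).
#' @param interactions Interaction data.frame for one sample.
#' @return The mean score, or `NA_real_` if no such interaction is recorded.
#' @export
mean_interaction_score <- function(gene_id, region, interactions) {
  sub <- interactions[interactions$bait_gene == gene_id, , drop = FALSE]
  if (nrow(sub) == 0L) return(NA_real_)
  oe <- interaction_granges(sub, "oe")
  hit <- IRanges::overlapsAny(oe, region, ignore.strand = TRUE)
  if (!any(hit)) return(NA_real_)
  mean(sub$score[hit])
}

#' Link super-enhancers to expressed gene promoters
#'
#' A (SE, gene) pair is linked in population p when all three conditions
#' hold there: (i) at least one recorded interaction with score >=
#' `score_min` from the gene's bait to a fragment overlapping the SE,
#' (ii) the gene is expressed above `rpkm_min` (strictly), and (iii) the SE
#' is active, i.e. called a super-enhancer, in that population.  One row is
#' returned per pair linked in at least one population, with per-population
#' mean scores, expression, activity and link flags.
#'
#' @param catalogue SE catalogue `GRanges` (regions with `region_id`).
#' @param se_results Named list of per-sample results from
#'   [call_superenhancers()] (one per population).
#' @param interactions Named list of interaction data.frames per population.
#' @param expression Genes x populations RPKM matrix.
#' @param score_min Interaction-score threshold (inclusive; default 5).
#' @param rpkm_min Expression threshold (exclusive; default 2).
#' @return A data.frame with one row per linked (SE, gene) pair and columns
#'   `se_id`, `gene_id`, then per population `mean_score_<p>`, `rpkm_<p>`,
#'   `se_active_<p>`, `linked_<p>`.
#' @export
link_ses_to_promoters <- function(catalogue, se_results, interactions,
                                  expression, score_min = 5, rpkm_min = 2) {
  pops <- names(interactions)
  stopifnot(all(pops %in% names(se_results)))
  genes_seen <- unique(unlist(lapply(interactions, function(x) x$bait_gene)))
  missing <- setdiff(genes_seen, rownames(expression))
  if (length(missing) > 0L) {
    stop("genes present in interactions but absent from expression table: ",
         paste(missing, collapse = ", "))
  }
  ids <- S4Vectors::mcols(catalogue)$region_id

  active_sets <- lapply(pops, function(p) {
    rk <- se_results[[p]]$ranked
    rk$region_id[rk$is_se]
  })
  names(active_sets) <- pops

  rows <- list()
  for (p in pops) {
    tab <- interactions[[p]]
    sig <- tab[tab$score >= score_min, , drop = FALSE]
    if (nrow(sig) == 0L) next
    oe <- interaction_granges(sig, "oe")
    ov <- GenomicRanges::findOverlaps(oe, catalogue, ignore.strand = TRUE)
    if (length(ov) == 0L) next
    cand <- unique(data.frame(
      se_id = ids[S4Vectors::subjectHits(ov)],
      gene_id = sig$bait_gene[S4Vectors::queryHits(ov)],
      stringsAsFactors = FALSE))
    rows[[p]] <- cand
  }
  pairs <- unique(do.call(rbind, rows))
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(data.frame(se_id = character(0), gene_id = character(0)))
  }
  pairs <- pairs[order(pairs$se_id, pairs$gene_id), , drop = FALSE]
  rownames(pairs) <- NULL

  out <- pairs
  linked_any <- rep(FALSE, nrow(pairs))
  for (p in pops) {
    tab <- interactions[[p]]
    ms <- vapply(seq_len(nrow(pairs)), function(i) {
      reg <- catalogue[ids == pairs$se_id[i]]
      mean_interaction_score(pairs$gene_id[i], reg, tab)
    }, 0)
    has_sig <- vapply(seq_len(nrow(pairs)), function(i) {
      reg <- catalogue[ids == pairs$se_id[i]]
      sub <- tab[tab$bait_gene == pairs$gene_id[i] & tab$score >= score_min, ,
                 drop = FALSE]
      nrow(sub) > 0L &&
        any(IRanges::overlapsAny(interaction_granges(sub, "oe"), reg,
                                 ignore.strand = TRUE))
    }, TRUE)
    rp <- expression[pairs$gene_id, p]
    act <- pairs$se_id %in% active_sets[[p]]
    lk <- has_sig & rp > rpkm_min & act
    out[[paste0("mean_score_", p)]] <- ms
    out[[paste0("rpkm_", p)]] <- unname(rp)
    out[[paste0("se_active_", p)]] <- act
    out[[paste0("linked_", p)]] <- lk
    linked_any <- linked_any | lk
  }
  out[linked_any, , drop = FALSE]
}

#' Log2 fold change relative to the row mean
#'
#' `out[p] = log2((x[p] + pseudo) / (mean(x) + pseudo))`; a constant row
#' maps to all zeros.
#'
#' @param values Non-negative numeric vector (one value per population).
#' @param pseudo Pseudo-count guarding zeros (default 0.5).
#' @return Numeric vector of log2 fold changes.
#' @export
relative_log2fc <- function(values, pseudo = 0.5) {
  if (any(values < 0)) stop("values must be non-negative")
  log2((values + pseudo) / (mean(values) + pseudo))
}

#' Deterministic k-means on matrix rows
#'
#' Lloyd's algorithm with k-means++ initialisation, run `restarts` times and
#' keeping the solution with the smallest within-cluster sum of squares.
#' All randomness comes from `seed`, so repeated calls are bit-identical.
#'
#' @param x Numeric matrix (rows are clustered) or vector (treated as a
#'   one-column matrix).
#' @param k Number of centers; must not exceed the number of rows.
#' @param seed Integer seed.
#' @param restarts Number of independent initialisations (default 10).
#' @param max_iter Lloyd iteration cap per run.
#' @return A list with `cluster` (integer labels, named by rownames),
#'   `centers` (k x ncol matrix) and `tot_withinss`.
#' @export
kmeans_rows <- function(x, k, seed = 1L, restarts = 10L, max_iter = 100L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k exceeds the number of rows")
  if (k < 1L) stop("k must be >= 1")
  .with_seed(.child_seed(seed, "kmeans"), {
    best <- NULL
    for (r in seq_len(restarts)) {
      centers <- .kmeanspp_init(x, k)
      fit <- tryCatch(
        stats::kmeans(x, centers = centers, iter.max = max_iter,
                      algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) {
          suppressWarnings(stats::kmeans(x, centers = centers,
                                         iter.max = max_iter,
                                         algorithm = "Lloyd"))
        })
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) stop("k-means failed on all restarts (degenerate input?)")
    cl <- best$cluster
    names(cl) <- rownames(x)
    list(cluster = cl, centers = best$centers,
         tot_withinss = best$tot.withinss)
  })
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center; duplicates jittered out by falling
# back to the farthest point.
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[idx[1L], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      pool <- setdiff(seq_len(n), idx[seq_len(j - 1L)])
      idx[j] <- pool[sample.int(length(pool), 1L)]
    } else {
      idx[j] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums((x - matrix(x[idx[j], ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  m <- x[idx, , drop = FALSE]
  # stats::kmeans requires distinct centers
  dup <- duplicated(m)
  if (any(dup)) {
    for (j in which(dup)) {
      far <- which.max(d2)
      m[j, ] <- x[far, ] + stats::runif(ncol(x), -1e-9, 1e-9)
    }
  }
  m
}

#' Virtual 4C profile for one bait
#'
#' Collapses a sample's interaction table onto one viewpoint: one track
#' entry per distinct other-end fragment of the bait, the value being the
#' interaction score (duplicate bait/other-end records are summed), sorted
#' by genomic coordinate.  Use [write_bedgraph()] to emit the track.
#'
#' @param interactions Interaction data.frame.
#' @param bait_gene Gene whose bait is the viewpoint.
#' @return A list with `bait` (`GRanges` of the bait fragment), `track`
#'   (`GRanges` of other-end fragments) and `value` (numeric scores).
#' @export
virtual_4c <- function(interactions, bait_gene) {
  sub <- interactions[interactions$bait_gene == bait_gene, , drop = FALSE]
  if (nrow(sub) == 0L) stop("unknown bait gene: ", bait_gene)
  key <- paste(sub$oe_chrom, sub$oe_start, sub$oe_end, sep = ":")
  val <- tapply(sub$score, key, sum)
  first <- !duplicated(key)
  oe <- data.frame(chrom = sub$oe_chrom[first], start = sub$oe_start[first],
                   end = sub$oe_end[first], key = key[first],
                   stringsAsFactors = FALSE)
  oe$value <- as.numeric(val[oe$key])
  oe <- oe[order(oe$chrom, oe$start), , drop = FALSE]
  list(bait = GenomicRanges::GRanges(sub$bait_chrom[1L],
                                     IRanges::IRanges(sub$bait_start[1L],
                                                      sub$bait_end[1L])),
       track = GenomicRanges::GRanges(oe$chrom,
                                      IRanges::IRanges(oe$start, oe$end)),
       value = oe$value)
}

#' Quantile-normalise two count vectors against each other
#'
#' Both vectors are mapped onto the rank-wise means of their sorted values:
#' position i of the reference distribution is `(sort(a)[i] + sort(b)[i])/2`,
#' each value is replaced by the reference value at its rank, and a group of
#' tied values receives the mean of the reference over the positions the
#' group occupies.  After normalisation the sorted vectors of the two
#' samples coincide (exactly so in the absence of ties).
#'
#' @param a,b Numeric vectors of equal length.
#' @return A list with normalised vectors `a` and `b`.
#' @export
quantile_normalize_pair <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  n <- length(a)
  ref <- (sort(a) + sort(b)) / 2
  remap <- function(x) {
    o <- order(x)
    xs <- x[o]
    out <- numeric(n)
    i <- 1L
    while (i <= n) {
      j <- i
      while (j < n && xs[j + 1L] == xs[i]) j <- j + 1L
      out[o[i:j]] <- mean(ref[i:j])
      i <- j + 1L
    }
    out
  }
  list(a = remap(a), b = remap(b))
}

#' Percent change of interaction counts over a region between two samples
#'
#' For one bait, the raw read counts of its interactions are collected in
#' both samples over the union of other-end fragments (fragments absent
#' from one sample are imputed as 0), the two count vectors are
#' quantile-normalised against each other, normalised counts are summed
#' over fragments overlapping `region`, and the percent decrease
#' `100 * (1 - sum_b / sum_a)` is returned (negative values mean an
#' increase in sample b).
#'
#' @param interactions_a,interactions_b Interaction data.frames for the two
#'   samples (e.g. wild-type and mutant).
#' @param bait_gene Viewpoint gene; must be baited in both samples.
#' @param region `GRanges` region of interest.
#' @return The percent change (a single number).
#' @export
region_interaction_change <- function(interactions_a, interactions_b,
                                      bait_gene, region) {
  sub_a <- interactions_a[interactions_a$bait_gene == bait_gene, , drop = FALSE]
  sub_b <- interactions_b[interactions_b$bait_gene == bait_gene, , drop = FALSE]
  if (nrow(sub_a) == 0L || nrow(sub_b) == 0L) {
    stop("bait gene ", bait_gene, " must be present in both samples")
  }
  key_a <- paste(sub_a$oe_chrom, sub_a$oe_start, sub_a$oe_end, sep = ":")
  key_b <- paste(sub_b$oe_chrom, sub_b$oe_start, sub_b$oe_end, sep = ":")
  keys <- union(key_a, key_b)
  cnt <- function(key, n) {
    v <- tapply(n, key, sum)
    out <- stats::setNames(numeric(length(keys)), keys)
    out[names(v)] <- v
    out
  }
  va <- cnt(key_a, sub_a$n_reads)
  vb <- cnt(key_b, sub_b$n_reads)
  qn <- quantile_normalize_pair(va, vb)
  parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  frag <- GenomicRanges::GRanges(parts[, 1L],
                                 IRanges::IRanges(as.numeric(parts[, 2L]),
                                                  as.numeric(parts[, 3L])))
  inside <- IRanges::overlapsAny(frag, region, ignore.strand = TRUE)
  sum_a <- sum(qn$a[inside])
  sum_b <- sum(qn$b[inside])
  if (sum_a == 0) stop("no normalised signal over the region in sample a; ",
                       "percent change undefined")
  100 * (1 - sum_b / sum_a)
}
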