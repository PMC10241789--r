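# Accessibility-profile-driven motif discovery: promoter/enhancer peak
# classification, logCPM relative-accessibility matrices, profile
# clustering, Pearson ranking into peak sets, Fisher/BH motif enrichment,
# log-odds PWM scanning, and similarity-based representative selection.

#' Classify peaks into promoter and enhancer peaks
#'
#' A peak is a promoter peak when the distance from its midpoint to the
#' nearest TSS is strictly smaller than `tss_dist_bp`; everything else is an
#' enhancer peak.  Peaks on sex chromosomes are dropped from the enhancer
#' set (samples pooled across sexes make them unusable), but are still
#' classified.  The midpoint is `floor((start0 + end0)/2)` in half-open
#' coordinates.
#'
#' @param peaks `GRanges` of peaks (with a `peak_id` column).
#' @param annotation Gene annotation data.frame.
#' @param tss_dist_bp Promoter distance threshold (strict; default 1000).
#' @param sex_chroms Chromosomes excluded from the enhancer set.
#' @return A list with `enhancers` and `promoters` (`GRanges`), and
#'   `tss_distance` (named numeric, per input peak; `Inf` when the peak's
#'   chromosome has no annotated gene).
#' @export
classify_enhancer_peaks <- function(peaks, annotation, tss_dist_bp = 1000,
                                    sex_chroms = c("chrX", "chrY")) {
  if (nrow(annotation) == 0L) stop("annotation must be non-empty")
  chrom <- as.character(GenomeInfoDb::seqnames(peaks))
  mid0 <- floor((GenomicRanges::start(peaks) - 1 +
                   GenomicRanges::end(peaks)) / 2)
  tss0 <- annotation$tss - 1
  dist <- rep(Inf, length(peaks))
  for (ch in unique(chrom)) {
    t <- sort(tss0[annotation$chrom == ch])
    if (length(t) == 0L) next
    i <- chrom == ch
    idx <- findInterval(mid0[i], t)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(t))
    dist[i] <- pmin(abs(mid0[i] - t[lo]), abs(mid0[i] - t[hi]))
  }
  ids <- S4Vectors::mcols(peaks)$peak_id
  if (!is.null(ids)) names(dist) <- ids
  is_prom <- dist < tss_dist_bp
  list(enhancers = peaks[!is_prom & !(chrom %in% sex_chroms)],
       promoters = peaks[is_prom],
       tss_distance = dist)
}

#' Build a log-CPM accessibility matrix with relative rows
#'
#' `logcpm = log2(count / total * 1e6 + 1)`; `relative` subtracts each
#' peak's row mean, so every relative row sums to zero across samples.
#'
#' @param counts Peaks x samples count matrix.
#' @param library_totals Per-sample totals.
#' @return A list with `logcpm` and `relative` matrices.
#' @export
build_accessibility_matrix <- function(counts, library_totals) {
  logcpm <- log2(compute_cpm(counts, library_totals) + 1)
  relative <- logcpm - rowMeans(logcpm)
  list(logcpm = logcpm, relative = relative)
}

#' Cluster the peaks of a focus region by relative accessibility
#'
#' Runs deterministic k-means ([kmeans_rows()]) on the relative
#' accessibility rows of the peaks falling inside `region` and returns the
#' per-cluster mean profiles.
#'
#' @param acc Output of [build_accessibility_matrix()].
#' @param peaks `GRanges` with `peak_id` matching the matrix rows.
#' @param region Focus region (`GRanges` of length 1).
#' @param k Number of profile clusters (default 3).
#' @param seed Integer seed for the clustering.
#' @return A list with `peak_ids`, `labels` (named integer vector) and
#'   `mean_profiles` (k x samples matrix).
#' @export
cluster_region_peaks <- function(acc, peaks, region, k = 3L, seed = 1L) {
  ids <- S4Vectors::mcols(peaks)$peak_id
  inside <- IRanges::overlapsAny(peaks, region, ignore.strand = TRUE)
  sel <- ids[inside]
  if (length(sel) < k) stop("fewer than k peaks inside the region")
  rel <- acc$relative[sel, , drop = FALSE]
  if (nrow(unique(rel)) < k) {
    stop("degenerate input: fewer than k distinct accessibility profiles ",
         "in the region")
  }
  fit <- kmeans_rows(rel, k = k, seed = seed)
  prof <- do.call(rbind, lapply(seq_len(k), function(c)
    colMeans(rel[fit$cluster == c, , drop = FALSE])))
  rownames(prof) <- paste0("cluster", seq_len(k))
  list(peak_ids = sel, labels = fit$cluster, mean_profiles = prof)
}

#' Rank enhancers by correlation to cluster profiles and form peak sets
#'
#' Every enhancer's relative-accessibility row is correlated (Pearson) with
#' each cluster mean profile; the enhancer is assigned to its best profile
#' (ties to the lowest cluster index), and within each profile the `top_n`
#' enhancers by correlation are kept (ties broken by genomic coordinate
#' order).  Assignment-before-ranking makes the sets pairwise disjoint by
#' construction.  All residual enhancers form the control set.  A
#' zero-variance enhancer row has no defined correlation and scores 0
#' against every profile.
#'
#' @param acc Output of [build_accessibility_matrix()].
#' @param peaks Enhancer `GRanges` with `peak_id` (defines the universe and
#'   the coordinate tie-break).
#' @param profiles Cluster mean-profile matrix (k x samples), non-constant
#'   rows.
#' @param top_n Set size cap (default 1000).
#' @return A list with `correlation` (peaks x k), `assignment`, `sets`
#'   (list of k character vectors of peak ids) and `control`.
#' @export
rank_by_profile <- function(acc, peaks, profiles, top_n = 1000L) {
  if (any(apply(profiles, 1L, stats::sd) == 0)) {
    stop("cluster profiles must be non-constant")
  }
  ids <- S4Vectors::mcols(peaks)$peak_id
  rel <- acc$relative[ids, , drop = FALSE]
  rv <- apply(rel, 1L, stats::sd)
  r <- matrix(0, nrow = nrow(rel), ncol = nrow(profiles),
              dimnames = list(ids, rownames(profiles)))
  ok <- rv > 0
  if (any(ok)) {
    r[ok, ] <- stats::cor(t(rel[ok, , drop = FALSE]), t(profiles))
  }
  assignment <- max.col(r, ties.method = "first")
  names(assignment) <- ids
  coord_rank <- order(as.character(GenomeInfoDb::seqnames(peaks)),
                      GenomicRanges::start(peaks))
  coord_pos <- match(seq_along(ids), coord_rank)
  sets <- lapply(seq_len(nrow(profiles)), function(c) {
    member <- which(assignment == c)
    if (length(member) == 0L) return(character(0))
    o <- member[order(-r[member, c], coord_pos[member])]
    ids[utils::head(o, top_n)]
  })
  names(sets) <- rownames(profiles)
  control <- setdiff(ids, unlist(sets))
  list(correlation = r, assignment = assignment, sets = sets,
       control = control)
}

.motif_prob <- function(motif, pseudocount = 0.01) {
  cts <- motif$counts
  sweep(cts + pseudocount, 2L, colSums(cts) + 4 * pseudocount, "/")
}

#' Log2-odds position weight matrix from a PFM
#'
#' Counts are converted to probabilities with a pseudocount per cell and
#' scored against a uniform background of 0.25.
#'
#' @param motif A motif ([read_jaspar_pfm()] layout).
#' @param pseudocount Per-cell pseudocount (default 0.01).
#' @param background Background base probability (default 0.25, uniform).
#' @return A 4 x L matrix of log2-odds scores.
#' @export
pwm_log_odds <- function(motif, pseudocount = 0.01, background = 0.25) {
  log2(.motif_prob(motif, pseudocount) / background)
}

.BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

#' Scan a sequence for motif hits above an absolute score
#'
#' Scores every offset of the sequence on both strands with the log2-odds
#' PWM ([pwm_log_odds()]) and reports offsets scoring at least `tau`.
#' Windows containing any non-ACGT base (e.g. N) score `-Inf`.  A sequence
#' shorter than the motif yields an empty hit list.
#'
#' @param sequence A character string or `DNAString` over A, C, G, T, N.
#' @param motif A motif ([read_jaspar_pfm()] layout).
#' @param tau Minimum log2-odds score (default 10.0).
#' @return A data.frame with `start` (1-based offset of the window on the
#'   forward sequence), `strand` and `score`.
#' @export
scan_pwm <- function(sequence, motif, tau = 10.0) {
  pwm <- pwm_log_odds(motif)
  L <- ncol(pwm)
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  empty <- data.frame(start = integer(0), strand = character(0),
                      score = numeric(0))
  if (n < L) return(empty)
  code <- unname(.BASE_CODE[strsplit(s, "", fixed = TRUE)[[1L]]])
  n_off <- n - L + 1L
  score_with <- function(m) {
    sc <- numeric(n_off)
    for (j in seq_len(L)) {
      col <- m[, j][code[j:(j + n_off - 1L)]]
      sc <- sc + col
    }
    sc[is.na(sc)] <- -Inf
    sc
  }
  fwd <- score_with(pwm)
  # reverse complement of the PWM: reverse columns, complement rows
  rc <- pwm[4:1, L:1, drop = FALSE]
  rev <- score_with(rc)
  fi <- which(fwd >= tau)
  ri <- which(rev >= tau)
  hits <- rbind(
    data.frame(start = fi, strand = rep("+", length(fi)),
               score = unname(fwd[fi])),
    data.frame(start = ri, strand = rep("-", length(ri)),
               score = unname(rev[ri])))
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Count motif hits across a set of peak sequences
#'
#' @param sequences Named `DNAStringSet` (or character vector), one entry
#'   per peak.
#' @param motifs Named list of motifs.
#' @param tau Minimum log2-odds score.
#' @return An integer matrix, peaks x motifs, of hit counts (both strands).
#' @export
count_motif_hits <- function(sequences, motifs, tau = 10.0) {
  seqs <- as.character(sequences)
  if (is.null(names(seqs))) names(seqs) <- names(sequences)
  out <- matrix(0L, nrow = length(seqs), ncol = length(motifs),
                dimnames = list(names(seqs), names(motifs)))
  for (m in names(motifs)) {
    out[, m] <- vapply(seqs, function(s)
      nrow(scan_pwm(s, motifs[[m]], tau = tau)), 0L, USE.NAMES = FALSE)
  }
  out
}

#' Motif hit rates per kilobase
#'
#' Peaks differ in length, so hit counts are converted to hits per kb and
#' averaged (unweighted) across peaks per motif.
#'
#' @param hit_counts Peaks x motifs matrix from [count_motif_hits()].
#' @param widths_bp Peak widths in bp (one per row).
#' @return A list with `rates` (peaks x motifs, hits/kb) and `mean_rates`
#'   (per-motif unweighted mean over peaks).
#' @export
hit_rate_per_kb <- function(hit_counts, widths_bp) {
  if (length(widths_bp) != nrow(hit_counts)) {
    stop("need one width per peak row")
  }
  rates <- hit_counts * 1000 / widths_bp
  list(rates = rates, mean_rates = colMeans(rates))
}

#' Motif enrichment of peak sets against the control set
#'
#' For every (motif, set) pair a 2x2 table of peaks with at least one hit
#' versus peaks without is tested against the control set with a one-sided
#' Fisher's exact test (enrichment direction), and p-values are corrected
#' by Benjamini-Hochberg across all (motif, set) pairs.  Motifs significant
#' (FDR < `fdr_threshold`) in at least one set are marked selected.
#'
#' @param sets Named list of peak-id vectors (the profile-correlated sets).
#' @param control Character vector of control peak ids (non-empty).
#' @param hit_counts Peaks x motifs hit-count matrix covering all ids.
#' @param fdr_threshold Selection threshold on the FDR (default 0.001).
#' @return A data.frame with one row per (motif, set): hit tallies, odds
#'   ratio, `p_value`, `fdr` and per-motif `selected`.
#' @export
motif_enrichment <- function(sets, control, hit_counts,
                             fdr_threshold = 0.001) {
  if (length(control) == 0L) stop("control set must be non-empty")
  present <- hit_counts >= 1L
  rows <- list()
  for (s in names(sets)) {
    ids <- sets[[s]]
    for (m in colnames(hit_counts)) {
      a <- sum(present[ids, m])
      b <- length(ids) - a
      c_ <- sum(present[control, m])
      d <- length(control) - c_
      ft <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2L),
                               alternative = "greater")
      rows[[length(rows) + 1L]] <-
        data.frame(motif_id = m, set = s, n_set_hit = a,
                   n_set = length(ids), n_control_hit = c_,
                   n_control = length(control),
                   odds_ratio = unname(ft$estimate),
                   p_value = ft$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  sel_motifs <- unique(out$motif_id[out$fdr < fdr_threshold])
  out$selected <- out$motif_id %in% sel_motifs
  out
}

#' Ungapped similarity between two motifs
#'
#' The maximum Pearson correlation between the flattened probability
#' columns of the two motifs over all ungapped alignments with at least
#' `min_overlap` overlapping columns (or the full shorter motif when it is
#' shorter than that), considering both orientations of the second motif.
#'
#' @param m1,m2 Motifs ([read_jaspar_pfm()] layout).
#' @param min_overlap Minimum overlapping columns (default 4).
#' @return A similarity in [-1, 1].
#' @export
motif_similarity <- function(m1, m2, min_overlap = 4L) {
  p1 <- .motif_prob(m1)
  orientations <- list(.motif_prob(m2))
  orientations[[2L]] <- orientations[[1L]][4:1, ncol(orientations[[1L]]):1,
                                           drop = FALSE]
  best <- -1
  L1 <- ncol(p1)
  for (q in orientations) {
    L2 <- ncol(q)
    ov_min <- min(min_overlap, L1, L2)
    for (s in seq(-(L2 - ov_min), L1 - ov_min)) {
      c1 <- seq(max(1L, 1L + s), min(L1, L2 + s))
      a <- as.vector(p1[, c1, drop = FALSE])
      b <- as.vector(q[, c1 - s, drop = FALSE])
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        cand <- if (isTRUE(all.equal(a, b))) 1 else -1
      } else {
        cand <- stats::cor(a, b)
      }
      if (cand > best) best <- cand
    }
  }
  best
}

#' Pairwise motif similarity matrix
#'
#' @param motifs Named list of motifs.
#' @param min_overlap Minimum overlapping columns per alignment.
#' @return A symmetric similarity matrix with unit diagonal.
#' @export
motif_similarity_matrix <- function(motifs, min_overlap = 4L) {
  n <- length(motifs)
  S <- matrix(1, n, n, dimnames = list(names(motifs), names(motifs)))
  if (n < 2L) return(S)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      S[i, j] <- S[j, i] <- motif_similarity(motifs[[i]], motifs[[j]],
                                             min_overlap = min_overlap)
    }
  }
  S
}

#' Select representative motifs from the enriched list
#'
#' Motifs are first split into two groups by 1-D k-means on their mean hit
#' rate per kb and only the higher-rate group is retained; pairwise motif
#' similarities S give distances D = 1 - S, the retained motifs are grouped
#' into `min(k_similarity, n)` clusters by k-means on the rows of D, and in
#' each cluster the motif with the least average distance to the other
#' members is chosen as representative (ties broken by lexicographic motif
#' id; singleton clusters represent themselves).
#'
#' @param motifs Named list of motifs (>= 2).
#' @param mean_rates Per-motif mean hit rates per kb (named as `motifs`).
#' @param seed Integer seed driving both k-means steps.
#' @param k_similarity Number of similarity clusters (default 10).
#' @return A list with `table` (data.frame: motif_id, cluster,
#'   avg_distance, representative) and `representatives` (character vector).
#' @export
select_representatives <- function(motifs, mean_rates, seed = 1L,
                                   k_similarity = 10L) {
  if (length(motifs) < 2L) stop("need at least 2 motifs")
  mean_rates <- mean_rates[names(motifs)]
  km2 <- kmeans_rows(matrix(mean_rates, ncol = 1L,
                            dimnames = list(names(motifs), NULL)),
                     k = 2L, seed = seed)
  hi <- which.max(km2$centers[, 1L])
  keep <- names(motifs)[km2$cluster == hi]
  if (length(keep) < 2L) {
    stop("fewer than 2 motifs in the higher-rate group")
  }
  S <- motif_similarity_matrix(motifs[keep])
  D <- 1 - S
  k <- min(k_similarity, length(keep))
  kmS <- kmeans_rows(D, k = k, seed = seed)
  tab <- data.frame(motif_id = keep, cluster = unname(kmS$cluster),
                    avg_distance = NA_real_, representative = FALSE,
                    stringsAsFactors = FALSE)
  for (c in sort(unique(tab$cluster))) {
    member <- tab$motif_id[tab$cluster == c]
    if (length(member) == 1L) {
      tab$avg_distance[tab$motif_id == member] <- 0
      tab$representative[tab$motif_id == member] <- TRUE
      next
    }
    avg <- vapply(member, function(m)
      mean(D[m, setdiff(member, m)]), 0)
    tab$avg_distance[match(member, tab$motif_id)] <- avg
    rep_id <- member[order(avg, member)][1L]
    tab$representative[tab$motif_id == rep_id] <- TRUE
  }
  list(table = tab, representatives = tab$motif_id[tab$representative])
}
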