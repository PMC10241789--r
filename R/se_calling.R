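# Super-enhancer calling: promoter/blacklist filtering, stitching of
# H3K27ac peaks within 12.5 kb, CPM quantification, the hockey-stick cutoff
# on the ranked signal, and the >= 3 constituent-peak rule.

#' Counts-per-million normalisation
#'
#' `cpm[p, s] = raw[p, s] / library_total[s] * 1e6`.
#'
#' @param raw_counts Peaks x samples matrix of raw counts.
#' @param library_totals Per-sample totals (named as the columns); all > 0.
#' @return Matrix of CPM values, same shape as `raw_counts`.
#' @export
compute_cpm <- function(raw_counts, library_totals) {
  raw_counts <- as.matrix(raw_counts)
  if (!is.null(names(library_totals)) && !is.null(colnames(raw_counts))) {
    library_totals <- library_totals[colnames(raw_counts)]
  }
  if (length(library_totals) != ncol(raw_counts)) {
    stop("library_totals must have one entry per sample column")
  }
  if (any(library_totals <= 0)) stop("library totals must be positive")
  sweep(raw_counts, 2L, library_totals, "/") * 1e6
}

#' Filter peaks to promoter-distal, non-blacklisted, allowed chromosomes
#'
#' Removes peaks that overlap a promoter window (TSS +/- `promoter_flank`
#' bp), peaks overlapping a blacklist interval, and peaks on chromosomes
#' outside `allowed_chroms`.  Input order is preserved.
#'
#' @param peaks `GRanges` of peaks.
#' @param annotation Gene annotation data.frame (one TSS per gene).
#' @param blacklist `GRanges` of blacklisted intervals (may be empty).
#' @param allowed_chroms Character vector of chromosomes to keep; must be
#'   non-empty.
#' @param promoter_flank Promoter half-window in bp (default 2500).
#' @return The filtered `GRanges`.
#' @export
filter_peaks <- function(peaks, annotation,
                         blacklist = GenomicRanges::GRanges(),
                         allowed_chroms, promoter_flank = 2500) {
  if (missing(allowed_chroms) || length(allowed_chroms) == 0L) {
    stop("allowed_chroms must be a non-empty set of chromosome names")
  }
  if (any(duplicated(annotation$gene_id))) {
    stop("annotation must have one TSS per gene")
  }
  prom <- .promoter_windows(annotation, flank = promoter_flank)
  keep <- as.character(GenomeInfoDb::seqnames(peaks)) %in% allowed_chroms
  keep <- keep & !IRanges::overlapsAny(peaks, prom, ignore.strand = TRUE)
  if (length(blacklist) > 0L) {
    keep <- keep & !IRanges::overlapsAny(peaks, blacklist,
                                         ignore.strand = TRUE)
  }
  peaks[keep]
}

#' Stitch peaks within a maximum gap into candidate regions
#'
#' Peaks are sorted by (chromosome, start) and consecutive peaks are merged
#' into one region whenever the inter-peak gap (next start minus previous
#' end, half-open sense) is at most `gap_bp`; the region interval spans the
#' merged peaks, per-sample signals are summed over constituents.  Regions
#' whose span overlaps a promoter window are removed when `annotation` is
#' supplied.
#'
#' @param peaks `GRanges` with a `peak_id` metadata column.
#' @param signal Peaks x samples matrix (CPM), rownames matching `peak_id`.
#' @param gap_bp Maximum stitching gap in bp (inclusive; default 12500).
#' @param annotation Optional annotation for post-stitch promoter removal.
#' @param promoter_flank Promoter half-window used for that removal.
#' @return A list with `regions` (`GRanges` with `region_id` and `n_peaks`),
#'   `signal` (regions x samples matrix of summed CPM), and `peaks_of`
#'   (list of constituent `peak_id`s per region).
#' @export
stitch_peaks <- function(peaks, signal, gap_bp = 12500, annotation = NULL,
                         promoter_flank = 2500) {
  if (gap_bp < 0) stop("gap_bp must be non-negative")
  signal <- as.matrix(signal)
  ids <- S4Vectors::mcols(peaks)$peak_id
  if (is.null(ids)) stop("peaks must carry a peak_id column")
  if (!all(ids %in% rownames(signal))) {
    stop("signal matrix is missing rows for some peaks")
  }
  if (length(peaks) == 0L) {
    return(list(regions = GenomicRanges::GRanges(),
                signal = signal[0L, , drop = FALSE], peaks_of = list()))
  }
  ord <- order(as.character(GenomeInfoDb::seqnames(peaks)),
               GenomicRanges::start(peaks), GenomicRanges::end(peaks))
  peaks <- peaks[ord]
  ids <- ids[ord]
  chrom <- as.character(GenomeInfoDb::seqnames(peaks))
  st <- GenomicRanges::start(peaks)
  en <- GenomicRanges::end(peaks)

  grp <- integer(length(peaks))
  grp[1L] <- 1L
  run_end <- en[1L]
  for (i in seq_along(peaks)[-1L]) {
    # gap in half-open coordinates: next.start0 - prev.end0 = st-1 - en
    if (chrom[i] == chrom[i - 1L] && (st[i] - 1L) - run_end <= gap_bp) {
      grp[i] <- grp[i - 1L]
      run_end <- max(run_end, en[i])
    } else {
      grp[i] <- grp[i - 1L] + 1L
      run_end <- en[i]
    }
  }

  idx <- split(seq_along(peaks), grp)
  reg_chrom <- vapply(idx, function(j) chrom[j[1L]], "")
  reg_start <- vapply(idx, function(j) min(st[j]), 0)
  reg_end <- vapply(idx, function(j) max(en[j]), 0)
  regions <- GenomicRanges::GRanges(reg_chrom,
                                    IRanges::IRanges(reg_start, reg_end))
  peaks_of <- lapply(idx, function(j) ids[j])
  sig <- do.call(rbind, lapply(idx, function(j)
    colSums(signal[ids[j], , drop = FALSE])))

  if (!is.null(annotation)) {
    prom <- .promoter_windows(annotation, flank = promoter_flank)
    keep <- !IRanges::overlapsAny(regions, prom, ignore.strand = TRUE)
    regions <- regions[keep]
    peaks_of <- peaks_of[keep]
    sig <- sig[keep, , drop = FALSE]
  }
  region_id <- sprintf("region%04d", seq_along(regions))
  S4Vectors::mcols(regions)$region_id <- region_id
  S4Vectors::mcols(regions)$n_peaks <- lengths(peaks_of)
  rownames(sig) <- region_id
  names(peaks_of) <- region_id
  list(regions = regions, signal = sig, peaks_of = peaks_of)
}

#' Hockey-stick cutoff on a ranked signal vector
#'
#' Sorts the signals ascending as `s_1..s_n`, rescales ranks and signals to
#' the unit square (`u_i = i/n`, `v_i = (s_i - s_1)/(s_n - s_1)`) and takes
#' the rank maximising `u_i - v_i` (ties to the smallest index) -- the
#' discrete form of sliding a unit-slope line tangent to the ranked curve.
#' Super-enhancers are the regions with signal strictly above the returned
#' cutoff value.  If all signals are equal the cutoff equals that common
#' value and nothing lies above it.
#'
#' @param signals Numeric vector of per-region signals (length >= 2).
#' @return A list with `cutoff_value` and `cutoff_rank` (rank in the
#'   ascending sorted order; `NA` for a degenerate all-equal input).
#' @export
rose_cutoff <- function(signals) {
  n <- length(signals)
  if (n < 2L) stop("need at least 2 signals")
  s <- sort(signals)
  if (s[1L] == s[n]) {
    return(list(cutoff_value = s[1L], cutoff_rank = NA_integer_))
  }
  u <- seq_len(n) / n
  v <- (s - s[1L]) / (s[n] - s[1L])
  i <- which.max(u - v)   # which.max takes the first (smallest) index on ties
  list(cutoff_value = s[i], cutoff_rank = i)
}

#' Call super-enhancers for one sample
#'
#' Applies the hockey-stick cutoff to the sample's stitched-region signal and
#' keeps regions with signal strictly above the cutoff and at least
#' `min_peaks` constituent peaks.
#'
#' @param stitched Output of [stitch_peaks()].
#' @param sample_id Column of the signal matrix to use.
#' @param min_peaks Minimum number of constituent peaks (default 3).
#' @return A list with `sample_id`, `cutoff_signal`, `superenhancers` (a
#'   `GRanges` subset of the regions) and `ranked` (data.frame: region_id,
#'   rank, signal, n_peaks, is_se; rank 1 = strongest).
#' @export
call_superenhancers <- function(stitched, sample_id, min_peaks = 3L) {
  if (min_peaks < 1L) stop("min_peaks must be >= 1")
  if (!sample_id %in% colnames(stitched$signal)) {
    stop("no signal column for sample ", sample_id)
  }
  sig <- stitched$signal[, sample_id]
  cut <- rose_cutoff(sig)
  npk <- S4Vectors::mcols(stitched$regions)$n_peaks
  is_se <- sig > cut$cutoff_value & npk >= min_peaks
  ranked <- data.frame(region_id = names(sig), rank = rank(-sig,
                                                           ties.method = "first"),
                       signal = unname(sig), n_peaks = npk,
                       is_se = unname(is_se), stringsAsFactors = FALSE)
  ranked <- ranked[order(ranked$rank), ]
  rownames(ranked) <- NULL
  list(sample_id = sample_id, cutoff_signal = cut$cutoff_value,
       superenhancers = stitched$regions[is_se], ranked = ranked)
}

#' Call super-enhancers across all samples and form the union catalogue
#'
#' Runs [call_superenhancers()] per sample; the putative SE catalogue is the
#' set of regions called in at least one sample.
#'
#' @param stitched Output of [stitch_peaks()].
#' @param min_peaks Minimum constituent peaks.
#' @return A list with `per_sample` (named list of per-sample results) and
#'   `catalogue` (`GRanges` of regions that are an SE in >= 1 sample, with
#'   an `active_in` comma-separated sample list).
#' @export
se_catalogue <- function(stitched, min_peaks = 3L) {
  samples <- colnames(stitched$signal)
  per_sample <- lapply(samples, function(s)
    call_superenhancers(stitched, s, min_peaks = min_peaks))
  names(per_sample) <- samples
  ids <- S4Vectors::mcols(stitched$regions)$region_id
  active <- sapply(ids, function(r) {
    hit <- vapply(per_sample, function(res)
      r %in% res$ranked$region_id[res$ranked$is_se], TRUE)
    paste(samples[hit], collapse = ",")
  })
  keep <- nzchar(active)
  catalogue <- stitched$regions[keep]
  S4Vectors::mcols(catalogue)$active_in <- unname(active[keep])
  list(per_sample = per_sample, catalogue = catalogue)
}
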