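# Synthetic-data generators with planted ground truth.
#
# One root seed drives everything: each generator derives a child seed from
# the root seed and a fixed label, so adding a new generator never perturbs
# the streams of existing ones, and a fixed root seed gives byte-identical
# output across calls.

.child_seed <- function(seed, label) {
  v <- utf8ToInt(label)
  h <- sum(v * seq_along(v)) %% 97651L
  (as.integer(seed) %% 1000000L) * 2017L + h
}

.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic CNCC study
#'
#' Bundles every knob of the synthetic-data generators.  The defaults define
#' the study conditions used throughout the test suite: four CNCC
#' subpopulations (FNP, Mx, Md, PA2), a small three-chromosome genome,
#' HindIII-like restriction fragments of ~4 kb mean length, a heavy-tailed
#' log-normal H3K27ac signal body with planted super-enhancer clusters
#' multiplied by `se_signal_scale`, population-specific planted
#' promoter-SE interaction links, a two-condition accessibility matrix with
#' three planted temporal profiles, and peak sequences with planted motif
#' instances.
#'
#' @param seed Integer root seed; all generators derive their streams from it.
#' @param n_chromosomes,chrom_length_bp Genome geometry (chromosomes are
#'   named `chr1..chrN` and are all autosomal unless renamed).
#' @param n_genes Number of annotated genes (one TSS each).
#' @param populations Character vector of population (sample) names.
#' @param n_peaks Total number of H3K27ac peaks, planted constituents
#'   included.
#' @param n_planted_se Number of planted super-enhancer clusters (each has
#'   3-5 constituent peaks within the stitching distance).
#' @param se_signal_scale Multiplier applied to the raw counts of planted
#'   constituent peaks in the populations where the SE is active (> 1).
#' @param se_active_populations `"all"` (planted SEs are acetylated in every
#'   population, as HIRE-like elements are) or an integer k: each planted SE
#'   is active in k randomly chosen populations.
#' @param n_planted_links Number of planted (SE, gene, population) links.
#' @param fragment_mean_bp Mean restriction-fragment length (HindIII-like).
#' @param acc_n_region_peaks,acc_n_background_peaks Accessibility peaks
#'   inside the focus region and genome-wide.
#' @param acc_n_per_class Background accessibility peaks planted per
#'   temporal profile class.
#' @param acc_conditions,acc_n_replicates Condition names and replicates of
#'   the accessibility experiment.
#' @param acc_fold Accessibility fold change of the "up" condition.
#' @param acc_base_count Mean background accessibility count per peak.
#' @param peak_width_bp Width of accessibility peaks (sequence length used
#'   for motif scanning).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 3L,
                       chrom_length_bp = 8e6,
                       n_genes = 60L,
                       populations = c("FNP", "Mx", "Md", "PA2"),
                       n_peaks = 200L,
                       n_planted_se = 12L,
                       se_signal_scale = 20,
                       se_active_populations = "all",
                       n_planted_links = 8L,
                       fragment_mean_bp = 4000L,
                       acc_n_region_peaks = 30L,
                       acc_n_background_peaks = 4000L,
                       acc_n_per_class = 400L,
                       acc_conditions = c("E10.5", "E12.5"),
                       acc_n_replicates = 2L,
                       acc_fold = 4,
                       acc_base_count = 100,
                       peak_width_bp = 400L) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.numeric(chrom_length_bp),
              n_genes = as.integer(n_genes), populations = populations,
              n_peaks = as.integer(n_peaks),
              n_planted_se = as.integer(n_planted_se),
              se_signal_scale = se_signal_scale,
              se_active_populations = se_active_populations,
              n_planted_links = as.integer(n_planted_links),
              fragment_mean_bp = as.integer(fragment_mean_bp),
              acc_n_region_peaks = as.integer(acc_n_region_peaks),
              acc_n_background_peaks = as.integer(acc_n_background_peaks),
              acc_n_per_class = as.integer(acc_n_per_class),
              acc_conditions = acc_conditions,
              acc_n_replicates = as.integer(acc_n_replicates),
              acc_fold = acc_fold, acc_base_count = acc_base_count,
              peak_width_bp = as.integer(peak_width_bp))
  counts <- c("n_chromosomes", "chrom_length_bp", "n_genes", "n_peaks",
              "n_planted_se", "fragment_mean_bp", "acc_n_region_peaks",
              "acc_n_background_peaks", "acc_n_replicates", "peak_width_bp")
  for (nm in counts) {
    if (cfg[[nm]] <= 0) stop("sim_config: ", nm, " must be positive")
  }
  if (cfg$n_planted_links < 0) {
    stop("sim_config: n_planted_links must be non-negative")
  }
  if (cfg$se_signal_scale < 1) stop("sim_config: se_signal_scale must be >= 1")
  if (length(cfg$populations) < 1L) stop("sim_config: need >= 1 population")
  class(cfg) <- "sim_config"
  cfg
}

.chrom_names <- function(config) paste0("chr", seq_len(config$n_chromosomes))

#' Simulate gene annotation and a restriction-fragment map
#'
#' Genes get one TSS each, placed on a coarse grid so TSSs never coincide;
#' restriction fragments tile each chromosome without gaps, with lengths
#' drawn i.i.d. from an exponential distribution with mean
#' `fragment_mean_bp` (truncated below at 150 bp, so the realised mean is
#' slightly larger), and the last fragment trimmed to the chromosome end.
#'
#' @param config A [sim_config()].
#' @return A list with `annotation` (data.frame: gene_id, chrom, tss, strand,
#'   gene_length_bp) and `fragments` (a `GRanges` tiling the genome, with a
#'   `fragment_id` column).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(.child_seed(config$seed, "annotation"), {
    chroms <- .chrom_names(config)
    # TSS grid: 8 kb spacing, away from chromosome ends
    grid_by <- 8000
    per_chrom <- diff(round(seq(0, config$n_genes, length.out =
                                  config$n_chromosomes + 1L)))
    ann <- do.call(rbind, lapply(seq_along(chroms), function(i) {
      ng <- per_chrom[i]
      if (ng == 0L) return(NULL)
      cand <- seq(20000, config$chrom_length_bp - 20000, by = grid_by)
      if (length(cand) < ng) {
        stop("chromosome too short for requested number of genes")
      }
      data.frame(chrom = chroms[i], tss = sort(sample(cand, ng)),
                 strand = sample(c("+", "-"), ng, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    ann$gene_id <- sprintf("gene%03d", seq_len(nrow(ann)))
    ann$gene_length_bp <- round(exp(stats::runif(nrow(ann), log(1000),
                                                 log(50000))))
    ann <- ann[, c("gene_id", "chrom", "tss", "strand", "gene_length_bp")]

    frag_df <- do.call(rbind, lapply(chroms, function(ch) {
      len <- config$chrom_length_bp
      n_guess <- ceiling(len / config$fragment_mean_bp * 1.5) + 10L
      sizes <- pmax(150, round(stats::rexp(n_guess, 1 / config$fragment_mean_bp)))
      while (sum(sizes) < len) {
        sizes <- c(sizes, pmax(150, round(stats::rexp(n_guess,
                                                      1 / config$fragment_mean_bp))))
      }
      ends <- cumsum(sizes)
      sizes <- sizes[seq_len(which(ends >= len)[1L])]
      ends <- cumsum(sizes)
      ends[length(ends)] <- len
      starts <- c(1, utils::head(ends, -1) + 1)
      keep <- ends >= starts
      data.frame(chrom = ch, start = starts[keep], end = ends[keep])
    }))
    frags <- GenomicRanges::GRanges(frag_df$chrom,
                                    IRanges::IRanges(frag_df$start,
                                                     frag_df$end))
    S4Vectors::mcols(frags)$fragment_id <- sprintf("frag%05d",
                                                   seq_along(frags))
    list(annotation = ann, fragments = frags)
  })
}

.promoter_windows <- function(annotation, flank = 2500) {
  GenomicRanges::GRanges(annotation$chrom,
                         IRanges::IRanges(pmax(1, annotation$tss - flank),
                                          annotation$tss + flank))
}

#' Simulate H3K27ac peaks with planted super-enhancer clusters
#'
#' Background peaks draw raw counts from a log-normal body (meanlog 3,
#' sdlog 0.8), giving the convex ranked-signal curve on which the
#' hockey-stick cutoff is defined.  `n_planted_se` clusters of 3-5 peaks
#' within the stitching distance are planted in reserved genomic blocks that
#' keep clear of promoter windows, and their counts are multiplied by
#' `se_signal_scale` in the populations where the SE is active.  Planted
#' (SE, gene, population) links are drawn here as well and recorded in the
#' ground truth, each link naming one population in which both the SE and
#' the gene will be active.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation()].
#' @return A list with `peaks` (`GRanges` with `peak_id`), `counts`
#'   (peaks x populations integer matrix), `library_totals` (per-population
#'   totals), and `ground_truth` (list with `planted_se` GRanges carrying
#'   `se_id` and `active_populations`, `peak_assignment`, and
#'   `planted_links` data.frame: se_id, gene_id, population).
#' @export
simulate_h3k27ac <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_planted_se * 3L > config$n_peaks) {
    stop("n_planted_se x 3 exceeds n_peaks")
  }
  ann <- annotation$annotation
  .with_seed(.child_seed(config$seed, "h3k27ac"), {
    chroms <- .chrom_names(config)
    npop <- length(config$populations)
    prom <- .promoter_windows(ann)

    # reserved blocks for planted clusters, clear of promoter windows
    block_w <- 25000
    block_sep <- 40000
    cand <- do.call(rbind, lapply(chroms, function(ch) {
      starts <- seq(30000, config$chrom_length_bp - block_w - 30000,
                    by = block_sep)
      data.frame(chrom = ch, start = starts, stringsAsFactors = FALSE)
    }))
    cand_gr <- GenomicRanges::GRanges(cand$chrom,
                                      IRanges::IRanges(cand$start - 15000,
                                                       cand$start + block_w + 15000))
    cand <- cand[!IRanges::overlapsAny(cand_gr, prom), , drop = FALSE]
    if (nrow(cand) < config$n_planted_se) {
      stop("genome too small for requested number of planted SEs")
    }
    picks <- cand[sample.int(nrow(cand), config$n_planted_se), , drop = FALSE]

    planted <- list()
    for (i in seq_len(config$n_planted_se)) {
      npk <- sample(3:5, 1L)
      widths <- sample(300:700, npk, replace = TRUE)
      gaps <- sample(500:2500, npk, replace = TRUE)
      starts <- picks$start[i] + cumsum(c(gaps[1L],
                                          utils::head(widths, -1) + gaps[-1L]))
      planted[[i]] <- data.frame(chrom = picks$chrom[i], start = starts,
                                 end = starts + widths - 1L,
                                 se_id = sprintf("SE%02d", i),
                                 stringsAsFactors = FALSE)
    }
    planted <- do.call(rbind, planted)

    # background peaks avoid the reserved blocks (+stitching buffer) so no
    # chain can join a planted cluster to anything else
    n_bg <- config$n_peaks - nrow(planted)
    if (n_bg < 0L) stop("planted clusters exceed n_peaks; increase n_peaks")
    avoid <- GenomicRanges::GRanges(picks$chrom,
                                    IRanges::IRanges(picks$start - 13000,
                                                     picks$start + block_w + 13000))
    bg <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0))
    while (nrow(bg) < n_bg) {
      need <- n_bg - nrow(bg)
      ch <- sample(chroms, need, replace = TRUE)
      w <- sample(300:700, need, replace = TRUE)
      st <- floor(stats::runif(need, 1, config$chrom_length_bp - 701))
      gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(st, st + w - 1L))
      ok <- !IRanges::overlapsAny(gr, avoid)
      bg <- rbind(bg, data.frame(chrom = ch[ok], start = st[ok],
                                 end = st[ok] + w[ok] - 1L,
                                 stringsAsFactors = FALSE)[seq_len(min(sum(ok), need)), ])
    }
    bg$se_id <- "background"

    all_pk <- rbind(planted, bg)
    ord <- order(all_pk$chrom, all_pk$start)
    all_pk <- all_pk[ord, ]
    all_pk$peak_id <- sprintf("peak%04d", seq_len(nrow(all_pk)))

    peaks <- GenomicRanges::GRanges(all_pk$chrom,
                                    IRanges::IRanges(all_pk$start, all_pk$end))
    S4Vectors::mcols(peaks)$peak_id <- all_pk$peak_id

    counts <- matrix(round(stats::rlnorm(nrow(all_pk) * npop, meanlog = 3,
                                         sdlog = 0.8)),
                     nrow = nrow(all_pk), ncol = npop,
                     dimnames = list(all_pk$peak_id, config$populations))

    # activity of each planted SE per population
    se_ids <- sprintf("SE%02d", seq_len(config$n_planted_se))
    if (identical(config$se_active_populations, "all")) {
      active <- stats::setNames(rep(list(config$populations), length(se_ids)),
                                se_ids)
    } else {
      k <- min(as.integer(config$se_active_populations), npop)
      active <- stats::setNames(lapply(se_ids, function(s)
        sample(config$populations, k)), se_ids)
    }
    for (s in se_ids) {
      rows <- all_pk$peak_id[all_pk$se_id == s]
      cols <- active[[s]]
      counts[rows, cols] <- round(counts[rows, cols] * config$se_signal_scale)
    }
    library_totals <- stats::setNames(round(colSums(counts) * 50),
                                      config$populations)

    span_df <- do.call(rbind, lapply(se_ids, function(s) {
      sub <- all_pk[all_pk$se_id == s, ]
      data.frame(chrom = sub$chrom[1L], start = min(sub$start),
                 end = max(sub$end))
    }))
    se_span <- GenomicRanges::GRanges(span_df$chrom,
                                      IRanges::IRanges(span_df$start,
                                                       span_df$end))
    S4Vectors::mcols(se_span)$se_id <- se_ids
    S4Vectors::mcols(se_span)$n_peaks <-
      vapply(se_ids, function(s) sum(all_pk$se_id == s), 0L)
    S4Vectors::mcols(se_span)$active_populations <-
      vapply(active, paste, "", collapse = ",")

    # planted links: SE -> gene on the same chromosome, >= 50 kb away,
    # in one population where the SE is active
    links <- NULL
    if (config$n_planted_links > 0L) {
      pick_se <- se_ids[((seq_len(config$n_planted_links) - 1L) %%
                           length(se_ids)) + 1L]
      used <- character(0)
      links <- do.call(rbind, lapply(pick_se, function(s) {
        span <- se_span[S4Vectors::mcols(se_span)$se_id == s]
        cand_g <- ann[ann$chrom == as.character(GenomeInfoDb::seqnames(span)) &
                        abs(ann$tss - GenomicRanges::start(span)) >= 50000 &
                        !(ann$gene_id %in% used), , drop = FALSE]
        if (nrow(cand_g) == 0L) cand_g <- ann[!(ann$gene_id %in% used), ,
                                              drop = FALSE]
        g <- cand_g$gene_id[sample.int(nrow(cand_g), 1L)]
        used <<- c(used, g)
        data.frame(se_id = s, gene_id = g,
                   population = sample(active[[s]], 1L),
                   stringsAsFactors = FALSE)
      }))
    }

    list(peaks = peaks, counts = counts, library_totals = library_totals,
         ground_truth = list(planted_se = se_span,
                             peak_assignment = stats::setNames(all_pk$se_id,
                                                               all_pk$peak_id),
                             planted_links = links))
  })
}

#' Simulate per-population expression tables
#'
#' Genes carrying a planted link are highly expressed (RPKM 10-100) in the
#' link's designated population and near-silent (RPKM < 1.5) elsewhere;
#' all other genes draw a population-independent RPKM from U(0, 8).  Raw
#' counts are derived from the target RPKM, the gene length and a fixed
#' library total, so `rpkm()` applied to the counts reproduces the targets
#' up to count rounding.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation()].
#' @param ground_truth Ground truth from [simulate_h3k27ac()].
#' @return A list with `counts` and `rpkm` (genes x populations matrices)
#'   and `library_totals`.
#' @export
simulate_expression <- function(config, annotation, ground_truth) {
  stopifnot(inherits(config, "sim_config"))
  ann <- annotation$annotation
  links <- ground_truth$planted_links
  .with_seed(.child_seed(config$seed, "expression"), {
    npop <- length(config$populations)
    total <- 2e7
    target <- matrix(stats::runif(nrow(ann), 0, 8), nrow = nrow(ann),
                     ncol = npop,
                     dimnames = list(ann$gene_id, config$populations))
    if (!is.null(links)) {
      for (i in seq_len(nrow(links))) {
        g <- links$gene_id[i]
        target[g, ] <- stats::runif(npop, 0, 1.5)
        target[g, links$population[i]] <- stats::runif(1, 10, 100)
      }
    }
    len_kb <- ann$gene_length_bp / 1000
    counts <- round(target * len_kb * (total / 1e6))
    rpkm_m <- counts / len_kb / (total / 1e6)
    list(counts = counts, rpkm = rpkm_m,
         library_totals = stats::setNames(rep(total, npop),
                                          config$populations))
  })
}

#' Simulate promoter-capture interaction tables per population
#'
#' Each gene's bait is the restriction fragment containing its TSS.
#' Background bait/other-end pairs draw scores from an exponential with mean
#' 1, so the fraction of background scores at or above the high-confidence
#' threshold of 5 follows the closed-form tail exp(-5).  For every planted
#' (SE, gene, population) link, all fragments overlapping the SE get scores
#' of 5 + Exp(mean 3) in the designated population and sub-threshold
#' background scores elsewhere.  Read counts are Poisson with a mean that
#' increases with the score, so n_reads and score are positively correlated.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation()].
#' @param ground_truth Ground truth from [simulate_h3k27ac()].
#' @param n_background_per_bait Background other-end fragments per bait.
#' @return A named list (one per population) of interaction data.frames in
#'   the [read_interaction_table()] layout (1-based starts).
#' @export
simulate_interactions <- function(config, annotation, ground_truth,
                                  n_background_per_bait = 12L) {
  stopifnot(inherits(config, "sim_config"))
  ann <- annotation$annotation
  frags <- annotation$fragments
  links <- ground_truth$planted_links
  se_span <- ground_truth$planted_se

  tss_gr <- GenomicRanges::GRanges(ann$chrom, IRanges::IRanges(ann$tss, ann$tss))
  hit <- GenomicRanges::findOverlaps(tss_gr, frags, select = "first")
  if (anyNA(hit)) stop("gene TSS not covered by the fragment map: ",
                       paste(ann$gene_id[is.na(hit)], collapse = ", "))
  bait_idx <- stats::setNames(hit, ann$gene_id)

  frag_df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(frags)),
                        start = GenomicRanges::start(frags),
                        end = GenomicRanges::end(frags),
                        stringsAsFactors = FALSE)

  .with_seed(.child_seed(config$seed, "interactions"), {
    out <- lapply(config$populations, function(pop) {
      rows <- list()
      for (gi in seq_len(nrow(ann))) {
        g <- ann$gene_id[gi]
        bi <- bait_idx[[g]]
        same_chrom <- which(frag_df$chrom == frag_df$chrom[bi])
        cand <- setdiff(same_chrom, bi)
        k <- min(n_background_per_bait, length(cand))
        oe <- sample(cand, k)
        score <- stats::rexp(k, 1)
        rows[[length(rows) + 1L]] <-
          data.frame(bait_chrom = frag_df$chrom[bi],
                     bait_start = frag_df$start[bi],
                     bait_end = frag_df$end[bi], bait_gene = g,
                     oe_chrom = frag_df$chrom[oe],
                     oe_start = frag_df$start[oe], oe_end = frag_df$end[oe],
                     n_reads = stats::rpois(k, 1 + 2 * score),
                     score = score, stringsAsFactors = FALSE)
      }
      if (!is.null(links)) {
        for (li in seq_len(nrow(links))) {
          s <- links$se_id[li]
          g <- links$gene_id[li]
          bi <- bait_idx[[g]]
          span <- se_span[S4Vectors::mcols(se_span)$se_id == s]
          oe <- S4Vectors::queryHits(GenomicRanges::findOverlaps(frags, span))
          oe <- setdiff(oe, bi)
          if (length(oe) == 0L) stop("planted SE not covered by fragments: ", s)
          if (pop == links$population[li]) {
            score <- 5 + stats::rexp(length(oe), 1 / 3)
            n_reads <- stats::rpois(length(oe), 5 + 4 * score)
          } else {
            # in populations without the planted contact the fragments look
            # like background: sub-threshold scores, background read law
            score <- stats::rexp(length(oe), 1)
            while (any(score >= 5)) {
              score[score >= 5] <- stats::rexp(sum(score >= 5), 1)
            }
            n_reads <- stats::rpois(length(oe), 1 + 2 * score)
          }
          rows[[length(rows) + 1L]] <-
            data.frame(bait_chrom = frag_df$chrom[bi],
                       bait_start = frag_df$start[bi],
                       bait_end = frag_df$end[bi], bait_gene = g,
                       oe_chrom = frag_df$chrom[oe],
                       oe_start = frag_df$start[oe],
                       oe_end = frag_df$end[oe],
                       n_reads = n_reads,
                       score = score, stringsAsFactors = FALSE)
        }
      }
      df <- do.call(rbind, rows)
      rownames(df) <- NULL
      df
    })
    stats::setNames(out, config$populations)
  })
}

#' Simulate a two-condition accessibility experiment
#'
#' Generates accessibility peaks and a count matrix over two conditions with
#' replicates.  Inside a fixed focus region on chr1, `acc_n_region_peaks`
#' peaks carry three planted temporal profiles in equal parts: profile 1 is
#' more accessible in the second condition, profile 2 in the first, and
#' profile 3 is flat.  Genome-wide background peaks include
#' `acc_n_per_class` peaks following each of the three profiles (these are
#' the recoverable analogues of the profile-correlated peak sets) plus flat
#' background.  Counts are Poisson around per-peak baselines.
#'
#' @param config A [sim_config()].
#' @return A list with `peaks` (`GRanges`, `peak_id` column), `counts`
#'   (peaks x samples), `library_totals`, `region` (the focus `GRanges`),
#'   and `ground_truth` (per-peak labels: "1", "2", "3" or "background").
#' @export
simulate_accessibility <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(.child_seed(config$seed, "accessibility"), {
    chroms <- .chrom_names(config)
    w <- config$peak_width_bp
    region_start <- round(config$chrom_length_bp * 0.70)
    region <- GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(region_start,
                                                      region_start + 400000 - 1))

    nr <- config$acc_n_region_peaks
    r_starts <- round(seq(region_start + 2000,
                          region_start + 400000 - w - 2000,
                          length.out = nr))
    region_pk <- data.frame(chrom = "chr1", start = r_starts,
                            label = as.character(rep_len(1:3, nr)),
                            stringsAsFactors = FALSE)

    nb <- config$acc_n_background_peaks
    b_chrom <- sample(chroms, nb, replace = TRUE)
    b_start <- floor(stats::runif(nb, 1, config$chrom_length_bp - w - 1))
    # keep background out of the focus region
    inside <- b_chrom == "chr1" & b_start > region_start - w &
      b_start < region_start + 400000
    while (any(inside)) {
      b_start[inside] <- floor(stats::runif(sum(inside), 1,
                                            config$chrom_length_bp - w - 1))
      inside <- b_chrom == "chr1" & b_start > region_start - w &
        b_start < region_start + 400000
    }
    b_label <- rep("background", nb)
    n_cls <- min(config$acc_n_per_class, floor(nb / 3))
    b_label[seq_len(3 * n_cls)] <- as.character(rep(1:3, each = n_cls))
    b_label <- sample(b_label)
    bg_pk <- data.frame(chrom = b_chrom, start = b_start, label = b_label,
                        stringsAsFactors = FALSE)

    pk <- rbind(region_pk, bg_pk)
    pk$end <- pk$start + w - 1L
    ord <- order(pk$chrom, pk$start)
    pk <- pk[ord, ]
    pk$peak_id <- sprintf("apeak%05d", seq_len(nrow(pk)))

    samples <- as.vector(outer(config$acc_conditions,
                               seq_len(config$acc_n_replicates),
                               function(c, r) paste0(c, "_r", r)))
    cond_of <- rep(config$acc_conditions, config$acc_n_replicates)

    base <- config$acc_base_count * stats::runif(nrow(pk), 0.5, 2)
    lam <- matrix(base, nrow = nrow(pk), ncol = length(samples),
                  dimnames = list(pk$peak_id, samples))
    up2 <- pk$label == "1"   # up in second condition
    up1 <- pk$label == "2"   # up in first condition
    second <- cond_of == config$acc_conditions[2L]
    lam[up2, second] <- lam[up2, second] * config$acc_fold
    lam[up1, !second] <- lam[up1, !second] * config$acc_fold
    counts <- matrix(stats::rpois(length(lam), lam), nrow = nrow(lam),
                     dimnames = dimnames(lam))

    peaks <- GenomicRanges::GRanges(pk$chrom,
                                    IRanges::IRanges(pk$start, pk$end))
    S4Vectors::mcols(peaks)$peak_id <- pk$peak_id
    list(peaks = peaks, counts = counts,
         library_totals = stats::setNames(round(colSums(counts) * 25),
                                          samples),
         region = region,
         ground_truth = stats::setNames(pk$label, pk$peak_id))
  })
}

#' The bundled synthetic motif set
#'
#' Eight synthetic position frequency matrices (8-10 bp, strongly peaked
#' columns) shipped with the package for simulation and testing.  They are
#' constructed, not downloaded: consensus-dominated columns (97 vs 1
#' counts) give consensus log2-odds scores well above the scanning
#' threshold while single-mismatch windows fall below it.
#'
#' @return A named list of motifs in the [read_jaspar_pfm()] layout.
#' @export
synthetic_motif_set <- function() {
  read_jaspar_pfm(system.file("extdata", "synthetic_motifs.jaspar",
                              package = "crestse", mustWork = TRUE))
}

#' Consensus sequence of a motif
#'
#' @param motif A motif as returned by [read_jaspar_pfm()].
#' @return The consensus string (per-column argmax base).
#' @export
motif_consensus <- function(motif) {
  paste(rownames(motif$counts)[apply(motif$counts, 2L, which.max)],
        collapse = "")
}

#' Simulate peak sequences with planted motif instances
#'
#' Background bases are i.i.d. uniform over A, C, G, T.  For every row of
#' `planting`, one consensus instance of the named motif is written into the
#' named peak at a uniformly random offset (on a uniformly random strand),
#' and the instance is recorded in the ground truth.
#'
#' @param config A [sim_config()] (provides the seed).
#' @param peaks `GRanges` with a `peak_id` column; sequence lengths are the
#'   peak widths.
#' @param motifs Named list of motifs ([read_jaspar_pfm()] layout).
#' @param planting Data frame with columns `peak_id` and `motif_id`, one row
#'   per instance to plant; `NULL` plants nothing.
#' @return A list with `sequences` (a named `DNAStringSet`) and `truth`
#'   (data.frame: peak_id, motif_id, start, strand; start is the 1-based
#'   offset of the instance within the peak sequence).
#' @export
simulate_sequences <- function(config, peaks, motifs, planting = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ids <- S4Vectors::mcols(peaks)$peak_id
  widths <- GenomicRanges::width(peaks)
  .with_seed(.child_seed(config$seed, "sequences"), {
    seqs <- vapply(widths, function(w)
      paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
            collapse = ""), "")
    names(seqs) <- ids
    truth <- data.frame(peak_id = character(0), motif_id = character(0),
                        start = integer(0), strand = character(0),
                        stringsAsFactors = FALSE)
    if (!is.null(planting) && nrow(planting) > 0L) {
      for (i in seq_len(nrow(planting))) {
        pid <- planting$peak_id[i]
        mid <- planting$motif_id[i]
        cons <- motif_consensus(motifs[[mid]])
        L <- nchar(cons)
        w <- nchar(seqs[[pid]])
        if (w < L) next
        off <- sample.int(w - L + 1L, 1L)
        strand <- sample(c("+", "-"), 1L)
        ins <- if (strand == "+") cons else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
        substr(seqs[[pid]], off, off + L - 1L) <- ins
        truth <- rbind(truth, data.frame(peak_id = pid, motif_id = mid,
                                         start = off, strand = strand,
                                         stringsAsFactors = FALSE))
      }
    }
    list(sequences = Biostrings::DNAStringSet(seqs), truth = truth)
  })
}

#' Write a complete synthetic data set to disk
#'
#' Emits every pipeline input in the on-disk formats the package reads:
#' peaks and blacklist BED, count and totals TSVs, gene annotation TSV,
#' fragment map BED, per-population interaction tables, expression TSV,
#' accessibility counts, peak FASTA, motif PFMs, and a ground-truth JSON.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
simulate_to_dir <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  annot <- simulate_annotation(config)
  chip <- simulate_h3k27ac(config, annot)
  expr <- simulate_expression(config, annot, chip$ground_truth)
  ints <- simulate_interactions(config, annot, chip$ground_truth)
  acc <- simulate_accessibility(config)

  write_annotation(annot$annotation, p("genes.tsv"))
  write_bed(annot$fragments, p("fragments.bed"))
  write_bed(chip$peaks, p("h3k27ac_peaks.bed"))
  write_matrix_tsv(chip$counts, p("h3k27ac_counts.tsv"), id_col = "peak_id")
  utils::write.table(data.frame(sample = names(chip$library_totals),
                                total = as.numeric(chip$library_totals)),
                     p("h3k27ac_totals.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (pop in names(ints)) {
    write_interaction_table(ints[[pop]],
                            p(sprintf("interactions_%s.tsv", pop)))
  }
  write_matrix_tsv(expr$rpkm, p("expression_rpkm.tsv"), id_col = "gene_id")
  write_bed(acc$peaks, p("atac_peaks.bed"))
  write_matrix_tsv(acc$counts, p("atac_counts.tsv"), id_col = "peak_id")

  gt <- chip$ground_truth
  truth <- list(
    planted_se = data.frame(
      se_id = S4Vectors::mcols(gt$planted_se)$se_id,
      chrom = as.character(GenomeInfoDb::seqnames(gt$planted_se)),
      start = GenomicRanges::start(gt$planted_se),
      end = GenomicRanges::end(gt$planted_se),
      active_populations = S4Vectors::mcols(gt$planted_se)$active_populations),
    planted_links = gt$planted_links,
    accessibility_labels = as.list(acc$ground_truth))
  jsonlite::write_json(truth, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(outdir)
}
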