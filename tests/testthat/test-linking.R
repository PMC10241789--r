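test_that("mean interaction score averages over all recorded interactions", {
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e5, 2e5))
  mk <- function(scores, oe_start = 110000) {
    data.frame(bait_chrom = "chr1", bait_start = 1000, bait_end = 5000,
               bait_gene = "geneA", oe_chrom = "chr1",
               oe_start = oe_start + seq_along(scores) * 3000,
               oe_end = oe_start + seq_along(scores) * 3000 + 2000,
               n_reads = 5, score = scores, stringsAsFactors = FALSE)
  }
  expect_equal(mean_interaction_score("geneA", region, mk(c(5, 7, 9))), 7)
  expect_equal(mean_interaction_score("geneA", region, mk(6)), 6)
  # sub-threshold scores are still part of the mean
  expect_equal(mean_interaction_score("geneA", region, mk(c(8, 2))), 5)
  # no recorded interaction: missing value, not zero
  far <- mk(5, oe_start = 9e5)
  expect_true(is.na(mean_interaction_score("geneA", region, far)))
  expect_true(is.na(mean_interaction_score("geneB", region, mk(5))))
})

test_that("linking enforces score >= 5, RPKM > 2 (strict) and SE activity", {
  catalogue <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e5, 2e5))
  S4Vectors::mcols(catalogue)$region_id <- "regionA"
  se_results <- list(P1 = list(ranked = data.frame(region_id = "regionA",
                                                   is_se = TRUE)))
  mk <- function(score) {
    list(P1 = data.frame(bait_chrom = "chr1", bait_start = 1000,
                         bait_end = 5000, bait_gene = "geneA",
                         oe_chrom = "chr1", oe_start = 150000,
                         oe_end = 153000, n_reads = 10, score = score,
                         stringsAsFactors = FALSE))
  }
  expr <- function(rpkm) matrix(rpkm, 1, 1,
                                dimnames = list("geneA", "P1"))
  # boundary: score exactly 5 is significant, RPKM exactly 2 is not expressed
  expect_equal(nrow(link_ses_to_promoters(catalogue, se_results, mk(5.0),
                                          expr(3))), 1L)
  expect_equal(nrow(link_ses_to_promoters(catalogue, se_results, mk(7.2),
                                          expr(2.0))), 0L)
  expect_equal(nrow(link_ses_to_promoters(catalogue, se_results, mk(4.99),
                                          expr(10))), 0L)
  # SE inactive in the population: no link
  inactive <- list(P1 = list(ranked = data.frame(region_id = "regionA",
                                                 is_se = FALSE)))
  expect_equal(nrow(link_ses_to_promoters(catalogue, inactive, mk(9),
                                          expr(10))), 0L)
  # gene missing from the expression table is an error naming the gene
  bad_expr <- matrix(3, 1, 1, dimnames = list("other", "P1"))
  expect_error(link_ses_to_promoters(catalogue, se_results, mk(5), bad_expr),
               "geneA")
})

test_that("planted links are recovered and sub-threshold pairs are not linked", {
  cfg <- sim_config(seed = 1)
  ann <- simulate_annotation(cfg)
  chip <- simulate_h3k27ac(cfg, ann)
  gt <- chip$ground_truth
  fp <- filter_peaks(chip$peaks, ann$annotation,
                     allowed_chroms = paste0("chr", 1:3))
  cpm <- compute_cpm(chip$counts[S4Vectors::mcols(fp)$peak_id, ],
                     chip$library_totals)
  st <- stitch_peaks(fp, cpm, annotation = ann$annotation)
  cat_res <- se_catalogue(st)
  ints <- simulate_interactions(cfg, ann, gt)
  expr <- simulate_expression(cfg, ann, gt)
  links <- link_ses_to_promoters(cat_res$catalogue, cat_res$per_sample, ints,
                                 expr$rpkm)
  # every planted (SE, gene, population) link is found in its population
  ids <- S4Vectors::mcols(cat_res$catalogue)$region_id
  for (i in seq_len(nrow(gt$planted_links))) {
    lk <- gt$planted_links[i, ]
    span <- gt$planted_se[S4Vectors::mcols(gt$planted_se)$se_id == lk$se_id]
    reg <- ids[IRanges::overlapsAny(cat_res$catalogue, span)]
    expect_length(reg, 1L)
    row <- links[links$se_id == reg & links$gene_id == lk$gene_id, ]
    expect_equal(nrow(row), 1L)
    expect_true(row[[paste0("linked_", lk$population)]])
  }
  # no linked pair has all scores < 5 in the population where it is linked
  for (p in cfg$populations) {
    lk_rows <- links[links[[paste0("linked_", p)]], , drop = FALSE]
    if (nrow(lk_rows) == 0L) next
    for (j in seq_len(nrow(lk_rows))) {
      reg <- cat_res$catalogue[ids == lk_rows$se_id[j]]
      sub <- ints[[p]][ints[[p]]$bait_gene == lk_rows$gene_id[j], ]
      hit <- IRanges::overlapsAny(interaction_granges(sub, "oe"), reg)
      expect_true(any(sub$score[hit] >= 5))
      expect_gt(lk_rows[[paste0("rpkm_", p)]][j], 2)
    }
  }
  # mean scores match a brute-force rescan of the table
  for (j in seq_len(min(nrow(links), 5))) {
    reg <- cat_res$catalogue[ids == links$se_id[j]]
    for (p in cfg$populations) {
      tab <- ints[[p]]
      acc <- c()
      for (r in seq_len(nrow(tab))) {
        if (tab$bait_gene[r] != links$gene_id[j]) next
        if (brute_overlap(tab$oe_start[r], tab$oe_end[r],
                          GenomicRanges::start(reg),
                          GenomicRanges::end(reg)) &&
            tab$oe_chrom[r] == as.character(GenomeInfoDb::seqnames(reg))) {
          acc <- c(acc, tab$score[r])
        }
      }
      want <- if (length(acc)) mean(acc) else NA_real_
      expect_equal(links[[paste0("mean_score_", p)]][j], want)
    }
  }
})

test_that("relative log2 fold changes match direct arithmetic", {
  expect_equal(relative_log2fc(c(4, 4, 4, 4)), c(0, 0, 0, 0))
  got <- relative_log2fc(c(8, 4, 4, 0), pseudo = 0.5)
  expect_equal(got, c(log2(8.5 / 4.5), 0, 0, log2(0.5 / 4.5)))
  expect_equal(round(got, 3), c(0.918, 0, 0, -3.170))
  # with pseudo 0 a common scale factor cancels
  x <- c(3, 6, 9, 12)
  expect_equal(relative_log2fc(2 * x, pseudo = 0),
               relative_log2fc(x, pseudo = 0))
  expect_error(relative_log2fc(c(-1, 2)), "non-negative")
})

test_that("k-means rows is deterministic and recovers planted centers", {
  set.seed(1)
  centers <- matrix(stats::rnorm(7 * 4, sd = 10), 7, 4)
  x <- centers[rep(1:7, each = 12), ] + stats::rnorm(7 * 12 * 4, sd = 0.1)
  rownames(x) <- sprintf("r%03d", seq_len(nrow(x)))
  fit <- kmeans_rows(x, k = 7, seed = 5)
  truth <- rep(1:7, each = 12)
  expect_equal(mclust::adjustedRandIndex(fit$cluster, truth), 1)
  fit2 <- kmeans_rows(x, k = 7, seed = 5)
  expect_identical(fit, fit2)
  # k = number of (distinct) rows: every row its own cluster, zero WCSS
  y <- matrix(1:12, 4, 3)
  fit3 <- kmeans_rows(y, k = 4, seed = 2)
  expect_equal(fit3$tot_withinss, 0)
  expect_equal(sort(unique(fit3$cluster)), 1:4)
  expect_error(kmeans_rows(y, k = 5, seed = 1), "exceeds")
})

test_that("virtual 4C aggregates duplicate fragments and conserves signal", {
  tab <- data.frame(bait_chrom = "chr1", bait_start = 1000, bait_end = 4000,
                    bait_gene = "geneA", oe_chrom = "chr1",
                    oe_start = c(10000, 50000, 10000, 90000),
                    oe_end = c(13000, 53000, 13000, 93000),
                    n_reads = c(3, 5, 2, 7), score = c(1.5, 2, 2.5, 3),
                    stringsAsFactors = FALSE)
  v <- virtual_4c(tab, "geneA")
  expect_length(v$track, 3L)  # duplicate (bait, other-end) summed
  expect_equal(v$value[GenomicRanges::start(v$track) == 10000], 4)
  expect_equal(sum(v$value), sum(tab$score))  # conservation
  # sorted by coordinate
  expect_true(!is.unsorted(GenomicRanges::start(v$track)))
  expect_error(virtual_4c(tab, "nope"), "unknown bait")
  # bedGraph emission round-trips through read_bed
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(v$track, v$value, bg)
  back <- read_bed(bg)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(v$track))
  expect_equal(as.numeric(S4Vectors::mcols(back)$name), v$value)
})

test_that("pairwise quantile normalisation equalises the two distributions", {
  qn <- quantile_normalize_pair(c(1, 2, 3), c(4, 5, 6))
  expect_equal(qn$a, c(2.5, 3.5, 4.5))
  expect_equal(qn$b, c(2.5, 3.5, 4.5))
  set.seed(14)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    a <- stats::runif(n) * 100  # continuous, tie-free
    b <- stats::rexp(n) * 50
    qn <- quantile_normalize_pair(a, b)
    expect_equal(sort(qn$a), sort(qn$b))
    expect_equal(order(qn$a), order(a))  # rank-preserving
  }
  # tie groups receive the mean of the reference over their positions
  qn2 <- quantile_normalize_pair(c(2, 2, 10), c(1, 3, 5))
  ref <- (sort(c(2, 2, 10)) + sort(c(1, 3, 5))) / 2  # 1.5, 2.5, 7.5
  expect_equal(qn2$a, c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
})

test_that("pairwise quantile normalisation agrees with limma on tie-free input", {
  set.seed(15)
  a <- stats::runif(40) * 10
  b <- stats::rlnorm(40)
  qn <- quantile_normalize_pair(a, b)
  ref <- limma::normalizeQuantiles(cbind(a, b))
  expect_equal(qn$a, unname(ref[, 1]))
  expect_equal(qn$b, unname(ref[, 2]))
})

test_that("region interaction change reproduces exact percent arithmetic", {
  mk <- function(starts, reads) {
    data.frame(bait_chrom = "chr1", bait_start = 1000, bait_end = 4000,
               bait_gene = "geneA", oe_chrom = "chr1", oe_start = starts,
               oe_end = starts + 2000, n_reads = reads,
               score = 1, stringsAsFactors = FALSE)
  }
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10000, 30000))
  starts <- c(10000, 20000, 50000, 80000)  # first two inside the region
  # same count multiset in both samples: normalisation is the identity,
  # region sums 100 (a) vs 73 (b)
  a <- mk(starts, c(60, 40, 70, 3))
  b <- mk(starts, c(70, 3, 60, 40))
  expect_equal(region_interaction_change(a, b, "geneA", region), 27)
  expect_equal(region_interaction_change(a, a, "geneA", region), 0)
  # both samples empty over the region: the normalised region signal in
  # sample a is zero and the change is undefined
  z <- mk(starts, c(0, 0, 5, 5))
  z2 <- mk(starts, c(0, 0, 60, 40))
  expect_error(region_interaction_change(z, z2, "geneA", region), "undefined")
  expect_error(region_interaction_change(a, b, "geneB", region),
               "both samples")
})
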