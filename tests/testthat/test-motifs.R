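test_that("promoter/enhancer classification uses a strict 1 kb midpoint rule", {
  ann <- one_gene_annotation(chrom = "chr1", tss = 10000)
  # half-open midpoints against tss0 = 9999: [10993, 11003) -> 10998 ->
  # 999 bp from the TSS; [10994, 11004) -> 10999 -> exactly 1000 bp
  pks <- make_peaks(c("chr1", "chr1", "chrX"),
                    c(10994, 10995, 500), c(11003, 11004, 900))
  out <- classify_enhancer_peaks(pks, ann)
  expect_equal(unname(out$tss_distance[1:2]), c(999, 1000))
  expect_equal(S4Vectors::mcols(out$promoters)$peak_id, "pk001")
  # the 1000 bp peak is an enhancer; the chrX peak is dropped from the set
  expect_equal(S4Vectors::mcols(out$enhancers)$peak_id, "pk002")
  expect_error(classify_enhancer_peaks(pks, ann[0, ]), "non-empty")
})

test_that("accessibility matrix is logCPM with centred relative rows", {
  counts <- matrix(c(0, 1, 10, 100), 2, 2,
                   dimnames = list(c("p1", "p2"), c("s1", "s2")))
  am <- build_accessibility_matrix(counts, c(s1 = 1e6, s2 = 1e6))
  expect_equal(am$logcpm["p1", "s1"], 0)    # log2(0 + 1)
  expect_equal(am$logcpm["p2", "s1"], 1)    # CPM 1 -> log2(2)
  expect_equal(unname(rowSums(am$relative)), c(0, 0))
})

test_that("region profile clustering recovers planted labels and is stable", {
  cfg <- sim_config(seed = 4)
  acc <- simulate_accessibility(cfg)
  am <- build_accessibility_matrix(acc$counts, acc$library_totals)
  cl <- cluster_region_peaks(am, acc$peaks, acc$region, k = 3, seed = 11)
  truth <- acc$ground_truth[cl$peak_ids]
  expect_gte(mclust::adjustedRandIndex(cl$labels, truth), 0.9)
  cl2 <- cluster_region_peaks(am, acc$peaks, acc$region, k = 3, seed = 11)
  expect_identical(cl$labels, cl2$labels)
  tiny <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2))
  expect_error(cluster_region_peaks(am, acc$peaks, tiny, k = 3, seed = 1),
               "fewer than k")
})

test_that("degenerate all-identical region rows cannot fill k clusters", {
  pks <- make_peaks("chr1", c(100, 300, 500, 700), c(200, 400, 600, 800))
  counts <- matrix(100, 4, 4, dimnames = list(S4Vectors::mcols(pks)$peak_id,
                                              paste0("s", 1:4)))
  am <- build_accessibility_matrix(counts, stats::setNames(rep(1e6, 4),
                                                           paste0("s", 1:4)))
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  expect_error(cluster_region_peaks(am, pks, region, k = 3, seed = 1),
               "degenerate|failed")
})

test_that("profile ranking computes Pearson correlations and disjoint sets", {
  profiles <- rbind(cluster1 = c(-1, -1, 1, 1), cluster2 = c(1, 1, -1, -1),
                    cluster3 = c(-1, 1, -1, 1))
  pks <- make_peaks("chr1", seq(100, by = 1000, length.out = 6),
                    seq(100, by = 1000, length.out = 6) + 400)
  rel <- rbind(c(-2, -2, 2, 2),      # = profile 1 pattern -> r = 1
               c(2, 2, -2, -2),      # = -profile 1 -> r = -1 with cluster1
               c(-1, -0.5, 0.5, 1),  # correlates with profile 1
               c(1, 0.5, -0.5, -1),
               c(0, 0, 0, 0),        # zero variance -> r = 0 everywhere
               c(-0.5, 1, -1, 0.5))
  rownames(rel) <- S4Vectors::mcols(pks)$peak_id
  acc <- list(relative = rel)
  rk <- rank_by_profile(acc, pks, profiles, top_n = 10)
  expect_equal(unname(rk$correlation["pk001", "cluster1"]), 1)
  expect_equal(unname(rk$correlation["pk002", "cluster1"]), -1)
  expect_equal(unname(rk$correlation["pk005", ]), c(0, 0, 0))
  # assignment is argmax; sets are disjoint and cover assigned peaks
  expect_equal(unname(rk$assignment[["pk001"]]), 1L)
  expect_equal(unname(rk$assignment[["pk002"]]), 2L)
  all_ids <- unlist(rk$sets)
  expect_false(any(duplicated(all_ids)))
  expect_setequal(c(all_ids, rk$control), S4Vectors::mcols(pks)$peak_id)
  # cap is respected
  rk2 <- rank_by_profile(acc, pks, profiles, top_n = 1)
  expect_true(all(lengths(rk2$sets) <= 1))
  expect_error(rank_by_profile(acc, pks, rbind(c(1, 1, 1, 1)), 10),
               "non-constant")
})

test_that("PWM scanning matches hand-derived log-odds arithmetic", {
  # 6-mer, per-position probability 0.97 consensus / 0.01 off
  m <- list(motif_id = "M", counts = matrix(1, 4, 6,
            dimnames = list(c("A", "C", "G", "T"), NULL)))
  cons <- c("A", "C", "G", "T", "A", "C")
  for (j in 1:6) m$counts[cons[j], j] <- 97
  hit <- scan_pwm("ACGTAC", m)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$score, 6 * log2((97.01 / 100.04) / 0.25), tolerance = 1e-9)
  expect_equal(hit$score, 11.74, tolerance = 1e-2)
  # any single mismatch drops below the threshold (~5.14)
  expect_equal(nrow(scan_pwm("TCGTAC", m)), 0L)
  mm_score <- 5 * log2((97.01 / 100.04) / 0.25) + log2((1.01 / 100.04) / 0.25)
  expect_equal(mm_score, 5.14, tolerance = 1e-2)
  # shorter than the motif: empty, not an error
  expect_equal(nrow(scan_pwm("ACGTA", m)), 0L)
  # N-containing windows never match
  expect_equal(nrow(scan_pwm("ACGNAC", m, tau = -100)), 0L)
})

test_that("PWM scanning equals the brute-force scorer on random inputs", {
  set.seed(77)
  for (i in 1:60) {
    L <- sample(4:12, 1)
    m <- random_motif(L)
    s <- random_dna(sample(L:120, 1),
                    alphabet = c("A", "C", "G", "T",
                                 if (i %% 5 == 0) "N"))
    tau <- sample(c(-2, 0, 2, 5), 1)
    got <- scan_pwm(s, m, tau = tau)
    want <- brute_scan(s, m, tau = tau)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("reverse-complementing a sequence preserves its hit count", {
  set.seed(78)
  for (i in 1:25) {
    m <- random_motif(sample(5:10, 1))
    s <- random_dna(80)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(nrow(scan_pwm(s, m, tau = 0)), nrow(scan_pwm(rc, m, tau = 0)))
  }
})

test_that("hit rates per kb and their mean follow the definition", {
  hits <- matrix(c(2L, 0L), 2, 1, dimnames = list(c("p1", "p2"), "M1"))
  hr <- hit_rate_per_kb(hits, c(500, 250))
  expect_equal(unname(hr$rates[, 1]), c(4, 0))
  expect_equal(unname(hr$mean_rates), 2)
  expect_error(hit_rate_per_kb(hits, 500), "one width per peak")
})

test_that("Fisher enrichment matches the hypergeometric tail oracle", {
  set.seed(99)
  ids_set <- sprintf("s%04d", 1:1000)
  ids_ctl <- sprintf("c%04d", 1:1000)
  # derived example: 50/1000 hits in the set vs 10/1000 in the control
  hits <- matrix(0L, 2000, 1, dimnames = list(c(ids_set, ids_ctl), "M1"))
  hits[ids_set[1:50], 1] <- 1L
  hits[ids_ctl[1:10], 1] <- 1L
  res <- motif_enrichment(list(set1 = ids_set), ids_ctl, hits)
  expect_equal(res$p_value, hyper_tail_p(50, 950, 10, 990), tolerance = 1e-12)
  # random tables with margins <= 2000
  for (i in 1:50) {
    n1 <- sample(10:1000, 1)
    n2 <- sample(10:1000, 1)
    a <- sample(0:n1, 1)
    c_ <- sample(0:n2, 1)
    p_fisher <- stats::fisher.test(matrix(c(a, n1 - a, c_, n2 - c_), 2),
                                   alternative = "greater")$p.value
    expect_equal(p_fisher, hyper_tail_p(a, n1 - a, c_, n2 - c_),
                 tolerance = 1e-9)
  }
  # identical composition: p ~ 1, never selected
  hits2 <- matrix(0L, 200, 1, dimnames = list(c(ids_set[1:100],
                                                ids_ctl[1:100]), "M1"))
  hits2[c(ids_set[1:30], ids_ctl[1:30]), 1] <- 1L
  res2 <- motif_enrichment(list(set1 = ids_set[1:100]), ids_ctl[1:100], hits2)
  expect_gt(res2$p_value, 0.4)
  expect_false(res2$selected)
  expect_error(motif_enrichment(list(s = ids_set), character(0), hits),
               "non-empty")
})

test_that("BH-adjusted FDR is monotone in the sorted raw p-values", {
  set.seed(101)
  ids <- sprintf("p%04d", 1:600)
  hits <- matrix(stats::rbinom(600 * 6, 1, 0.2), 600, 6,
                 dimnames = list(ids, sprintf("M%d", 1:6)))
  res <- motif_enrichment(list(s1 = ids[1:100], s2 = ids[101:200],
                               s3 = ids[201:300]), ids[301:600], hits)
  o <- order(res$p_value)
  expect_true(all(diff(res$fdr[o]) >= -1e-12))
  expect_equal(res$fdr, stats::p.adjust(res$p_value, "BH"))
})

test_that("motif similarity is symmetric with unit diagonal and finds shifts", {
  ms <- synthetic_motif_set()
  S <- motif_similarity_matrix(ms[1:4])
  expect_equal(unname(diag(S)), rep(1, 4))
  expect_equal(S, t(S))
  expect_true(all(S >= -1 & S <= 1 + 1e-12))
  # a shifted copy of a motif is recognised as near-identical
  m <- ms[[1]]
  shifted <- list(motif_id = "shift", counts = cbind(c(1, 1, 1, 97),
                                                     m$counts[, 1:6]))
  rownames(shifted$counts) <- rownames(m$counts)
  expect_gt(motif_similarity(m, shifted), 0.9)
  # the reverse complement orientation scores like the original
  rc <- list(motif_id = "rc",
             counts = m$counts[4:1, ncol(m$counts):1])
  rownames(rc$counts) <- rownames(m$counts)
  expect_equal(motif_similarity(m, rc), 1, tolerance = 1e-9)
})

test_that("representative selection keeps high-rate motifs and picks medoids", {
  ms <- synthetic_motif_set()
  # two planted families: shifted variants of MSYN01 and of MSYN02
  shift_of <- function(m, id, pad) {
    pad_col <- matrix(1, 4, 1, dimnames = list(rownames(m$counts), NULL))
    cts <- if (pad) cbind(pad_col, m$counts[, -ncol(m$counts)]) else m$counts
    list(motif_id = id, name = id, counts = cts)
  }
  fam <- list(A1 = shift_of(ms[[1]], "A1", FALSE),
              A2 = shift_of(ms[[1]], "A2", TRUE),
              A3 = shift_of(ms[[1]], "A3", TRUE),
              B1 = shift_of(ms[[2]], "B1", FALSE),
              B2 = shift_of(ms[[2]], "B2", TRUE),
              low = ms[[8]])
  rates <- c(A1 = 5, A2 = 4.5, A3 = 4.8, B1 = 6, B2 = 5.5, low = 0.05)
  sel <- select_representatives(fam, rates, seed = 3, k_similarity = 2)
  # the low-rate motif is dropped by the rate split
  expect_false("low" %in% sel$table$motif_id)
  # two non-empty similarity clusters matching the families
  cl <- split(sel$table$motif_id, sel$table$cluster)
  expect_length(cl, 2L)
  fams <- lapply(cl, function(x) unique(substr(x, 1, 1)))
  expect_setequal(unlist(fams), c("A", "B"))
  expect_length(sel$representatives, 2L)
  expect_error(select_representatives(fam[1], rates[1]), "at least 2")
})

test_that("identical motifs tie-break to the lexicographically first id", {
  ms <- synthetic_motif_set()
  same <- list(zeta = ms[[1]], alpha = ms[[1]], beta = ms[[1]],
               other = ms[[3]], low = ms[[8]])
  same$zeta$motif_id <- "zeta"; same$alpha$motif_id <- "alpha"
  same$beta$motif_id <- "beta"
  rates <- c(zeta = 5, alpha = 5, beta = 5, other = 5.2, low = 0.1)
  sel <- select_representatives(same, rates, seed = 1, k_similarity = 2)
  ident_cluster <- sel$table$cluster[sel$table$motif_id == "alpha"]
  reps <- sel$table$motif_id[sel$table$representative &
                               sel$table$cluster == ident_cluster]
  expect_equal(reps, "alpha")
})
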