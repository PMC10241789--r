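# Independent oracles used across the suite.  These deliberately share no
# code with the package: each re-derives the quantity by direct enumeration
# or a closed form.

# Exhaustive scan of the hockey-stick objective u_i - v_i.
brute_rose_rank <- function(signals) {
  s <- sort(signals)
  n <- length(s)
  best_i <- 1L
  best <- -Inf
  for (i in seq_len(n)) {
    val <- i / n - (s[i] - s[1]) / (s[n] - s[1])
    if (val > best) {
      best <- val
      best_i <- i
    }
  }
  best_i
}

# Window-by-window PWM scorer; probabilities recomputed from scratch.
brute_scan <- function(seq, motif, tau = 10, pseudocount = 0.01) {
  cts <- motif$counts
  prob <- cts
  for (j in seq_len(ncol(cts))) {
    prob[, j] <- (cts[, j] + pseudocount) / (sum(cts[, j]) + 4 * pseudocount)
  }
  bases <- strsplit(toupper(as.character(seq)), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  L <- ncol(cts)
  n <- length(bases)
  rows <- list()
  if (n >= L) {
    for (o in seq_len(n - L + 1L)) {
      win <- bases[o:(o + L - 1L)]
      for (strand in c("+", "-")) {
        w <- if (strand == "+") win else unname(rev(comp[win]))
        if (any(!w %in% c("A", "C", "G", "T"))) next  # N-window: -Inf
        sc <- 0
        for (j in seq_len(L)) sc <- sc + log2(prob[w[j], j] / 0.25)
        if (sc >= tau) {
          rows[[length(rows) + 1L]] <-
            data.frame(start = o, strand = strand, score = sc)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# One-sided (enrichment) hypergeometric tail for a 2x2 table
# [a, b; c, d] with a = set&hit, b = set&miss, c = control&hit,
# d = control&miss: P(X >= a) by direct summation of the density.
hyper_tail_p <- function(a, b, c_, d) {
  hits <- a + c_
  set_n <- a + b
  total <- a + b + c_ + d
  ks <- a:min(hits, set_n)
  sum(stats::dhyper(ks, hits, total - hits, set_n))
}

# Base-by-base interval overlap on small ranges (1-based closed).
brute_overlap <- function(s1, e1, s2, e2) {
  length(intersect(seq(s1, e1), seq(s2, e2))) > 0
}

# Small fixture helpers ------------------------------------------------------

make_peaks <- function(chrom, start, end, ids = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  if (is.null(ids)) ids <- sprintf("pk%03d", seq_along(gr))
  S4Vectors::mcols(gr)$peak_id <- ids
  gr
}

one_gene_annotation <- function(chrom = "chr1", tss = 1e6,
                                gene_id = "geneA", len = 2000) {
  data.frame(gene_id = gene_id, chrom = chrom, tss = tss, strand = "+",
             gene_length_bp = len, stringsAsFactors = FALSE)
}

random_motif <- function(L, id = "M") {
  counts <- matrix(stats::runif(4 * L, 0.5, 100), 4, L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  list(motif_id = id, name = id, counts = counts)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
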