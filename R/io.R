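#' @importFrom GenomicRanges GRanges start end width strand findOverlaps
#'   countOverlaps reduce seqnames mcols mcols<-
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors queryHits subjectHits DataFrame
#' @importFrom GenomeInfoDb seqnames
NULL

# Internal convention: all intervals live in GRanges (1-based, closed), the
# native Bioconductor representation.  BED and the interaction table are
# 0-based half-open on disk; readers add 1 to starts, writers subtract it, so
# widths are preserved exactly and round trips are the identity.
# Chromosome names are matched by exact string equality throughout; "chr6"
# and "6" are different sequences.

#' Read a BED3/BED6 file into a GRanges
#'
#' Coordinates on disk are interpreted as 0-based half-open (BED convention)
#' and converted to the 1-based closed convention of [GenomicRanges].
#' `track`, `browser` and `#` comment lines are skipped.  Input order is
#' preserved.
#'
#' @param path Path to a tab-delimited BED file with at least 3 columns.
#' @return A `GRanges`, with a `name` metadata column when a 4th BED column
#'   is present and a `score` column when a 5th is present.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr6\t100\t200", bed)
#' gr <- read_bed(bed)
#' GenomicRanges::width(gr)  # 100
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(track|browser|#)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED parse error at line ", lineno[which(nf < 3L)[1L]],
         ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0) | start0 != floor(start0) |
                 end0 != floor(end0))
  if (length(bad) > 0L) {
    stop("BED parse error at line ", lineno[bad[1L]],
         ": non-integer coordinates")
  }
  bad <- which(end0 <= start0 | start0 < 0)
  if (length(bad) > 0L) {
    stop("BED parse error at line ", lineno[bad[1L]],
         ": end <= start or negative start")
  }
  strand <- rep("*", length(lines))
  if (all(nf >= 6L)) {
    s <- vapply(fields, `[[`, "", 6L)
    strand <- ifelse(s %in% c("+", "-"), s, "*")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                               strand = strand)
  if (all(nf >= 4L)) {
    S4Vectors::mcols(gr)$name <- vapply(fields, `[[`, "", 4L)
  }
  if (all(nf >= 5L)) {
    S4Vectors::mcols(gr)$score <-
      suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  }
  gr
}

#' Write a GRanges as BED
#'
#' Inverse of [read_bed()]: emits 0-based half-open coordinates.  A `name`
#' metadata column becomes BED column 4; a `score` column becomes column 5;
#' strand is written as column 6 (with `*` emitted as `.`).
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  n <- length(gr)
  cols <- list(as.character(GenomeInfoDb::seqnames(gr)),
               format(GenomicRanges::start(gr) - 1, scientific = FALSE,
                      trim = TRUE),
               format(GenomicRanges::end(gr), scientific = FALSE, trim = TRUE))
  mc <- S4Vectors::mcols(gr)
  has_name <- "name" %in% colnames(mc)
  has_score <- "score" %in% colnames(mc)
  has_strand <- any(as.character(GenomicRanges::strand(gr)) != "*")
  if (has_name || has_score || has_strand) {
    cols <- c(cols, list(if (has_name) as.character(mc$name) else rep(".", n)))
  }
  if (has_score || has_strand) {
    cols <- c(cols, list(if (has_score) sprintf("%.6g", mc$score)
                         else rep("0", n)))
  }
  if (has_strand) {
    s <- as.character(GenomicRanges::strand(gr))
    cols <- c(cols, list(ifelse(s == "*", ".", s)))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

.interaction_cols <- c("bait_chrom", "bait_start", "bait_end", "bait_gene",
                       "oe_chrom", "oe_start", "oe_end", "n_reads", "score")

#' Read a promoter-capture interaction table
#'
#' The table is an ibed-like tab-delimited file with header columns
#' `bait_chrom, bait_start, bait_end, bait_gene, oe_chrom, oe_start, oe_end,
#' n_reads, score`.  Bait and other-end coordinates are restriction-fragment
#' intervals, 0-based half-open on disk and converted to 1-based starts in
#' the returned data frame.  `n_reads` is the raw read count N supporting
#' the interaction and `score` its CHiCAGO-like significance score.
#'
#' @param path Path to the table.
#' @return A data.frame with the columns above (starts 1-based).
#' @export
read_interaction_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.interaction_cols, colnames(df))
  if (length(missing) > 0L) {
    stop("interaction table is missing columns: ",
         paste(missing, collapse = ", "))
  }
  df <- df[, .interaction_cols]
  if (nrow(df) > 0L) {
    if (any(df$n_reads < 0)) stop("interaction table: negative n_reads")
    if (any(df$score < 0)) stop("interaction table: negative score")
    if (any(df$bait_end <= df$bait_start | df$oe_end <= df$oe_start)) {
      stop("interaction table: fragment end <= start")
    }
    same <- df$bait_chrom == df$oe_chrom & df$bait_start == df$oe_start &
      df$bait_end == df$oe_end
    if (any(same)) {
      stop("interaction table: bait and other-end must be distinct fragments")
    }
    df$bait_start <- df$bait_start + 1L
    df$oe_start <- df$oe_start + 1L
  }
  df
}

#' Write a promoter-capture interaction table
#'
#' Inverse of [read_interaction_table()]; scores are formatted at 6
#' significant digits, coordinates are emitted 0-based half-open.
#'
#' @param interactions Data frame as returned by [read_interaction_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(interactions, path) {
  df <- interactions[, .interaction_cols]
  df$bait_start <- df$bait_start - 1L
  df$oe_start <- df$oe_start - 1L
  df$score <- sprintf("%.6g", df$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Turn interaction-table fragment coordinates into GRanges
#'
#' @param interactions Interaction data.frame.
#' @param which `"oe"` for other-end fragments (default) or `"bait"`.
#' @return A `GRanges`, one range per table row.
#' @export
interaction_granges <- function(interactions, which = c("oe", "bait")) {
  which <- match.arg(which)
  pre <- paste0(which, "_")
  GenomicRanges::GRanges(
    interactions[[paste0(pre, "chrom")]],
    IRanges::IRanges(interactions[[paste0(pre, "start")]],
                     interactions[[paste0(pre, "end")]]))
}

#' Read motifs in JASPAR PFM text format
#'
#' Parses the JASPAR flat format: a `>ID name` header line followed by four
#' rows `A [ n1 n2 ... ]`, `C [...]`, `G [...]`, `T [...]`.  Brackets are
#' optional.  Rows must appear in A, C, G, T order and have equal length.
#'
#' @param path Path to the motif file.
#' @return A named list of motifs; each element is a list with `motif_id`,
#'   `name` and `counts` (a 4 x L numeric matrix with rownames A, C, G, T).
#' @export
read_jaspar_pfm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  headers <- grep("^>", lines)
  if (length(headers) == 0L) stop("no motif headers ('>') found in ", path)
  out <- vector("list", length(headers))
  bounds <- c(headers, length(lines) + 1L)
  for (i in seq_along(headers)) {
    hdr <- sub("^>\\s*", "", lines[headers[i]])
    parts <- strsplit(hdr, "\\s+")[[1L]]
    motif_id <- parts[1L]
    name <- if (length(parts) > 1L) paste(parts[-1L], collapse = " ") else motif_id
    body <- lines[seq(headers[i] + 1L, length.out = bounds[i + 1L] - headers[i] - 1L)]
    if (length(body) < 4L) {
      stop("motif ", motif_id, ": expected 4 base rows, found ", length(body))
    }
    body <- body[1:4]
    bases <- toupper(substr(body, 1L, 1L))
    if (!identical(bases, c("A", "C", "G", "T"))) {
      stop("motif ", motif_id, ": rows must be in A, C, G, T order ",
           "(missing or misordered base row)")
    }
    rows <- lapply(body, function(x) {
      x <- sub("^[ACGTacgt]\\s*", "", x)
      x <- gsub("[\\[\\]]", " ", x, perl = TRUE)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(x), "\\s+")[[1L]]))
      if (anyNA(vals)) stop("motif ", motif_id, ": non-numeric count")
      vals
    })
    if (length(unique(lengths(rows))) != 1L) {
      stop("motif ", motif_id, ": rows of unequal length")
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    if (ncol(counts) < 1L) stop("motif ", motif_id, ": zero-length matrix")
    if (any(counts < 0)) stop("motif ", motif_id, ": negative counts")
    if (any(colSums(counts) <= 0)) {
      stop("motif ", motif_id, ": column with non-positive sum")
    }
    out[[i]] <- list(motif_id = motif_id, name = name, counts = counts)
  }
  names(out) <- vapply(out, `[[`, "", "motif_id")
  out
}

#' Write motifs in JASPAR PFM text format
#'
#' Inverse of [read_jaspar_pfm()].
#'
#' @param motifs A list of motifs as returned by [read_jaspar_pfm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(motifs, path) {
  lines <- unlist(lapply(motifs, function(m) {
    c(paste0(">", m$motif_id, " ", if (is.null(m$name)) m$motif_id else m$name),
      vapply(c("A", "C", "G", "T"), function(b) {
        paste0(b, "  [ ", paste(format(m$counts[b, ], trim = TRUE),
                                collapse = " "), " ]")
      }, ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write a bedGraph track
#'
#' @param gr A `GRanges` of track intervals.
#' @param value Numeric vector of track values, one per range.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(gr, value, path) {
  stopifnot(length(gr) == length(value))
  writeLines(paste(as.character(GenomeInfoDb::seqnames(gr)),
                   format(GenomicRanges::start(gr) - 1, scientific = FALSE,
                          trim = TRUE),
                   format(GenomicRanges::end(gr), scientific = FALSE,
                          trim = TRUE),
                   sprintf("%.6g", value), sep = "\t"), path)
  invisible(path)
}

#' Read a minimal TSV gene annotation
#'
#' The annotation contract is a tab-delimited file with header columns
#' `gene_id, chrom, tss, strand, gene_length_bp`, one row per gene with a
#' single transcription start site (1-based position).
#'
#' @param path Path to the annotation file.
#' @return A data.frame with those columns.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand", "gene_length_bp")
  missing <- setdiff(need, colnames(df))
  if (length(missing) > 0L) {
    stop("annotation is missing columns: ", paste(missing, collapse = ", "))
  }
  if (any(duplicated(df$gene_id))) stop("annotation: duplicated gene_id")
  if (any(df$gene_length_bp <= 0)) stop("annotation: gene_length_bp must be > 0")
  df[, need]
}

#' Write the minimal TSV gene annotation
#'
#' @param annotation Data frame as returned by [read_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a count/expression matrix with a header
#'
#' First column is the feature identifier (peak or gene id); remaining
#' columns are per-sample numeric values.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix with feature ids as rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Write a count/expression matrix with a header
#'
#' @param m Numeric matrix with rownames.
#' @param path Output path.
#' @param id_col Name for the identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Parse a "chr:start-end" region string into a GRanges
#'
#' Coordinates quoted in running text (e.g. genome-browser style
#' `chr6:50,913,170-51,087,888`) are 1-based and inclusive; commas are
#' permitted and stripped.
#'
#' @param x A character vector of region strings.
#' @return A `GRanges` with one range per input string.
#' @export
parse_region <- function(x) {
  x2 <- gsub(",", "", x, fixed = TRUE)
  m <- regmatches(x2, regexec("^(.+):([0-9]+)-([0-9]+)$", x2))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stop("cannot parse region string: ", x[bad][1L])
  GenomicRanges::GRanges(
    vapply(m, `[[`, "", 2L),
    IRanges::IRanges(as.numeric(vapply(m, `[[`, "", 3L)),
                     as.numeric(vapply(m, `[[`, "", 4L))))
}
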