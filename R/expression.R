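#' FPKM normalisation of a gene count matrix
#'
#' \deqn{FPKM_{gs} = counts_{gs} \times 10^9 / (length_g \times N_s)}
#' where `N_s` is the total mapped fragments of sample s.
#'
#' @param counts genes x samples non-negative count matrix (rownames =
#'   gene ids).
#' @param gene_lengths numeric vector of transcript lengths in bp, aligned
#'   with the rows of `counts`.
#' @return FPKM matrix of the same shape.
#' @export
fpkm_normalize <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  stopifnot(length(gene_lengths) == nrow(counts), all(gene_lengths > 0),
            all(counts >= 0))
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  sweep(counts / gene_lengths, 2L, lib, "/") * 1e9
}

#' Two-group differential expression by t-test
#'
#' Per-gene two-sided two-sample t-test on (optionally log-transformed)
#' FPKM between the high and low body-weight groups. Student's equal-variance
#' test is the default; Welch's is available. A gene with zero variance in
#' both groups is flagged degenerate (with `t = 0, p = 1` when the means are
#' also equal).
#'
#' @param fpkm genes x samples expression matrix.
#' @param groups character/factor vector aligned with the columns, two
#'   levels (e.g. `"HBW"`, `"LBW"`).
#' @param variant `"student"` or `"welch"`.
#' @param log2_transform test `log2(x + 1)` instead of raw values.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame: `gene_id`, `mean_1`, `mean_2` (in the order of the
#'   factor levels), `t_statistic`, `p_value`, `significant`, `degenerate`.
#' @export
de_ttest <- function(fpkm, groups, variant = c("student", "welch"),
                     log2_transform = FALSE, alpha = 0.05) {
  variant <- match.arg(variant)
  fpkm <- as.matrix(fpkm)
  groups <- factor(groups)
  stopifnot(length(groups) == ncol(fpkm), nlevels(groups) == 2L)
  g1 <- groups == levels(groups)[1L]
  g2 <- groups == levels(groups)[2L]
  if (sum(g1) < 2L || sum(g2) < 2L)
    stop("each group needs at least 2 samples")
  x <- if (log2_transform) log2(fpkm + 1) else fpkm
  res <- lapply(seq_len(nrow(x)), function(i) {
    v1 <- x[i, g1]
    v2 <- x[i, g2]
    gene <- if (!is.null(rownames(x))) rownames(x)[i] else as.character(i)
    if (stats::var(v1) == 0 && stats::var(v2) == 0) {
      same <- mean(v1) == mean(v2)
      return(data.frame(gene_id = gene, mean_1 = mean(v1), mean_2 = mean(v2),
                        t_statistic = if (same) 0 else NA_real_,
                        p_value = if (same) 1 else NA_real_,
                        significant = FALSE, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(v1, v2, var.equal = (variant == "student"))
    data.frame(gene_id = gene, mean_1 = mean(v1), mean_2 = mean(v2),
               t_statistic = unname(tt$statistic), p_value = tt$p.value,
               significant = tt$p.value < alpha, degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[2:3] <- paste0("mean_", tolower(levels(groups)))
  out
}

#' Assign STR loci to overlapping or nearby genes
#'
#' A locus falling within a gene span is annotated `inside`; otherwise every
#' gene whose span lies within `max_distance_bp` is returned with the
#' strand-aware side relation (`upstream` when the locus precedes the gene's
#' 5' end, `downstream` otherwise). Loci with no gene in range map to no row.
#'
#' @param catalog an `str_catalog` or a data.frame with `scaffold`, `start`,
#'   `end` and optionally `locus_id`.
#' @param annotation data.frame with `gene_id`, `scaffold`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @param max_distance_bp search window around each gene (default 25000).
#' @return data.frame: `locus_id`, `gene_id`, `relation`, `distance_bp`.
#' @export
annotate_str_to_genes <- function(catalog, annotation,
                                  max_distance_bp = 25000L) {
  loci <- if (inherits(catalog, "str_catalog")) catalog$loci else catalog
  stopifnot(all(c("scaffold", "start", "end") %in% names(loci)),
            all(c("gene_id", "scaffold", "start", "end", "strand") %in%
                names(annotation)),
            max_distance_bp >= 0, all(annotation$start <= annotation$end))
  if (is.null(loci$locus_id))
    loci$locus_id <- paste0(loci$scaffold, "_", loci$start)
  empty <- data.frame(locus_id = character(), gene_id = character(),
                      relation = character(), distance_bp = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(loci) == 0L || nrow(annotation) == 0L) return(empty)
  lr <- GenomicRanges::GRanges(loci$scaffold,
                               IRanges::IRanges(loci$start, loci$end))
  gr <- GenomicRanges::GRanges(annotation$scaffold,
                               IRanges::IRanges(annotation$start,
                                                annotation$end),
                               strand = annotation$strand)
  hits <- GenomicRanges::findOverlaps(lr, gr, maxgap = max_distance_bp)
  if (length(hits) == 0L) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  relation <- character(length(qi))
  distance <- integer(length(qi))
  for (k in seq_along(qi)) {
    l <- loci[qi[k], ]
    g <- annotation[si[k], ]
    if (l$start <= g$end && l$end >= g$start) {
      relation[k] <- "inside"
      distance[k] <- 0L
    } else if (l$end < g$start) {
      distance[k] <- g$start - l$end
      relation[k] <- if (g$strand == "-") "downstream" else "upstream"
    } else {
      distance[k] <- l$start - g$end
      relation[k] <- if (g$strand == "-") "upstream" else "downstream"
    }
  }
  data.frame(locus_id = loci$locus_id[qi], gene_id = annotation$gene_id[si],
             relation = relation, distance_bp = distance,
             stringsAsFactors = FALSE)
}

#' Read a gene annotation from GFF3 or BED
#'
#' @param path a GFF3 (`.gff`, `.gff3`) or BED file of gene spans.
#' @param feature GFF3 feature type to keep (default `"gene"`).
#' @return data.frame with `gene_id`, `scaffold`, `start`, `end`, `strand`.
#' @export
read_gene_annotation <- function(path, feature = "gene") {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package")
    g <- rtracklayer::import(path)
    g <- g[as.character(g$type) == feature]
    ids <- if (!is.null(g$ID)) as.character(g$ID) else as.character(g$gene_id)
    data.frame(gene_id = ids,
               scaffold = as.character(GenomicRanges::seqnames(g)),
               start = GenomicRanges::start(g), end = GenomicRanges::end(g),
               strand = as.character(GenomicRanges::strand(g)),
               stringsAsFactors = FALSE)
  } else {
    b <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    data.frame(gene_id = if (ncol(b) >= 4L) b[[4L]]
               else paste0(b[[1L]], "_", b[[2L]]),
               scaffold = b[[1L]], start = b[[2L]] + 1L, end = b[[3L]],
               strand = if (ncol(b) >= 6L) b[[6L]] else "+",
               stringsAsFactors = FALSE)
  }
}
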