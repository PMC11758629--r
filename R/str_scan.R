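#' Scanner thresholds for perfect STR identification
#'
#' MISA-style thresholds: a repeat run is reported when it reaches the
#' per-period minimum repeat count *and* the minimum region length in bases.
#' The defaults require a 10 bp region and 10/5/4/3/3/3 repeats for
#' mono- through hexanucleotide motifs.
#'
#' @param min_repeats_by_period integer vector of length 6; element `p` is the
#'   minimum number of complete repeat units for a period-`p` motif.
#' @param min_region_bp minimum locus length in bases.
#' @return an object of class `scan_thresholds`.
#' @export
scan_thresholds <- function(min_repeats_by_period = c(10L, 5L, 4L, 3L, 3L, 3L),
                            min_region_bp = 10L) {
  stopifnot(length(min_repeats_by_period) == 6L,
            all(min_repeats_by_period >= 1L),
            min_region_bp >= 1L)
  structure(list(min_repeats_by_period = as.integer(min_repeats_by_period),
                 min_region_bp = as.integer(min_region_bp)),
            class = "scan_thresholds")
}

# TRUE when the motif is not itself a repetition of a shorter unit
is_primitive_motif <- function(motif) {
  p <- nchar(motif)
  if (p == 1L) return(TRUE)
  for (d in seq_len(p - 1L)) {
    if (p %% d != 0L) next
    unit <- substr(motif, 1L, d)
    if (strrep(unit, p %/% d) == motif) return(FALSE)
  }
  TRUE
}

#' Identify perfect short tandem repeats in one sequence
#'
#' Finds every maximal run of a tandemly repeated 1-6 bp unit that meets the
#' thresholds. Runs are perfect (no interruptions), never span an `N`, and are
#' reported once, at the smallest primitive period that describes them.
#' Trailing partial units are excluded from the locus, so `length_bp` is always
#' `period * n_repeats`.
#'
#' @param seq a single nucleotide string over `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive).
#' @param thresholds a [scan_thresholds()] object.
#' @param scaffold sequence name recorded in the output.
#' @return a data.frame with columns `scaffold`, `start`, `end` (1-based
#'   inclusive), `motif`, `period`, `n_repeats`, `length_bp`, sorted by start
#'   position then period.
#' @export
scan_sequence <- function(seq, thresholds = scan_thresholds(),
                          scaffold = "seq") {
  stopifnot(is.character(seq), length(seq) == 1L,
            inherits(thresholds, "scan_thresholds"))
  seq <- toupper(seq)
  n <- nchar(seq)
  empty <- data.frame(scaffold = character(), start = integer(),
                      end = integer(), motif = character(),
                      period = integer(), n_repeats = integer(),
                      length_bp = integer(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) {
    stop("invalid character '", chars[bad[1L]], "' at position ", bad[1L])
  }
  min_reps <- thresholds$min_repeats_by_period
  min_bp <- thresholds$min_region_bp
  out <- vector("list", 64L)
  n_out <- 0L
  is_n <- chars == "N"
  for (p in 1:6) {
    if (n < 2L * p) next
    i <- seq_len(n - p)
    eq <- chars[i] == chars[i + p] & !is_n[i] & !is_n[i + p]
    r <- rle(eq)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    for (k in which(r$values)) {
      total_bp <- r$lengths[k] + p        # full repeated region incl. partial
      n_rep <- total_bp %/% p
      if (n_rep < min_reps[p]) next
      len <- n_rep * p
      if (len < min_bp) next
      s0 <- run_start[k]
      motif <- substr(seq, s0, s0 + p - 1L)
      if (!is_primitive_motif(motif)) next  # reported at its smaller period
      n_out <- n_out + 1L
      out[[n_out]] <- data.frame(scaffold = scaffold, start = s0,
                                 end = s0 + len - 1L, motif = motif,
                                 period = p, n_repeats = n_rep,
                                 length_bp = len, stringsAsFactors = FALSE)
    }
  }
  if (n_out == 0L) return(empty)
  res <- do.call(rbind, out[seq_len(n_out)])
  res <- res[order(res$start, res$period), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan a FASTA genome for perfect STRs
#'
#' @param fasta path to a (multi-record, possibly line-wrapped) FASTA file.
#' @param thresholds a [scan_thresholds()] object.
#' @return an `str_catalog`: list with `loci` (as in [scan_sequence()], all
#'   scaffolds, sorted by scaffold then start) and `genome_lengths` (named
#'   numeric, bp per scaffold).
#' @export
scan_fasta <- function(fasta, thresholds = scan_thresholds()) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  nm <- sub("\\s.*$", "", names(seqs))
  loci <- lapply(seq_along(seqs), function(i) {
    scan_sequence(as.character(seqs[[i]]), thresholds, scaffold = nm[i])
  })
  str_catalog(do.call(rbind, loci), stats::setNames(Biostrings::width(seqs), nm))
}

#' Construct an STR catalog
#'
#' @param loci data.frame of loci as returned by [scan_sequence()].
#' @param genome_lengths named vector of scaffold lengths in bp.
#' @return an object of class `str_catalog`.
#' @export
str_catalog <- function(loci, genome_lengths) {
  stopifnot(is.data.frame(loci),
            all(c("scaffold", "start", "end", "motif", "period",
                  "n_repeats", "length_bp") %in% names(loci)),
            !is.null(names(genome_lengths)), all(genome_lengths > 0))
  if (nrow(loci) > 0L) {
    if (!all(loci$scaffold %in% names(genome_lengths)))
      stop("loci reference scaffolds absent from genome_lengths")
    if (any(loci$end > genome_lengths[loci$scaffold]) || any(loci$start < 1L))
      stop("locus coordinates out of scaffold bounds")
    loci <- loci[order(loci$scaffold, loci$start, loci$period), , drop = FALSE]
    rownames(loci) <- NULL
  }
  structure(list(loci = loci, genome_lengths = genome_lengths),
            class = "str_catalog")
}

#' Canonical motif class of a repeat unit
#'
#' Maps a repeat unit to the lexicographically smallest string among its
#' cyclic rotations, optionally pooling the rotations of the reverse
#' complement as well (so that e.g. `AAT`, `TAA`, `ATA`, `ATT`, `TTA` and
#' `TAT` share one class). Rotation-equivalent motifs always share a label.
#'
#' @param motif repeat unit (1-6 bp, primitive).
#' @param merge_revcomp also pool the reverse complement's rotations.
#' @return the canonical class label. Vectorised over `motif`.
#' @export
canonical_motif <- function(motif, merge_revcomp = FALSE) {
  vapply(motif, function(m) {
    m <- toupper(m)
    ch <- strsplit(m, "", fixed = TRUE)[[1L]]
    if (!all(ch %in% c("A", "C", "G", "T")))
      stop("motif contains a non-ACGT character: ", m)
    p <- length(ch)
    rots <- vapply(seq_len(p), function(k) {
      paste(ch[c(k:p, seq_len(k - 1L))[seq_len(p)]], collapse = "")
    }, character(1))
    if (merge_revcomp) {
      rc <- rev(c(A = "T", C = "G", G = "C", T = "A")[ch])
      rots <- c(rots, vapply(seq_len(p), function(k) {
        paste(rc[c(k:p, seq_len(k - 1L))[seq_len(p)]], collapse = "")
      }, character(1)))
    }
    min(rots)
  }, character(1), USE.NAMES = FALSE)
}

#' Genome STR landscape statistics
#'
#' Summarises an STR catalog into the statistics commonly reported for a
#' genome: locus count, relative abundance (loci per Mb), density (STR bases
#' per Mb), percent of genome covered, and composition by unit size and by
#' canonical motif class.
#'
#' @param catalog an [str_catalog()].
#' @param merge_revcomp passed to [canonical_motif()] for the class table.
#' @return a list of class `landscape_stats` with fields `n_str`,
#'   `relative_abundance`, `density_bp_per_mb`, `percent_genome`,
#'   `unit_size_proportions` (length 6) and `motif_class_proportions`.
#' @export
landscape_stats <- function(catalog, merge_revcomp = FALSE) {
  stopifnot(inherits(catalog, "str_catalog"))
  gsize <- sum(catalog$genome_lengths)
  if (gsize <= 0) stop("total genome length must be positive")
  loci <- catalog$loci
  n <- nrow(loci)
  str_bp <- if (n > 0L) sum(as.numeric(loci$length_bp)) else 0
  unit_prop <- stats::setNames(numeric(6), as.character(1:6))
  class_prop <- numeric(0)
  if (n > 0L) {
    tab <- table(factor(loci$period, levels = 1:6))
    unit_prop[] <- as.numeric(tab) / n
    cls <- table(canonical_motif(loci$motif, merge_revcomp))
    class_prop <- stats::setNames(as.numeric(cls) / n, names(cls))
  }
  structure(list(
    n_str = n,
    relative_abundance = n / (gsize / 1e6),
    density_bp_per_mb = str_bp / (gsize / 1e6),
    percent_genome = 100 * str_bp / gsize,
    unit_size_proportions = unit_prop,
    motif_class_proportions = class_prop
  ), class = "landscape_stats")
}

#' A/T composition summary of a set of repeat units
#'
#' Classifies repeat units by whether every base of the unit is A or T — the
#' composition pattern repeatedly singled out among growth-associated STRs —
#' and counts the mononucleotide A/T units among them.
#'
#' @param units character vector of repeat units.
#' @return list with `n`, `n_at_only`, `pct_at_only` (percent of units made
#'   of A/T bases only), `n_mono_at` (single-base A or T units), and the
#'   logical vector `at_only`.
#' @export
motif_at_summary <- function(units) {
  stopifnot(length(units) > 0L)
  at_only <- vapply(toupper(units), function(u) {
    ch <- strsplit(u, "", fixed = TRUE)[[1L]]
    all(ch %in% c("A", "T"))
  }, logical(1), USE.NAMES = FALSE)
  mono_at <- toupper(units) %in% c("A", "T")
  list(n = length(units), n_at_only = sum(at_only),
       pct_at_only = 100 * mean(at_only), n_mono_at = sum(mono_at),
       at_only = at_only)
}

#' Convert an STR density to percent of genome
#'
#' A density of `d` STR bases per Mb corresponds to `d / 1e4` percent of the
#' genome.
#'
#' @param density_bp_per_mb STR bases per megabase.
#' @return percent of the genome made of STRs.
#' @export
percent_from_density <- function(density_bp_per_mb) {
  stopifnot(density_bp_per_mb >= 0, density_bp_per_mb <= 1e6)
  density_bp_per_mb / 1e4
}

#' Fraction of non-overlapping windows containing a marker
#'
#' Tiles each scaffold with windows `[k*w + 1, (k+1)*w]` (the last window may
#' be short) and returns the fraction of windows containing at least one
#' marker position. Used to compare the genome-wide evenness of marker sets
#' at several window sizes.
#'
#' @param marker_positions named list: scaffold -> integer positions (1-based).
#' @param window_bp window size in bp.
#' @param genome_lengths named vector of scaffold lengths.
#' @return fraction of windows occupied, in `[0, 1]`.
#' @export
window_occupancy <- function(marker_positions, window_bp, genome_lengths) {
  stopifnot(window_bp >= 1, all(genome_lengths >= 1))
  total_windows <- 0
  occupied <- 0
  for (sc in names(genome_lengths)) {
    len <- genome_lengths[[sc]]
    nw <- ceiling(len / window_bp)
    total_windows <- total_windows + nw
    pos <- marker_positions[[sc]]
    if (is.null(pos) || length(pos) == 0L) next
    if (any(pos < 1 | pos > len))
      stop("marker position out of bounds on ", sc)
    occupied <- occupied + length(unique((pos - 1) %/% window_bp))
  }
  if (total_windows == 0) stop("no windows: empty genome")
  occupied / total_windows
}

#' Marker density inside versus outside a set of regions
#'
#' Splits the genome into the union of the given regions and its complement
#' and reports the marker density (markers per Mb) on each side. Used e.g. to
#' compare SNP density in STR-containing versus STR-free sequence.
#'
#' @param marker_positions named list: scaffold -> integer positions.
#' @param regions data.frame with `scaffold`, `start`, `end` (1-based
#'   inclusive, non-overlapping within scaffold).
#' @param genome_lengths named vector of scaffold lengths.
#' @return list with `inside_per_mb`, `outside_per_mb` (NA when the
#'   corresponding side has zero extent), and the raw counts and bp totals.
#' @export
region_marker_density <- function(marker_positions, regions, genome_lengths) {
  stopifnot(is.data.frame(regions),
            all(c("scaffold", "start", "end") %in% names(regions)))
  if (nrow(regions) > 0L) {
    if (any(regions$start < 1) ||
        any(regions$end > genome_lengths[regions$scaffold]))
      stop("region out of scaffold bounds")
    if (any(regions$end < regions$start)) stop("region end before start")
  }
  inside_bp <- 0
  n_inside <- 0
  n_total <- 0
  for (sc in names(genome_lengths)) {
    reg <- regions[regions$scaffold == sc, , drop = FALSE]
    if (nrow(reg) > 1L) {
      reg <- reg[order(reg$start), , drop = FALSE]
      if (any(reg$start[-1L] <= reg$end[-nrow(reg)]))
        stop("overlapping regions on ", sc, "; merge them first")
    }
    inside_bp <- inside_bp + sum(as.numeric(reg$end - reg$start + 1))
    pos <- marker_positions[[sc]]
    if (is.null(pos) || length(pos) == 0L) next
    if (any(pos < 1 | pos > genome_lengths[[sc]]))
      stop("marker position out of bounds on ", sc)
    n_total <- n_total + length(pos)
    if (nrow(reg) > 0L) {
      # position is inside iff the nearest region start at-or-before it
      # has an end at-or-after it
      idx <- findInterval(pos, reg$start)
      inside <- idx >= 1L & pos <= reg$end[pmax(idx, 1L)]
      n_inside <- n_inside + sum(inside)
    }
  }
  genome_bp <- sum(as.numeric(genome_lengths))
  outside_bp <- genome_bp - inside_bp
  list(
    inside_per_mb = if (inside_bp > 0) n_inside / (inside_bp / 1e6) else NA_real_,
    outside_per_mb = if (outside_bp > 0)
      (n_total - n_inside) / (outside_bp / 1e6) else NA_real_,
    n_inside = n_inside, n_outside = n_total - n_inside,
    inside_bp = inside_bp, outside_bp = outside_bp
  )
}

#' Write an STR catalog as BED-like TSV and HipSTR-style regions files
#'
#' @param catalog an [str_catalog()].
#' @param bed path for the BED-like file (scaffold, start-1, end, motif,
#'   period, n_repeats); `NULL` to skip.
#' @param regions path for the HipSTR-style regions file (scaffold, start,
#'   end, period, n_repeats, name); `NULL` to skip.
#' @return invisibly, the catalog.
#' @export
write_catalog <- function(catalog, bed = NULL, regions = NULL) {
  stopifnot(inherits(catalog, "str_catalog"))
  loci <- catalog$loci
  if (!is.null(bed)) {
    utils::write.table(
      data.frame(loci$scaffold, loci$start - 1L, loci$end, loci$motif,
                 loci$period, loci$n_repeats),
      bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(regions)) {
    utils::write.table(
      data.frame(loci$scaffold, loci$start, loci$end, loci$period,
                 loci$n_repeats,
                 paste0(loci$scaffold, "_", loci$start)),
      regions, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(catalog)
}
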