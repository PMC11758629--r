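#' Read a phenotype table
#'
#' @param path TSV with header columns `id`, `sex`, `tank`, `ibw`, `hbw`.
#' @return data.frame with `id` as character.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("id", "sex", "tank", "ibw", "hbw")
  if (!all(need %in% names(df)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  df$id <- as.character(df$id)
  df
}

#' Read a pedigree table
#'
#' @param path TSV with header columns `id`, `sire`, `dam`; `0` marks an
#'   unknown parent.
#' @return a [pedigree()].
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  pedigree(df)
}

#' Write / read a dosage matrix as TSV
#'
#' Loci as rows (first columns: locus_id, scaffold, pos, period), samples as
#' columns, `NA` for missing.
#'
#' @param mat a `dosage_matrix`.
#' @param path output path.
#' @return invisibly `mat` (write) / a `dosage_matrix` (read).
#' @export
write_dosage <- function(mat, path) {
  stopifnot(inherits(mat, "dosage_matrix"))
  df <- cbind(mat$loci[, c("locus_id", "scaffold", "pos", "period")],
              as.data.frame(mat$dosage))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mat)
}

#' @rdname write_dosage
#' @export
read_dosage <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("locus_id", "scaffold", "pos", "period")
  d <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(d) <- df$locus_id
  structure(list(loci = df[, meta], samples = colnames(d), dosage = d),
            class = "dosage_matrix")
}

#' Write a genomic relationship matrix as square TSV with header ids
#'
#' @param g a `grm`.
#' @param path output path.
#' @export
write_grm <- function(g, path) {
  stopifnot(inherits(g, "grm"))
  m <- as.data.frame(g$matrix)
  names(m) <- g$sample_ids
  utils::write.table(cbind(id = g$sample_ids, m), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}
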