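#' Default pipeline configuration
#'
#' All thresholds default to the values used throughout the package:
#' posterior 0.9, flank/stutter fractions 0.15, GWAS presence rate 0.2, GRM
#' missing rate 0.1, suggestive alpha 5e-4, correlation threshold 0.5, DE
#' alpha 0.05.
#'
#' @param vcf STR VCF path (required).
#' @param pheno phenotype TSV path (required).
#' @param ped pedigree TSV path (required).
#' @param out_dir output directory.
#' @param counts,groups optional expression counts TSV (gene, length, sample
#'   columns) and group TSV (sample, group) for the DE stage.
#' @param annotation optional gene annotation (GFF3/BED) for STR-to-gene
#'   assignment of the suggestive hits.
#' @param ... overrides for thresholds: `min_posterior`, `max_flank`,
#'   `max_stutter`, `min_presence`, `grm_max_missing`, `alpha`,
#'   `r_threshold`, `de_alpha`, `max_distance_bp`, `n_pcs`, `mode`, `seed`.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, pheno, ped, out_dir = "strdose_out",
                            counts = NULL, groups = NULL, annotation = NULL,
                            ...) {
  cfg <- list(vcf = vcf, pheno = pheno, ped = ped, out_dir = out_dir,
              counts = counts, groups = groups, annotation = annotation,
              min_posterior = 0.9, max_flank = 0.15, max_stutter = 0.15,
              min_presence = 0.2, grm_max_missing = 0.1, alpha = 5e-4,
              r_threshold = 0.5, de_alpha = 0.05, max_distance_bp = 25000L,
              n_pcs = 5L, mode = "p3d", seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown pipeline options: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

stage <- function(name, expr) {
  message("[strdose] stage: ", name)
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the STR-dosage analysis pipeline end to end
#'
#' Executes genotypes (VCF parsing, call filters, dosage) -> locus QC ->
#' GRM + principal components -> REML mixed-model GWAS -> pedigree BLUP
#' adjusted phenotypes -> correlation filter on the suggestive hits ->
#' optional differential expression and STR-to-gene annotation. Writes every
#' stage's table, the resolved configuration, and a machine-readable summary
#' under `out_dir`.
#'
#' @param config a [pipeline_config()] (or a path to a YAML file with the
#'   same fields).
#' @return invisibly, a list with the per-stage results and the summary.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    cfg_list <- yaml::read_yaml(config)
    config <- do.call(pipeline_config, cfg_list)
  }
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("vcf", "pheno", "ped")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop("input file for '", f, "' not found: ",
           if (is.null(config[[f]])) "(unset)" else config[[f]])
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))],
                   file.path(config$out_dir, "resolved_config.yaml"))
  summary <- list()

  calls <- stage("genotypes", {
    raw <- read_str_vcf(config$vcf)
    n_raw <- sum(!is.na(raw$calls$bp1))
    flt <- filter_calls(raw, config$min_posterior, config$max_flank,
                        config$max_stutter)
    n_flt <- sum(!is.na(flt$calls$bp1))
    summary$calls <- list(loci = nrow(raw$loci),
                           samples = length(raw$samples),
                           calls_in = n_raw, calls_surviving = n_flt)
    message("[strdose]   calls in: ", n_raw, ", surviving filters: ", n_flt)
    flt
  })
  dm <- dosage_matrix(calls)

  qc <- stage("locus_qc", locus_qc(calls))
  utils::write.table(qc, file.path(config$out_dir, "locus_qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  grm_obj <- stage("grm", {
    dm_grm <- filter_loci(dm, "grm", max_missing = config$grm_max_missing)
    summary$grm <- list(loci_used = nrow(dm_grm$loci))
    message("[strdose]   GRM loci: ", nrow(dm_grm$loci))
    vanraden_grm(dm_grm)
  })
  write_grm(grm_obj, file.path(config$out_dir, "grm.tsv"))
  pcs <- grm_pca(grm_obj, k = config$n_pcs)

  pheno <- read_phenotypes(config$pheno)
  gwas <- stage("gwas", {
    dm_gwas <- filter_loci(dm, "gwas", min_presence = config$min_presence)
    write_dosage(dm_gwas, file.path(config$out_dir, "dosage_gwas.tsv"))
    keep <- pheno$id %in% grm_obj$sample_ids
    pheno_g <- pheno[keep, , drop = FALSE]
    ord <- match(pheno_g$id, grm_obj$sample_ids)
    X <- gwas_design(pheno_g, pcs$components[ord, , drop = FALSE])
    spec <- mixed_model_spec(pheno_g$hbw, X,
                             grm_obj$matrix[ord, ord, drop = FALSE],
                             pheno_g$id)
    vc <- reml_fit(spec)
    res <- assoc_scan(spec, dm_gwas, mode = config$mode, vc = vc,
                      alpha = config$alpha)
    summary$gwas <- list(loci_tested = sum(!res$degenerate),
                          suggestive = sum(res$suggestive),
                          sigma_a2 = vc$sigma_a2, sigma_e2 = vc$sigma_e2,
                          h2 = vc$h2)
    message("[strdose]   loci tested: ", sum(!res$degenerate),
            ", suggestive hits: ", sum(res$suggestive))
    res
  })
  utils::write.table(gwas, file.path(config$out_dir, "gwas.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  adj <- stage("adjust", {
    ped <- read_pedigree(config$ped)
    blup <- animal_model_blup(pheno, ped)
    summary$adjust <- list(sigma_a2 = blup$varcomp$sigma_a2,
                            sigma_e2 = blup$varcomp$sigma_e2)
    ys <- adjust_phenotypes(blup)
    utils::write.table(
      data.frame(id = names(ys), a_hat = blup$a_hat[names(ys)],
                 e_hat = blup$e_hat[names(ys)], y_star = ys),
      file.path(config$out_dir, "adjusted_phenotypes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    ys
  })

  hits <- gwas$locus_id[gwas$suggestive]
  corr <- stage("correlate", {
    if (length(hits) == 0L) {
      message("[strdose]   no suggestive hits; correlation stage empty")
      data.frame(locus_id = character(), n = integer(), r = numeric(),
                 p_value = numeric(), passes = logical(),
                 degenerate = logical(), stringsAsFactors = FALSE)
    } else {
      correlate_dosage(dm, adj, loci = hits, threshold = config$r_threshold)
    }
  })
  summary$correlate <- list(hits_in = length(hits),
                            passing = sum(corr$passes))
  utils::write.table(corr, file.path(config$out_dir, "correlation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  de <- NULL
  if (!is.null(config$counts) && !is.null(config$groups)) {
    de <- stage("de", {
      ct <- utils::read.table(config$counts, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, check.names = FALSE)
      gr <- utils::read.table(config$groups, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      m <- as.matrix(ct[, setdiff(names(ct), c("gene", "length")),
                        drop = FALSE])
      rownames(m) <- ct$gene
      fp <- fpkm_normalize(m, ct$length)
      res <- de_ttest(fp, gr$group[match(colnames(m), gr$sample)],
                      alpha = config$de_alpha)
      summary$de <- list(genes = nrow(res),
                          significant = sum(res$significant, na.rm = TRUE))
      res
    })
    utils::write.table(de, file.path(config$out_dir, "de.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  annot <- NULL
  if (!is.null(config$annotation) && length(hits) > 0L) {
    annot <- stage("annotate", {
      ann <- read_gene_annotation(config$annotation)
      loci <- dm$loci[dm$loci$locus_id %in% hits, , drop = FALSE]
      loci$start <- loci$pos
      loci$end <- loci$pos
      annotate_str_to_genes(loci, ann, config$max_distance_bp)
    })
    utils::write.table(annot, file.path(config$out_dir, "annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(calls = calls, dosage = dm, qc = qc, grm = grm_obj,
                 pcs = pcs, gwas = gwas, adjusted = adj, correlation = corr,
                 de = de, annotation = annot, summary = summary))
}
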