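# Plain-text readers/writers for cohort fixtures: dosage matrix TSV,
# phenotype TSV, sparse kinship TSV, VCF (hard calls), true-parameter
# JSON sidecar.

#' Write a simulated cohort to a directory
#'
#' Emits dosages.tsv (individuals x variants), phenotypes.tsv,
#' kinship.tsv (sparse triplets id1/id2/kinship), proportions.tsv,
#' genotypes.vcf (GT hard calls) and truth.json (generative parameters
#' for recovery tests).
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param write_vcf Also write a VCF (default TRUE).
#' @return Named character vector of the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_vcf = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(dosages = file.path(dir, "dosages.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             kinship = file.path(dir, "kinship.tsv"),
             proportions = file.path(dir, "proportions.tsv"),
             truth = file.path(dir, "truth.json"))
  X <- cohort$genotypes$dosage
  dos <- data.frame(id = rownames(X), X, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(dos, paths["dosages"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$phenotypes, paths["phenotypes"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$kinship_edges, paths["kinship"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  Q <- cohort$genotypes$proportions
  write.table(data.frame(id = rownames(Q), Q, check.names = FALSE),
              paths["proportions"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- list(seed = cohort$config$seed,
                heritability_prs = cohort$config$heritability_prs,
                m_variants = cohort$config$m_variants,
                m_causal = cohort$config$m_causal,
                causal_idx = cohort$causal_effects$causal_idx,
                group_residual_sd_sbp = as.list(cohort$config$group_residual_sd_sbp),
                group_residual_sd_dbp = as.list(cohort$config$group_residual_sd_dbp),
                fst = lapply(cohort$config$ancestries, function(a)
                  setNames(list(a$fst), a$name)))
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  if (write_vcf) {
    paths <- c(paths, vcf = file.path(dir, "genotypes.vcf"))
    write_vcf_dosages(cohort$genotypes, paths["vcf"])
  }
  invisible(paths)
}

#' Write hard-call genotypes as a minimal VCF
#'
#' VCFv4.2 with GT fields only; dosages 0/1/2 become 0/0, 0/1, 1/1 and
#' missing dosages `./.`. REF is the panel's other allele and ALT the
#' counted effect allele, so allele dosage equals ALT-allele count.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_dosages <- function(genotypes, path) {
  X <- genotypes$dosage
  v <- genotypes$variants
  gt <- matrix(c("0/0", "0/1", "1/1")[X + 1L], nrow = nrow(X))
  gt[is.na(X)] <- "./."
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(X)), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$id, v$other_allele, v$effect_allele, ".",
                "PASS", ".", "GT",
                apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genotypes from a VCF or a dosage-matrix TSV
#'
#' VCF input (via the vcfR package) uses GT hard calls counted on the ALT
#' allele; TSV input expects the layout written by [write_cohort()]
#' (first column `id`, remaining columns variant ids).
#'
#' @param path File path (`.vcf` or `.tsv`).
#' @return A `genotype_matrix` (without ancestry proportions).
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop_input("reading VCF requires the vcfR package")
    vc <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(vc, element = "GT")
    count_alt <- function(s) {
      out <- rep(NA_integer_, length(s))
      out[s %in% c("0/0", "0|0")] <- 0L
      out[s %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
      out[s %in% c("1/1", "1|1")] <- 2L
      out
    }
    X <- t(apply(gt, 1L, count_alt))
    fix <- vcfR::getFIX(vc)
    variants <- data.frame(id = variant_id(fix[, "CHROM"],
                                           as.integer(fix[, "POS"]),
                                           fix[, "REF"], fix[, "ALT"]),
                           chrom = fix[, "CHROM"],
                           pos = as.integer(fix[, "POS"]),
                           other_allele = fix[, "REF"],
                           effect_allele = fix[, "ALT"],
                           stringsAsFactors = FALSE)
    X <- t(X)
    dimnames(X) <- list(colnames(gt), variants$id)
  } else {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- tab[[1L]]
    X <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(X) <- ids
    parts <- strsplit(colnames(X), ":", fixed = TRUE)
    variants <- data.frame(id = colnames(X),
                           chrom = vapply(parts, `[[`, character(1), 1L),
                           pos = as.integer(vapply(parts, `[[`, character(1), 2L)),
                           other_allele = vapply(parts, `[[`, character(1), 3L),
                           effect_allele = vapply(parts, `[[`, character(1), 4L),
                           stringsAsFactors = FALSE)
  }
  structure(list(dosage = X, variants = variants, proportions = NULL),
            class = "genotype_matrix")
}

#' Read a sparse kinship triplet file
#'
#' @param path TSV with columns id1, id2, kinship.
#' @return data.frame with those columns.
#' @export
read_kinship <- function(path) {
  k <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id1", "id2", "kinship")
  if (!all(need %in% names(k)))
    stop_input("kinship file needs columns: ", paste(need, collapse = ", "))
  if (any(k$kinship < 0)) stop_input("negative kinship coefficients")
  k
}
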