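#' Construct a genotype matrix
#'
#' Container for biallelic genotype dosages: a samples-by-variants numeric
#' matrix with values in \{0, 1, 2\} (count of the ALT allele) or `NA` for a
#' missing call, together with a variant table.
#'
#' @param dosage Numeric matrix, samples in rows, variants in columns.
#'   Entries must be 0, 1, 2 or `NA`.
#' @param variants Data frame with one row per variant and columns
#'   `id`, `chrom`, `pos`, `ref`, `alt`, and optionally `effect_allele`
#'   (`"alt"` or `"ref"`, default `"alt"`). Positions are 1-based and must be
#'   strictly increasing within a chromosome.
#' @param sample_ids Character vector of sample identifiers; defaults to the
#'   row names of `dosage`.
#'
#' @return An object of class `"genotype_matrix"`: a list with elements
#'   `dosage`, `variants` and `sample_ids`.
#' @export
genotype_matrix <- function(dosage, variants, sample_ids = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- paste0("S", seq_len(nrow(dosage)))
  }
  sample_ids <- as.character(sample_ids)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0L) {
    stop("variant table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(variants$effect_allele)) variants$effect_allele <- "alt"
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  if (nrow(variants) != ncol(dosage)) {
    stop("variant table has ", nrow(variants), " rows but dosage has ",
         ncol(dosage), " columns")
  }
  if (length(sample_ids) != nrow(dosage)) {
    stop("sample_ids length does not match dosage rows")
  }
  if (anyDuplicated(variants$id)) {
    stop("variant ids are not unique")
  }
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) {
    stop("dosage values must be 0, 1, 2 or NA")
  }
  if (any(variants$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0L)) {
      stop("positions are not strictly increasing on chromosome ", ch)
    }
  }
  dimnames(dosage) <- list(sample_ids, variants$id)
  structure(list(dosage = dosage, variants = variants,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants\n")
  nmiss <- sum(is.na(x$dosage))
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = " "), "\n")
  cat("  missing calls:", nmiss,
      sprintf("(%.2f%%)\n", 100 * nmiss / length(x$dosage)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

n_samples <- function(gm) nrow(gm$dosage)
n_variants <- function(gm) ncol(gm$dosage)

#' Subset a genotype matrix by variant
#'
#' @param gm A [genotype_matrix()].
#' @param ids Character vector of variant ids to keep (order preserved as in
#'   the matrix).
#' @return A `genotype_matrix` restricted to the requested variants.
#' @export
subset_variants <- function(gm, ids) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- gm$variants$id %in% ids
  out <- gm
  out$dosage <- gm$dosage[, keep, drop = FALSE]
  out$variants <- gm$variants[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  out
}

chrom_is_autosomal <- function(chrom) {
  sub("^chr", "", as.character(chrom)) %in% as.character(1:22)
}

#' Write genotypes as VCF v4.2
#'
#' Emits a plain-text VCF with GT genotype fields only, one ALT allele per
#' record. Missing dosages become `./.`; dosage 1 is written as `0/1`
#' (phase is not modelled).
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$variants
  gt_codes <- c("0/0", "0/1", "1/1")
  d <- t(gm$dosage)  # variants x samples
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_codes[d[ok] + 1]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mrgxe",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t")
  )
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses a VCF (v4.x) with vcfR and converts GT fields to ALT-allele
#' dosages. Only biallelic records are accepted; a multi-allelic ALT raises
#' an error naming the offending record.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    stop("multi-allelic record(s) not supported: ",
         paste(utils::head(fix$ID[multi], 5L), collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  map <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  d <- map[gt]
  d[gt %in% c("./.", ".")] <- NA_real_
  unknown <- !(gt %in% c(names(map), "./.", ".")) & !is.na(gt)
  if (any(unknown)) {
    stop("unrecognised GT value(s): ",
         paste(utils::head(unique(gt[unknown]), 5L), collapse = ", "))
  }
  d <- matrix(d, nrow = nrow(gt), dimnames = dimnames(gt))
  variants <- data.frame(id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  genotype_matrix(t(d), variants, sample_ids = colnames(gt))
}

#' Write and read the phenotype/covariate table
#'
#' Tab-separated table with columns `sample_id`, `age`, `sex`, `bmi`,
#' `metformin`, `hba1c` and one or more `metabolite_*` columns.
#'
#' @param phenotypes Data frame as produced by [simulate_cohort()].
#' @param path File path.
#' @return `write_phenotypes()` returns `path` invisibly;
#'   `read_phenotypes()` returns the data frame.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("sample_id", "age", "sex", "bmi", "metformin", "hba1c")
  miss <- setdiff(req, names(ph))
  if (length(miss) > 0L) {
    stop("phenotype table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!any(grepl("^metabolite_", names(ph)))) {
    stop("phenotype table has no metabolite_* column")
  }
  ph$sample_id <- as.character(ph$sample_id)
  ph
}

#' Read a SNP blocklist
#'
#' One variant id per line; empty lines and `#` comments are ignored. The
#' blocklist stands in for a lookup of variants previously reported
#' associated with the outcome in public databases.
#'
#' @param path File path, or `NULL` for an empty blocklist.
#' @return Character vector of variant ids.
#' @export
read_blocklist <- function(path) {
  if (is.null(path)) return(character(0))
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
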