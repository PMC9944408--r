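#' Read and write SNP tables as TSV
#'
#' The TSV layout is one row per site: columns `site`, `chrom`, `pos`,
#' `allele_mm`, `allele_pi`, then one column per sample with calls `MM`,
#' `PI` or `NA`.
#'
#' @param snps A `snp_table`.
#' @param path File path.
#' @return `read_snp_table` returns a `snp_table`.
#' @export
write_snp_table <- function(snps, path) {
  stopifnot(inherits(snps, "snp_table"))
  out <- cbind(snps$sites, as.data.frame(snps$calls,
                                         stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_table
#' @export
read_snp_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  fixed <- c("site", "chrom", "pos", "allele_mm", "allele_pi")
  stopifnot(all(fixed %in% names(x)))
  calls <- as.matrix(x[, setdiff(names(x), fixed), drop = FALSE])
  calls[calls == "NA" | calls == ""] <- NA_character_
  rownames(calls) <- x$site
  structure(list(sites = x[, fixed], calls = calls), class = "snp_table")
}

#' Write a SNP table as a minimal VCF
#'
#' Emits VCFv4.2 with CHROM/POS/ID/REF/ALT (REF = MM allele, ALT = PI
#' allele) and homozygous GT calls per sample (`0/0` MM, `1/1` PI, `./.`
#' missing).
#'
#' @param snps A `snp_table`.
#' @param path Output path (plain text).
#' @export
write_snp_vcf <- function(snps, path) {
  stopifnot(inherits(snps, "snp_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=rileqtl",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       colnames(snps$calls)), collapse = "\t")), con)
  gt <- matrix("./.", nrow(snps$calls), ncol(snps$calls))
  gt[snps$calls == "MM"] <- "0/0"
  gt[snps$calls == "PI"] <- "1/1"
  body <- cbind(snps$sites$chrom, snps$sites$pos, snps$sites$site,
                snps$sites$allele_mm, snps$sites$allele_pi,
                ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a SNP table from a VCF file
#'
#' Uses the `vcfR` package when available. Per-sample parental-allele calls
#' are derived from the GT field by matching each sample's homozygous
#' genotype to the two parental alleles taken from the designated parent
#' sample columns (heterozygous or half-missing calls become NA).
#'
#' @param path VCF path.
#' @param mm_sample,pi_sample Sample names of one replicate of each parent
#'   (used to orient REF/ALT to MM/PI); defaults assume REF = MM.
#' @return A `snp_table`.
#' @export
read_snp_vcf <- function(path, mm_sample = NULL, pi_sample = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_snp_vcf() requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  code <- matrix(NA_character_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt %in% c("0/0", "0|0")] <- "REF"
  code[gt %in% c("1/1", "1|1")] <- "ALT"
  mm_is_ref <- TRUE
  if (!is.null(mm_sample) && !is.null(pi_sample)) {
    mm_ref <- mean(code[, mm_sample] == "REF", na.rm = TRUE)
    pi_ref <- mean(code[, pi_sample] == "REF", na.rm = TRUE)
    mm_is_ref <- mm_ref >= pi_ref
  }
  calls <- code
  calls[code == "REF"] <- if (mm_is_ref) "MM" else "PI"
  calls[code == "ALT"] <- if (mm_is_ref) "PI" else "MM"
  sites <- data.frame(
    site = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                  paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"]),
    chrom = type.convert(fix[, "CHROM"], as.is = TRUE),
    pos = as.numeric(fix[, "POS"]),
    allele_mm = if (mm_is_ref) fix[, "REF"] else fix[, "ALT"],
    allele_pi = if (mm_is_ref) fix[, "ALT"] else fix[, "REF"],
    stringsAsFactors = FALSE)
  rownames(calls) <- sites$site
  structure(list(sites = sites, calls = calls), class = "snp_table")
}

#' Write a genotype matrix and marker map as TSV
#'
#' @param gm A `geno_map`.
#' @param map_path,geno_path Output paths; either may be NULL to skip.
#' @export
write_geno_map <- function(gm, map_path = NULL, geno_path = NULL) {
  stopifnot(inherits(gm, "geno_map"))
  if (!is.null(map_path))
    utils::write.table(gm$map, map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(geno_path)) {
    codes <- matrix(c("PI", "MM")[gm$geno + 1L], nrow(gm$geno),
                    dimnames = dimnames(gm$geno))
    utils::write.table(data.frame(line = rownames(codes), codes,
                                  check.names = FALSE),
                       geno_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(gm)
}

#' Write genomic intervals as BED (0-based half-open)
#'
#' @param df data.frame with columns `chrom`, plus start/end columns named
#'   by `start_col`/`end_col` (1-based inclusive bp unless
#'   `already_0based`).
#' @param path Output path.
#' @param name_col Optional column used as the BED name field.
#' @param start_col,end_col Column names of the interval bounds.
#' @param already_0based Set TRUE when the intervals are already 0-based
#'   half-open (e.g. hotspot bins).
#' @export
write_bed <- function(df, path, name_col = NULL,
                      start_col = "start_bp", end_col = "end_bp",
                      already_0based = FALSE) {
  start <- df[[start_col]]
  if (!already_0based) start <- start - 1
  bed <- data.frame(chrom = df$chrom, start = format(start, scientific = FALSE,
                                                     trim = TRUE),
                    end = format(df[[end_col]], scientific = FALSE,
                                 trim = TRUE))
  if (!is.null(name_col)) bed$name <- df[[name_col]]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write count matrices and sample metadata as TSV
#'
#' Counts are genes x samples with a leading `gene` column; metadata has
#' columns `sample`, `line`, `treatment`, `is_parent`, `replicate`;
#' annotation has `gene`, `chrom`, `start`, `end` and optionally `length`
#' (defaults to end - start + 1).
#'
#' @param counts_path,metadata_path,annotation_path TSV paths.
#' @return An `expr_set` with the counts layer filled.
#' @export
read_expr_tsv <- function(counts_path, metadata_path, annotation_path) {
  cnt <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  counts <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(counts) <- cnt[[1]]
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  if (is.null(ann$length)) ann$length <- ann$end - ann$start + 1
  meta <- meta[match(colnames(counts), meta$sample), ]
  ann <- ann[match(rownames(counts), ann$gene), ]
  expr_set(counts, meta, ann)
}

#' @rdname read_expr_tsv
#' @param em An `expr_set`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @export
write_expr_tsv <- function(em, dir, prefix = "expr") {
  stopifnot(inherits(em, "expr_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (layer in c("counts", "tpm", "tpm_log", "tpm_rat")) {
    if (is.null(em[[layer]])) next
    utils::write.table(
      data.frame(gene = rownames(em[[layer]]), em[[layer]],
                 check.names = FALSE),
      file.path(dir, sprintf("%s_%s.tsv", prefix, layer)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(em$samples, file.path(dir, paste0(prefix, "_samples.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(em$genes, file.path(dir, paste0(prefix, "_genes.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read gene annotation from GFF3
#'
#' Uses `rtracklayer` when available; keeps records of type `gene` (or all
#' records when none are typed `gene`) and extracts the id from the given
#' attribute.
#'
#' @param path GFF3 path.
#' @param id_attribute Attribute holding the gene id.
#' @return data.frame: gene, chrom, start, end, strand, length.
#' @export
read_gene_annotation_gff3 <- function(path, id_attribute = "ID") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gene_annotation_gff3() requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
  id <- S4Vectors::mcols(gr)[[id_attribute]]
  data.frame(gene = as.character(id),
             chrom = type.convert(as.character(GenomicRanges::seqnames(gr)),
                                  as.is = TRUE),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             length = GenomicRanges::width(gr),
             stringsAsFactors = FALSE)
}
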