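# Readers/writers for the pipeline's on-disk formats. Tables go through
# data.table, sparse matrices through Matrix (MatrixMarket triplets),
# variant call sets through VCF (vcfR for parsing), gene sets through GMT.

#' Write / read the read-observation table
#'
#' One row per read: `chrom`, `pos`, `ref`, `alt`, `cell_barcode`, `umi`,
#' `observed_allele` (`ref`/`alt`/`other`).
#'
#' @param obs Observation `data.frame`.
#' @param path TSV path.
#' @export
write_observations <- function(obs, path) {
  data.table::fwrite(obs, path, sep = "\t")
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  obs <- as.data.frame(data.table::fread(path, sep = "\t",
                                         colClasses = list(character = "chrom")))
  need <- c("chrom", "pos", "ref", "alt", "cell_barcode", "umi",
            "observed_allele")
  if (!all(need %in% names(obs)))
    stop("observation table must have columns: ", paste(need, collapse = ", "))
  bad <- !obs$observed_allele %in% c("ref", "alt", "other")
  if (any(bad)) stop("observed_allele must be one of ref/alt/other")
  obs
}

.vcf_info_header <- c(
  '##INFO=<ID=CALLERS,Number=.,Type=String,Description="Callers supporting the variant">',
  '##INFO=<ID=TVAF,Number=1,Type=Float,Description="Tumor variant allele fraction">',
  '##INFO=<ID=NVAF,Number=1,Type=Float,Description="Normal variant allele fraction">',
  '##INFO=<ID=TDEPTH,Number=1,Type=Integer,Description="Tumor depth (ref+alt)">',
  '##INFO=<ID=NDEPTH,Number=1,Type=Integer,Description="Normal depth (ref+alt)">',
  '##INFO=<ID=TRC,Number=1,Type=Integer,Description="Tumor ref read count">',
  '##INFO=<ID=TAC,Number=1,Type=Integer,Description="Tumor alt read count">',
  '##INFO=<ID=NRC,Number=1,Type=Integer,Description="Normal ref read count">',
  '##INFO=<ID=NAC,Number=1,Type=Integer,Description="Normal alt read count">',
  '##INFO=<ID=EXONIC,Number=0,Type=Flag,Description="Variant is exonic">',
  '##INFO=<ID=DBSNP,Number=0,Type=Flag,Description="Variant in dbSNP">',
  '##INFO=<ID=COSMIC,Number=0,Type=Flag,Description="Variant in COSMIC">')

#' Write somatic call records as a biallelic VCF
#'
#' Emits one biallelic record per row with the call-set annotations in
#' INFO: `CALLERS`, `TVAF`/`NVAF`, `TDEPTH`/`NDEPTH`, exact read counts
#' (`TRC`/`TAC`/`NRC`/`NAC`) and the `EXONIC`/`DBSNP`/`COSMIC` flags.
#'
#' @param records Somatic call `data.frame` (see
#'   [simulate_somatic_callsets()]).
#' @param path Output `.vcf` path (uncompressed).
#' @export
write_somatic_vcf <- function(records, path) {
  td <- records$tumor_ref_count + records$tumor_alt_count
  nd <- records$normal_ref_count + records$normal_alt_count
  fmt_vaf <- function(a, d) ifelse(d > 0, format(a / d, digits = 10), "NA")
  info <- paste0(
    "CALLERS=", gsub("\\|", ",", records$callers),
    ";TVAF=", fmt_vaf(records$tumor_alt_count, td),
    ";NVAF=", fmt_vaf(records$normal_alt_count, nd),
    ";TDEPTH=", td, ";NDEPTH=", nd,
    ";TRC=", records$tumor_ref_count, ";TAC=", records$tumor_alt_count,
    ";NRC=", records$normal_ref_count, ";NAC=", records$normal_alt_count,
    ifelse(records$exonic, ";EXONIC", ""),
    ifelse(records$in_dbsnp, ";DBSNP", ""),
    ifelse(records$in_cosmic, ";COSMIC", ""))
  body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                ".", ".", info, sep = "\t")
  writeLines(c("##fileformat=VCFv4.2", .vcf_info_header,
               paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT",
                                   "QUAL", "FILTER", "INFO"),
                                 collapse = "\t")),
               body), path)
  invisible(path)
}

#' Read a biallelic somatic VCF back into a call-record table
#'
#' Multi-allelic rows are rejected; sites must be pre-split. Exact read
#' counts are taken from the `TRC`/`TAC`/`NRC`/`NAC` keys when present and
#' reconstructed from VAF x depth otherwise.
#'
#' @param path VCF path.
#' @return Somatic call `data.frame`.
#' @export
read_somatic_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    stop("multi-allelic VCF rows are not supported; split sites first")
  num <- function(key) suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, element = key)))
  info_str <- vcf@fix[, "INFO"]
  flag <- function(key) grepl(paste0("(^|;)", key, "(;|$)"), info_str)
  trc <- num("TRC"); tac <- num("TAC"); nrc <- num("NRC"); nac <- num("NAC")
  if (anyNA(trc)) {
    td <- num("TDEPTH"); nd <- num("NDEPTH")
    tac <- round(num("TVAF") * td); trc <- td - tac
    nac <- round(num("NVAF") * nd); nrc <- nd - nac
    tac[is.na(tac)] <- 0; trc[is.na(trc)] <- td[is.na(trc)]
    nac[is.na(nac)] <- 0; nrc[is.na(nrc)] <- nd[is.na(nrc)]
  }
  data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    variant_class = ifelse(nchar(fix$REF) == nchar(fix$ALT), "SNV", "indel"),
    callers = gsub(",", "|", vcfR::extract.info(vcf, element = "CALLERS")),
    tumor_ref_count = as.integer(trc), tumor_alt_count = as.integer(tac),
    normal_ref_count = as.integer(nrc), normal_alt_count = as.integer(nac),
    exonic = flag("EXONIC"), in_dbsnp = flag("DBSNP"),
    in_cosmic = flag("COSMIC"),
    stringsAsFactors = FALSE)
}

#' Write / read an expression matrix as MatrixMarket triplets
#'
#' Writes `matrix.mtx`, `barcodes.tsv`, `features.tsv` and `cell_meta.tsv`
#' into `dir`; reading reconstructs a
#' [SingleCellExperiment::SingleCellExperiment].
#'
#' @param sce A `SingleCellExperiment` with a `counts` assay.
#' @param dir Output directory (created if needed).
#' @export
write_expression_mtx <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(SummarizedExperiment::assay(sce, "counts"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
  data.table::fwrite(as.data.frame(SummarizedExperiment::rowData(sce)),
                     file.path(dir, "features.tsv"), sep = "\t")
  data.table::fwrite(as.data.frame(SummarizedExperiment::colData(sce)),
                     file.path(dir, "cell_meta.tsv"), sep = "\t")
  invisible(dir)
}

#' @rdname write_expression_mtx
#' @export
read_expression_mtx <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  features <- as.data.frame(data.table::fread(file.path(dir, "features.tsv")))
  meta <- as.data.frame(data.table::fread(file.path(dir, "cell_meta.tsv")))
  dimnames(counts) <- list(features$symbol, barcodes)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(meta, row.names = barcodes),
    rowData = S4Vectors::DataFrame(features, row.names = features$symbol))
}

#' Read a GMT gene-set file
#'
#' Thin wrapper over [fgsea::gmtPathways()].
#'
#' @param path GMT path.
#' @return Named list of gene vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (any(lengths(sets) == 0)) stop("GMT file contains an empty gene set")
  sets
}

#' Write gene sets to GMT
#'
#' @param sets Named list of gene vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write the full synthetic cohort to a directory
#'
#' Emits every pipeline input as plain text: read observations (TSV),
#' somatic calls (VCF), germline calls (TSV), expression (MTX triplet +
#' TSVs), CNV matrix (TSV), band table, cell metadata, sample geography,
#' and the ground truth as JSON.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_observations(cohort$observations, file.path(dir, "observations.tsv"))
  write_somatic_vcf(cohort$somatic_calls, file.path(dir, "somatic.vcf"))
  data.table::fwrite(cohort$germline_calls, file.path(dir, "germline.tsv"),
                     sep = "\t")
  data.table::fwrite(cohort$variants, file.path(dir, "variants.tsv"),
                     sep = "\t")
  write_expression_mtx(cohort$sce, file.path(dir, "expression"))
  cnv <- data.frame(cell_barcode = rownames(cohort$cnv$matrix),
                    cohort$cnv$matrix, check.names = FALSE)
  data.table::fwrite(cnv, file.path(dir, "cnv_matrix.tsv"), sep = "\t")
  data.table::fwrite(cohort$band_table, file.path(dir, "band_table.tsv"),
                     sep = "\t")
  data.table::fwrite(cohort$cells, file.path(dir, "cells.tsv"), sep = "\t")
  data.table::fwrite(cohort$samples, file.path(dir, "samples.tsv"), sep = "\t")
  truth <- list(
    molecule_counts = cohort$obs_truth,
    somatic_truth = cohort$somatic_calls[, c("chrom", "pos", "truth_pass",
                                             "planted_reasons")],
    germline_truth = cohort$germline_calls[, c("chrom", "pos", "truth_pass",
                                               "planted_reasons")],
    programs = S4Vectors::metadata(cohort$sce)$programs,
    cnv = cohort$cnv$truth)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
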