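# Consensus variant filtering. Every boundary comparison is implemented
# exactly as printed in the originating criteria:
#   somatic:  |callers| >= 2 (within the class's caller set), tumor depth
#             >= 14, normal depth >= 8, tumor VAF >= 0.05, normal VAF
#             <= 0.02, indel length < 100 (strict), exonic, and NOT
#             (in dbSNP AND NOT in COSMIC);
#   germline: alt depth >= 5 and alt fraction >= 0.20 in BOTH samples,
#             coding region, population frequency < 0.05%.
# VAF = alt/(ref+alt) (biallelic convention); depth = ref+alt. Zero depth
# makes the VAF undefined: the record fails with reason "no-depth".

#' Default somatic consensus-filter thresholds
#'
#' @param min_callers Minimum supporting callers within the variant class's
#'   caller set (SNV: strelka/varscan/mutect; indel: strelka/varscan/pindel).
#' @param min_tumor_depth,min_normal_depth Minimum ref+alt depth.
#' @param min_tumor_vaf Minimum tumor VAF (inclusive).
#' @param max_normal_vaf Maximum normal VAF (inclusive).
#' @param max_indel_length Indel length must be strictly below this.
#' @return Named list of thresholds.
#' @export
somatic_thresholds <- function(min_callers = 2L,
                               min_tumor_depth = 14L,
                               min_normal_depth = 8L,
                               min_tumor_vaf = 0.05,
                               max_normal_vaf = 0.02,
                               max_indel_length = 100L) {
  list(min_callers = min_callers, min_tumor_depth = min_tumor_depth,
       min_normal_depth = min_normal_depth, min_tumor_vaf = min_tumor_vaf,
       max_normal_vaf = max_normal_vaf, max_indel_length = max_indel_length)
}

.caller_sets <- list(SNV = c("strelka", "varscan", "mutect"),
                     indel = c("strelka", "varscan", "pindel"))

.split_callers <- function(x) strsplit(x, "|", fixed = TRUE)

#' Apply the somatic consensus filter
#'
#' A record passes iff every rule holds; the fail table lists every
#' violated rule per record (semicolon-separated `reasons`). `pass` and
#' `fail` partition the input rows.
#'
#' @param records Somatic call `data.frame` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `variant_class`, `callers` (`|`-separated),
#'   `tumor_ref_count`, `tumor_alt_count`, `normal_ref_count`,
#'   `normal_alt_count`, `exonic`, `in_dbsnp`, `in_cosmic`.
#' @param thresholds See [somatic_thresholds()].
#' @return List with `pass` and `fail` data frames; `fail` carries a
#'   `reasons` column.
#' @export
filter_somatic <- function(records, thresholds = somatic_thresholds()) {
  th <- thresholds
  n <- nrow(records)
  if (n == 0L)
    return(list(pass = records,
                fail = cbind(records, reasons = character(0))))
  td <- records$tumor_ref_count + records$tumor_alt_count
  nd <- records$normal_ref_count + records$normal_alt_count
  is_indel <- records$variant_class == "indel"
  indel_len <- abs(nchar(records$ref) - nchar(records$alt))
  n_callers <- mapply(function(cl, set)
    length(intersect(cl, .caller_sets[[set]])),
    .split_callers(records$callers), records$variant_class)

  viol <- cbind(
    `caller-support` = n_callers < th$min_callers,
    `tumor-depth` = td < th$min_tumor_depth,
    `normal-depth` = nd < th$min_normal_depth,
    `tumor-vaf` = td > 0 & records$tumor_alt_count / td < th$min_tumor_vaf,
    `normal-vaf` = nd > 0 & records$normal_alt_count / nd > th$max_normal_vaf,
    `indel-length` = is_indel & indel_len >= th$max_indel_length,
    `not-exonic` = !records$exonic,
    `dbsnp-not-cosmic` = records$in_dbsnp & !records$in_cosmic,
    `no-depth` = td == 0 | nd == 0)
  .partition_filtered(records, viol)
}

#' Default germline filter thresholds
#'
#' @param min_alt_depth Minimum alt read count in each sample (inclusive).
#' @param min_alt_fraction Minimum alt fraction in each sample (inclusive).
#' @param max_pop_af Records with population frequency at or above this
#'   are removed (the rule is `pop_af < max_pop_af`).
#' @return Named list of thresholds.
#' @export
germline_thresholds <- function(min_alt_depth = 5L,
                                min_alt_fraction = 0.20,
                                max_pop_af = 0.0005) {
  list(min_alt_depth = min_alt_depth, min_alt_fraction = min_alt_fraction,
       max_pop_af = max_pop_af)
}

#' Apply the germline filter
#'
#' Pass iff alt depth and alt fraction meet their thresholds in both the
#' tumor and the normal sample, the variant lies in the coding region set,
#' and its population frequency is below the cutoff.
#'
#' @param records Germline call `data.frame` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `tumor_ref_count`, `tumor_alt_count`,
#'   `normal_ref_count`, `normal_alt_count`, `pop_af`, `in_coding_region`.
#' @param thresholds See [germline_thresholds()].
#' @return List with `pass` and `fail` data frames.
#' @export
filter_germline <- function(records, thresholds = germline_thresholds()) {
  th <- thresholds
  if (nrow(records) == 0L)
    return(list(pass = records,
                fail = cbind(records, reasons = character(0))))
  td <- records$tumor_ref_count + records$tumor_alt_count
  nd <- records$normal_ref_count + records$normal_alt_count
  taf <- ifelse(td > 0, records$tumor_alt_count / td, NA_real_)
  naf <- ifelse(nd > 0, records$normal_alt_count / nd, NA_real_)
  viol <- cbind(
    `allelic-depth` = records$tumor_alt_count < th$min_alt_depth |
      records$normal_alt_count < th$min_alt_depth,
    `allele-frequency` = (!is.na(taf) & taf < th$min_alt_fraction) |
      (!is.na(naf) & naf < th$min_alt_fraction),
    `non-coding` = !records$in_coding_region,
    `population-frequency` = records$pop_af >= th$max_pop_af,
    `no-depth` = td == 0 | nd == 0)
  .partition_filtered(records, viol)
}

.partition_filtered <- function(records, viol) {
  failed <- rowSums(viol) > 0
  reasons <- apply(viol, 1L, function(v)
    paste(colnames(viol)[v], collapse = ";"))
  fail <- records[failed, , drop = FALSE]
  fail$reasons <- reasons[failed]
  list(pass = records[!failed, , drop = FALSE], fail = fail)
}

#' Per-locus hotspot VAFs from base readcounts
#'
#' For each hotspot base position, reports every non-reference base with a
#' positive read count, with `vaf = count(b) / (count(b) + count(ref))` —
#' the biallelic, per-alternate convention. Positions with zero coverage
#' across all four bases are reported once with `vaf = NA` and
#' `no_coverage = TRUE`.
#'
#' @param readcounts `data.frame` with `chrom`, `pos`, `ref_base` and
#'   integer columns `A`, `C`, `G`, `T`.
#' @return `data.frame` with `chrom`, `pos`, `ref_base`, `alt_base`,
#'   `alt_count`, `ref_count`, `vaf`, `no_coverage`.
#' @export
hotspot_vafs <- function(readcounts) {
  stopifnot(all(c("chrom", "pos", "ref_base", "A", "C", "G", "T") %in%
                  names(readcounts)),
            all(readcounts$ref_base %in% c("A", "C", "G", "T")))
  bases <- c("A", "C", "G", "T")
  out <- lapply(seq_len(nrow(readcounts)), function(i) {
    row <- readcounts[i, ]
    counts <- unlist(row[bases])
    if (any(counts < 0)) stop("negative base count at row ", i)
    if (sum(counts) == 0)
      return(data.frame(chrom = row$chrom, pos = row$pos,
                        ref_base = row$ref_base, alt_base = NA_character_,
                        alt_count = NA_integer_, ref_count = NA_integer_,
                        vaf = NA_real_, no_coverage = TRUE,
                        stringsAsFactors = FALSE))
    alts <- setdiff(bases, row$ref_base)
    alts <- alts[counts[alts] > 0]
    if (!length(alts)) return(NULL)
    data.frame(chrom = row$chrom, pos = row$pos, ref_base = row$ref_base,
               alt_base = alts,
               alt_count = as.integer(counts[alts]),
               ref_count = as.integer(counts[[row$ref_base]]),
               vaf = counts[alts] / (counts[alts] + counts[[row$ref_base]]),
               no_coverage = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = integer(),
                      ref_base = character(), alt_base = character(),
                      alt_count = integer(), ref_count = integer(),
                      vaf = numeric(), no_coverage = logical())
  rownames(out) <- NULL
  out
}
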