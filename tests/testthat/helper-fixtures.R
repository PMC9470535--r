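# Shared fixtures and independent oracles for the test suite.

small_cfg <- function(seed = 42L, ...) {
  args <- list(...)
  defaults <- list(
    seed = seed,
    n_cells_per_group = c(tumor = 80L, panin = 50L, adm = 30L,
                          normal_duct = 50L, acinar = 30L),
    n_genes = 300L, n_clusters = 3L, program_size = 40L,
    n_somatic_records = 150L, n_germline_records = 150L)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

# Independent rule-by-rule re-application of the somatic consensus filter,
# written record-by-record with literal comparisons.
brute_somatic_pass <- function(rec, th = somatic_thresholds()) {
  vapply(seq_len(nrow(rec)), function(i) {
    r <- rec[i, ]
    td <- r$tumor_ref_count + r$tumor_alt_count
    nd <- r$normal_ref_count + r$normal_alt_count
    if (td == 0 || nd == 0) return(FALSE)
    allowed <- if (r$variant_class == "SNV")
      c("strelka", "varscan", "mutect") else c("strelka", "varscan", "pindel")
    supp <- intersect(strsplit(r$callers, "|", fixed = TRUE)[[1]], allowed)
    length(supp) >= th$min_callers &&
      td >= th$min_tumor_depth &&
      nd >= th$min_normal_depth &&
      r$tumor_alt_count / td >= th$min_tumor_vaf &&
      r$normal_alt_count / nd <= th$max_normal_vaf &&
      (r$variant_class != "indel" ||
         abs(nchar(r$ref) - nchar(r$alt)) < th$max_indel_length) &&
      r$exonic &&
      !(r$in_dbsnp && !r$in_cosmic)
  }, logical(1))
}

brute_germline_pass <- function(rec, th = germline_thresholds()) {
  vapply(seq_len(nrow(rec)), function(i) {
    r <- rec[i, ]
    td <- r$tumor_ref_count + r$tumor_alt_count
    nd <- r$normal_ref_count + r$normal_alt_count
    if (td == 0 || nd == 0) return(FALSE)
    r$tumor_alt_count >= th$min_alt_depth &&
      r$normal_alt_count >= th$min_alt_depth &&
      r$tumor_alt_count / td >= th$min_alt_fraction &&
      r$normal_alt_count / nd >= th$min_alt_fraction &&
      r$in_coding_region &&
      r$pop_af < th$max_pop_af
  }, logical(1))
}

# Arbitrary-precision oracle for the Z statistic (mpmath at 50 digits).
# Returns data.frame(z, p) with NA where the test is skipped.
mpmath_z_oracle <- function(x_t, n_t, x_n, n_n) {
  script <- system.file("oracle", "zscore_oracle.py", package = "scvarmap")
  stopifnot(nzchar(script))
  fin <- tempfile(fileext = ".txt")
  on.exit(unlink(fin))
  utils::write.table(data.frame(x_t, n_t, x_n, n_n), fin,
                     row.names = FALSE, col.names = FALSE)
  out <- system2("python", c(shQuote(script), shQuote(fin)), stdout = TRUE)
  parts <- do.call(rbind, strsplit(out, "\t", fixed = TRUE))
  data.frame(z = suppressWarnings(as.numeric(parts[, 1])),
             p = suppressWarnings(as.numeric(parts[, 2])))
}

# Exhaustive-enumeration oracle for the hypergeometric upper tail:
# probability that a uniformly drawn deg set of size n_deg from a universe
# of size n_u (of which the first n_set genes form the set) overlaps the
# set in >= k genes. Enumerates every possible draw.
ora_enum_p <- function(n_u, n_set, n_deg, k) {
  draws <- utils::combn(n_u, n_deg)
  mean(colSums(draws <= n_set) >= k)
}
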