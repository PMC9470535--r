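rec_somatic <- function(variant_class = "SNV", callers = "strelka|varscan",
                        tr = 19L, ta = 1L, nr = 10L, na = 0L, exonic = TRUE,
                        dbsnp = FALSE, cosmic = FALSE, ref = "G", alt = "A") {
  data.frame(chrom = "12", pos = 25398284L, ref = ref, alt = alt,
             variant_class = variant_class, callers = callers,
             tumor_ref_count = tr, tumor_alt_count = ta,
             normal_ref_count = nr, normal_alt_count = na,
             exonic = exonic, in_dbsnp = dbsnp, in_cosmic = cosmic,
             stringsAsFactors = FALSE)
}

test_that("somatic filter honors every printed boundary", {
  # tumor VAF exactly 0.05 at depth 20, clean normal, exonic, COSMIC: pass
  r <- rec_somatic(cosmic = TRUE)
  expect_equal(nrow(filter_somatic(r)$pass), 1L)
  # called only by mutect: caller-support failure
  r <- rec_somatic(callers = "mutect", tr = 10L, ta = 10L)
  out <- filter_somatic(r)
  expect_equal(nrow(out$pass), 0L)
  expect_match(out$fail$reasons, "caller-support")
  # indel of length exactly 100 fails the strict < 100 rule; 99 passes
  long <- rec_somatic("indel", "strelka|pindel",
                      ref = paste0("A", strrep("T", 100)), alt = "A",
                      tr = 10L, ta = 10L)
  expect_match(filter_somatic(long)$fail$reasons, "indel-length")
  ok <- rec_somatic("indel", "strelka|pindel",
                    ref = paste0("A", strrep("T", 99)), alt = "A",
                    tr = 10L, ta = 10L)
  expect_equal(nrow(filter_somatic(ok)$pass), 1L)
  # normal VAF just above 0.02 fails
  r <- rec_somatic(tr = 10L, ta = 10L, nr = 38L, na = 1L)  # 1/39 > 0.02
  expect_match(filter_somatic(r)$fail$reasons, "normal-vaf")
  # dbSNP without COSMIC is excluded; dbSNP with COSMIC is kept
  expect_match(filter_somatic(rec_somatic(ta = 2L, dbsnp = TRUE))$fail$reasons,
               "dbsnp-not-cosmic")
  expect_equal(nrow(filter_somatic(rec_somatic(ta = 2L, dbsnp = TRUE,
                                               cosmic = TRUE))$pass), 1L)
  # pindel support does not count towards an SNV's caller tally
  r <- rec_somatic(callers = "pindel|strelka", ta = 2L)
  expect_match(filter_somatic(r)$fail$reasons, "caller-support")
})

test_that("zero-depth samples fail with reason no-depth, never crash", {
  r <- rec_somatic(tr = 0L, ta = 0L)
  out <- filter_somatic(r)
  expect_equal(nrow(out$fail), 1L)
  expect_match(out$fail$reasons, "no-depth")
  g <- data.frame(chrom = "1", pos = 1L, ref = "G", alt = "A",
                  tumor_ref_count = 0L, tumor_alt_count = 0L,
                  normal_ref_count = 20L, normal_alt_count = 10L,
                  pop_af = 0, in_coding_region = TRUE)
  expect_match(filter_germline(g)$fail$reasons, "no-depth")
})

test_that("germline filter applies both-sample depth/AF and population rules", {
  g <- function(ta = 5L, tr = 20L, na = 5L, nr = 16L, pop = 0,
                coding = TRUE) {
    data.frame(chrom = "13", pos = 32339000L, ref = "G", alt = "A",
               tumor_ref_count = tr, tumor_alt_count = ta,
               normal_ref_count = nr, normal_alt_count = na,
               pop_af = pop, in_coding_region = coding,
               stringsAsFactors = FALSE)
  }
  # AF exactly 0.20 tumor, ~0.238 normal, coding, absent from gnomAD: pass
  expect_equal(nrow(filter_germline(g())$pass), 1L)
  # population frequency exactly 0.05% is excluded (rule is >= 0.0005)
  expect_match(filter_germline(g(pop = 0.0005))$fail$reasons,
               "population-frequency")
  # normal alt count 4 fails allelic depth
  expect_match(filter_germline(g(na = 4L))$fail$reasons, "allelic-depth")
  # tumor AF below 0.20 fails even with normal passing
  expect_match(filter_germline(g(ta = 5L, tr = 21L))$fail$reasons,
               "allele-frequency")
  expect_match(filter_germline(g(coding = FALSE))$fail$reasons, "non-coding")
})

test_that("pass and fail partition the input and reasons list every violation", {
  cfg <- small_cfg(seed = 21)
  som <- simulate_somatic_callsets(cfg, 400)
  out <- filter_somatic(som)
  expect_equal(nrow(out$pass) + nrow(out$fail), nrow(som))
  key <- function(d) paste(d$chrom, d$pos)
  expect_setequal(c(key(out$pass), key(out$fail)), key(som))
  # a record violating several rules reports all of them
  multi <- rec_somatic(callers = "mutect", tr = 5L, ta = 0L, exonic = FALSE)
  rs <- filter_somatic(multi)$fail$reasons
  for (r in c("caller-support", "tumor-depth", "tumor-vaf", "not-exonic"))
    expect_match(rs, r)
})

test_that("filters equal brute-force per-rule re-application on random records", {
  cfg <- small_cfg(seed = 33)
  som <- simulate_somatic_callsets(cfg, 2000)
  out <- filter_somatic(som)
  oracle <- brute_somatic_pass(som)
  expect_identical(paste(out$pass$chrom, out$pass$pos),
                   paste(som$chrom, som$pos)[oracle])
  expect_true(all(out$pass$truth_pass))
  expect_false(any(out$fail$truth_pass))
  germ <- simulate_germline_callsets(cfg, 2000)
  outg <- filter_germline(germ)
  oracleg <- brute_germline_pass(germ)
  expect_identical(paste(outg$pass$chrom, outg$pass$pos),
                   paste(germ$chrom, germ$pos)[oracleg])
})

test_that("loosening any single somatic threshold never shrinks the pass set", {
  cfg <- small_cfg(seed = 55)
  som <- simulate_somatic_callsets(cfg, 800)
  base <- filter_somatic(som)$pass
  key <- function(d) paste(d$chrom, d$pos)
  looser <- list(
    somatic_thresholds(min_callers = 1L),
    somatic_thresholds(min_tumor_depth = 5L),
    somatic_thresholds(min_normal_depth = 2L),
    somatic_thresholds(min_tumor_vaf = 0.01),
    somatic_thresholds(max_normal_vaf = 0.10),
    somatic_thresholds(max_indel_length = 500L))
  for (th in looser) {
    wider <- filter_somatic(som, th)$pass
    expect_true(all(key(base) %in% key(wider)))
  }
})

test_that("hotspot VAFs follow the per-alternate biallelic convention", {
  rc <- data.frame(chrom = "12", pos = c(25398284L, 25398285L, 25398286L,
                                         25398287L),
                   ref_base = "G",
                   A = c(5L, 0L, 5L, 0L), C = 0L, G = c(95L, 100L, 90L, 0L),
                   T = c(0L, 0L, 5L, 0L))
  out <- hotspot_vafs(rc)
  # 5/(5+95)
  expect_equal(out$vaf[out$pos == 25398284L], 0.05)
  # all-reference position emits no alt rows
  expect_false(25398285L %in% out$pos[!out$no_coverage &
                                        !is.na(out$alt_base)])
  # two alternates each use ref + that alt as denominator: 5/95
  two <- out[out$pos == 25398286L, ]
  expect_equal(nrow(two), 2L)
  expect_equal(two$vaf, rep(5 / 95, 2))
  expect_setequal(two$alt_base, c("A", "T"))
  # zero total coverage flagged with missing VAF
  nc <- out[out$pos == 25398287L, ]
  expect_true(nc$no_coverage)
  expect_true(is.na(nc$vaf))
})
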