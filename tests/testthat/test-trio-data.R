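# Pedigree parsing, trio extraction, genotype/region input, cohort assembly,
# and the rare/common partition.

test_that("a minimal pedigree parses with resolving parent links", {
  path <- write_ped_lines(c(
    "F1 P1 0 0 1 0",
    "F1 M1 0 0 2 0",
    "F1 C1 P1 M1 1 0"
  ))
  ped <- read_pedigree(path)
  expect_equal(nrow(ped), 3)
  expect_equal(ped$father_id, c(NA, NA, "P1"))
  expect_equal(ped$mother_id, c(NA, NA, "M1"))
})

test_that("malformed and duplicate pedigree rows are rejected by line", {
  expect_error(read_pedigree(write_ped_lines("F1 C1 P1")), "line 1")
  expect_error(
    read_pedigree(write_ped_lines(c("F1 A 0 0 1 0", "F1 A 0 0 1 0"))),
    "duplicate"
  )
  expect_warning(
    read_pedigree(write_ped_lines("F1 C1 P9 M9 1 0")),
    "absent"
  )
})

test_that("two families with two children each give eight individuals", {
  lines <- unlist(lapply(c("F1", "F2"), function(f) c(
    paste(f, "P 0 0 1 0"), paste(f, "M 0 0 2 0"),
    paste(f, "C1 P M 1 0"), paste(f, "C2 P M 2 0")
  )))
  # individual ids are unique within family only; qualify them
  lines <- unlist(lapply(c("F1", "F2"), function(f) c(
    paste(f, paste0(f, "_P"), "0 0 1 0"),
    paste(f, paste0(f, "_M"), "0 0 2 0"),
    paste(f, paste0(f, "_C1"), paste0(f, "_P"), paste0(f, "_M"), "1 0"),
    paste(f, paste0(f, "_C2"), paste0(f, "_P"), paste0(f, "_M"), "2 0")
  )))
  ped <- read_pedigree(write_ped_lines(lines))
  expect_equal(nrow(ped), 8)
  trios <- extract_trios(ped, ped$individual_id, seed = 4)
  expect_equal(nrow(trios), 2)
  expect_equal(anyDuplicated(trios[, c("father_id", "mother_id")]), 0L)
})

test_that("trio extraction is seed-deterministic and respects completeness", {
  lines <- c(
    "F1 P 0 0 1 0", "F1 M 0 0 2 0",
    "F1 C1 P M 1 0", "F1 C2 P M 1 0", "F1 C3 P M 2 0"
  )
  ped <- read_pedigree(write_ped_lines(lines))
  all_ids <- ped$individual_id
  t1 <- extract_trios(ped, all_ids, seed = 7)
  t2 <- extract_trios(ped, all_ids, seed = 7)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 1)
  # draws land on different children across seeds (uniform among the three)
  picks <- vapply(1:30, function(s) extract_trios(ped, all_ids, s)$offspring_id,
                  character(1))
  expect_gt(length(unique(picks)), 1)
  # ungenotyped mother disqualifies the family
  expect_equal(nrow(extract_trios(ped, setdiff(all_ids, "M"), seed = 1)), 0)
  # offspring must themselves be genotyped; selection is among genotyped only
  t3 <- extract_trios(ped, c("P", "M", "C2"), seed = 99)
  expect_equal(t3$offspring_id, "C2")
  # empty pedigree: empty result, not an error
  expect_equal(nrow(extract_trios(ped[0, ], all_ids, seed = 1)), 0)
})

test_that("half-siblings form distinct parent pairs", {
  lines <- c(
    "F1 P 0 0 1 0", "F1 M1 0 0 2 0", "F1 M2 0 0 2 0",
    "F1 C1 P M1 1 0", "F1 C2 P M2 1 0"
  )
  ped <- read_pedigree(write_ped_lines(lines))
  trios <- extract_trios(ped, ped$individual_id, seed = 3)
  expect_equal(nrow(trios), 2)
})

test_that("VCF GT decoding handles het, missing and multiallelic records", {
  gt <- rbind(
    c("0/0", "0/1", "0/0", "0/0"),
    c("0/1", "1/1", "./.", "0|1"),
    c("0/1", "1/2", "0/0", "1/1")   # multiallelic row (ALT has comma)
  )
  path <- write_toy_vcf(gt[1:2, ], samples = c("s1", "s2", "s3", "s4"))
  geno <- read_genotype_vcf(path)
  expect_equal(dim(geno$dosage), c(4, 2))
  expect_equal(unname(geno$dosage[, 1]), c(0L, 1L, 0L, 0L))
  expect_equal(unname(geno$dosage[, 2]), c(1L, 2L, NA, 1L))
  expect_error(read_genotype_vcf(path, samples = c("s1", "sX")), "sX")
})

test_that("multiallelic records are skipped with a warning", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    paste(c("1", "10", "v1", "A", "C", ".", "PASS", ".", "GT", "0/1"),
          collapse = "\t"),
    paste(c("1", "20", "v2", "A", "C,G", ".", "PASS", ".", "GT", "1/2"),
          collapse = "\t")
  ), path)
  expect_warning(geno <- read_genotype_vcf(path), "multiallelic")
  expect_equal(geno$variants$variant_id, "v1")
})

test_that("cohort assembly recodes to the parental minor allele", {
  # variant 1: ALT frequency 0.75 in parents -> REF becomes the coded allele
  GF <- matrix(c(2L, 1L), 2, 1)
  GM <- matrix(c(2L, 1L), 2, 1)
  X <- matrix(c(2L, 1L), 2, 1)
  co <- toy_cohort(GF, GM, X)
  expect_equal(co$variants$coded_allele, "ref")
  expect_equal(unname(co$GF[, 1]), c(0L, 1L))   # 1/1 parent gets dosage 0
  expect_equal(co$variants$maf, 0.25)
  # heterozygotes are fixed points of recoding; homozygotes map d -> 2 - d
  expect_equal(unname(co$X[, 1]), c(0L, 1L))
})

test_that("ties at frequency 0.5 keep the ALT allele coded", {
  GF <- matrix(c(1L, 1L), 2, 1)
  GM <- matrix(c(1L, 1L), 2, 1)
  co <- toy_cohort(GF, GM, matrix(c(0L, 2L), 2, 1))
  expect_equal(co$variants$coded_allele, "alt")
  expect_equal(co$variants$maf, 0.5)
})

test_that("Mendelian-inconsistent offspring cells become missing, counted", {
  GF <- matrix(0L, 2, 1)
  GM <- matrix(0L, 2, 1)
  X <- matrix(c(1L, 0L), 2, 1)    # impossible: parents 0/0 -> offspring 1
  expect_warning(co <- toy_cohort(GF, GM, X), "Mendelian")
  expect_equal(co$n_mendel_errors, 1L)
  expect_true(is.na(co$X[1, 1]))
})

test_that("variant partition strata are exhaustive, disjoint, boundary-inclusive", {
  # 50 trios -> 200 parental alleles; realize exact coded-allele counts by
  # planting het parents: counts 2, 10, 12, 80, 0 -> MAF 0.01, 0.05 (still
  # rare: boundary inclusive), 0.06, 0.40, 0 (monomorphic)
  N <- 50
  counts <- c(2L, 10L, 12L, 80L, 0L)
  GF <- sapply(counts, function(k) c(rep(1L, min(k, N)), rep(0L, N - min(k, N))))
  GM <- sapply(counts, function(k) {
    extra <- max(k - N, 0)
    c(rep(1L, extra), rep(0L, N - extra))
  })
  X <- matrix(0L, N, length(counts))
  X[GF == 1 & GM == 0] <- 1L   # het father may transmit the coded allele
  co <- toy_cohort(GF, GM, X)
  part <- partition_variants(co)
  expect_equal(part$maf, counts / 200, tolerance = 1e-12)
  expect_equal(as.character(part$stratum),
               c("rare", "rare", "common", "common", "monomorphic"))
  # exhaustive and pairwise disjoint by construction of a single factor
  expect_false(anyNA(part$stratum))
  stratum_ids <- trioskat:::stratum_variants(co, "all")
  expect_length(stratum_ids, 4)
  expect_setequal(c(trioskat:::stratum_variants(co, "rare"),
                    trioskat:::stratum_variants(co, "common")),
                  stratum_ids)
})

test_that("region files resolve gene variant sets in both dialects", {
  setid <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("GENE1\tv1", "GENE1\tv2", "GENE2\tv3"), setid)
  reg <- read_regions(setid)
  variants <- tibble::tibble(variant_id = c("v1", "v2", "v3", "v4"),
                             chrom = "1", pos = c(100L, 150L, 300L, 400L))
  expect_equal(gene_variants(reg, "GENE1", variants), c("v1", "v2"))
  expect_equal(gene_variants(reg, "GENEX", variants), character())

  bed <- withr::local_tempfile(fileext = ".bed")
  # 0-based half-open [99, 150) must catch pos 100 and 150 via start < pos <= end
  writeLines(c("1\t99\t150\tGENE1", "1\t250\t400\tGENE2"), bed)
  regb <- read_regions(bed)
  expect_equal(gene_variants(regb, "GENE1", variants), c("v1", "v2"))
  expect_equal(gene_variants(regb, "GENE2", variants), c("v3", "v4"))
})

test_that("a dosage-matrix TSV round-trips into a genotype object", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\ts1\ts2", "v1\t0\t1", "v2\t2\tNA"), path)
  geno <- read_dosage_matrix(path)
  expect_equal(dim(geno$dosage), c(2, 2))
  expect_equal(unname(geno$dosage["s2", ]), c(1L, NA))
})
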