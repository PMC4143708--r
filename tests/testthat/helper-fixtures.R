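# Shared fixtures, all built in code at test time.

# tiny hand-constructed cohort: `n` trios x `m` variants with explicit dosages
toy_cohort <- function(GF, GM, X, traits = NULL) {
  N <- nrow(X)
  trios <- tibble::tibble(
    family_id = paste0("FAM", seq_len(N)),
    father_id = paste0("F_", seq_len(N)),
    mother_id = paste0("M_", seq_len(N)),
    offspring_id = paste0("O_", seq_len(N)),
    trio = seq_len(N)
  )
  m <- ncol(X)
  dosage <- rbind(GF, GM, X)
  rownames(dosage) <- c(trios$father_id, trios$mother_id, trios$offspring_id)
  variants <- tibble::tibble(
    variant_id = paste0("v", seq_len(m)), chrom = "1",
    pos = seq_len(m) * 100L, ref = "A", alt = "C"
  )
  if (is.null(traits)) traits <- tibble::tibble(y = seq_len(N))
  trio_cohort(trios, list(dosage = dosage, variants = variants), traits)
}

# write a minimal pedigree file; lines = character vector of rows
write_ped_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".ped", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# minimal VCF with given GT strings (variants x samples matrix)
write_toy_vcf <- function(gt, samples, chrom = "1", pos = NULL,
                          ref = "A", alt = "C", ids = NULL) {
  path <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  m <- nrow(gt)
  pos <- pos %||% seq_len(m) * 10L
  ids <- ids %||% paste0("v", seq_len(m))
  ref <- rep_len(ref, m)
  alt <- rep_len(alt, m)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(m), function(j) {
    paste(c(chrom, pos[j], ids[j], ref[j], alt[j], ".", "PASS", ".", "GT",
            gt[j, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force sum-form statistics (the explicit double-loop expressions)
bruteforce_q_skat <- function(r, S, w) {
  total <- 0
  for (j in seq_along(w)) {
    sj <- 0
    for (i in seq_along(r)) sj <- sj + r[i] * S[i, j]
    total <- total + w[j]^2 * sj^2
  }
  total
}

bruteforce_q_burden <- function(r, S, w) {
  acc <- 0
  for (j in seq_along(w)) {
    sj <- 0
    for (i in seq_along(r)) sj <- sj + r[i] * S[i, j]
    acc <- acc + w[j] * sj
  }
  acc^2
}
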