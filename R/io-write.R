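# Plain-text export of simulated cohorts (VCF + PED + phenotype/truth TSV)
# and the results writer shared by the CLI subcommands.

#' Write a simulated cohort to VCF / PED / TSV files
#'
#' Emits `<prefix>.vcf` (trio genotypes, samples F_i / M_i / O_i),
#' `<prefix>.ped` (6-column pedigree), `<prefix>.pheno.tsv` (offspring
#' traits) and, when `truth` is given, `<prefix>.truth.tsv`.
#'
#' @param cohort A `trio_cohort`.
#' @param prefix Output path prefix.
#' @param truth Optional truth tibble from [generate_cohort()].
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, prefix, truth = NULL) {
  paths <- c(vcf = paste0(prefix, ".vcf"), ped = paste0(prefix, ".ped"),
             pheno = paste0(prefix, ".pheno.tsv"))
  trios <- cohort$trios
  samples <- c(trios$father_id, trios$mother_id, trios$offspring_id)
  # back to ALT-allele counts for VCF output
  to_alt <- function(mat) {
    flip <- cohort$variants$coded_allele == "ref"
    mat[, flip] <- 2L - mat[, flip]
    mat
  }
  alt_dosage <- rbind(to_alt(cohort$GF), to_alt(cohort$GM), to_alt(cohort$X))
  gt <- matrix(c("0/0", "0/1", "1/1")[alt_dosage + 1L],
               nrow(alt_dosage), ncol(alt_dosage))
  gt[is.na(gt)] <- "./."
  v <- cohort$variants
  na_default <- function(x, d) ifelse(is.na(x), d, as.character(x))
  body <- vapply(seq_len(ncol(cohort$X)), function(j) {
    paste(c(na_default(v$chrom[j], "1"), na_default(v$pos[j], j),
            v$variant_id[j], na_default(v$ref[j], "A"),
            na_default(v$alt[j], "C"), ".", "PASS", ".", "GT", gt[, j]),
          collapse = "\t")
  }, character(1))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), paths["vcf"])
  cat(paste(body, collapse = "\n"), "\n", sep = "", file = paths["vcf"],
      append = TRUE)

  ped <- rbind(
    data.frame(fid = trios$family_id, iid = trios$father_id,
               fat = "0", mot = "0", sex = 1L, phe = 0L),
    data.frame(fid = trios$family_id, iid = trios$mother_id,
               fat = "0", mot = "0", sex = 2L, phe = 0L),
    data.frame(fid = trios$family_id, iid = trios$offspring_id,
               fat = trios$father_id, mot = trios$mother_id, sex = 0L,
               phe = 0L)
  )
  utils::write.table(ped, paths["ped"], quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)

  pheno <- dplyr::bind_cols(tibble(individual_id = trios$offspring_id),
                            cohort$phenotypes)
  readr::write_tsv(pheno, paths["pheno"])
  if (!is.null(truth)) {
    paths["truth"] <- paste0(prefix, ".truth.tsv")
    readr::write_tsv(truth, paths["truth"])
  }
  invisible(paths)
}

# TSV writer with a commented provenance header
write_results_tsv <- function(tbl, path, seed = NULL, extra = character(),
                              timestamp = TRUE) {
  header <- c(
    sprintf("# trioskat %s", as.character(utils::packageVersion("trioskat"))),
    if (timestamp) sprintf("# written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)),
    extra
  )
  writeLines(header, path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
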