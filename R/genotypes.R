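# Genotype and region input, minor-allele recoding from parental samples,
# trio cohort assembly, and the rare/common variant partition.

#' Read biallelic genotypes from a VCF file
#'
#' Decodes the GT subfield into counts of the ALT allele. Multiallelic
#' records are skipped with a warning; missing genotypes become NA. Gzipped
#' files are accepted.
#'
#' @param path Path to a VCF (v4.x) file.
#' @param samples Optional character vector of sample ids to keep, in this
#'   order. An error lists any requested sample absent from the header.
#' @return A list with `dosage` (samples x variants integer matrix of ALT
#'   allele counts, rownames = sample ids) and `variants` (tibble with
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`).
#' @export
read_genotype_vcf <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning("skipping ", sum(multi), " multiallelic record(s)", call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(gt))
    if (length(missing) > 0) {
      stop("sample(s) absent from VCF: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    gt <- gt[, samples, drop = FALSE]
  }
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"),
                fix$ID)
  dosage <- matrix(gt_to_dosage(as.vector(gt)), nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = list(ids, colnames(gt)))
  list(
    dosage = t(dosage),
    variants = tibble(
      variant_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT
    )
  )
}

# "0/1", "0|1", "./." -> ALT allele count or NA
gt_to_dosage <- function(gt) {
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) != 2 || any(a == ".")) return(NA_integer_)
    sum(a == "1")
  }, integer(1))
}

#' Read a plain dosage matrix
#'
#' TSV alternative to VCF input: first column `variant_id`, one column per
#' individual, cells in \{0, 1, 2, NA\}.
#'
#' @param path Path to the TSV file.
#' @return Same structure as [read_genotype_vcf()]; `chrom`/`pos` are NA.
#' @export
read_dosage_matrix <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "integer"
  if (any(!is.na(mat) & !(mat %in% 0:2))) {
    stop("dosage cells must be 0, 1, 2 or NA", call. = FALSE)
  }
  rownames(mat) <- ids
  list(
    dosage = t(mat),
    variants = tibble(variant_id = ids, chrom = NA_character_,
                      pos = NA_integer_, ref = NA_character_,
                      alt = NA_character_)
  )
}

#' Read a gene-to-variant region set
#'
#' Two dialects: "setid" (two-column TSV: gene name, variant id) and "bed"
#' (3+ column BED with a name field; intervals are 0-based half-open, and are
#' matched against 1-based VCF positions as start < pos <= end).
#'
#' @param path Path to the region file.
#' @param format "auto" (by extension: .bed -> bed, else setid), "setid" or
#'   "bed".
#' @return A tibble: `gene`, `variant_id` for setid; `gene`, `chrom`,
#'   `start`, `end` for bed. Its `dialect` attribute records the format.
#' @export
read_regions <- function(path, format = c("auto", "setid", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "setid"
  }
  if (format == "bed") {
    tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                           comment = "#")
    if (ncol(tab) < 4) stop("BED region file needs a 4th (name) column", call. = FALSE)
    out <- tibble(gene = as.character(tab[[4]]), chrom = as.character(tab[[1]]),
                  start = as.integer(tab[[2]]), end = as.integer(tab[[3]]))
  } else {
    tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                           comment = "#")
    if (ncol(tab) < 2) stop("SetID region file needs 2 columns", call. = FALSE)
    out <- tibble(gene = as.character(tab[[1]]), variant_id = as.character(tab[[2]]))
    if (anyDuplicated(out)) {
      stop("duplicate variant id within a gene's set", call. = FALSE)
    }
  }
  attr(out, "dialect") <- format
  out
}

#' Resolve the variant ids belonging to one gene
#'
#' @param regions Tibble from [read_regions()].
#' @param gene Gene name to look up.
#' @param variants Variant metadata tibble (e.g. `cohort$variants`), needed to
#'   intersect BED intervals with variant positions.
#' @return Character vector of variant ids (possibly empty).
#' @export
gene_variants <- function(regions, gene, variants) {
  rows <- regions[regions$gene == gene, , drop = FALSE]
  if (nrow(rows) == 0) return(character())
  if (identical(attr(regions, "dialect"), "bed")) {
    hits <- purrr::pmap(rows, function(gene, chrom, start, end) {
      variants$variant_id[!is.na(variants$pos) & variants$chrom == chrom &
                            variants$pos > start & variants$pos <= end]
    })
    unique(unlist(hits))
  } else {
    intersect(rows$variant_id, variants$variant_id)
  }
}

#' Assemble an analysis-ready trio cohort
#'
#' Aligns offspring and parental genotypes by trio, recodes every variant to
#' count its minor allele as estimated from the parental samples only (a tie
#' at frequency 0.5 keeps the ALT/"1" allele), flags Mendelian-inconsistent
#' offspring genotypes as missing, and attaches phenotypes.
#'
#' @param trios Tibble from [extract_trios()] (columns `father_id`,
#'   `mother_id`, `offspring_id`).
#' @param genotypes List with `dosage` (samples x variants ALT counts) and
#'   `variants`, as returned by [read_genotype_vcf()] or
#'   [read_dosage_matrix()].
#' @param phenotypes Data frame of offspring traits: either one row per trio
#'   in trio order, or carrying an `individual_id`/`offspring_id` column used
#'   to align rows to trios.
#' @return A `trio_cohort`: list with `trios`, offspring dosages `X`,
#'   paternal/maternal dosages `GF`/`GM` (all N x m, recoded to the minor
#'   allele), `variants` (with `coded_allele` and parental `maf`),
#'   `phenotypes`, and `n_mendel_errors`.
#' @export
trio_cohort <- function(trios, genotypes, phenotypes) {
  dosage <- genotypes$dosage
  variants <- genotypes$variants
  need <- unique(c(trios$father_id, trios$mother_id, trios$offspring_id))
  missing <- setdiff(need, rownames(dosage))
  if (length(missing) > 0) {
    stop("trio member(s) without genotypes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  GF <- dosage[trios$father_id, , drop = FALSE]
  GM <- dosage[trios$mother_id, , drop = FALSE]
  X <- dosage[trios$offspring_id, , drop = FALSE]

  # minor allele from parents only; ties (freq exactly 0.5) keep the coded
  # ALT/"1" allele
  f_alt <- parental_maf(GF, GM)
  flip <- !is.na(f_alt) & f_alt > 0.5
  for (m in c("GF", "GM", "X")) {
    mat <- get(m)
    mat[, flip] <- 2L - mat[, flip]
    assign(m, mat)
  }
  variants$coded_allele <- ifelse(flip, "ref", "alt")
  variants$maf <- ifelse(flip, 1 - f_alt, f_alt)

  # Mendelian-inconsistent cells: observed offspring dosage has conditional
  # probability zero given the parents -> treat as missing, keep a count
  tf <- GF / 2
  tm <- GM / 2
  p_obs <- matrix(NA_real_, nrow(X), ncol(X))
  p_obs[which(X == 0)] <- ((1 - tf) * (1 - tm))[which(X == 0)]
  p_obs[which(X == 1)] <- (tf * (1 - tm) + (1 - tf) * tm)[which(X == 1)]
  p_obs[which(X == 2)] <- (tf * tm)[which(X == 2)]
  mendel <- !is.na(p_obs) & p_obs == 0
  if (any(mendel)) {
    warning(sum(mendel), " Mendelian-inconsistent genotype(s) set to missing",
            call. = FALSE)
    X[mendel] <- NA_integer_
  }

  pheno <- as_tibble(phenotypes)
  id_col <- intersect(c("offspring_id", "individual_id"), names(pheno))[1]
  if (!is.na(id_col)) {
    idx <- match(trios$offspring_id, pheno[[id_col]])
    if (anyNA(idx)) {
      stop("phenotype rows missing for offspring: ",
           paste(trios$offspring_id[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    pheno <- pheno[idx, setdiff(names(pheno), id_col), drop = FALSE]
  } else if (nrow(pheno) != nrow(trios)) {
    stop("phenotypes must have one row per trio or an id column", call. = FALSE)
  }

  dimnames(X) <- dimnames(GF) <- dimnames(GM) <-
    list(NULL, variants$variant_id)
  structure(
    list(trios = as_tibble(trios), X = X, GF = GF, GM = GM,
         variants = variants, phenotypes = pheno,
         n_mendel_errors = sum(mendel)),
    class = "trio_cohort"
  )
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat("<trio_cohort> ", nrow(x$X), " trios x ", ncol(x$X), " variants; traits: ",
      paste(names(x$phenotypes), collapse = ", "), "\n", sep = "")
  if (x$n_mendel_errors > 0) {
    cat("  ", x$n_mendel_errors, "Mendelian-inconsistent cells set missing\n")
  }
  invisible(x)
}

#' Partition variants into rare, common and monomorphic strata
#'
#' Strata are defined by the parental minor-allele frequency: rare means
#' 0 < MAF <= threshold, common means MAF > threshold; parent-monomorphic
#' variants carry no transmission information and are excluded from both.
#'
#' @param cohort A `trio_cohort`.
#' @param maf_threshold Rare/common boundary (inclusive for rare);
#'   default 0.05.
#' @return Tibble `variant_id`, `maf`, `stratum` (factor: rare, common,
#'   monomorphic).
#' @export
partition_variants <- function(cohort, maf_threshold = 0.05) {
  maf <- cohort$variants$maf
  stratum <- dplyr::case_when(
    is.na(maf) ~ NA_character_,
    maf == 0 ~ "monomorphic",
    maf <= maf_threshold ~ "rare",
    TRUE ~ "common"
  )
  tibble(
    variant_id = cohort$variants$variant_id,
    maf = maf,
    stratum = factor(stratum, levels = c("rare", "common", "monomorphic"))
  )
}

# variant ids eligible for a stratum choice ("rare", "common", "all");
# monomorphic and all-missing variants are never testable
stratum_variants <- function(cohort, stratum = c("all", "rare", "common"),
                             maf_threshold = 0.05) {
  stratum <- match.arg(stratum)
  part <- partition_variants(cohort, maf_threshold)
  keep <- switch(stratum,
    all = part$stratum %in% c("rare", "common"),
    rare = part$stratum == "rare",
    common = part$stratum == "common"
  )
  part$variant_id[keep & !is.na(part$stratum)]
}
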