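# Pedigree input and trio extraction. Trios are sampled so that each
# (father, mother) pair contributes at most one offspring: conditional on
# parental genotypes, transmissions in distinct trios are then independent.

#' Read a PED/FAM pedigree file
#'
#' Parses the standard 6+ column whitespace-delimited pedigree format
#' (family, individual, father, mother, sex, phenotype); "0" denotes a
#' missing parent. Extra columns are ignored.
#'
#' @param path Path to a PED or FAM file.
#' @return A tibble of class `trio_pedigree` with columns `family_id`,
#'   `individual_id`, `father_id`, `mother_id` (NA when missing), `sex`
#'   (1, 2 or NA). Parent references that do not resolve within the family
#'   are kept but flagged with a warning.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6)) {
    stop("malformed pedigree line(s) (fewer than 6 columns) at line ",
         paste(which(nf < 6), collapse = ", "), call. = FALSE)
  }
  ped <- tibble(
    family_id = vapply(fields, `[[`, "", 1),
    individual_id = vapply(fields, `[[`, "", 2),
    father_id = vapply(fields, `[[`, "", 3),
    mother_id = vapply(fields, `[[`, "", 4),
    sex = suppressWarnings(as.integer(vapply(fields, `[[`, "", 5)))
  )
  ped$father_id[ped$father_id == "0"] <- NA_character_
  ped$mother_id[ped$mother_id == "0"] <- NA_character_
  ped$sex[!ped$sex %in% c(1L, 2L)] <- NA_integer_
  key <- paste(ped$family_id, ped$individual_id)
  if (anyDuplicated(key)) {
    stop("duplicate (family, individual) id(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  dangling <- (!is.na(ped$father_id) & !paste(ped$family_id, ped$father_id) %in% key) |
    (!is.na(ped$mother_id) & !paste(ped$family_id, ped$mother_id) %in% key)
  if (any(dangling)) {
    warning(sum(dangling), " individual(s) reference parents absent from the ",
            "pedigree (treated as founders for trio extraction)", call. = FALSE)
  }
  structure(ped, class = c("trio_pedigree", class(ped)))
}

#' Extract conditionally independent trios from a pedigree
#'
#' Offspring are grouped by their (father, mother) pair. For every pair where
#' father, mother and at least one offspring are all genotyped, exactly one
#' genotyped offspring is selected uniformly at random, so each parent pair
#' contributes at most one trio and trios share no parents. Half-siblings form
#' distinct parent pairs and may each contribute a trio.
#'
#' @param pedigree A tibble from [read_pedigree()] (or any data frame with the
#'   same columns).
#' @param genotyped_ids Character vector of individual ids with complete
#'   genotype data; trios require all three members present here.
#' @param seed Integer seed making the random offspring draw reproducible.
#' @return A tibble with columns `family_id`, `father_id`, `mother_id`,
#'   `offspring_id` and `trio` (1..N), one row per trio.
#' @export
extract_trios <- function(pedigree, genotyped_ids, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  kids <- dplyr::filter(
    as_tibble(pedigree),
    !is.na(.data$father_id), !is.na(.data$mother_id),
    .data$individual_id %in% genotyped_ids,
    .data$father_id %in% genotyped_ids,
    .data$mother_id %in% genotyped_ids
  )
  if (nrow(kids) == 0) {
    return(tibble(family_id = character(), father_id = character(),
                  mother_id = character(), offspring_id = character(),
                  trio = integer()))
  }
  withr::with_seed(as.integer(seed), {
    picked <- kids |>
      dplyr::group_by(.data$family_id, .data$father_id, .data$mother_id) |>
      dplyr::slice_sample(n = 1) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$family_id, .data$father_id, .data$mother_id)
  })
  tibble(
    family_id = picked$family_id,
    father_id = picked$father_id,
    mother_id = picked$mother_id,
    offspring_id = picked$individual_id,
    trio = seq_len(nrow(picked))
  )
}
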