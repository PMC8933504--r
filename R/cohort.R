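# Family-cohort screening for rare recessive candidates: panel restriction,
# pathogenic-potential requirement, allele-frequency and homozygosity
# exclusions, zygosity tabulation and compound-heterozygote inference.

#' Read a pedigree table
#'
#' Tab-separated with columns `sample_id`, `family_id`, `affected` (0/1 or
#' TRUE/FALSE) and optional `father_id`, `mother_id` (`.` or empty for
#' founders).
#'
#' @param path Path to the TSV.
#' @return Tibble `sample_id`, `family_id`, `affected` (logical),
#'   `father_id`, `mother_id`.
#' @export
read_pedigree <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("sample_id", "family_id", "affected")
  if (!all(need %in% names(tab))) {
    abort(paste0("pedigree needs columns: ", paste(need, collapse = ", ")))
  }
  tibble(
    sample_id = tab$sample_id,
    family_id = tab$family_id,
    affected = tab$affected %in% c("1", "TRUE", "true", "yes"),
    father_id = if ("father_id" %in% names(tab)) tab$father_id
      else NA_character_,
    mother_id = if ("mother_id" %in% names(tab)) tab$mother_id
      else NA_character_
  )
}

#' Screen a family cohort for candidate causative mutations
#'
#' Takes delta-score-accepted calls with consequence annotations and keeps
#' those that (a) lie in a panel gene, (b) have pathogenic potential
#' (PTC-introducing or domain-disrupting), (c) have population allele
#' frequency not above `max_af` -- or unknown --, and (d) are never
#' homozygous in unaffected samples (hemizygous calls code as homozygous).
#' Zygosity is tabulated separately for affected and unaffected carriers.
#'
#' @param calls Consequence-annotated calls (see [call_consequences()]):
#'   needs `variant_id`, `gene_symbol` (or `gene_id`), `af`, `category`,
#'   `disrupted_domains`.
#' @param genotypes Long genotype tibble (`variant_id`, `sample_id`, `gt`;
#'   see [read_vcf_genotypes()]). Every screened variant must be genotyped
#'   (or explicitly `missing`) in every sample.
#' @param pedigree Pedigree tibble (see [read_pedigree()]).
#' @param panel Character vector of panel gene symbols/ids; NULL disables
#'   the panel restriction.
#' @param max_af Allele-frequency exclusion threshold: variants with
#'   `af > max_af` are dropped (default 0.01; unknown AF is retained).
#' @return Tibble of retained hits with counts `n_hom_affected`,
#'   `n_hom_unaffected`, `n_het_affected`, `n_het_unaffected` and a
#'   `carrier_samples` list-column.
#' @export
screen_cohort <- function(calls, genotypes, pedigree, panel = NULL,
                          max_af = 0.01) {
  unknown <- setdiff(genotypes$variant_id, calls$variant_id)
  if (length(unknown)) {
    abort(paste0("sample genotype references unknown variant ", unknown[1]))
  }
  bad_sample <- setdiff(genotypes$sample_id, pedigree$sample_id)
  if (length(bad_sample)) {
    abort(paste0("genotyped sample absent from pedigree: ", bad_sample[1]))
  }
  hits <- calls
  if (!is.null(panel)) {
    hits <- filter(hits, .data$gene_symbol %in% panel |
                     .data$gene_id %in% panel)
  }
  hits <- hits[pathogenic_potential(hits), ]
  hits <- filter(hits, is.na(af) | af <= max_af)
  if (nrow(hits) == 0L) return(mutate(
    hits, n_hom_affected = integer(), n_hom_unaffected = integer(),
    n_het_affected = integer(), n_het_unaffected = integer(),
    carrier_samples = list()))
  gt <- genotypes |>
    inner_join(pedigree[, c("sample_id", "affected")], by = "sample_id")
  tab <- gt |>
    filter(variant_id %in% hits$variant_id, gt %in% c("het", "hom_alt")) |>
    group_by(variant_id) |>
    summarise(
      n_hom_affected = sum(gt == "hom_alt" & affected),
      n_hom_unaffected = sum(gt == "hom_alt" & !affected),
      n_het_affected = sum(gt == "het" & affected),
      n_het_unaffected = sum(gt == "het" & !affected),
      carrier_samples = list(sample_id[gt %in% c("het", "hom_alt")]),
      .groups = "drop")
  out <- hits |>
    inner_join(tab, by = "variant_id") |>
    filter(.data$n_hom_unaffected == 0L)
  out
}

#' Detect compound-heterozygous candidate pairs within genes
#'
#' For each affected sample heterozygous for two or more retained hits in
#' one gene, emits the candidate pairs. Phase is inferred from relatives in
#' the same family: if any relative carries exactly one variant of the pair,
#' the pair can segregate apart and is flagged `in_trans`; otherwise phase
#' is `unknown`.
#'
#' @param hits Screened hits (see [screen_cohort()]).
#' @param genotypes Long genotype tibble.
#' @param pedigree Pedigree tibble.
#' @return Tibble `gene_symbol`, `sample_id`, `variant_a`, `variant_b`,
#'   `phase` (`in_trans` / `unknown`), `informative_relative`.
#' @export
detect_compound_het <- function(hits, genotypes, pedigree) {
  out <- list()
  gt <- genotypes |>
    inner_join(pedigree[, c("sample_id", "family_id", "affected")],
               by = "sample_id")
  for (g in unique(hits$gene_symbol)) {
    vids <- hits$variant_id[hits$gene_symbol == g]
    if (length(vids) < 2L) next
    sub <- filter(gt, variant_id %in% vids)
    aff <- filter(sub, affected, gt == "het")
    for (s in unique(aff$sample_id)) {
      mine <- sort(unique(aff$variant_id[aff$sample_id == s]))
      if (length(mine) < 2L) next
      fam <- pedigree$family_id[pedigree$sample_id == s]
      relatives <- setdiff(
        pedigree$sample_id[pedigree$family_id == fam], s)
      prs <- combn(mine, 2L)
      for (k in seq_len(ncol(prs))) {
        va <- prs[1, k]; vb <- prs[2, k]
        carrier <- function(v) {
          sub$sample_id[sub$variant_id == v & sub$sample_id %in% relatives &
                          sub$gt %in% c("het", "hom_alt")]
        }
        ca <- carrier(va); cb <- carrier(vb)
        informative <- union(setdiff(ca, cb), setdiff(cb, ca))
        out[[length(out) + 1L]] <- tibble(
          gene_symbol = g, sample_id = s, variant_a = va, variant_b = vb,
          phase = if (length(informative)) "in_trans" else "unknown",
          informative_relative = if (length(informative)) informative[1]
          else NA_character_)
      }
    }
  }
  if (length(out)) bind_rows(out) else
    tibble(gene_symbol = character(), sample_id = character(),
           variant_a = character(), variant_b = character(),
           phase = character(), informative_relative = character())
}

#' Fraction of diagnoses added by novel candidate mutations
#'
#' Of `n_potential` candidate mutations, `n_overlap` are already registered
#' as known pathogenic; the remainder, relative to the `n_known` known
#' pathogenic mutations, is the added fraction in percent (one decimal,
#' half away from zero).
#'
#' @param n_potential Candidate mutations with pathogenic potential.
#' @param n_overlap Candidates already among the known pathogenic set.
#' @param n_known Known pathogenic mutations (> 0).
#' @return Percentage, one decimal.
#' @export
compute_added_fraction <- function(n_potential, n_overlap, n_known) {
  stopifnot(n_overlap <= n_potential)
  if (n_known <= 0) abort("added fraction undefined: n_known must be > 0")
  round_half_up(100 * (n_potential - n_overlap) / n_known)
}
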