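#' Read SNVs from a VCF file
#'
#' Loads a VCF via [vcfR::read.vcfR()] into a tidy variants tibble. Only
#' biallelic SNV records are meaningful downstream; set `snv_only = TRUE`
#' (default) to drop anything else. Allele frequency is pulled from the INFO
#' field named by `af_field` (missing values become `NA`, which the filter
#' cascade treats as "rare by assumption"). The raw INFO string is kept so
#' that precomputed splice-gain annotations can be parsed later with
#' [read_delta_score()].
#'
#' @param path Path to a VCF (plain text or gzipped).
#' @param af_field INFO key holding the allele frequency (default `"AF"`).
#' @param snv_only Drop non-SNV records (default TRUE).
#' @return Tibble with columns `variant_id`, `contig`, `pos`, `ref`, `alt`,
#'   `af`, `info`.
#' @export
read_vcf <- function(path, af_field = "AF", snv_only = TRUE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  out <- tibble(
    variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste0(fix$CHROM, ":", fix$POS, fix$REF, ">", fix$ALT),
                        fix$ID),
    contig = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    info = ifelse(is.na(fix$INFO), "", fix$INFO)
  )
  if (snv_only) {
    out <- out |>
      filter(nchar(ref) == 1L, nchar(alt) == 1L, !grepl(",", alt, fixed = TRUE))
  }
  out$af <- parse_info_numeric(out$info, af_field)
  select(out, variant_id, contig, pos, ref, alt, af, info)
}

# pull a single numeric INFO value (NA when absent)
parse_info_numeric <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) {
    if (length(x) < 2L) return(NA_real_)
    suppressWarnings(as.numeric(x[2]))
  }, numeric(1))
}

#' Validate variants against a reference genome
#'
#' Asserts that every record is an SNV, that `ref != alt`, and that the REF
#' base matches the genome. Errors on the first violation.
#'
#' @param variants Variants tibble (see [read_vcf()]).
#' @param genome A `DNAStringSet`.
#' @return The variants tibble, invisibly usable in a pipe.
#' @export
validate_variants <- function(variants, genome) {
  if (nrow(variants) == 0L) return(variants)
  if (any(nchar(variants$ref) != 1L | nchar(variants$alt) != 1L)) {
    abort("indels rejected: ref and alt must be single bases")
  }
  if (any(variants$ref == variants$alt)) {
    abort("ref must differ from alt")
  }
  for (i in seq_len(nrow(variants))) {
    base <- get_seq(genome, variants$contig[i], variants$pos[i],
                    variants$pos[i])
    if (base != variants$ref[i]) {
      abort(sprintf("ref mismatch at %s:%d (genome %s, variant %s)",
                    variants$contig[i], variants$pos[i], base,
                    variants$ref[i]))
    }
  }
  variants
}

#' Extract the splice-gain delta score from variant annotations
#'
#' Parses the SpliceAI-dialect INFO annotation
#' `SpliceAI=ALT|GENE|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL`
#' and returns the maximum of the two *gain* scores (acceptor gain `DS_AG`
#' and donor gain `DS_DG`); when several gene entries are present
#' (comma-separated) the maximum over entries is taken. Loss scores are not
#' thresholded: disruption of annotated sites is screened separately.
#' A plain numeric INFO field (`override_field`) may be used instead when no
#' structured annotation is present.
#'
#' @param variants Variants tibble with an `info` column.
#' @param annotation_field INFO key of the structured annotation
#'   (default `"SpliceAI"`).
#' @param override_field INFO key of a plain numeric delta score fallback
#'   (default `"DS"`).
#' @return The variants tibble with a `delta_score` column in `[0, 1]`.
#' @export
read_delta_score <- function(variants, annotation_field = "SpliceAI",
                             override_field = "DS") {
  pat <- paste0("(?:^|;)", annotation_field, "=([^;]+)")
  m <- regmatches(variants$info, regexec(pat, variants$info))
  ds <- vapply(seq_along(m), function(i) {
    x <- m[[i]]
    if (length(x) >= 2L) {
      entries <- strsplit(x[2], ",", fixed = TRUE)[[1]]
      gains <- vapply(entries, function(e) {
        f <- strsplit(e, "|", fixed = TRUE)[[1]]
        if (length(f) < 5L) return(NA_real_)
        suppressWarnings(max(as.numeric(f[3]), as.numeric(f[5])))
      }, numeric(1))
      return(max(gains, na.rm = TRUE))
    }
    parse_info_numeric(variants$info[i], override_field)
  }, numeric(1))
  if (anyNA(ds)) {
    bad <- variants$variant_id[which(is.na(ds))[1]]
    abort(paste0("no delta score source for variant ", bad))
  }
  mutate(variants, delta_score = ds)
}

#' Read per-sample genotypes from a multi-sample VCF
#'
#' @param path Path to a multi-sample VCF with a GT FORMAT field.
#' @param af_field INFO key holding the allele frequency.
#' @return List with `variants` (tibble, as [read_vcf()]) and `genotypes`
#'   (long tibble: `variant_id`, `sample_id`, `gt` in
#'   `hom_ref`/`het`/`hom_alt`/`missing`; haploid calls count as homozygous).
#' @export
read_vcf_genotypes <- function(path, af_field = "AF") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  variants <- read_vcf(path, af_field = af_field, snv_only = FALSE)
  gtm <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gtm)) abort("VCF carries no GT field")
  long <- as_tibble(gtm, rownames = NULL) |>
    mutate(variant_id = variants$variant_id) |>
    tidyr::pivot_longer(-variant_id, names_to = "sample_id",
                        values_to = "raw") |>
    mutate(gt = code_genotype(.data$raw)) |>
    select(variant_id, sample_id, gt)
  list(variants = variants, genotypes = long)
}

code_genotype <- function(raw) {
  alleles <- strsplit(gsub("\\|", "/", ifelse(is.na(raw), ".", raw)), "/")
  vapply(alleles, function(a) {
    a <- a[a != ""]
    if (length(a) == 0L || any(a == ".")) return("missing")
    n_alt <- sum(a != "0")
    if (n_alt == 0L) "hom_ref"
    else if (n_alt == length(a)) "hom_alt"  # incl. hemizygous "1"
    else "het"
  }, character(1))
}
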