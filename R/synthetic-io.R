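# Junction-read simulation, synthetic family cohorts, and plain-text writers
# for the fixture formats (VCF, junction TSV, pedigree TSV, toy SAM).

#' Simulate junction-read evidence for planted calls
#'
#' For every planted true call, carrier samples draw novel-junction reads
#' from `Binomial(depth, planned JAF)` and annotated-junction reads as the
#' remainder; non-carriers see annotated-only coverage. Realised counts are
#' returned alongside the junction table so tests can reconcile them.
#'
#' @param planted A `planted_scms` (see [plant_scms()]).
#' @param carriers Tibble `variant_id`, `sample_id` assigning one or more
#'   carrier samples per true variant; NULL assigns carrier `CARRIER_<id>`
#'   and non-carrier `CTRL_<id>` per variant.
#' @param depth Junction coverage per locus (default 50).
#' @param seed RNG seed.
#' @return List with `junctions` (tibble `sample_id`, `contig`,
#'   `intron_start`, `intron_end`, `strand`, `unique_reads`) and `counts`
#'   (tibble `variant_id`, `sample_id`, `J_n`, `J_a`, `jaf_realised`,
#'   `jaf_planned`).
#' @export
simulate_junction_evidence <- function(planted, carriers = NULL, depth = 50L,
                                       seed = 1L) {
  stopifnot(inherits(planted, "planted_scms"), depth >= 1L)
  truth <- filter(planted$truth, class == "true")
  if (is.null(carriers)) {
    carriers <- tibble(variant_id = truth$variant_id,
                       sample_id = paste0("CARRIER_", truth$variant_id))
  }
  withr::with_seed(seed + 2L, {
    jrows <- list()
    crows <- list()
    strands <- planted$db$transcripts$strand[
      match(truth$transcript_id, planted$db$transcripts$transcript_id)]
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      strand <- strands[i]
      who <- carriers$sample_id[carriers$variant_id == tr$variant_id]
      for (s in who) {
        jn <- rbinom(1L, depth, tr$jaf_planned)
        ja <- depth - jn
        jrows[[length(jrows) + 1L]] <- tibble(
          sample_id = s, contig = tr$contig,
          intron_start = c(tr$novel_intron_start, tr$annotated_intron_start),
          intron_end = c(tr$novel_intron_end, tr$annotated_intron_end),
          strand = strand, unique_reads = c(jn, ja))
        crows[[length(crows) + 1L]] <- tibble(
          variant_id = tr$variant_id, sample_id = s, J_n = jn, J_a = ja,
          jaf_realised = if (jn + ja > 0L) jn / (jn + ja) else NA_real_,
          jaf_planned = tr$jaf_planned)
      }
      ctrl <- paste0("CTRL_", tr$variant_id)
      jrows[[length(jrows) + 1L]] <- tibble(
        sample_id = ctrl, contig = tr$contig,
        intron_start = tr$annotated_intron_start,
        intron_end = tr$annotated_intron_end,
        strand = strand, unique_reads = depth)
      crows[[length(crows) + 1L]] <- tibble(
        variant_id = tr$variant_id, sample_id = ctrl, J_n = 0L, J_a = depth,
        jaf_realised = 0, jaf_planned = 0)
    }
    list(junctions = bind_rows(jrows), counts = bind_rows(crows))
  })
}

#' Generate a synthetic family cohort with genotypes and pedigree
#'
#' Builds families around planted causal calls: one recessive family in
#' which three affected members are homozygous for a PTC-introducing call
#' and one unaffected member is heterozygous; one compound-heterozygote
#' family in which an affected child carries two calls in the same gene in
#' trans, with an unaffected sibling carrying exactly one of them
#' (phase-informative); one family with a decoy call homozygous in an
#' unaffected member; plus unremarkable carrier families.
#'
#' @param planted A `planted_scms`.
#' @param n_families Total families (>= 3; default 6).
#' @param seed RNG seed.
#' @return List with `pedigree`, `genotypes` (long tibble), `variants`
#'   (cohort variant subset) and `key` (named list: `hom_variant`,
#'   `ch_pair`, `ch_gene`, `decoy_variant`, sample roles).
#' @export
generate_cohort <- function(planted, n_families = 6L, seed = 1L) {
  stopifnot(inherits(planted, "planted_scms"), n_families >= 3L)
  truth <- filter(planted$truth, class == "true")
  ptc <- filter(truth, category %in% c("PTC_frameshift", "PTC_in_novel_exon"))
  if (nrow(ptc) < 3L) abort("need at least three PTC-introducing true calls")
  # a gene carrying two PTC calls, for the compound-het family
  by_gene <- ptc |> count(gene_id) |> filter(n >= 2L)
  if (nrow(by_gene) == 0L) abort("no gene with two PTC calls for the CH pair")
  ch_gene <- by_gene$gene_id[1]
  ch_pair <- head(ptc$variant_id[ptc$gene_id == ch_gene], 2L)
  hom_variant <- ptc$variant_id[!ptc$gene_id == ch_gene][1]
  decoy_variant <- ptc$variant_id[!ptc$variant_id %in%
                                    c(ch_pair, hom_variant)][1]
  extra <- setdiff(truth$variant_id,
                   c(ch_pair, hom_variant, decoy_variant))
  withr::with_seed(seed + 3L, {
    cohort_vids <- c(hom_variant, ch_pair, decoy_variant,
                     head(extra, max(0L, n_families - 3L)))
    ped <- list()
    gts <- list()
    add_member <- function(fam, sid, affected, geno) {
      ped[[length(ped) + 1L]] <<- tibble(
        sample_id = sid, family_id = fam, affected = affected,
        father_id = NA_character_, mother_id = NA_character_)
      full <- setNames(rep("hom_ref", length(cohort_vids)), cohort_vids)
      full[names(geno)] <- geno
      gts[[length(gts) + 1L]] <<- tibble(
        variant_id = cohort_vids, sample_id = sid, gt = unname(full))
    }
    # family 1: recessive, three affected homozygotes + unaffected het
    add_member("FAM1", "F1_A1", TRUE, setNames("hom_alt", hom_variant))
    add_member("FAM1", "F1_A2", TRUE, setNames("hom_alt", hom_variant))
    add_member("FAM1", "F1_A3", TRUE, setNames("hom_alt", hom_variant))
    add_member("FAM1", "F1_U1", FALSE, setNames("het", hom_variant))
    # family 2: compound het in trans with informative sibling
    add_member("FAM2", "F2_FA", FALSE, setNames("het", ch_pair[1]))
    add_member("FAM2", "F2_MO", FALSE, setNames("het", ch_pair[2]))
    add_member("FAM2", "F2_A1", TRUE,
               setNames(c("het", "het"), ch_pair))
    add_member("FAM2", "F2_S1", FALSE, setNames("het", ch_pair[2]))
    # family 3: decoy homozygous in an unaffected member
    add_member("FAM3", "F3_A1", TRUE, setNames("het", decoy_variant))
    add_member("FAM3", "F3_U1", FALSE, setNames("hom_alt", decoy_variant))
    # remaining families: single-carrier affected individuals
    for (f in seq_len(n_families - 3L)) {
      v <- cohort_vids[3L + f]
      if (is.na(v)) break
      add_member(sprintf("FAM%d", 3L + f), sprintf("F%d_A1", 3L + f),
                 TRUE, setNames("het", v))
    }
    pedigree <- bind_rows(ped)
    genotypes <- bind_rows(gts)
    variants <- planted$variants[planted$variants$variant_id %in%
                                   cohort_vids, ]
    list(pedigree = pedigree, genotypes = genotypes, variants = variants,
         key = list(hom_variant = hom_variant, ch_pair = ch_pair,
                    ch_gene = ch_gene, decoy_variant = decoy_variant,
                    ch_sample = "F2_A1", informative_sibling = "F2_S1"))
  })
}

# ---- plain-text writers ---------------------------------------------------

#' Write variants (optionally with genotypes) to a VCF text file
#'
#' @param variants Variants tibble with `contig`, `pos`, `variant_id`,
#'   `ref`, `alt` and optional `info`.
#' @param path Output path.
#' @param genotypes Optional long genotype tibble (`variant_id`,
#'   `sample_id`, `gt`) emitted as GT columns.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, genotypes = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
           paste0("##INFO=<ID=SpliceAI,Number=.,Type=String,Description=",
                  "\"SpliceAI-format delta scores: ",
                  "ALT|GENE|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL\">"))
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  info <- if ("info" %in% names(variants)) {
    ifelse(is.na(variants$info) | variants$info == "", ".", variants$info)
  } else "."
  body <- paste(variants$contig, variants$pos, variants$variant_id,
                variants$ref, variants$alt, ".", "PASS", info, sep = "\t")
  if (!is.null(genotypes)) {
    hdr <- c(hdr,
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
    samples <- sort(unique(genotypes$sample_id))
    cols <- c(cols, "FORMAT", samples)
    code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
              missing = "./.")
    gt_wide <- vapply(samples, function(s) {
      g <- genotypes[genotypes$sample_id == s, ]
      unname(code[g$gt[match(variants$variant_id, g$variant_id)]])
    }, character(nrow(variants)))
    gt_wide[is.na(gt_wide)] <- "./."
    gt_wide <- matrix(gt_wide, nrow = nrow(variants))
    body <- paste(body, "GT",
                  apply(gt_wide, 1L, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(hdr, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

#' Write a junction count table to TSV
#'
#' @param junctions Junction tibble (see [simulate_junction_evidence()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junction_tsv <- function(junctions, path) {
  readr::write_tsv(junctions, path)
  invisible(path)
}

#' Write a pedigree table to TSV
#'
#' @param pedigree Pedigree tibble (see [read_pedigree()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree_tsv <- function(pedigree, path) {
  out <- pedigree
  out$affected <- as.integer(out$affected)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write toy split-read alignments over a junction to a SAM text file
#'
#' Emits `n_reads` reads spanning the given intron with an N-CIGAR gap and
#' `overhang` aligned bases on each side, plus a header for the contig.
#' Useful for exercising alignment-based junction counting without binary
#' fixtures.
#'
#' @param path Output SAM path.
#' @param genome A `DNAStringSet` (for contig lengths and read sequence).
#' @param contig Contig name.
#' @param intron_start,intron_end Intron interval (1-based inclusive).
#' @param n_reads Number of split reads (default 5).
#' @param overhang Aligned bases flanking the gap per read (default 10).
#' @return `path`, invisibly.
#' @export
write_junction_sam <- function(path, genome, contig, intron_start,
                               intron_end, n_reads = 5L, overhang = 10L) {
  clen <- Biostrings::width(genome)[match(contig, names(genome))]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", contig, clen))
  gap <- intron_end - intron_start + 1L
  reads <- vapply(seq_len(n_reads), function(i) {
    start <- intron_start - overhang
    cigar <- sprintf("%dM%dN%dM", overhang, gap, overhang)
    seq <- paste0(get_seq(genome, contig, start, intron_start - 1L),
                  get_seq(genome, contig, intron_end + 1L,
                          intron_end + overhang))
    paste(sprintf("read%03d", i), 0L, contig, start, 60L, cigar, "*", 0L, 0L,
          seq, strrep("I", nchar(seq)), sep = "\t")
  }, character(1))
  writeLines(c(hdr, reads), path)
  invisible(path)
}

#' Write every synthetic fixture of a planted genome to a directory
#'
#' Emits FASTA, GTF, VCF and a ground-truth TSV with deterministic content.
#'
#' @param planted A `planted_scms`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_fixtures <- function(planted, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    vcf = file.path(dir, "variants.vcf"),
    truth = file.path(dir, "truth.tsv"))
  write_genome(planted$genome, paths[["fasta"]])
  write_gtf(planted$db, paths[["gtf"]])
  write_vcf(planted$variants, paths[["vcf"]])
  readr::write_tsv(select(planted$truth, -"altered_mrna"), paths[["truth"]])
  invisible(paths)
}
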