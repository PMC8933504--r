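# Junction-read validation: junction counting from tables or alignments,
# junction allele fraction, expression rules, the known-mutation benchmark
# set, and sensitivity/specificity/PPV arithmetic.

#' Read a splice-junction count table
#'
#' Tab-separated with columns `contig`, `intron_start`, `intron_end`,
#' `strand`, `unique_reads` (a column subset compatible with STAR
#' SJ.out.tab-style junction output; an optional leading `sample_id` column
#' is kept when present). Coordinates are the first and last intronic base,
#' 1-based inclusive.
#'
#' @param path Path to the TSV.
#' @return Tibble of junction counts.
#' @export
read_junction_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("contig", "intron_start", "intron_end", "strand", "unique_reads")
  if (!all(need %in% names(tab))) {
    abort(paste0("junction table needs columns: ",
                 paste(need, collapse = ", ")))
  }
  as_tibble(tab)
}

#' Count reads supporting an exact splice junction
#'
#' For a junction-count table, returns the recorded count for the exact
#' intron interval (0 if absent). For alignments (SAM/BAM with N-CIGAR split
#' reads), counts reads with a gap exactly matching the intron interval and
#' at least `min_overhang` aligned bases on both sides of the gap.
#'
#' @param x A junction tibble (see [read_junction_table()]) or a path to a
#'   SAM/BAM file.
#' @param contig,intron_start,intron_end The intron interval (first and last
#'   intronic base, 1-based inclusive).
#' @param strand Strand of the junction (used for table lookup; alignments
#'   are counted strand-blind, as unstranded libraries are).
#' @param sample_id Optional sample restriction when the table carries a
#'   `sample_id` column.
#' @param min_overhang Minimum aligned bases flanking the gap (default 6).
#' @return Integer read count.
#' @export
count_junction_reads <- function(x, contig, intron_start, intron_end,
                                 strand = "+", sample_id = NULL,
                                 min_overhang = 6L) {
  if (is.character(x) && length(x) == 1L) {
    return(count_junctions_from_alignments(x, contig, intron_start,
                                           intron_end, min_overhang))
  }
  tab <- x
  if (!is.null(sample_id) && "sample_id" %in% names(tab)) {
    tab <- tab[tab$sample_id == sample_id, ]
  }
  hit <- tab$contig == contig & tab$intron_start == intron_start &
    tab$intron_end == intron_end & tab$strand == strand
  if (!any(hit)) return(0L)
  as.integer(sum(tab$unique_reads[hit]))
}

count_junctions_from_alignments <- function(path, contig, intron_start,
                                            intron_end, min_overhang = 6L) {
  bam <- if (grepl("\\.sam$", path)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  gal <- GenomicAlignments::readGAlignments(bam)
  gal <- gal[as.character(GenomicRanges::seqnames(gal)) == contig]
  if (length(gal) == 0L) return(0L)
  n <- 0L
  cig <- GenomicAlignments::cigar(gal)
  starts <- GenomicRanges::start(gal)
  for (i in seq_along(gal)) {
    ops <- GenomicAlignments::explodeCigarOps(cig[i])[[1]]
    lens <- GenomicAlignments::explodeCigarOpLengths(cig[i])[[1]]
    refpos <- starts[i]
    consumed <- ops %in% c("M", "D", "N", "=", "X")
    for (k in seq_along(ops)) {
      if (ops[k] == "N") {
        gap_start <- refpos
        gap_end <- refpos + lens[k] - 1L
        if (gap_start == intron_start && gap_end == intron_end) {
          left <- sum(lens[seq_len(k - 1L)][ops[seq_len(k - 1L)] %in%
                                              c("M", "=", "X")])
          right <- sum(lens[-seq_len(k)][ops[-seq_len(k)] %in%
                                           c("M", "=", "X")])
          if (left >= min_overhang && right >= min_overhang) n <- n + 1L
        }
      }
      if (consumed[k]) refpos <- refpos + lens[k]
    }
  }
  n
}

#' Junction allele fraction
#'
#' `JAF = J_n / (J_n + J_a)`, the relative usage of the novel junction
#' against the annotated one; ranges from 0 (annotated only) to 1 (novel
#' only). Undefined when no junction reads exist at all.
#'
#' @param j_n Reads supporting the novel junction (vectorised).
#' @param j_a Reads supporting the annotated junction.
#' @return Numeric vector in `[0, 1]`.
#' @export
compute_jaf <- function(j_n, j_a) {
  if (any(j_n < 0 | j_a < 0)) abort("junction counts must be non-negative")
  if (any(j_n + j_a == 0)) {
    abort("JAF undefined: no junction reads at locus (J_n + J_a == 0)")
  }
  j_n / (j_n + j_a)
}

#' Locus expression rule from junction coverage
#'
#' A locus counts as expressed when at least five junction reads cover
#' either the novel junction or the annotated junction. The literal
#' either-junction reading (`J_n >= 5` or `J_a >= 5`) is the default; a
#' combined-sum variant (`J_n + J_a >= 5`) is available by flag.
#'
#' @param j_n,j_a Junction read counts (vectorised).
#' @param min_reads Coverage threshold (default 5).
#' @param rule `"either"` (default) or `"combined"`.
#' @return Logical vector.
#' @export
expression_check <- function(j_n, j_a, min_reads = 5L,
                             rule = c("either", "combined")) {
  rule <- match.arg(rule)
  if (rule == "either") j_n >= min_reads | j_a >= min_reads
  else (j_n + j_a) >= min_reads
}

#' Build the known splice-creating benchmark set from a clinical table
#'
#' Retains variants that (1) are classified pathogenic or likely pathogenic,
#' (2) lie in intronic regions within `intron_window` nt of an annotated
#' boundary or at synonymous exonic sites, and (3) create a GT or AG on the
#' representative transcript without disrupting an annotated splice
#' dinucleotide. Rows with unrecognised significance labels are skipped.
#'
#' @param clinical Tibble with columns `contig`, `pos`, `ref`, `alt`,
#'   `significance` (free text; matched case-insensitively against
#'   "pathogenic" / "likely pathogenic").
#' @param db A `transcript_db`.
#' @param genome A `DNAStringSet`.
#' @param intron_window Near-boundary window (default 50).
#' @return Tibble of qualifying variants with `transcript_id` and `region`
#'   columns attached.
#' @export
build_known_scm_set <- function(clinical, db, genome, intron_window = 50L) {
  sig <- tolower(gsub("[_ ]+", " ", clinical$significance))
  keep <- sig %in% c("pathogenic", "likely pathogenic")
  clin <- clinical[keep, ]
  if (nrow(clin) == 0L) return(clin)
  if (!"variant_id" %in% names(clin)) {
    clin$variant_id <- paste0(clin$contig, ":", clin$pos, clin$ref, ">",
                              clin$alt)
  }
  out <- list()
  for (tm in representative_models(db)) {
    hit <- clin$contig == tm$contig &
      clin$pos >= min(tm$exons$start) & clin$pos <= max(tm$exons$end)
    if (!any(hit)) next
    sub <- classify_variant_region(clin[hit, ], tm,
                                   intron_window = intron_window)
    # region rule: near-boundary intronic, or synonymous exonic
    ok_int <- sub$region == "intronic_near"
    ok_ex <- sub$region == "exonic"
    if (any(ok_ex)) {
      cat_ex <- annotate_genic_category(sub[ok_ex, ], tm, genome)
      ok_ex[ok_ex] <- cat_ex$genic_category == "synonymous"
    }
    sub <- sub[ok_int | ok_ex, ]
    if (nrow(sub) == 0L) next
    # creation rule: GT/AG created ...
    cand <- scan_dinucleotide_creation(sub, genome, tm)
    if (nrow(cand) == 0L) next
    # ... and annotated splice dinucleotides untouched by the SNV itself
    anno <- splice_dinucleotides(tm)
    disrupts <- vapply(cand$pos, function(p) {
      any(p >= anno$start & p <= anno$end)
    }, logical(1))
    cand <- cand[!disrupts, ]
    if (nrow(cand)) out[[tm$transcript_id]] <- cand
  }
  if (length(out)) distinct(bind_rows(out), variant_id, .keep_all = TRUE)
  else clin[0, ]
}

#' Round half away from zero to a fixed number of decimals
#'
#' Matches how printed percentages are conventionally rounded (68.15 -> 68.2
#' rather than banker's rounding).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Pipeline validation metrics: sensitivity, specificity, PPV
#'
#' Sensitivity is the fraction of the truth set recovered by the detected
#' set; specificity is the fraction of all calls not contradicted by
#' junction evidence from non-carriers (`(total - fp) / total`); the
#' positive predictive value is the fraction of expressed call loci whose
#' novel junction is actually supported by reads. All reported as
#' percentages rounded to one decimal, half away from zero.
#'
#' @param detected Character vector of detected variant ids.
#' @param truth Character vector of known-true variant ids.
#' @param fp_count False-positive calls among `total`.
#' @param total Total number of calls screened for specificity.
#' @param expressed_supported Expressed loci with novel-junction read
#'   support.
#' @param expressed_total Expressed loci examined.
#' @return One-row tibble with counts (`tp`, `fn`, `fp`) and percentages
#'   (`sensitivity`, `specificity`, `ppv`); a metric with a zero denominator
#'   is `NA`.
#' @export
compute_validation_metrics <- function(detected, truth, fp_count, total,
                                       expressed_supported, expressed_total) {
  stopifnot(fp_count >= 0, total >= 0, expressed_supported >= 0,
            expressed_total >= 0)
  tp <- length(intersect(detected, truth))
  fn <- length(setdiff(truth, detected))
  tibble(
    tp = tp, fn = fn, fp = as.integer(fp_count),
    sensitivity = if (tp + fn > 0) round_half_up(100 * tp / (tp + fn))
      else NA_real_,
    specificity = if (total > 0) round_half_up(100 * (total - fp_count) / total)
      else NA_real_,
    ppv = if (expressed_total > 0) {
      round_half_up(100 * expressed_supported / expressed_total)
    } else NA_real_
  )
}

#' Compare a carrier's expression level against non-carriers
#'
#' Flags whether the carrier's normalised expression lies strictly below the
#' median of the non-carrier levels. No significance test is attempted: a
#' single carrier per locus does not support one.
#'
#' @param carrier Numeric scalar, the carrier's normalised expression.
#' @param non_carriers Numeric vector of non-carrier levels (>= 1 value).
#' @return Logical flag (`TRUE` when below the non-carrier median).
#' @export
compare_expression <- function(carrier, non_carriers) {
  if (length(non_carriers) == 0L) abort("no non-carrier expression levels")
  carrier < median(non_carriers)
}
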