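#' Classify variant positions relative to gene structure
#'
#' For each variant, reports whether it falls inside an exon of the given
#' transcript (`exonic`), inside an intron within `intron_window` nt of the
#' nearest annotated exon-intron boundary (`intronic_near`), deeper inside an
#' intron (`intronic_deep`), or outside the transcript span (`outside_gene`).
#' Intronic distance counts the first intronic base as 1 and is measured to
#' the *nearest* of the two flanking boundaries.
#'
#' @param variants Variants tibble (needs `contig`, `pos`).
#' @param tm A `transcript_model`.
#' @param intron_window Near-boundary window in nt (default 50, the reach of
#'   conventional exome capture around exons).
#' @return The variants tibble with columns `region`,
#'   `distance_to_boundary` (NA unless intronic) and `flank_exon_index`
#'   (index, in transcription order, of the exon containing the variant or
#'   of the closest exon for intronic variants).
#' @export
classify_variant_region <- function(variants, tm, intron_window = 50L) {
  stopifnot(inherits(tm, "transcript_model"))
  n <- nrow(variants)
  region <- rep("outside_gene", n)
  dist <- rep(NA_integer_, n)
  flank <- rep(NA_integer_, n)
  span <- c(min(tm$exons$start), max(tm$exons$end))
  intr <- introns(tm)
  same <- variants$contig == tm$contig
  for (i in seq_len(n)) {
    if (!same[i]) next
    p <- variants$pos[i]
    ex_hit <- which(p >= tm$exons$start & p <= tm$exons$end)
    if (length(ex_hit)) {
      region[i] <- "exonic"
      flank[i] <- ex_hit[1]
      next
    }
    if (p < span[1] || p > span[2]) next
    in_hit <- which(p >= intr$start & p <= intr$end)
    if (length(in_hit) == 0L) next  # between transcripts sharing the contig
    j <- in_hit[1]
    d_left <- p - intr$start[j] + 1L
    d_right <- intr$end[j] - p + 1L
    dist[i] <- min(d_left, d_right)
    region[i] <- if (dist[i] <= intron_window) "intronic_near" else
      "intronic_deep"
    # closest exon in transcription order: intron j sits between exon j and
    # j+1; pick by which genomic boundary is nearer, strand-resolved
    upstream_is_left <- tm$strand == "+"
    nearer_left <- d_left <= d_right
    flank[i] <- if (xor(upstream_is_left, nearer_left)) j + 1L else j
  }
  variants |>
    mutate(region = region, distance_to_boundary = dist,
           flank_exon_index = flank)
}

#' Codon-level genic annotation of SNVs on a transcript
#'
#' Assigns exactly one category per (variant, transcript):
#' `intronic`, `synonymous`, `nonsynonymous`, `stopgain`, `ncRNA`,
#' `UTR5` or `UTR3`. Non-coding transcripts yield `ncRNA` everywhere within
#' their span. Variants outside the transcript span are an error.
#'
#' @param variants Variants tibble (`contig`, `pos`, `ref`, `alt`).
#' @param tm A `transcript_model`.
#' @param genome A `DNAStringSet`.
#' @return The variants tibble with a `genic_category` column.
#' @export
annotate_genic_category <- function(variants, tm, genome) {
  stopifnot(inherits(tm, "transcript_model"))
  span <- c(min(tm$exons$start), max(tm$exons$end))
  if (any(variants$contig != tm$contig | variants$pos < span[1] |
            variants$pos > span[2])) {
    abort("variant outside transcript span")
  }
  cds <- cds_tx_range(tm)
  mrna <- NULL
  cat <- vapply(seq_len(nrow(variants)), function(i) {
    p <- variants$pos[i]
    tpos <- genomic_to_tx(tm, p)
    if (is.na(tpos)) return("intronic")
    if (is.null(cds)) return("ncRNA")
    if (tpos < cds[1]) return("UTR5")
    if (tpos > cds[2]) return("UTR3")
    if (is.null(mrna)) mrna <<- transcript_sequence(tm, genome)
    cds_off <- tpos - cds[1]           # 0-based offset into CDS
    codon_start <- cds[1] + 3L * (cds_off %/% 3L)
    codon <- substr(mrna, codon_start, codon_start + 2L)
    alt_tx <- if (tm$strand == "+") variants$alt[i] else
      comp_base(variants$alt[i])
    pos_in_codon <- tpos - codon_start + 1L
    alt_codon <- codon
    substr(alt_codon, pos_in_codon, pos_in_codon) <- alt_tx
    aa_ref <- translate_codon(codon)
    aa_alt <- translate_codon(alt_codon)
    if (aa_alt == aa_ref) "synonymous"
    else if (aa_alt == "*") "stopgain"
    else "nonsynonymous"
  }, character(1))
  mutate(variants, genic_category = cat)
}

translate_codon <- function(codon) {
  if (grepl("N", codon, fixed = TRUE)) return("X")
  unname(Biostrings::GENETIC_CODE[codon])
}

# translate an in-frame DNA string codon-by-codon (trailing partial codon
# dropped); returns an AA string with "*" for stops, "X" for ambiguity
translate_frame <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return("")
  codons <- substring(seq, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
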