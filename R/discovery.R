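# Discovery of splice-site-creating SNVs: dinucleotide scan, candidate
# strength windows, and the staged filter cascade.

#' Scan SNVs for created splice-site dinucleotides
#'
#' Examines, on the transcript's strand, both dinucleotides overlapping each
#' variant position and emits one candidate per position where the ALT allele
#' completes `GT` (donor) or `AG` (acceptor) that the REF allele did not.
#' Candidates coinciding with the transcript's own annotated splice
#' dinucleotides are excluded (those disrupt or recreate an existing site
#' rather than creating a novel one).
#'
#' @param variants Variants tibble (`variant_id`, `contig`, `pos`, `ref`,
#'   `alt`, ...); REF must match the genome.
#' @param genome A `DNAStringSet`.
#' @param tm A `transcript_model`.
#' @return A candidates tibble: the variant columns plus `transcript_id`,
#'   `gene_id`, `gene_symbol`, `site_type`, `site_strand`, `dinuc_start`,
#'   `dinuc_end` (genomic, 1-based) and `mutated_base_index` (1 or 2, the
#'   variant's position within the created dinucleotide, strand-resolved).
#' @export
scan_dinucleotide_creation <- function(variants, genome, tm) {
  stopifnot(inherits(tm, "transcript_model"))
  validate_variants(variants, genome)
  anno <- splice_dinucleotides(tm)
  anno_key <- paste(anno$start, anno$end)
  res <- list()
  width <- Biostrings::width(genome)[match(tm$contig, names(genome))]
  for (i in seq_len(nrow(variants))) {
    if (variants$contig[i] != tm$contig) next
    p <- variants$pos[i]
    for (a in c(p - 1L, p)) {
      if (a < 1L || a + 1L > width) next
      plus_pair_ref <- get_seq(genome, tm$contig, a, a + 1L, "+")
      plus_pair_alt <- plus_pair_ref
      substr(plus_pair_alt, p - a + 1L, p - a + 1L) <- variants$alt[i]
      if (tm$strand == "+") {
        pre <- plus_pair_ref; post <- plus_pair_alt
        idx <- p - a + 1L
      } else {
        pre <- revcomp(plus_pair_ref); post <- revcomp(plus_pair_alt)
        idx <- a - p + 2L
      }
      site <- if (post == "GT") "donor" else if (post == "AG") "acceptor"
        else NA_character_
      if (is.na(site) || pre == post) next
      if (paste(a, a + 1L) %in% anno_key) next
      res[[length(res) + 1L]] <- dplyr::bind_cols(
        variants[i, ],
        tibble(transcript_id = tm$transcript_id, gene_id = tm$gene_id,
               gene_symbol = tm$gene_symbol, site_type = site,
               site_strand = tm$strand, dinuc_start = a, dinuc_end = a + 1L,
               mutated_base_index = idx))
    }
  }
  if (length(res)) bind_rows(res) else empty_candidates(variants)
}

empty_candidates <- function(variants) {
  dplyr::bind_cols(
    variants[0, ],
    tibble(transcript_id = character(), gene_id = character(),
           gene_symbol = character(), site_type = character(),
           site_strand = character(), dinuc_start = integer(),
           dinuc_end = integer(), mutated_base_index = integer()))
}

#' Extract the strength-scoring window around a created splice site
#'
#' The window is anchored on the *novel* boundary geometry: donors get a
#' 9-mer (3 bases on the novel-exonic side, 6 on the novel-intronic side,
#' created GT at window positions 4-5); acceptors get a 23-mer (20
#' novel-intronic + 3 novel-exonic bases, created AG at positions 19-20).
#' The ALT allele is substituted into the window and the sequence is
#' strand-resolved.
#'
#' @param candidates Candidates tibble from [scan_dinucleotide_creation()].
#' @param genome A `DNAStringSet`.
#' @return The candidates tibble with a `strength_window` column.
#' @export
extract_strength_window <- function(candidates, genome) {
  win <- vapply(seq_len(nrow(candidates)), function(i) {
    r <- candidates[i, ]
    plus <- r$site_strand == "+"
    if (r$site_type == "donor") {
      if (plus) { gs <- r$dinuc_start - 3L; ge <- r$dinuc_start + 5L }
      else { gs <- r$dinuc_end - 5L; ge <- r$dinuc_end + 3L }
    } else {
      if (plus) { gs <- r$dinuc_start - 18L; ge <- r$dinuc_start + 4L }
      else { gs <- r$dinuc_end - 4L; ge <- r$dinuc_end + 18L }
    }
    w <- get_seq(genome, r$contig, gs, ge, r$site_strand)
    off <- if (plus) r$pos - gs + 1L else ge - r$pos + 1L
    base <- if (plus) r$alt else comp_base(r$alt)
    substr(w, off, off) <- base
    w
  }, character(1))
  mutate(candidates, strength_window = win)
}

#' Run the staged filter cascade for splice-site-creating mutations
#'
#' Applies, in order: gene-body membership (representative transcripts of the
#' panel genes), positional filter (exonic, or intronic within
#' `intron_window` nt of a boundary), GT/AG creation, splice-site strength
#' at least `min_strength`, allele frequency at most `max_af` (unknown AF
#' passes -- rare by assumption -- and is tallied), and splice-gain delta
#' score at least `min_delta`. Per-stage variant counts are recorded in a
#' filter trace (retrievable with [filter_trace()] or [tidy()]).
#'
#' @param variants Variants tibble (see [read_vcf()]).
#' @param genome A `DNAStringSet`.
#' @param db A `transcript_db`.
#' @param panel Optional character vector of gene ids/symbols restricting the
#'   search space; NULL means all genes in `db`.
#' @param thresholds Named list overriding any of `max_af` (0.01),
#'   `min_strength` (0), `min_delta` (0.80), `intron_window` (50).
#' @param strength_backend A `pwm_model` or `maxent_model`; NULL (default)
#'   trains a PWM from `db` and `genome`.
#' @return An `scm_set`: tibble of accepted calls (one row per
#'   variant x transcript candidate) with region, window, strength and delta
#'   score columns, carrying the filter trace and settings as attributes.
#' @export
run_filter_cascade <- function(variants, genome, db, panel = NULL,
                               thresholds = list(),
                               strength_backend = NULL) {
  th <- utils::modifyList(
    list(max_af = 0.01, min_strength = 0, min_delta = 0.80,
         intron_window = 50L), thresholds)
  if (is.null(strength_backend)) strength_backend <- train_pwm(db, genome)
  trace <- tibble(stage = "input", n_variants = nrow(variants),
                  n_candidates = NA_integer_)
  bump <- function(stage, tbl) {
    trace <<- bind_rows(trace, tibble(
      stage = stage,
      n_variants = length(unique(tbl$variant_id)),
      n_candidates = if ("site_type" %in% names(tbl)) nrow(tbl)
      else NA_integer_))
  }
  models <- representative_models(db, genes = panel)

  # stage 1: gene body -- pair each variant with every representative
  # transcript whose span contains it (a variant inside two genes yields
  # independent candidates per gene)
  paired <- list()
  for (tm in models) {
    hit <- variants$contig == tm$contig &
      variants$pos >= min(tm$exons$start) - 0L &
      variants$pos <= max(tm$exons$end)
    if (any(hit)) {
      paired[[tm$transcript_id]] <- variants[hit, ] |>
        classify_variant_region(tm, intron_window = th$intron_window) |>
        mutate(transcript_id = tm$transcript_id)
    }
  }
  inside <- if (length(paired)) bind_rows(paired) else
    mutate(variants[0, ], region = character(),
           distance_to_boundary = integer(), flank_exon_index = integer(),
           transcript_id = character())
  bump("gene_body", inside)

  # stage 2: positional filter
  near <- filter(inside, region %in% c("exonic", "intronic_near"))
  bump("region", near)

  # stage 3: dinucleotide creation
  cands <- list()
  for (id in unique(near$transcript_id)) {
    tm <- models[[id]]
    sub <- near[near$transcript_id == id, ]
    got <- scan_dinucleotide_creation(
      select(sub, -transcript_id), genome, tm)
    if (nrow(got)) cands[[id]] <- got
  }
  cands <- if (length(cands)) bind_rows(cands) else {
    dplyr::bind_cols(
      near[0, ] |> select(-transcript_id),
      tibble(transcript_id = character(), gene_id = character(),
             gene_symbol = character(), site_type = character(),
             site_strand = character(), dinuc_start = integer(),
             dinuc_end = integer(), mutated_base_index = integer()))
  }
  bump("dinucleotide_creation", cands)

  # stage 4: splice-site strength
  if (nrow(cands)) {
    cands <- extract_strength_window(cands, genome)
    cands$strength_score <- vapply(seq_len(nrow(cands)), function(i) {
      score_strength(cands$strength_window[i], cands$site_type[i],
                     strength_backend)
    }, numeric(1))
  } else {
    cands$strength_window <- character(0)
    cands$strength_score <- numeric(0)
  }
  strong <- filter(cands, strength_score >= th$min_strength)
  bump("strength", strong)

  # stage 5: allele frequency (unknown AF passes, tallied)
  n_unknown_af <- sum(is.na(strong$af[!duplicated(strong$variant_id)]))
  rare <- filter(strong, is.na(af) | af <= th$max_af)
  bump("allele_frequency", rare)
  if (n_unknown_af > 0L) {
    warn(sprintf("%d variant(s) with unknown allele frequency passed the AF filter",
                 n_unknown_af))
  }

  # stage 6: splice-gain delta score
  final <- if (nrow(rare)) {
    rare |> read_delta_score() |> filter(delta_score >= th$min_delta)
  } else {
    mutate(rare, delta_score = numeric(0))
  }
  bump("delta_score", final)

  structure(
    final,
    trace = trace,
    thresholds = th,
    n_unknown_af = n_unknown_af,
    strength_backend = class(strength_backend)[1],
    class = c("scm_set", class(tibble())))
}

#' Retrieve the per-stage filter trace of a cascade run
#'
#' @param x An `scm_set` from [run_filter_cascade()].
#' @return Tibble with `stage`, `n_variants` (distinct SNVs surviving) and
#'   `n_candidates` (variant x transcript x site rows, where defined).
#' @export
filter_trace <- function(x) {
  attr(x, "trace")
}
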