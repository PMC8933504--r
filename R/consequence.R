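# From a created splice-site dinucleotide to the altered transcript and its
# functional consequence: novel-junction geometry, transcript reassembly,
# premature-termination-codon and NMD calls, and protein-interval mapping.

# strand-oriented "is a after b in transcription direction"
tx_after <- function(strand, a, b) if (strand == "+") a > b else a < b

#' Derive the novel junction implied by a created splice site
#'
#' A created donor GT ends its exon immediately before the GT; a created
#' acceptor AG begins its exon immediately after the AG. The offset is the
#' distance (nt) between the novel and the annotated boundary in
#' transcription orientation; the event is an exon `extension` when the
#' novel boundary lies on the intronic side of the annotated one and a
#' `shrinkage` when it lies on the exonic side.
#'
#' @param candidates Candidates tibble (see [scan_dinucleotide_creation()]
#'   or an `scm_set`).
#' @param db A `transcript_db`.
#' @return The candidates tibble with junction columns:
#'   `affected_exon_index` (transcription order), `event`, `offset_nt`,
#'   `novel_boundary`, `annotated_boundary` (genomic positions of the new
#'   and old exon edge), and the genomic intervals of the novel and the
#'   annotated intron (`novel_intron_start`/`_end`,
#'   `annotated_intron_start`/`_end`).
#' @export
derive_novel_junction <- function(candidates, db) {
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    r <- candidates[i, ]
    tm <- transcript_model(db, r$transcript_id)
    j <- derive_one_junction(r, tm)
    dplyr::bind_cols(r, j)
  })
  if (length(rows)) bind_rows(rows) else {
    dplyr::bind_cols(candidates, tibble(
      affected_exon_index = integer(), event = character(),
      offset_nt = integer(), novel_boundary = integer(),
      annotated_boundary = integer(), novel_intron_start = integer(),
      novel_intron_end = integer(), annotated_intron_start = integer(),
      annotated_intron_end = integer()))
  }
}

derive_one_junction <- function(r, tm) {
  dir <- if (tm$strand == "+") 1L else -1L
  plus <- tm$strand == "+"
  d_first <- if (plus) r$dinuc_start else r$dinuc_end  # 5'-most dinuc base
  d_last <- if (plus) r$dinuc_end else r$dinuc_start
  intr <- introns(tm)
  p <- r$pos
  ex_hit <- which(p >= tm$exons$start & p <= tm$exons$end)
  in_hit <- if (nrow(intr)) which(p >= intr$start & p <= intr$end) else
    integer(0)

  if (r$site_type == "donor") {
    novel <- d_first - dir                     # last base of the novel exon
    if (length(ex_hit)) {                      # shrinkage within exon ex_hit
      ex <- ex_hit[1]
      if (ex == nrow(tm$exons)) {
        abort("created donor in the terminal exon has no downstream acceptor")
      }
      rel_intron <- ex
    } else if (length(in_hit)) {               # extension into intron in_hit
      ex <- in_hit[1]
      rel_intron <- in_hit[1]
    } else abort("candidate position is neither exonic nor intronic")
    annotated <- if (plus) tm$exons$end[ex] else tm$exons$start[ex]
    if (novel == annotated) abort("not novel: boundary equals annotated")
    event <- if (tx_after(tm$strand, novel, annotated)) "extension" else
      "shrinkage"
    if (event == "extension" &&
          tx_after(tm$strand, d_last,
                   if (plus) intr$end[rel_intron] else intr$start[rel_intron])) {
      abort("candidate beyond neighboring exon")
    }
    # novel intron keeps the annotated acceptor of the relevant intron
    ni <- if (plus) c(d_first, intr$end[rel_intron]) else
      c(intr$start[rel_intron], d_first)
    ai <- c(intr$start[rel_intron], intr$end[rel_intron])
  } else {
    novel <- d_last + dir                      # first base of the novel exon
    if (length(ex_hit)) {
      ex <- ex_hit[1]
      if (ex == 1L) {
        abort("created acceptor in the first exon has no upstream donor")
      }
      rel_intron <- ex - 1L
    } else if (length(in_hit)) {
      ex <- in_hit[1] + 1L
      rel_intron <- in_hit[1]
    } else abort("candidate position is neither exonic nor intronic")
    annotated <- if (plus) tm$exons$start[ex] else tm$exons$end[ex]
    if (novel == annotated) abort("not novel: boundary equals annotated")
    event <- if (tx_after(tm$strand, annotated, novel)) "extension" else
      "shrinkage"
    # novel intron keeps the annotated donor of the relevant intron
    ni <- if (plus) c(intr$start[rel_intron], d_last) else
      c(d_last, intr$end[rel_intron])
    ai <- c(intr$start[rel_intron], intr$end[rel_intron])
  }
  tibble(
    affected_exon_index = ex,
    event = event,
    offset_nt = abs(novel - annotated),
    novel_boundary = novel,
    annotated_boundary = annotated,
    novel_intron_start = ni[1], novel_intron_end = ni[2],
    annotated_intron_start = ai[1], annotated_intron_end = ai[2])
}

#' Rebuild the mature transcript implied by a novel junction
#'
#' Resizes the affected exon to the novel boundary, substitutes the ALT
#' allele(s) into the genome, splices the exons and re-threads the CDS from
#' the annotated start codon. The exon count is unchanged.
#'
#' @param junction One row of a junction tibble (see
#'   [derive_novel_junction()]).
#' @param db A `transcript_db`.
#' @param genome A `DNAStringSet`.
#' @param variants Variants to apply to the genome before assembly
#'   (typically the single causal SNV); NULL for none.
#' @return A `rebuilt_transcript`: list with `model_alt` (altered
#'   `transcript_model`), `model` (original), `mrna` (altered mature mRNA,
#'   5'->3'), `cds_start_alt` and `annotated_stop_alt` (altered-transcript
#'   coordinates of the annotated start codon's first base and stop codon's
#'   last base; NA when the alteration removed them), and the junction row.
#' @export
rebuild_transcript <- function(junction, db, genome, variants = NULL) {
  stopifnot(nrow(junction) == 1L)
  tm <- transcript_model(db, junction$transcript_id)
  mut <- if (!is.null(variants) && nrow(variants) > 0L) {
    apply_variants_to_reference(genome, variants)
  } else genome
  plus <- tm$strand == "+"
  ex <- junction$affected_exon_index
  tm2 <- tm
  if (junction$site_type == "donor") {
    if (plus) tm2$exons$end[ex] <- junction$novel_boundary
    else tm2$exons$start[ex] <- junction$novel_boundary
  } else {
    if (plus) tm2$exons$start[ex] <- junction$novel_boundary
    else tm2$exons$end[ex] <- junction$novel_boundary
  }
  if (tm2$exons$start[ex] > tm2$exons$end[ex]) {
    abort("exon eliminated: resized exon length <= 0")
  }
  mrna <- transcript_sequence(tm2, mut)
  cds <- cds_tx_range(tm)
  cds_start_alt <- NA_integer_
  stop_alt <- NA_integer_
  if (!is.null(cds)) {
    g_start <- tx_to_genomic(tm, cds[1])
    g_stop <- tx_to_genomic(tm, cds[2])
    cds_start_alt <- genomic_to_tx(tm2, g_start)
    stop_alt <- genomic_to_tx(tm2, g_stop)
  }
  structure(list(model_alt = tm2, model = tm, mrna = mrna,
                 cds_start_alt = cds_start_alt,
                 annotated_stop_alt = stop_alt,
                 junction = junction, coding = !is.null(cds),
                 cds_tx = cds),
            class = "rebuilt_transcript")
}

# affected interval of the alteration in ORIGINAL transcript coordinates:
# shrinkage -> removed interval c(r1, r2); extension -> insertion point a
# (insertion falls between a and a+1 for donors, between a-1 and a for
# acceptors; normalised here to "after position a")
alteration_original_coords <- function(rb) {
  j <- rb$junction
  tm <- rb$model
  if (j$event == "shrinkage") {
    a <- genomic_to_tx(tm, j$annotated_boundary)
    n <- genomic_to_tx(tm, j$novel_boundary)
    if (j$site_type == "donor") c(n + 1L, a) else c(a, n - 1L)
  } else {
    a <- genomic_to_tx(tm, j$annotated_boundary)
    if (j$site_type == "donor") c(a, a) else c(a - 1L, a - 1L)
  }
}

#' Classify premature termination arising from a novel junction
#'
#' Translates the rebuilt transcript from the annotated start codon and scans
#' for the first stop. A stop ending earlier than the annotated stop is a
#' premature termination codon (PTC). Categories follow a four-way
#' partition: `PTC_in_novel_exon` when the stop codon lies inside the
#' altered exon, `PTC_frameshift` for other PTCs, `no_PTC` when translation
#' reaches the annotated stop, and `not_in_CDS` when the alteration does not
#' touch the coding sequence. Alterations that remove the annotated start
#' (or stop) codon are reported via a `status` of `start_lost`/`stop_lost`
#' with `category = NA` -- outside the four-way partition.
#'
#' @param rb A `rebuilt_transcript` (see [rebuild_transcript()]).
#' @return One-row tibble: `category`, `status`, `frame_preserved`,
#'   `aa_deleted`, `aa_inserted`, `ptc_tx_pos` (altered-transcript
#'   coordinate of the stop codon's first base, NA if none),
#'   `nmd_predicted`.
#' @export
classify_ptc <- function(rb) {
  stopifnot(inherits(rb, "rebuilt_transcript"))
  j <- rb$junction
  out <- tibble(category = NA_character_, status = "ok",
                frame_preserved = j$offset_nt %% 3L == 0L,
                aa_deleted = 0L, aa_inserted = 0L,
                ptc_tx_pos = NA_integer_, nmd_predicted = FALSE)
  if (!rb$coding) {
    out$category <- "not_in_CDS"
    return(out)
  }
  cds <- rb$cds_tx
  alt_iv <- alteration_original_coords(rb)
  if (j$event == "shrinkage") {
    if (alt_iv[2] < cds[1] || alt_iv[1] > cds[2]) {
      out$category <- "not_in_CDS"
      return(out)
    }
    if (alt_iv[1] <= cds[1] + 2L && alt_iv[2] >= cds[1]) {
      out$status <- "start_lost"
      return(out)
    }
    if (alt_iv[2] >= cds[2] - 2L && alt_iv[1] <= cds[2]) {
      out$status <- "stop_lost"
      return(out)
    }
  } else {
    # insertion after original position alt_iv[1]
    if (alt_iv[1] < cds[1] || alt_iv[1] >= cds[2]) {
      out$category <- "not_in_CDS"
      return(out)
    }
  }
  if (is.na(rb$cds_start_alt)) {
    out$status <- "start_lost"
    return(out)
  }
  aa <- translate_frame(substr(rb$mrna, rb$cds_start_alt, nchar(rb$mrna)))
  stop_codon <- regexpr("*", aa, fixed = TRUE)[1]
  ptc_first <- if (stop_codon > 0L) {
    rb$cds_start_alt + 3L * (stop_codon - 1L)
  } else NA_integer_
  stop_last <- if (!is.na(ptc_first)) ptc_first + 2L else NA_integer_
  is_ptc <- !is.na(stop_last) && !is.na(rb$annotated_stop_alt) &&
    stop_last < rb$annotated_stop_alt
  if (is_ptc) {
    ex <- j$affected_exon_index
    lens <- exon_lengths(rb$model_alt)
    ex_start <- sum(lens[seq_len(ex - 1L)]) + 1L
    ex_end <- ex_start + lens[ex] - 1L
    in_novel <- ptc_first <= ex_end && stop_last >= ex_start
    out$category <- if (in_novel) "PTC_in_novel_exon" else "PTC_frameshift"
    out$ptc_tx_pos <- ptc_first
    out$nmd_predicted <- predict_nmd(ptc_first, rb$model_alt)
  } else {
    out$category <- "no_PTC"
    if (out$frame_preserved) {
      if (j$event == "shrinkage") out$aa_deleted <- j$offset_nt %/% 3L
      else out$aa_inserted <- j$offset_nt %/% 3L
    }
  }
  out
}

#' Predict nonsense-mediated decay by the 50-nt last-junction rule
#'
#' A PTC is predicted to trigger NMD when its stop codon starts at least
#' 50 nt upstream of the final exon-exon junction of the altered transcript.
#' PTCs in the last exon (or within 50 nt of the last junction), and any PTC
#' in a single-exon transcript, do not trigger NMD under this rule.
#'
#' @param ptc_tx_pos Transcript coordinate of the stop codon's first base in
#'   the altered transcript.
#' @param tm_alt The altered `transcript_model`.
#' @return Logical flag.
#' @export
predict_nmd <- function(ptc_tx_pos, tm_alt) {
  lens <- exon_lengths(tm_alt)
  if (length(lens) < 2L || is.na(ptc_tx_pos)) return(FALSE)
  last_junction <- sum(lens) - lens[length(lens)]
  (last_junction - ptc_tx_pos) >= 50L
}

#' Map an alteration to the protein amino-acid interval it affects
#'
#' Frame-preserving events yield the deleted (shrinkage) or inserted
#' (extension) amino-acid interval, 1-based on the relevant protein; PTC
#' events yield the interval from the first altered residue to the PTC.
#'
#' @param rb A `rebuilt_transcript`.
#' @param call The one-row consequence tibble from [classify_ptc()].
#' @return One-row tibble `aa_start`, `aa_end`.
#' @export
map_alteration_to_protein <- function(rb, call) {
  if (is.na(call$category) || call$category == "not_in_CDS") {
    abort("alteration does not touch the coding sequence")
  }
  j <- rb$junction
  cds <- rb$cds_tx
  alt_iv <- alteration_original_coords(rb)
  if (call$category == "no_PTC") {
    if (j$event == "shrinkage") {
      a <- max(alt_iv[1], cds[1]) - cds[1] + 1L
      b <- min(alt_iv[2], cds[2]) - cds[1] + 1L
      return(tibble(aa_start = (a + 2L) %/% 3L, aa_end = (b + 2L) %/% 3L))
    }
    c_ins <- alt_iv[1] - cds[1] + 1L     # retained CDS bases before insertion
    aa_start <- c_ins %/% 3L + 1L
    n_aa <- j$offset_nt %/% 3L + as.integer(c_ins %% 3L != 0L)
    return(tibble(aa_start = aa_start, aa_end = aa_start + n_aa - 1L))
  }
  # PTC cases: first altered residue .. PTC residue (altered protein)
  first_cds <- if (j$event == "shrinkage") {
    max(alt_iv[1], cds[1]) - cds[1] + 1L
  } else {
    alt_iv[1] - cds[1] + 2L
  }
  aa_start <- (first_cds + 2L) %/% 3L
  ptc_aa <- (call$ptc_tx_pos - rb$cds_start_alt) %/% 3L + 1L
  tibble(aa_start = aa_start, aa_end = ptc_aa)
}

#' End-to-end consequence calls for a set of accepted candidates
#'
#' Convenience wrapper: derives the novel junction, rebuilds the transcript
#' (applying each candidate's own SNV), classifies the PTC/NMD consequence
#' and maps the protein interval, one row per candidate.
#'
#' @param scms An `scm_set` or candidates tibble with junction columns
#'   absent (they are derived here).
#' @param db A `transcript_db`.
#' @param genome A `DNAStringSet`.
#' @param domains Optional domain annotation tibble (see
#'   [read_domain_table()]); enables `disrupted_domains` and
#'   [pathogenic_potential()] flags.
#' @return Tibble: candidate + junction columns + consequence columns
#'   (`category`, `status`, `frame_preserved`, `aa_deleted`, `aa_inserted`,
#'   `ptc_tx_pos`, `nmd_predicted`, `aa_start`, `aa_end`,
#'   `disrupted_domains` (list-column), `pathogenic`).
#' @export
call_consequences <- function(scms, db, genome, domains = NULL) {
  jx <- derive_novel_junction(scms, db)
  rows <- lapply(seq_len(nrow(jx)), function(i) {
    r <- jx[i, ]
    rb <- rebuild_transcript(r, db, genome,
                             variants = r[, c("contig", "pos", "ref", "alt")])
    call <- classify_ptc(rb)
    aa <- if (!is.na(call$category) && call$category != "not_in_CDS") {
      map_alteration_to_protein(rb, call)
    } else tibble(aa_start = NA_integer_, aa_end = NA_integer_)
    hit <- if (!is.null(domains) && !is.na(aa$aa_start)) {
      domain_overlap(aa$aa_start, aa$aa_end,
                     domains[domains$protein_id %in%
                               c(r$transcript_id, r$gene_id, r$gene_symbol), ])
    } else character(0)
    dplyr::bind_cols(r, call, aa) |>
      mutate(disrupted_domains = list(hit))
  })
  out <- bind_rows(rows)
  if (nrow(out)) {
    out$pathogenic <- pathogenic_potential(out)
  } else {
    out$pathogenic <- logical(0)
  }
  out
}
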