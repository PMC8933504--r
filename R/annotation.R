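#' Read gene models from a GENCODE-dialect GTF
#'
#' Parses `gene`/`transcript`/`exon`/`CDS` features via
#' [rtracklayer::import()] and assembles a transcript database: a list with a
#' per-transcript summary table, an exon table and a CDS-segment table, all
#' 1-based inclusive in genomic coordinates. Exon rank is stored in
#' transcription order (rank 1 is the 5'-most exon of the mature transcript).
#'
#' @param path Path to a GTF file with `gene_id`, `transcript_id` and
#'   (optionally) `gene_name` attributes.
#' @param genome Optional genome (`DNAStringSet`); when supplied together with
#'   `strict = TRUE`, every annotated intron is asserted to be canonical
#'   (starts GT, ends AG, strand-resolved) and at least 4 nt long.
#' @param strict Assert canonical introns (requires `genome`); default FALSE
#'   (lenient parse mode).
#' @return An object of class `transcript_db`: list with tibbles
#'   `transcripts` (`transcript_id`, `gene_id`, `gene_symbol`, `contig`,
#'   `strand`, `tx_start`, `tx_end`, `exonic_length`, `n_exons`, `coding`,
#'   `representative`), `exons` (`transcript_id`, `exon_rank`, `start`,
#'   `end`) and `cds` (`transcript_id`, `start`, `end`).
#' @export
read_gtf <- function(path, genome = NULL, strict = FALSE) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  tbl <- tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    gene_id = as.character(md$gene_id),
    transcript_id = if ("transcript_id" %in% names(md)) {
      as.character(md$transcript_id)
    } else NA_character_,
    gene_symbol = if ("gene_name" %in% names(md)) {
      as.character(md$gene_name)
    } else as.character(md$gene_id)
  )
  build_transcript_db(tbl, genome = genome, strict = strict)
}

build_transcript_db <- function(tbl, genome = NULL, strict = FALSE) {
  ex <- tbl |>
    filter(.data$type == "exon") |>
    arrange(transcript_id, start) |>
    group_by(transcript_id) |>
    mutate(exon_rank = if (dplyr::first(.data$strand) == "-") {
      rev(row_number())
    } else row_number()) |>
    ungroup() |>
    arrange(transcript_id, exon_rank) |>
    select(transcript_id, exon_rank, start, end)

  cds <- tbl |>
    filter(.data$type == "CDS") |>
    select(transcript_id, start, end) |>
    arrange(transcript_id, start)

  tx <- tbl |>
    filter(.data$type == "exon") |>
    group_by(transcript_id) |>
    summarise(
      gene_id = dplyr::first(gene_id),
      gene_symbol = dplyr::first(gene_symbol),
      contig = dplyr::first(contig),
      strand = dplyr::first(strand),
      tx_start = min(start),
      tx_end = max(end),
      exonic_length = sum(end - start + 1L),
      n_exons = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(
      coding = transcript_id %in% cds$transcript_id,
      representative = FALSE
    )

  db <- structure(list(transcripts = tx, exons = ex, cds = cds),
                  class = "transcript_db")
  db <- select_representative_transcripts(db)
  if (strict) {
    if (is.null(genome)) abort("strict = TRUE requires a genome")
    bad <- check_canonical_introns(db, genome)
    if (nrow(bad) > 0L) {
      abort(sprintf(
        "non-canonical or undersized intron in transcript %s (intron %d: %s..%s)",
        bad$transcript_id[1], bad$intron_rank[1],
        bad$donor_dinuc[1], bad$acceptor_dinuc[1]))
    }
  }
  db
}

#' @export
print.transcript_db <- function(x, ...) {
  cat(sprintf("<transcript_db> %d transcripts, %d genes, %d exons\n",
              nrow(x$transcripts), length(unique(x$transcripts$gene_id)),
              nrow(x$exons)))
  invisible(x)
}

#' Mark the representative (longest) isoform of every gene
#'
#' The representative isoform is the one with the greatest summed exon length
#' (mature-transcript length, not genomic span). Ties are broken by
#' lexicographically smallest `transcript_id`, so the choice is deterministic.
#'
#' @param db A `transcript_db`.
#' @return The database with the `representative` flag set on exactly one
#'   transcript per gene.
#' @export
select_representative_transcripts <- function(db) {
  reps <- db$transcripts |>
    arrange(gene_id, dplyr::desc(exonic_length), transcript_id) |>
    group_by(gene_id) |>
    slice(1L) |>
    ungroup() |>
    pull(transcript_id)
  db$transcripts$representative <- db$transcripts$transcript_id %in% reps
  db
}

#' Pick the representative isoform from a set of transcript models
#'
#' Single-gene form of [select_representative_transcripts()]: given the
#' isoforms of one gene, returns the one with the greatest summed exon length
#' (lexicographically smallest `transcript_id` on ties).
#'
#' @param models A list of `transcript_model` objects for one gene.
#' @return The chosen `transcript_model`, with `representative = TRUE`.
#' @export
select_representative_transcript <- function(models) {
  if (length(models) == 0L) abort("no transcripts")
  len <- map_int(models, function(m) sum(m$exons$end - m$exons$start + 1L))
  ids <- map_chr(models, "transcript_id")
  best <- order(-len, ids)[1]
  m <- models[[best]]
  m$representative <- TRUE
  m
}

#' Materialise one transcript model from a database
#'
#' @param db A `transcript_db`.
#' @param transcript_id Transcript identifier.
#' @return A `transcript_model`: list with `transcript_id`, `gene_id`,
#'   `gene_symbol`, `contig`, `strand`, `exons` (tibble `start`, `end` in
#'   transcription order), `cds` (genomic CDS segments or NULL) and
#'   `representative`.
#' @export
transcript_model <- function(db, transcript_id) {
  row <- db$transcripts[db$transcripts$transcript_id == transcript_id, ]
  if (nrow(row) != 1L) abort(paste0("unknown transcript: ", transcript_id))
  ex <- db$exons[db$exons$transcript_id == transcript_id, c("start", "end")]
  cds <- db$cds[db$cds$transcript_id == transcript_id, c("start", "end")]
  structure(list(
    transcript_id = transcript_id,
    gene_id = row$gene_id, gene_symbol = row$gene_symbol,
    contig = row$contig, strand = row$strand,
    exons = ex, cds = if (nrow(cds)) cds else NULL,
    representative = row$representative
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s %d exon(s)%s\n",
              x$transcript_id, x$gene_symbol, x$contig, x$strand,
              nrow(x$exons), if (is.null(x$cds)) " non-coding" else ""))
  invisible(x)
}

representative_models <- function(db, genes = NULL) {
  tx <- db$transcripts[db$transcripts$representative, ]
  if (!is.null(genes)) {
    tx <- tx[tx$gene_id %in% genes | tx$gene_symbol %in% genes, ]
  }
  setNames(lapply(tx$transcript_id, transcript_model, db = db),
           tx$transcript_id)
}

# ---- transcript-coordinate arithmetic ------------------------------------

exon_lengths <- function(tm) tm$exons$end - tm$exons$start + 1L

tx_length <- function(tm) sum(exon_lengths(tm))

#' Introns of a transcript model, in transcription order
#'
#' @param tm A `transcript_model`.
#' @return Tibble with `intron_rank`, `start`, `end` (genomic, 1-based
#'   inclusive). Empty for single-exon transcripts.
#' @export
introns <- function(tm) {
  n <- nrow(tm$exons)
  if (n < 2L) {
    return(tibble(intron_rank = integer(), start = integer(), end = integer()))
  }
  if (tm$strand == "+") {
    tibble(intron_rank = seq_len(n - 1L),
           start = tm$exons$end[-n] + 1L,
           end = tm$exons$start[-1] - 1L)
  } else {
    # transcription order runs against genomic coordinates
    tibble(intron_rank = seq_len(n - 1L),
           start = tm$exons$end[-1] + 1L,
           end = tm$exons$start[-n] - 1L)
  }
}

# genomic position -> transcript coordinate (NA if intronic / outside)
genomic_to_tx <- function(tm, gpos) {
  lens <- exon_lengths(tm)
  cum <- cumsum(c(0L, lens))[seq_along(lens)]
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_len(nrow(tm$exons))) {
    s <- tm$exons$start[i]; e <- tm$exons$end[i]
    hit <- which(gpos >= s & gpos <= e)
    if (length(hit)) {
      out[hit] <- if (tm$strand == "+") {
        cum[i] + (gpos[hit] - s + 1L)
      } else {
        cum[i] + (e - gpos[hit] + 1L)
      }
    }
  }
  out
}

# transcript coordinate -> genomic position
tx_to_genomic <- function(tm, tpos) {
  lens <- exon_lengths(tm)
  cum <- cumsum(c(0L, lens))
  out <- rep(NA_integer_, length(tpos))
  for (i in seq_along(lens)) {
    hit <- which(tpos > cum[i] & tpos <= cum[i + 1L])
    if (length(hit)) {
      off <- tpos[hit] - cum[i]
      out[hit] <- if (tm$strand == "+") {
        tm$exons$start[i] + off - 1L
      } else {
        tm$exons$end[i] - off + 1L
      }
    }
  }
  out
}

# CDS span in transcript coordinates, c(start, end), or NULL for non-coding
cds_tx_range <- function(tm) {
  if (is.null(tm$cds)) return(NULL)
  pos <- c(genomic_to_tx(tm, tm$cds$start), genomic_to_tx(tm, tm$cds$end))
  pos <- pos[!is.na(pos)]
  if (length(pos) == 0L) return(NULL)
  c(min(pos), max(pos))
}

# mature mRNA sequence (5'->3' on the transcript strand)
transcript_sequence <- function(tm, genome) {
  paste(vapply(seq_len(nrow(tm$exons)), function(i) {
    get_seq(genome, tm$contig, tm$exons$start[i], tm$exons$end[i], tm$strand)
  }, character(1)), collapse = "")
}

# annotated splice dinucleotide intervals (genomic), one row per site
splice_dinucleotides <- function(tm) {
  intr <- introns(tm)
  if (nrow(intr) == 0L) {
    return(tibble(site_type = character(), start = integer(), end = integer()))
  }
  if (tm$strand == "+") {
    bind_rows(
      tibble(site_type = "donor", start = intr$start, end = intr$start + 1L),
      tibble(site_type = "acceptor", start = intr$end - 1L, end = intr$end)
    )
  } else {
    bind_rows(
      tibble(site_type = "donor", start = intr$end - 1L, end = intr$end),
      tibble(site_type = "acceptor", start = intr$start, end = intr$start + 1L)
    )
  }
}

#' Check that every annotated intron is canonical
#'
#' Scans all introns of all transcripts and reports those whose
#' strand-resolved first two bases are not `GT`, whose last two are not `AG`,
#' or whose length is below 4 nt (no room for GT...AG).
#'
#' @param db A `transcript_db`.
#' @param genome A `DNAStringSet`.
#' @return Tibble of violations (empty when all introns are canonical).
#' @export
check_canonical_introns <- function(db, genome) {
  out <- list()
  for (id in db$transcripts$transcript_id) {
    tm <- transcript_model(db, id)
    intr <- introns(tm)
    if (nrow(intr) == 0L) next
    for (i in seq_len(nrow(intr))) {
      len <- intr$end[i] - intr$start[i] + 1L
      if (len < 4L) {
        out[[length(out) + 1L]] <- tibble(
          transcript_id = id, intron_rank = i,
          donor_dinuc = NA_character_, acceptor_dinuc = NA_character_,
          reason = "length < 4")
        next
      }
      s <- get_seq(genome, tm$contig, intr$start[i], intr$end[i], tm$strand)
      d <- substr(s, 1L, 2L)
      a <- substr(s, len - 1L, len)
      if (d != "GT" || a != "AG") {
        out[[length(out) + 1L]] <- tibble(
          transcript_id = id, intron_rank = i,
          donor_dinuc = d, acceptor_dinuc = a, reason = "non-canonical")
      }
    }
  }
  if (length(out)) bind_rows(out) else
    tibble(transcript_id = character(), intron_rank = integer(),
           donor_dinuc = character(), acceptor_dinuc = character(),
           reason = character())
}

#' Write a transcript database to GTF
#'
#' Emits `gene`, `transcript`, `exon` and `CDS` features with GENCODE-dialect
#' attributes (`gene_id`, `transcript_id`, `gene_name`), via
#' [rtracklayer::export()]. Round-trips exactly through [read_gtf()].
#'
#' @param db A `transcript_db`.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(db, path) {
  tx <- db$transcripts
  ex <- db$exons |> left_join(tx, by = "transcript_id")
  cds <- db$cds |> left_join(tx, by = "transcript_id")
  gene <- tx |>
    group_by(gene_id) |>
    summarise(gene_symbol = dplyr::first(gene_symbol),
              contig = dplyr::first(contig), strand = dplyr::first(strand),
              start = min(.data$tx_start), end = max(.data$tx_end),
              .groups = "drop")
  # CDS phase: bases of the previous segments modulo 3, transcription order
  cds <- cds |>
    arrange(transcript_id, start) |>
    group_by(transcript_id) |>
    mutate(.ord = if (dplyr::first(.data$strand) == "-") {
      dplyr::n() - row_number() + 1L
    } else row_number()) |>
    arrange(.data$.ord, .by_group = TRUE) |>
    mutate(phase = (3L - cumsum(dplyr::lag(end - start + 1L, default = 0L))
                    %% 3L) %% 3L) |>
    ungroup() |>
    select(-".ord")
  rows <- bind_rows(
    gene |> mutate(type = "gene", transcript_id = NA_character_,
                   phase = NA_integer_),
    tx |> mutate(type = "transcript", start = .data$tx_start,
                 end = .data$tx_end, phase = NA_integer_) |>
      select(gene_id, gene_symbol, contig, strand, start, end,
             type, transcript_id, phase),
    ex |> mutate(type = "exon", phase = NA_integer_) |>
      select(gene_id, gene_symbol, contig, strand, start, end,
             type, transcript_id, phase),
    cds |> mutate(type = "CDS") |>
      select(gene_id, gene_symbol, contig, strand, start, end,
             type, transcript_id, phase)
  ) |>
    arrange(contig, start, end)
  gr <- GenomicRanges::GRanges(
    seqnames = rows$contig,
    ranges = IRanges::IRanges(rows$start, rows$end),
    strand = rows$strand,
    type = rows$type,
    phase = rows$phase,
    gene_id = rows$gene_id,
    transcript_id = rows$transcript_id,
    gene_name = rows$gene_symbol
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
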