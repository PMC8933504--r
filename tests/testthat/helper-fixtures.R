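# Shared fixtures (memoised per test run) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

# the default study-scale fixture: 20 genes, 100 planted true calls,
# 400 planted negatives
shared_fixture <- function() {
  if (is.null(.fixture_cache$full)) {
    syn <- generate_genome(seed = 1)
    planted <- plant_scms(syn, seed = 1)
    scms <- run_filter_cascade(planted$variants, planted$genome, planted$db)
    .fixture_cache$full <- list(syn = syn, planted = planted, scms = scms)
  }
  .fixture_cache$full
}

shared_consequences <- function() {
  if (is.null(.fixture_cache$cons)) {
    fx <- shared_fixture()
    .fixture_cache$cons <- call_consequences(fx$scms, fx$planted$db,
                                             fx$planted$genome)
  }
  .fixture_cache$cons
}

small_plan <- function() {
  dplyr::bind_rows(
    tibble::tibble(class = "true", site_type = "donor", event = "extension",
                   offset = c(9L, 12L), target = "any"),
    tibble::tibble(class = "true", site_type = "acceptor",
                   event = "extension", offset = c(11L, 14L), target = "any"),
    tibble::tibble(class = "true", site_type = "acceptor",
                   event = "shrinkage", offset = c(51L, 20L),
                   target = c("clean", "any")),
    tibble::tibble(class = "true", site_type = "donor", event = "shrinkage",
                   offset = c(7L, 12L), target = "any"),
    tibble::tibble(class = "deep_intronic", site_type = "donor",
                   event = "extension", offset = NA_integer_,
                   target = "any")[rep(1, 2), ],
    tibble::tibble(class = "wrong_dinuc", site_type = NA_character_,
                   event = NA_character_, offset = NA_integer_,
                   target = "any")[rep(1, 2), ],
    tibble::tibble(class = "high_af", site_type = "donor",
                   event = "extension", offset = c(15L, 21L),
                   target = "any"),
    tibble::tibble(class = "low_delta", site_type = "acceptor",
                   event = "extension", offset = c(16L, 24L),
                   target = "any")
  )
}

small_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    syn <- generate_genome(n_genes = 6, seed = 11)
    planted <- plant_scms(syn, plan = small_plan(), seed = 11)
    .fixture_cache$small <- list(syn = syn, planted = planted)
  }
  .fixture_cache$small
}

# ---- toy gene construction ------------------------------------------------

# assemble a single-gene genome from transcription-oriented exon and intron
# strings; CDS runs from `u5 + 1` for `cds_len` bases of the mature mRNA
toy_gene <- function(exons, introns, strand = "+", u5, cds_len,
                     contig = "chrT") {
  stopifnot(length(introns) == length(exons) - 1L)
  pad <- strrep("CATCATGACCATTACGATCA", 10L)  # 200 nt flank
  body <- exons[1]
  for (i in seq_along(introns)) body <- paste0(body, introns[i],
                                               exons[i + 1L])
  tx_seq <- paste0(pad, body, pad)
  L <- nchar(tx_seq)
  loc_start <- integer(length(exons)); loc_end <- integer(length(exons))
  cursor <- 200L
  for (i in seq_along(exons)) {
    loc_start[i] <- cursor + 1L
    loc_end[i] <- cursor + nchar(exons[i])
    cursor <- loc_end[i] + if (i < length(exons)) nchar(introns[i]) else 0L
  }
  if (strand == "+") {
    seqs <- tx_seq; gstart <- loc_start; gend <- loc_end
  } else {
    seqs <- revcomp(tx_seq)
    gstart <- L - loc_end + 1L; gend <- L - loc_start + 1L
  }
  # CDS genomic segments
  mstart <- cumsum(c(1L, head(nchar(exons), -1L)))
  mend <- cumsum(nchar(exons))
  cds_lo <- u5 + 1L; cds_hi <- u5 + cds_len
  cds_rows <- list()
  for (i in seq_along(exons)) {
    a <- max(mstart[i], cds_lo); b <- min(mend[i], cds_hi)
    if (a > b) next
    la <- loc_start[i] + (a - mstart[i]); lb <- loc_start[i] + (b - mstart[i])
    cds_rows[[i]] <- if (strand == "+") {
      tibble::tibble(start = la, end = lb)
    } else {
      tibble::tibble(start = L - lb + 1L, end = L - la + 1L)
    }
  }
  cdsr <- dplyr::bind_rows(cds_rows)
  feat <- dplyr::bind_rows(
    tibble::tibble(contig = contig, start = gstart, end = gend,
                   strand = strand, type = "exon", gene_id = "TOYG",
                   transcript_id = "TOYT", gene_symbol = "TOY"),
    if (nrow(cdsr)) tibble::tibble(
      contig = contig, start = cdsr$start, end = cdsr$end, strand = strand,
      type = "CDS", gene_id = "TOYG", transcript_id = "TOYT",
      gene_symbol = "TOY"))
  genome <- Biostrings::DNAStringSet(setNames(seqs, contig))
  db <- splicegain:::build_transcript_db(feat)
  list(genome = genome, db = db, tm = transcript_model(db, "TOYT"),
       loc_start = loc_start, loc_end = loc_end, L = L, strand = strand,
       contig = contig)
}

ala <- function(n) strrep("GCT", n)  # stop-free filler codons

# canonical intron with designed acceptor tail (transcription orientation);
# `tail` replaces the final nchar(tail) bases and must end in AG
toy_intron <- function(len = 90L, tail = paste0(strrep("CT", 9L), "AG")) {
  stopifnot(endsWith(tail, "AG"), len >= nchar(tail) + 10L)
  paste0("GTAAGT", strrep("A", len - 6L - nchar(tail)), tail)
}

# variant tibble helper (single SNV)
toy_variant <- function(contig, pos, ref, alt, af = 1e-4, id = "var1",
                        delta = 0.95) {
  tibble::tibble(variant_id = id, contig = contig, pos = pos, ref = ref,
                 alt = alt, af = af,
                 info = sprintf("AF=%g;SpliceAI=.|TOYG|%.2f|0|%.2f|0|0|0|0|0",
                                af, delta, delta))
}

# transcription-oriented local position -> plus-strand genomic position
toy_local_to_genomic <- function(toy, el_start_loc, el_end_loc, k) {
  loc <- el_start_loc + k - 1L
  if (toy$strand == "+") loc else toy$L - loc + 1L
}

# ---- independent brute-force splice-translate-scan oracle -----------------

# literal string surgery without the package's transcript machinery:
# resize the affected exon on the raw contig string, splice, translate with
# seqinr, scan for the first stop, and classify with the shared category
# definition. Works in transcription-oriented local coordinates.
oracle_consequence <- function(contig_seq, loc_start, loc_end, strand, u5,
                               cds_len, site_type, event, offset,
                               affected_exon) {
  tx <- if (strand == "+") contig_seq else
    paste(rev(strsplit(chartr("ACGT", "TGCA", contig_seq), "")[[1]]),
          collapse = "")
  n_ex <- length(loc_start)
  s <- loc_start; e <- loc_end
  if (site_type == "donor") {
    if (event == "extension") e[affected_exon] <- e[affected_exon] + offset
    else e[affected_exon] <- e[affected_exon] - offset
  } else {
    if (event == "extension") s[affected_exon] <- s[affected_exon] - offset
    else s[affected_exon] <- s[affected_exon] + offset
  }
  pieces <- vapply(seq_len(n_ex), function(i) substr(tx, s[i], e[i]),
                   character(1))
  mrna <- paste(pieces, collapse = "")
  cds_seq <- substr(mrna, u5 + 1L, nchar(mrna))
  codons <- substring(cds_seq, seq(1L, nchar(cds_seq) - 2L, by = 3L),
                      seq(3L, nchar(cds_seq), by = 3L))
  aa <- seqinr::translate(unlist(strsplit(paste(codons, collapse = ""), "")))
  first_stop <- which(aa == "*")[1]
  shift <- if (event == "extension") offset else -offset
  anno_stop_last <- u5 + cds_len + shift
  ptc_first <- if (!is.na(first_stop)) u5 + 1L + 3L * (first_stop - 1L) else NA
  is_ptc <- !is.na(ptc_first) && (ptc_first + 2L) < anno_stop_last
  lens2 <- nchar(pieces)
  ex_lo <- sum(lens2[seq_len(affected_exon - 1L)]) + 1L
  ex_hi <- ex_lo + lens2[affected_exon] - 1L
  category <- if (!is_ptc) "no_PTC" else if (ptc_first <= ex_hi &&
                                               ptc_first + 2L >= ex_lo) {
    "PTC_in_novel_exon"
  } else "PTC_frameshift"
  list(category = category, ptc_first = if (is_ptc) ptc_first else NA,
       mrna = mrna)
}

# ---- strand-flip helpers for the symmetry invariant -----------------------

flip_world <- function(genome, db, variants) {
  lens <- setNames(Biostrings::width(genome), names(genome))
  tx <- db$transcripts
  ctg <- setNames(tx$contig, tx$transcript_id)
  flip_tbl <- function(tbl, type) {
    L <- unname(lens[ctg[tbl$transcript_id]])
    tibble::tibble(
      contig = unname(ctg[tbl$transcript_id]),
      start = L - tbl$end + 1L, end = L - tbl$start + 1L,
      strand = ifelse(tx$strand[match(tbl$transcript_id,
                                      tx$transcript_id)] == "+", "-", "+"),
      type = type,
      gene_id = tx$gene_id[match(tbl$transcript_id, tx$transcript_id)],
      transcript_id = tbl$transcript_id,
      gene_symbol = tx$gene_symbol[match(tbl$transcript_id,
                                         tx$transcript_id)])
  }
  feat <- dplyr::bind_rows(flip_tbl(db$exons, "exon"),
                           flip_tbl(db$cds, "CDS"))
  v <- variants
  v$pos <- unname(lens[v$contig]) - v$pos + 1L
  v$ref <- splicegain:::comp_base(v$ref)
  v$alt <- splicegain:::comp_base(v$alt)
  list(genome = Biostrings::reverseComplement(genome),
       db = splicegain:::build_transcript_db(feat), variants = v)
}

# brute-force oracle agreement over n random junction geometries; returns
# c(checked, mismatches)
ptc_oracle_agreement <- function(n = 500L, seed = 99L) {
  fx <- small_fixture()
  db <- fx$syn$db
  genome <- fx$syn$genome
  meta <- fx$syn$genes
  set.seed(seed)
  n_checked <- 0L
  mismatches <- 0L
  while (n_checked < n) {
    gm <- meta[sample.int(nrow(meta), 1L), ]
    tm <- transcript_model(db, gm$transcript_id)
    lens <- tm$exons$end - tm$exons$start + 1L
    intr <- introns(tm)
    site <- sample(c("donor", "acceptor"), 1L)
    event <- sample(c("extension", "shrinkage"), 1L)
    if (event == "extension") {
      i <- sample.int(nrow(intr), 1L)
      ilen <- intr$end[i] - intr$start[i] + 1L
      offset <- sample(3:min(50L, ilen - 30L), 1L)
      ex <- if (site == "donor") i else i + 1L
      # dinucleotide local position within the intron
      loc <- if (site == "donor") offset + 1L else ilen - offset - 1L
      g1 <- splicegain:::local_to_genomic(tm$strand, intr$start[i],
                                          intr$end[i], loc)
      g2 <- splicegain:::local_to_genomic(tm$strand, intr$start[i],
                                          intr$end[i], loc + 1L)
    } else {
      ex <- if (site == "donor") {
        sample(seq_len(gm$n_exons - 1L), 1L)
      } else {
        sample(2:gm$n_exons, 1L)
      }
      exlen <- lens[ex]
      max_off <- exlen - 12L
      if (site == "donor" && ex == 1L) max_off <- exlen - gm$u5 - 12L
      if (site == "acceptor" && ex == gm$n_exons) {
        max_off <- exlen - gm$u3 - 12L
      }
      if (max_off < 6L) next
      offset <- sample(6:max_off, 1L)
      loc <- if (site == "donor") exlen - offset + 1L else offset - 1L
      g1 <- splicegain:::exon_local_genomic(tm, ex, loc)
      g2 <- splicegain:::exon_local_genomic(tm, ex, loc + 1L)
    }
    cand <- tibble::tibble(
      variant_id = "probe", contig = gm$contig, pos = g1,
      ref = get_seq(genome, gm$contig, min(g1, g2), min(g1, g2)),
      alt = "N", transcript_id = gm$transcript_id,
      site_type = site, site_strand = tm$strand,
      dinuc_start = min(g1, g2), dinuc_end = max(g1, g2),
      mutated_base_index = 1L)
    jx <- tryCatch(derive_novel_junction(cand, db), error = function(e) NULL)
    if (is.null(jx)) next
    rb <- tryCatch(rebuild_transcript(jx, db, genome, variants = NULL),
                   error = function(e) NULL)
    if (is.null(rb)) next
    call <- classify_ptc(rb)
    if (!is.na(call$status) && call$status != "ok") next
    # transcription-oriented local exon coordinates for the oracle
    L <- gm$contig_len
    if (tm$strand == "+") {
      ls <- tm$exons$start; le <- tm$exons$end
    } else {
      ls <- L - tm$exons$end + 1L; le <- L - tm$exons$start + 1L
    }
    o <- oracle_consequence(
      as.character(genome[[gm$contig]]), ls, le, tm$strand,
      u5 = gm$u5, cds_len = 3L * gm$n_aa,
      site_type = site, event = jx$event, offset = jx$offset_nt,
      affected_exon = ex)
    expect_equal(jx$event, event)
    expect_equal(jx$offset_nt, offset)
    same_cat <- identical(call$category, o$category)
    same_ptc <- (is.na(call$ptc_tx_pos) && is.na(o$ptc_first)) ||
      (!is.na(call$ptc_tx_pos) && !is.na(o$ptc_first) &&
         call$ptc_tx_pos == o$ptc_first)
    if (!(same_cat && same_ptc)) mismatches <- mismatches + 1L
    n_checked <- n_checked + 1L
  }
  c(checked = n_checked, mismatches = mismatches)
}

# ---- worked case-study toy geometries -------------------------------------

# acceptor created 13 nt inside the intron: 11-nt exon extension
toy_acceptor_extension_11 <- function() {
  tail <- paste0("CTTCTTCTTCTT", "GG", "TTCTTCTTC", "AG")
  toy <- toy_gene(
    exons = c(paste0(strrep("C", 9), "ATG", ala(20)),
              ala(30),
              paste0(ala(20), "TAA", strrep("C", 12))),
    introns = c(toy_intron(120L), toy_intron(130L, tail = tail)),
    strand = "+", u5 = 9L, cds_len = 3L * (1L + 20L + 30L + 20L + 1L))
  pos <- toy$loc_start[3] - 13L  # intron offset -13, ref G
  list(toy = toy,
       variant = toy_variant(toy$contig, pos, "G", "A"))
}

# acceptor created 51 nt into a codon-aligned exon: in-frame 17-aa deletion
toy_acceptor_shrinkage_51 <- function() {
  exon2 <- paste0(ala(16), "TTG", ala(10))      # TTG puts T,G at 49..51
  toy <- toy_gene(
    exons = c(paste0(strrep("C", 9), "ATG", ala(20)),
              exon2,
              paste0(ala(20), "TAA", strrep("C", 12))),
    introns = c(toy_intron(120L), toy_intron(130L)),
    strand = "+", u5 = 9L, cds_len = 3L * (1L + 20L + 27L + 20L + 1L))
  pos <- toy$loc_start[2] + 49L  # exon position 50, ref T
  list(toy = toy, variant = toy_variant(toy$contig, pos, "T", "A"))
}

# acceptor created 35 nt into an exon: frameshifting shrinkage
toy_acceptor_shrinkage_35 <- function() {
  # exon2: 33 nt of alanine, then GG at 34..35, then more filler
  exon2 <- paste0(ala(11), "GG", ala(10))
  # exon3 carries a TAA that is in frame only after the -35 shift
  exon3 <- paste0("C", "GCTAAC", ala(8), "TAA", strrep("C", 12))
  toy <- toy_gene(
    exons = c(paste0(strrep("C", 9), "ATG", ala(11)), exon2, exon3),
    introns = c(toy_intron(120L), toy_intron(130L)),
    strand = "+", u5 = 9L,
    cds_len = 36L + 65L + 34L)
  pos <- toy$loc_start[2] + 33L  # exon position 34, ref G
  list(toy = toy, variant = toy_variant(toy$contig, pos, "G", "A"))
}

# donor created 42 nt into the intron: 41-nt extension with in-frame stop
toy_donor_extension_41 <- function() {
  intron1 <- paste0("GTAAGT", "TAA", strrep("C", 32), "AT",
                    strrep("A", 60), paste0(strrep("CT", 9L), "AG"))
  toy <- toy_gene(
    exons = c(paste0(strrep("C", 9), "ATG", ala(20)),
              ala(30),
              paste0(ala(20), "TAA", strrep("C", 12))),
    introns = c(intron1, toy_intron(130L)),
    strand = "+", u5 = 9L, cds_len = 3L * (1L + 20L + 30L + 20L + 1L))
  pos <- toy$loc_end[1] + 42L  # intron offset 42, ref A
  list(toy = toy, variant = toy_variant(toy$contig, pos, "A", "G"))
}

scan_one <- function(case) {
  got <- scan_dinucleotide_creation(case$variant, case$toy$genome,
                                    case$toy$tm)
  expect_equal(nrow(got), 1L)
  got
}
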