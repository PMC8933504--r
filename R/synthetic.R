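# Seeded synthetic fixtures: a multi-gene genome with canonical introns and
# complete CDSs, planted splice-creating SNVs (and negatives) with full
# ground truth, simulated junction-read evidence, and a family cohort.
#
# Every generator is deterministic for a fixed seed. Planted sites are
# written into the reference with consensus-like sequence context so that a
# self-trained PWM assigns them positive strength -- emulating the fact that
# real created splice sites that function resemble annotated ones.

DONOR_MOTIFS <- c("GTAAGT", "GTGAGT", "GTAAGA", "GTATGT")
DONOR_MOTIF_P <- c(0.6, 0.2, 0.1, 0.1)
STOP_FREE_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

rand_dna <- function(n, bases = c("A", "C", "G", "T"),
                     prob = NULL) {
  paste(sample(bases, n, replace = TRUE, prob = prob), collapse = "")
}

#' Generate a synthetic multi-gene genome with annotation
#'
#' Builds `n_genes` single-isoform protein-coding genes, one per contig, on
#' random strands: a complete CDS (ATG...stop, length a multiple of 3,
#' internally stop-free) split over 4-8 exons, canonical GT...AG introns
#' with a polypyrimidine tract upstream of each acceptor, and untranslated
#' leaders/trailers confined to the terminal exons. Deterministic for a
#' fixed seed.
#'
#' @param n_genes Number of genes (default 20).
#' @param exons_per_gene Integer range `c(min, max)` of exon counts
#'   (default 4-8).
#' @param intron_range Intron length range in nt (default 200-2000).
#' @param seed RNG seed.
#' @return A `synthetic_genome`: list with `genome` (`DNAStringSet`), `db`
#'   (`transcript_db`), `genes` (per-gene metadata tibble) and `seed`.
#' @export
generate_genome <- function(n_genes = 20L, exons_per_gene = c(4L, 8L),
                            intron_range = c(200L, 2000L), seed = 1L) {
  if (n_genes < 1L) abort("n_genes must be >= 1")
  withr::with_seed(seed, {
    contigs <- list()
    feat <- list()
    meta <- list()
    for (g in seq_len(n_genes)) {
      n_ex <- sample(seq(exons_per_gene[1], exons_per_gene[2]), 1L)
      strand <- sample(c("+", "-"), 1L)
      u5 <- sample(30:90, 1L)
      u3 <- sample(60:200, 1L)
      n_aa <- sample(160:400, 1L)
      # mature transcript must accommodate all exon minima
      min_len <- max(70L * n_ex + u5 + u3, 450L)
      n_aa <- as.integer(max(n_aa, ceiling((min_len - u5 - u3) / 3) + 2L))
      cds <- paste0("ATG",
                    paste(sample(STOP_FREE_CODONS, n_aa - 2L, replace = TRUE),
                          collapse = ""),
                    "TAA")
      mrna <- paste0(rand_dna(u5), cds, rand_dna(u3))
      total <- nchar(mrna)
      # exon chunk lengths: terminal exons keep the UTRs plus a CDS margin
      min_chunk <- rep(60L, n_ex)
      min_chunk[1] <- u5 + 30L
      min_chunk[n_ex] <- u3 + 30L
      extra <- total - sum(min_chunk)
      w <- runif(n_ex)
      add <- as.integer(floor(extra * w / sum(w)))
      add[1] <- add[1] + (extra - sum(add))
      chunk <- min_chunk + add
      stopifnot(sum(chunk) == total)
      # introns, transcription orientation
      intron_seqs <- vapply(seq_len(n_ex - 1L), function(i) {
        len <- sample(seq(intron_range[1], intron_range[2]), 1L)
        donor6 <- sample(DONOR_MOTIFS, 1L, prob = DONOR_MOTIF_P)
        ppt <- rand_dna(18L, c("C", "T"))
        paste0(donor6, rand_dna(len - 26L), ppt, "AG")
      }, character(1))
      # assemble contig in transcription orientation
      pad5 <- rand_dna(300L)
      pad3 <- rand_dna(300L)
      cuts <- cumsum(chunk)
      exon_seqs <- substring(mrna, c(1L, head(cuts, -1L) + 1L), cuts)
      body <- exon_seqs[1]
      for (i in seq_len(n_ex - 1L)) {
        body <- paste0(body, intron_seqs[i], exon_seqs[i + 1L])
      }
      tx_seq <- paste0(pad5, body, pad3)
      L <- nchar(tx_seq)
      # exon intervals in transcription-oriented local coordinates
      loc_start <- integer(n_ex); loc_end <- integer(n_ex)
      cursor <- 300L
      for (i in seq_len(n_ex)) {
        loc_start[i] <- cursor + 1L
        loc_end[i] <- cursor + chunk[i]
        cursor <- loc_end[i] +
          if (i < n_ex) nchar(intron_seqs[i]) else 0L
      }
      contig <- sprintf("ctg%02d", g)
      if (strand == "+") {
        contigs[[contig]] <- tx_seq
        gstart <- loc_start; gend <- loc_end
      } else {
        contigs[[contig]] <- revcomp(tx_seq)
        gstart <- L - loc_end + 1L; gend <- L - loc_start + 1L
      }
      gene_id <- sprintf("GENE%03d", g)
      tx_id <- sprintf("TX%03d", g)
      sym <- sprintf("SG%d", g)
      feat[[g]] <- tibble(
        contig = contig, start = gstart, end = gend, strand = strand,
        type = "exon", gene_id = gene_id, transcript_id = tx_id,
        gene_symbol = sym)
      # CDS genomic segments: mRNA interval (u5+1 .. u5+3*n_aa) per exon
      cds_lo <- u5 + 1L; cds_hi <- u5 + 3L * n_aa
      mstart <- c(1L, head(cuts, -1L) + 1L)
      cds_rows <- list()
      for (i in seq_len(n_ex)) {
        a <- max(mstart[i], cds_lo); b <- min(cuts[i], cds_hi)
        if (a > b) next
        # local coords of mRNA positions a..b within exon i
        la <- loc_start[i] + (a - mstart[i])
        lb <- loc_start[i] + (b - mstart[i])
        if (strand == "+") {
          cds_rows[[i]] <- tibble(start = la, end = lb)
        } else {
          cds_rows[[i]] <- tibble(start = L - lb + 1L, end = L - la + 1L)
        }
      }
      cdsr <- bind_rows(cds_rows)
      feat[[n_genes + g]] <- tibble(
        contig = contig, start = cdsr$start, end = cdsr$end, strand = strand,
        type = "CDS", gene_id = gene_id, transcript_id = tx_id,
        gene_symbol = sym)
      meta[[g]] <- tibble(
        gene_id = gene_id, transcript_id = tx_id, gene_symbol = sym,
        contig = contig, strand = strand, n_exons = n_ex, u5 = u5, u3 = u3,
        n_aa = n_aa, mrna_len = total, contig_len = L)
    }
    genome <- Biostrings::DNAStringSet(unlist(contigs))
    db <- build_transcript_db(bind_rows(feat))
    structure(list(genome = genome, db = db, genes = bind_rows(meta),
                   seed = seed),
              class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %d gene(s), seed %d\n",
              nrow(x$genes), x$seed))
  invisible(x)
}

#' Default planting plan: 100 true calls and 400 negatives
#'
#' True rows mix donor/acceptor extensions and shrinkages over a range of
#' offsets, including an 11-nt acceptor extension, a 41-nt donor extension
#' carrying an in-frame stop in the extended segment, a 35-nt frameshifting
#' exon shrinkage and a 51-nt in-frame shrinkage deleting 17 residues --
#' the canonical case-study geometries. Negatives split evenly over four
#' failure classes: deep intronic (> 50 nt from any boundary), wrong
#' dinucleotide created, common allele (AF 0.05) and low delta score (0.3).
#'
#' @return A plan tibble consumed by [plant_scms()].
#' @export
default_scm_plan <- function() {
  true_ext_d <- c(41L, 9L, 10L, 12L, 15L, 18L, 21L, 24L, 27L, 33L, 39L, 45L)
  true_ext_a <- c(11L, 5L, 8L, 13L, 17L, 20L, 23L, 29L, 35L, 40L, 44L, 48L)
  true_shr_a <- c(51L, 35L, rep(c(21L, 24L, 27L, 30L, 33L, 36L, 39L, 42L,
                                  45L, 48L, 22L, 25L, 28L, 31L, 34L, 37L,
                                  40L, 43L), length.out = 36L))
  true_shr_d <- rep(c(6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L, 14L, 15L, 16L,
                      17L, 18L, 19L), length.out = 38L)
  trues <- bind_rows(
    tibble(class = "true", site_type = "donor", event = "extension",
           offset = true_ext_d,
           target = c("stop_in_novel", rep("any", length(true_ext_d) - 1L))),
    tibble(class = "true", site_type = "acceptor", event = "extension",
           offset = true_ext_a, target = "any"),
    tibble(class = "true", site_type = "acceptor", event = "shrinkage",
           offset = true_shr_a,
           target = c("clean", rep("any", length(true_shr_a) - 1L))),
    tibble(class = "true", site_type = "donor", event = "shrinkage",
           offset = true_shr_d, target = "any")
  )
  stopifnot(nrow(trues) == 100L)
  neg_like <- bind_rows(
    tibble(site_type = "donor", event = "extension",
           offset = c(10L, 14L, 20L, 26L, 32L, 38L, 44L, 9L, 13L, 19L,
                      25L, 31L, 37L, 43L, 11L)),
    tibble(site_type = "acceptor", event = "extension",
           offset = c(6L, 10L, 14L, 18L, 22L, 26L, 30L, 34L, 38L, 42L,
                      7L, 12L, 16L, 21L, 25L)),
    tibble(site_type = "acceptor", event = "shrinkage",
           offset = c(20L, 23L, 26L, 29L, 32L, 38L, 41L, 44L, 47L, 50L)),
    tibble(site_type = "donor", event = "shrinkage",
           offset = c(6L, 8L, 10L, 12L, 14L, 16L, 18L, 7L, 9L, 11L))
  ) |> mutate(target = "any")
  bind_rows(
    trues,
    tibble(class = "deep_intronic", site_type = "donor", event = "extension",
           offset = NA_integer_, target = "any")[rep(1L, 100L), ],
    tibble(class = "wrong_dinuc", site_type = NA_character_,
           event = NA_character_, offset = NA_integer_,
           target = "any")[rep(1L, 100L), ],
    mutate(neg_like[rep(seq_len(nrow(neg_like)), length.out = 100L), ],
           class = "high_af"),
    mutate(neg_like[rep(seq_len(nrow(neg_like)), length.out = 100L), ],
           class = "low_delta")
  )
}

# map transcription-oriented local coordinate (1 = first base of the element
# in transcription direction) to a plus-strand genomic position
local_to_genomic <- function(strand, el_start, el_end, k) {
  if (strand == "+") el_start + k - 1L else el_end - k + 1L
}

# overwrite genome so that the element's transcription-oriented local
# positions k .. k+nchar(s)-1 read as `s` on the transcript strand
rewrite_local <- function(genome, contig, strand, el_start, el_end, k, s) {
  n <- nchar(s)
  if (strand == "+") {
    gs <- el_start + k - 1L
    Biostrings::subseq(genome[[contig]], gs, gs + n - 1L) <-
      Biostrings::DNAString(s)
  } else {
    ge <- el_end - k + 1L
    Biostrings::subseq(genome[[contig]], ge - n + 1L, ge) <-
      Biostrings::DNAString(revcomp(s))
  }
  genome
}

#' Plant splice-creating SNVs and negatives into a synthetic genome
#'
#' For each plan row a locus is chosen where a single substitution completes
#' a GT (donor) or AG (acceptor) at the planned offset from an annotated
#' boundary; the local context is written with consensus-like donor motifs
#' or polypyrimidine tracts so the created site carries a strong strength
#' window, the pre-mutation sequence is guaranteed to lack the
#' dinucleotide, and the created pair never coincides with an annotated
#' splice dinucleotide. Reference coding sequences are re-verified stop-free
#' after every exonic rewrite. Delta scores and allele frequencies are
#' attached per plan and emitted in SpliceAI-dialect INFO strings.
#'
#' @param syn A `synthetic_genome` (its genome is copied and modified; use
#'   the returned genome downstream).
#' @param plan Plan tibble (see [default_scm_plan()]).
#' @param seed RNG seed for context sampling.
#' @return A `planted_scms`: list with `variants` (tibble with `info`
#'   SpliceAI-dialect strings, `af`, `delta`, `class`), `truth` (per-variant
#'   expected geometry and consequence), `genome` (rewritten reference),
#'   `db`, `genes`.
#' @export
plant_scms <- function(syn, plan = default_scm_plan(), seed = 1L) {
  stopifnot(inherits(syn, "synthetic_genome"))
  withr::with_seed(seed + 1L, {
    genome <- syn$genome
    db <- syn$db
    models <- representative_models(db)
    meta <- syn$genes
    used <- new.env(parent = emptyenv())
    reserve <- function(contig, a, b) {
      m <- used[[contig]] %||% matrix(integer(), ncol = 2)
      if (nrow(m) && any(m[, 1] <= b & m[, 2] >= a)) return(FALSE)
      used[[contig]] <- rbind(m, c(a, b))
      TRUE
    }
    placements <- list()
    gene_cursor <- 0L
    n_genes <- nrow(meta)

    place_row <- function(row, idx) {
      for (trial in seq_len(n_genes * 12L)) {
        gene_cursor <<- gene_cursor + 1L
        gm <- meta[(gene_cursor - 1L) %% n_genes + 1L, ]
        tm <- models[[gm$transcript_id]]
        pl <- try_place_in_gene(row, gm, tm, genome, reserve)
        if (!is.null(pl)) {
          genome <<- pl$genome
          pl$genome <- NULL
          pl$row <- row
          pl$idx <- idx
          return(pl)
        }
      }
      abort(sprintf(
        "no valid position found for plan row %d (class %s, %s %s offset %s)",
        idx, row$class, row$site_type %||% "?", row$event %||% "?",
        row$offset))
    }

    for (i in seq_len(nrow(plan))) {
      placements[[i]] <- place_row(plan[i, ], i)
    }

    # truths computed on the final (fully rewritten) reference
    truth <- bind_rows(lapply(placements, synthetic_truth,
                              genome = genome, db = db, meta = meta))
    jafs <- rep(c(0.2, 0.35, 0.5, 0.65, 0.8),
                length.out = sum(truth$class == "true"))
    truth$jaf_planned <- NA_real_
    truth$jaf_planned[truth$class == "true"] <- jafs

    variants <- truth |>
      select(variant_id, contig, pos, ref, alt, af, delta, class) |>
      mutate(info = scm_info_string(.data$af, .data$delta, truth$site_type,
                                    truth$gene_id))
    structure(list(variants = variants, truth = truth, genome = genome,
                   db = db, genes = meta),
              class = "planted_scms")
  })
}

scm_info_string <- function(af, delta, site_type, gene_id) {
  ds_ag <- ifelse(!is.na(site_type) & site_type == "acceptor", delta, 0)
  ds_dg <- ifelse(!is.na(site_type) & site_type == "donor", delta, 0)
  paste0(
    ifelse(is.na(af), "", sprintf("AF=%g;", af)),
    sprintf("SpliceAI=.|%s|%.2f|0.00|%.2f|0.00|0|0|0|0",
            gene_id, ds_ag, ds_dg))
}

# attempt one plan row in one gene; returns NULL when no slot fits, else a
# placement list (with the updated genome)
try_place_in_gene <- function(row, gm, tm, genome, reserve) {
  cls <- row$class
  if (cls == "wrong_dinuc") return(place_wrong_dinuc(gm, tm, genome, reserve))
  if (cls == "deep_intronic") return(place_deep(gm, tm, genome, reserve))
  if (row$event == "extension") {
    place_extension(row, gm, tm, genome, reserve)
  } else {
    place_shrinkage(row, gm, tm, genome, reserve)
  }
}

# interior exon indices: fully inside the CDS, never carrying start/stop
interior_exons <- function(gm) {
  if (gm$n_exons < 3L) return(integer(0))
  2:(gm$n_exons - 1L)
}

af_delta_for <- function(class) {
  switch(class,
         true = list(af = 1e-4, delta = 0.92),
         high_af = list(af = 0.05, delta = 0.9),
         low_delta = list(af = 1e-4, delta = 0.3),
         deep_intronic = list(af = 1e-4, delta = 0.85),
         wrong_dinuc = list(af = 1e-4, delta = 0))
}

place_extension <- function(row, gm, tm, genome, reserve) {
  intr <- introns(tm)
  d <- row$offset
  for (i in seq_len(nrow(intr))) {
    len <- intr$end[i] - intr$start[i] + 1L
    # the insertion point (an internal exon boundary) is always inside the
    # CDS here: terminal exons carry the UTRs plus a CDS margin
    ex_aff <- if (row$site_type == "donor") i else i + 1L
    if (row$site_type == "donor") {
      if (d < 9L || len < d + 30L) next
      k <- d - 2L                                   # rewrite start (local)
      # a targeted in-frame stop needs the whole extension segment protected
      # from later rewrites; plain rows only reserve their window
      res_lo <- if (row$target == "stop_in_novel") 1L else k
      gs <- sort(c(local_to_genomic(tm$strand, intr$start[i], intr$end[i],
                                    res_lo),
                   local_to_genomic(tm$strand, intr$start[i], intr$end[i],
                                    d + 6L)))
      if (!reserve(gm$contig, gs[1] - 2L, gs[2] + 2L)) next
      post <- paste0("CAC", "GTAAGT")
      refc <- "C"                                   # ref base under the G
      ref9 <- paste0("CAC", refc, "TAAGT")
      genome <- rewrite_local(genome, gm$contig, tm$strand,
                              intr$start[i], intr$end[i], k, ref9)
      if (row$target == "stop_in_novel") {
        # in-frame TAA inside the extension segment (intron bases 1..d)
        q <- cds_rel_exon_end(tm, ex_aff)           # CDS bases before insert
        s <- 7L
        while ((q + s - 1L) %% 3L != 0L) s <- s + 1L
        if (s + 2L <= d - 3L) {
          genome <- rewrite_local(genome, gm$contig, tm$strand,
                                  intr$start[i], intr$end[i], s, "TAA")
        }
      }
      mut_local <- d + 1L
      dinuc_local <- c(d + 1L, d + 2L)
    } else {
      if (d < 3L || len < d + 30L) next
      k <- len - d - 19L
      if (k < 8L) next                              # keep clear of the donor
      gs <- sort(c(local_to_genomic(tm$strand, intr$start[i], intr$end[i], k),
                   local_to_genomic(tm$strand, intr$start[i], intr$end[i],
                                    len - d)))
      if (!reserve(gm$contig, gs[1] - 2L, gs[2] + 2L)) next
      ppt <- rand_dna(17L, c("C", "T"))
      ref23i <- paste0(ppt, "C", "C", "G")          # ...C[ref C]G, AG on mut
      genome <- rewrite_local(genome, gm$contig, tm$strand,
                              intr$start[i], intr$end[i], k, ref23i)
      mut_local <- len - d - 1L
      dinuc_local <- c(len - d - 1L, len - d)
    }
    ad <- af_delta_for(row$class)
    gpos <- local_to_genomic(tm$strand, intr$start[i], intr$end[i], mut_local)
    dg <- sort(vapply(dinuc_local, function(kk) {
      local_to_genomic(tm$strand, intr$start[i], intr$end[i], kk)
    }, integer(1)))
    return(list(
      genome = genome, gene = gm, pos = gpos,
      ref = if (tm$strand == "+") "C" else comp_base("C"),
      alt = if (row$site_type == "donor") {
        if (tm$strand == "+") "G" else comp_base("G")
      } else {
        if (tm$strand == "+") "A" else comp_base("A")
      },
      af = ad$af, delta = ad$delta, site_type = row$site_type,
      event = "extension", offset = d, intron_index = i,
      affected_exon = ex_aff, dinuc = dg, mutated_base_index = 1L))
  }
  NULL
}

place_shrinkage <- function(row, gm, tm, genome, reserve) {
  o <- row$offset
  n_ex <- gm$n_exons
  cand <- if (row$site_type == "acceptor") 2:n_ex else seq_len(n_ex - 1L)
  for (ex in cand) {
    exlen <- exon_lengths(tm)[ex]
    if (row$site_type == "acceptor") {
      if (o < 6L || exlen < o + 9L) next
      # in the terminal exon the whole altered window and the removed head
      # must stay clear of the stop codon and the 3' UTR
      if (ex == n_ex && o + 9L > exlen - gm$u3 - 3L) next
      if (row$target == "clean" &&
            (o %% 3L != 0L || cds_rel_exon_start(tm, ex) %% 3L != 1L)) next
      k <- max(1L, o - 19L)
      gs <- sort(c(exon_local_genomic(tm, ex, k),
                   exon_local_genomic(tm, ex, o + 3L)))
      if (!reserve(gm$contig, gs[1] - 2L, gs[2] + 2L)) next
      n_ppt <- (o - 1L) - k            # pyrimidines before the ref base
      ref_block <- paste0(rand_dna(n_ppt, c("C", "T")), "C", "G", "CCT")
      g2 <- rewrite_local(genome, gm$contig, tm$strand,
                          tm$exons$start[ex], tm$exons$end[ex], k, ref_block)
      if (!cds_stop_free(tm, g2)) next
      genome <- g2
      mut_local <- o - 1L
      dinuc_local <- c(o - 1L, o)
      altb <- "A"
    } else {
      if (o < 6L || exlen < o + 9L) next
      k <- exlen - o - 2L
      if (k < 2L) next
      # in the first exon the rewrite window must stay inside the CDS
      if (ex == 1L && k < gm$u5 + 5L) next
      gs <- sort(c(exon_local_genomic(tm, ex, k),
                   exon_local_genomic(tm, ex, exlen - o + 6L)))
      if (!reserve(gm$contig, gs[1] - 2L, gs[2] + 2L)) next
      ref_block <- paste0("CAC", "C", "TATGT")      # mutates to CACGTATGT
      g2 <- rewrite_local(genome, gm$contig, tm$strand,
                          tm$exons$start[ex], tm$exons$end[ex], k, ref_block)
      if (!cds_stop_free(tm, g2)) next
      genome <- g2
      mut_local <- exlen - o + 1L
      dinuc_local <- c(exlen - o + 1L, exlen - o + 2L)
      altb <- "G"
    }
    ad <- af_delta_for(row$class)
    gpos <- exon_local_genomic(tm, ex, mut_local)
    dg <- sort(vapply(dinuc_local, function(kk) exon_local_genomic(tm, ex, kk),
                      integer(1)))
    return(list(
      genome = genome, gene = gm, pos = gpos,
      ref = if (tm$strand == "+") "C" else comp_base("C"),
      alt = if (tm$strand == "+") altb else comp_base(altb),
      af = ad$af, delta = ad$delta, site_type = row$site_type,
      event = "shrinkage", offset = o, intron_index = NA_integer_,
      affected_exon = ex, dinuc = dg, mutated_base_index = 1L))
  }
  NULL
}

place_deep <- function(gm, tm, genome, reserve) {
  intr <- introns(tm)
  for (i in seq_len(nrow(intr))) {
    len <- intr$end[i] - intr$start[i] + 1L
    if (len < 160L) next
    for (k0 in seq(60L, len - 90L, by = 31L)) {
      d <- k0
      gs <- sort(c(local_to_genomic(tm$strand, intr$start[i], intr$end[i],
                                    d - 2L),
                   local_to_genomic(tm$strand, intr$start[i], intr$end[i],
                                    d + 6L)))
      if (!reserve(gm$contig, gs[1] - 2L, gs[2] + 2L)) next
      genome <- rewrite_local(genome, gm$contig, tm$strand,
                              intr$start[i], intr$end[i], d - 2L,
                              paste0("CAC", "C", "TAAGT"))
      ad <- af_delta_for("deep_intronic")
      gpos <- local_to_genomic(tm$strand, intr$start[i], intr$end[i], d + 1L)
      dg <- sort(c(local_to_genomic(tm$strand, intr$start[i], intr$end[i],
                                    d + 1L),
                   local_to_genomic(tm$strand, intr$start[i], intr$end[i],
                                    d + 2L)))
      return(list(
        genome = genome, gene = gm, pos = gpos,
        ref = if (tm$strand == "+") "C" else "G",
        alt = if (tm$strand == "+") "G" else "C",
        af = ad$af, delta = ad$delta, site_type = "donor",
        event = "extension", offset = d, intron_index = i,
        affected_exon = i, dinuc = dg, mutated_base_index = 1L))
    }
  }
  NULL
}

place_wrong_dinuc <- function(gm, tm, genome, reserve) {
  for (ex in interior_exons(gm)) {
    exlen <- exon_lengths(tm)[ex]
    for (k in seq(25L, exlen - 25L, by = 17L)) {
      gs <- sort(c(exon_local_genomic(tm, ex, k - 1L),
                   exon_local_genomic(tm, ex, k + 1L)))
      if (!reserve(gm$contig, gs[1] - 2L, gs[2] + 2L)) next
      g2 <- rewrite_local(genome, gm$contig, tm$strand,
                          tm$exons$start[ex], tm$exons$end[ex], k - 1L, "CCC")
      if (!cds_stop_free(tm, g2)) next
      ad <- af_delta_for("wrong_dinuc")
      gpos <- exon_local_genomic(tm, ex, k)
      return(list(
        genome = g2, gene = gm, pos = gpos,
        ref = if (tm$strand == "+") "C" else "G",
        alt = if (tm$strand == "+") "A" else "T",
        af = ad$af, delta = ad$delta, site_type = NA_character_,
        event = NA_character_, offset = NA_integer_,
        intron_index = NA_integer_, affected_exon = ex,
        dinuc = c(NA_integer_, NA_integer_), mutated_base_index = NA_integer_))
    }
  }
  NULL
}

exon_local_genomic <- function(tm, ex, k) {
  local_to_genomic(tm$strand, tm$exons$start[ex], tm$exons$end[ex], k)
}

# CDS-relative (1-based) position of the first base of exon `ex`
cds_rel_exon_start <- function(tm, ex) {
  cds <- cds_tx_range(tm)
  lens <- exon_lengths(tm)
  sum(lens[seq_len(ex - 1L)]) + 1L - cds[1] + 1L
}

# number of CDS bases transcribed before the end of exon `ex`
cds_rel_exon_end <- function(tm, ex) {
  cds <- cds_tx_range(tm)
  lens <- exon_lengths(tm)
  sum(lens[seq_len(ex)]) - cds[1] + 1L
}

cds_stop_free <- function(tm, genome) {
  cds <- cds_tx_range(tm)
  mrna <- transcript_sequence(tm, genome)
  aa <- translate_frame(substr(mrna, cds[1], cds[2]))
  !grepl("*", substr(aa, 1L, nchar(aa) - 1L), fixed = TRUE)
}

# expected geometry + consequence for one placement, on the final reference
synthetic_truth <- function(pl, genome, db, meta) {
  gm <- pl$gene
  tm <- transcript_model(db, gm$transcript_id)
  vid <- sprintf("scm%03d", pl$idx)
  base <- tibble(
    variant_id = vid, class = pl$row$class, contig = gm$contig,
    pos = pl$pos, ref = pl$ref, alt = pl$alt, af = pl$af, delta = pl$delta,
    gene_id = gm$gene_id, transcript_id = gm$transcript_id,
    gene_symbol = gm$gene_symbol, site_type = pl$site_type,
    event = pl$event, offset_nt = pl$offset,
    mutated_base_index = pl$mutated_base_index,
    dinuc_start = pl$dinuc[1], dinuc_end = pl$dinuc[2],
    affected_exon_index = pl$affected_exon)
  if (pl$row$class %in% c("wrong_dinuc", "deep_intronic")) {
    return(mutate(base,
                  annotated_boundary = NA_integer_,
                  novel_boundary = NA_integer_,
                  novel_intron_start = NA_integer_,
                  novel_intron_end = NA_integer_,
                  annotated_intron_start = NA_integer_,
                  annotated_intron_end = NA_integer_,
                  category = NA_character_, frame_preserved = NA,
                  aa_deleted = NA_integer_, aa_inserted = NA_integer_,
                  nmd_predicted = NA, altered_mrna = NA_character_,
                  strength_window = NA_character_))
  }
  # geometry by construction (independent of the discovery code path)
  intr <- introns(tm)
  lens <- exon_lengths(tm)
  ex <- pl$affected_exon
  plus <- tm$strand == "+"
  if (pl$site_type == "donor") {
    anno <- if (plus) tm$exons$end[ex] else tm$exons$start[ex]
  } else {
    anno <- if (plus) tm$exons$start[ex] else tm$exons$end[ex]
  }
  dirn <- if (plus) 1L else -1L
  novel <- if (pl$site_type == "donor") {
    if (pl$event == "extension") anno + dirn * pl$offset else
      anno - dirn * pl$offset
  } else {
    if (pl$event == "extension") anno - dirn * pl$offset else
      anno + dirn * pl$offset
  }
  rel_intron <- if (pl$event == "extension") pl$intron_index else {
    if (pl$site_type == "donor") ex else ex - 1L
  }
  if (pl$site_type == "donor") {
    ni <- if (plus) c(novel + 1L, intr$end[rel_intron]) else
      c(intr$start[rel_intron], novel - 1L)
  } else {
    ni <- if (plus) c(intr$start[rel_intron], novel - 1L) else
      c(novel + 1L, intr$end[rel_intron])
  }
  # altered mRNA by straightforward string surgery
  exon_seq <- vapply(seq_len(nrow(tm$exons)), function(i) {
    get_seq(genome, tm$contig, tm$exons$start[i], tm$exons$end[i], tm$strand)
  }, character(1))
  intron_seq_at <- function(i) {
    get_seq(genome, tm$contig, intr$start[i], intr$end[i], tm$strand)
  }
  d <- pl$offset
  alt_seq <- exon_seq
  if (pl$site_type == "donor") {
    alt_seq[ex] <- if (pl$event == "extension") {
      paste0(exon_seq[ex], substr(intron_seq_at(rel_intron), 1L, d))
    } else {
      substr(exon_seq[ex], 1L, nchar(exon_seq[ex]) - d)
    }
  } else {
    iseq <- if (pl$event == "extension") intron_seq_at(rel_intron) else NULL
    alt_seq[ex] <- if (pl$event == "extension") {
      paste0(substr(iseq, nchar(iseq) - d + 1L, nchar(iseq)), exon_seq[ex])
    } else {
      substr(exon_seq[ex], d + 1L, nchar(exon_seq[ex]))
    }
  }
  mrna2 <- paste(alt_seq, collapse = "")
  shift <- if (pl$event == "extension") d else -d
  cds_start <- gm$u5 + 1L                        # upstream of any alteration
  stop_last_alt <- gm$u5 + 3L * gm$n_aa + shift  # annotated stop, altered
  aa <- translate_frame(substr(mrna2, cds_start, nchar(mrna2)))
  first_stop <- regexpr("*", aa, fixed = TRUE)[1]
  ptc_first <- if (first_stop > 0L) cds_start + 3L * (first_stop - 1L) else NA
  is_ptc <- !is.na(ptc_first) && (ptc_first + 2L) < stop_last_alt
  lens2 <- nchar(alt_seq)
  ex_lo <- sum(lens2[seq_len(ex - 1L)]) + 1L
  ex_hi <- ex_lo + lens2[ex] - 1L
  category <- if (!is_ptc) "no_PTC" else {
    if (ptc_first <= ex_hi && (ptc_first + 2L) >= ex_lo) "PTC_in_novel_exon"
    else "PTC_frameshift"
  }
  frame_ok <- d %% 3L == 0L
  last_junction <- sum(lens2) - lens2[length(lens2)]
  nmd <- is_ptc && length(lens2) >= 2L && (last_junction - ptc_first) >= 50L
  # recorded post-mutation strength window (ground truth for extraction)
  win <- window_truth(pl, tm, genome)
  mutate(base,
         annotated_boundary = anno, novel_boundary = novel,
         novel_intron_start = ni[1], novel_intron_end = ni[2],
         annotated_intron_start = intr$start[rel_intron],
         annotated_intron_end = intr$end[rel_intron],
         category = category, frame_preserved = frame_ok,
         aa_deleted = if (!is_ptc && frame_ok && pl$event == "shrinkage")
           d %/% 3L else 0L,
         aa_inserted = if (!is_ptc && frame_ok && pl$event == "extension")
           d %/% 3L else 0L,
         nmd_predicted = nmd, altered_mrna = mrna2,
         strength_window = win)
}

# post-mutation window string straight from the planted geometry
window_truth <- function(pl, tm, genome) {
  plus <- tm$strand == "+"
  d1 <- if (plus) pl$dinuc[1] else pl$dinuc[2]
  w <- if (pl$site_type == "donor") {
    if (plus) get_seq(genome, tm$contig, d1 - 3L, d1 + 5L, "+")
    else get_seq(genome, tm$contig, d1 - 5L, d1 + 3L, "-")
  } else {
    if (plus) get_seq(genome, tm$contig, d1 - 18L, d1 + 4L, "+")
    else get_seq(genome, tm$contig, d1 - 4L, d1 + 18L, "-")
  }
  # substitute the planted ALT (windows anchor on the dinucleotide's first
  # base; the planted variant always mutates that base)
  off <- if (pl$site_type == "donor") 4L else 19L
  alt_tx <- if (plus) pl$alt else comp_base(pl$alt)
  substr(w, off, off) <- alt_tx
  w
}
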