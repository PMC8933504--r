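# Worked junction geometries mirroring the published case studies, plus
# property checks of the transcript-rebuild / PTC machinery against a
# brute-force splice-translate-scan oracle.

test_that("an acceptor created at intron -13 extends the exon by 11 nt", {
  case <- toy_acceptor_extension_11()
  jx <- derive_novel_junction(scan_one(case), case$toy$db)
  expect_equal(jx$site_type, "acceptor")
  expect_equal(jx$event, "extension")
  expect_equal(jx$offset_nt, 11L)
  expect_equal(jx$mutated_base_index, 1L)
  rb <- rebuild_transcript(jx, case$toy$db, case$toy$genome, case$variant)
  orig_len <- sum(case$toy$tm$exons$end - case$toy$tm$exons$start + 1L)
  expect_equal(nchar(rb$mrna), orig_len + 11L)
})

test_that("a donor created at intron +42 extends the exon by 41 nt with a PTC in it", {
  case <- toy_donor_extension_41()
  jx <- derive_novel_junction(scan_one(case), case$toy$db)
  expect_equal(jx$site_type, "donor")
  expect_equal(jx$event, "extension")
  expect_equal(jx$offset_nt, 41L)
  rb <- rebuild_transcript(jx, case$toy$db, case$toy$genome, case$variant)
  orig_len <- sum(case$toy$tm$exons$end - case$toy$tm$exons$start + 1L)
  expect_equal(nchar(rb$mrna), orig_len + 41L)
  call <- classify_ptc(rb)
  expect_equal(call$category, "PTC_in_novel_exon")
  expect_true(call$nmd_predicted)
})

test_that("a 51-nt in-frame shrinkage deletes 17 residues without a PTC", {
  case <- toy_acceptor_shrinkage_51()
  jx <- derive_novel_junction(scan_one(case), case$toy$db)
  expect_equal(jx$event, "shrinkage")
  expect_equal(jx$offset_nt, 51L)
  rb <- rebuild_transcript(jx, case$toy$db, case$toy$genome, case$variant)
  orig_len <- sum(case$toy$tm$exons$end - case$toy$tm$exons$start + 1L)
  expect_equal(nchar(rb$mrna), orig_len - 51L)
  call <- classify_ptc(rb)
  expect_equal(call$category, "no_PTC")
  expect_true(call$frame_preserved)
  expect_equal(call$aa_deleted, 17L)
  aa <- map_alteration_to_protein(rb, call)
  expect_equal(aa$aa_end - aa$aa_start + 1L, 17L)
  expect_equal(aa$aa_start, 22L)  # after ATG + 20 alanines
})

test_that("a 35-nt shrinkage shifts the frame and creates a downstream PTC", {
  case <- toy_acceptor_shrinkage_35()
  jx <- derive_novel_junction(scan_one(case), case$toy$db)
  expect_equal(jx$offset_nt, 35L)
  rb <- rebuild_transcript(jx, case$toy$db, case$toy$genome, case$variant)
  call <- classify_ptc(rb)
  expect_false(call$frame_preserved)
  expect_equal(call$category, "PTC_frameshift")
  # the oracle agrees on this worked example
  toy <- case$toy
  o <- oracle_consequence(
    as.character(toy$genome[[toy$contig]]), toy$loc_start, toy$loc_end,
    "+", u5 = 9L, cds_len = 36L + 65L + 34L,
    site_type = "acceptor", event = "shrinkage", offset = 35L,
    affected_exon = 2L)
  expect_equal(call$category, o$category)
  expect_equal(call$ptc_tx_pos, o$ptc_first)
})

test_that("alterations confined to untranslated regions are not_in_CDS", {
  # acceptor shrinkage in a pure-3'UTR terminal exon
  exon4 <- paste0(strrep("C", 20), "GG", strrep("C", 30))
  toy <- toy_gene(
    exons = c(paste0(strrep("C", 9), "ATG", ala(20)), ala(30),
              paste0(ala(10), "TAA", strrep("C", 12)), exon4),
    introns = c(toy_intron(120L), toy_intron(130L), toy_intron(110L)),
    strand = "+", u5 = 9L, cds_len = 3L * (1L + 20L + 30L + 10L + 1L))
  stopifnot(substr(exon4, 21L, 22L) == "GG")
  v <- toy_variant(toy$contig, toy$loc_start[4] + 20L, "G", "A")
  jx <- derive_novel_junction(
    scan_dinucleotide_creation(v, toy$genome, toy$tm), toy$db)
  rb <- rebuild_transcript(jx[1, ], toy$db, toy$genome, v)
  call <- classify_ptc(rb)
  expect_equal(call$category, "not_in_CDS")
  expect_error(map_alteration_to_protein(rb, call), "coding")
})

test_that("classify_ptc agrees with the generator's independent truth registry", {
  fx <- shared_fixture()
  cons <- shared_consequences()
  truth <- dplyr::filter(fx$planted$truth, class == "true")
  m <- dplyr::inner_join(tibble::as_tibble(cons), truth,
                         by = "variant_id", suffix = c("", ".t"))
  expect_equal(nrow(m), 100L)
  expect_equal(m$category, m$category.t)
  expect_equal(m$frame_preserved, m$frame_preserved.t)
  expect_equal(m$nmd_predicted, m$nmd_predicted.t)
  expect_equal(m$aa_deleted, m$aa_deleted.t)
  expect_equal(m$aa_inserted, m$aa_inserted.t)
})

test_that("frame-preserving events conserve offset = 3 x (aa deleted + inserted)", {
  cons <- shared_consequences()
  fp <- dplyr::filter(cons, frame_preserved, category == "no_PTC")
  expect_gt(nrow(fp), 0L)
  expect_equal(3L * (fp$aa_deleted + fp$aa_inserted), fp$offset_nt)
})

test_that("consequence categories partition the accepted calls", {
  cons <- shared_consequences()
  expect_equal(nrow(cons), 100L)
  ok <- cons$status == "ok"
  expect_true(all(cons$category[ok] %in%
                    c("PTC_frameshift", "PTC_in_novel_exon", "no_PTC",
                      "not_in_CDS")))
  counts <- table(cons$category[ok])
  expect_equal(sum(counts), sum(ok))
})

test_that("the 50-nt last-junction rule drives the NMD prediction", {
  mk_alt <- function(lens) {
    starts <- cumsum(c(1L, head(lens + 200L, -1L)))
    structure(list(transcript_id = "t", gene_id = "g", gene_symbol = "g",
                   contig = "c", strand = "+",
                   exons = tibble::tibble(start = starts,
                                          end = starts + lens - 1L),
                   cds = NULL, representative = TRUE),
              class = "transcript_model")
  }
  five <- mk_alt(c(200L, 150L, 150L, 150L, 300L))
  last_junction <- 650L
  expect_true(predict_nmd(last_junction - 200L, five))   # 200 nt upstream
  expect_true(predict_nmd(last_junction - 50L, five))    # boundary: exactly 50
  expect_false(predict_nmd(last_junction - 49L, five))
  expect_false(predict_nmd(last_junction + 10L, five))   # in the last exon
  expect_false(predict_nmd(100L, mk_alt(900L)))          # single exon
})

test_that("protein mapping handles codon-boundary insertions", {
  # a 3-nt acceptor extension at a codon boundary: one inserted residue
  # (inserted segment reads CAG = Gln; AG created at intron -5/-4)
  tail <- paste0(strrep("CT", 8L), "GG", "C", "AG")
  intron2 <- paste0("GTAAGT", strrep("A", 130L - 6L - nchar(tail)), tail)
  toy2 <- toy_gene(
    exons = c(paste0(strrep("C", 9), "ATG", ala(20)), ala(30),
              paste0(ala(20), "TAA", strrep("C", 12))),
    introns = c(toy_intron(120L), intron2),
    strand = "+", u5 = 9L, cds_len = 3L * (1L + 20L + 30L + 20L + 1L))
  v <- toy_variant(toy2$contig, toy2$loc_start[3] - 5L, "G", "A")
  jx <- derive_novel_junction(
    scan_dinucleotide_creation(v, toy2$genome, toy2$tm), toy2$db)
  expect_equal(jx$offset_nt, 3L)
  rb <- rebuild_transcript(jx, toy2$db, toy2$genome, v)
  call <- classify_ptc(rb)
  expect_equal(call$category, "no_PTC")
  expect_equal(call$aa_inserted, 1L)
  aa <- map_alteration_to_protein(rb, call)
  expect_equal(aa$aa_end - aa$aa_start + 1L, 1L)
})

test_that("domain overlap keeps E <= 0.001 domains sharing at least one residue", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tdomain\taa_start\taa_end\tevalue",
               "P1\tDENN\t400\t700\t1e-10",
               "P1\tWeak\t100\t200\t0.5",
               "P1\tEdge\t637\t700\t1e-5"), path)
  dom <- read_domain_table(path)
  expect_equal(nrow(dom), 2L)  # E-value 0.5 dropped on load
  expect_equal(domain_overlap(620L, 636L, dom), "DENN")
  expect_equal(sort(domain_overlap(620L, 637L, dom)),
               c("DENN", "Edge"))  # single shared residue counts
  expect_equal(domain_overlap(10L, 50L, dom), character(0))
})

test_that("hmmscan domtblout tables parse with the per-domain E-value", {
  path <- withr::local_tempfile(fileext = ".txt")
  fields <- c("DENN", "PF01234.1", "300", "P1", "-", "800",
              "1e-20", "100.0", "0.1", "1", "1", "1e-18", "5e-19",
              "99.0", "0.1", "1", "290", "401", "698", "395", "700", "0.98",
              "description here")
  writeLines(c("# comment line", paste(fields, collapse = " ")), path)
  dom <- read_domain_table(path)
  expect_equal(dom$domain_name, "DENN")
  expect_equal(dom$protein_id, "P1")
  expect_equal(dom$aa_start, 401L)
  expect_equal(dom$aa_end, 698L)
  expect_equal(dom$e_value, 5e-19)
})

test_that("pathogenic potential requires a PTC or a disrupted domain", {
  calls <- tibble::tibble(
    category = c("PTC_frameshift", "no_PTC", "no_PTC", "not_in_CDS"),
    disrupted_domains = list(character(0), "DENN", character(0),
                             character(0)))
  expect_equal(pathogenic_potential(calls), c(TRUE, TRUE, FALSE, FALSE))
})
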