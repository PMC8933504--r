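test_that("genome generation is byte-deterministic under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- generate_genome(n_genes = 5, seed = 1)
  s2 <- generate_genome(n_genes = 5, seed = 1)
  write_genome(s1$genome, file.path(d1, "g.fa"))
  write_genome(s2$genome, file.path(d2, "g.fa"))
  write_gtf(s1$db, file.path(d1, "a.gtf"))
  write_gtf(s2$db, file.path(d2, "a.gtf"))
  expect_identical(readLines(file.path(d1, "g.fa")),
                   readLines(file.path(d2, "g.fa")))
  expect_identical(readLines(file.path(d1, "a.gtf")),
                   readLines(file.path(d2, "a.gtf")))
  # a different seed changes the sequence
  s3 <- generate_genome(n_genes = 5, seed = 2)
  expect_false(identical(as.character(s1$genome), as.character(s3$genome)))
})

test_that("generated gene models satisfy their structural invariants", {
  syn <- generate_genome(n_genes = 8, seed = 3)
  expect_equal(nrow(check_canonical_introns(syn$db, syn$genome)), 0L)
  for (id in syn$db$transcripts$transcript_id) {
    tm <- transcript_model(syn$db, id)
    # exons strictly ordered and non-overlapping in transcription direction
    if (tm$strand == "+") {
      expect_true(all(diff(tm$exons$start) > 0))
      expect_true(all(tm$exons$start[-1] > head(tm$exons$end, -1)))
    } else {
      expect_true(all(diff(tm$exons$start) < 0))
      expect_true(all(head(tm$exons$start, -1) > tm$exons$end[-1]))
    }
    # CDS translates start to stop with no internal stop
    cds <- splicegain:::cds_tx_range(tm)
    expect_equal((cds[2] - cds[1] + 1L) %% 3L, 0L)
    mrna <- splicegain:::transcript_sequence(tm, syn$genome)
    aa <- splicegain:::translate_frame(substr(mrna, cds[1], cds[2]))
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1L), fixed = TRUE))
    # every intron is at least 4 nt (room for GT...AG)
    intr <- introns(tm)
    expect_true(all(intr$end - intr$start + 1L >= 4L))
  }
})

test_that("planting is deterministic and honours the planned geometry", {
  fx <- small_fixture()
  p2 <- plant_scms(generate_genome(n_genes = 6, seed = 11),
                   plan = small_plan(), seed = 11)
  expect_identical(as.character(fx$planted$genome),
                   as.character(p2$genome))
  expect_equal(as.data.frame(fx$planted$truth[, 1:10]),
               as.data.frame(p2$truth[, 1:10]))
  truth <- dplyr::filter(fx$planted$truth, class == "true")
  # pre-mutation pairs never read as the created dinucleotide
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    strand <- fx$planted$db$transcripts$strand[
      fx$planted$db$transcripts$transcript_id == r$transcript_id]
    pre <- get_seq(fx$planted$genome, r$contig, r$dinuc_start, r$dinuc_end,
                   strand)
    expect_false(pre %in% c("GT", "AG")[match(r$site_type,
                                              c("donor", "acceptor"))])
  }
})

test_that("planted geometries round-trip through the discovery machinery", {
  fx <- small_fixture()
  planted <- fx$planted
  scms <- run_filter_cascade(planted$variants, planted$genome, planted$db)
  truth <- dplyr::filter(planted$truth, class == "true")
  expect_setequal(scms$variant_id, truth$variant_id)
  jx <- derive_novel_junction(scms, planted$db)
  m <- dplyr::inner_join(tibble::as_tibble(jx), truth,
                         by = "variant_id", suffix = c("", ".t"))
  expect_equal(m$event, m$event.t)
  expect_equal(m$offset_nt, m$offset_nt.t)
  expect_equal(m$novel_boundary, m$novel_boundary.t)
  # the planted 11-nt acceptor extension and 51-nt clean shrinkage are there
  expect_true(any(m$site_type == "acceptor" & m$event == "extension" &
                    m$offset_nt == 11L))
  clean <- dplyr::filter(truth, event == "shrinkage", offset_nt == 51L)
  expect_equal(clean$aa_deleted, 17L)
  expect_equal(clean$category, "no_PTC")
})

test_that("negative classes die at their designed cascade stages", {
  fx <- small_fixture()
  planted <- fx$planted
  scms <- run_filter_cascade(planted$variants, planted$genome, planted$db)
  got <- unique(scms$variant_id)
  for (cls in c("deep_intronic", "wrong_dinuc", "high_af", "low_delta")) {
    ids <- planted$truth$variant_id[planted$truth$class == cls]
    expect_length(intersect(ids, got), 0L)
  }
})

test_that("simulated junction evidence matches its own registry and plan", {
  fx <- small_fixture()
  sim <- simulate_junction_evidence(fx$planted, depth = 1000L, seed = 5)
  carriers <- dplyr::filter(sim$counts, grepl("^CARRIER", sample_id))
  # binomial concentration at depth 1000: realised JAF within 0.05
  expect_true(all(abs(carriers$jaf_realised - carriers$jaf_planned) <=
                    0.05))
  # non-carriers have no novel-junction reads
  ctrls <- dplyr::filter(sim$counts, grepl("^CTRL", sample_id))
  expect_true(all(ctrls$J_n == 0L))
  # table counts equal the registry
  truth <- dplyr::filter(fx$planted$truth, class == "true")
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    strand <- fx$planted$db$transcripts$strand[
      fx$planted$db$transcripts$transcript_id == r$transcript_id]
    cc <- dplyr::filter(sim$counts, variant_id == r$variant_id,
                        grepl("^CARRIER", sample_id))
    got_n <- count_junction_reads(sim$junctions, r$contig,
                                  r$novel_intron_start, r$novel_intron_end,
                                  strand = strand,
                                  sample_id = cc$sample_id)
    got_a <- count_junction_reads(sim$junctions, r$contig,
                                  r$annotated_intron_start,
                                  r$annotated_intron_end,
                                  strand = strand, sample_id = cc$sample_id)
    expect_equal(got_n, cc$J_n)
    expect_equal(got_a, cc$J_a)
    expect_equal(compute_jaf(got_n, got_a), cc$jaf_realised)
  }
})

test_that("the synthetic cohort reproduces the recessive and compound-het patterns", {
  fx <- shared_fixture()
  coh <- generate_cohort(fx$planted, seed = 1)
  cons <- call_consequences(
    fx$scms[fx$scms$variant_id %in% coh$variants$variant_id, ],
    fx$planted$db, fx$planted$genome)
  hits <- screen_cohort(cons, coh$genotypes, coh$pedigree)
  # the recessive call is retained with the 3-hom/1-het pattern
  hom <- dplyr::filter(hits, variant_id == coh$key$hom_variant)
  expect_equal(nrow(hom), 1L)
  expect_equal(hom$n_hom_affected, 3L)
  expect_equal(hom$n_hom_unaffected, 0L)
  expect_equal(hom$n_het_unaffected, 1L)
  # the decoy (hom in an unaffected) is excluded
  expect_false(coh$key$decoy_variant %in% hits$variant_id)
  # the compound-het pair is detected in trans via the informative sibling
  ch <- detect_compound_het(hits, coh$genotypes, coh$pedigree)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$sample_id, coh$key$ch_sample)
  expect_setequal(c(ch$variant_a, ch$variant_b), coh$key$ch_pair)
  expect_equal(ch$phase, "in_trans")
})

test_that("fixtures round-trip through their plain-text formats", {
  fx <- small_fixture()
  dir <- withr::local_tempdir()
  paths <- write_synthetic_fixtures(fx$planted, dir)
  expect_true(all(file.exists(paths)))
  genome2 <- read_genome(paths[["fasta"]])
  expect_identical(as.character(genome2), as.character(fx$planted$genome))
  v2 <- read_vcf(paths[["vcf"]])
  expect_equal(nrow(v2), nrow(fx$planted$variants))
  expect_equal(v2$pos, fx$planted$variants$pos)
  expect_equal(v2$af, fx$planted$variants$af)
  expect_equal(read_delta_score(v2)$delta_score, fx$planted$variants$delta)
  # genotyped cohort VCF round-trips genotype codes
  coh <- generate_cohort(shared_fixture()$planted, seed = 1)
  vcf_path <- file.path(dir, "cohort.vcf")
  write_vcf(shared_fixture()$planted$variants[
    shared_fixture()$planted$variants$variant_id %in%
      coh$variants$variant_id, ], vcf_path, genotypes = coh$genotypes)
  back <- read_vcf_genotypes(vcf_path)
  merged <- dplyr::inner_join(back$genotypes, coh$genotypes,
                              by = c("variant_id", "sample_id"))
  expect_gt(nrow(merged), 0L)
  expect_equal(merged$gt.x, merged$gt.y)
})
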