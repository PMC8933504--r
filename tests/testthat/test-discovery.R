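test_that("dinucleotide scan agrees with brute-force enumeration of all SNVs", {
  # a plus-strand toy gene; enumerate every position of a window around the
  # first exon-intron boundary and every alternate base, and compare the
  # scan against literal string checking of both overlapping pairs
  toy <- toy_gene(
    exons = c(paste0(strrep("C", 9), "ATG", ala(25)),
              paste0(ala(20), "TAA", strrep("C", 12))),
    introns = toy_intron(120L),
    strand = "+", u5 = 9L, cds_len = 3L * 48L)
  g <- toy$genome
  tm <- toy$tm
  anno <- splicegain:::splice_dinucleotides(tm)
  seqc <- as.character(g[[toy$contig]])
  for (pos in seq(toy$loc_end[1] - 6L, toy$loc_end[1] + 40L)) {
    ref <- substr(seqc, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      v <- tibble::tibble(variant_id = "v", contig = toy$contig, pos = pos,
                          ref = ref, alt = alt, af = NA_real_, info = "")
      got <- scan_dinucleotide_creation(v, g, tm)
      expected <- 0L
      for (a in c(pos - 1L, pos)) {
        pre <- substr(seqc, a, a + 1L)
        post <- pre
        substr(post, pos - a + 1L, pos - a + 1L) <- alt
        if (post %in% c("GT", "AG") && pre != post &&
              !any(anno$start == a & anno$end == a + 1L)) {
          expected <- expected + 1L
        }
      }
      expect_equal(nrow(got), expected,
                   info = sprintf("pos %d %s>%s", pos, ref, alt))
    }
  }
})

test_that("scan reports site type, interval and mutated-base index", {
  toy <- toy_gene(
    exons = c(paste0(strrep("C", 9), "ATG", ala(25)),
              paste0(ala(20), "TAA", strrep("C", 12))),
    introns = toy_intron(120L),
    strand = "+", u5 = 9L, cds_len = 3L * 48L)
  g2 <- toy$genome
  # write AC at intron positions 20-21: C>G at the second base creates AG
  p0 <- toy$loc_end[1] + 20L
  Biostrings::subseq(g2[[toy$contig]], p0, p0 + 1L) <- Biostrings::DNAString("AC")
  got <- scan_dinucleotide_creation(
    tibble::tibble(variant_id = "v", contig = toy$contig, pos = p0 + 1L,
                   ref = "C", alt = "G", af = NA_real_, info = ""),
    g2, toy$tm)
  expect_equal(nrow(got), 1L)
  expect_equal(got$site_type, "acceptor")
  expect_equal(c(got$dinuc_start, got$dinuc_end), c(p0, p0 + 1L))
  expect_equal(got$mutated_base_index, 2L)
  # CAT at 29-31: A>G at the middle base creates GT only (donor, index 1)
  g3 <- toy$genome
  p1 <- toy$loc_end[1] + 30L
  Biostrings::subseq(g3[[toy$contig]], p1 - 1L, p1 + 1L) <-
    Biostrings::DNAString("CAT")
  got <- scan_dinucleotide_creation(
    tibble::tibble(variant_id = "v", contig = toy$contig, pos = p1,
                   ref = "A", alt = "G", af = NA_real_, info = ""),
    g3, toy$tm)
  expect_equal(got$site_type, "donor")
  expect_equal(got$mutated_base_index, 1L)
  # a variant creating neither dinucleotide yields nothing
  got <- scan_dinucleotide_creation(
    tibble::tibble(variant_id = "v", contig = toy$contig,
                   pos = toy$loc_end[1] + 50L, ref = "A", alt = "C",
                   af = NA_real_, info = ""),
    toy$genome, toy$tm)
  expect_equal(nrow(got), 0L)
})

test_that("strength windows have the mandated widths and match planted truth", {
  fx <- shared_fixture()
  truth <- dplyr::filter(fx$planted$truth, class == "true")
  cands <- dplyr::inner_join(
    fx$scms, truth[, c("variant_id", "strength_window")],
    by = "variant_id", suffix = c("", "_truth"))
  expect_equal(nrow(cands), 100L)
  expect_true(all(nchar(cands$strength_window[cands$site_type == "donor"])
                  == 9L))
  expect_true(all(nchar(cands$strength_window[cands$site_type == "acceptor"])
                  == 23L))
  expect_equal(cands$strength_window, cands$strength_window_truth)
  # created dinucleotide sits at the documented window positions
  expect_true(all(substr(cands$strength_window[cands$site_type == "donor"],
                         4, 5) == "GT"))
  expect_true(all(substr(cands$strength_window[cands$site_type == "acceptor"],
                         19, 20) == "AG"))
})

test_that("PWM scoring peaks at the consensus and punishes any substitution", {
  # handcrafted training set with a unique argmax at every donor position
  toy <- toy_gene(
    exons = c(paste0(strrep("C", 9), "ATG", ala(25)),
              ala(30), paste0(ala(20), "TAA", strrep("C", 12))),
    introns = c(toy_intron(120L), toy_intron(150L)),
    strand = "+", u5 = 9L, cds_len = 3L * 78L)
  pwm <- train_pwm(toy$db, toy$genome)
  cons <- pwm_consensus(pwm, "donor")
  expect_equal(score_strength(cons$window, "donor", pwm), cons$score)
  for (i in 1:9) {
    for (b in setdiff(c("A", "C", "G", "T"),
                      substr(cons$window, i, i))) {
      w <- cons$window
      substr(w, i, i) <- b
      expect_lt(score_strength(w, "donor", pwm), cons$score)
    }
  }
  # a window scores identically across repeated calls (deterministic)
  expect_equal(score_strength("CAGGTAAGT", "donor", pwm),
               score_strength("CAGGTAAGT", "donor", pwm))
  expect_error(score_strength("CAGGTAAG", "donor", pwm), "9 nt")
  expect_error(score_strength("CAGGTANGT", "donor", pwm), "strict")
})

test_that("maxent table backend loads converted tables and errors without them", {
  expect_error(score_strength("CAGGTAAGT", "donor", "maxent_tables"),
               "table files")
  expect_error(score_strength("CAGGTAAGT", "donor", "pwm"), "trained model")
  expect_error(score_strength("CAGGTAAGT", "donor", "nonsense"),
               "unknown backend")
  # a tiny two-submodel donor table with hand-computable scores
  don <- withr::local_tempfile(fileext = ".tsv")
  acc <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("model\tsign\tpositions\tkmer\tscore",
               "m1\t1\t1,2\tCA\t2",
               "m1\t1\t1,2\tAA\t-1",
               "m2\t-1\t4,5\tGT\t0.5"), don)
  writeLines(c("model\tsign\tpositions\tkmer\tscore",
               "m1\t1\t19,20\tAG\t1"), acc)
  me <- load_maxent_tables(don, acc)
  expect_equal(score_strength("CAGGTAAGT", "donor", me), 2 - 0.5)
  expect_equal(score_strength("AAGGTAAGT", "donor", me), -1 - 0.5)
  expect_error(score_strength("TTGGTAAGT", "donor", me), "absent")
  expect_error(load_maxent_tables("missing-file.tsv", acc), "not found")
})

test_that("delta scores are the maximum gain over annotation entries", {
  v <- tibble::tibble(
    variant_id = c("a", "b", "c"),
    info = c("SpliceAI=G|GENE1|0.91|0.30|0.02|0.10|5|-3|2|7",
             "SpliceAI=T|GENE1|0.00|0.00|0.00|0.00|0|0|0|0",
             paste0("SpliceAI=A|GENE1|0.30|0.00|0.10|0.00|0|0|0|0,",
                    "A|GENE2|0.20|0.00|0.85|0.00|0|0|0|0")))
  got <- read_delta_score(v)
  expect_equal(got$delta_score, c(0.91, 0.0, 0.85))
  # numeric override field; absence is an error
  expect_equal(read_delta_score(
    tibble::tibble(variant_id = "d", info = "DS=0.42"))$delta_score, 0.42)
  expect_error(read_delta_score(
    tibble::tibble(variant_id = "e", info = "AF=0.1")),
    "no delta score source")
})

test_that("cascade recovers exactly the planted calls with a monotone trace", {
  fx <- shared_fixture()
  truth_ids <- fx$planted$truth$variant_id[fx$planted$truth$class == "true"]
  got <- unique(fx$scms$variant_id)
  expect_setequal(got, truth_ids)
  tr <- filter_trace(fx$scms)
  expect_true(all(diff(tr$n_variants) <= 0))
  expect_equal(tr$n_variants[tr$stage == "input"], 500L)
  expect_equal(tr$n_variants[tr$stage == "delta_score"], 100L)
  # each negative class dies at its designed stage
  expect_equal(tr$n_variants[tr$stage == "region"], 400L)            # deep
  expect_equal(tr$n_variants[tr$stage == "dinucleotide_creation"], 300L)
  expect_equal(tr$n_variants[tr$stage == "allele_frequency"], 200L)  # af 0.05
  # tidiers expose the trace and the settings
  expect_equal(tidy(fx$scms), tr)
  gl <- glance(fx$scms)
  expect_equal(gl$n_accepted_variants, 100L)
  expect_equal(gl$min_delta, 0.8)
})

test_that("borderline allele frequency and delta score are filtered as specified", {
  fx <- small_fixture()
  v <- fx$planted$variants
  truth <- fx$planted$truth
  one_true <- truth$variant_id[truth$class == "true"][1]
  # AF 0.02 fails the <= 0.01 rule even with everything else passing
  v_af <- dplyr::mutate(v, af = ifelse(variant_id == one_true, 0.02, af))
  got <- run_filter_cascade(v_af, fx$planted$genome, fx$planted$db)
  expect_false(one_true %in% got$variant_id)
  # delta 0.79 fails the >= 0.80 rule
  v_d <- v
  i <- v_d$variant_id == one_true
  v_d$info[i] <- sub("\\|0\\.92\\|", "|0.79|", v_d$info[i])
  v_d$info[i] <- sub("\\|0\\.92\\|", "|0.79|", v_d$info[i])
  got <- run_filter_cascade(v_d, fx$planted$genome, fx$planted$db)
  expect_false(one_true %in% got$variant_id)
  # unknown AF passes with a warning, tallied in the trace attributes
  v_na <- dplyr::mutate(v, af = ifelse(variant_id == one_true, NA, af),
                        info = ifelse(variant_id == one_true,
                                      sub("^AF=[^;]+;", "", info), info))
  expect_warning(
    got <- run_filter_cascade(v_na, fx$planted$genome, fx$planted$db),
    "unknown allele frequency")
  expect_true(one_true %in% got$variant_id)
  expect_equal(attr(got, "n_unknown_af"), 1L)
})

test_that("strength, AF and delta filters commute", {
  fx <- shared_fixture()
  loose <- run_filter_cascade(
    fx$planted$variants, fx$planted$genome, fx$planted$db,
    thresholds = list(min_strength = -Inf, max_af = 1, min_delta = 0))
  final <- dplyr::filter(loose, strength_score >= 0,
                         is.na(af) | af <= 0.01, delta_score >= 0.80)
  final2 <- dplyr::filter(loose, delta_score >= 0.80) |>
    dplyr::filter(is.na(af) | af <= 0.01) |>
    dplyr::filter(strength_score >= 0)
  expect_setequal(final$variant_id, final2$variant_id)
  expect_setequal(final$variant_id, fx$scms$variant_id)
})

test_that("discovery is symmetric under reverse complement of the whole world", {
  fx <- small_fixture()
  fw <- run_filter_cascade(fx$planted$variants, fx$planted$genome,
                           fx$planted$db)
  flip <- flip_world(fx$planted$genome, fx$planted$db, fx$planted$variants)
  rv <- run_filter_cascade(flip$variants, flip$genome, flip$db)
  expect_setequal(fw$variant_id, rv$variant_id)
  m <- dplyr::inner_join(
    tibble::as_tibble(fw)[, c("variant_id", "site_type", "strength_window")],
    tibble::as_tibble(rv)[, c("variant_id", "site_type", "strength_window")],
    by = "variant_id")
  expect_equal(m$site_type.x, m$site_type.y)
  expect_equal(m$strength_window.x, m$strength_window.y)
})

test_that("accepted dinucleotides re-read as GT/AG from the mutated genome", {
  fx <- shared_fixture()
  mut <- apply_variants_to_reference(
    fx$planted$genome,
    dplyr::distinct(tibble::as_tibble(fx$scms)[, c("contig", "pos", "ref", "alt")]))
  for (i in seq_len(nrow(fx$scms))) {
    r <- fx$scms[i, ]
    pair <- get_seq(mut, r$contig, r$dinuc_start, r$dinuc_end, r$site_strand)
    expect_equal(pair, if (r$site_type == "donor") "GT" else "AG")
  }
})
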