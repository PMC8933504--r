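# Positional-frequency and mutational-spectrum summaries of accepted calls,
# tandem-site motif tagging, and splice-site information content.

# signed position of each variant base relative to its annotated boundary,
# on the axis used for positional spectra: donors count exonic bases
# negative (-1 = last exonic base) and intronic positive (+1 = first
# intronic base); acceptors count intronic negative (-1 = last intronic
# base) and exonic positive (+1 = first exonic base). There is no 0.
boundary_relative_position <- function(junctions) {
  dir <- ifelse(junctions$site_strand == "+", 1L, -1L)
  delta <- (junctions$pos - junctions$annotated_boundary) * dir
  ifelse(junctions$site_type == "donor",
         ifelse(delta >= 1L, delta, delta - 1L),
         ifelse(delta >= 0L, delta + 1L, delta))
}

#' Bin accepted calls by position and alternate base
#'
#' Counts calls per (site type, signed boundary-relative position, alternate
#' base), strand-resolved so that the alternate base is reported in
#' splice-site orientation. Calls farther than `window` nt from the
#' annotated boundary are not binned; their count is kept in the
#' `out_of_window` attribute so totals are conserved.
#'
#' @param junctions Junction-annotated calls
#'   (see [derive_novel_junction()]).
#' @param window Half-width of the positional window (default 20).
#' @return Tibble `site_type`, `position`, `alt_base`, `count`, with
#'   attribute `out_of_window`.
#' @export
bin_positions <- function(junctions, window = 20L) {
  if (nrow(junctions) == 0L) {
    out <- tibble(site_type = character(), position = integer(),
                  alt_base = character(), count = integer())
    attr(out, "out_of_window") <- 0L
    return(out)
  }
  pos <- boundary_relative_position(junctions)
  alt_site <- ifelse(junctions$site_strand == "+", junctions$alt,
                     comp_base(junctions$alt))
  inside <- abs(pos) <= window
  out <- tibble(site_type = junctions$site_type[inside],
                position = pos[inside], alt_base = alt_site[inside]) |>
    count(site_type, position, alt_base, name = "count") |>
    arrange(site_type, position, alt_base)
  attr(out, "out_of_window") <- sum(!inside)
  out
}

#' Tag tandem splice-site motifs created 3 nt from the annotated site
#'
#' A created donor GT lying exactly 3 nt from the annotated GT forms a
#' GYNGYN tandem donor; a created acceptor AG 3 nt from the annotated AG
#' forms a NAGNAG tandem acceptor. The pattern is checked on the
#' post-mutation sequence, strand-resolved.
#'
#' @param junctions Junction-annotated calls (see
#'   [derive_novel_junction()]).
#' @param genome The *reference* `DNAStringSet`; each call's own SNV is
#'   applied before pattern matching.
#' @return The tibble with a `motif_tag` column
#'   (`"GYNGYN"`, `"NAGNAG"` or `"none"`).
#' @export
tag_motif <- function(junctions, genome) {
  tag <- vapply(seq_len(nrow(junctions)), function(i) {
    r <- junctions[i, ]
    dir <- if (r$site_strand == "+") 1L else -1L
    d_first <- if (dir == 1L) r$dinuc_start else r$dinuc_end
    if (r$site_type == "donor") {
      anno_first <- r$annotated_boundary + dir     # annotated GT first base
    } else {
      anno_first <- r$annotated_boundary - 2L * dir  # annotated AG first base
    }
    if (abs(d_first - anno_first) != 3L) return("none")
    mut <- apply_variants_to_reference(
      genome, r[, c("contig", "pos", "ref", "alt")])
    # strand-oriented 6-mer anchored at the transcriptionally earlier site
    f <- if (tx_after(r$site_strand, d_first, anno_first)) anno_first else
      d_first
    if (r$site_type == "donor") {
      s <- if (dir == 1L) get_seq(mut, r$contig, f, f + 5L, "+") else
        get_seq(mut, r$contig, f - 5L, f, "-")
      ok <- substr(s, 1, 1) == "G" && substr(s, 2, 2) %in% c("C", "T") &&
        substr(s, 4, 4) == "G" && substr(s, 5, 5) %in% c("C", "T")
      if (ok) "GYNGYN" else "none"
    } else {
      # include one N base before the earlier AG: N A G N A G
      s <- if (dir == 1L) get_seq(mut, r$contig, f - 1L, f + 4L, "+") else
        get_seq(mut, r$contig, f - 4L, f + 1L, "-")
      ok <- substr(s, 2, 2) == "A" && substr(s, 3, 3) == "G" &&
        substr(s, 5, 5) == "A" && substr(s, 6, 6) == "G"
      if (ok) "NAGNAG" else "none"
    }
  }, character(1))
  mutate(junctions, motif_tag = tag)
}

#' Per-position information content of aligned splice-site windows
#'
#' For each window position `i`, `IC_i = 2 + sum_b p_bi * log2(p_bi)` bits
#' (with `0 * log 0 := 0`); no small-sample correction is applied. 2 bits is
#' a fully conserved position, 0 a uniformly random one.
#'
#' @param windows Character vector of equal-length DNA strings (>= 1).
#' @return Tibble `position`, `ic` (bits, in `[0, 2]`).
#' @export
information_content <- function(windows) {
  if (length(windows) == 0L) abort("need at least one window")
  if (length(unique(nchar(windows))) != 1L) {
    abort("windows must have equal lengths")
  }
  m <- do.call(rbind, strsplit(windows, ""))
  ic <- vapply(seq_len(ncol(m)), function(i) {
    p <- table(factor(m[, i], levels = c("A", "C", "G", "T"))) / nrow(m)
    p <- as.numeric(p)
    2 + sum(ifelse(p > 0, p * log2(p), 0))
  }, numeric(1))
  tibble(position = seq_len(ncol(m)), ic = ic)
}
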