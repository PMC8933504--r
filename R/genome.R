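#' Read a reference genome from FASTA
#'
#' Loads a (multi-)FASTA file into a named `DNAStringSet`. Contig names are
#' taken from the first whitespace-delimited token of each header line, the
#' convention used by FASTA index sidecars. Sequences are uppercased so that
#' downstream dinucleotide comparisons are case-insensitive.
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @return A named [Biostrings::DNAStringSet-class], one entry per contig.
#' @export
read_genome <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  names(dna) <- sub("\\s.*$", "", names(dna))
  Biostrings::DNAStringSet(toupper(dna))
}

#' Write a genome to FASTA
#'
#' @param genome A named `DNAStringSet`.
#' @param path Output FASTA path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  Biostrings::writeXStringSet(genome, path, width = width)
  invisible(path)
}

#' Extract a strand-resolved genomic subsequence
#'
#' Coordinates are 1-based inclusive. Minus-strand retrieval returns the
#' reverse complement of the plus-strand sequence, so the result always reads
#' 5' to 3' on the requested strand and has exactly `end - start + 1` bases.
#'
#' @param genome A named `DNAStringSet` (see [read_genome()]).
#' @param contig Contig name.
#' @param start,end 1-based inclusive genomic coordinates (`start <= end`).
#' @param strand `"+"` or `"-"`.
#' @return A character scalar of DNA.
#' @export
get_seq <- function(genome, contig, start, end, strand = "+") {
  if (!contig %in% names(genome)) {
    abort(paste0("unknown contig: ", contig))
  }
  w <- length(genome[[contig]])
  if (start < 1L || end > w || start > end) {
    abort(sprintf("coordinates [%d, %d] out of range for contig %s (1..%d)",
                  start, end, contig, w))
  }
  s <- as.character(Biostrings::subseq(genome[[contig]], start, end))
  if (identical(strand, "-")) s <- revcomp(s) else s
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

#' Apply SNVs to a reference genome
#'
#' Builds a personalised genome by substituting the ALT base at every variant
#' position. Used both to re-read created splice dinucleotides from mutated
#' sequence and to emulate personal-reference construction for junction-read
#' mapping. Sequence lengths are preserved; only SNVs are accepted.
#'
#' @param genome A named `DNAStringSet`.
#' @param variants A variants tibble with columns `contig`, `pos`, `ref`,
#'   `alt` (see [read_vcf()]).
#' @return A mutated `DNAStringSet` of identical shape.
#' @export
apply_variants_to_reference <- function(genome, variants) {
  if (nrow(variants) == 0L) return(genome)
  if (any(nchar(variants$ref) != 1L | nchar(variants$alt) != 1L)) {
    abort("only SNVs are supported (single-base ref and alt)")
  }
  key <- paste(variants$contig, variants$pos)
  if (anyDuplicated(key)) {
    abort("position collision: two variants at one genomic position")
  }
  out <- genome
  for (ctg in unique(variants$contig)) {
    v <- variants[variants$contig == ctg, ]
    if (!ctg %in% names(out)) abort(paste0("unknown contig: ", ctg))
    seq <- out[[ctg]]
    have <- as.character(Biostrings::extractAt(
      seq, IRanges::IRanges(v$pos, v$pos)))
    bad <- which(have != v$ref)
    if (length(bad) > 0L) {
      abort(sprintf("ref mismatch at %s:%d (genome %s, variant ref %s)",
                    ctg, v$pos[bad[1]], have[bad[1]], v$ref[bad[1]]))
    }
    out[[ctg]] <- Biostrings::replaceLetterAt(
      seq, v$pos, paste(v$alt, collapse = ""))
  }
  out
}
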