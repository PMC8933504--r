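# Protein-domain annotations and the domain-disruption / pathogenic-potential
# calls layered on top of consequence classification.

#' Read a protein-domain table
#'
#' Accepts either hmmscan `--domtblout` output (whitespace-delimited; domain
#' name from the target column, protein from the query column, per-domain
#' independent E-value, alignment coordinates) or a simplified TSV with
#' columns `protein_id`, `domain`, `aa_start`, `aa_end`, `evalue`. Domains
#' with E-value above `max_evalue` are dropped on load.
#'
#' @param path Path to the table.
#' @param format `"auto"` (default), `"domtblout"` or `"tsv"`.
#' @param max_evalue Retention threshold on the E-value (default 0.001).
#' @return Tibble `protein_id`, `domain_name`, `aa_start`, `aa_end`,
#'   `e_value`, filtered to `e_value <= max_evalue`.
#' @export
read_domain_table <- function(path, format = c("auto", "domtblout", "tsv"),
                              max_evalue = 0.001) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "#") || !grepl("\t", first)) "domtblout"
      else "tsv"
  }
  if (format == "domtblout") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    f <- strsplit(trimws(lines), "\\s+")
    bad <- which(vapply(f, length, integer(1)) < 22L)
    if (length(bad)) {
      abort(sprintf("malformed domtblout line %d: fewer than 22 fields",
                    bad[1]))
    }
    out <- tibble(
      protein_id = vapply(f, `[[`, character(1), 4L),
      domain_name = vapply(f, `[[`, character(1), 1L),
      aa_start = as.integer(vapply(f, `[[`, character(1), 18L)),
      aa_end = as.integer(vapply(f, `[[`, character(1), 19L)),
      e_value = as.numeric(vapply(f, `[[`, character(1), 13L))
    )
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("protein_id", "domain", "aa_start", "aa_end", "evalue")
    if (!all(need %in% names(tab))) {
      abort(paste0("simplified domain TSV needs columns: ",
                   paste(need, collapse = ", ")))
    }
    out <- tibble(
      protein_id = as.character(tab$protein_id),
      domain_name = as.character(tab$domain),
      aa_start = as.integer(tab$aa_start),
      aa_end = as.integer(tab$aa_end),
      e_value = as.numeric(tab$evalue)
    )
  }
  filter(out, e_value <= max_evalue)
}

#' Domains intersecting an altered amino-acid interval
#'
#' @param aa_start,aa_end 1-based inclusive interval of altered residues.
#' @param domains Domain tibble (see [read_domain_table()]), already
#'   filtered at the E-value threshold.
#' @return Character vector of disrupted domain names (>= 1 shared residue).
#' @export
domain_overlap <- function(aa_start, aa_end, domains) {
  if (is.null(domains) || nrow(domains) == 0L || is.na(aa_start)) {
    return(character(0))
  }
  unique(domains$domain_name[domains$aa_start <= aa_end &
                               domains$aa_end >= aa_start])
}

#' Flag consequence calls with pathogenic potential
#'
#' A call is potentially pathogenic when it introduces a premature
#' termination codon (by frameshift or within the novel exon) or when the
#' altered protein segment disrupts an annotated domain.
#'
#' @param calls Consequence tibble with `category` and (optionally) a
#'   `disrupted_domains` list-column.
#' @return Logical vector, one flag per row.
#' @export
pathogenic_potential <- function(calls) {
  ptc <- !is.na(calls$category) &
    calls$category %in% c("PTC_frameshift", "PTC_in_novel_exon")
  dom <- if ("disrupted_domains" %in% names(calls)) {
    lengths(calls$disrupted_domains) > 0L
  } else rep(FALSE, nrow(calls))
  ptc | dom
}
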