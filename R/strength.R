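# Splice-site strength scoring: a self-trained position-weight-matrix (PWM)
# backend (default, no external data needed) and a loader for externally
# supplied maximum-entropy model tables.

# strand-resolved window at an annotated boundary.
# donor:   9-mer  = 3 exonic + 6 intronic, GT at window positions 4-5;
#          `boundary` is the last exonic base (strand-oriented).
# acceptor: 23-mer = 20 intronic + 3 exonic, AG at window positions 19-20;
#          `boundary` is the first exonic base (strand-oriented).
window_at_boundary <- function(genome, contig, strand, boundary, site_type) {
  if (site_type == "donor") {
    if (strand == "+") get_seq(genome, contig, boundary - 2L, boundary + 6L, "+")
    else get_seq(genome, contig, boundary - 6L, boundary + 2L, "-")
  } else {
    if (strand == "+") get_seq(genome, contig, boundary - 20L, boundary + 2L, "+")
    else get_seq(genome, contig, boundary - 2L, boundary + 20L, "-")
  }
}

#' Train position-weight-matrix splice-site models from annotation
#'
#' Collects the strand-resolved sequence windows of every annotated splice
#' site of the representative transcripts (donor: 9-mer, 3 exonic + 6
#' intronic bases; acceptor: 23-mer, 20 intronic + 3 exonic bases) and builds
#' per-position log-odds matrices with pseudocount 1 against the
#' training-set base composition. Deterministic for fixed input: a window's
#' score is then `sum_i log2(p[b_i, i] / q[b_i])`, so a score of 0 means
#' "no better than background".
#'
#' @param db A `transcript_db`.
#' @param genome A `DNAStringSet`.
#' @return An object of class `pwm_model` with elements `donor`, `acceptor`
#'   (4 x width log-odds matrices), `bg` (background base frequencies) and
#'   `n_windows`.
#' @export
train_pwm <- function(db, genome) {
  donors <- character()
  acceptors <- character()
  for (tm in representative_models(db)) {
    intr <- introns(tm)
    if (nrow(intr) == 0L) next
    for (i in seq_len(nrow(intr))) {
      if (tm$strand == "+") {
        d_boundary <- intr$start[i] - 1L   # last exonic base, upstream exon
        a_boundary <- intr$end[i] + 1L     # first exonic base, downstream exon
      } else {
        d_boundary <- intr$end[i] + 1L
        a_boundary <- intr$start[i] - 1L
      }
      dw <- tryCatch(window_at_boundary(genome, tm$contig, tm$strand,
                                        d_boundary, "donor"),
                     error = function(e) NA_character_)
      aw <- tryCatch(window_at_boundary(genome, tm$contig, tm$strand,
                                        a_boundary, "acceptor"),
                     error = function(e) NA_character_)
      if (!is.na(dw) && !grepl("N", dw, fixed = TRUE)) donors <- c(donors, dw)
      if (!is.na(aw) && !grepl("N", aw, fixed = TRUE)) {
        acceptors <- c(acceptors, aw)
      }
    }
  }
  if (length(donors) == 0L || length(acceptors) == 0L) {
    abort("no training windows: annotation has no usable introns")
  }
  bg_counts <- colSums(rbind(base_counts(donors), base_counts(acceptors)))
  bg <- bg_counts / sum(bg_counts)
  structure(list(
    donor = pwm_logodds(donors, bg),
    acceptor = pwm_logodds(acceptors, bg),
    bg = bg,
    n_windows = c(donor = length(donors), acceptor = length(acceptors))
  ), class = "pwm_model")
}

base_counts <- function(windows) {
  m <- do.call(rbind, strsplit(windows, ""))
  t(vapply(c("A", "C", "G", "T"), function(b) sum(m == b),
           numeric(1)))
}

pwm_logodds <- function(windows, bg, pseudocount = 1) {
  m <- do.call(rbind, strsplit(windows, ""))
  w <- ncol(m)
  counts <- vapply(seq_len(w), function(i) {
    vapply(c("A", "C", "G", "T"), function(b) sum(m[, i] == b), numeric(1))
  }, numeric(4))
  p <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  lo <- log2(sweep(p, 1, bg, "/"))
  rownames(lo) <- c("A", "C", "G", "T")
  lo
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("<pwm_model> trained on %d donor / %d acceptor windows\n",
              x$n_windows[["donor"]], x$n_windows[["acceptor"]]))
  invisible(x)
}

#' Load externally supplied maximum-entropy splice-site score tables
#'
#' Reads per-site-type model tables in a plain-text converted layout: a TSV
#' with columns `model` (submodel id), `sign` (+1/-1, how the submodel enters
#' the log-score), `positions` (comma-separated window positions the submodel
#' reads) and `kmer`/`score` pairs giving log2 probabilities (or odds) for
#' every k-mer over those positions. A window's score is
#' `sum over submodels of sign * score(kmer at positions)`; a single
#' full-window submodel degenerates to a plain lookup table.
#'
#' @param donor_file,acceptor_file Paths to the two tables.
#' @return An object of class `maxent_model`.
#' @export
load_maxent_tables <- function(donor_file, acceptor_file) {
  read_one <- function(path) {
    if (!file.exists(path)) {
      abort(paste0("maxent table file not found: ", path))
    }
    tab <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             model = readr::col_character(),
                             sign = readr::col_double(),
                             positions = readr::col_character(),
                             kmer = readr::col_character(),
                             score = readr::col_double()))
    if (!all(c("model", "sign", "positions", "kmer", "score") %in%
               names(tab)) || nrow(tab) == 0L) {
      abort(paste0("malformed maxent table: ", path))
    }
    split(tab, tab$model)
  }
  structure(list(donor = read_one(donor_file),
                 acceptor = read_one(acceptor_file)),
            class = "maxent_model")
}

#' Score a candidate splice-site window
#'
#' @param window A DNA string of the site-appropriate width (donor 9,
#'   acceptor 23).
#' @param site_type `"donor"` or `"acceptor"`.
#' @param backend A trained `pwm_model` (see [train_pwm()]) or a
#'   `maxent_model` (see [load_maxent_tables()]). Passing the bare backend
#'   name without a model is an error.
#' @param strict Error on `N` bases (default TRUE).
#' @return Numeric score in log2-odds units; >= 0 means at least as likely
#'   under the site model as under background.
#' @export
score_strength <- function(window, site_type = c("donor", "acceptor"),
                           backend, strict = TRUE) {
  site_type <- match.arg(site_type)
  if (is.character(backend)) {
    if (backend == "pwm") {
      abort("pwm backend requires a trained model: see train_pwm()")
    }
    if (backend == "maxent_tables") {
      abort(paste0("maxent_tables backend requires table files: ",
                   "see load_maxent_tables()"))
    }
    abort(paste0("unknown backend: ", backend))
  }
  expected <- if (site_type == "donor") 9L else 23L
  if (any(nchar(window) != expected)) {
    abort(sprintf("%s window must be %d nt", site_type, expected))
  }
  if (strict && any(grepl("N", window, fixed = TRUE))) {
    abort("window contains N (strict mode)")
  }
  if (inherits(backend, "pwm_model")) {
    mat <- backend[[site_type]]
    vapply(window, function(w) {
      b <- match(strsplit(w, "")[[1]], rownames(mat))
      sum(mat[cbind(b, seq_along(b))])
    }, numeric(1), USE.NAMES = FALSE)
  } else if (inherits(backend, "maxent_model")) {
    models <- backend[[site_type]]
    vapply(window, function(w) {
      b <- strsplit(w, "")[[1]]
      total <- 0
      for (sub in models) {
        pos <- as.integer(strsplit(sub$positions[1], ",")[[1]])
        kmer <- paste(b[pos], collapse = "")
        hit <- match(kmer, sub$kmer)
        if (is.na(hit)) {
          abort(paste0("k-mer ", kmer, " absent from maxent table"))
        }
        total <- total + sub$sign[1] * sub$score[hit]
      }
      total
    }, numeric(1), USE.NAMES = FALSE)
  } else {
    abort("unknown backend: expected pwm_model or maxent_model")
  }
}

#' Maximum attainable score of a PWM model
#'
#' @param backend A `pwm_model`.
#' @param site_type `"donor"` or `"acceptor"`.
#' @return List with `score` (sum of per-position maxima) and `window` (the
#'   argmax consensus string).
#' @export
pwm_consensus <- function(backend, site_type = c("donor", "acceptor")) {
  site_type <- match.arg(site_type)
  stopifnot(inherits(backend, "pwm_model"))
  mat <- backend[[site_type]]
  idx <- apply(mat, 2, which.max)
  list(score = sum(mat[cbind(idx, seq_len(ncol(mat)))]),
       window = paste(rownames(mat)[idx], collapse = ""))
}
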