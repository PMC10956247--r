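# standard-format readers and writers: FASTA, BED, MEME minimal motif
# format, prediction TSVs, and the plain-text run configuration

#' Read a FASTA file into a tibble
#'
#' Order-preserving; bases are uppercased; record ids are the header up to
#' the first whitespace. Sequences containing non-ACGT letters are kept here
#' and dropped later by [prepare_corpus()] (which logs the count).
#'
#' @param path FASTA file.
#' @return Tibble with `id`, `seq`.
#' @export
read_fasta <- function(path) {
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) abort(paste0("malformed FASTA ", path, ": ",
                                                 conditionMessage(e))))
  if (length(x) == 0) abort(paste0("empty FASTA file: ", path))
  tibble(id = sub("\\s.*$", "", names(x)),
         seq = unname(toupper(as.character(x))))
}

#' Write sequences to FASTA
#'
#' @param sequences Tibble with `id`, `seq`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  write_atomic(path, function(tmp) {
    x <- Biostrings::BStringSet(setNames(sequences$seq, sequences$id))
    Biostrings::writeXStringSet(x, tmp)
  })
  invisible(path)
}

#' Read a prepared corpus directory
#'
#' Reads the `corpus.fa` / `manifest.tsv` pair written by the `prepare`
#' command back into a corpus tibble.
#'
#' @param dir Directory containing `corpus.fa` and `manifest.tsv`.
#' @return Tibble with `id`, `seq`, `label`, `split`, `paired_id`.
#' @export
read_corpus_dir <- function(dir) {
  fa <- file.path(dir, "corpus.fa")
  manifest <- file.path(dir, "manifest.tsv")
  if (!file.exists(fa) || !file.exists(manifest)) {
    abort(paste0(dir, " is not a prepared corpus directory (needs corpus.fa and manifest.tsv)"))
  }
  seqs <- read_fasta(fa)
  meta <- readr::read_tsv(manifest, show_col_types = FALSE, progress = FALSE)
  dplyr::left_join(seqs, meta, by = "id")
}

#' Read a BED file of (possibly scored) intervals
#'
#' BED's 0-based half-open coordinates are converted to the 1-based
#' inclusive coordinates used internally.
#'
#' @param path BED file (3 columns, plus a numeric score in column 4 or 5
#'   when `scored = TRUE`; column 5 wins if both parse, matching
#'   name-then-score BED6 layouts).
#' @param scored Require and read a score column.
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive) and
#'   `score` when requested.
#' @export
read_bed <- function(path, scored = FALSE) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(raw) < 3) abort(paste0(path, " is not a 3+ column BED file"))
  out <- tibble(chrom = as.character(raw[[1]]),
                start = as.integer(raw[[2]]) + 1L,
                end = as.integer(raw[[3]]))
  if (scored) {
    score <- NULL
    for (col in c(5L, 4L)) {
      if (ncol(raw) >= col && is.numeric(raw[[col]])) { score <- raw[[col]]; break }
    }
    if (is.null(score)) abort(paste0(path, " has no numeric score column"))
    out$score <- score
  }
  out
}

#' Write intervals to BED
#'
#' Converts the 1-based inclusive internal coordinates back to BED's 0-based
#' half-open convention. Extra columns (`name`, `score`, `strand`) are
#' written when present.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  out <- tibble(chrom = intervals$chrom,
                start = intervals$start - 1L,
                end = intervals$end)
  for (col in c("name", "score", "strand")) {
    if (col %in% names(intervals)) out[[col]] <- intervals[[col]]
  }
  write_atomic(path, function(tmp) {
    readr::write_tsv(out, tmp, col_names = FALSE)
  })
  invisible(path)
}

#' Write motifs in MEME minimal format
#'
#' Emits the version line, `ALPHABET= ACGT`, strand line, uniform background
#' frequencies, and one `letter-probability matrix` block per motif with its
#' width and supporting-site count; probabilities are printed to 6 decimals.
#' The file is consumable by TOMTOM-style motif-comparison tools.
#'
#' @param motif_set A `"motif_set"` from [find_motifs()], or a bare list of
#'   motifs (each with `pwm` and `nsites`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motif_set, path) {
  motifs <- if (inherits(motif_set, "motif_set")) motif_set$motifs else motif_set
  if (length(motifs) == 0) warn("writing a MEME file with no motifs (header only)")
  write_atomic(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(c("MEME version 4", "",
                 "ALPHABET= ACGT", "",
                 "strands: + -", "",
                 "Background letter frequencies",
                 "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
    for (i in seq_along(motifs)) {
      mo <- motifs[[i]]
      w <- ncol(mo$pwm)
      writeLines(sprintf("MOTIF motif_%d %s", i,
                         mo$consensus %||% pwm_consensus(mo$pwm)), con)
      writeLines(sprintf(
        "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0", w,
        mo$nsites), con)
      for (j in seq_len(w)) {
        writeLines(paste(sprintf("%.6f", mo$pwm[, j]), collapse = " "), con)
      }
      writeLines("", con)
    }
  })
  invisible(path)
}

#' Parse a MEME minimal motif file
#'
#' @param path A file written by [write_meme()] (or any MEME minimal file
#'   over the ACGT alphabet).
#' @return A list of motifs, each with `pwm`, `nsites`, `length`, `name`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  purrr::map(starts, function(s) {
    name <- strsplit(lines[s], "\\s+")[[1]][2]
    hdr <- lines[s + 1]
    if (!grepl("letter-probability matrix", hdr)) {
      abort(paste0("malformed MEME motif block at line ", s + 1))
    }
    w <- as.integer(sub(".*w= *(\\d+).*", "\\1", hdr))
    nsites <- as.integer(sub(".*nsites= *(\\d+).*", "\\1", hdr))
    rows <- lines[(s + 2):(s + 1 + w)]
    pwm <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }, numeric(4), USE.NAMES = FALSE))
    pwm <- t(pwm)
    rownames(pwm) <- DNA_BASES
    list(pwm = structure(pwm, class = c("pwm", "matrix")),
         nsites = nsites, length = w, name = name,
         consensus = pwm_consensus(pwm))
  })
}

#' Default run configuration
#'
#' Every tunable of the pipeline, with its default, as a flat named list.
#' [write_run_config()] serializes it as `key = value` lines and
#' [read_run_config()] parses it back (types inferred from the defaults;
#' unknown keys are rejected), so `read(write(c))` round-trips.
#'
#' @return Named list of class `"run_config"`.
#' @export
default_run_config <- function() {
  structure(list(
    lenk = 5L, flank = 50L, top_n = 1500L,
    dc = 50L, ds = 50L, dj = 50L, dsq = 150L,
    epochs = 30L, lr = 0.001, decay = 0.001, loss = "iterloss",
    threshold = 0.5, min_sites = 5L, pseudocount = 0.25,
    max_mismatch = 0.25, mi_method = "cosine", seed = 1L
  ), class = "run_config")
}

#' @rdname default_run_config
#' @param config A `"run_config"` (possibly modified).
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  write_atomic(path, function(tmp) {
    writeLines(vapply(names(config), function(k) {
      v <- config[[k]]
      paste0(k, " = ", format(v, digits = 17, scientific = FALSE))
    }, character(1)), tmp)
  })
  invisible(path)
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  defaults <- default_run_config()
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  config <- defaults
  for (line in lines) {
    parts <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) abort(paste0("malformed config line: ", line))
    k <- trimws(parts[1]); v <- trimws(parts[2])
    if (!k %in% names(defaults)) abort(paste0("unknown config key: ", k))
    config[[k]] <- if (is.integer(defaults[[k]])) as.integer(v)
    else if (is.numeric(defaults[[k]])) as.numeric(v)
    else v
  }
  config
}

#' Write a JSON metrics report
#'
#' @param report Output of [evaluate_predictions()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  values <- as.list(setNames(report$value, report$metric))
  polygon <- radar_vertices(report)
  write_atomic(path, function(tmp) {
    jsonlite::write_json(
      list(metrics = values,
           undefined = report$metric[report$undefined],
           radar_polygon = polygon),
      tmp, auto_unbox = TRUE, digits = NA)
  })
  invisible(path)
}
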