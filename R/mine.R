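#' Find perfect microsatellite repeats in a nucleotide sequence
#'
#' Scans one contig for maximal perfect tandem repeats of primitive di-,
#' tri- and tetra-nucleotide motifs with at least `min_repeats` whole copies.
#' Only perfect repeats count: a trailing partial motif copy is excluded from
#' the tract, and any non-ACGT character (e.g. `N`) terminates a run. Each
#' maximal tract is reported exactly once, labelled with its canonical motif
#' class (lexicographically smallest rotation, strand preserved); a tract of a
#' period-p motif is never also reported under a multiple of p.
#'
#' Loci whose repeat tracts lie within `compound_gap` bases of another
#' reported tract are flagged `compound = TRUE` (informational only).
#'
#' @param sequence character scalar: contig sequence (uppercased on input).
#' @param contig_id character scalar: identifier carried into the output.
#' @param min_repeats minimum number of whole motif copies (default 8).
#' @param periods motif lengths to scan, subset of `c(2, 3, 4)`.
#' @param flank_len bases of flanking sequence to extract on each side for
#'   downstream primer design; clipped at contig edges (default 200).
#' @param compound_gap maximum number of intervening bases for two tracts to
#'   be flagged compound (default 10).
#' @return A data frame of class `"ssr_loci"` with columns `contig`,
#'   `motif_class`, `motif_observed`, `period`, `start`, `end` (0-based
#'   half-open), `repeat_count`, `compound`, `left_flank`, `right_flank`,
#'   ordered by `start`. Zero rows when nothing is found.
#' @examples
#' find_ssrs(paste0(strrep("GATTACCA", 6), strrep("AC", 9)), "c1")
#' @seealso [mine_fasta()] for multi-record FASTA input,
#'   [write_ssr_report()] for TSV/GFF3 output.
#' @export
find_ssrs <- function(sequence, contig_id = "contig",
                      min_repeats = 8L, periods = c(2L, 3L, 4L),
                      flank_len = 200L, compound_gap = 10L) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop("`sequence` must be a single string", call. = FALSE)
  }
  min_repeats <- as.integer(min_repeats)
  if (is.na(min_repeats) || min_repeats < 2L) {
    stop("`min_repeats` must be an integer >= 2", call. = FALSE)
  }
  periods <- unique(as.integer(periods))
  if (length(periods) == 0L || !all(periods %in% 2:4)) {
    stop("`periods` must be a subset of {2, 3, 4}", call. = FALSE)
  }
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < min(periods) * min_repeats) {
    return(empty_ssr_loci())
  }
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  valid <- s %in% c("A", "C", "G", "T")

  rows <- list()
  for (p in sort(periods)) {
    if (L <= p) next
    idx <- seq_len(L - p)
    # m[i] TRUE when position i matches the base one period ahead; a tract of
    # k motif copies is a TRUE-run of length (k-1)*p (+ any partial copy).
    m <- (s[idx] == s[idx + p]) & valid[idx] & valid[idx + p]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- r$values & (r$lengths + p >= min_repeats * p)
    for (j in which(hit)) {
      i0 <- starts[j]                        # 1-based tract start
      k <- (r$lengths[j] + p) %/% p          # whole copies only
      motif <- substr(sequence, i0, i0 + p - 1L)
      if (primitive_period(motif) != p) next # belongs to a shorter period
      rows[[length(rows) + 1L]] <- list(
        start = i0 - 1L, end = i0 - 1L + k * p, period = p,
        motif_observed = motif, motif_class = min_rotation(motif),
        repeat_count = k)
    }
  }
  if (length(rows) == 0L) {
    return(empty_ssr_loci())
  }
  loci <- do.call(rbind, lapply(rows, as.data.frame))
  loci <- loci[order(loci$start, loci$end), , drop = FALSE]

  n <- nrow(loci)
  compound <- logical(n)
  if (n > 1L) {
    gap <- loci$start[-1L] - loci$end[-n]
    near <- gap <= compound_gap
    compound[-n] <- compound[-n] | near
    compound[-1L] <- compound[-1L] | near
  }
  flank_len <- as.integer(flank_len)
  out <- data.frame(
    contig = contig_id,
    motif_class = loci$motif_class,
    motif_observed = loci$motif_observed,
    period = loci$period,
    start = loci$start,
    end = loci$end,
    repeat_count = loci$repeat_count,
    compound = compound,
    left_flank = substr(rep(sequence, n),
                        pmax(1L, loci$start - flank_len + 1L), loci$start),
    right_flank = substr(rep(sequence, n),
                         loci$end + 1L, pmin(L, loci$end + flank_len)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ssr_loci", "data.frame")
  out
}

empty_ssr_loci <- function() {
  out <- data.frame(
    contig = character(0), motif_class = character(0),
    motif_observed = character(0), period = integer(0),
    start = integer(0), end = integer(0), repeat_count = integer(0),
    compound = logical(0), left_flank = character(0),
    right_flank = character(0), stringsAsFactors = FALSE)
  class(out) <- c("ssr_loci", "data.frame")
  out
}

#' Mine microsatellites from a FASTA file
#'
#' Applies [find_ssrs()] to every record of a (plain or gzipped) FASTA file.
#'
#' @param fasta path to a FASTA file, or a named character vector of
#'   sequences (names become contig ids).
#' @inheritParams find_ssrs
#' @return An `"ssr_loci"` data frame combining all contigs, in file order.
#' @export
mine_fasta <- function(fasta, min_repeats = 8L, periods = c(2L, 3L, 4L),
                       flank_len = 200L, compound_gap = 10L) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    contig_ids <- sub("\\s.*$", "", names(seqs))
    seqs <- as.character(seqs)
  } else {
    seqs <- fasta
    contig_ids <- names(seqs)
    if (is.null(contig_ids)) {
      contig_ids <- paste0("contig_", seq_along(seqs))
    }
  }
  res <- mapply(find_ssrs, seqs, contig_ids,
                MoreArgs = list(min_repeats = min_repeats, periods = periods,
                                flank_len = flank_len,
                                compound_gap = compound_gap),
                SIMPLIFY = FALSE)
  out <- do.call(rbind, c(res, list(empty_ssr_loci())))
  rownames(out) <- NULL
  class(out) <- c("ssr_loci", "data.frame")
  out
}

#' Write (and read back) an SSR mining report
#'
#' `write_ssr_report()` serializes mined loci as TSV (0-based half-open
#' coordinates, one row per locus) or GFF3 (1-based inclusive coordinates,
#' feature type `microsatellite`, motif and repeat count in the attributes).
#' `read_ssr_report()` parses the TSV flavour back; the pair round-trips
#' losslessly.
#'
#' @param loci an `"ssr_loci"` data frame from [find_ssrs()]/[mine_fasta()].
#' @param path optional output file; when `NULL` the text is only returned.
#' @param format `"tsv"` or `"gff3"`.
#' @return The report text, invisibly when `path` is given.
#' @export
write_ssr_report <- function(loci, path = NULL, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(loci))
  if (format == "tsv") {
    cols <- c("contig", "motif_class", "motif_observed", "period", "start",
              "end", "repeat_count", "compound", "left_flank", "right_flank")
    header <- paste(cols, collapse = "\t")
    body <- if (nrow(loci) == 0L) character(0) else {
      do.call(paste, c(unname(lapply(loci[cols], as.character)), sep = "\t"))
    }
    text <- paste0(paste(c(header, body), collapse = "\n"), "\n")
  } else {
    lines <- "##gff-version 3"
    if (nrow(loci) > 0L) {
      attrs <- sprintf(
        "ID=ssr_%d;motif=%s;motif_class=%s;repeat_count=%d;compound=%s",
        seq_len(nrow(loci)), loci$motif_observed, loci$motif_class,
        loci$repeat_count, tolower(as.character(loci$compound)))
      lines <- c(lines, paste(loci$contig, "ssrtools", "microsatellite",
                              loci$start + 1L, loci$end, ".", "+", ".",
                              attrs, sep = "\t"))
    }
    text <- paste0(paste(lines, collapse = "\n"), "\n")
  }
  if (!is.null(path)) {
    writeLines(sub("\n$", "", text), path)
    return(invisible(text))
  }
  text
}

#' @rdname write_ssr_report
#' @param file path to, or literal text of, a TSV report.
#' @export
read_ssr_report <- function(file) {
  if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    txt <- readLines(file)
  } else {
    txt <- strsplit(paste(file, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  txt <- txt[nzchar(txt)]
  out <- utils::read.table(text = txt, header = TRUE, sep = "\t",
                           colClasses = c("character", "character",
                                          "character", "integer", "integer",
                                          "integer", "integer", "logical",
                                          "character", "character"),
                           na.strings = NULL, quote = "")
  class(out) <- c("ssr_loci", "data.frame")
  out
}
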