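#' Canonical repeat motif classes
#'
#' A repeat motif class groups all cyclic rotations of a primitive motif:
#' the tract `CACACA...` can be read as `(CA)n` or `(AC)n` depending on frame,
#' but both describe the same locus. The class representative ("canonical"
#' motif) is the lexicographically smallest rotation. Reverse complements are
#' deliberately *not* collapsed: transcript sequence is stranded, so `AC` and
#' `GT` remain distinct classes and mining reports the observed strand.
#'
#' A motif is *primitive* when it is not a whole-number repetition of a
#' shorter motif (`ACAC` is two copies of `AC` and is rejected; so are
#' homopolymers such as `AA`). There are exactly 6 primitive dinucleotide,
#' 20 trinucleotide and 60 tetranucleotide classes.
#'
#' @param periods integer vector, subset of `c(2, 3, 4)`: motif lengths to
#'   enumerate.
#' @return Character vector of canonical motifs, sorted lexicographically.
#' @examples
#' enumerate_motif_classes(2)   # "AC" "AG" "AT" "CG" "CT" "GT"
#' length(enumerate_motif_classes(2:4))  # 86
#' @export
enumerate_motif_classes <- function(periods = c(2L, 3L, 4L)) {
  periods <- unique(as.integer(periods))
  if (length(periods) == 0L || anyNA(periods) || !all(periods %in% 2:4)) {
    stop("`periods` must be a non-empty subset of {2, 3, 4}", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (p in sort(periods)) {
    grid <- do.call(expand.grid,
                    c(rep(list(bases), p), stringsAsFactors = FALSE))
    motifs <- do.call(paste0, grid[rev(seq_len(p))])
    keep <- vapply(motifs, function(m) {
      primitive_period(m) == p && m == min_rotation(m)
    }, logical(1))
    out <- c(out, sort(motifs[keep]))
  }
  out
}

#' Canonicalize a repeat motif
#'
#' Maps a motif to its class representative: the lexicographically smallest
#' cyclic rotation. Non-primitive motifs (whole-number repetitions of a
#' shorter motif, e.g. `"ACAC"` or `"AAA"`) are rejected with an error naming
#' the shorter period, because the corresponding tract belongs to the
#' shorter-period class.
#'
#' @param motif character scalar, 2-4 bases over ACGT (case-insensitive).
#' @return A list with elements `canonical` (character) and `period`
#'   (integer), invisibly classed `"motif_class"`.
#' @examples
#' canonical_motif("CAG")$canonical  # "AGC"
#' canonical_motif("TG")$canonical   # "GT"
#' @export
canonical_motif <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || is.na(motif)) {
    stop("`motif` must be a single string", call. = FALSE)
  }
  motif <- toupper(motif)
  p <- nchar(motif)
  if (p < 2L || p > 4L) {
    stop("motif length must be 2-4, got ", p, call. = FALSE)
  }
  if (grepl("[^ACGT]", motif)) {
    stop("motif contains non-ACGT characters: ", motif, call. = FALSE)
  }
  pp <- primitive_period(motif)
  if (pp != p) {
    stop("degenerate motif '", motif, "': period-", pp,
         " repetition, not a primitive period-", p, " motif", call. = FALSE)
  }
  structure(list(canonical = min_rotation(motif), period = as.integer(p)),
            class = "motif_class")
}

# All cyclic rotations of a short string.
rotations <- function(m) {
  p <- nchar(m)
  vapply(seq_len(p) - 1L, function(k) {
    paste0(substr(m, k + 1L, p), substr(m, 1L, k))
  }, character(1))
}

min_rotation <- function(m) min(rotations(m))

# Smallest d dividing nchar(m) such that m is (d-prefix) repeated.
primitive_period <- function(m) {
  p <- nchar(m)
  for (d in seq_len(p)) {
    if (p %% d == 0L &&
        m == strrep(substr(m, 1L, d), p %/% d)) {
      return(d)
    }
  }
  p
}
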