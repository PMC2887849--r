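#' Multi-population diploid microsatellite genotype table
#'
#' The central container for genotyping data: diploid allele-size calls
#' (fragment lengths in bp, positive integers) for individuals grouped into
#' populations, across a fixed set of loci. Missing data is a distinct state
#' (both alleles `NA`), never an allele code of 0.
#'
#' @param ind_id character vector of individual identifiers.
#' @param ind_pop character vector (same length) of population labels.
#' @param alleles integer array `n_individuals x n_loci x 2` of allele sizes;
#'   a call with any non-positive or `NA` allele is treated as missing.
#' @param loci character vector of locus names (length = `dim(alleles)[2]`).
#' @return An object of class `"genotype_table"`: a list with elements
#'   `loci`, `pops` (unique population labels in order of first appearance),
#'   `ind_id`, `ind_pop` and `alleles`.
#' @export
genotype_table <- function(ind_id, ind_pop, alleles, loci) {
  ind_id <- as.character(ind_id)
  ind_pop <- as.character(ind_pop)
  loci <- as.character(loci)
  stopifnot(length(ind_id) == length(ind_pop))
  if (length(dim(alleles)) != 3L || dim(alleles)[3] != 2L) {
    stop("`alleles` must be an n x loci x 2 array", call. = FALSE)
  }
  if (dim(alleles)[1] != length(ind_id) || dim(alleles)[2] != length(loci)) {
    stop("`alleles` dimensions do not match individuals/loci", call. = FALSE)
  }
  storage.mode(alleles) <- "integer"
  bad <- !is.na(alleles) & alleles <= 0L
  if (any(bad)) alleles[bad] <- NA_integer_
  # half-missing calls become fully missing
  miss <- is.na(alleles[, , 1L, drop = FALSE]) |
    is.na(alleles[, , 2L, drop = FALSE])
  if (any(miss)) {
    alleles[, , 1L][miss[, , 1L]] <- NA_integer_
    alleles[, , 2L][miss[, , 1L]] <- NA_integer_
  }
  if (length(ind_pop) == 0L) {
    stop("a genotype table needs at least one individual", call. = FALSE)
  }
  dimnames(alleles) <- list(ind_id, loci, NULL)
  structure(list(loci = loci, pops = unique(ind_pop), ind_id = ind_id,
                 ind_pop = ind_pop, alleles = alleles),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals, %d populations, %d loci\n",
              length(x$ind_id), length(x$pops), length(x$loci)))
  miss <- mean(is.na(x$alleles[, , 1L]))
  cat(sprintf("  loci: %s\n  missing calls: %.2f%%\n",
              paste(utils::head(x$loci, 8L), collapse = ", "), 100 * miss))
  invisible(x)
}

#' Read a GenePop genotype file
#'
#' Parses the classic GenePop dialect: a title line, locus names (one per
#' line or comma-separated on one line), then population blocks delimited by
#' lines reading `Pop` (any case). Each individual line is
#' `name , a1a2 a1a2 ...` with 2- or 3-digit allele codes; `0000`/`000000`
#' (or any allele code 0) marks a missing call. The population label is taken
#' from the first individual of each block.
#'
#' @param file path to a GenePop file, or its literal text.
#' @return A [genotype_table()].
#' @export
read_genepop <- function(file) {
  if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- strsplit(paste(file, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3L) stop("GenePop file too short", call. = FALSE)
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no 'Pop' line found", call. = FALSE)
  header <- lines[2:(first_pop - 1L)]
  loci <- unlist(strsplit(header, ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L) stop("no locus names found", call. = FALSE)
  n_loci <- length(loci)

  ind_id <- character(0); ind_pop <- character(0)
  geno <- list()
  pop_idx <- 0L
  pop_label <- NA_character_
  for (i in seq(first_pop, length(lines))) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (is_pop[i]) {
      pop_idx <- pop_idx + 1L
      pop_label <- NA_character_
      next
    }
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2L) {
      stop("line ", i, ": expected 'name , genotypes'", call. = FALSE)
    }
    name <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                      "\\s+")[[1]]
    codes <- codes[nzchar(codes)]
    if (length(codes) != n_loci) {
      stop("line ", i, ": ", length(codes), " genotypes for ", n_loci,
           " declared loci", call. = FALSE)
    }
    w <- nchar(codes)
    if (any(w != 4L & w != 6L) || any(grepl("\\D", codes))) {
      stop("line ", i, ": genotype codes must be 4 or 6 digits",
           call. = FALSE)
    }
    half <- w %/% 2L
    a1 <- as.integer(substr(codes, 1L, half))
    a2 <- as.integer(substr(codes, half + 1L, w))
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    if (is.na(pop_label)) pop_label <- name
    ind_id <- c(ind_id, name)
    ind_pop <- c(ind_pop, pop_label)
    geno[[length(geno) + 1L]] <- cbind(a1, a2)
  }
  if (length(geno) == 0L) stop("no individuals found", call. = FALSE)
  alleles <- array(NA_integer_, c(length(geno), n_loci, 2L))
  for (j in seq_along(geno)) alleles[j, , ] <- geno[[j]]
  genotype_table(ind_id, ind_pop, alleles, loci)
}

#' Write a genotype table in GenePop format
#'
#' @param table a [genotype_table()].
#' @param path optional output file.
#' @param digits allele code width, 2 or 3 (default 3). Allele sizes that do
#'   not fit the width are an error.
#' @param title title line (first line of the file).
#' @return The GenePop text, invisibly when `path` is given.
#' @export
write_genepop <- function(table, path = NULL, digits = 3L,
                          title = "ssrtools export") {
  stopifnot(inherits(table, "genotype_table"), digits %in% c(2L, 3L))
  amax <- suppressWarnings(max(table$alleles, na.rm = TRUE))
  if (is.finite(amax) && amax >= 10^digits) {
    stop("allele size ", amax, " does not fit ", digits, "-digit codes",
         call. = FALSE)
  }
  fmt <- paste0("%0", digits, "d")
  lines <- c(title, table$loci)
  for (p in table$pops) {
    lines <- c(lines, "Pop")
    for (j in which(table$ind_pop == p)) {
      a <- table$alleles[j, , , drop = FALSE]
      code <- paste0(sprintf(fmt, ifelse(is.na(a[1, , 1]), 0L, a[1, , 1])),
                     sprintf(fmt, ifelse(is.na(a[1, , 2]), 0L, a[1, , 2])))
      lines <- c(lines, paste0(table$ind_id[j], " ,  ",
                               paste(code, collapse = " ")))
    }
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(text))
  }
  text
}

#' Read/write a long-format genotype TSV
#'
#' A simple interchange format with one row per individual/locus call:
#' columns `individual`, `population`, `locus`, `allele1`, `allele2`
#' (empty/NA = missing).
#'
#' @param file path or literal TSV text.
#' @return `read_genotypes_tsv()`: a [genotype_table()].
#' @export
read_genotypes_tsv <- function(file) {
  if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    df <- utils::read.table(file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(text = file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  }
  need <- c("individual", "population", "locus", "allele1", "allele2")
  if (!all(need %in% names(df))) {
    stop("TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  inds <- unique(df[c("individual", "population")])
  loci <- unique(df$locus)
  alleles <- array(NA_integer_, c(nrow(inds), length(loci), 2L))
  ii <- match(df$individual, inds$individual)
  jj <- match(df$locus, loci)
  alleles[cbind(ii, jj, 1L)] <- as.integer(df$allele1)
  alleles[cbind(ii, jj, 2L)] <- as.integer(df$allele2)
  genotype_table(inds$individual, inds$population, alleles, loci)
}

#' @rdname read_genotypes_tsv
#' @param table a [genotype_table()].
#' @param path optional output file.
#' @export
write_genotypes_tsv <- function(table, path = NULL) {
  n <- length(table$ind_id); L <- length(table$loci)
  df <- data.frame(
    individual = rep(table$ind_id, times = L),
    population = rep(table$ind_pop, times = L),
    locus = rep(table$loci, each = n),
    allele1 = as.vector(table$alleles[, , 1L]),
    allele2 = as.vector(table$alleles[, , 2L]),
    stringsAsFactors = FALSE)
  text <- paste0(paste(c(paste(names(df), collapse = "\t"),
                         do.call(paste, c(df, sep = "\t"))),
                       collapse = "\n"), "\n")
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(text))
  }
  text
}

#' Allele frequencies at a locus
#'
#' Frequencies are computed over the `2 * n` gene copies of the non-missing
#' individuals in scope (one population, or all populations pooled).
#'
#' @param table a [genotype_table()].
#' @param locus locus name.
#' @param population a population label, or `NULL` for all individuals
#'   pooled.
#' @return A named numeric vector of frequencies summing to 1, names being
#'   allele sizes; `NULL` when the scope has no data (distinct from a zero
#'   frequency).
#' @export
allele_frequencies <- function(table, locus, population = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  j <- match(locus, table$loci)
  if (is.na(j)) stop("unknown locus: ", locus, call. = FALSE)
  keep <- if (is.null(population)) rep(TRUE, length(table$ind_pop)) else {
    if (!population %in% table$pops) {
      stop("unknown population: ", population, call. = FALSE)
    }
    table$ind_pop == population
  }
  a <- c(table$alleles[keep, j, 1L], table$alleles[keep, j, 2L])
  a <- a[!is.na(a)]
  if (length(a) == 0L) return(NULL)
  tab <- table(a)
  stats::setNames(as.numeric(tab) / length(a), names(tab))
}

#' Per-locus summary statistics
#'
#' For each locus, over **all** individuals pooled: the number of distinct
#' alleles, observed heterozygosity `H_o` (heterozygotes / non-missing
#' individuals), expected heterozygosity `H_e = 1 - sum(p^2)` from pooled
#' allele frequencies (gene diversity; optional small-sample correction
#' `2n/(2n-1)`), and percent missing calls. When populations are
#' differentiated, pooling legitimately depresses `H_o` relative to `H_e`
#' (Wahlund effect).
#'
#' @param table a [genotype_table()].
#' @param groups optional named vector mapping locus name to a multiplex
#'   group label (e.g. PCR mix number), carried into the output.
#' @param bias_correct apply the `2n/(2n-1)` small-sample correction to
#'   `H_e` (default `FALSE`).
#' @return A data frame with columns `locus`, `n_typed`, `allele_count`,
#'   `H_o`, `H_e`, `percent_missing`, `group`. A locus with no data gets
#'   `NA` statistics (not zeros).
#' @export
locus_summaries <- function(table, groups = NULL, bias_correct = FALSE) {
  stopifnot(inherits(table, "genotype_table"))
  n_ind <- length(table$ind_id)
  out <- lapply(seq_along(table$loci), function(j) {
    a1 <- table$alleles[, j, 1L]; a2 <- table$alleles[, j, 2L]
    typed <- !is.na(a1)
    n <- sum(typed)
    if (n == 0L) {
      return(data.frame(locus = table$loci[j], n_typed = 0L,
                        allele_count = NA_integer_, H_o = NA_real_,
                        H_e = NA_real_,
                        percent_missing = 100, stringsAsFactors = FALSE))
    }
    p <- allele_frequencies(table, table$loci[j])
    he <- 1 - sum(p^2)
    if (bias_correct) he <- he * (2 * n) / (2 * n - 1)
    data.frame(locus = table$loci[j], n_typed = n,
               allele_count = length(p),
               H_o = sum(a1[typed] != a2[typed]) / n,
               H_e = he,
               percent_missing = 100 * (n_ind - n) / n_ind,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$group <- if (is.null(groups)) NA_character_ else {
    as.character(groups[out$locus])
  }
  rownames(out) <- NULL
  out
}
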