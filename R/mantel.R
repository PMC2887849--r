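#' Permutation Mantel test between two labelled distance matrices
#'
#' Measures concordance between two distance matrices (e.g. pairwise Fst
#' from two marker systems) as the Pearson correlation `r` over the
#' `n(n-1)/2` off-diagonal pairs, with significance from a permutation null:
#' rows and columns of the second matrix are permuted simultaneously
#' `n_perm` times and the p-value is `(1 + #{r_perm >= r_obs}) / (1 + n_perm)`
#' for the default one-sided "greater" alternative (the two-sided variant
#' compares `|r_perm|` to `|r_obs|`). The add-one rule means p is never 0
#' and has resolution `1/(n_perm + 1)`.
#'
#' Matrices are aligned **by label**, not by row position, which guards
#' against silent row-order mismatches; their label sets must be identical.
#' Pairs undefined (`NA`) in either matrix are dropped pairwise with a
#' warning. Note the permutation null is the standard Mantel construction:
#' resampling schemes that bootstrap pairs independently would break the
#' exchangeability the test relies on.
#'
#' @param a,b symmetric numeric matrices with identical label sets as
#'   dimnames (order may differ).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for the permutation generator (optional but
#'   recommended; recorded in the result).
#' @param alternative `"greater"` (default), `"two.sided"` or `"less"`.
#' @return A list of class `"mantel_result"`: `r`, `p`, `n_perm`,
#'   `n_labels`, `n_pairs`, `alternative`, `seed`.
#' @export
mantel_test <- function(a, b, n_perm = 10000L, seed = NULL,
                        alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) {
    stop("`n_perm` must be a positive integer", call. = FALSE)
  }
  stopifnot(is.matrix(a), is.matrix(b))
  la <- rownames(a); lb <- rownames(b)
  if (is.null(la) || is.null(lb)) {
    stop("both matrices need row/column labels", call. = FALSE)
  }
  if (!setequal(la, lb)) {
    stop("label sets differ; only in first: {",
         paste(setdiff(la, lb), collapse = ", "), "}; only in second: {",
         paste(setdiff(lb, la), collapse = ", "), "}", call. = FALSE)
  }
  b <- b[la, la, drop = FALSE]
  n <- length(la)
  if (n < 4L) stop("need >= 4 labels for a Mantel test", call. = FALSE)
  ut <- upper.tri(a)
  va <- a[ut]; vb <- b[ut]
  keep <- !is.na(va) & !is.na(vb)
  if (!all(keep)) {
    warning(sum(!keep), " undefined pair(s) dropped from both matrices")
  }
  r_obs <- stats::cor(va[keep], vb[keep])

  with_seed(seed, {
    count <- 0L
    for (k in seq_len(n_perm)) {
      perm <- sample.int(n)
      vp <- b[perm, perm][ut]
      r_p <- stats::cor(va[keep], vp[keep])
      hit <- switch(alternative,
                    greater = r_p >= r_obs,
                    less = r_p <= r_obs,
                    two.sided = abs(r_p) >= abs(r_obs))
      if (isTRUE(hit)) count <- count + 1L
    }
  })
  structure(list(r = r_obs, p = (1 + count) / (1 + n_perm),
                 n_perm = n_perm, n_labels = n, n_pairs = sum(keep),
                 alternative = alternative,
                 seed = if (is.null(seed)) NA_integer_ else
                   as.integer(seed)),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf(
    "Mantel test: r = %.4f, p = %.4g (%s, %d permutations, n = %d)\n",
    x$r, x$p, x$alternative, x$n_perm, x$n_labels))
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's global RNG state is untouched. `seed = NULL` uses (and advances)
# the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
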