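#' Build a 2x2 haplotype-carrier contingency table for one site
#'
#' Counts, at a single site, how many mutant-labeled and wild-type-labeled
#' haplotypes carry the variant allele.  The table feeds
#' [fisher_one_sided_greater()]: `a` mutant haplotypes carrying, `b` mutant
#' not carrying, `c` wild-type carrying, `d` wild-type not carrying.
#'
#' @param site site identifier (position) present in the common site index.
#' @param mutant_vectors,wildtype_vectors lists of haplotype vectors as
#'   returned by [extract_haplotype_vectors()], or a binary matrix with
#'   sites as columns (column names = site index).
#' @return object of class `counts2x2`: list with integer fields
#'   `a`, `b`, `c`, `d`.
#' @export
tabulate_haplotype_counts <- function(site, mutant_vectors, wildtype_vectors) {
  mm <- .stack_vectors(mutant_vectors)
  wm <- .stack_vectors(wildtype_vectors)
  key <- as.character(site)
  if (!key %in% colnames(mm) || !key %in% colnames(wm)) {
    stop("site ", key, " absent from the common site index")
  }
  a <- sum(mm[, key] == 1L)
  c_ <- sum(wm[, key] == 1L)
  counts2x2(a, nrow(mm) - a, c_, nrow(wm) - c_)
}

#' Construct a 2x2 haplotype contingency table
#'
#' @param a,b,c,d non-negative counts: mutant carrying / mutant not
#'   carrying / wild-type carrying / wild-type not carrying.
#' @return object of class `counts2x2`.
#' @export
counts2x2 <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop("counts must be non-negative integers")
  }
  structure(as.list(setNames(as.integer(x), names(x))), class = "counts2x2")
}

#' @export
print.counts2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("mutant", "wild_type"),
                              c("carrier", "non_carrier")))
  print(m)
  invisible(x)
}

#' One-sided Fisher exact test for haplotype over-representation
#'
#' Upper-tail hypergeometric probability `P(X >= a)` with
#' `X ~ Hypergeometric(N = a+b+c+d, K = a+c, n = a+b)`: the probability,
#' under random assignment of the `K` carrier haplotypes to the two
#' labels, of seeing at least `a` of them on the mutant side.  This is
#' the one-sided ("greater") Fisher exact test used to fine-map a focal
#' region by haplotype contingency.  The tail sum is accumulated in log
#' space from `lchoose` terms, so tables like (14,0,0,14) (p on the
#' order of 1e-8) are computed without underflow.
#'
#' @param t a `counts2x2` table (see [counts2x2()]).
#' @return the p-value, a number in (0, 1].
#' @examples
#' fisher_one_sided_greater(counts2x2(14, 0, 0, 14))  # 1 / choose(28, 14)
#' @export
fisher_one_sided_greater <- function(t) {
  stopifnot(inherits(t, "counts2x2"))
  a <- t$a; b <- t$b; c_ <- t$c; d <- t$d
  N <- a + b + c_ + d
  K <- a + c_        # carrier haplotypes overall
  n <- a + b         # mutant-labeled haplotypes
  if (N == 0L) return(1)
  lo <- max(0L, n - (N - K))
  hi <- min(K, n)
  if (a <= lo) return(1)
  xs <- a:hi
  lp <- lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)
  m <- max(lp)
  p <- exp(m + log(sum(exp(lp - m))))
  min(p, 1)
}

#' Fine-map a focal region by per-site haplotype over-representation
#'
#' For every site in the (optionally restricted) common site index,
#' tabulates carrier counts on mutant vs wild-type haplotypes and applies
#' the one-sided exact test, returning an ascending-p ranking.  Raw
#' p-values are reported (no multiple-testing correction in the primary
#' column, mirroring how such scans are usually displayed against a fixed
#' significance reference line); a Bonferroni column is included for
#' convenience.  Ties in p are broken by genomic position.
#'
#' @param mutant_vectors,wildtype_vectors lists of haplotype vectors
#'   (label mutant / wild_type) over a shared site index, or binary
#'   matrices with site columns.
#' @param site_restriction optional vector of sites (subset of the site
#'   index) to test, e.g. the concordant-site list from
#'   [site_concordance()].  `NULL` tests every site.
#' @return data.frame of class `finemap_result`, one row per tested site:
#'   `site`, `a`, `b`, `c`, `d`, `p`, `bonferroni`, `rank`, ordered by
#'   rank.
#' @export
fine_map_region <- function(mutant_vectors, wildtype_vectors,
                            site_restriction = NULL) {
  mm <- .stack_vectors(mutant_vectors)
  wm <- .stack_vectors(wildtype_vectors)
  if (!identical(colnames(mm), colnames(wm))) {
    stop("mutant and wild-type vectors must share one site index")
  }
  sites <- colnames(mm)
  if (!is.null(site_restriction)) {
    keep <- as.character(site_restriction)
    if (length(keep) == 0L) stop("empty site restriction")
    missing <- setdiff(keep, sites)
    if (length(missing)) {
      stop("restriction sites not in the site index: ",
           paste(head(missing, 5), collapse = ", "))
    }
    sites <- sites[sites %in% keep]
  }
  n1 <- nrow(mm); n2 <- nrow(wm)
  a <- colSums(mm[, sites, drop = FALSE] == 1L)
  cc <- colSums(wm[, sites, drop = FALSE] == 1L)
  p <- vapply(seq_along(sites), function(i) {
    fisher_one_sided_greater(counts2x2(a[i], n1 - a[i], cc[i], n2 - cc[i]))
  }, numeric(1))
  res <- data.frame(
    site = as.numeric(sites),
    a = as.integer(a), b = n1 - as.integer(a),
    c = as.integer(cc), d = n2 - as.integer(cc),
    p = p,
    bonferroni = pmin(p * length(sites), 1),
    row.names = NULL
  )
  ord <- order(res$p, res$site)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  class(res) <- c("finemap_result", "data.frame")
  res
}

#' @export
print.finemap_result <- function(x, n = 10L, ...) {
  cat("Haplotype fine-mapping: ", nrow(x), " sites tested (",
      x$a[1] + x$b[1], " mutant vs ", x$c[1] + x$d[1],
      " wild-type haplotypes)\n", sep = "")
  cat("Top sites by one-sided exact p:\n")
  print.data.frame(head(as.data.frame(x), n))
  invisible(x)
}

# Accept either a list of haplotype_vector objects or a plain 0/1 matrix
# with site columns; always return an integer matrix with site colnames.
.stack_vectors <- function(v) {
  if (is.matrix(v)) {
    if (is.null(colnames(v))) stop("matrix input needs site column names")
    storage.mode(v) <- "integer"
    return(v)
  }
  if (inherits(v, "haplotype_vector")) v <- list(v)
  if (!length(v)) stop("no haplotype vectors supplied")
  idx <- v[[1]]$site_index
  for (h in v) {
    if (!identical(h$site_index, idx)) stop("mismatched site indices")
  }
  m <- do.call(rbind, lapply(v, function(h) as.integer(h$values)))
  colnames(m) <- as.character(idx)
  rownames(m) <- vapply(v, function(h) {
    if (is.null(h$haplotype_id)) "" else as.character(h$haplotype_id)
  }, character(1))
  m
}
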