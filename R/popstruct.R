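#' Filter a genotype dosage matrix for ancestry PCA
#'
#' Retains sites with minor allele frequency at or above `min_maf`
#' (computed on non-missing dosages across the combined cohort) and a
#' missing-call fraction strictly below `max_missing` — the usual
#' site-quality gate before a genotype-level ancestry PCA.
#'
#' @param gm list with `samples`, `sites`, and `dosages` (samples x sites
#'   matrix with values 0/1/2 or NA), or a bare dosage matrix.
#' @param min_maf minimum minor allele frequency (inclusive, default 0.05).
#' @param max_missing maximum missing fraction (exclusive, default 0.1).
#' @return the filtered object of the same shape.
#' @export
filter_sites_for_pca <- function(gm, min_maf = 0.05, max_missing = 0.1) {
  d <- if (is.list(gm) && !is.data.frame(gm)) gm$dosages else gm
  if (!is.matrix(d) || nrow(d) == 0L || ncol(d) == 0L) {
    stop("nonempty dosage matrix required")
  }
  miss <- colMeans(is.na(d))
  f <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- 0
  keep <- maf >= min_maf & miss < max_missing
  if (!any(keep)) warning("all sites removed by the MAF/missingness filter")
  if (is.list(gm) && !is.data.frame(gm)) {
    gm$dosages <- d[, keep, drop = FALSE]
    gm$sites <- gm$sites[keep]
    gm
  } else {
    d[, keep, drop = FALSE]
  }
}

#' Principal component analysis with a fixed sign convention
#'
#' Column-mean-centered (optionally variance-scaled) PCA via singular
#' value decomposition, as \code{\link[stats]{prcomp}} computes it.  Each
#' component's sign is fixed by forcing its largest-magnitude loading
#' positive, so scores are reproducible across platforms and row
#' permutations.  A constant (zero-variance) input yields all-zero scores
#' rather than an error.
#'
#' @param matrix numeric matrix, rows = samples or haplotypes; missing
#'   entries must be imputed beforehand.
#' @param center,scale passed to the decomposition (defaults: center,
#'   no scaling — 0/1 haplotype columns keep their natural weights).
#' @param n_components number of components to return
#'   (default `min(10, rank)`).
#' @return object of class `pca_result`: `scores` (rows x components),
#'   `explained_variance_fraction`, `component_loadings` (sites x
#'   components), `center`, `total_variance`.
#' @export
run_pca <- function(matrix, center = TRUE, scale = FALSE,
                    n_components = 10L) {
  if (nrow(matrix) < 2L || ncol(matrix) < 1L) {
    stop("need >= 2 rows and >= 1 column")
  }
  if (anyNA(matrix)) stop("missing entries must be imputed before PCA")
  sds <- apply(matrix, 2, stats::sd)
  if (all(sds == 0)) {
    k <- min(n_components, ncol(matrix))
    scores <- base::matrix(0, nrow(matrix), k,
                           dimnames = list(rownames(matrix),
                                           paste0("PC", seq_len(k))))
    return(structure(list(
      scores = scores,
      explained_variance_fraction = rep(0, k),
      component_loadings = base::matrix(0, ncol(matrix), k),
      center = colMeans(matrix), total_variance = 0
    ), class = "pca_result"))
  }
  if (scale) {
    # avoid division by zero on constant columns
    matrix <- matrix[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(matrix, center = center, scale. = scale)
  total <- sum(pc$sdev^2)
  k <- min(n_components, sum(pc$sdev > 1e-12), ncol(pc$rotation))
  k <- max(k, 1L)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sign(load[which.max(abs(load[, j])), j])
    if (s < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  structure(list(
    scores = scores,
    explained_variance_fraction = pc$sdev[seq_len(k)]^2 / total,
    component_loadings = load,
    center = if (isTRUE(center)) pc$center else rep(0, ncol(matrix)),
    total_variance = total
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA: ", nrow(x$scores), " rows, ", ncol(x$scores),
      " components; explained variance: ",
      paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction[
        seq_len(min(4, ncol(x$scores)))]), collapse = ", "),
      if (ncol(x$scores) > 4) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Assign query samples to populations by nearest panel centroid
#'
#' Each query is given the label of the nearest centroid of the labeled
#' panel scores in the selected component subspace.  Components 2 and 3
#' are the default, the axes on which continental reference panels
#' typically separate.  Exact ties go to the lexicographically smaller
#' label and are flagged.
#'
#' @param query_scores,panel_scores score matrices from a joint PCA.
#' @param panel_labels population label per panel row (>= 2 distinct).
#' @param components column indices of the subspace (default `c(2, 3)`).
#' @return data.frame: label, distance (to the winning centroid), margin
#'   (runner-up distance minus winning distance), tie flag.
#' @export
assign_population <- function(query_scores, panel_scores, panel_labels,
                              components = c(2, 3)) {
  if (is.null(dim(query_scores))) query_scores <- rbind(query_scores)
  if (!nrow(panel_scores)) stop("empty panel")
  if (length(unique(panel_labels)) < 2L) stop("panel must cover >= 2 labels")
  components <- components[components <= ncol(panel_scores)]
  ps <- panel_scores[, components, drop = FALSE]
  qs <- query_scores[, components, drop = FALSE]
  labs <- sort(unique(panel_labels))
  cent <- t(vapply(labs, function(l) colMeans(ps[panel_labels == l, , drop = FALSE]),
                   numeric(ncol(ps))))
  out <- lapply(seq_len(nrow(qs)), function(i) {
    d <- sqrt(rowSums((cent - rep(qs[i, ], each = nrow(cent)))^2))
    o <- order(d, labs)
    tie <- length(d) > 1L &&
      isTRUE(all.equal(unname(d[o[1]]), unname(d[o[2]])))
    data.frame(label = labs[o[1]], distance = d[o[1]],
               margin = if (length(d) > 1L) d[o[2]] - d[o[1]] else NA_real_,
               tie = tie, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- rownames(qs)
  res
}

#' Joint haplotype PCA with a per-haplotype report table
#'
#' Stacks mutant and wild-type haplotype vectors (cohort and panel
#' jointly, unweighted) into a 0/1 matrix over their common site index,
#' runs [run_pca()], and returns the result together with a tidy table
#' (haplotype id, label, origin, population, PC scores) ready for
#' plotting.
#'
#' @param vectors list of `haplotype_vector` objects sharing one site
#'   index (>= 3).
#' @param n_components components to keep (default 10).
#' @return list of class `haplotype_pca`: `pca` (a `pca_result`) and
#'   `table` (data.frame).
#' @export
haplotype_pca_report <- function(vectors, n_components = 10L) {
  if (length(vectors) < 3L) stop("need >= 3 haplotype vectors")
  m <- .stack_vectors(vectors)
  pca <- run_pca(m, n_components = n_components)
  tab <- data.frame(
    haplotype_id = vapply(vectors, function(h) as.character(h$haplotype_id),
                          character(1)),
    label = vapply(vectors, function(h) h$label, character(1)),
    origin = vapply(vectors, function(h) h$origin, character(1)),
    population = vapply(vectors, function(h) h$population, character(1)),
    stringsAsFactors = FALSE
  )
  tab <- cbind(tab, as.data.frame(pca$scores, row.names = FALSE))
  structure(list(pca = pca, table = tab), class = "haplotype_pca")
}

#' @export
print.haplotype_pca <- function(x, ...) {
  cat("Haplotype PCA of ", nrow(x$table), " haplotypes (",
      sum(x$table$label == "mutant"), " mutant / ",
      sum(x$table$label == "wild_type"), " wild-type)\n", sep = "")
  print(x$pca)
  invisible(x)
}

#' Plot a haplotype PCA report
#'
#' Scatter of two principal components, colored by population, with
#' mutant haplotypes as filled and wild-type as open symbols.
#'
#' @param x a `haplotype_pca` object.
#' @param components two components to display (default `c(1, 2)`).
#' @param ... passed to [plot()].
#' @export
plot.haplotype_pca <- function(x, components = c(1, 2), ...) {
  t <- x$table
  cx <- paste0("PC", components[1]); cy <- paste0("PC", components[2])
  pops <- sort(unique(t$population))
  col <- setNames(seq_along(pops) + 1L, pops)
  ev <- 100 * x$pca$explained_variance_fraction[components]
  plot(t[[cx]], t[[cy]],
       col = col[t$population],
       pch = ifelse(t$label == "mutant", 19, 1),
       xlab = sprintf("%s (%.1f%%)", cx, ev[1]),
       ylab = sprintf("%s (%.1f%%)", cy, ev[2]), ...)
  graphics::legend("topright", legend = pops, col = col, pch = 19, cex = 0.8)
  invisible(x)
}
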