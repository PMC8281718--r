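#' Build a panel of normals from per-normal call sets
#'
#' A site enters the artifact blacklist when it is observed in at least
#' `min_samples` normal samples — recurrent observation across unrelated
#' normals marks a systematic artifact rather than a genuine somatic
#' event.
#'
#' @param normal_call_sets list of data.frames with chrom/pos/ref/alt.
#' @param min_samples minimum normals a site must appear in (default 2).
#' @return object of class `panel_of_normals`: data.frame of artifact
#'   sites with their observation counts.
#' @export
build_pon <- function(normal_call_sets, min_samples = 2) {
  keys <- unlist(lapply(normal_call_sets, function(d) {
    if (!nrow(d)) return(character(0))
    unique(paste(d$chrom, d$pos, d$ref, d$alt, sep = ":"))
  }))
  tab <- table(keys)
  art <- names(tab)[tab >= min_samples]
  sites <- if (length(art)) {
    parts <- do.call(rbind, strsplit(art, ":", fixed = TRUE))
    data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
               ref = parts[, 3], alt = parts[, 4],
               n_observed = as.integer(tab[art]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), n_observed = integer(),
               stringsAsFactors = FALSE)
  }
  structure(list(sites = sites, min_samples = min_samples,
                 n_normals = length(normal_call_sets)),
            class = "panel_of_normals")
}

#' @export
print.panel_of_normals <- function(x, ...) {
  cat("Panel of normals: ", nrow(x$sites), " artifact sites (seen in >= ",
      x$min_samples, " of ", x$n_normals, " normals)\n", sep = "")
  invisible(x)
}

#' Somatic SNV filter cascade with a per-call audit
#'
#' Applies, in order: panel-of-normals removal, strict variant allele
#' fraction threshold (`vaf > min_vaf`), minimum variant read support
#' (`alt_reads >= min_alt`), and database population-frequency removal
#' (`population_af > max_pop_af` removed).  Inequality strictness follows
#' the stated rules exactly.  Every input call appears exactly once in
#' the audit, either retained or removed with the first rule that
#' rejected it.
#'
#' @param calls data.frame with chrom, pos, ref, alt, alt_reads, depth,
#'   vaf, population_af.
#' @param pon a `panel_of_normals` (or `NULL` to skip).
#' @param min_vaf VAF threshold, strict ">" (default 0.10).
#' @param min_alt minimum variant reads, ">=" (default 6).
#' @param max_pop_af database AF above which a call is removed, strict
#'   ">" (default 0.001).
#' @return list of class `filter_result`: `retained` (data.frame),
#'   `removed` (data.frame with `reason`), `audit` (full table with
#'   `kept` and `reason`).
#' @export
filter_somatic <- function(calls, pon = NULL, min_vaf = 0.10, min_alt = 6,
                           max_pop_af = 0.001) {
  reason <- rep(NA_character_, nrow(calls))
  if (!is.null(pon)) {
    stopifnot(inherits(pon, "panel_of_normals"))
    key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
    pkey <- paste(pon$sites$chrom, pon$sites$pos, pon$sites$ref,
                  pon$sites$alt, sep = ":")
    reason[is.na(reason) & key %in% pkey] <- "panel_of_normals"
  }
  reason[is.na(reason) & !(calls$vaf > min_vaf)] <- "low_vaf"
  reason[is.na(reason) & calls$alt_reads < min_alt] <- "low_alt_reads"
  reason[is.na(reason) & calls$population_af > max_pop_af] <- "population_af"
  audit <- calls
  audit$kept <- is.na(reason)
  audit$reason <- ifelse(is.na(reason), "retained", reason)
  structure(list(
    retained = calls[is.na(reason), , drop = FALSE],
    removed = cbind(calls[!is.na(reason), , drop = FALSE],
                    reason = reason[!is.na(reason)]),
    audit = audit
  ), class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("Filter cascade: ", nrow(x$retained), " retained / ",
      nrow(x$removed), " removed\n", sep = "")
  if (nrow(x$removed)) print(table(x$removed$reason))
  invisible(x)
}

#' Filter germline calls to disruptive candidates
#'
#' Retains calls in candidate genes whose consequence is in the
#' disruptive set (splice, frameshift, nonsense by default) and whose
#' population allele frequency is strictly below `max_pop_af`.  Calls
#' lacking gene or consequence annotation are excluded with an audit
#' reason.
#'
#' @param calls data.frame with gene, consequence, population_af columns.
#' @param candidate_genes character vector of gene symbols.
#' @param disruptive_classes consequence classes treated as disruptive.
#' @param max_pop_af strict "<" population AF threshold (default 0.001).
#' @return `filter_result` (see [filter_somatic()]).
#' @export
filter_germline_candidates <- function(calls, candidate_genes,
                                       disruptive_classes = c(
                                         "splice", "frameshift", "stop_gain",
                                         "nonsense", "deletion"),
                                       max_pop_af = 0.001) {
  reason <- rep(NA_character_, nrow(calls))
  unann <- is.na(calls$gene) | is.na(calls$consequence)
  reason[unann] <- "unannotated"
  reason[is.na(reason) & !(calls$gene %in% candidate_genes)] <- "not_candidate_gene"
  reason[is.na(reason) & !(calls$consequence %in% disruptive_classes)] <-
    "not_disruptive"
  reason[is.na(reason) & !(calls$population_af < max_pop_af)] <- "population_af"
  audit <- calls
  audit$kept <- is.na(reason)
  audit$reason <- ifelse(is.na(reason), "retained", reason)
  structure(list(
    retained = calls[is.na(reason), , drop = FALSE],
    removed = cbind(calls[!is.na(reason), , drop = FALSE],
                    reason = reason[!is.na(reason)]),
    audit = audit
  ), class = "filter_result")
}

#' Genotype compound risk alleles per sample
#'
#' For each risk-allele specification, reports per sample whether it is
#' homozygous, heterozygous, or a non-carrier.  A composite specification
#' (several component variants under one name, e.g. a two-variant risk
#' allele) requires every component in the same sample; its zygosity is
#' the minimum across components.  Samples with no call at a spec site
#' are treated as homozygous reference there and flagged.
#'
#' @param calls `variant_calls` data.frame (multi-sample).
#' @param specs data.frame: name, chrom, pos, ref, alt (rows sharing a
#'   name form one composite allele).
#' @return data.frame: sample_id, name, status (hom_risk / het /
#'   non_carrier), imputed_hom_ref (any component site without a call).
#' @export
genotype_risk_alleles <- function(calls, specs) {
  if (anyDuplicated(specs[c("name", "chrom", "pos")]) > 0) {
    stop("sites must be distinct within a risk-allele spec")
  }
  samples <- unique(calls$sample_id)
  out <- list()
  for (nm in unique(specs$name)) {
    sp <- specs[specs$name == nm, , drop = FALSE]
    for (s in samples) {
      doses <- integer(nrow(sp)); imputed <- FALSE
      for (j in seq_len(nrow(sp))) {
        hit <- calls$sample_id == s & calls$chrom == sp$chrom[j] &
          calls$pos == sp$pos[j] & calls$ref == sp$ref[j] &
          calls$alt == sp$alt[j]
        if (any(hit)) {
          d <- calls[which(hit)[1], ]
          doses[j] <- d$allele1 + d$allele2
        } else {
          doses[j] <- 0L   # absent call = hom-ref
          imputed <- TRUE
        }
      }
      dmin <- min(doses)
      status <- if (dmin >= 2L) "hom_risk" else if (dmin == 1L) "het" else "non_carrier"
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, name = nm, status = status,
        imputed_hom_ref = imputed, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Detect kataegis clusters on one chromosome
#'
#' Reports maximal runs of at least `min_run` consecutive SNVs in which
#' every adjacent inter-mutation distance is at most `max_imd` — the
#' field-standard operational definition of kataegis (localized
#' hypermutation).  Duplicated positions are removed before clustering.
#' A rainfall table (position, distance to previous SNV) is returned for
#' plotting.
#'
#' @param positions sorted SNV positions on one chromosome (unsorted
#'   input is sorted; duplicates dropped).
#' @param max_imd maximum inter-mutation distance within a cluster in bp
#'   (default 1000).
#' @param min_run minimum SNVs per cluster (default 6).
#' @return list of class `kataegis_result`: `clusters` (data.frame:
#'   start, end, n, span) and `rainfall` (data.frame: position, imd).
#' @export
detect_kataegis <- function(positions, max_imd = 1000, min_run = 6) {
  pos <- sort(unique(positions))
  n <- length(pos)
  imd <- c(NA, diff(pos))
  clusters <- data.frame(start = numeric(0), end = numeric(0),
                         n = integer(0), span = numeric(0))
  if (n >= 2L) {
    close_ <- diff(pos) <= max_imd
    r <- rle(close_)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (r$values[j] && r$lengths[j] + 1L >= min_run) {
        i1 <- idx_start[j]; i2 <- idx_end[j] + 1L
        clusters <- rbind(clusters, data.frame(
          start = pos[i1], end = pos[i2], n = i2 - i1 + 1L,
          span = pos[i2] - pos[i1]))
      }
    }
  }
  structure(list(clusters = clusters,
                 rainfall = data.frame(position = pos, imd = imd)),
            class = "kataegis_result")
}

#' @export
print.kataegis_result <- function(x, ...) {
  cat("Kataegis: ", nrow(x$clusters), " cluster(s) among ",
      nrow(x$rainfall), " SNVs\n", sep = "")
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Trait-carrier enrichment against a population frequency
#'
#' Fold enrichment of trait carriers in a cohort over the expected
#' population frequency, with a one-sided binomial tail p-value
#' `P(X >= carriers)` for `X ~ Binomial(cohort_n, population_freq)`.
#'
#' @param carriers observed carriers in the cohort.
#' @param cohort_n cohort size.
#' @param population_freq carrier frequency in the reference population
#'   (must be > 0).
#' @return list: `fold`, `p_value`.
#' @export
trait_enrichment <- function(carriers, cohort_n, population_freq) {
  if (!(population_freq > 0 && population_freq <= 1)) {
    stop("population_freq must lie in (0, 1]")
  }
  if (carriers > cohort_n) stop("carriers cannot exceed cohort_n")
  list(
    fold = (carriers / cohort_n) / population_freq,
    p_value = if (carriers == 0) 1 else
      pbinom(carriers - 1, cohort_n, population_freq, lower.tail = FALSE)
  )
}

#' Infer sample sex from the chrX:chrY read ratio
#'
#' Computes the ratio of reads mapped to chrX over chrY and calls female
#' when the ratio is at or above the boundary (the geometric mean,
#' ~12.65, of the anchor ratios 40:1 for females and 4:1 for males) and
#' male below it.  Ratios within a factor 1.25 of the boundary are
#' flagged indeterminate.  Zero chrY reads yields a female call with an
#' infinite ratio.
#'
#' @param read_counts named numeric vector of per-chromosome read counts;
#'   must contain `chrX` and `chrY`.
#' @param boundary decision boundary on the ratio (default
#'   `sqrt(40 * 4)`).
#' @param indeterminate_factor half-width of the indeterminate band as a
#'   multiplicative factor (default 1.25).
#' @return list of class `sex_call`: `counts`, `x_to_y_ratio`, `call`.
#' @export
infer_sex <- function(read_counts, boundary = sqrt(40 * 4),
                      indeterminate_factor = 1.25) {
  if (!all(c("chrX", "chrY") %in% names(read_counts))) {
    stop("read_counts must contain chrX and chrY")
  }
  x <- read_counts[["chrX"]]; y <- read_counts[["chrY"]]
  ratio <- if (y == 0) Inf else x / y
  call <- if (is.infinite(ratio)) {
    "female"
  } else if (ratio >= boundary / indeterminate_factor &&
             ratio <= boundary * indeterminate_factor) {
    "indeterminate"
  } else if (ratio >= boundary) "female" else "male"
  structure(list(counts = read_counts, x_to_y_ratio = ratio, call = call),
            class = "sex_call")
}

#' @export
print.sex_call <- function(x, ...) {
  cat("Sex inference: chrX:chrY = ",
      if (is.infinite(x$x_to_y_ratio)) "Inf" else
        sprintf("%.2f", x$x_to_y_ratio),
      ":1 -> ", x$call, "\n", sep = "")
  invisible(x)
}
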