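#' Read phased variant calls from a VCF
#'
#' Parses a VCF v4.2 file (via \pkg{vcfR}) into a long call table, one row
#' per biallelic record per sample.  Multiallelic records are decomposed
#' into biallelic records (the PS tag is kept); for record k of a
#' multiallelic site, allele index k maps to 1 and all other alleles to 0.
#' Phased genotypes (`a|b`) carry their PS phase-set id and PQ phase
#' quality when present.  Records with a missing genotype for a sample are
#' omitted for that sample.
#'
#' @param path VCF file path.
#' @param sample_id sample(s) to extract; `NULL` for all samples.
#' @return data.frame of class `variant_calls`: chrom, pos, ref, alt,
#'   allele1, allele2, phased, phase_set, phase_quality, sample_id.
#' @export
read_phased_vcf <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  .validate_vcf_lines(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  samples <- colnames(vcf@gt)[-1]
  if (is.null(sample_id)) sample_id <- samples
  missing <- setdiff(sample_id, samples)
  if (length(missing)) stop("sample(s) not in VCF: ",
                            paste(missing, collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ps <- tryCatch(vcfR::extract.gt(vcf, element = "PS"),
                 error = function(e) NULL)
  pq <- tryCatch(vcfR::extract.gt(vcf, element = "PQ"),
                 error = function(e) NULL)
  out <- list()
  for (s in sample_id) {
    for (i in seq_len(nrow(fix))) {
      g <- gt[i, s]
      if (is.na(g) || g %in% c(".", "./.", ".|.")) next
      phased <- grepl("|", g, fixed = TRUE)
      al <- suppressWarnings(as.integer(strsplit(g, "[|/]")[[1]]))
      if (length(al) != 2L || any(is.na(al))) next
      alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
      psv <- if (!is.null(ps) && phased) suppressWarnings(as.integer(ps[i, s])) else NA_integer_
      pqv <- if (!is.null(pq)) suppressWarnings(as.integer(pq[i, s])) else NA_integer_
      for (k in seq_along(alts)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
          ref = fix[i, "REF"], alt = alts[k],
          allele1 = as.integer(al[1] == k), allele2 = as.integer(al[2] == k),
          phased = phased, phase_set = psv, phase_quality = pqv,
          sample_id = s, stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), allele1 = integer(), allele2 = integer(),
               phased = logical(), phase_set = integer(),
               phase_quality = integer(), sample_id = character(),
               stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  class(calls) <- c("variant_calls", "data.frame")
  calls
}

# field-count validation so malformed records fail with a line number
# (the upstream parser does not report one)
.validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("parse error: no #CHROM header line in ", path)
  n_fields <- length(strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]])
  for (i in seq_along(lines)) {
    if (i <= hdr[1] || !nzchar(lines[i])) next
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf != n_fields) {
      stop("parse error at line ", i, " of ", basename(path),
           ": expected ", n_fields, " fields, found ", nf)
    }
  }
  invisible(TRUE)
}

#' Assemble phase-set haplotype blocks from one sample's calls
#'
#' Heterozygous phased calls with phase quality at or above the threshold
#' are grouped by their PS phase-set id into haplotype blocks; calls below
#' threshold (or unphased, or homozygous) are excluded from blocks and
#' returned in the `excluded` attribute.  The default threshold of 23
#' marks the phase quality at which a call is considered reliable for
#' assignment to a single haplotype block.
#'
#' @param calls a `variant_calls` data.frame from one sample.
#' @param min_phase_quality minimum PQ for inclusion (default 23).
#' @return list of `haplotype_block` objects (fields: sample_id, chrom,
#'   phase_set, sites, ref, alt, hap1, hap2), with excluded calls in
#'   `attr(, "excluded")`.
#' @export
build_haplotype_blocks <- function(calls, min_phase_quality = 23) {
  if (length(unique(calls$sample_id)) > 1L) {
    stop("calls must come from a single sample")
  }
  het <- calls$allele1 != calls$allele2
  qual <- !is.na(calls$phase_quality) & calls$phase_quality >= min_phase_quality
  keep <- het & calls$phased & !is.na(calls$phase_set) & qual
  excluded <- calls[het & !keep, , drop = FALSE]
  inb <- calls[keep, , drop = FALSE]
  blocks <- lapply(split(seq_len(nrow(inb)), inb$phase_set), function(ix) {
    d <- inb[ix, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    if (anyDuplicated(d$pos)) d <- d[!duplicated(d$pos), , drop = FALSE]
    structure(list(
      sample_id = d$sample_id[1], chrom = d$chrom[1],
      phase_set = d$phase_set[1], sites = d$pos,
      ref = d$ref, alt = d$alt,
      hap1 = d$allele1, hap2 = d$allele2
    ), class = "haplotype_block")
  })
  blocks <- unname(blocks[order(vapply(blocks, function(b) min(b$sites), numeric(1)))])
  attr(blocks, "excluded") <- excluded
  blocks
}

#' @export
print.haplotype_block <- function(x, ...) {
  cat("Haplotype block ", x$sample_id, " PS=", x$phase_set, ": ",
      length(x$sites), " sites [", min(x$sites), "-", max(x$sites), "]\n",
      sep = "")
  invisible(x)
}

#' Stitch broken haplotype blocks using a bridging sample
#'
#' Two adjacent blocks of the target sample are merged when a single
#' bridge block (typically from the matched tumor or normal of the same
#' patient) overlaps both with at least `min_informative` shared
#' heterozygous sites on each side and the bridge's haplotype assignment
#' agrees with a consistent orientation (fraction of agreeing alleles at
#' least `min_consistency`, counting the better of the keep/flip
#' orientations) on both sides.  Merging only concatenates sites and
#' possibly swaps hap1/hap2 of the downstream block; allele values are
#' never altered.  Non-stitchable input is returned unchanged.
#'
#' @param target_blocks blocks of the sample to repair.
#' @param bridge_blocks blocks of the bridging sample.
#' @param min_informative minimum shared het sites per side (default 3).
#' @param min_consistency minimum allele-agreement fraction (default 0.9).
#' @return list of `haplotype_block` objects after stitching.
#' @export
stitch_blocks <- function(target_blocks, bridge_blocks,
                          min_informative = 3, min_consistency = 0.9) {
  blocks <- target_blocks
  repeat {
    if (length(blocks) < 2L) break
    blocks <- blocks[order(vapply(blocks, function(b) min(b$sites), numeric(1)))]
    merged <- FALSE
    for (i in seq_len(length(blocks) - 1L)) {
      A <- blocks[[i]]; B <- blocks[[i + 1L]]
      for (br in bridge_blocks) {
        oA <- .block_orientation(A, br, min_informative, min_consistency)
        if (is.na(oA)) next
        oB <- .block_orientation(B, br, min_informative, min_consistency)
        if (is.na(oB)) next
        blocks[[i]] <- .merge_blocks(A, B, swap_b = (oA != oB))
        blocks[[i + 1L]] <- NULL
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  blocks
}

# orientation of block vs bridge: TRUE = bridge hap1 tracks block hap1,
# FALSE = tracks block hap2, NA = insufficient or inconsistent evidence
.block_orientation <- function(block, bridge, min_informative, min_consistency) {
  shared <- intersect(block$sites, bridge$sites)
  if (length(shared) < min_informative) return(NA)
  bi <- match(shared, block$sites)
  ri <- match(shared, bridge$sites)
  agree_same <- mean(block$hap1[bi] == bridge$hap1[ri])
  if (agree_same >= min_consistency) return(TRUE)
  if ((1 - agree_same) >= min_consistency) return(FALSE)
  NA
}

.merge_blocks <- function(A, B, swap_b) {
  h1b <- if (swap_b) B$hap2 else B$hap1
  h2b <- if (swap_b) B$hap1 else B$hap2
  sites <- c(A$sites, B$sites)
  ord <- order(sites)
  structure(list(
    sample_id = A$sample_id, chrom = A$chrom, phase_set = A$phase_set,
    sites = sites[ord],
    ref = c(A$ref, B$ref)[ord], alt = c(A$alt, B$alt)[ord],
    hap1 = c(A$hap1, h1b)[ord], hap2 = c(A$hap2, h2b)[ord]
  ), class = "haplotype_block")
}

#' Extract labeled binary haplotype vectors around a focal allele
#'
#' From a sample's (possibly stitched) haplotype blocks, returns the two
#' haplotype vectors over `panel_sites` restricted to the closed window
#' `[focal - halfwidth, focal + halfwidth]`.  The haplotype carrying the
#' focal alternate allele is labeled `mutant`, the other `wild_type`
#' (both `wild_type` if neither carries it).  Heterozygous sites take
#' their phased alleles from the covering block; homozygous calls (which
#' need no phasing) are filled in from `calls` when supplied; window
#' sites without any call in the sample are imputed as reference (0),
#' the usual state of sites absent from a per-sample caller's output.
#' The window's heterozygous sites must belong to a single phase set,
#' otherwise a fragmented-haplotype error names the gap.
#'
#' @param blocks list of `haplotype_block` objects for one sample.
#' @param focal focal-allele position (bp).
#' @param halfwidth_bp half-width of the window (default 100000).
#' @param panel_sites ordered positions retained for comparability with a
#'   reference panel.
#' @param calls optional `variant_calls` for the same sample, used to
#'   fill homozygous genotypes.
#' @param origin,population annotations copied onto the output vectors.
#' @return list of two `haplotype_vector` objects (fields: haplotype_id,
#'   site_index, values, label, origin, population).
#' @export
extract_haplotype_vectors <- function(blocks, focal, halfwidth_bp = 100000,
                                      panel_sites, calls = NULL,
                                      origin = "cohort",
                                      population = "unknown") {
  if (!length(panel_sites)) stop("panel_sites must be nonempty")
  lo <- focal - halfwidth_bp; hi <- focal + halfwidth_bp
  inwin <- lapply(blocks, function(b) which(b$sites >= lo & b$sites <= hi))
  covering <- which(vapply(inwin, length, integer(1)) > 0L)
  if (length(covering) == 0L) stop("no haplotype block covers the window")
  if (length(covering) > 1L) {
    ends <- vapply(blocks[covering], function(b) max(b$sites), numeric(1))
    starts <- vapply(blocks[covering], function(b) min(b$sites), numeric(1))
    o <- order(starts)
    stop("fragmented haplotype: window [", lo, ", ", hi, "] spans ",
         length(covering), " phase sets with a gap near [",
         ends[o][1], ", ", starts[o][2], "]")
  }
  b <- blocks[[covering]]
  sites <- panel_sites[panel_sites >= lo & panel_sites <= hi]
  idx <- match(sites, b$sites)
  v1 <- ifelse(is.na(idx), 0L, b$hap1[idx])
  v2 <- ifelse(is.na(idx), 0L, b$hap2[idx])
  if (!is.null(calls)) {
    hom <- calls[calls$allele1 == calls$allele2, , drop = FALSE]
    hidx <- match(sites, hom$pos)
    fill <- !is.na(hidx) & is.na(idx)
    v1[fill] <- hom$allele1[hidx[fill]]
    v2[fill] <- hom$allele2[hidx[fill]]
  }
  f <- match(focal, sites)
  lab1 <- "wild_type"; lab2 <- "wild_type"
  if (!is.na(f)) {
    if (v1[f] == 1L) lab1 <- "mutant"
    if (v2[f] == 1L) lab2 <- "mutant"
  }
  mk <- function(values, label, hap) {
    structure(list(
      haplotype_id = paste0(b$sample_id, "_hap", hap),
      site_index = sites, values = as.integer(values), label = label,
      origin = origin, population = population
    ), class = "haplotype_vector")
  }
  list(mk(v1, lab1, 1L), mk(v2, lab2, 2L))
}

#' @export
print.haplotype_vector <- function(x, ...) {
  cat("Haplotype vector ", x$haplotype_id, " [", x$label, ", ", x$origin,
      "/", x$population, "]: ", length(x$values), " sites, ",
      sum(x$values), " alt alleles\n", sep = "")
  invisible(x)
}

#' Concordance between two call sets
#'
#' A (sample, site) record is concordant when both call sets contain the
#' same chrom/pos/ref/alt with the same unordered genotype.  The fraction
#' is computed relative to the union of records, and the concordant site
#' list is returned for downstream restriction (e.g. fine-mapping on
#' jointly confirmed sites only).
#'
#' @param calls_a,calls_b `variant_calls` data.frames over the same
#'   samples.
#' @return list with `fraction` and `concordant` (data.frame of
#'   concordant records).
#' @export
site_concordance <- function(calls_a, calls_b) {
  key <- function(d) paste(d$sample_id, d$chrom, d$pos, d$ref, d$alt,
                           pmin(d$allele1, d$allele2),
                           pmax(d$allele1, d$allele2), sep = ":")
  ka <- key(calls_a); kb <- key(calls_b)
  conc <- intersect(ka, kb)
  uni <- union(ka, kb)
  list(
    fraction = if (length(uni)) length(conc) / length(uni) else 1,
    concordant = calls_a[ka %in% conc, , drop = FALSE]
  )
}
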