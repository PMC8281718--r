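#' Write a complete fixture bundle for the pipeline
#'
#' Serializes a simulated study into the file formats the pipeline
#' consumes: a multi-sample phased VCF for the cohort (GT with `|`,
#' FORMAT PS and PQ), a tabular reference panel of labeled haplotypes, a
#' reference FASTA, a BEDPE-like breakpoint table with assembled contig
#' sequences, an SV truth table, repeat and gene BED tracks (0-based
#' half-open, genes with strand), a per-gene expression table, the
#' somatic call set with its synthetic normals, and a manifest listing
#' every emitted file with its MD5 checksum.  Output is byte-identical
#' across runs for a fixed input and seed.
#'
#' @param panel a `simulated_panel` with injected carriers.
#' @param sv_truth result of [simulate_sv_truth()] (or `NULL`).
#' @param somatic result of [simulate_somatic_calls()] (or `NULL`).
#' @param out_dir output directory (created if needed).
#' @param cohort_size number of carrier individuals written as the cohort
#'   VCF (spread round-robin across populations, default 14).
#' @param chrom chromosome name used for the focal window (default
#'   "chr11", the beta-globin locus analogue).
#' @param seed RNG seed for the synthetic annotation tracks.
#' @return data.frame manifest (file, md5, bytes), invisibly; also
#'   written as `manifest.tsv`.
#' @export
write_fixture_bundle <- function(panel, sv_truth = NULL, somatic = NULL,
                                 out_dir, cohort_size = 14L, chrom = "chr11",
                                 seed = 1) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  }
  files <- character(0)
  ch <- cohort_individuals(panel, cohort_size)
  vcf_path <- file.path(out_dir, "cohort.vcf")
  .write_cohort_vcf(panel, ch, vcf_path, chrom = chrom)
  files <- c(files, vcf_path)

  pan_path <- file.path(out_dir, "panel_haplotypes.tsv")
  cohort_rows <- as.vector(rbind(2L * ch - 1L, 2L * ch))
  .write_haplotype_tsv(panel, setdiff(seq_len(nrow(panel$haplotypes)),
                                      cohort_rows),
                       origin = "panel", pan_path)
  files <- c(files, pan_path)

  sites_path <- file.path(out_dir, "panel_sites.tsv")
  write.table(cbind(chrom = chrom, panel$sites), sites_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  files <- c(files, sites_path)

  if (!is.null(sv_truth) && nrow(sv_truth$records)) {
    fa_path <- file.path(out_dir, "reference.fasta")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(sv_truth$reference), fa_path)
    bp_path <- file.path(out_dir, "breakpoints.tsv")
    cols <- c("event_id", "chrom1", "pos1", "strand1", "chrom2", "pos2",
              "strand2", "event_type", "contig_seq")
    write.table(sv_truth$records[, cols], bp_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    truth_path <- file.path(out_dir, "sv_truth.tsv")
    write.table(sv_truth$records, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    set.seed(seed)
    tr <- .synthetic_tracks(sv_truth$reference)
    rep_path <- file.path(out_dir, "repeats.bed")
    gene_path <- file.path(out_dir, "genes.bed")
    expr_path <- file.path(out_dir, "expression.tsv")
    .write_bed(tr$repeats, rep_path)
    .write_bed(tr$genes, gene_path)
    write.table(tr$expression, expr_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, fa_path, bp_path, truth_path, rep_path, gene_path,
               expr_path)
  }

  if (!is.null(somatic)) {
    som_path <- file.path(out_dir, "somatic_calls.tsv")
    write.table(somatic$calls, som_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    norm_path <- file.path(out_dir, "normals.tsv")
    norm <- do.call(rbind, lapply(names(somatic$normals), function(id) {
      d <- somatic$normals[[id]]
      if (!nrow(d)) return(NULL)
      cbind(normal_id = id, d)
    }))
    if (is.null(norm)) {
      norm <- data.frame(normal_id = character(), chrom = character(),
                         pos = integer(), ref = character(),
                         alt = character())
    }
    write.table(norm, norm_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, som_path, norm_path)
  }

  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    bytes = unname(file.size(files)),
    stringsAsFactors = FALSE
  )
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Cohort individual indices for a simulated panel
#'
#' Picks carrier individuals round-robin across populations (first
#' carriers of each population) to act as the sequenced cohort.
#'
#' @param panel a `simulated_panel` with carriers injected.
#' @param cohort_size number of individuals.
#' @return integer vector of individual indices (1-based over the panel's
#'   diploid pairing).
#' @export
cohort_individuals <- function(panel, cohort_size = 14L) {
  cfg <- panel$config
  hpp <- cfg$haplotypes_per_population
  offsets <- cumsum(c(0L, hpp[-length(hpp)])) %/% 2L
  ncarr <- panel$truth$cores$carriers
  if (is.null(ncarr)) stop("panel has no injected carriers")
  pool <- lapply(seq_along(hpp), function(k) offsets[k] + seq_len(ncarr[k]))
  picked <- integer(0)
  i <- 1L
  while (length(picked) < cohort_size) {
    k <- ((i - 1L) %% length(pool)) + 1L
    j <- (i - 1L) %/% length(pool) + 1L
    if (j <= length(pool[[k]])) picked <- c(picked, pool[[k]][j])
    i <- i + 1L
    if (i > 10L * cohort_size) stop("not enough carrier individuals")
  }
  picked
}

# multi-sample phased VCF: one record per panel site, FORMAT GT:PS:PQ
.write_cohort_vcf <- function(panel, individuals, path, chrom = "chr11",
                              phase_set = 1L, phase_quality = 30L) {
  H <- panel$haplotypes
  sites <- panel$sites
  sample_names <- sprintf("CASE%02d", seq_along(individuals))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=haploscope_syndata",
    sprintf("##contig=<ID=%s,length=%d>", chrom, panel$window_bp),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=PS,Number=1,Type=Integer,Description="Phase set">',
    '##FORMAT=<ID=PQ,Number=1,Type=Integer,Description="Phase quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  rows <- vapply(seq_len(nrow(sites)), function(i) {
    gts <- vapply(individuals, function(ind) {
      a1 <- H[2L * ind - 1L, i]; a2 <- H[2L * ind, i]
      sprintf("%d|%d:%d:%d", a1, a2, phase_set, phase_quality)
    }, character(1))
    paste(c(chrom, sites$position[i], ".", sites$ref[i], sites$alt[i],
            ".", "PASS", ".", "GT:PS:PQ", gts), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

.write_haplotype_tsv <- function(panel, rows, origin, path) {
  H <- panel$haplotypes[rows, , drop = FALSE]
  d <- data.frame(
    haplotype_id = rownames(H),
    label = ifelse(panel$carrier_flag[rows], "mutant", "wild_type"),
    origin = origin,
    population = panel$population_label[rows],
    stringsAsFactors = FALSE
  )
  colnames(H) <- paste0("p", colnames(H))
  write.table(cbind(d, H), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a haplotype-vector TSV into haplotype_vector objects
#'
#' Inverse of the tabular haplotype export: columns haplotype_id, label,
#' origin, population, then one 0/1 column per site (`p<position>`).
#'
#' @param path TSV path.
#' @return list of `haplotype_vector` objects.
#' @export
read_haplotype_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  site_cols <- grep("^p[0-9]+$", names(d))
  sites <- as.integer(sub("^p", "", names(d)[site_cols]))
  lapply(seq_len(nrow(d)), function(i) {
    structure(list(
      haplotype_id = d$haplotype_id[i],
      site_index = sites,
      values = as.integer(d[i, site_cols]),
      label = d$label[i], origin = d$origin[i], population = d$population[i]
    ), class = "haplotype_vector")
  })
}

# synthetic gene/repeat tracks + expression over reference fragments
.synthetic_tracks <- function(reference, genes_per_seq = 3L,
                              repeats_per_seq = 5L) {
  classes <- c("Alu", "L1", "LTR", "MIR")
  genes <- list(); reps <- list()
  for (nm in names(reference)) {
    len <- nchar(reference[[nm]])
    glen <- len %/% (2L * genes_per_seq)
    starts <- sort(sample.int(len - glen, genes_per_seq))
    for (i in seq_len(genes_per_seq)) {
      genes[[length(genes) + 1L]] <- data.frame(
        chrom = nm, start = starts[i], end = starts[i] + glen,
        name = sprintf("GENE_%s_%d", nm, i), score = 0,
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
    }
    rlen <- 150L
    rstarts <- sort(sample.int(len - rlen, repeats_per_seq))
    for (i in seq_len(repeats_per_seq)) {
      reps[[length(reps) + 1L]] <- data.frame(
        chrom = nm, start = rstarts[i], end = rstarts[i] + rlen,
        name = sample(classes, 1L), score = 0, strand = "+",
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, genes)
  list(
    genes = genes,
    repeats = do.call(rbind, reps),
    expression = data.frame(gene = genes$name,
                            tpm = round(stats::rexp(nrow(genes), 1 / 10), 2))
  )
}

.write_bed <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE-like breakpoint table
#'
#' @param path TSV with columns event_id, chrom1, pos1, strand1, chrom2,
#'   pos2, strand2, event_type, contig_seq.
#' @return data.frame.
#' @export
read_breakpoints <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
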