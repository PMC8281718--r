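test_that("junction classifier resolves blunt, microhomology and insertion", {
  blunt <- classify_junction("TTTTAAAA", "GGGGCCCC", "AAAAGGGG")
  expect_identical(blunt$class, "blunt")
  expect_identical(blunt$microhomology_len, 0L)
  expect_identical(blunt$inserted_seq, "")
  # "CA" is assignable to either flank: three equivalent splits
  mh <- classify_junction("TTGATTACA", "CAGGGTT", "GATTACAGGG")
  expect_identical(mh$class, "microhomology")
  expect_identical(mh$microhomology_len, 2L)
  expect_equal(mh$ambiguous_shift_range, c(5, 7))
  ins <- classify_junction("TTTTAAAA", "GGGGCCCC", "AAAATTGGGG")
  expect_identical(ins$class, "insertion")
  expect_identical(ins$inserted_seq, "TT")
  expect_identical(ins$microhomology_len, 0L)
  expect_error(classify_junction("AAAA", "CCCC", "GGGGGGGG"), "unalignable")
})

test_that("classifier agrees with the naive split-enumeration oracle", {
  ref <- simulate_reference(4, 12000, seed = 44)
  svt <- simulate_sv_truth(ref, 250, seed = 45)
  rec <- svt$records
  for (i in seq_len(nrow(rec))) {
    jc <- classify_junction(rec$left_flank[i], rec$right_flank[i],
                            rec$contig_seq[i])
    or <- oracle_junction(rec$left_flank[i], rec$right_flank[i],
                          rec$contig_seq[i])
    expect_identical(jc$class, or$class)
    expect_identical(jc$microhomology_len, as.integer(or$mh))
    expect_identical(jc$inserted_seq, or$ins)
    expect_equal(jc$ambiguous_shift_range, or$splits)
  }
})

test_that("every call reconstructs its fusion contig from the flanks", {
  ref <- simulate_reference(3, 8000, seed = 46)
  svt <- simulate_sv_truth(ref, 100, seed = 47)
  rec <- svt$records
  for (i in seq_len(nrow(rec))) {
    jc <- classify_junction(rec$left_flank[i], rec$right_flank[i],
                            rec$contig_seq[i])
    s <- jc$ambiguous_shift_range[1]   # canonical leftmost split
    m <- nchar(rec$contig_seq[i])
    left_part <- substr(rec$contig_seq[i], 1, s)
    right_part <- substr(rec$contig_seq[i],
                         s + nchar(jc$inserted_seq) + 1L, m)
    expect_identical(paste0(left_part, jc$inserted_seq, right_part),
                     rec$contig_seq[i])
    # left part really is left-flank sequence, right part right-flank
    expect_true(grepl(left_part, rec$left_flank[i], fixed = TRUE) || s == 0)
    expect_true(grepl(right_part, rec$right_flank[i], fixed = TRUE))
  }
})

test_that("junction summaries tally classes against the designed truth", {
  ref <- simulate_reference(seed = 50)
  svt <- simulate_sv_truth(ref, 60, seed = 51)
  rec <- svt$records
  calls <- lapply(seq_len(nrow(rec)), function(i)
    classify_junction(rec$left_flank[i], rec$right_flank[i],
                      rec$contig_seq[i]))
  s <- summarize_junction_classes(calls)
  expect_equal(s$n, 60)
  expect_equal(as.vector(s$class_counts[names(table(rec$designed_class))]),
               as.vector(table(rec$designed_class)))
  expect_equal(sum(s$class_fractions), 1)
  e <- summarize_junction_classes(list())
  expect_equal(e$n, 0)
  expect_equal(sum(e$class_counts), 0)
})

test_that("breakpoint annotation follows half-open BED semantics", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150),
                                  name = "GENE1")
  reps <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150),
                                 name = "Alu")
  # GRanges [51,150] is BED [50,150): pos 100 inside, pos 150 outside
  bp <- data.frame(chrom = c("chr1", "chr1", "chr1", "chrUn"),
                   pos = c(100, 150, 50, 10))
  expr <- data.frame(gene = "GENE1", tpm = 5)
  expect_warning(ann <- annotate_breakpoints(bp, reps, genes, expr),
                 "unknown chrom")
  expect_true(ann$genic[1]); expect_identical(ann$repeat_class[1], "Alu")
  expect_true(ann$transcribed[1])
  expect_false(ann$genic[2]); expect_true(is.na(ann$repeat_class[2]))
  expect_true(ann$genic[3])   # pos 50 = BED start, included
  expect_true(is.na(ann$genic[4]))
  # below the expression threshold the gene is not transcribed
  ann2 <- annotate_breakpoints(bp[1, ], reps, genes,
                               data.frame(gene = "GENE1", tpm = 0.5))
  expect_true(ann2$genic[1])
  expect_false(ann2$transcribed[1])
})

test_that("annotation equals a brute-force scan on random breakpoints", {
  set.seed(60)
  n_iv <- 40
  track <- data.frame(
    chrom = sample(c("c1", "c2"), n_iv, TRUE),
    start = sample(0:900, n_iv), name = sample(c("Alu", "L1", "LTR"), n_iv, TRUE))
  track$end <- track$start + sample(20:120, n_iv, TRUE)
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1, track$end),
                               name = track$name)
  bp <- data.frame(chrom = sample(c("c1", "c2"), 300, TRUE),
                   pos = sample(0:1100, 300, TRUE))
  ann <- annotate_breakpoints(bp, gr, gr, NULL)
  for (i in seq_len(nrow(bp))) {
    hit <- oracle_point_overlap(bp$chrom[i], bp$pos[i], track)
    expect_identical(ann$genic[i], !is.na(hit))
    if (!is.na(hit)) expect_false(is.na(ann$repeat_class[i]))
  }
})

test_that("percent identity matches the dynamic-programming oracle", {
  expect_equal(as.numeric(percent_identity("ACGTACGT", "ACGTACGT")), 100)
  expect_equal(as.numeric(percent_identity("ACGT", "ACGA")), 75)
  set.seed(71)
  # random pairs: the optimal score (matches - gap cost) is unique even
  # when co-optimal alignments trade matches against gaps, so score is
  # the quantity the oracle must reproduce exactly
  for (i in 1:15) {
    a <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
    pid <- percent_identity(a, b)
    cols <- attr(pid, "columns")
    impl_score <- attr(pid, "matches") - (2 * cols - nchar(a) - nchar(b))
    expect_equal(impl_score, oracle_nw_score(a, b), tolerance = 1e-9)
  }
  # high-identity pairs (unique optimum): identity itself must agree
  for (i in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    b <- paste0(substr(a, 1, 30), substr(a, 32, 60))       # one deletion
    substr(b, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(b, 10, 10))[1]     # one mismatch
    expect_equal(as.numeric(percent_identity(a, b)),
                 oracle_nw_identity(a, b), tolerance = 1e-9)
  }
  expect_error(percent_identity("", "ACGT"), "nonempty")
})

test_that("fusion transcript orientation and splice flags on a toy genome", {
  # gene A: + strand [11,60]; gene B: - strand [111,160]
  genes <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(c(11, 111), c(60, 160)),
    strand = c("+", "-"), name = c("GENEA", "GENEB"))
  g <- paste(rep("A", 200), collapse = "")
  # donor cut after base 40 (retained left, + strand): GT at 41-42
  substr(g, 41, 42) <- "GT"
  # acceptor at base 130 retained right (+ direction): AG at 128-129
  substr(g, 128, 129) <- "AG"
  genome <- setNames(g, "chrT")
  j <- list(donor = list(chrom = "chrT", pos = 40, retained = "left"),
            acceptor = list(chrom = "chrT", pos = 130, retained = "right"))
  out <- classify_fusion_transcript(j, genome, genes)
  expect_identical(out$class, "sense-to-antisense")  # B is on -, read on +
  expect_true(out$donor_gt)
  expect_true(out$acceptor_ag)
  # acceptor outside any gene: sense-to-intergenic
  j2 <- j; j2$acceptor$pos <- 180
  expect_identical(classify_fusion_transcript(j2, genome, genes)$class,
                   "sense-to-intergenic")
  # acceptor read against gene B's strand from the other side: sense-to-sense
  g3 <- g
  substr(g3, 131, 132) <- "CT"   # revcomp "AG" on the minus strand
  j3 <- j; j3$acceptor <- list(chrom = "chrT", pos = 130, retained = "left")
  out3 <- classify_fusion_transcript(j3, setNames(g3, "chrT"), genes)
  expect_identical(out3$class, "sense-to-sense")
  expect_true(out3$acceptor_ag)
  # donor in no gene: antisense-origin
  j4 <- j; j4$donor$pos <- 90
  expect_identical(classify_fusion_transcript(j4, genome, genes)$class,
                   "antisense-origin")
  expect_error(classify_fusion_transcript(
    list(donor = list(chrom = "chrX", pos = 1, retained = "left"),
         acceptor = j$acceptor), genome, genes), "outside")
})
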