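write_toy_vcf <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "toy.vcf")
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=PS,Number=1,Type=Integer,Description="Phase set">',
           '##FORMAT=<ID=PQ,Number=1,Type=Integer,Description="Phase quality">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S1"), collapse = "\t"))
  writeLines(c(hdr, lines), path)
  path
}

test_that("phased and unphased records map to calls correctly", {
  p <- write_toy_vcf(c(
    "chr11\t100\t.\tA\tT\t.\tPASS\t.\tGT:PS:PQ\t0|1:7312:30",
    "chr11\t200\t.\tG\tC\t.\tPASS\t.\tGT:PS:PQ\t0/1:.:12",
    "chr11\t300\t.\tT\tA\t.\tPASS\t.\tGT:PS:PQ\t1|1:7312:40"
  ))
  calls <- read_phased_vcf(p, "S1")
  expect_equal(nrow(calls), 3)
  r1 <- calls[calls$pos == 100, ]
  expect_true(r1$phased)
  expect_equal(r1$phase_set, 7312L)
  expect_equal(r1$phase_quality, 30L)
  expect_equal(c(r1$allele1, r1$allele2), c(0L, 1L))
  r2 <- calls[calls$pos == 200, ]
  expect_false(r2$phased)
  expect_true(is.na(r2$phase_set))
  r3 <- calls[calls$pos == 300, ]
  expect_equal(c(r3$allele1, r3$allele2), c(1L, 1L))
})

test_that("multiallelic records decompose into biallelic calls with PS kept", {
  p <- write_toy_vcf("chr11\t100\t.\tA\tT,G\t.\tPASS\t.\tGT:PS:PQ\t1|2:5:25")
  calls <- read_phased_vcf(p)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$alt, c("T", "G"))
  expect_equal(calls$allele1, c(1L, 0L))
  expect_equal(calls$allele2, c(0L, 1L))
  expect_true(all(calls$phase_set == 5L))
})

test_that("malformed records raise a parse error naming the line", {
  p <- write_toy_vcf(c(
    "chr11\t100\t.\tA\tT\t.\tPASS\t.\tGT:PS:PQ\t0|1:1:30",
    "chr11\t200\t.\tG\tC\t.\tPASS"     # truncated
  ))
  expect_error(read_phased_vcf(p), "line 7")
  expect_error(read_phased_vcf("does/not/exist.vcf"), "not found")
})

test_that("blocks group qualifying het calls by phase set", {
  mk <- function(pos, a1, a2, ps, pq, phased = TRUE) {
    data.frame(chrom = "chr11", pos = pos, ref = "A", alt = "T",
               allele1 = a1, allele2 = a2, phased = phased,
               phase_set = ps, phase_quality = pq, sample_id = "S1",
               stringsAsFactors = FALSE)
  }
  calls <- rbind(
    mk(100, 0L, 1L, 1L, 30), mk(200, 1L, 0L, 1L, 30), mk(300, 0L, 1L, 1L, 25),
    mk(400, 0L, 1L, 1L, 24), mk(500, 1L, 0L, 1L, 23),   # PQ 23 included
    mk(600, 0L, 1L, 1L, 22),                            # PQ 22 excluded
    mk(700, 0L, 1L, 2L, 30), mk(800, 1L, 0L, 2L, 30),   # second phase set
    mk(900, 1L, 1L, 1L, 30)                             # hom: never in block
  )
  blocks <- build_haplotype_blocks(calls)
  expect_length(blocks, 2)
  ps <- vapply(blocks, function(b) b$phase_set, integer(1))
  expect_setequal(ps, c(1L, 2L))
  b1 <- blocks[[match(1L, ps)]]
  expect_equal(b1$sites, c(100, 200, 300, 400, 500))
  expect_equal(blocks[[match(2L, ps)]]$sites, c(700, 800))
  excl <- attr(blocks, "excluded")
  expect_true(600 %in% excl$pos)
  # every qualifying het call lands in exactly one block
  all_sites <- unlist(lapply(blocks, function(b) b$sites))
  expect_false(anyDuplicated(all_sites) > 0)
  expect_setequal(all_sites, c(100, 200, 300, 400, 500, 700, 800))
  # mixed samples rejected
  bad <- rbind(calls, transform(mk(110, 0L, 1L, 1L, 30), sample_id = "S2"))
  expect_error(build_haplotype_blocks(bad), "single sample")
})

test_that("stitching merges across a bridge, flipping when needed", {
  A <- toy_block(c(10, 20, 30), c(1, 0, 1), c(0, 1, 0), ps = 1L)
  B <- toy_block(c(40, 50, 60), c(0, 0, 1), c(1, 1, 0), ps = 2L)
  # bridge hap1 matches A hap1 (3/3) and B hap2 (3/3) -> merge with swap
  bridge <- toy_block(c(10, 20, 30, 40, 50, 60),
                      c(1, 0, 1, 1, 1, 0), c(0, 1, 0, 0, 0, 1),
                      sample = "T1")
  out <- stitch_blocks(list(A, B), list(bridge))
  expect_length(out, 1)
  m <- out[[1]]
  expect_equal(m$sites, c(10, 20, 30, 40, 50, 60))
  expect_equal(m$hap1, c(1L, 0L, 1L, 1L, 1L, 0L))
  expect_equal(m$hap2, c(0L, 1L, 0L, 0L, 0L, 1L))
  # stitching conserves the unordered genotype multiset
  gt <- function(b) paste(b$sites, pmin(b$hap1, b$hap2), pmax(b$hap1, b$hap2))
  expect_setequal(gt(m), c(gt(A), gt(B)))
})

test_that("stitching refuses on partial overlap or ambiguous evidence", {
  A <- toy_block(c(10, 20, 30), c(1, 0, 1), c(0, 1, 0), ps = 1L)
  B <- toy_block(c(40, 50, 60), c(0, 0, 1), c(1, 1, 0), ps = 2L)
  only_a <- toy_block(c(10, 20, 30), c(1, 0, 1), c(0, 1, 0), sample = "T1")
  expect_length(stitch_blocks(list(A, B), list(only_a)), 2)
  # 50/50 agreement on the B side: ambiguous, no merge
  half <- toy_block(c(10, 20, 30, 40, 50, 60, 70, 80),
                    c(1, 0, 1, 0, 1, 0, 1, 0), c(0, 1, 0, 1, 0, 1, 0, 1),
                    sample = "T1")
  B4 <- toy_block(c(40, 50, 60, 70), c(0, 1, 1, 0), c(1, 0, 0, 1), ps = 2L)
  expect_length(stitch_blocks(list(A, B4), list(half)), 2)
})

test_that("haplotype vectors label the focal carrier and impute absences", {
  b <- toy_block(c(50, 100, 150), c(0, 0, 1), c(1, 1, 0))
  v <- extract_haplotype_vectors(list(b), focal = 100, halfwidth_bp = 100,
                                 panel_sites = c(0, 50, 100, 150, 200))
  labs <- vapply(v, function(h) h$label, character(1))
  expect_equal(labs, c("wild_type", "mutant"))
  # window closed at both ends: site at focal +/- halfwidth included
  expect_equal(v[[1]]$site_index, c(0, 50, 100, 150, 200))
  # absent sites imputed as reference
  expect_equal(v[[2]]$values, c(0L, 1L, 1L, 0L, 0L))
  # neither haplotype carries the focal alt
  b2 <- toy_block(c(50, 150), c(0, 1), c(1, 0))
  v2 <- extract_haplotype_vectors(list(b2), 100, 100, c(50, 100, 150))
  expect_true(all(vapply(v2, function(h) h$label, character(1)) ==
                    "wild_type"))
})

test_that("homozygous calls fill in from the call table", {
  b <- toy_block(c(100, 200), c(1, 0), c(0, 1))
  calls <- data.frame(chrom = "chr11", pos = c(100, 150, 200),
                      ref = "A", alt = "T",
                      allele1 = c(0L, 1L, 0L), allele2 = c(1L, 1L, 1L),
                      phased = TRUE, phase_set = 1L, phase_quality = 30L,
                      sample_id = "S1", stringsAsFactors = FALSE)
  v <- extract_haplotype_vectors(list(b), 100, 100,
                                 panel_sites = c(100, 150, 200),
                                 calls = calls)
  expect_equal(v[[1]]$values, c(1L, 1L, 0L))
  expect_equal(v[[2]]$values, c(0L, 1L, 1L))
})

test_that("a fragmented window raises an error naming the gap", {
  b1 <- toy_block(c(10, 20), c(1, 0), c(0, 1), ps = 1L)
  b2 <- toy_block(c(80, 90), c(1, 0), c(0, 1), ps = 2L)
  expect_error(
    extract_haplotype_vectors(list(b1, b2), 50, 50, panel_sites = c(10, 90)),
    "fragmented haplotype.*\\[20, 80\\]")
  expect_error(
    extract_haplotype_vectors(list(b1), 500, 50, panel_sites = c(10, 90)),
    "no haplotype block")
  expect_error(
    extract_haplotype_vectors(list(b1), 15, 10, panel_sites = numeric(0)),
    "nonempty")
})

test_that("site concordance counts matching unordered genotypes", {
  mk <- function(pos, alt, a1, a2) {
    data.frame(chrom = "chr11", pos = pos, ref = "A", alt = alt,
               allele1 = a1, allele2 = a2, phased = TRUE, phase_set = 1L,
               phase_quality = 30L, sample_id = "S1",
               stringsAsFactors = FALSE)
  }
  a <- rbind(mk(1, "T", 0L, 1L), mk(2, "T", 1L, 1L), mk(3, "T", 0L, 1L),
             mk(4, "T", 0L, 1L))
  expect_equal(site_concordance(a, a)$fraction, 1)
  # one of four discordant (different alt allele at pos 4)
  b <- rbind(mk(1, "T", 0L, 1L), mk(2, "T", 1L, 1L), mk(3, "T", 0L, 1L),
             mk(4, "G", 0L, 1L))
  sc <- site_concordance(a, b)
  expect_equal(sc$fraction, 3 / 5)  # union has 5 records
  expect_setequal(sc$concordant$pos, c(1, 2, 3))
  # swapped phase is still the same unordered genotype
  c_ <- rbind(mk(1, "T", 1L, 0L))
  expect_equal(site_concordance(a[1, ], c_)$fraction, 1)
})
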