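test_that("panel simulation is deterministic and respects the F=0 limit", {
  cfg <- panel_sim_config(n_sites = 50, haplotypes_per_population = 10,
                          seed = 3)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_identical(p1$sites, p2$sites)

  cfg0 <- panel_sim_config(n_sites = 30, haplotypes_per_population = 4,
                           fst = 0, seed = 5)
  p0 <- simulate_panel(cfg0)
  pf <- p0$truth$pop_freq
  expect_true(all(apply(pf, 2, function(x) diff(range(x)) == 0)))
})

test_that("Balding-Nichols sampling has the expected mean and variance", {
  cfg <- panel_sim_config(n_populations = 3, haplotypes_per_population = 2,
                          n_sites = 10000, fst = 0.5,
                          ancestral_freq_dist = function(n) rep(0.5, n),
                          seed = 17)
  p <- simulate_panel(cfg)
  pf <- p$truth$pop_freq
  # Beta mean identity: E[pop freq] = p0
  se <- sqrt(0.5 * 0.5 * 0.5 / length(pf))
  expect_lt(abs(mean(pf) - 0.5), 3 * se)
  # across-population variance of site frequency ~ F p0 (1 - p0)
  v <- mean(apply(pf, 2, stats::var))
  expect_lt(abs(v - 0.5 * 0.25) / (0.5 * 0.25), 0.1)
})

test_that("config validation rejects impossible parameters", {
  expect_error(panel_sim_config(fst = 1), "fst")
  expect_error(panel_sim_config(fst = -0.1), "fst")
  expect_error(panel_sim_config(n_sites = 0), "n_sites")
  expect_error(panel_sim_config(focal_position = 300000), "within the window")
  expect_error(panel_sim_config(haplotypes_per_population = 7), "even")
})

test_that("IBD cores copy a template within each population", {
  cfg <- panel_sim_config(n_sites = 200, haplotypes_per_population = 20,
                          core_halfwidth_bp = 40000, seed = 9)
  panel <- inject_ibd_core(simulate_panel(cfg), carrier_assignment = 5)
  pos <- panel$sites$position
  core <- pos >= 60000 & pos <= 140000
  H <- panel$haplotypes
  carr <- which(panel$carrier_flag)
  pops <- panel$population_label
  # same population: identical inside the core
  same <- carr[pops[carr] == "POP1"]
  expect_gt(length(same), 1)
  for (r in same[-1]) {
    expect_identical(H[same[1], core], H[r, core])
  }
  # different populations: focal allele shared, cores generally differ
  cross <- c(same[1], carr[pops[carr] == "POP2"][1])
  focal_col <- match(panel$focal_position, pos)
  expect_equal(unname(H[cross, focal_col]), c(1L, 1L))
  expect_gt(sum(H[cross[1], core] != H[cross[2], core]), 0)
  # carrier flag <=> focal allele, for every haplotype
  expect_identical(unname(H[, focal_col] == 1L), panel$carrier_flag)
})

test_that("degenerate IBD cores only touch the focal site", {
  cfg <- panel_sim_config(n_sites = 100, haplotypes_per_population = 10,
                          seed = 21)
  base <- simulate_panel(cfg)
  panel <- inject_ibd_core(base, carrier_assignment = 2,
                           core_halfwidth_bp = 0)
  focal_col <- match(panel$focal_position, panel$sites$position)
  diff_cols <- unname(which(colSums(panel$haplotypes != base$haplotypes) > 0))
  expect_identical(diff_cols, focal_col)
  expect_error(inject_ibd_core(base, core_halfwidth_bp = 150000),
               "exceeds the simulation window")
  expect_error(inject_ibd_core(base, carrier_assignment = 99),
               "exceeds individuals")
})

test_that("SV truth generator round-trips through the junction classifier", {
  ref <- simulate_reference(4, 12000, seed = 2)
  svt <- simulate_sv_truth(ref, 200, seed = 4)
  rec <- svt$records
  expect_equal(nrow(rec), 200)
  for (i in seq_len(nrow(rec))) {
    jc <- classify_junction(rec$left_flank[i], rec$right_flank[i],
                            rec$contig_seq[i])
    expect_identical(jc$class, rec$designed_class[i])
    expect_identical(jc$microhomology_len, rec$designed_mh[i])
    expect_identical(jc$inserted_seq, rec$designed_ins[i])
  }
  # flanks must re-extract from the (edited) returned reference
  for (i in seq_len(nrow(rec))) {
    lf <- substr(svt$reference[[rec$chrom1[i]]], rec$pos1[i] - 29, rec$pos1[i])
    expect_identical(lf, rec$left_flank[i])
  }
})

test_that("SV truth generator handles degenerate requests", {
  ref <- simulate_reference(seed = 2)
  expect_equal(nrow(simulate_sv_truth(ref, 0)$records), 0)
  blunt <- simulate_sv_truth(ref, 10, class_mix = c(blunt = 1), seed = 1)
  for (i in 1:10) {
    jc <- classify_junction(blunt$records$left_flank[i],
                            blunt$records$right_flank[i],
                            blunt$records$contig_seq[i])
    expect_identical(jc$class, "blunt")
    expect_identical(jc$microhomology_len, 0L)
  }
  expect_error(simulate_sv_truth(ref, 5, mh_range = c(25, 30)),
               "exceeds contig flank")
  expect_error(simulate_sv_truth(setNames("ACGT", "tiny"), 1), "exceed")
})

test_that("somatic simulator plants artifacts into multiple normals", {
  som <- simulate_somatic_calls(n_real = 20, n_artifact = 5,
                                kataegis_clusters = 1, seed = 6)
  art <- som$calls[som$calls$truth == "artifact", ]
  expect_equal(nrow(art), 5)
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  counts <- table(unlist(lapply(som$normals, function(d) unique(key(d)))))
  expect_true(all(key(art) %in% names(counts)))
  expect_true(all(counts[key(art)] >= 2))
  # PON built at the >= 2 rule removes every artifact
  pon <- build_pon(som$normals, min_samples = 2)
  fr <- filter_somatic(som$calls, pon)
  expect_false(any(fr$retained$truth == "artifact"))
  expect_true(all(fr$removed$reason[fr$removed$truth == "artifact"] ==
                    "panel_of_normals"))
  # kataegis cluster present with <= 1 kb spacing
  kat <- som$calls[som$calls$truth == "kataegis", ]
  expect_equal(nrow(kat), 8)
  expect_true(all(diff(sort(kat$pos)) <= 1000))
  # empty request
  e <- simulate_somatic_calls(0, 0, 0, seed = 1)
  expect_equal(nrow(e$calls), 0)
  expect_error(simulate_somatic_calls(-1, 0), "non-negative")
})

test_that("fixture bundles round-trip and are byte-deterministic", {
  cfg <- panel_sim_config(n_sites = 40, haplotypes_per_population = c(8, 8, 8),
                          seed = 13)
  panel <- inject_ibd_core(simulate_panel(cfg))
  ref <- simulate_reference(2, 2000, seed = 13)
  svt <- simulate_sv_truth(ref, 6, seed = 13)
  som <- simulate_somatic_calls(5, 2, seed = 13)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_fixture_bundle(panel, svt, som, d1, cohort_size = 4, seed = 13)
  m2 <- write_fixture_bundle(panel, svt, som, d2, cohort_size = 4, seed = 13)
  # manifest lists every emitted file (all but itself)
  expect_setequal(m1$file, setdiff(list.files(d1), "manifest.tsv"))
  # byte-level determinism
  expect_identical(m1$md5, m2$md5)

  # VCF round-trip: genotypes match the simulated haplotypes exactly
  calls <- read_phased_vcf(file.path(d1, "cohort.vcf"))
  ch <- cohort_individuals(panel, 4)
  for (j in seq_along(ch)) {
    cc <- calls[calls$sample_id == sprintf("CASE%02d", j), ]
    cc <- cc[order(cc$pos), ]
    expect_identical(cc$allele1, unname(panel$haplotypes[2 * ch[j] - 1, ]))
    expect_identical(cc$allele2, unname(panel$haplotypes[2 * ch[j], ]))
    expect_true(all(cc$phased))
    expect_true(all(cc$phase_quality == 30))
  }
  # panel TSV round-trip preserves labels and values
  pan <- read_haplotype_tsv(file.path(d1, "panel_haplotypes.tsv"))
  expect_equal(length(pan), nrow(panel$haplotypes) - 2 * length(ch))
  expect_true(all(vapply(pan, function(h)
    (h$label == "mutant") == (h$values[match(panel$focal_position,
                                             h$site_index)] == 1),
    logical(1))))
})
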