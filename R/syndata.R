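#' Configuration for the phased-panel simulator
#'
#' Describes a focal window (default 200 kb) holding a risk allele, a
#' reference panel of trait-carrier haplotypes with population structure,
#' and identity-by-descent (IBD) cores around the focal allele.  Population
#' divergence follows the Balding-Nichols model: per site an ancestral
#' frequency `p0` is drawn from `ancestral_freq_dist`, and each
#' population's frequency from `Beta(p0 (1-F)/F, (1-p0)(1-F)/F)`.
#'
#' Defaults emulate the motivating study design: three African
#' populations, 137 trait-carrier haplotype pairs in the panel
#' (46 + 46 + 45 diploid carriers), a 200-kb window with the focal allele
#' at its center, IBD cores spanning the whole window (shared segments
#' around such an allele extend megabases in real data, well beyond a
#' 200-kb view), and a mild subpopulation divergence of F = 0.02.
#'
#' @param n_populations number of populations.
#' @param haplotypes_per_population haplotypes per population (scalar or
#'   vector of length `n_populations`); must be even, haplotypes are
#'   paired into diploid individuals.
#' @param window_bp window length in bp.
#' @param n_sites number of polymorphic sites in the window.
#' @param ancestral_freq_dist function of `n` returning ancestral allele
#'   frequencies in (0, 1).
#' @param fst Balding-Nichols divergence parameter F in `[0, 1)`.
#' @param focal_position bp offset of the focal risk allele in the window.
#' @param core_halfwidth_bp IBD core half-width in bp.
#' @param seed RNG seed.
#' @return object of class `panel_sim_config`.
#' @export
panel_sim_config <- function(n_populations = 3,
                             haplotypes_per_population = c(92, 92, 90),
                             window_bp = 200000,
                             n_sites = 400,
                             ancestral_freq_dist = function(n) runif(n, 0.05, 0.95),
                             fst = 0.02,
                             focal_position = 100000,
                             core_halfwidth_bp = 100000,
                             seed = 1) {
  if (length(haplotypes_per_population) == 1L) {
    haplotypes_per_population <- rep(haplotypes_per_population, n_populations)
  }
  stopifnot(length(haplotypes_per_population) == n_populations)
  if (any(haplotypes_per_population %% 2 != 0)) {
    stop("haplotypes_per_population must be even (diploid pairing)")
  }
  if (!is.numeric(fst) || fst < 0 || fst >= 1) {
    stop("fst must lie in [0, 1)")
  }
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (focal_position < 1 || focal_position > window_bp) {
    stop("focal_position must lie within the window")
  }
  structure(list(
    n_populations = as.integer(n_populations),
    haplotypes_per_population = as.integer(haplotypes_per_population),
    window_bp = as.integer(window_bp),
    n_sites = as.integer(n_sites),
    ancestral_freq_dist = ancestral_freq_dist,
    fst = fst,
    focal_position = as.integer(focal_position),
    core_halfwidth_bp = as.integer(core_halfwidth_bp),
    seed = as.integer(seed)
  ), class = "panel_sim_config")
}

#' Simulate a phased haplotype panel with population structure
#'
#' Draws a haplotype-by-site 0/1 matrix under the Balding-Nichols model
#' described in [panel_sim_config()].  The focal site is forced to 0 on
#' every haplotype; carriers are created afterwards with
#' [inject_ibd_core()], so the carrier-flag/focal-allele invariant holds
#' at every stage.
#'
#' @param config a `panel_sim_config`.
#' @return object of class `simulated_panel`: list with `sites`
#'   (data.frame position/ref/alt), `haplotypes` (0/1 integer matrix,
#'   haplotype x site, site positions as column names), `population_label`,
#'   `carrier_flag`, `focal_position`, `window_bp`, `truth`, `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_sim_config"))
  set.seed(config$seed)
  n_sites <- config$n_sites
  # site positions: focal site always present
  pool <- setdiff(seq_len(config$window_bp), config$focal_position)
  pos <- sort(c(config$focal_position,
                sample(pool, n_sites - 1L)))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  p0 <- config$ancestral_freq_dist(n_sites)
  if (any(p0 <= 0 | p0 >= 1)) stop("ancestral frequencies must lie in (0,1)")
  F <- config$fst
  npop <- config$n_populations
  hpp <- config$haplotypes_per_population
  pop_freq <- matrix(NA_real_, npop, n_sites)
  for (k in seq_len(npop)) {
    pop_freq[k, ] <- if (F > 0) {
      rbeta(n_sites, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
    } else p0
  }
  total <- sum(hpp)
  H <- matrix(0L, total, n_sites)
  poplab <- character(total)
  row <- 0L
  for (k in seq_len(npop)) {
    for (h in seq_len(hpp[k])) {
      row <- row + 1L
      H[row, ] <- rbinom(n_sites, 1L, pop_freq[k, ])
      poplab[row] <- sprintf("POP%d", k)
    }
  }
  focal_idx <- match(config$focal_position, pos)
  H[, focal_idx] <- 0L   # carriers are created by inject_ibd_core()
  colnames(H) <- as.character(pos)
  rownames(H) <- sprintf("%s_hap%03d", poplab, stats::ave(
    seq_len(total), poplab, FUN = seq_along))
  structure(list(
    sites = data.frame(position = pos, ref = ref, alt = alt,
                       stringsAsFactors = FALSE),
    haplotypes = H,
    population_label = poplab,
    carrier_flag = rep(FALSE, total),
    focal_position = config$focal_position,
    window_bp = config$window_bp,
    truth = list(pop_freq = pop_freq, p0 = p0, cores = NULL),
    config = config
  ), class = "simulated_panel")
}

#' @export
print.simulated_panel <- function(x, ...) {
  cat("Simulated phased panel: ", nrow(x$haplotypes), " haplotypes (",
      sum(x$carrier_flag), " carriers), ", nrow(x$sites),
      " sites in a ", x$window_bp, "-bp window; focal allele at ",
      x$focal_position, "\n", sep = "")
  invisible(x)
}

#' Inject shared IBD cores around the focal allele
#'
#' Within each population, the alleles of one template haplotype inside
#' `[focal - halfwidth, focal + halfwidth]` are copied onto all designated
#' carrier haplotypes of that population, and the focal-site allele is set
#' to 1.  Outside the core, alleles are untouched.  Carriers are taken as
#' haplotype 1 of the first individuals of each population, so each trait
#' carrier is heterozygous: haplotype 1 mutant, haplotype 2 wild-type.
#'
#' This reproduces, deliberately without mutation or recombination decay,
#' the signature of a risk allele arising independently on a handful of
#' ancestral haplotypes: carriers within a population are identical across
#' the core, carriers in different populations share only the focal allele.
#'
#' @param panel a `simulated_panel`.
#' @param carrier_assignment carriers (diploid individuals) per population;
#'   scalar, vector, or `NULL` for "every individual is a carrier".
#' @param core_halfwidth_bp core half-width; defaults to the config value.
#' @return the modified `simulated_panel`, with `carrier_flag` set and
#'   per-population core boundaries recorded in `truth$cores`.
#' @export
inject_ibd_core <- function(panel, carrier_assignment = NULL,
                            core_halfwidth_bp = NULL) {
  stopifnot(inherits(panel, "simulated_panel"))
  cfg <- panel$config
  if (is.null(core_halfwidth_bp)) core_halfwidth_bp <- cfg$core_halfwidth_bp
  lo <- panel$focal_position - core_halfwidth_bp
  hi <- panel$focal_position + core_halfwidth_bp
  if (lo < 0 || hi > panel$window_bp) {
    stop("IBD core [", lo, ", ", hi, "] exceeds the simulation window")
  }
  hpp <- cfg$haplotypes_per_population
  if (is.null(carrier_assignment)) carrier_assignment <- hpp %/% 2L
  if (length(carrier_assignment) == 1L) {
    carrier_assignment <- rep(carrier_assignment, cfg$n_populations)
  }
  if (any(carrier_assignment > hpp %/% 2L)) {
    stop("carrier count exceeds individuals in a population")
  }
  pos <- panel$sites$position
  core_cols <- which(pos >= lo & pos <= hi)
  focal_col <- match(panel$focal_position, pos)
  offset <- 0L
  cores <- data.frame(population = sprintf("POP%d", seq_len(cfg$n_populations)),
                      core_start = lo, core_end = hi,
                      carriers = as.integer(carrier_assignment))
  for (k in seq_len(cfg$n_populations)) {
    nc <- carrier_assignment[k]
    if (nc > 0L) {
      # carriers: haplotype 1 of the first nc individuals of this population
      carrier_rows <- offset + 2L * seq_len(nc) - 1L
      template <- panel$haplotypes[carrier_rows[1], core_cols]
      for (r in carrier_rows) panel$haplotypes[r, core_cols] <- template
      panel$haplotypes[carrier_rows, focal_col] <- 1L
      panel$carrier_flag[carrier_rows] <- TRUE
    }
    offset <- offset + hpp[k]
  }
  panel$truth$cores <- cores
  panel
}

#' Simulate a structural-variant truth set with designed junction chemistry
#'
#' Samples non-overlapping breakpoint pairs on the supplied reference
#' sequences and builds, for each event, an assembled fusion contig with a
#' designed junction class: blunt join, k-bp microhomology, or untemplated
#' insertion.  For microhomology events the reference is edited so that
#' the first k bases downstream of the right breakpoint equal the last k
#' bases upstream of the left breakpoint, making the junction placement
#' ambiguous over exactly k + 1 positions.  Insertion sequences are
#' resampled until they extend neither flank, so the designed class is
#' unambiguous.  The (possibly edited) reference is returned alongside the
#' records so that downstream flank extraction is consistent.
#'
#' @param reference named character vector or `Biostrings::DNAStringSet`.
#' @param n_events number of events.
#' @param class_mix named probabilities over
#'   `c("blunt", "microhomology", "insertion")`; must sum to 1.
#' @param seed RNG seed.
#' @param flank_len reference flank length stored per breakpoint.
#' @param contig_flank bases of each flank included in the fusion contig
#'   (must be `< flank_len`).
#' @param mh_range inclusive range of designed microhomology lengths.
#' @param ins_range inclusive range of designed insertion lengths.
#' @return list with `records` (data.frame: event_id, chrom1, pos1,
#'   strand1, chrom2, pos2, strand2, event_type, designed_class,
#'   designed_mh, designed_ins, left_flank, right_flank, contig_seq) and
#'   `reference` (named character vector after microhomology edits).
#' @export
simulate_sv_truth <- function(reference, n_events,
                              class_mix = c(blunt = 0.5, microhomology = 0.3,
                                            insertion = 0.2),
                              seed = 1, flank_len = 30L, contig_flank = 18L,
                              mh_range = c(1L, 5L), ins_range = c(1L, 4L)) {
  ref <- .as_seq_vector(reference)
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (any(!names(class_mix) %in% c("blunt", "microhomology", "insertion"))) {
    stop("class_mix names must be blunt/microhomology/insertion")
  }
  if (contig_flank >= flank_len) stop("contig_flank must be < flank_len")
  if (mh_range[2] >= contig_flank) stop("microhomology exceeds contig flank")
  if (any(nchar(ref) < 2L * flank_len + 2L)) {
    stop("each reference sequence must exceed twice the flank length")
  }
  set.seed(seed)
  if (n_events == 0L) {
    return(list(records = data.frame(), reference = ref))
  }
  used <- lapply(ref, function(s) integer(0))  # occupied positions per seq
  bases <- c("A", "C", "G", "T")
  recs <- vector("list", n_events)
  for (i in seq_len(n_events)) {
    cls <- sample(names(class_mix), 1L, prob = class_mix)
    k <- if (cls == "microhomology") {
      sample(seq(mh_range[1], mh_range[2]), 1L)
    } else 0L
    ev_type <- if (length(ref) >= 2L && runif(1) < 0.5) "translocation" else "deletion"
    # rejection-sample non-overlapping breakpoints with full flank context
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      if (attempts > 2000L) {
        stop("reference too small to place ", n_events,
             " non-overlapping events")
      }
      if (ev_type == "translocation") {
        cs <- sample(names(ref), 2L)
        c1 <- cs[1]; c2 <- cs[2]
      } else {
        c1 <- c2 <- sample(names(ref), 1L)
      }
      p1 <- sample(seq(flank_len, nchar(ref[[c1]]) - flank_len), 1L)
      p2 <- sample(seq(flank_len + 1L, nchar(ref[[c2]]) - flank_len), 1L)
      if (ev_type == "deletion") {
        if (p2 <= p1 + 2L * flank_len) next
      }
      win1 <- (p1 - flank_len + 1L):(p1 + 2L)
      win2 <- (p2 - flank_len):(p2 + flank_len - 1L)
      if (any(win1 %in% used[[c1]])) next
      if (c1 == c2 && any(win2 %in% win1)) next
      if (any(win2 %in% used[[c2]])) next
      break
    }
    used[[c1]] <- c(used[[c1]], win1)
    used[[c2]] <- c(used[[c2]], win2)
    left_flank <- substr(ref[[c1]], p1 - flank_len + 1L, p1)
    if (cls == "microhomology") {
      # edit reference: first k bases at/after the right breakpoint get the
      # microhomology segment copied from the left flank end
      mh_seq <- substr(left_flank, flank_len - k + 1L, flank_len)
      substr(ref[[c2]], p2, p2 + k - 1L) <- mh_seq
    }
    right_flank <- substr(ref[[c2]], p2, p2 + flank_len - 1L)
    ins <- ""
    if (cls == "insertion") {
      len <- sample(seq(ins_range[1], ins_range[2]), 1L)
      repeat {
        ins <- paste(sample(bases, len, replace = TRUE), collapse = "")
        ok_r <- substr(ins, 1L, 1L) != substr(right_flank, 1L, 1L)
        ok_l <- substr(ins, len, len) != substr(left_flank, flank_len, flank_len)
        if (ok_r && ok_l) break
      }
    }
    left_part <- substr(left_flank, flank_len - contig_flank + 1L, flank_len)
    right_part <- substr(right_flank, k + 1L, k + contig_flank)
    contig <- paste0(left_part, ins, right_part)
    recs[[i]] <- data.frame(
      event_id = sprintf("SV%04d", i),
      chrom1 = c1, pos1 = p1, strand1 = "+",
      chrom2 = c2, pos2 = p2, strand2 = "+",
      event_type = ev_type,
      designed_class = cls,
      designed_mh = k,
      designed_ins = ins,
      left_flank = left_flank,
      right_flank = right_flank,
      contig_seq = contig,
      stringsAsFactors = FALSE
    )
  }
  list(records = do.call(rbind, recs), reference = ref)
}

#' Simulate a somatic SNV call set with artifact and kataegis structure
#'
#' Builds a tumor call table with three truth strata: genuine dispersed
#' somatic SNVs, recurrent technical artifacts planted into two or more
#' synthetic normals (for panel-of-normals filtering), and kataegis
#' clusters of closely spaced SNVs.  Read support uses a fixed-depth
#' binomial model (default depth 80, the scale of a deeply sequenced
#' tumor genome).
#'
#' @param n_real genuine dispersed somatic SNVs.
#' @param n_artifact recurrent artifacts (each planted in >= 2 normals).
#' @param kataegis_clusters number of kataegis clusters.
#' @param vaf_dist function of `n` returning variant allele fractions.
#' @param seed RNG seed.
#' @param depth sequencing depth per site.
#' @param n_normals number of synthetic normal samples.
#' @param kataegis_size SNVs per kataegis cluster.
#' @param common_af_sites additional calls given a database population
#'   allele frequency above 0.1 percent (germline leakage analogue).
#' @return list with `calls` (data.frame: chrom, pos, ref, alt, alt_reads,
#'   depth, vaf, population_af, truth) and `normals` (list of per-normal
#'   data.frames with chrom/pos/ref/alt).
#' @export
simulate_somatic_calls <- function(n_real, n_artifact, kataegis_clusters = 0L,
                                   vaf_dist = function(n) runif(n, 0.15, 0.6),
                                   seed = 1, depth = 80L, n_normals = 12L,
                                   kataegis_size = 8L, common_af_sites = 0L) {
  if (n_real < 0 || n_artifact < 0 || kataegis_clusters < 0) {
    stop("counts must be non-negative")
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  mk <- function(n, chrom, pos, truth, af = 0) {
    if (n == 0L) return(NULL)
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    vaf <- vaf_dist(n)
    alt_reads <- rbinom(n, depth, vaf)
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               alt_reads = alt_reads, depth = as.integer(depth),
               vaf = alt_reads / depth, population_af = af,
               truth = truth, stringsAsFactors = FALSE)
  }
  parts <- list()
  if (n_real > 0L) {
    parts$real <- mk(n_real, sample(paste0("chr", 1:21), n_real, replace = TRUE),
                     sort(sample.int(5e7, n_real)), "somatic")
  }
  if (n_artifact > 0L) {
    parts$artifact <- mk(n_artifact,
                         sample(paste0("chr", 1:21), n_artifact, replace = TRUE),
                         sort(sample.int(5e7, n_artifact)) + 5e7, "artifact")
  }
  if (kataegis_clusters > 0L) {
    kat <- list()
    start <- 0
    for (j in seq_len(kataegis_clusters)) {
      start <- start + sample.int(5e5, 1L) + 1e5
      gaps <- sample(100:900, kataegis_size - 1L, replace = TRUE)
      pos <- start + c(0L, cumsum(gaps))
      kat[[j]] <- mk(kataegis_size, "chr22", pos, "kataegis")
      start <- max(pos)
    }
    parts$kataegis <- do.call(rbind, kat)
  }
  if (common_af_sites > 0L) {
    parts$common <- mk(common_af_sites,
                       sample(paste0("chr", 1:21), common_af_sites, replace = TRUE),
                       sort(sample.int(4e7, common_af_sites)) + 1.1e8,
                       "common_germline", af = runif(common_af_sites, 0.002, 0.05))
  }
  calls <- do.call(rbind, parts)
  if (is.null(calls)) {
    calls <- data.frame(chrom = character(), pos = integer(), ref = character(),
                        alt = character(), alt_reads = integer(),
                        depth = integer(), vaf = numeric(),
                        population_af = numeric(), truth = character(),
                        stringsAsFactors = FALSE)
  }
  rownames(calls) <- NULL
  # plant each artifact in >= 2 normals
  normals <- replicate(n_normals, NULL, simplify = FALSE)
  art <- calls[calls$truth == "artifact", c("chrom", "pos", "ref", "alt")]
  if (nrow(art) > 0L) {
    for (i in seq_len(nrow(art))) {
      ks <- sample.int(n_normals, sample(2:min(4L, n_normals), 1L))
      for (k in ks) normals[[k]] <- rbind(normals[[k]], art[i, ])
    }
  }
  normals <- lapply(normals, function(d) {
    if (is.null(d)) data.frame(chrom = character(), pos = integer(),
                               ref = character(), alt = character(),
                               stringsAsFactors = FALSE) else d
  })
  names(normals) <- sprintf("NORMAL%02d", seq_len(n_normals))
  list(calls = calls, normals = normals)
}

.as_seq_vector <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    ref <- as.character(reference)
  } else if (is.character(reference)) {
    ref <- reference
  } else stop("reference must be a named character vector or DNAStringSet")
  if (is.null(names(ref)) || any(!nzchar(names(ref)))) {
    stop("reference sequences must be named")
  }
  ref
}

#' Generate a random reference of named DNA fragments
#'
#' Convenience generator for synthetic reference fragments used by the
#' SV truth simulator and fixture bundles.
#'
#' @param n_seqs number of fragments.
#' @param len length of each fragment in bp.
#' @param seed RNG seed.
#' @return named character vector of DNA sequences.
#' @export
simulate_reference <- function(n_seqs = 3L, len = 5000L, seed = 1) {
  set.seed(seed)
  setNames(
    vapply(seq_len(n_seqs), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1)),
    sprintf("frag%d", seq_len(n_seqs))
  )
}
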