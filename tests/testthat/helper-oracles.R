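# Independent brute-force oracles, deliberately written with naive loops
# so they share no code path with the package implementations.

# one-sided Fisher p by exhaustive enumeration of equiprobable carrier
# placements (exact for small N)
oracle_fisher_enum <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c          # carriers
  n <- a + b          # mutant-labeled
  if (n == 0L || N == 0L) return(1)
  hits <- 0L
  total <- 0L
  sets <- if (n == N) matrix(seq_len(N), ncol = 1) else utils::combn(N, n)
  for (j in seq_len(ncol(sets))) {
    x <- sum(sets[, j] <= K)   # carriers landing on the mutant side
    total <- total + 1L
    if (x >= a) hits <- hits + 1L
  }
  hits / total
}

# enumeration oracle for junction splits: split s valid iff contig[1..s]
# occurs in left flank and contig[s+1..m] occurs in right flank
oracle_junction <- function(left, right, contig) {
  m <- nchar(contig)
  occurs <- function(piece, seqc) {
    lp <- nchar(piece)
    if (lp == 0L) return(TRUE)
    ls <- nchar(seqc)
    if (lp > ls) return(FALSE)
    for (st in 1:(ls - lp + 1L)) {
      if (substr(seqc, st, st + lp - 1L) == piece) return(TRUE)
    }
    FALSE
  }
  valid <- integer(0)
  for (s in 0:m) {
    if (occurs(substr(contig, 1, s), left) &&
        occurs(substr(contig, s + 1L, m), right)) {
      valid <- c(valid, s)
    }
  }
  if (length(valid)) {
    mh <- length(valid) - 1L
    list(class = if (mh == 0L) "blunt" else "microhomology",
         mh = mh, ins = "", splits = range(valid))
  } else {
    L <- 0L
    for (s in 0:m) if (occurs(substr(contig, 1, s), left)) L <- s
    R <- 0L
    for (r in 0:m) if (occurs(substr(contig, m - r + 1L, m), right)) R <- r
    list(class = "insertion", mh = 0L,
         ins = substr(contig, L + 1L, m - R), splits = c(L, L))
  }
}

# Needleman-Wunsch optimal score oracle (unique even with co-optimal paths)
oracle_nw_score <- function(a, b, g = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -g * (0:n); S[1, ] <- -g * (0:m)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(S[i, j] + (av[i] == bv[j]),
                           S[i, j + 1] - g, S[i + 1, j] - g)
  }
  S[n + 1, m + 1]
}

# Needleman-Wunsch identity oracle: match +1, mismatch 0, linear gap -g
oracle_nw_identity <- function(a, b, g = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -g * (0:n); S[1, ] <- -g * (0:m)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(S[i, j] + (av[i] == bv[j]),
                           S[i, j + 1] - g, S[i + 1, j] - g)
  }
  # traceback to count matches and columns
  i <- n; j <- m; matches <- 0L; cols <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        abs(S[i + 1, j + 1] - (S[i, j] + (av[i] == bv[j]))) < 1e-9) {
      matches <- matches + (av[i] == bv[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && abs(S[i + 1, j + 1] - (S[i, j + 1] - g)) < 1e-9) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    cols <- cols + 1L
  }
  100 * matches / cols
}

# brute-force point-in-interval annotation: p in [start, end)
oracle_point_overlap <- function(chrom, pos, track) {
  hit <- NA_character_
  for (i in seq_len(nrow(track))) {
    if (track$chrom[i] == chrom && pos >= track$start[i] &&
        pos < track$end[i]) {
      hit <- track$name[i]
      break
    }
  }
  hit
}

# small toy haplotype_block constructor for stitching tests
toy_block <- function(sites, hap1, hap2, sample = "S1", ps = 1L) {
  structure(list(sample_id = sample, chrom = "chr11", phase_set = ps,
                 sites = sites, ref = rep("A", length(sites)),
                 alt = rep("T", length(sites)),
                 hap1 = as.integer(hap1), hap2 = as.integer(hap2)),
            class = "haplotype_block")
}

toy_vector <- function(sites, values, label, id = "h", origin = "panel",
                       population = "POP1") {
  structure(list(haplotype_id = id, site_index = sites,
                 values = as.integer(values), label = label,
                 origin = origin, population = population),
            class = "haplotype_vector")
}

# mutant/wild-type cohort vectors straight from a simulated panel's truth
panel_cohort_vectors <- function(panel, n_cases = 14L) {
  ch <- cohort_individuals(panel, n_cases)
  sites <- panel$sites$position
  mk <- function(row, label) {
    toy_vector(sites, panel$haplotypes[row, ], label,
               id = rownames(panel$haplotypes)[row],
               origin = "cohort",
               population = panel$population_label[row])
  }
  list(
    mutant = lapply(2L * ch - 1L, mk, label = "mutant"),
    wild_type = lapply(2L * ch, mk, label = "wild_type")
  )
}

# panel (non-cohort) haplotypes as labeled vectors
panel_vectors <- function(panel, exclude_individuals = integer(0)) {
  rows <- setdiff(seq_len(nrow(panel$haplotypes)),
                  as.vector(rbind(2L * exclude_individuals - 1L,
                                  2L * exclude_individuals)))
  lapply(rows, function(r) {
    toy_vector(panel$sites$position, panel$haplotypes[r, ],
               if (panel$carrier_flag[r]) "mutant" else "wild_type",
               id = rownames(panel$haplotypes)[r], origin = "panel",
               population = panel$population_label[r])
  })
}
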