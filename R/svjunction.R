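#' Classify one SV fusion junction at nucleotide resolution
#'
#' Given the reference flank ending at the left breakpoint, the reference
#' flank starting at the right breakpoint, and the assembled fusion
#' contig, finds every junction split position `s` such that the contig's
#' first `s` bases occur co-linearly in the left flank and the remaining
#' bases occur in the right flank.  Because a microhomologous segment is
#' present in both flanks, each base of microhomology adds one equivalent
#' split, so `microhomology_len = (number of valid splits) - 1`.  When no
#' split is valid, the maximal flank-explained prefix and suffix are
#' removed and the unexplained middle is reported as an untemplated
#' insertion.  The canonical junction placement is the leftmost valid
#' split; all equivalent placements are reported in
#' `ambiguous_shift_range`.
#'
#' @param left_flank reference sequence ending at the left breakpoint
#'   (last retained base).
#' @param right_flank reference sequence starting at the right breakpoint
#'   (first retained base).
#' @param fusion_contig assembled sequence across the junction.
#' @param max_scan maximum microhomology or insertion length considered
#'   explainable (default 20); beyond it the contig is "unalignable".
#' @param event_id optional identifier copied to the result.
#' @return object of class `junction_call`: `event_id`,
#'   `microhomology_len`, `inserted_seq`, `class` (blunt / microhomology
#'   / insertion), `ambiguous_shift_range` (range of valid splits, in
#'   contig coordinates of the last left-assigned base).
#' @examples
#' classify_junction("TTTTAAAA", "GGGGCCCC", "AAAAGGGG")        # blunt
#' classify_junction("TTGATTACA", "CAGGGTT", "GATTACAGGG")      # 2-bp mh
#' classify_junction("TTTTAAAA", "GGGGCCCC", "AAAATTGGGG")      # ins "TT"
#' @export
classify_junction <- function(left_flank, right_flank, fusion_contig,
                              max_scan = 20L, event_id = NA_character_) {
  m <- nchar(fusion_contig)
  if (m == 0L) stop("unalignable contig: empty fusion contig")
  pre <- substring(fusion_contig, 1L, 0:m)           # contig[1..s]
  suf <- substring(fusion_contig, 1:(m + 1L), m)     # contig[s+1..m]
  in_left <- c(TRUE, vapply(pre[-1], function(p)
    grepl(p, left_flank, fixed = TRUE), logical(1)))
  in_right <- c(vapply(suf[-(m + 1L)], function(p)
    grepl(p, right_flank, fixed = TRUE), logical(1)), TRUE)
  valid <- which(in_left & in_right) - 1L            # split positions 0..m
  if (length(valid)) {
    mh <- length(valid) - 1L
    if (mh > max_scan) {
      stop("unalignable contig: microhomology exceeds scan limit (",
           mh, " > ", max_scan, ")")
    }
    return(structure(list(
      event_id = event_id, microhomology_len = mh, inserted_seq = "",
      class = if (mh == 0L) "blunt" else "microhomology",
      ambiguous_shift_range = range(valid)
    ), class = "junction_call"))
  }
  L <- max(which(in_left)) - 1L
  R <- m + 1L - min(which(in_right))
  if (L == 0L || R == 0L || L + R >= m) {
    stop("unalignable contig: inconsistent with both flanks")
  }
  ins <- substr(fusion_contig, L + 1L, m - R)
  if (nchar(ins) > max_scan) {
    stop("unalignable contig: insertion exceeds scan limit (",
         nchar(ins), " > ", max_scan, ")")
  }
  structure(list(
    event_id = event_id, microhomology_len = 0L, inserted_seq = ins,
    class = "insertion", ambiguous_shift_range = c(L, L)
  ), class = "junction_call")
}

#' @export
print.junction_call <- function(x, ...) {
  cat("Junction", if (!is.na(x$event_id)) x$event_id else "", ": ",
      x$class,
      if (x$class == "microhomology") paste0(" (", x$microhomology_len, " bp)"),
      if (x$class == "insertion") paste0(" (\"", x$inserted_seq, "\")"),
      ", splits [", x$ambiguous_shift_range[1], ", ",
      x$ambiguous_shift_range[2], "]\n", sep = "")
  invisible(x)
}

#' Summarize junction classes over a call set
#'
#' @param calls list of `junction_call` objects (or a data.frame with
#'   `class` and `microhomology_len` columns).
#' @return list of class `junction_summary`: `n`, `class_counts`,
#'   `class_fractions`, `mh_counts` (table over microhomology lengths).
#' @export
summarize_junction_classes <- function(calls) {
  if (is.data.frame(calls)) {
    cls <- calls$class; mh <- calls$microhomology_len
  } else {
    cls <- vapply(calls, function(x) x$class, character(1))
    mh <- vapply(calls, function(x) as.integer(x$microhomology_len), integer(1))
  }
  n <- length(cls)
  cc <- table(factor(cls, levels = c("blunt", "microhomology", "insertion")))
  structure(list(
    n = n,
    class_counts = cc,
    class_fractions = if (n) cc / n else cc,
    mh_counts = table(mh[cls != "insertion"])
  ), class = "junction_summary")
}

#' @export
print.junction_summary <- function(x, ...) {
  cat("Junction classes over", x$n, "evaluable events:\n")
  for (k in names(x$class_counts)) {
    cat(sprintf("  %-14s %d/%d\n", k, x$class_counts[[k]], x$n))
  }
  if (length(x$mh_counts)) {
    cat("  microhomology lengths:",
        paste(sprintf("%sbp:%d", names(x$mh_counts), x$mh_counts),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Annotate breakpoints against repeat and gene tracks
#'
#' Point-in-interval overlap of breakpoints against 0-based half-open BED
#' intervals: a breakpoint at position `p` overlaps `[start, end)` iff
#' `start <= p < end`.  A breakpoint is genic if inside any gene
#' interval, and transcribed if additionally the gene's expression is at
#' or above `min_tpm`.  When several repeats overlap, the one with the
#' largest overlap is reported (ties by track order).
#'
#' @param breakpoints data.frame with `chrom` and `pos`.
#' @param repeat_bed,gene_bed BED file path or `GRanges` (gene track must
#'   carry interval names; strand used by downstream orientation calls).
#' @param expression named numeric vector of TPM per gene, or a
#'   data.frame with columns `gene` and `tpm`.
#' @param min_tpm expression threshold for the transcribed flag
#'   (default 1).
#' @return data.frame: chrom, pos, genic, gene, transcribed, repeat_class.
#' @export
annotate_breakpoints <- function(breakpoints, repeat_bed, gene_bed,
                                 expression = NULL, min_tpm = 1) {
  rep_gr <- .as_track(repeat_bed)
  gene_gr <- .as_track(gene_bed)
  tpm <- .as_tpm(expression)
  n <- nrow(breakpoints)
  out <- data.frame(chrom = breakpoints$chrom, pos = breakpoints$pos,
                    genic = FALSE, gene = NA_character_,
                    transcribed = FALSE, repeat_class = NA_character_,
                    stringsAsFactors = FALSE)
  known <- unique(c(as.character(GenomicRanges::seqnames(rep_gr)),
                    as.character(GenomicRanges::seqnames(gene_gr))))
  for (i in seq_len(n)) {
    if (!breakpoints$chrom[i] %in% known) {
      warning("unknown chrom in breakpoint: ", breakpoints$chrom[i])
      out$genic[i] <- NA
      out$transcribed[i] <- NA
      next
    }
    # half-open point query: p in [start, end)  <=>  1-based p+1 in the track
    q <- GenomicRanges::GRanges(breakpoints$chrom[i],
                                IRanges::IRanges(breakpoints$pos[i] + 1L,
                                                 width = 1L))
    gh <- GenomicRanges::findOverlaps(q, gene_gr, ignore.strand = TRUE)
    if (length(gh)) {
      g <- gene_gr[S4Vectors::subjectHits(gh)[1]]
      out$genic[i] <- TRUE
      out$gene[i] <- g$name
      gt <- tpm[g$name]
      out$transcribed[i] <- !is.na(gt) && gt >= min_tpm
    }
    rh <- GenomicRanges::findOverlaps(q, rep_gr, ignore.strand = TRUE)
    if (length(rh)) {
      hits <- rep_gr[S4Vectors::subjectHits(rh)]
      w <- GenomicRanges::width(GenomicRanges::pintersect(
        rep(q, length(hits)), hits))
      out$repeat_class[i] <- hits$name[which.max(w)]
    }
  }
  out
}

.as_track <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(rtracklayer::import(x, format = "BED"))
  }
  stop("track must be a GRanges or a BED file path")
}

.as_tpm <- function(expression) {
  if (is.null(expression)) return(setNames(numeric(0), character(0)))
  if (is.data.frame(expression)) {
    nm <- tolower(names(expression))
    return(setNames(expression[[which(nm %in% c("tpm", "expression"))[1]]],
                    expression[[which(nm == "gene")[1]]]))
  }
  expression
}

#' Percent identity between two sequences by global alignment
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0, and a
#' linear gap penalty (default 1 per gapped position); identity is the
#' number of matched columns over all alignment columns, in percent.
#' Used to score homologous gene pairs flanking a breakpoint pair.
#'
#' Ties between co-optimal alignments are resolved by the aligner; the
#' alignment score (matches minus gap cost) is unique, and is exposed
#' together with the match and column counts as attributes.
#'
#' @param seq_a,seq_b nonempty DNA sequences (character).
#' @param gap_penalty linear per-base gap penalty (default 1).
#' @return identity in percent, with attributes `matches`, `columns`,
#'   `score`.
#' @export
percent_identity <- function(seq_a, seq_b, gap_penalty = 1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be nonempty")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                 baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "global", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = gap_penalty)
  matches <- Biostrings::nmatch(aln)
  sc <- Biostrings::score(aln)
  # with mismatch = 0: score = matches - gap_penalty * (gapped positions),
  # so alignment columns follow from the score identity
  total_gaps <- round((matches - sc) / gap_penalty)
  cols <- (nchar(seq_a) + nchar(seq_b) + total_gaps) / 2
  structure(100 * matches / cols,
            matches = matches, columns = cols, score = sc)
}

#' Classify a fusion transcript's orientation with splice-site flags
#'
#' Each end of an RNA fusion junction is described by its genomic
#' position and which side of that position is retained in the
#' transcript.  The transcribed direction at an end follows from the
#' retained side (retained-left reads the + strand into the junction;
#' retained-right reads the - strand).  The donor end is sense when a
#' gene on the transcribed strand overlaps it; the acceptor end then
#' decides the class: sense-to-sense (gene in the same transcriptional
#' direction), sense-to-antisense (opposite), or sense-to-intergenic (no
#' gene).  Junctions whose donor is not inside a co-directional gene are
#' classed antisense-origin.  The GT donor flag checks the two genomic
#' bases immediately past the donor cut on the transcribed strand; the AG
#' acceptor flag the two bases immediately before the acceptor cut.
#'
#' @param rna_junction list with `donor` and `acceptor`, each a list
#'   `(chrom, pos, retained)` with `retained` one of "left"/"right";
#'   `pos` is the 1-based retained base adjacent to the junction (the
#'   last retained base when `retained = "left"`, the first when
#'   `retained = "right"`).
#' @param genome named character vector or `DNAStringSet`.
#' @param gene_bed gene track (BED path or GRanges) with name and strand.
#' @return list of class `fusion_orientation`: `class`, `donor_gene`,
#'   `acceptor_gene`, `donor_gt`, `acceptor_ag`, `donor_strand`,
#'   `acceptor_strand`.
#' @export
classify_fusion_transcript <- function(rna_junction, genome, gene_bed) {
  ref <- .as_seq_vector(genome)
  genes <- .as_track(gene_bed)
  end_info <- function(end, role) {
    if (!end$chrom %in% names(ref)) {
      stop("junction outside provided genome: ", end$chrom)
    }
    seqlen <- nchar(ref[[end$chrom]])
    if (end$pos < 1L || end$pos > seqlen) {
      stop("junction outside provided genome: ", end$chrom, ":", end$pos)
    }
    tx_strand <- if (end$retained == "left") "+" else "-"
    q <- GenomicRanges::GRanges(end$chrom,
                                IRanges::IRanges(end$pos, width = 1L))
    h <- GenomicRanges::findOverlaps(q, genes, ignore.strand = TRUE)
    gene <- NA_character_; gene_strand <- NA_character_
    if (length(h)) {
      g <- genes[S4Vectors::subjectHits(h)[1]]
      gene <- g$name
      gene_strand <- as.character(BiocGenerics::strand(g))
    }
    # dinucleotide just past the cut (donor GT) or before it (acceptor AG),
    # on the transcribed strand
    dinuc <- function(offset_past) {
      if (end$retained == "left") {
        lo <- end$pos + 1L; hi <- end$pos + 2L
        if (hi > seqlen) return(NA_character_)
        s <- substr(ref[[end$chrom]], lo, hi)
        if (offset_past) s else .revcomp(s)
      } else {
        lo <- end$pos - 2L; hi <- end$pos - 1L
        if (lo < 1L) return(NA_character_)
        s <- substr(ref[[end$chrom]], lo, hi)
        if (offset_past) .revcomp(s) else s
      }
    }
    flank_past <- dinuc(TRUE)    # intronic side, transcribed strand, 5'->3'
    list(tx_strand = tx_strand, gene = gene, gene_strand = gene_strand,
         flank_past = flank_past)
  }
  don <- end_info(rna_junction$donor, "donor")
  acc <- end_info(rna_junction$acceptor, "acceptor")
  donor_sense <- !is.na(don$gene) && don$gene_strand == don$tx_strand
  # acceptor transcribed direction: transcript continues OUT of the junction
  acc_tx <- if (rna_junction$acceptor$retained == "right") "+" else "-"
  cls <- if (!donor_sense) {
    "antisense-origin"
  } else if (is.na(acc$gene)) {
    "sense-to-intergenic"
  } else if (acc$gene_strand == acc_tx) {
    "sense-to-sense"
  } else {
    "sense-to-antisense"
  }
  # acceptor AG: two bases immediately 5' of the first retained base,
  # read on the acceptor's transcribed strand
  accref <- ref[[rna_junction$acceptor$chrom]]
  apos <- rna_junction$acceptor$pos
  acceptor_ag <- if (rna_junction$acceptor$retained == "right") {
    if (apos - 2L >= 1L) substr(accref, apos - 2L, apos - 1L) == "AG" else FALSE
  } else {
    if (apos + 2L <= nchar(accref))
      .revcomp(substr(accref, apos + 1L, apos + 2L)) == "AG" else FALSE
  }
  structure(list(
    class = cls,
    donor_gene = don$gene, acceptor_gene = acc$gene,
    donor_gt = !is.na(don$flank_past) && don$flank_past == "GT",
    acceptor_ag = acceptor_ag,
    donor_strand = don$tx_strand, acceptor_strand = acc_tx
  ), class = "fusion_orientation")
}

#' @export
print.fusion_orientation <- function(x, ...) {
  cat("Fusion transcript: ", x$class,
      " (donor ", ifelse(is.na(x$donor_gene), "intergenic", x$donor_gene),
      if (x$donor_gt) " [GT]", " -> acceptor ",
      ifelse(is.na(x$acceptor_gene), "intergenic", x$acceptor_gene),
      if (x$acceptor_ag) " [AG]", ")\n", sep = "")
  invisible(x)
}

.revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
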