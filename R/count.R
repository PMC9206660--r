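# Paired-read processing: exact-prefix demultiplexing of read 1, cached
# alignment of read 2 against the reference amplicon, quality filtering and
# allele classification, accumulated into a peptide x replicate count table.

#' Demultiplex reads by exact 8-nt prefix
#'
#' Assigns each read-1 sequence to the unique library member whose coding
#' sequence starts with the same first eight nucleotides. Matching is exact
#' with no error tolerance; anything else (including reads shorter than the
#' prefix) is unassigned.
#'
#' @param reads1 Character vector of read-1 sequences.
#' @param library Encoded peptide library; its 8-nt prefixes must be unique
#'   (checked, construction-time failure otherwise).
#' @param prefix_len Prefix length (default 8).
#' @return Character vector of `peptide_id`s, `NA` where unassigned.
#' @export
demux_peptide <- function(reads1, library, prefix_len = 8L) {
  if (anyNA(library$nt_seq)) stop("library has records without nt_seq")
  pref <- substr(library$nt_seq, 1L, prefix_len)
  if (anyDuplicated(pref)) {
    stop("library ", prefix_len, "-nt prefixes are not unique")
  }
  hit <- match(substr(reads1, 1L, prefix_len), pref)
  short <- nchar(reads1) < prefix_len
  hit[short] <- NA_integer_
  library$peptide_id[hit]
}

# quality strings (equal length) -> integer matrix, rows = reads
qual_matrix <- function(quals, len) {
  n <- length(quals)
  if (n == 0L) return(matrix(integer(0), 0L, len))
  m <- matrix(utf8ToInt(paste(quals, collapse = "")) - 33L,
              nrow = n, ncol = len, byrow = TRUE)
  m
}

# Classify all reads sharing one read-2 sequence, given the cached
# alignment. Vectorized over reads: only the quality-dependent masking
# varies within the group. Returns a character vector of categories or
# "dropped_low_quality".
classify_group <- function(aln, quals, spec, min_mean_q = 30,
                           min_base_q = 30, min_flank = 3L) {
  n <- length(quals)
  len <- nchar(aln$query)
  qm <- qual_matrix(quals, len)
  out <- rep(NA_character_, n)
  dropped <- rowMeans(qm) < min_mean_q
  out[dropped] <- "dropped_low_quality"
  live <- !dropped
  if (!any(live)) return(out)

  ev <- aln$events
  L <- nchar(spec$ref_allele)
  region0 <- spec$edit_start
  alt <- strsplit(spec$alt_allele, "")[[1]]
  refA <- strsplit(spec$ref_allele, "")[[1]]

  # indel events: unmasked when >= min_flank high-quality flanking matches
  # on both sides
  idx_indel <- which(ev$type != "mismatch")
  has_indel <- rep(FALSE, n)
  for (i in idx_indel) {
    left <- aln$match_qpos[aln$match_cols < ev$col[i]]
    right <- aln$match_qpos[aln$match_cols > ev$col[i] + ev$len[i] - 1L]
    lo <- if (length(left)) rowSums(qm[, left, drop = FALSE] >= min_base_q)
          else rep(0L, n)
    ro <- if (length(right)) rowSums(qm[, right, drop = FALSE] >= min_base_q)
          else rep(0L, n)
    has_indel <- has_indel | (lo >= min_flank & ro >= min_flank)
  }

  # mismatch events: masked per read when base quality < min_base_q
  idx_mm <- which(ev$type == "mismatch")
  in_region <- ev$ref_pos[idx_mm] >= region0 & ev$ref_pos[idx_mm] < region0 + L
  n_unmasked_out <- rep(0L, n)
  n_unmasked_any <- rep(0L, n)
  region_ok <- rep(TRUE, n)
  # region positions never touched by a mismatch must already agree with alt
  touched <- rep(FALSE, L)
  if (length(idx_mm) > 0L) {
    for (t in seq_along(idx_mm)) {
      i <- idx_mm[t]
      unm <- qm[, ev$q_pos[i]] >= min_base_q
      n_unmasked_any <- n_unmasked_any + unm
      if (in_region[t]) {
        off <- ev$ref_pos[i] - region0 + 1L
        touched[off] <- TRUE
        ok_u <- ev$qbase[i] == alt[off]   # unmasked: query base must be alt
        ok_m <- refA[off] == alt[off]     # masked: reverts to reference
        region_ok <- region_ok & ifelse(unm, ok_u, ok_m)
      } else {
        n_unmasked_out <- n_unmasked_out + unm
      }
    }
  }
  if (any(!touched & refA != alt)) region_ok <- rep(FALSE, n)

  cat <- ifelse(has_indel, "indel",
         ifelse(region_ok & n_unmasked_out == 0L, "prime_edited",
         ifelse(n_unmasked_any == 0L, "unedited", "other")))
  out[live] <- cat[live]
  out
}

#' Process one read pair end to end
#'
#' Reference single-read path: demultiplex read 1, align read 2, apply the
#' quality filters and classify. [count_outcomes()] computes the same
#' result over whole FASTQ files with alignment caching; the two paths are
#' interchangeable.
#'
#' @param read1,read2 Read sequences (plain character).
#' @param qual2 PHRED qualities for read 2 (string or integer vector).
#' @param library Encoded peptide library.
#' @param spec [edit_spec()].
#' @inheritParams filter_read
#' @return A list with `peptide_id` (`NA` if unassigned), `disposition`,
#'   and `category` (`NA` unless kept).
#' @export
process_pair <- function(read1, read2, qual2, library, spec,
                         min_mean_q = 30, min_base_q = 30, min_flank = 3L) {
  pid <- demux_peptide(read1, library)
  if (is.na(pid)) {
    return(list(peptide_id = NA_character_,
                disposition = "unassigned_peptide", category = NA_character_))
  }
  aln <- align_target(read2, spec$ref_amplicon)
  fl <- filter_read(aln, qual2, min_mean_q, min_base_q, min_flank)
  if (fl$disposition != "kept") {
    return(list(peptide_id = pid, disposition = fl$disposition,
                category = NA_character_))
  }
  list(peptide_id = pid, disposition = "kept",
       category = classify_outcome(fl$alignment, spec))
}

OUTCOME_CATEGORIES <- c("prime_edited", "unedited", "indel", "other")

#' Count editing outcomes per peptide and replicate
#'
#' Streams paired FASTQ files (one pair per replicate, as listed in the
#' sample sheet), demultiplexes read 1 by exact 8-nt prefix, aligns each
#' distinct read-2 sequence once against the reference amplicon, applies
#' the quality filters per read, classifies alleles, and tabulates
#' per-peptide, per-replicate category counts. Reads whose read 2 fails the
#' mean-quality filter are dropped; read 1 is used only for demultiplexing.
#'
#' @param sample_sheet `data.frame` with columns `replicate`, `r1`, `r2`
#'   and optionally `orientation` (`"forward"` default, or `"reverse"` to
#'   reverse-complement read 2 before alignment).
#' @param library Encoded peptide library (validated on entry).
#' @param spec [edit_spec()].
#' @inheritParams filter_read
#' @return A `data.frame` with one row per peptide x replicate: `n` (kept
#'   reads), `prime_edited`, `unedited`, `indel`, `other`. All library
#'   peptides appear in every replicate (zero rows included). Attribute
#'   `"tallies"` holds per-replicate totals of input, unassigned, dropped
#'   and kept reads.
#' @export
count_outcomes <- function(sample_sheet, library, spec,
                           min_mean_q = 30, min_base_q = 30, min_flank = 3L) {
  stopifnot(is.data.frame(sample_sheet),
            all(c("replicate", "r1", "r2") %in% names(sample_sheet)))
  if (anyNA(sample_sheet$replicate) || any(!nzchar(sample_sheet$replicate))) {
    stop("sample sheet contains missing replicate labels")
  }
  validate_library(library, tile_len = unique(nchar(library$aa_seq))[1])
  reps <- as.character(sample_sheet$replicate)
  grid <- expand.grid(peptide_id = library$peptide_id,
                      replicate = unique(reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  acc <- matrix(0L, nrow = nrow(grid), ncol = length(OUTCOME_CATEGORIES),
                dimnames = list(NULL, OUTCOME_CATEGORIES))
  key <- paste(grid$peptide_id, grid$replicate, sep = "\r")
  tallies <- NULL

  for (s in seq_len(nrow(sample_sheet))) {
    rlab <- reps[s]
    r1 <- Biostrings::readDNAStringSet(sample_sheet$r1[s], format = "fastq",
                                       with.qualities = TRUE)
    r2 <- Biostrings::readDNAStringSet(sample_sheet$r2[s], format = "fastq",
                                       with.qualities = TRUE)
    if (length(r1) != length(r2)) {
      stop("read pair count mismatch in replicate ", rlab)
    }
    seq1 <- as.character(r1)
    seq2 <- as.character(r2)
    qual2 <- as.character(S4Vectors::mcols(r2)$qualities)
    orient <- if ("orientation" %in% names(sample_sheet))
      sample_sheet$orientation[s] else "forward"
    if (identical(orient, "reverse")) {
      seq2 <- revcomp(seq2)
      qual2 <- vapply(qual2, function(q) {
        intToUtf8(rev(utf8ToInt(q)))
      }, character(1), USE.NAMES = FALSE)
    }

    pid <- demux_peptide(seq1, library)
    n_total <- length(seq1)
    assigned <- !is.na(pid)
    n_unassigned <- sum(!assigned)
    pid <- pid[assigned]
    seq2 <- seq2[assigned]
    qual2 <- qual2[assigned]

    n_dropped <- 0L
    if (length(seq2) > 0L) {
      groups <- split(seq_along(seq2), seq2)
      alns <- align_many(names(groups), spec$ref_amplicon)
      res_all <- character(length(seq2))
      for (g in seq_along(groups)) {
        idx <- groups[[g]]
        res_all[idx] <- classify_group(alns[[g]], qual2[idx], spec,
                                       min_mean_q, min_base_q, min_flank)
      }
      dropped <- res_all == "dropped_low_quality"
      n_dropped <- sum(dropped)
      if (any(!dropped)) {
        tab <- table(
          factor(paste(pid[!dropped], rlab, sep = "\r"), levels = key),
          factor(res_all[!dropped], levels = OUTCOME_CATEGORIES))
        tab <- unclass(tab)             # plain matrix; keep dims on "+"
        dimnames(tab) <- list(NULL, OUTCOME_CATEGORIES)
        acc <- acc + tab
      }
    }
    tallies <- rbind(tallies, data.frame(
      replicate = rlab, total = n_total, unassigned = n_unassigned,
      dropped_low_quality = n_dropped,
      kept = n_total - n_unassigned - n_dropped,
      stringsAsFactors = FALSE))
  }

  counts <- data.frame(grid, acc, stringsAsFactors = FALSE)
  counts$n <- rowSums(acc)
  counts <- counts[, c("peptide_id", "replicate", "n", OUTCOME_CATEGORIES)]
  attr(counts, "tallies") <- tallies
  counts
}
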