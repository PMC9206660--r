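# Global alignment of target-site reads against the reference amplicon and
# extraction of per-position events (mismatch / insertion / deletion) with
# query coordinates, for quality-aware filtering and allele classification.
#
# Scoring follows the screen's scheme: match +1, mismatch -1, gap open -5,
# gap extend 0 -- i.e. any gap costs 5 regardless of length, and end gaps
# are penalized like internal ones (true global alignment).

NW_MATCH <- 1
NW_MISMATCH <- -1
NW_GAP_OPEN <- 5
NW_GAP_EXTEND <- 0

nw_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = NW_MATCH,
                                           mismatch = NW_MISMATCH,
                                           baseOnly = FALSE)
}

# Decompose a pair of equal-length aligned strings (with "-" gaps) into an
# event table plus the query positions of matched columns.
events_from_aligned <- function(qa, ra) {
  qc <- strsplit(qa, "")[[1]]
  rc <- strsplit(ra, "")[[1]]
  stopifnot(length(qc) == length(rc))
  qgap <- qc == "-"
  rgap <- rc == "-"
  # 0-based ref offset consumed before each column; 1-based query position
  ref_before <- cumsum(!rgap) - as.integer(!rgap)   # offset of this column's ref base
  q_at <- cumsum(!qgap)                             # query pos at non-gap query cols

  is_mm <- !qgap & !rgap & qc != rc
  is_match <- !qgap & !rgap & qc == rc

  mm <- data.frame(
    type = rep("mismatch", sum(is_mm)),
    ref_pos = ref_before[is_mm],
    len = rep(1L, sum(is_mm)),
    q_pos = q_at[is_mm],
    qbase = qc[is_mm],
    rbase = rc[is_mm],
    col = which(is_mm),
    stringsAsFactors = FALSE
  )

  run_events <- function(gapmask, type) {
    if (!any(gapmask)) return(NULL)
    r <- rle(gapmask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    do.call(rbind, lapply(keep, function(i) {
      s <- starts[i]; e <- ends[i]
      if (type == "insertion") {
        data.frame(type = "insertion",
                   ref_pos = cumsum(!rgap)[s] - as.integer(!rgap[s]),
                   len = e - s + 1L,
                   q_pos = q_at[s],
                   qbase = paste(qc[s:e], collapse = ""),
                   rbase = "",
                   col = s, stringsAsFactors = FALSE)
      } else {
        data.frame(type = "deletion",
                   ref_pos = ref_before[s],
                   len = e - s + 1L,
                   q_pos = NA_integer_,
                   qbase = "",
                   rbase = paste(rc[s:e], collapse = ""),
                   col = s, stringsAsFactors = FALSE)
      }
    }))
  }

  ev <- rbind(mm, run_events(rgap, "insertion"), run_events(qgap, "deletion"))
  if (is.null(ev) || nrow(ev) == 0L) {
    ev <- data.frame(type = character(0), ref_pos = integer(0),
                     len = integer(0), q_pos = integer(0),
                     qbase = character(0), rbase = character(0),
                     col = integer(0), stringsAsFactors = FALSE)
  } else {
    ev <- ev[order(ev$col), , drop = FALSE]
    rownames(ev) <- NULL
  }
  ev$masked <- rep(FALSE, nrow(ev))
  list(events = ev,
       match_cols = which(is_match),
       match_qpos = q_at[is_match])
}

#' Align target-site reads to the reference amplicon
#'
#' Needleman-Wunsch global alignment of one or more reads against the
#' reference, under the fixed scheme match +1 / mismatch -1 / gap open -5 /
#' gap extend 0: a gap of any length costs 5, and end gaps count. The
#' optimal score is computed by [Biostrings::pairwiseAlignment()]; event
#' extraction (mismatches, insertions, deletions with reference and query
#' coordinates) is performed on the aligned strings.
#'
#' @param query Read sequence (plain character). `align_many` accepts a
#'   character vector and returns a list of alignments.
#' @param ref Reference amplicon sequence.
#' @return An object of class `target_alignment`: the input sequences, the
#'   gapped aligned strings, the alignment `score`, an `events` data frame
#'   (`type`, 0-based `ref_pos`, `len`, 1-based `q_pos`, `qbase`, `rbase`,
#'   alignment column `col`, `masked`), and the query positions of matched
#'   columns used by the indel flank filter.
#' @examples
#' aln <- align_target("ACGT", "AGT")
#' aln$score
#' @export
align_target <- function(query, ref) {
  align_many(query, ref)[[1L]]
}

# Rebuild the gapped aligned strings from the reference-projected pattern
# (deletions as "-", insertions removed) plus the insertion ranges, which
# Biostrings anchors on reference coordinates (start = ref position after
# which the insertion sits, + 1). Much cheaper than the per-alignment
# alignedPattern()/alignedSubject() accessors.
rebuild_aligned <- function(query, ref, proj, ins) {
  if (is.null(ins) || nrow(ins) == 0L) {
    return(list(qa = proj, ra = ref))
  }
  projc <- strsplit(proj, "")[[1]]
  refc <- strsplit(ref, "")[[1]]
  ins <- ins[order(ins$start), , drop = FALSE]
  out_q <- character(0); out_r <- character(0)
  qcount <- 0L; k <- 1L
  emit_ins <- function(r) {
    while (k <= nrow(ins) && ins$start[k] == r) {
      w <- ins$end[k] - ins$start[k] + 1L
      out_q <<- c(out_q, substr(query, qcount + 1L, qcount + w))
      out_r <<- c(out_r, strrep("-", w))
      qcount <<- qcount + w
      k <<- k + 1L
    }
  }
  for (r in seq_along(refc)) {
    emit_ins(r)
    out_q <- c(out_q, projc[r])
    out_r <- c(out_r, refc[r])
    if (projc[r] != "-") qcount <- qcount + 1L
  }
  emit_ins(length(refc) + 1L)
  list(qa = paste(out_q, collapse = ""), ra = paste(out_r, collapse = ""))
}

#' @rdname align_target
#' @export
align_many <- function(query, ref) {
  stopifnot(length(ref) == 1L, nzchar(ref), all(nzchar(query)))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(query), Biostrings::DNAString(ref),
    substitutionMatrix = nw_submat(),
    gapOpening = NW_GAP_OPEN, gapExtension = NW_GAP_EXTEND, type = "global")
  proj <- as.character(Biostrings::aligned(pa))
  ins_df <- as.data.frame(Biostrings::insertion(pa))
  ins_by <- split(ins_df[, c("start", "end"), drop = FALSE], ins_df$group)
  sc <- Biostrings::score(pa)
  rebuilt <- lapply(seq_along(query), function(i) {
    rebuild_aligned(query[i], ref, proj[i], ins_by[[as.character(i)]])
  })
  qa <- vapply(rebuilt, `[[`, character(1), "qa")
  ra <- vapply(rebuilt, `[[`, character(1), "ra")
  lapply(seq_along(query), function(i) {
    ex <- events_from_aligned(qa[i], ra[i])
    structure(
      list(query = query[i], ref = ref,
           query_aligned = qa[i], ref_aligned = ra[i],
           score = sc[i],
           events = ex$events,
           match_cols = ex$match_cols,
           match_qpos = ex$match_qpos),
      class = "target_alignment")
  })
}

#' @export
print.target_alignment <- function(x, ...) {
  cat("target_alignment (score ", x$score, ")\n", sep = "")
  cat("  Q: ", x$query_aligned, "\n  R: ", x$ref_aligned, "\n", sep = "")
  n_mask <- sum(x$events$masked)
  cat("  events: ", nrow(x$events),
      if (n_mask > 0L) paste0(" (", n_mask, " masked)"), "\n", sep = "")
  invisible(x)
}
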