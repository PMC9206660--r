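# Quality-aware read filtering and allele classification.
#
# Filtering rules applied to each aligned target read:
#   * reads with mean PHRED quality below 30 are dropped;
#   * mismatches at bases with quality below 30 are masked (treated as
#     reference);
#   * indels lacking at least three matching nucleotides with quality >= 30
#     on BOTH sides are masked (removed before classification).

#' Filter an aligned read on PHRED quality
#'
#' Applies the screen's three quality rules to a [align_target()] result:
#' the whole read is dropped when its mean quality is below `min_mean_q`;
#' surviving reads get mismatch events at bases below `min_base_q` masked,
#' and indel events masked unless at least `min_flank` matching nucleotides
#' with quality >= `min_base_q` lie on each side of the indel. Masked
#' events are treated as reference by [classify_outcome()].
#'
#' @param aln A `target_alignment`.
#' @param qualities Integer PHRED scores (or a single offset-33 quality
#'   string) for the ungapped query; length must equal the query length.
#' @param min_mean_q Mean-quality threshold for keeping the read.
#' @param min_base_q Per-base threshold for mismatch masking and for a
#'   flanking match to count.
#' @param min_flank Matching high-quality nucleotides required on each side
#'   of an indel.
#' @return A list with `disposition` (`"kept"` or `"dropped_low_quality"`)
#'   and `alignment` (the input with `events$masked` updated).
#' @export
filter_read <- function(aln, qualities, min_mean_q = 30, min_base_q = 30,
                        min_flank = 3L) {
  stopifnot(inherits(aln, "target_alignment"))
  if (is.character(qualities)) qualities <- phred_to_int(qualities)
  if (length(qualities) != nchar(aln$query)) {
    stop("quality vector length (", length(qualities),
         ") does not match query length (", nchar(aln$query), ")")
  }
  if (mean(qualities) < min_mean_q) {
    return(list(disposition = "dropped_low_quality", alignment = aln))
  }
  ev <- aln$events
  if (nrow(ev) > 0L) {
    for (i in seq_len(nrow(ev))) {
      if (ev$type[i] == "mismatch") {
        ev$masked[i] <- qualities[ev$q_pos[i]] < min_base_q
      } else {
        left <- aln$match_qpos[aln$match_cols < ev$col[i]]
        right <- aln$match_qpos[aln$match_cols > ev$col[i] + ev$len[i] - 1L]
        ok <- sum(qualities[left] >= min_base_q) >= min_flank &&
          sum(qualities[right] >= min_base_q) >= min_flank
        ev$masked[i] <- !ok
      }
    }
  }
  aln$events <- ev
  list(disposition = "kept", alignment = aln)
}

#' Classify a kept read into a prime-editing outcome
#'
#' Precedence: any unmasked indel makes the read `indel`; otherwise, if the
#' edited region (reference bases overwritten by unmasked mismatches) reads
#' exactly as the programmed alternative allele and no unmasked mismatch
#' lies outside the region, the read is `prime_edited`; otherwise a read
#' with zero unmasked differences is `unedited`; everything else --
#' including partial installations of the edit -- is `other`. Masked events
#' are treated as reference, so edit calling is all-or-nothing.
#'
#' @param aln A (filtered) `target_alignment`.
#' @param spec An [edit_spec()].
#' @return One of `"prime_edited"`, `"unedited"`, `"indel"`, `"other"`.
#' @export
classify_outcome <- function(aln, spec) {
  stopifnot(inherits(aln, "target_alignment"), inherits(spec, "edit_spec"))
  ev <- aln$events[!aln$events$masked, , drop = FALSE]
  if (any(ev$type != "mismatch")) return("indel")
  L <- nchar(spec$ref_allele)
  in_region <- ev$ref_pos >= spec$edit_start & ev$ref_pos < spec$edit_start + L
  region <- strsplit(spec$ref_allele, "")[[1]]
  if (any(in_region)) {
    idx <- ev$ref_pos[in_region] - spec$edit_start + 1L
    region[idx] <- ev$qbase[in_region]
  }
  if (paste(region, collapse = "") == spec$alt_allele && !any(!in_region)) {
    return("prime_edited")
  }
  if (nrow(ev) == 0L) return("unedited")
  "other"
}
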