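# Reference amplicon and programmed edit description.

#' Describe the programmed edit on a reference amplicon
#'
#' Bundles the target-site reference sequence with the edit the pegRNA is
#' programmed to install: the reference allele found at `edit_start`
#' (0-based) and the alternative allele written by prime editing. The
#' screen's edit replaces the 6-nt linker sequence CCTCTG with GAATTC.
#'
#' @param ref_amplicon Reference target-site sequence (plain character).
#' @param edit_start 0-based offset of the edited region in `ref_amplicon`.
#' @param ref_allele Reference bases at the edited region.
#' @param alt_allele Bases installed by the programmed edit; for this assay
#'   the alleles have equal length (a multi-nucleotide substitution).
#' @return An object of class `edit_spec`.
#' @examples
#' spec <- example_edit_spec()
#' substr(spec$ref_amplicon, spec$edit_start + 1, spec$edit_start + 6)
#' @export
edit_spec <- function(ref_amplicon, edit_start, ref_allele = "CCTCTG",
                      alt_allele = "GAATTC") {
  stopifnot(is.character(ref_amplicon), length(ref_amplicon) == 1L,
            nzchar(ref_allele), nzchar(alt_allele),
            edit_start >= 0L,
            edit_start + nchar(ref_allele) <= nchar(ref_amplicon))
  found <- substr(ref_amplicon, edit_start + 1L,
                  edit_start + nchar(ref_allele))
  if (found != ref_allele) {
    stop("ref_amplicon[", edit_start, ":", edit_start + nchar(ref_allele),
         ") is '", found, "', not the stated ref_allele '", ref_allele, "'")
  }
  if (identical(ref_allele, alt_allele)) {
    stop("ref_allele and alt_allele are identical; nothing to edit")
  }
  structure(
    list(ref_amplicon = ref_amplicon, edit_start = as.integer(edit_start),
         ref_allele = ref_allele, alt_allele = alt_allele),
    class = "edit_spec"
  )
}

#' @export
print.edit_spec <- function(x, ...) {
  cat("edit_spec: ", nchar(x$ref_amplicon), " nt amplicon, ",
      x$ref_allele, " -> ", x$alt_allele, " at 0-based ", x$edit_start,
      "\n", sep = "")
  invisible(x)
}

# Synthetic 120-nt linker-site amplicon used throughout examples and
# simulations. The published linker sequence is not reproduced here; this
# stand-in carries the programmed CCTCTG site once, with GAATTC absent, so
# allele classification is unambiguous.
SYNTHETIC_AMPLICON <- paste0(
  "CAAGTGACACGATATTTACGTAAGTAACCCCCTTAGCTTACCCCATCCCAAAATTTG",
  "CCTCTG",
  "AACCTGAGGTGCACTTTGGAAGGACTCAAACGGACAGATGAGCGCCTTAGCCGGGCA"
)

#' Synthetic example edit specification
#'
#' A fixed synthetic 120-nt amplicon carrying the programmed CCTCTG->GAATTC
#' edit site at 0-based position 57. Used as the default target in the
#' simulator and in examples; it is not the published linker sequence.
#' @return An `edit_spec`.
#' @export
example_edit_spec <- function() {
  edit_spec(SYNTHETIC_AMPLICON, 57L)
}

#' Apply an edit spec's alternative allele to a sequence
#' @noRd
apply_edit <- function(spec, seq = spec$ref_amplicon, allele = spec$alt_allele) {
  paste0(substr(seq, 1L, spec$edit_start),
         allele,
         substr(seq, spec$edit_start + nchar(spec$ref_allele) + 1L, nchar(seq)))
}
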