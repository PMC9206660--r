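# Tiled peptide library construction: overlapping tiles across source
# proteins, phosphomimetic (S/T -> E) point variants, and codon-level
# nucleotide encoding with library-wide demultiplexing prefixes.

#' Tile a protein into fixed-length overlapping peptides
#'
#' Cuts a protein sequence into `tile_len`-residue peptides, each tile
#' starting `step` residues after the previous one. If the last regular tile
#' does not reach the C-terminus, a final tile anchored at
#' `length - tile_len` is appended so that every residue is covered and all
#' peptides keep the same length. With the default 85/45 geometry interior
#' residues are covered by exactly two tiles.
#'
#' @param protein_seq Single amino-acid string (one-letter code).
#' @param protein_id Identifier used to derive peptide ids.
#' @param tile_len Tile length in residues (default 85).
#' @param step Offset between consecutive tile starts in residues
#'   (default 45).
#' @param variant_class Class assigned to the tiles, `"wt"` for screen
#'   members or `"control"` for housekeeping-derived control peptides.
#' @return A peptide library `data.frame` with one row per tile and columns
#'   `peptide_id`, `source_protein`, `tile_start` (0-based residue offset),
#'   `aa_seq`, `variant_class`, `sub_position`, `nt_seq`, `tag9`. The
#'   nucleotide columns are `NA` until [encode_library()] is applied.
#' @examples
#' tiles <- tile_protein(strrep("ACDEFGHIKLMNPQRSTVWY", 10), "prot1")
#' tiles$tile_start
#' @export
tile_protein <- function(protein_seq, protein_id = "protein", tile_len = 85L,
                         step = 45L, variant_class = c("wt", "control")) {
  variant_class <- match.arg(variant_class)
  stopifnot(is.character(protein_seq), length(protein_seq) == 1L,
            tile_len >= 1L, step >= 1L)
  len <- nchar(protein_seq)
  if (len < tile_len) {
    stop("protein '", protein_id, "' too short: ", len, " residues < tile_len ",
         tile_len)
  }
  starts <- seq.int(0L, len - tile_len, by = step)
  if (max(starts) + tile_len < len) {
    starts <- c(starts, len - tile_len)
  }
  data.frame(
    peptide_id = sprintf("%s_t%04d", protein_id, starts),
    source_protein = protein_id,
    tile_start = as.integer(starts),
    aa_seq = substring(protein_seq, starts + 1L, starts + tile_len),
    variant_class = variant_class,
    sub_position = NA_integer_,
    nt_seq = NA_character_,
    tag9 = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Enumerate single phosphomimetic variants of wild-type peptides
#'
#' For every serine or threonine in each parent peptide, emits one variant
#' with exactly that residue substituted by glutamate (S->E or T->E),
#' imitating constitutive phosphorylation. Parents with no S/T yield no
#' variants.
#'
#' @param parents Peptide library `data.frame` rows with
#'   `variant_class == "wt"` (see [tile_protein()]).
#' @return A `data.frame` of phosphomimetic records; `sub_position` is the
#'   0-based residue index of the substitution within the peptide.
#' @examples
#' p <- tile_protein(strrep("SATA", 25), "p")
#' nrow(phosphomimetic_variants(p[1, ]))
#' @export
phosphomimetic_variants <- function(parents) {
  stopifnot(is.data.frame(parents), nrow(parents) >= 1L)
  if (!all(parents$variant_class == "wt")) {
    stop("phosphomimetic variants are generated from wild-type parents only")
  }
  out <- lapply(seq_len(nrow(parents)), function(r) {
    p <- parents[r, ]
    aa <- strsplit(p$aa_seq, "")[[1]]
    pos <- which(aa %in% c("S", "T")) - 1L   # 0-based
    if (length(pos) == 0L) return(NULL)
    seqs <- vapply(pos, function(i) {
      v <- aa
      v[i + 1L] <- "E"
      paste(v, collapse = "")
    }, character(1))
    data.frame(
      peptide_id = sprintf("%s_pm%03d", p$peptide_id, pos),
      source_protein = p$source_protein,
      tile_start = p$tile_start,
      aa_seq = seqs,
      variant_class = "phosphomimetic",
      sub_position = pos,
      nt_seq = NA_character_,
      tag9 = NA_character_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- tile_protein(strrep("A", 85), "x")[0, ]
  }
  rownames(out) <- NULL
  out
}

#' Default codon-usage table
#'
#' Uniform weights over the sense codons of the standard genetic code,
#' keyed by codon. Supply your own named numeric vector (same keys) to
#' encode with organism-specific usage.
#' @return Named numeric vector of codon weights.
#' @export
default_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  w <- rep(1, sum(gc != "*"))
  names(w) <- names(gc)[gc != "*"]
  w
}

# codons grouped by encoded amino acid, with weights
codons_by_aa <- function(codon_table) {
  gc <- Biostrings::GENETIC_CODE[names(codon_table)]
  split(codon_table, unname(gc))
}

sample_codons <- function(aa, by_aa) {
  vapply(strsplit(aa, "")[[1]], function(a) {
    w <- by_aa[[a]]
    if (is.null(w)) stop("no codon for residue '", a, "'")
    if (length(w) == 1L) return(names(w))
    sample(names(w), 1L, prob = w)
  }, character(1), USE.NAMES = FALSE)
}

#' Encode a peptide library as nucleotide sequences
#'
#' Assigns each record a codon-sampled nucleotide sequence translating back
#' to its amino-acid sequence, with two library-wide contracts: the first
#' eight nucleotides are unique across the library (the exact-match
#' demultiplexing key used by read processing) and every phosphomimetic
#' record carries a unique 9-nt tag. The tag sits 3' of the open reading
#' frame, outside the translated frame, so `aa_seq` is unaffected; it is
#' stored in the `tag9` column and appended to the FASTA/read-1 sequence by
#' downstream code. Prefix collisions are resolved by resampling synonymous
#' codons for the first three residues. Note the prefix space is bounded by
#' the codon degeneracy of those residues: families of peptides sharing a
#' low-degeneracy start (in the extreme, Met-Trp-Met admits a single
#' possible prefix) can make the uniqueness contract unattainable, in which
#' case the colliding records are reported as an error.
#'
#' @param records Peptide library `data.frame` (see [tile_protein()],
#'   [phosphomimetic_variants()]).
#' @param codon_table Named codon-weight vector; defaults to
#'   [default_codon_table()].
#' @param seed Integer seed; encoding is deterministic given the seed.
#' @param max_tries Bounded retries for prefix/tag collisions before the
#'   colliding records are reported as an error.
#' @return The input `data.frame` with `nt_seq` (length `3 * nchar(aa_seq)`)
#'   and `tag9` filled in.
#' @export
encode_library <- function(records, codon_table = default_codon_table(),
                           seed = 1L, max_tries = 200L) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  by_aa <- codons_by_aa(codon_table)
  with_seed(seed, {
    nt <- vapply(records$aa_seq, function(aa) {
      paste(sample_codons(aa, by_aa), collapse = "")
    }, character(1), USE.NAMES = FALSE)

    # enforce first-8-nt uniqueness by resampling the first 3 codons
    for (try in seq_len(max_tries)) {
      pref <- substr(nt, 1L, 8L)
      dup <- duplicated(pref) | duplicated(pref, fromLast = TRUE)
      # keep the first record of each colliding group fixed
      redo <- which(dup & duplicated(pref))
      if (length(redo) == 0L) break
      for (r in redo) {
        head3 <- paste(sample_codons(substr(records$aa_seq[r], 1L, 3L), by_aa),
                       collapse = "")
        nt[r] <- paste0(head3, substr(nt[r], 10L, nchar(nt[r])))
      }
    }
    pref <- substr(nt, 1L, 8L)
    if (anyDuplicated(pref)) {
      bad <- records$peptide_id[pref %in% pref[duplicated(pref)]]
      stop("could not resolve 8-nt prefix collisions for: ",
           paste(bad, collapse = ", "))
    }
    records$nt_seq <- nt

    # unique 9-nt tags for phosphomimetic records
    is_pm <- records$variant_class == "phosphomimetic"
    n_pm <- sum(is_pm)
    if (n_pm > 0L) {
      tags <- character(0)
      for (try in seq_len(max_tries)) {
        tags <- unique(c(tags, random_dna(n_pm - length(tags), 9L)))
        if (length(tags) >= n_pm) break
      }
      if (length(tags) < n_pm) {
        stop("could not generate ", n_pm, " unique 9-nt tags")
      }
      records$tag9[is_pm] <- tags[seq_len(n_pm)]
    }
  })
  records
}

#' Validate the library contracts used downstream
#'
#' Checks fixed peptide length, translation round-trip of every encoded
#' sequence, 8-nt prefix uniqueness and tag uniqueness. Called by the read
#' processor before demultiplexing.
#'
#' @param library Encoded peptide library `data.frame`.
#' @param tile_len Expected peptide length in residues.
#' @return Invisibly `TRUE`; stops with a message on the first violation.
#' @export
validate_library <- function(library, tile_len = 85L) {
  stopifnot(is.data.frame(library), nrow(library) >= 1L)
  if (!all(nchar(library$aa_seq) == tile_len)) {
    stop("peptides must all be ", tile_len, " residues long")
  }
  if (anyDuplicated(library$peptide_id)) stop("duplicate peptide_id values")
  enc <- !is.na(library$nt_seq)
  if (any(enc)) {
    nt <- library$nt_seq[enc]
    if (anyDuplicated(substr(nt, 1L, 8L))) {
      stop("8-nt demultiplexing prefixes are not unique")
    }
    aa_back <- as.character(suppressWarnings(
      Biostrings::translate(Biostrings::DNAStringSet(nt),
                            no.init.codon = TRUE)))
    if (!all(aa_back == library$aa_seq[enc])) {
      stop("nt_seq does not translate back to aa_seq for some records")
    }
  }
  tags <- library$tag9[!is.na(library$tag9)]
  if (anyDuplicated(tags)) stop("phosphomimetic 9-nt tags are not unique")
  invisible(TRUE)
}

#' Build a tiled screen library from protein sequences
#'
#' Convenience wrapper: tiles every protein, adds phosphomimetic variants
#' for the non-control proteins, appends control tiles, and encodes the
#' whole library.
#'
#' @param proteins Named character vector of protein sequences (screen
#'   members).
#' @param controls Named character vector of control (housekeeping) protein
#'   sequences; their tiles get `variant_class = "control"` and no
#'   phosphomimetic expansion.
#' @param tile_len,step Tiling geometry (see [tile_protein()]).
#' @param phosphomimetics Whether to add S/T->E variants of screen tiles.
#' @param codon_table,seed Passed to [encode_library()].
#' @return Encoded peptide library `data.frame`.
#' @export
design_library <- function(proteins, controls = character(0), tile_len = 85L,
                           step = 45L, phosphomimetics = TRUE,
                           codon_table = default_codon_table(), seed = 1L) {
  stopifnot(length(proteins) >= 1L)
  if (is.null(names(proteins)) && length(proteins) > 0L) {
    names(proteins) <- sprintf("prot%03d", seq_along(proteins))
  }
  tiles <- do.call(rbind, lapply(names(proteins), function(id) {
    tile_protein(proteins[[id]], id, tile_len, step, "wt")
  }))
  lib <- tiles
  if (phosphomimetics) {
    pm <- phosphomimetic_variants(tiles)
    if (nrow(pm) > 0L) lib <- rbind(lib, pm)
  }
  if (length(controls) > 0L) {
    if (is.null(names(controls))) {
      names(controls) <- sprintf("ctrl%03d", seq_along(controls))
    }
    ctl <- do.call(rbind, lapply(names(controls), function(id) {
      tile_protein(controls[[id]], id, tile_len, step, "control")
    }))
    lib <- rbind(lib, ctl)
  }
  rownames(lib) <- NULL
  lib <- encode_library(lib, codon_table, seed)
  validate_library(lib, tile_len)
  lib
}

#' Read / write a peptide library table
#'
#' Plain TSV with the canonical column set; `NA` fields are written empty.
#' @param library Peptide library `data.frame`.
#' @param path File path.
#' @return `write_library` returns `path` invisibly; `read_library` returns
#'   the library `data.frame`.
#' @export
write_library <- function(library, path) {
  utils::write.table(library, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  lib <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = "",
                           colClasses = "character")
  lib$tile_start <- as.integer(lib$tile_start)
  lib$sub_position <- as.integer(lib$sub_position)
  lib
}

#' Write library nucleotide sequences as FASTA
#'
#' Emits the full synthesized sequence per record: the open reading frame
#' followed by the 9-nt tag where present.
#' @param library Encoded peptide library.
#' @param path Output FASTA path.
#' @export
write_library_fasta <- function(library, path) {
  stopifnot(!anyNA(library$nt_seq))
  full <- paste0(library$nt_seq, ifelse(is.na(library$tag9), "", library$tag9))
  x <- Biostrings::DNAStringSet(full)
  names(x) <- library$peptide_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
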