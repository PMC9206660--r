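# Ground-truthed simulator for paired-end self-editing screen data.
#
# The generative model mirrors the inference model: each peptide i carries
# Beta(alpha_i, beta_i) editing propensity; the realized per-replicate rate
# p_ij is a Beta draw; read outcomes are multinomial at the simulated depth
# with prime-edited probability (1 - indel_rate) * p_ij * (1 - partial_frac),
# so edited counts reduce to Bin(n, p_ij) when indel and partial rates are
# zero. Read 1 carries the peptide coding sequence (the 8-nt demultiplexing
# prefix), read 2 the target amplicon with the planted allele.

#' Assign true beta-binomial effect parameters to a library
#'
#' Gives every peptide a Beta(alpha, beta) editing law with mean
#' `control_mean`, except the designated enhancers whose mean is
#' `control_mean * enhancer_fold`; all peptides share the concentration
#' `alpha + beta`. Deterministic: the parameters follow directly from the
#' stated means and concentration.
#'
#' @param library Peptide library `data.frame`.
#' @param control_mean Baseline mean editing rate (default 0.2, the middle
#'   of the 16-28% edited-allele range typical of this assay).
#' @param enhancer_ids Peptide ids planted as enhancers.
#' @param enhancer_fold Multiplier on the baseline mean for enhancers; the
#'   resulting mean must stay below 1.
#' @param concentration Shared `alpha + beta`; smaller values mean more
#'   replicate-to-replicate overdispersion.
#' @return `data.frame` with `peptide_id`, `alpha`, `beta`, `mean`,
#'   `is_enhancer`.
#' @export
draw_true_effects <- function(library, control_mean = 0.2,
                              enhancer_ids = character(0),
                              enhancer_fold = 1.5, concentration = 50) {
  stopifnot(control_mean > 0, control_mean < 1, concentration > 0,
            enhancer_fold > 0)
  if (control_mean * enhancer_fold >= 1) {
    stop("enhancer mean control_mean * enhancer_fold = ",
         control_mean * enhancer_fold, " must be < 1")
  }
  if (!all(enhancer_ids %in% library$peptide_id)) {
    stop("enhancer_ids not in library: ",
         paste(setdiff(enhancer_ids, library$peptide_id), collapse = ", "))
  }
  is_enh <- library$peptide_id %in% enhancer_ids
  m <- ifelse(is_enh, control_mean * enhancer_fold, control_mean)
  data.frame(
    peptide_id = library$peptide_id,
    alpha = m * concentration,
    beta = (1 - m) * concentration,
    mean = m,
    is_enhancer = is_enh,
    stringsAsFactors = FALSE
  )
}

# mutate one read: substitution errors + low-quality positions
apply_read_noise <- function(seqs, error_rate, q_high, q_low, low_q_frac) {
  n <- length(seqs)
  len <- nchar(seqs)
  hi_char <- intToUtf8(q_high + 33L)
  lo_char <- intToUtf8(q_low + 33L)
  quals <- strrep(hi_char, len)
  if (error_rate <= 0 && low_q_frac <= 0) return(list(seqs = seqs, quals = quals))
  nerr <- stats::rbinom(n, len, error_rate)
  nlow <- stats::rbinom(n, len, low_q_frac)
  for (i in which(nerr > 0L | nlow > 0L)) {
    chars <- strsplit(seqs[i], "")[[1]]
    qv <- rep(hi_char, len[i])
    if (nerr[i] > 0L) {
      pos <- sample.int(len[i], nerr[i])
      chars[pos] <- vapply(chars[pos], function(b) {
        sample(setdiff(DNA_BASES, b), 1L)
      }, character(1), USE.NAMES = FALSE)
      qv[pos] <- lo_char
    }
    if (nlow[i] > 0L) {
      qv[sample.int(len[i], nlow[i])] <- lo_char
    }
    seqs[i] <- paste(chars, collapse = "")
    quals[i] <- paste(qv, collapse = "")
  }
  list(seqs = seqs, quals = quals)
}

# one random nick-proximal indel allele on the unedited amplicon
random_indel_allele <- function(spec, window = 6L, max_len = 3L) {
  ref <- spec$ref_amplicon
  L <- nchar(spec$ref_allele)
  lo <- max(0L, spec$edit_start - window)
  hi <- min(nchar(ref) - max_len, spec$edit_start + L + window)
  pos <- sample(seq.int(lo, hi), 1L)       # 0-based
  len <- sample.int(max_len, 1L)
  if (stats::runif(1) < 0.5) {             # deletion
    paste0(substr(ref, 1L, pos), substr(ref, pos + len + 1L, nchar(ref)))
  } else {                                 # insertion
    paste0(substr(ref, 1L, pos), random_dna(1L, len),
           substr(ref, pos + 1L, nchar(ref)))
  }
}

# partial-edit alleles: a proper prefix of the alternative allele written
# over the reference, restricted to prefixes distinguishable from both the
# reference and the full edit
partial_alleles <- function(spec) {
  L <- nchar(spec$ref_allele)
  cand <- vapply(seq_len(L - 1L), function(m) {
    paste0(substr(spec$alt_allele, 1L, m),
           substr(spec$ref_allele, m + 1L, L))
  }, character(1))
  unique(cand[cand != spec$ref_allele & cand != spec$alt_allele])
}

#' Simulate a paired-end self-editing screen
#'
#' For every peptide and replicate, draws the realized editing rate from the
#' peptide's Beta law, assigns each of `depth` reads an outcome
#' (prime-edited, partial edit, nick-proximal indel, unedited), builds the
#' corresponding read pairs, applies per-base substitution errors with
#' low-quality scores at error positions, and writes gzipped paired FASTQ
#' plus a planted truth table. Deterministic given `seed`.
#'
#' Indel alleles are 1-3 nt insertions or deletions placed uniformly within
#' `indel_window` nt of the edited region; partial edits carry a proper
#' prefix of the alternative allele. Replicates sharing a `batches` label
#' share their Beta draws, emulating replicates with common library
#' integration.
#'
#' @param library Encoded peptide library (`nt_seq` required).
#' @param effects Output of [draw_true_effects()] (or any `data.frame` with
#'   `peptide_id`, `alpha`, `beta` covering the library).
#' @param spec [edit_spec()] describing the target amplicon.
#' @param depth Reads per peptide per replicate.
#' @param replicates Number of replicates (labelled `rep1`, `rep2`, ...).
#' @param indel_rate Per-read probability of an indel allele.
#' @param error_rate Per-base substitution error rate.
#' @param partial_frac Fraction of edited reads carrying only a partial
#'   edit (classified `other`).
#' @param q_high,q_low PHRED scores of the two-level quality model; error
#'   positions (and a `low_q_frac` fraction of random positions) get
#'   `q_low`.
#' @param low_q_frac Fraction of random positions assigned `q_low`.
#' @param batches Integer batch label per replicate; equal labels share
#'   Beta draws. Default: all distinct.
#' @param read1_len Length of read 1 (prefix of the peptide coding
#'   sequence plus tag).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return A list: `sample_sheet` (`replicate`, `r1`, `r2`, `orientation`),
#'   `truth` (per peptide x replicate: realized `p_true` and planted
#'   category counts summing to `depth`), `effects`, and the echoed
#'   `config`. The sheet and truth table are also written as TSV into
#'   `out_dir`.
#' @export
simulate_screen <- function(library, effects, spec = example_edit_spec(),
                            depth = 1000L, replicates = 3L,
                            indel_rate = 0.005, error_rate = 0.001,
                            partial_frac = 0.01, q_high = 37L, q_low = 15L,
                            low_q_frac = 0, batches = NULL,
                            read1_len = 50L, out_dir = tempfile("screen"),
                            seed = 1L) {
  stopifnot(depth >= 1L, replicates >= 1L,
            indel_rate >= 0, indel_rate <= 1, error_rate >= 0, error_rate <= 1,
            partial_frac >= 0, partial_frac <= 1)
  if (anyNA(library$nt_seq)) stop("library has records without nt_seq")
  effects <- effects[match(library$peptide_id, effects$peptide_id), ]
  if (anyNA(effects$alpha)) stop("effects missing for some library peptides")
  batches <- batches %||% seq_len(replicates)
  stopifnot(length(batches) == replicates)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  n_pep <- nrow(library)
  rep_labels <- sprintf("rep%d", seq_len(replicates))
  cats <- c("prime_edited", "other", "indel", "unedited")
  full_seq <- paste0(library$nt_seq,
                     ifelse(is.na(library$tag9), "", library$tag9))
  r1_by_pep <- substr(full_seq, 1L, read1_len)
  edited_seq <- apply_edit(spec)
  part_seqs <- vapply(partial_alleles(spec), function(a) apply_edit(spec, allele = a),
                      character(1), USE.NAMES = FALSE)

  truth <- NULL
  sheet <- NULL
  with_seed(seed, {
    # Beta draws per batch, shared across replicates with the same label
    ub <- unique(batches)
    p_batch <- vapply(ub, function(b) {
      stats::rbeta(n_pep, effects$alpha, effects$beta)
    }, numeric(n_pep))
    p_batch <- matrix(p_batch, nrow = n_pep)

    for (j in seq_len(replicates)) {
      p <- p_batch[, match(batches[j], ub)]
      probs <- rbind(
        prime_edited = (1 - indel_rate) * p * (1 - partial_frac),
        other = (1 - indel_rate) * p * partial_frac,
        indel = rep(indel_rate, n_pep),
        unedited = (1 - indel_rate) * (1 - p)
      )
      cnt <- vapply(seq_len(n_pep), function(i) {
        stats::rmultinom(1L, depth, probs[, i])[, 1L]
      }, integer(4))                      # 4 x n_pep
      truth <- rbind(truth, data.frame(
        peptide_id = library$peptide_id,
        replicate = rep_labels[j],
        batch = batches[j],
        p_true = p,
        n = depth,
        prime_edited = cnt[1L, ],
        other = cnt[2L, ],
        indel = cnt[3L, ],
        unedited = cnt[4L, ],
        stringsAsFactors = FALSE
      ))

      cat_per_read <- rep(rep(cats[c(1L, 2L, 3L, 4L)], n_pep),
                          times = as.vector(cnt))
      pid_per_read <- rep(library$peptide_id, times = colSums(cnt))
      N <- length(pid_per_read)

      r2 <- character(N)
      r2[cat_per_read == "unedited"] <- spec$ref_amplicon
      r2[cat_per_read == "prime_edited"] <- edited_seq
      n_other <- sum(cat_per_read == "other")
      if (n_other > 0L) {
        r2[cat_per_read == "other"] <- sample(part_seqs, n_other, replace = TRUE)
      }
      idx_indel <- which(cat_per_read == "indel")
      if (length(idx_indel) > 0L) {
        r2[idx_indel] <- vapply(idx_indel, function(i) random_indel_allele(spec),
                                character(1))
      }
      r1 <- r1_by_pep[match(pid_per_read, library$peptide_id)]

      noisy1 <- apply_read_noise(r1, error_rate, q_high, q_low, low_q_frac)
      noisy2 <- apply_read_noise(r2, error_rate, q_high, q_low, low_q_frac)

      ord <- sample.int(N)
      nm <- sprintf("%s:%07d:%s", rep_labels[j], seq_len(N),
                    cat_per_read)[ord]
      f1 <- file.path(out_dir, sprintf("%s_R1.fastq.gz", rep_labels[j]))
      f2 <- file.path(out_dir, sprintf("%s_R2.fastq.gz", rep_labels[j]))
      s1 <- Biostrings::DNAStringSet(noisy1$seqs[ord]); names(s1) <- nm
      s2 <- Biostrings::DNAStringSet(noisy2$seqs[ord]); names(s2) <- nm
      Biostrings::writeXStringSet(s1, f1, format = "fastq", compress = TRUE,
                                  qualities = Biostrings::BStringSet(noisy1$quals[ord]))
      Biostrings::writeXStringSet(s2, f2, format = "fastq", compress = TRUE,
                                  qualities = Biostrings::BStringSet(noisy2$quals[ord]))
      sheet <- rbind(sheet, data.frame(replicate = rep_labels[j], r1 = f1,
                                       r2 = f2, orientation = "forward",
                                       stringsAsFactors = FALSE))
    }
  })
  rownames(truth) <- NULL
  utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sheet, file.path(out_dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(
    sample_sheet = sheet,
    truth = truth,
    effects = effects,
    config = list(depth = depth, replicates = replicates,
                  indel_rate = indel_rate, error_rate = error_rate,
                  partial_frac = partial_frac, q_high = q_high, q_low = q_low,
                  low_q_frac = low_q_frac, batches = batches,
                  read1_len = read1_len, seed = seed, out_dir = out_dir)
  )
}

#' Simulate a dual-peptide combination screen
#'
#' Generates control-normalized editing observations for every N-terminal x
#' C-terminal peptide pair under an additive model:
#' `observed = baseline + a[n] + b[c] + Gaussian noise`. Peptides with
#' effect 0 (typically the control) anchor the scale.
#'
#' @param n_effects Named numeric vector of N-terminal position effects.
#' @param c_effects Named numeric vector of C-terminal position effects.
#' @param baseline Editing level of the zero-effect (control-control) pair.
#' @param noise_sd Gaussian noise standard deviation per observation.
#' @param replicates Observations per pair.
#' @param seed Integer seed.
#' @return A list: `observations` (`n_term_id`, `c_term_id`, `replicate`,
#'   `normalized_edited_fraction`) with one row per pair per replicate, and
#'   `truth` (baseline and both effect vectors).
#' @export
simulate_dual_screen <- function(n_effects, c_effects, baseline = 1,
                                 noise_sd = 0.05, replicates = 1L, seed = 1L) {
  stopifnot(length(n_effects) >= 1L, length(c_effects) >= 1L,
            !is.null(names(n_effects)), !is.null(names(c_effects)),
            noise_sd >= 0, replicates >= 1L)
  grid <- expand.grid(n_term_id = names(n_effects),
                      c_term_id = names(c_effects),
                      replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- baseline + n_effects[grid$n_term_id] + c_effects[grid$c_term_id]
  obs <- with_seed(seed, mu + stats::rnorm(nrow(grid), 0, noise_sd))
  grid$normalized_edited_fraction <- unname(obs)
  list(observations = grid,
       truth = list(baseline = baseline, n_effects = n_effects,
                    c_effects = c_effects))
}
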