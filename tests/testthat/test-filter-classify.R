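# Constructed reads exercising each quality-filter clause and the
# classification precedence, against the synthetic example amplicon.

spec <- example_edit_spec()
REF <- spec$ref_amplicon
REFLEN <- nchar(REF)
EDITED <- paste0(substr(REF, 1, 57), "GAATTC", substr(REF, 64, REFLEN))

qv <- function(len, q = 37L) rep(q, len)

test_that("perfect high-quality reads are kept unmasked and unedited", {
  aln <- align_target(REF, REF)
  fl <- filter_read(aln, qv(REFLEN))
  expect_equal(fl$disposition, "kept")
  expect_equal(nrow(fl$alignment$events), 0L)
  expect_equal(classify_outcome(fl$alignment, spec), "unedited")
})

test_that("reads below mean Q30 are dropped", {
  aln <- align_target(REF, REF)
  fl <- filter_read(aln, qv(REFLEN, 29L))
  expect_equal(fl$disposition, "dropped_low_quality")
  # boundary: mean exactly 30 is kept
  fl30 <- filter_read(aln, qv(REFLEN, 30L))
  expect_equal(fl30$disposition, "kept")
})

test_that("low-quality mismatches are masked and classify as reference", {
  read <- paste0(substr(REF, 1, 9), "T", substr(REF, 11, REFLEN))
  stopifnot(substr(REF, 10, 10) != "T")
  aln <- align_target(read, REF)
  q <- qv(REFLEN); q[10] <- 15L
  fl <- filter_read(aln, q)
  expect_equal(fl$disposition, "kept")
  expect_true(fl$alignment$events$masked)
  expect_equal(classify_outcome(fl$alignment, spec), "unedited")
  # same mismatch at high quality is a real difference -> other
  fl_hi <- filter_read(aln, qv(REFLEN))
  expect_false(fl_hi$alignment$events$masked)
  expect_equal(classify_outcome(fl_hi$alignment, spec), "other")
})

test_that("edit calling is all-or-nothing over the programmed region", {
  aln <- align_target(EDITED, REF)
  fl <- filter_read(aln, qv(REFLEN))
  expect_equal(classify_outcome(fl$alignment, spec), "prime_edited")

  # partial installation (prefix of the alt allele) -> other
  partial <- paste0(substr(REF, 1, 57), "GAAT",
                    substr(REF, 62, REFLEN))
  flp <- filter_read(align_target(partial, REF), qv(REFLEN))
  expect_equal(classify_outcome(flp$alignment, spec), "other")

  # full edit plus an extra high-quality mismatch elsewhere -> other
  extra <- paste0(substr(EDITED, 1, 19),
                  chartr("ACGT", "GTAC", substr(EDITED, 20, 20)),
                  substr(EDITED, 21, REFLEN))
  fle <- filter_read(align_target(extra, REF), qv(REFLEN))
  expect_equal(classify_outcome(fle$alignment, spec), "other")

  # one edited base masked by low quality: the region reverts to reference
  # there, so the edit is no longer complete -> other
  alnE <- align_target(EDITED, REF)
  q <- qv(REFLEN); q[58] <- 10L        # first base of the region
  flm <- filter_read(alnE, q)
  expect_equal(classify_outcome(flm$alignment, spec), "other")
})

test_that("indels need three high-quality flanking matches on both sides", {
  # mid-amplicon deletion, everything high quality -> indel
  del <- paste0(substr(REF, 1, 20), substr(REF, 23, REFLEN))
  aln <- align_target(del, REF)
  fl <- filter_read(aln, qv(nchar(del)))
  expect_false(fl$alignment$events$masked)
  expect_equal(classify_outcome(fl$alignment, spec), "indel")

  # only two matching nucleotides on the left side -> masked -> unedited
  del_left <- substr(REF, 1, REFLEN)
  del_left <- paste0(substr(REF, 1, 2), substr(REF, 6, REFLEN))
  aln_l <- align_target(del_left, REF)
  fl_l <- filter_read(aln_l, qv(nchar(del_left)))
  expect_true(all(fl_l$alignment$events$masked[
    fl_l$alignment$events$type != "mismatch"]))
  expect_equal(classify_outcome(fl_l$alignment, spec), "unedited")

  # flanks exist but left-side quality is too low to count -> masked
  aln2 <- align_target(del, REF)
  q <- qv(nchar(del))
  q[1:18] <- 29L                      # 20 left matches, only 2 at Q >= 30
  fl2 <- filter_read(aln2, q)
  expect_equal(fl2$disposition, "kept")
  expect_true(fl2$alignment$events$masked)
  expect_equal(classify_outcome(fl2$alignment, spec), "unedited")
})

test_that("unmasked indels take precedence over any mismatch pattern", {
  read <- paste0(substr(EDITED, 1, 20), substr(EDITED, 23, REFLEN))
  fl <- filter_read(align_target(read, REF), qv(nchar(read)))
  expect_equal(classify_outcome(fl$alignment, spec), "indel")
})

test_that("raising the quality threshold never unmasks events", {
  set.seed(53)
  for (i in 1:25) {
    s <- strsplit(REF, "")[[1]]
    p <- sample(REFLEN, sample(1:4, 1))
    s[p] <- sample(c("A", "C", "G", "T"), length(p), replace = TRUE)
    if (i %% 3 == 0) s <- s[-sample(REFLEN - 5, 1)]
    read <- paste(s, collapse = "")
    aln <- align_target(read, REF)
    q <- sample(c(15L, 25L, 32L, 37L), nchar(read), replace = TRUE)
    unmasked <- vapply(c(20, 30, 40), function(th) {
      fl <- filter_read(aln, q, min_mean_q = 0, min_base_q = th)
      sum(!fl$alignment$events$masked)
    }, numeric(1))
    expect_true(all(diff(unmasked) <= 0))
  }
})

test_that("quality vectors must match the read length", {
  aln <- align_target(REF, REF)
  expect_error(filter_read(aln, qv(REFLEN - 1)), "does not match")
})
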