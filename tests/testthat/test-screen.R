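# 30-bp reference window with a variant site at position 20 (ref base 'A')
REF_WIN <- "ACGTTGCAATGCCGTAGGCTAACGGTTCAG"
SITE <- 20L
stopifnot(substr(REF_WIN, SITE, SITE) == "T")

test_that("realignment classifies reference, substituted and shifted reads", {
  # read identical to a window substring covering the site
  expect_equal(realign_read(substr(REF_WIN, 6, 25), REF_WIN, SITE), "wildtype")
  # single substitution at the site with matching flanks
  read <- substr(REF_WIN, 6, 25)
  substr(read, SITE - 5L, SITE - 5L) <- "G"   # site 20 is offset 15 in read
  expect_equal(realign_read(read, REF_WIN, SITE), "supports_mutant")
  expect_equal(realign_read(read, REF_WIN, SITE, alt = "G"), "supports_mutant")
  expect_equal(realign_read(read, REF_WIN, SITE, alt = "C"), "wildtype")
  # a 2-bp deletion upstream of the site: naively the bases shift to fake a
  # mutant, but the optimal gapped alignment restores the reference base
  read_del <- paste0(substr(REF_WIN, 3, 14), substr(REF_WIN, 17, 28))
  expect_equal(realign_read(read_del, REF_WIN, SITE), "wildtype")
  expect_error(realign_read("", REF_WIN, SITE), "empty")
})

test_that("realignment agrees with the brute-force affine-gap oracle", {
  set.seed(31)
  n_checked <- 0L
  for (i in 1:40) {
    win <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
    site <- sample(10:21, 1)
    start <- sample(1:6, 1); end <- sample(24:29, 1)
    read <- substr(win, start, end)
    kind <- sample(c("ref", "sub", "del"), 1)
    if (kind == "sub") {
      off <- site - start + 1L
      substr(read, off, off) <- sample(setdiff(c("A", "C", "G", "T"),
                                               substr(win, site, site)), 1)
    } else if (kind == "del") {
      cut <- sample(seq(start + 2L, site - 3L), 1)
      read <- paste0(substr(win, start, cut),
                     substr(win, cut + sample(1:2, 1) + 1L, end))
    }
    got <- realign_read(read, win, site)
    base <- oracle_base_at(read, win, site)
    want <- if (is.na(base) || base == "-" || base == substr(win, site, site))
      "wildtype" else "supports_mutant"
    expect_equal(got, want,
                 info = sprintf("case %d (%s): read %s", i, kind, read))
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 40L)
})

test_that("quality valley fails only on a strict minimum at the variant base", {
  expect_equal(quality_valley_filter(c(30, 30, 10, 30, 30), offset = 2), "fail")
  expect_equal(quality_valley_filter(c(30, 30, 30, 30, 30), offset = 2), "pass")
  # window truncated at the read end
  expect_equal(quality_valley_filter(c(35, 20, 12), offset = 2), "fail")
  # a tie with a neighbour is not a strict valley
  expect_equal(quality_valley_filter(c(30, 10, 10, 30, 30), offset = 2), "pass")
  # only the window matters: a distant low base does not rescue the variant
  expect_equal(quality_valley_filter(c(2, 30, 30, 30, 25, 30, 30), offset = 4,
                                     window = 5), "fail")
})

test_that("overlap-only check fails iff all support sits in mate overlaps", {
  expect_equal(overlap_only_filter(rep(TRUE, 4)), "fail")
  expect_equal(overlap_only_filter(c(TRUE, TRUE, TRUE, FALSE)), "pass")
  expect_error(overlap_only_filter(logical(0)), "no mutant")
})

make_evidence <- function(n, duplicate = FALSE, overlap = FALSE,
                          valley = FALSE, wildtype = FALSE) {
  read <- substr(REF_WIN, 6, 25)
  off <- SITE - 6L   # 0-based offset of the site within the read
  if (!wildtype) substr(read, off + 1L, off + 1L) <- "G"
  quals <- rep(35L, nchar(read))
  if (valley) quals[off + 1L] <- 8L
  data.frame(
    read_id = paste0("r", seq_len(n), "_", sample.int(1e6, 1)),
    sequence = read,
    qualities = paste(quals, collapse = ","),
    offset = off,
    orientation = "forward",
    duplicate = duplicate, overlap = overlap,
    stringsAsFactors = FALSE
  )
}

test_that("site screening pipeline composes the filters and the read minimum", {
  set.seed(32)
  # all duplicates: nothing to count
  res <- screen_site(make_evidence(5, duplicate = TRUE), REF_WIN, SITE)
  expect_equal(res$validated_mutant_count, 0L)
  expect_false(res$present)
  expect_true(all(res$fail_reasons == "duplicate"))
  # exactly three clean reads, one outside the mate overlap: present
  ev <- rbind(make_evidence(2, overlap = TRUE), make_evidence(1, overlap = FALSE))
  res3 <- screen_site(ev, REF_WIN, SITE)
  expect_equal(res3$validated_mutant_count, 3L)
  expect_true(res3$present)
  # two clean reads fall below the minimum
  res2 <- screen_site(make_evidence(2), REF_WIN, SITE)
  expect_equal(res2$validated_mutant_count, 2L)
  expect_false(res2$present)
  # all support inside mate overlaps is a fragment artefact
  res_ov <- screen_site(make_evidence(4, overlap = TRUE), REF_WIN, SITE)
  expect_equal(res_ov$validated_mutant_count, 0L)
  expect_true(all(res_ov$fail_reasons == "overlap_only"))
  # wild-type and valley reads are removed with their reasons
  ev_mix <- rbind(make_evidence(3), make_evidence(1, wildtype = TRUE),
                  make_evidence(1, valley = TRUE))
  res_mix <- screen_site(ev_mix, REF_WIN, SITE)
  expect_equal(res_mix$validated_mutant_count, 3L)
  expect_equal(unname(res_mix$fail_reasons[4:5]),
               c("realign_wildtype", "quality_valley"))
})

test_that("screening is invariant to duplicates and monotone in clean evidence", {
  set.seed(33)
  ev <- make_evidence(3)
  base <- screen_site(ev, REF_WIN, SITE)
  with_dup <- screen_site(rbind(ev, make_evidence(2, duplicate = TRUE)),
                          REF_WIN, SITE)
  expect_equal(with_dup$validated_mutant_count, base$validated_mutant_count)
  expect_equal(with_dup$present, base$present)
  # adding a passing non-duplicate read never flips present -> absent
  more <- screen_site(rbind(ev, make_evidence(1)), REF_WIN, SITE)
  expect_false(base$present && !more$present)
  expect_equal(more$validated_mutant_count, base$validated_mutant_count + 1L)
})

test_that("evidence TSV ingestion validates its invariants", {
  ev <- make_evidence(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ev2 <- read_evidence(path)
  expect_equal(ev2$sequence, ev$sequence)
  expect_equal(ev2$offset, ev$offset)
  bad <- ev; bad$offset[2] <- 99L
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_evidence(path2), "row")
})
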