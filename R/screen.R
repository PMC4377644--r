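# Site-specific screening of low-frequency mutant read evidence.
#
# Mutant-supporting reads at a candidate site are re-examined before they
# count toward a presence call: PCR duplicates are dropped, each read is
# locally realigned to the reference window around the site (reads whose best
# alignment restores the reference base were alignment artefacts), reads
# whose variant base sits at a strict quality "valley" are dropped, and if
# the only surviving support comes from the overlap of forward/reverse mate
# pairs the site as a whole is treated as a fragment artefact.

# Smith-Waterman scoring used throughout: match +2, mismatch -1,
# gap open -3, gap extend -1. Chosen so that a single short gap is preferred
# over scattered mismatches, the artefact mode the realignment check targets.
.SW_MATCH <- 2L
.SW_MISMATCH <- -1L
.SW_GAP_OPEN <- 3L   # cost (positive) as Biostrings expects
.SW_GAP_EXT <- 1L

#' Realign one read to the reference window around a variant site
#'
#' Computes the best Smith-Waterman local alignment of the read against the
#' reference window (the reference sequence with up to 100 bp of flank on
#' each side of the site) and inspects which read base the alignment places
#' at the variant position. If the best alignment restores the reference
#' base at the site -- or deletes the site, or does not reach it -- the
#' mutant allele was an alignment artefact and the read is wild-type.
#'
#' @param read_sequence Read bases (character scalar).
#' @param reference_window Reference bases around the site.
#' @param variant_site 1-based position of the variant within
#'   `reference_window`.
#' @param alt Optional mutant base; when supplied, the read supports the
#'   mutant only if the aligned base equals `alt` (otherwise any non-reference
#'   base counts as mutant support).
#' @return `"supports_mutant"` or `"wildtype"`.
#' @examples
#' realign_read("ACGTA", "ACGCATTACGCA", variant_site = 4)   # matches ref
#' @export
realign_read <- function(read_sequence, reference_window, variant_site,
                         alt = NULL) {
  if (!nzchar(read_sequence) || !nzchar(reference_window)) {
    stop("empty read or reference sequence")
  }
  stopifnot(variant_site >= 1, variant_site <= nchar(reference_window))
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = .SW_MATCH, mismatch = .SW_MISMATCH, baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = read_sequence, subject = reference_window, type = "local",
    substitutionMatrix = sub_mat,
    gapOpening = .SW_GAP_OPEN, gapExtension = .SW_GAP_EXT)
  ref_base <- substr(reference_window, variant_site, variant_site)
  aligned <- .aligned_base_at(pa, variant_site)
  if (is.na(aligned) || aligned == "-" || aligned == ref_base) {
    return("wildtype")
  }
  if (!is.null(alt) && aligned != alt) {
    return("wildtype")
  }
  "supports_mutant"
}

# Read base aligned to subject (reference window) position `site` in a local
# pairwise alignment; NA if the alignment does not cover the site.
.aligned_base_at <- function(pa, site) {
  sub_start <- Biostrings::start(Biostrings::subject(pa))
  pat_gapped <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub_gapped <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  sub_pos <- sub_start - 1L
  for (i in seq_along(sub_gapped)) {
    if (sub_gapped[i] != "-") sub_pos <- sub_pos + 1L
    if (sub_pos == site && sub_gapped[i] != "-") {
      return(pat_gapped[i])
    }
  }
  NA_character_
}

#' Quality-valley filter for a mutant-supporting read
#'
#' Flags a read when the base quality at the variant position is the strict
#' minimum of a window (default 5 bp) centred on the variant -- the local
#' "valley" pattern characteristic of sequencing error. The window is
#' truncated at read ends. Ties are not a strict valley, so flat-quality
#' reads pass.
#'
#' @param qualities Integer vector of Phred base qualities for the read.
#' @param offset 0-based index of the variant base within the read.
#' @param window Window width in bases (odd; default 5).
#' @return `"pass"` or `"fail"`.
#' @examples
#' quality_valley_filter(c(30, 30, 10, 30, 30), offset = 2)  # fail
#' @export
quality_valley_filter <- function(qualities, offset, window = 5L) {
  stopifnot(.is_count(window, min = 1L), window %% 2L == 1L,
            offset >= 0, offset < length(qualities))
  i <- offset + 1L
  half <- (window - 1L) %/% 2L
  lo <- max(1L, i - half); hi <- min(length(qualities), i + half)
  others <- qualities[setdiff(lo:hi, i)]
  if (length(others) > 0L && qualities[i] < min(others)) "fail" else "pass"
}

#' Overlap-only filter for a site's mutant evidence
#'
#' Paired-end fragments shorter than twice the read length are sequenced
#' twice in the mate-overlap region; a mutant allele seen exclusively inside
#' such overlaps is a fragment-level artefact (e.g. a PCR error propagated to
#' both mates). The check applies to all mutant-supporting evidence at a
#' site: it fails iff every supporting read lies in a mate overlap.
#'
#' @param in_overlap Logical vector: whether each mutant-supporting read lies
#'   in the overlap of its mate pair.
#' @return `"pass"` or `"fail"`.
#' @export
overlap_only_filter <- function(in_overlap) {
  if (length(in_overlap) == 0L) {
    stop("no mutant-supporting evidence supplied")
  }
  stopifnot(is.logical(in_overlap), !anyNA(in_overlap))
  if (all(in_overlap)) "fail" else "pass"
}

#' Read a per-read evidence table from TSV
#'
#' Columns: `read_id`, `sequence`, `qualities` (comma-separated Phred
#' integers, one per base), `offset` (0-based variant index in the read),
#' `orientation` (`forward`/`reverse`), `duplicate`, `overlap` (logical).
#'
#' @param path Path to the TSV.
#' @return Data frame of evidence records.
#' @export
read_evidence <- function(path) {
  ev <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("read_id", "sequence", "qualities", "offset", "orientation",
                "duplicate", "overlap")
  missing <- setdiff(required, names(ev))
  if (length(missing) > 0L) {
    stop("missing evidence columns: ", paste(missing, collapse = ", "))
  }
  ev$duplicate <- as.logical(ev$duplicate)
  ev$overlap <- as.logical(ev$overlap)
  quals <- lapply(strsplit(ev$qualities, ",", fixed = TRUE), as.integer)
  bad <- which(vapply(quals, length, integer(1)) != nchar(ev$sequence) |
                 ev$offset < 0 | ev$offset >= nchar(ev$sequence))
  if (length(bad) > 0L) {
    stop("evidence invariant violated (qualities length / offset) at row(s) ",
         paste(bad, collapse = ", "))
  }
  ev
}

#' Screen the mutant read evidence at one genomic site
#'
#' Full screening pipeline for one site in one sample: drop PCR duplicates,
#' realign each remaining read to the reference window
#' ([realign_read()]), apply the quality-valley check
#' ([quality_valley_filter()]), then apply the site-level overlap-only check
#' ([overlap_only_filter()]) to the survivors. The validated mutant count is
#' the number of reads passing all checks, and the mutant allele is called
#' present when at least `min_reads` non-duplicate reads survive.
#'
#' @param evidence Data frame of evidence records (see [read_evidence()]).
#' @param reference_window Reference sequence around the site.
#' @param variant_site 1-based variant position within `reference_window`.
#' @param alt Optional expected mutant base, passed to [realign_read()].
#' @param min_reads Minimum surviving reads for a presence call (default 3).
#' @param window Quality-valley window width (default 5).
#' @return An object of class `"screen_result"`: list with
#'   `validated_mutant_count`, `present`, `fail_reasons` (named by `read_id`;
#'   `NA` for reads that passed), `n_input`.
#' @export
screen_site <- function(evidence, reference_window, variant_site, alt = NULL,
                        min_reads = 3L, window = 5L) {
  stopifnot(is.data.frame(evidence), nrow(evidence) >= 1L)
  reasons <- setNames(rep(NA_character_, nrow(evidence)), evidence$read_id)
  reasons[evidence$duplicate] <- "duplicate"
  quals <- lapply(strsplit(evidence$qualities, ",", fixed = TRUE), as.integer)
  for (i in which(is.na(reasons))) {
    if (realign_read(evidence$sequence[i], reference_window, variant_site,
                     alt = alt) == "wildtype") {
      reasons[i] <- "realign_wildtype"
    } else if (quality_valley_filter(quals[[i]], evidence$offset[i],
                                     window = window) == "fail") {
      reasons[i] <- "quality_valley"
    }
  }
  survivors <- which(is.na(reasons))
  if (length(survivors) > 0L &&
      overlap_only_filter(evidence$overlap[survivors]) == "fail") {
    reasons[survivors] <- "overlap_only"
    survivors <- integer(0)
  }
  structure(
    list(validated_mutant_count = length(survivors),
         present = length(survivors) >= min_reads,
         fail_reasons = reasons,
         n_input = nrow(evidence)),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("Site screen: %d/%d reads validated -> mutant allele %s\n",
              x$validated_mutant_count, x$n_input,
              if (x$present) "PRESENT" else "ABSENT"))
  fails <- x$fail_reasons[!is.na(x$fail_reasons)]
  if (length(fails) > 0L) {
    tab <- table(fails)
    cat("  failed:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
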