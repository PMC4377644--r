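# Ingestion, validation and categorisation of somatic variant read counts.
#
# Canonical table: one row per somatic variant with mutant/total read counts
# at diagnosis (dx), relapse (rel) and remission (rem). Coordinates are
# 1-based, VCF-style. The `diploid` flag marks copy-neutral loci without LOH;
# non-diploid variants are retained here and excluded at the clustering stage.

.VARIANT_COLS <- c("case_id", "chrom", "pos", "ref", "alt",
                   "dx_mut", "dx_tot", "rel_mut", "rel_tot",
                   "rem_mut", "rem_tot", "diploid", "gene", "effect", "pathway")
.COUNT_COLS <- c("dx_mut", "dx_tot", "rel_mut", "rel_tot", "rem_mut", "rem_tot")

.validate_variants <- function(v, lines = seq_len(nrow(v)) + 1L) {
  problems <- character(0)
  note <- function(rows, msg) {
    if (any(rows)) {
      problems <<- c(problems, paste0(msg, " (line ", lines[which(rows)], ")"))
    }
  }
  for (cc in .COUNT_COLS) {
    bad <- !is.finite(v[[cc]]) | v[[cc]] < 0 | v[[cc]] != round(v[[cc]])
    note(bad, paste0("non-count value in ", cc))
  }
  for (tp in c("dx", "rel", "rem")) {
    mu <- v[[paste0(tp, "_mut")]]; to <- v[[paste0(tp, "_tot")]]
    note(is.finite(mu) & is.finite(to) & mu > to,
         paste0("mutant reads exceed total reads at ", tp))
  }
  note(!is.finite(v$pos) | v$pos < 1, "position must be >= 1")
  note(v$ref == v$alt, "ref and alt alleles are identical")
  if (length(problems) > 0L) {
    stop("invalid variant rows:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(v)
}

#' Read a somatic variant table from TSV or VCF
#'
#' The TSV dialect has a header row and tab-separated columns `case_id,
#' chrom, pos, ref, alt, dx_mut, dx_tot, rel_mut, rel_tot, rem_mut, rem_tot,
#' diploid, gene, effect, pathway` (the last three optional). VCF input must
#' be a standard 4.x file with a per-sample `AD` (allelic depths) FORMAT
#' field for the diagnosis/relapse/remission trio; `sample_map` names which
#' VCF sample corresponds to which timepoint. Coordinates are 1-based in both
#' formats. Rows violating the count invariants (mutant reads > total reads,
#' negative counts, `ref == alt`) abort with a diagnostic naming the
#' offending line numbers.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"vcf"`.
#' @param sample_map For VCF: named character vector
#'   `c(diagnosis = ..., relapse = ..., remission = ...)` mapping timepoints
#'   to VCF sample names. `remission` may be omitted (counts set to 0).
#' @param case_id For VCF: case identifier to assign (default the file name).
#' @return A data frame in the canonical variant-table layout.
#' @seealso [write_variants()], [classify_presence()]
#' @export
read_variants <- function(path, format = c("tsv", "vcf"), sample_map = NULL,
                          case_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    v <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    required <- setdiff(.VARIANT_COLS, c("gene", "effect", "pathway"))
    missing <- setdiff(required, names(v))
    if (length(missing) > 0L) {
      stop("missing required columns: ", paste(missing, collapse = ", "))
    }
    for (opt in c("gene", "effect", "pathway")) {
      if (is.null(v[[opt]])) v[[opt]] <- NA_character_
    }
    for (ch in c("case_id", "chrom", "ref", "alt", "gene", "effect", "pathway")) {
      v[[ch]] <- as.character(v[[ch]])
    }
    v$diploid <- as.logical(v$diploid)
    v <- v[, .VARIANT_COLS]
    .validate_variants(v)
    return(v)
  }
  # VCF: per-sample allelic depths mapped to timepoints
  if (is.null(sample_map) || !all(c("diagnosis", "relapse") %in% names(sample_map))) {
    stop("VCF input requires sample_map with at least 'diagnosis' and 'relapse' entries")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  fmt <- colnames(vcf@gt)[1L]
  if (!grepl("\\bAD\\b", vcf@gt[1L, fmt])) {
    stop("VCF lacks per-sample AD (allelic depth) FORMAT field")
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  get_counts <- function(tp) {
    sm <- sample_map[[tp]]
    if (is.null(sm) || is.na(sm)) {
      return(list(mut = rep(0L, nrow(fix)), tot = rep(0L, nrow(fix))))
    }
    if (!sm %in% colnames(ad)) stop("sample not in VCF: ", sm)
    parts <- strsplit(ad[, sm], ",", fixed = TRUE)
    bad <- vapply(parts, function(p) length(p) < 2L || anyNA(suppressWarnings(as.integer(p))),
                  logical(1))
    if (any(bad)) {
      stop("missing or malformed AD depths for sample ", sm,
           " at record(s) ", paste(which(bad), collapse = ", "))
    }
    refd <- vapply(parts, function(p) as.integer(p[1L]), integer(1))
    altd <- vapply(parts, function(p) as.integer(p[2L]), integer(1))
    list(mut = altd, tot = refd + altd)
  }
  dx <- get_counts("diagnosis"); rel <- get_counts("relapse"); rem <- get_counts("remission")
  v <- data.frame(
    case_id = if (is.null(case_id)) basename(path) else case_id,
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    dx_mut = dx$mut, dx_tot = dx$tot,
    rel_mut = rel$mut, rel_tot = rel$tot,
    rem_mut = rem$mut, rem_tot = rem$tot,
    diploid = TRUE, gene = NA_character_, effect = NA_character_,
    pathway = NA_character_, stringsAsFactors = FALSE
  )
  .validate_variants(v)
  v
}

#' Write a variant table as TSV
#'
#' Inverse of [read_variants()] for the TSV dialect; `write_variants()`
#' followed by `read_variants()` is the identity on valid tables.
#'
#' @param variants Canonical variant data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  stopifnot(all(setdiff(.VARIANT_COLS, c("gene", "effect", "pathway")) %in%
                  names(variants)))
  for (opt in c("gene", "effect", "pathway")) {
    if (is.null(variants[[opt]])) variants[[opt]] <- NA_character_
  }
  write.table(variants[, .VARIANT_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a variant table as a minimal VCF 4.2 with per-sample allelic depths
#'
#' Emits one record per variant with a `DP:AD` FORMAT and three samples
#' (diagnosis, relapse, remission). Useful for interoperating with VCF-based
#' tooling and for round-trip testing against [read_variants()].
#'
#' @param variants Canonical variant data frame (single case).
#' @param path Output path.
#' @param sample_names Named character vector giving the VCF sample names for
#'   `diagnosis`, `relapse`, `remission`.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path,
                               sample_names = c(diagnosis = "DIAGNOSIS",
                                                relapse = "RELAPSE",
                                                remission = "REMISSION")) {
  stopifnot(length(unique(variants$case_id)) <= 1L)
  ad <- function(mut, tot) paste0(tot - mut, ",", mut)
  gt <- function(tp) {
    mut <- variants[[paste0(tp, "_mut")]]; tot <- variants[[paste0(tp, "_tot")]]
    paste0(tot, ":", ad(mut, tot))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names[c("diagnosis", "relapse", "remission")]),
          collapse = "\t")
  )
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                ".", "PASS", ".", "DP:AD",
                gt("dx"), gt("rel"), gt("rem"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Mutant allele fraction from read counts
#'
#' @param mut_reads,total_reads Mutant and total read counts (vectorised).
#' @return `mut_reads / total_reads`. A zero total depth gives `NA` with a
#'   warning: the MAF is undefined there, which is distinct from an observed
#'   MAF of 0.
#' @examples
#' compute_maf(5, 100)
#' @export
compute_maf <- function(mut_reads, total_reads) {
  stopifnot(length(mut_reads) == length(total_reads), all(mut_reads >= 0),
            all(total_reads >= 0))
  if (any(mut_reads > total_reads)) stop("mutant reads exceed total reads")
  if (any(total_reads == 0)) {
    warning("total_reads = 0: MAF undefined, returning NA")
  }
  ifelse(total_reads >= 1, mut_reads / total_reads, NA_real_)
}

#' Presence calls and diagnosis/relapse category for somatic variants
#'
#' A mutant allele is called present at a timepoint when its mutant allele
#' fraction is at least `maf_floor` AND it is supported by at least
#' `min_reads` mutant reads on the available (platform-combined) depth. The
#' two tumour calls then categorise the variant as diagnosis-specific,
#' relapse-specific or shared. Variants absent at both tumour timepoints get
#' an `NA` category with a warning; they carry no lineage information.
#'
#' @param variants Canonical variant data frame (see [read_variants()]).
#' @param maf_floor Minimum mutant allele fraction for presence (default
#'   0.01, the detection floor at deep combined coverage).
#' @param min_reads Minimum mutant read support (default 3 non-duplicate
#'   reads).
#' @return `variants` with added logical columns `present_dx`,
#'   `present_rel`, `present_rem` and a character `category` in
#'   `c("dx_specific", "rel_specific", "shared")`.
#' @examples
#' v <- data.frame(case_id = "X", chrom = "1", pos = 1, ref = "A", alt = "G",
#'                 dx_mut = 10, dx_tot = 883, rel_mut = 0, rel_tot = 900,
#'                 rem_mut = 0, rem_tot = 900, diploid = TRUE)
#' classify_presence(v)$category
#' @export
classify_presence <- function(variants, maf_floor = 0.01, min_reads = 3) {
  stopifnot(.is_fraction(maf_floor, open_lo = TRUE, open_hi = TRUE),
            .is_count(min_reads, min = 1L))
  present <- function(tp) {
    mu <- variants[[paste0(tp, "_mut")]]; to <- variants[[paste0(tp, "_tot")]]
    to >= 1 & mu >= min_reads & (mu / pmax(to, 1)) >= maf_floor
  }
  variants$present_dx <- present("dx")
  variants$present_rel <- present("rel")
  variants$present_rem <- present("rem")
  variants$category <- ifelse(
    variants$present_dx & variants$present_rel, "shared",
    ifelse(variants$present_dx, "dx_specific",
           ifelse(variants$present_rel, "rel_specific", NA_character_)))
  if (anyNA(variants$category)) {
    warning(sum(is.na(variants$category)),
            " variant(s) absent at both tumour timepoints; category undefined: ",
            paste(head(.variant_key(variants[is.na(variants$category), ]), 5L),
                  collapse = ", "))
  }
  variants
}

#' Combine per-variant read counts from two sequencing platforms
#'
#' Sums mutant and total read counts per timepoint for variants reported by
#' two platforms (e.g. whole-exome and targeted capture), matching variants
#' on `(case_id, chrom, pos, ref, alt)`. One table's keys must be a subset of
#' the other's (an empty table is the identity); any key present in only the
#' smaller table is an error.
#'
#' @param calls_a,calls_b Canonical variant data frames.
#' @return Combined variant table with summed counts.
#' @export
merge_platforms <- function(calls_a, calls_b) {
  if (nrow(calls_b) == 0L) return(calls_a)
  if (nrow(calls_a) == 0L) return(calls_b)
  ka <- .variant_key(calls_a); kb <- .variant_key(calls_b)
  if (all(ka %in% kb) && !all(kb %in% ka)) {
    tmp <- calls_a; calls_a <- calls_b; calls_b <- tmp
    tmp <- ka; ka <- kb; kb <- tmp
  }
  if (!all(kb %in% ka)) {
    stop("variant key mismatch: ",
         paste(head(setdiff(kb, ka), 5L), collapse = ", "),
         " present in only one platform and not a subset of the other")
  }
  out <- calls_a
  idx <- match(kb, ka)
  for (cc in .COUNT_COLS) {
    out[[cc]][idx] <- out[[cc]][idx] + calls_b[[cc]]
  }
  .validate_variants(out)
  out
}
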