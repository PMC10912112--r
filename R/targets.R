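#' Classify a ref/alt allele pair
#'
#' Determines the variant type from a VCF-style left-anchored allele pair.
#' Only simple variants are supported: single-nucleotide substitutions and
#' left-anchored insertions/deletions (the alt extends the ref, or the ref
#' extends the alt). Multi-nucleotide substitutions are rejected.
#'
#' @param ref Reference allele string (A/C/G/T characters).
#' @param alt Alternative allele string.
#' @return One of `"SNV"`, `"INS"`, `"DEL"`.
#' @export
classify_variant <- function(ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt)) {
    stop("alleles must be non-empty A/C/G/T strings (got ref='", ref,
         "', alt='", alt, "')")
  }
  nr <- nchar(ref)
  na <- nchar(alt)
  if (nr == 1L && na == 1L) {
    if (ref == alt) stop("ref and alt alleles are identical ('", ref, "')")
    return("SNV")
  }
  if (na > nr && startsWith(alt, ref)) return("INS")
  if (nr > na && startsWith(ref, alt)) return("DEL")
  stop("unsupported allele pair ref='", ref, "' alt='", alt,
       "': multi-nucleotide substitutions are out of scope; ",
       "indels must be left-anchored (alt extends ref or ref extends alt)")
}

#' Inserted or deleted bases of an indel target
#'
#' For an insertion, the bases added after the anchor; for a deletion, the
#' bases removed after the anchor. This is the motif searched for in the
#' pileup string (`+nSEQ` / `-nSEQ`).
#'
#' @param target One-row data frame (or list) with `ref`, `alt`,
#'   `variant_type`.
#' @return Upper-case motif string; `""` for an SNV.
#' @export
indel_motif <- function(target) {
  switch(target$variant_type,
    SNV = "",
    INS = toupper(substring(target$alt, nchar(target$ref) + 1L)),
    DEL = toupper(substring(target$ref, nchar(target$alt) + 1L)),
    stop("unknown variant_type '", target$variant_type, "'")
  )
}

#' Read and validate a variant target table
#'
#' Reads the tab-separated table of targeted de novo variants (one row per
#' family) and validates every row: positions are 1-based positive
#' integers, alleles are A/C/G/T strings, and the declared `variant_type`
#' must agree with the allele pair (SNV: both length 1; INS: alt extends
#' ref; DEL: ref extends alt, both left-anchored as in VCF).
#'
#' @param path Path to a TSV with header columns `family_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `variant_type`, `pool_id`.
#' @return A data frame of validated targets, one row per family.
#'   Duplicate (chrom, pos, alt) triples across families are allowed but
#'   raise a warning, as does an empty (header-only) file.
#' @export
parse_target_table <- function(path) {
  cols <- c("family_id", "chrom", "pos", "ref", "alt", "variant_type", "pool_id")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (!all(cols %in% names(df))) {
    stop("target table ", path, " is missing column(s): ",
         paste(setdiff(cols, names(df)), collapse = ", "))
  }
  df <- df[, cols]
  if (nrow(df) == 0L) {
    warning("target table ", path, " contains no variant rows")
    df$pos <- integer(0)
    return(df)
  }
  pos <- suppressWarnings(as.integer(df$pos))
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header is line 1
    if (is.na(pos[i]) || pos[i] < 1L) {
      stop("target table line ", line, ": position '", df$pos[i],
           "' is not a positive integer")
    }
    vt <- df$variant_type[i]
    if (!vt %in% c("SNV", "INS", "DEL")) {
      stop("target table line ", line, ": unknown variant_type '", vt, "'")
    }
    implied <- tryCatch(classify_variant(df$ref[i], df$alt[i]),
                        error = function(e) {
                          stop("target table line ", line, ": ",
                               conditionMessage(e), call. = FALSE)
                        })
    if (implied != vt) {
      stop("target table line ", line, ": alleles ref='", df$ref[i],
           "' alt='", df$alt[i], "' imply variant_type ", implied,
           " but the row declares ", vt)
    }
    if (any(df$family_id[i] == "", df$pool_id[i] == "", df$chrom[i] == "")) {
      stop("target table line ", line, ": empty family_id/chrom/pool_id")
    }
  }
  df$pos <- pos
  df$ref <- toupper(df$ref)
  df$alt <- toupper(df$alt)
  key <- paste(df$chrom, df$pos, df$alt, sep = ":")
  if (anyDuplicated(key)) {
    warning("duplicate (chrom, pos, alt) across families: ",
            paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  df
}

#' Read a sample manifest
#'
#' The manifest maps each sequenced parental sample to its family, its role
#' within that family, and the capture pool it was sequenced in. Samples
#' act as controls for every other family in their pool.
#'
#' @param path TSV with header columns `sample_id`, `family_id`, `role`
#'   (father/mother), `pool_id`.
#' @return Validated data frame.
#' @export
read_manifest <- function(path) {
  cols <- c("sample_id", "family_id", "role", "pool_id")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (!all(cols %in% names(df))) {
    stop("manifest ", path, " is missing column(s): ",
         paste(setdiff(cols, names(df)), collapse = ", "))
  }
  df <- df[, cols]
  bad <- !df$role %in% c("father", "mother")
  if (any(bad)) {
    stop("manifest ", path, ": invalid role(s) ",
         paste(unique(df$role[bad]), collapse = ", "),
         " (expected father/mother; control status is derived per target)")
  }
  if (anyDuplicated(df$sample_id)) {
    stop("manifest ", path, ": duplicated sample_id(s)")
  }
  df
}

#' Write a table with self-describing header comments
#'
#' @param df Data frame.
#' @param path Output path.
#' @param comments Character vector of comment lines (written as `# ...`).
#' @export
write_tsv_commented <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_tsv_commented()]
#'
#' @param path Input path.
#' @return Data frame (comment lines starting with `#` are skipped).
#' @export
read_tsv_commented <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
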