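#' Tokenize a samtools-mpileup base string
#'
#' Splits the per-position pileup base column into tokens. Base-level
#' tokens are reference matches (`.` forward / `,` reverse strand),
#' substitution base calls (`ACGTN` / `acgtn`), deletion placeholders
#' (`*`, `#`), and reference skips (`>` / `<`). Indel motifs (`+nSEQ`,
#' `-nSEQ`) are attached as separate tokens immediately following the base
#' they modify; they do not add to depth. Read-start markers (`^` plus one
#' mapping-quality character) and read-end markers (`$`) contribute no
#' tokens.
#'
#' @param bases A single pileup base string.
#' @return Data frame with columns `type` (one of `ref_fwd`, `ref_rev`,
#'   `sub`, `ins`, `del`, `del_pad`, `ref_skip`) and `value` (the raw
#'   symbol, or the indel motif as written, case preserved), in the order
#'   encountered.
#' @export
parse_pileup_bases <- function(bases) {
  stopifnot(is.character(bases), length(bases) == 1L, !is.na(bases))
  if (bases == "" || bases == "*") {
    # mpileup prints "*" in the bases column at zero-depth positions
    return(data.frame(type = character(), value = character(),
                      stringsAsFactors = FALSE))
  }
  ch <- strsplit(bases, "", fixed = TRUE)[[1]]
  n <- length(ch)
  keep <- rep(TRUE, n)

  # read-start markers: '^' consumes exactly the next character (which may
  # itself be any symbol, including '^', '+', '$' or a digit)
  carets <- which(ch == "^")
  last_consumed <- 0L
  for (p in carets) {
    if (p <= last_consumed) next
    if (p == n) stop("truncated read-start marker '^' at position ", p)
    keep[p] <- FALSE
    keep[p + 1L] <- FALSE
    last_consumed <- p + 1L
  }

  # indels: [+-]<len><SEQ>; the sign/length/sequence are removed from the
  # base-level stream and recorded as a single motif token
  ind <- which((ch == "+" | ch == "-") & keep)
  itype <- character(length(ind))
  ival <- character(length(ind))
  for (j in seq_along(ind)) {
    p <- ind[j]
    if (!keep[p]) next  # consumed by an earlier (malformed) overlap
    q <- p + 1L
    while (q <= n && ch[q] >= "0" && ch[q] <= "9") q <- q + 1L
    if (q == p + 1L) {
      stop("pileup parse error at position ", p, ": '", ch[p],
           "' not followed by an indel length")
    }
    len <- as.integer(paste(ch[(p + 1L):(q - 1L)], collapse = ""))
    if (q + len - 1L > n) {
      stop("pileup parse error at position ", p, ": indel motif of length ",
           len, " runs past the end of the string")
    }
    seq <- paste(ch[q:(q + len - 1L)], collapse = "")
    if (!grepl("^[ACGTNacgtn*]+$", seq)) {
      stop("pileup parse error at position ", p,
           ": invalid indel motif '", seq, "'")
    }
    keep[p:(q + len - 1L)] <- FALSE
    itype[j] <- if (ch[p] == "+") "ins" else "del"
    ival[j] <- seq
  }
  used <- itype != ""

  # read-end markers
  keep[ch == "$" & keep] <- FALSE

  idx <- which(keep)
  sym <- ch[idx]
  type <- character(length(sym))
  type[sym == "."] <- "ref_fwd"
  type[sym == ","] <- "ref_rev"
  type[sym %in% c("A", "C", "G", "T", "N", "a", "c", "g", "t", "n")] <- "sub"
  type[sym == "*" | sym == "#"] <- "del_pad"
  type[sym == ">" | sym == "<"] <- "ref_skip"
  if (any(type == "")) {
    bad <- which(type == "")[1L]
    stop("pileup parse error at position ", idx[bad],
         ": unexpected character '", sym[bad], "'")
  }

  out <- data.frame(
    type = c(type, itype[used]),
    value = c(sym, ival[used]),
    ord = c(idx, ind[used]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$ord), c("type", "value")]
  rownames(out) <- NULL
  out
}

#' Count a target motif in one pileup record
#'
#' Counts reference and alternative-motif occurrences for one sample at one
#' targeted position. For an SNV the alternative count is the
#' case-insensitive count of the alt base among substitution calls; for an
#' insertion/deletion it is the count of `+nSEQ`/`-nSEQ` tokens whose motif
#' equals the inserted/deleted bases (case-insensitive; reverse-strand
#' motifs are lower case in mpileup). Depth is the number of base-level
#' symbols (reference matches, substitutions and `*` deletion
#' placeholders), excluding reference skips; indel motif tokens are
#' attachments and are not counted in depth. `*` placeholders count in
#' depth but never as alternative (a deletion event is counted once, at its
#' anchor).
#'
#' @param record One-row data frame (or list) with `chrom`, `pos`, `bases`.
#' @param target One-row data frame (or list) with `chrom`, `pos`, `ref`,
#'   `alt`, `variant_type`.
#' @return One-row data frame with `ref_count`, `alt_count`, `depth`, `af`
#'   (NA when depth is 0) and `af_undefined`.
#' @export
count_motif <- function(record, target) {
  if (record$pos != target$pos || record$chrom != target$chrom) {
    stop("pileup record (", record$chrom, ":", record$pos,
         ") does not match target (", target$chrom, ":", target$pos, ")")
  }
  tok <- parse_pileup_bases(record$bases)
  count_motif_tokens(tok, target)
}

#' @rdname count_motif
#' @param tokens Token data frame from [parse_pileup_bases()].
#' @export
count_motif_tokens <- function(tokens, target) {
  base_level <- tokens$type %in% c("ref_fwd", "ref_rev", "sub", "del_pad")
  depth <- sum(base_level)
  ref_count <- sum(tokens$type %in% c("ref_fwd", "ref_rev"))
  alt_count <- switch(target$variant_type,
    SNV = sum(tokens$type == "sub" &
                toupper(tokens$value) == toupper(target$alt)),
    INS = sum(tokens$type == "ins" &
                toupper(tokens$value) == indel_motif(target)),
    DEL = sum(tokens$type == "del" &
                toupper(tokens$value) == indel_motif(target)),
    stop("unknown variant_type '", target$variant_type, "'")
  )
  data.frame(
    ref_count = ref_count,
    alt_count = alt_count,
    depth = depth,
    af = if (depth > 0L) alt_count / depth else NA_real_,
    af_undefined = depth == 0L,
    stringsAsFactors = FALSE
  )
}

#' Read a single-sample mpileup file
#'
#' Reads the 6-column samtools-mpileup text format (chrom, pos, ref,
#' depth, bases, quals), one line per targeted position. Base qualities
#' are kept but not used downstream (counts are post-UMI-deduplication; no
#' quality filter is applied).
#'
#' @param path Path to an mpileup text file.
#' @return Data frame with columns `chrom`, `pos`, `ref_base`,
#'   `depth_field`, `bases`, `quals`.
#' @export
read_mpileup <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          colClasses = c("character", "integer", "character",
                                         "integer", "character", "character"),
                          stringsAsFactors = FALSE)
  if (ncol(df) != 6L) stop("mpileup file ", path, ": expected 6 columns")
  names(df) <- c("chrom", "pos", "ref_base", "depth_field", "bases", "quals")
  df
}

#' Build the global genotyping table
#'
#' For every targeted position, counts ref/alt/total in the two parental
#' samples of the target's family and in the control samples of the pool
#' (parents of families with a distinct variant in the same pool). This is
#' the table every downstream step (detection, power) consumes.
#'
#' @param pileups Named list: `pileups[[sample_id]]` is a data frame from
#'   [read_mpileup()].
#' @param targets Target table from [parse_target_table()].
#' @param manifest Manifest from [read_manifest()].
#' @param control_bounds Length-2 integer vector; a warning is raised when
#'   the number of control samples at a position falls outside it.
#' @return Data frame with one row per (sample, target) pair: `sample_id`,
#'   `family_id` (the *tested* family), `role` (father/mother/control
#'   relative to that family), `chrom`, `pos`, `ref`, `alt`,
#'   `variant_type`, `pool_id`, `ref_count`, `alt_count`, `depth`, `af`,
#'   `missing` (TRUE when the sample had no pileup line at the position).
#'   A target whose father or mother sample is absent from the manifest is
#'   flagged via `parent_missing`; detection for that family is disabled
#'   downstream.
#' @export
build_genotyping_table <- function(pileups, targets, manifest,
                                   control_bounds = c(40L, 48L)) {
  if (nrow(targets) == 0L) {
    return(empty_genotyping_table())
  }
  # per-sample lookup chrom:pos -> row index
  lookup <- lapply(pileups, function(df) {
    stats::setNames(seq_len(nrow(df)), paste(df$chrom, df$pos, sep = ":"))
  })
  rows <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    tg <- targets[i, ]
    pool <- manifest[manifest$pool_id == tg$pool_id, ]
    own <- pool$family_id == tg$family_id
    role <- ifelse(own, pool$role, "control")
    n_ctrl <- sum(!own)
    if (n_ctrl < control_bounds[1] || n_ctrl > control_bounds[2]) {
      warning("target ", tg$chrom, ":", tg$pos, " (family ", tg$family_id,
              ") has ", n_ctrl, " controls, outside [",
              control_bounds[1], ", ", control_bounds[2], "]")
    }
    parent_missing <- !all(c("father", "mother") %in% role)
    if (parent_missing) {
      warning("family ", tg$family_id,
              " is missing a parent sample; detection disabled")
    }
    key <- paste(tg$chrom, tg$pos, sep = ":")
    cnt <- lapply(seq_len(nrow(pool)), function(j) {
      sid <- pool$sample_id[j]
      ridx <- lookup[[sid]][key]
      if (is.null(lookup[[sid]]) || is.na(ridx)) {
        data.frame(ref_count = 0L, alt_count = 0L, depth = 0L,
                   af = NA_real_, af_undefined = TRUE)
      } else {
        count_motif(pileups[[sid]][ridx, ], tg)
      }
    })
    cnt <- do.call(rbind, cnt)
    rows[[i]] <- data.frame(
      sample_id = pool$sample_id,
      family_id = tg$family_id,
      role = role,
      chrom = tg$chrom,
      pos = tg$pos,
      ref = tg$ref,
      alt = tg$alt,
      variant_type = tg$variant_type,
      pool_id = tg$pool_id,
      ref_count = cnt$ref_count,
      alt_count = cnt$alt_count,
      depth = cnt$depth,
      af = cnt$af,
      missing = cnt$af_undefined,
      parent_missing = parent_missing,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_genotyping_table <- function() {
  data.frame(
    sample_id = character(), family_id = character(), role = character(),
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), variant_type = character(), pool_id = character(),
    ref_count = integer(), alt_count = integer(), depth = integer(),
    af = numeric(), missing = logical(), parent_missing = logical(),
    stringsAsFactors = FALSE
  )
}

#' Write / read the genotyping table
#'
#' @param table Genotyping table from [build_genotyping_table()] or
#'   [simulate_cohort()].
#' @param path Output path.
#' @export
write_genotyping_table <- function(table, path) {
  write_tsv_commented(table, path, comments = c(
    "genotyping table: one row per (sample, targeted position)",
    "role is relative to the tested family; af = alt_count / depth"
  ))
}

#' @rdname write_genotyping_table
#' @export
read_genotyping_table <- function(path) {
  df <- read_tsv_commented(path)
  needed <- c("sample_id", "family_id", "role", "chrom", "pos", "ref", "alt",
              "ref_count", "alt_count", "depth", "af")
  if (!all(needed %in% names(df))) {
    stop("genotyping table ", path, " is missing column(s): ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  }
  df
}
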