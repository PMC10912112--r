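test_that("pileup base strings tokenize with correct marker semantics", {
  tok <- parse_pileup_bases(".,.,GgN.")
  expect_equal(nrow(tok), 8L)
  expect_equal(sum(tok$type == "sub" & toupper(tok$value) == "G"), 2L)
  expect_equal(sum(tok$type %in% c("ref_fwd", "ref_rev")), 5L)

  # '^' consumes exactly one character (any character); '$' is a marker
  tok <- parse_pileup_bases("^!.,$")
  expect_equal(nrow(tok), 2L)
  expect_setequal(tok$type, c("ref_fwd", "ref_rev"))
  # mapping-quality char may itself be '^', '$', '+', or a digit
  for (s in c("^^.", "^$.", "^+.", "^5.")) {
    expect_equal(nrow(parse_pileup_bases(s)), 1L)
  }

  # indels attach to the preceding base as separate non-depth tokens
  tok <- parse_pileup_bases(",.+2AG.,")
  expect_equal(sum(tok$type != "ins"), 4L)
  expect_equal(tok$value[tok$type == "ins"], "AG")
  tok <- parse_pileup_bases(".-3TGA,,")
  expect_equal(tok$value[tok$type == "del"], "TGA")
  expect_equal(sum(tok$type != "del"), 3L)

  # multi-digit indel lengths
  tok <- parse_pileup_bases(paste0(".+12", strrep("A", 12), ","))
  expect_equal(tok$value[tok$type == "ins"], strrep("A", 12))

  # deletion placeholders and reference skips
  tok <- parse_pileup_bases(".*>,<#")
  expect_equal(sum(tok$type == "del_pad"), 2L)
  expect_equal(sum(tok$type == "ref_skip"), 2L)
})

test_that("malformed pileup strings raise parse errors naming the position", {
  expect_error(parse_pileup_bases(".+5AG"), "runs past the end")
  expect_error(parse_pileup_bases(".+AG."), "indel length")
  expect_error(parse_pileup_bases(".^"), "truncated")
  expect_error(parse_pileup_bases(".!,"), "unexpected character")
})

test_that("token counts reconcile with depth up to reference skips", {
  set.seed(31)
  syms <- c(".", ",", "A", "c", "*", ">", "<")
  for (rep in 1:20) {
    s <- paste(sample(syms, 50, replace = TRUE), collapse = "")
    tok <- parse_pileup_bases(s)
    n_skip <- sum(tok$type == "ref_skip")
    depth <- sum(tok$type %in% c("ref_fwd", "ref_rev", "sub", "del_pad"))
    expect_equal(depth + n_skip, nchar(s))
  }
})

test_that("motif counting matches targets case-insensitively", {
  snv <- list(chrom = "chr7", pos = 100L, ref = "A", alt = "G",
              variant_type = "SNV")
  rec <- list(chrom = "chr7", pos = 100L, bases = ".,.,GgN.")
  cnt <- count_motif(rec, snv)
  expect_equal(cnt$alt_count, 2L)
  expect_equal(cnt$depth, 8L)
  expect_equal(cnt$af, 0.25)

  ins <- list(chrom = "chr7", pos = 100L, ref = "A", alt = "AAG",
              variant_type = "INS")
  cnt <- count_motif(list(chrom = "chr7", pos = 100L, bases = ",.+2AG.,"), ins)
  expect_equal(cnt$alt_count, 1L)
  expect_equal(cnt$depth, 4L)
  expect_equal(cnt$af, 0.25)

  del <- list(chrom = "chr7", pos = 100L, ref = "ATGA", alt = "A",
              variant_type = "DEL")
  cnt <- count_motif(list(chrom = "chr7", pos = 100L, bases = ".-3TGA,,"), del)
  expect_equal(cnt$alt_count, 1L)
  expect_equal(cnt$depth, 3L)

  # lower-case (reverse-strand) motif counts too; wrong motif does not
  cnt <- count_motif(list(chrom = "chr7", pos = 100L, bases = ",-3tga.."), del)
  expect_equal(cnt$alt_count, 1L)
  cnt <- count_motif(list(chrom = "chr7", pos = 100L, bases = ".-2TG,,"), del)
  expect_equal(cnt$alt_count, 0L)

  # a single alternative read in one sample is still a count of one
  cnt <- count_motif(list(chrom = "chr7", pos = 100L,
                          bases = paste0(strrep(".", 5000), "-3TGA")), del)
  expect_equal(cnt$alt_count, 1L)
  expect_equal(cnt$depth, 5000L)

  # '*' placeholders count in depth but never as alternative
  cnt <- count_motif(list(chrom = "chr7", pos = 100L, bases = "*.*,"), del)
  expect_equal(cnt$alt_count, 0L)
  expect_equal(cnt$depth, 4L)

  # zero depth is flagged, not an error
  cnt <- count_motif(list(chrom = "chr7", pos = 100L, bases = "*"), snv)
  expect_equal(cnt$depth, 0L)
  expect_true(cnt$af_undefined)
  expect_true(is.na(cnt$af))
})

test_that("alt counts are invariant under swapping strand case", {
  set.seed(77)
  snv <- list(chrom = "c", pos = 1L, ref = "A", alt = "G",
              variant_type = "SNV")
  for (i in 1:10) {
    s <- paste(sample(c(".", ",", "G", "g", "t", "C"), 40, TRUE),
               collapse = "")
    swapped <- chartr("ACGTNacgtn", "acgtnACGTN", s)
    a1 <- count_motif(list(chrom = "c", pos = 1L, bases = s), snv)$alt_count
    a2 <- count_motif(list(chrom = "c", pos = 1L, bases = swapped),
                      snv)$alt_count
    expect_equal(a1, a2)
  }
})

test_that("target tables are validated row by row", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family_id\tchrom\tpos\tref\talt\tvariant_type\tpool_id",
               "FAM1\tchr7\t100\tA\tG\tSNV\tpool1",
               "FAM2\tchr2\t55\tA\tAAG\tINS\tpool1",
               "FAM3\tchr3\t9\tATG\tA\tDEL\tpool1"), path)
  tg <- parse_target_table(path)
  expect_equal(nrow(tg), 3L)
  expect_equal(tg$variant_type, c("SNV", "INS", "DEL"))
  expect_equal(tg$pos, c(100L, 55L, 9L))

  # declared type must match the allele pair
  writeLines(c("family_id\tchrom\tpos\tref\talt\tvariant_type\tpool_id",
               "FAM1\tchr7\t100\tA\tAAG\tSNV\tpool1"), path)
  expect_error(parse_target_table(path), "line 2")

  writeLines(c("family_id\tchrom\tpos\tref\talt\tvariant_type\tpool_id",
               "FAM1\tchr7\t100\tA\tG\tMNV\tpool1"), path)
  expect_error(parse_target_table(path), "variant_type")

  # multi-nucleotide substitutions are rejected
  writeLines(c("family_id\tchrom\tpos\tref\talt\tvariant_type\tpool_id",
               "FAM1\tchr7\t100\tAT\tGC\tSNV\tpool1"), path)
  expect_error(parse_target_table(path), "multi-nucleotide")

  # header-only file: empty table with a warning
  writeLines("family_id\tchrom\tpos\tref\talt\tvariant_type\tpool_id", path)
  expect_warning(tg <- parse_target_table(path), "no variant rows")
  expect_equal(nrow(tg), 0L)
})

test_that("genotyping a cohort produces one row per sample and target", {
  dir <- withr::local_tempdir()
  targets <- data.frame(
    family_id = c("F1", "F2"), chrom = c("chr1", "chr2"),
    pos = c(10L, 20L), ref = c("A", "C"), alt = c("G", "CTT"),
    variant_type = c("SNV", "INS"), pool_id = "p1",
    stringsAsFactors = FALSE)
  manifest <- data.frame(
    sample_id = c("F1_F", "F1_M", "F2_F", "F2_M"),
    family_id = c("F1", "F1", "F2", "F2"),
    role = c("father", "mother", "father", "mother"),
    pool_id = "p1", stringsAsFactors = FALSE)
  mk <- function(b10, b20) {
    data.frame(chrom = c("chr1", "chr2"), pos = c(10L, 20L),
               ref_base = c("A", "C"), depth_field = c(4L, 4L),
               bases = c(b10, b20), quals = "IIII",
               stringsAsFactors = FALSE)
  }
  pileups <- list(
    F1_F = mk(".,G.", ".,.,"), F1_M = mk("....", ",,,,"),
    F2_F = mk(",,..", ".+2TT,.."), F2_M = mk("..", "..,,"))
  tab <- suppressWarnings(
    build_genotyping_table(pileups, targets, manifest,
                           control_bounds = c(1L, 48L)))
  expect_equal(nrow(tab), 8L)  # 2 targets x 4 pool samples
  f1f <- tab[tab$family_id == "F1" & tab$sample_id == "F1_F", ]
  expect_equal(f1f$role, "father")
  expect_equal(f1f$alt_count, 1L)
  f2f <- tab[tab$family_id == "F2" & tab$sample_id == "F2_F", ]
  expect_equal(f2f$alt_count, 1L)
  # F1 samples are controls for F2 and vice versa
  expect_equal(sum(tab$role == "control"), 4L)

  # absent position yields a flagged zero-depth row, not an error
  pileups$F2_M <- pileups$F2_M[1, , drop = FALSE]  # drop chr2:20 line
  tab <- suppressWarnings(
    build_genotyping_table(pileups, targets, manifest,
                           control_bounds = c(1L, 48L)))
  row <- tab[tab$sample_id == "F2_M" & tab$pos == 20L, ]
  expect_true(row$missing)
  expect_equal(row$depth, 0L)

  # empty target list gives an empty table
  expect_equal(nrow(build_genotyping_table(pileups, targets[0, ], manifest)),
               0L)

  # missing parent disables the family (flagged, with a warning)
  manifest2 <- manifest[manifest$sample_id != "F1_M", ]
  expect_warning(
    tab <- build_genotyping_table(pileups[-2], targets, manifest2,
                                  control_bounds = c(1L, 48L)),
    "missing a parent")
  expect_true(all(tab$parent_missing[tab$family_id == "F1"]))
})
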