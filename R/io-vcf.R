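# Phased-VCF reader/writer (WhatsHap / MAtCHap style output).
#
# Reading goes through vcfR; only biallelic heterozygous records with a
# `|`-separated genotype become sites. Records sharing a PS (phase set)
# value form one block; phased records without a PS tag form blocks by
# contiguity (consecutive phased records until an unphased record or a
# chromosome change). The writer emits minimal plain-text VCF that
# round-trips through the reader.

#' Read a phased VCF into a phasing result
#'
#' Only biallelic heterozygous `|`-separated genotypes become sites
#' (`0|1` gives `h1 = 0`, `1|0` gives `h1 = 1`); `/`-separated genotypes
#' are skipped silently, and homozygous or multi-allelic records are
#' skipped and counted (the count is attached as attribute `n_skipped` and
#' reported in one warning). Records sharing a `PS` FORMAT value form one
#' block; phased records lacking `PS` are grouped by contiguity, so
#' emitters that omit the tag for a single global block still parse.
#'
#' @param path Path to a plain or gzip/bgzip-compressed VCF.
#' @param tool_name Tool label; defaults to the file name.
#' @param sample Sample column to use (default: the first).
#' @return A raw (un-normalized) `phasing` object with attribute
#'   `n_skipped` counting skipped homozygous/multi-allelic records.
#' @export
read_phased_vcf <- function(path, tool_name = NULL, sample = 1L) {
  tool_name <- tool_name %||% sub("\\.vcf(\\.gz)?$", "", basename(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)

  empty <- phasing(
    tibble(block_id = character(), position = integer(), h1 = integer()),
    tool_name = tool_name
  )
  if (nrow(v@fix) == 0L) {
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  if (ncol(v@gt) < 2L) {
    hc_abort("VCF has no genotype (sample) column", "format_error")
  }

  chrom <- vcfR::getCHROM(v)
  if (length(unique(chrom)) > 1L) {
    hc_abort(
      paste0("VCF mixes chromosomes: ", paste(unique(chrom), collapse = ", ")),
      "chromosome_error"
    )
  }
  pos <- vcfR::getPOS(v)
  alt <- vcfR::getALT(v)
  gt <- vcfR::extract.gt(v, element = "GT")[, sample]
  ps <- tryCatch(
    vcfR::extract.gt(v, element = "PS")[, sample],
    error = function(e) rep(NA_character_, length(gt))
  )

  multi <- !is.na(alt) & grepl(",", alt)
  phased_gt <- !is.na(gt) & grepl("\\|", gt)
  a1 <- suppressWarnings(as.integer(sub("\\|.*", "", gt)))
  a2 <- suppressWarnings(as.integer(sub(".*\\|", "", gt)))
  het <- phased_gt & !is.na(a1) & !is.na(a2) & (a1 + a2 == 1L) &
    a1 %in% 0:1 & a2 %in% 0:1

  n_skipped <- sum(multi | (phased_gt & !het))
  keep <- het & !multi
  if (n_skipped > 0L) {
    warn(paste0(
      "skipped ", n_skipped,
      " non-biallelic-heterozygous record(s) while reading ", basename(path)
    ))
  }
  if (!any(keep)) {
    attr(empty, "n_skipped") <- as.integer(n_skipped)
    return(empty)
  }

  # Block labels: PS where present, else contiguity runs of phased records
  # (any unphased, skipped or PS-tagged record in between breaks the run).
  block <- ps
  no_ps <- keep & is.na(ps)
  if (any(no_ps)) {
    block[no_ps] <- paste0("noPS_", cumsum(!no_ps)[no_ps])
  }

  res <- phasing(
    tibble(
      block_id = block[keep],
      position = pos[keep],
      h1 = a1[keep],
      h2 = a2[keep],
      chromosome = chrom[keep]
    ),
    tool_name = tool_name
  )
  attr(res, "n_skipped") <- as.integer(n_skipped)
  res
}

#' Write a phasing result as a minimal phased VCF
#'
#' Emits a small valid VCF in which block membership is encoded in the `PS`
#' FORMAT tag (numeric block IDs are kept as-is; other labels are replaced
#' by the block's first position, the usual PS convention). Unphased sites
#' are written as `./.`. `read_phased_vcf()` on the written file reproduces
#' positions, alleles and block membership of the phased sites.
#'
#' @param x A `phasing` object.
#' @param path Output path (gzip-compressed when it ends in `.gz`).
#' @param sample_name Sample column header.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(x, path, sample_name = NULL) {
  assert_phasing(x)
  sample_name <- sample_name %||% phasing_tool(x)
  chrom <- phasing_chromosome(x)
  if (is.na(chrom)) chrom <- "chrUn"

  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=hapcompare"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  sites <- as_tibble(x)
  if (nrow(sites) == 0L) {
    readr::write_lines(header, path)
    return(invisible(path))
  }

  first_pos <- tapply(sites$position, sites$block_id, min)
  ps_num <- suppressWarnings(as.integer(sites$block_id))
  sites$ps <- ifelse(is.na(ps_num), as.integer(first_pos[sites$block_id]), ps_num)

  sites <- sites[order(sites$position), , drop = FALSE]
  gt <- ifelse(
    is.na(sites$h1), "./.",
    paste0(sites$h1, "|", sites$h2)
  )
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:PS\t%s:%d",
    chrom, sites$position, "A", "T", gt, sites$ps
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read a known-haplotype ("gold standard") position set from a phased VCF
#'
#' Loads every genotyped position (including homozygous-reference `0|0`
#' records, which dominate high-confidence call sets) with its genotype
#' class, for use as the reference set in [position_overlap()].
#'
#' @param path Path to a phased VCF.
#' @param het_only Keep only heterozygous (`0|1` / `1|0`) positions.
#' @param sample Sample column to use (default: the first).
#' @return Tibble with columns `position` (sorted, unique) and `genotype`.
#' @export
read_known_haplotypes <- function(path, het_only = FALSE, sample = 1L) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) {
    hc_abort("known-haplotype VCF contains no records", "empty_input_error")
  }
  pos <- vcfR::getPOS(v)
  gt <- vcfR::extract.gt(v, element = "GT")[, sample]
  out <- tibble(position = as.integer(pos), genotype = unname(gt))
  out <- out[!is.na(out$genotype), , drop = FALSE]
  if (het_only) {
    out <- out[out$genotype %in% c("0|1", "1|0"), , drop = FALSE]
  }
  out <- out[!duplicated(out$position), , drop = FALSE]
  out[order(out$position), , drop = FALSE]
}
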