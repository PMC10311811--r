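# Reader/writer for the HapCUT2-style block text format and its dialects.
#
# Grammar (shared by HapCUT2, MixSIH, PEATH, SDhaP, MAtCHap):
#   BLOCK: offset: <id> len: <n> phased: <n> ...   <- block header
#   <index> <h1> <h2> <chrom> <position> <...>     <- one line per site
#   ********                                       <- block terminator
# h1/h2 are 0, 1 or "-" (unphased). Trailing fields (ref/alt alleles,
# genotype, scores) are preserved as opaque annotation and never
# interpreted. SDhaP positions are 0-based and are shifted to 1-based on
# read (and back on write).

DIALECTS <- list(
  hapcut2 = list(name = "hapcut2", coordinate_basis = "1-based", sort_order = "by_block_id"),
  mixsih  = list(name = "mixsih",  coordinate_basis = "1-based", sort_order = "by_block_id"),
  peath   = list(name = "peath",   coordinate_basis = "1-based", sort_order = "clean"),
  sdhap   = list(name = "sdhap",   coordinate_basis = "0-based", sort_order = "by_block_id"),
  matchap = list(name = "matchap", coordinate_basis = "1-based", sort_order = "clean")
)

#' Block-file dialects
#'
#' The five supported block-format emitters share one grammar but differ in
#' coordinate basis and the order they write lines in: SDhaP uses 0-based
#' positions (all others 1-based); HapCUT2, MixSIH and SDhaP sort output by
#' block ID (so positions can be locally out of order), while PEATH and
#' MAtCHap emit cleanly ordered files. The reader accepts any line order;
#' the dialect's `sort_order` controls how [write_block_file()] lays the
#' file out.
#'
#' @param name One of `"hapcut2"`, `"mixsih"`, `"peath"`, `"sdhap"`,
#'   `"matchap"`, or an existing dialect list (returned unchanged).
#' @return A list with fields `name`, `coordinate_basis`, `sort_order`.
#' @export
#' @examples
#' block_dialect("sdhap")$coordinate_basis
block_dialect <- function(name) {
  if (is.list(name) && all(c("name", "coordinate_basis", "sort_order") %in% names(name))) {
    return(name)
  }
  stopifnot_scalar_chr(name, "name")
  if (!name %in% names(DIALECTS)) {
    hc_abort(
      paste0("unknown block dialect '", name, "'; expected one of ",
             paste(names(DIALECTS), collapse = ", ")),
      "usage_error"
    )
  }
  DIALECTS[[name]]
}

#' Read a HapCUT2-style block file
#'
#' Parses block text output from HapCUT2, MixSIH, PEATH, SDhaP or MAtCHap
#' into a [phasing()] result. Blocks are delimited by `BLOCK:` header lines
#' and asterisk terminator lines; each site line carries the VCF variant
#' index, the two haplotype alleles (0/1/`-`), the chromosome and the
#' position, with any trailing columns kept as opaque annotation. SDhaP's
#' 0-based positions are shifted to 1-based automatically. The returned
#' result is *not* normalized; pass it through [normalize_phasing()] before
#' comparing.
#'
#' @param path Path to a plain or gzip-compressed block file.
#' @param dialect Dialect name or object, see [block_dialect()].
#' @param tool_name Tool label; defaults to the file name without extension.
#' @return A raw (un-normalized) `phasing` object.
#' @export
read_block_file <- function(path, dialect = "hapcut2", tool_name = NULL) {
  dialect <- block_dialect(dialect)
  tool_name <- tool_name %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readr::read_lines(path)

  is_hdr <- grepl("^BLOCK:", lines)
  is_term <- grepl("^\\*+\\s*$", lines)
  is_blank <- !nzchar(trimws(lines))
  is_site <- !is_hdr & !is_term & !is_blank

  if (!any(is_site)) {
    return(phasing(
      tibble(block_id = character(), position = integer(), h1 = integer()),
      tool_name = tool_name,
      coordinate_basis = dialect$coordinate_basis
    ))
  }

  block_no <- cumsum(is_hdr)
  if (any(is_site & block_no == 0L)) {
    hc_abort(
      paste0("site line before any BLOCK: header at line ",
             which(is_site & block_no == 0L)[1]),
      "parse_error"
    )
  }
  hdr_ids <- vapply(lines[is_hdr], function(h) {
    m <- regmatches(h, regexec("offset:\\s*(\\S+)", h))[[1]]
    if (length(m) == 2L) m[2] else NA_character_
  }, character(1), USE.NAMES = FALSE)
  hdr_ids <- ifelse(is.na(hdr_ids), as.character(seq_along(hdr_ids)), hdr_ids)

  site_lines <- lines[is_site]
  site_no <- which(is_site)
  fields <- strsplit(trimws(site_lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 5L)) {
    hc_abort(
      paste0("malformed site line (need >= 5 fields) at line ",
             site_no[which(nf < 5L)[1]]),
      "parse_error"
    )
  }
  h1c <- vapply(fields, `[[`, character(1), 2L)
  h2c <- vapply(fields, `[[`, character(1), 3L)
  bad <- !(h1c %in% c("0", "1", "-")) | !(h2c %in% c("0", "1", "-"))
  if (any(bad)) {
    hc_abort(
      paste0("allele code outside {0,1,-} at line ", site_no[which(bad)[1]]),
      "parse_error"
    )
  }
  hom <- h1c != "-" & h1c == h2c
  if (any(hom)) {
    hc_abort(
      paste0("h1 == h2 on a phased line (biallelic violation) at line ",
             site_no[which(hom)[1]]),
      "biallelic_error"
    )
  }
  chrom <- vapply(fields, `[[`, character(1), 4L)
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 5L)))
  if (any(is.na(pos))) {
    hc_abort(
      paste0("non-numeric position at line ", site_no[which(is.na(pos))[1]]),
      "parse_error"
    )
  }
  annot <- vapply(fields, function(f) {
    if (length(f) > 5L) paste(f[-(1:5)], collapse = " ") else NA_character_
  }, character(1))

  sites <- tibble(
    block_id = hdr_ids[block_no[is_site]],
    position = pos,
    h1 = suppressWarnings(as.integer(h1c)),   # "-" becomes NA (unphased)
    h2 = suppressWarnings(as.integer(h2c)),
    chromosome = chrom,
    annotation = annot
  )
  res <- phasing(sites,
    tool_name = tool_name,
    coordinate_basis = dialect$coordinate_basis
  )
  if (dialect$coordinate_basis == "0-based") {
    res <- shift_coordinates(res, 1L)
  }
  res
}

#' Write a phasing result as a block file
#'
#' Emits the `BLOCK:`/site-line/asterisk layout of [read_block_file()].
#' Re-reading the written file reproduces the positions, alleles and block
#' membership of the input. With the `sdhap` dialect positions are written
#' 0-based; with a `by_block_id` dialect blocks are ordered by block label,
#' otherwise by first position.
#'
#' @param x A `phasing` object.
#' @param path Output path (gzip-compressed when it ends in `.gz`).
#' @param dialect Dialect name or object, see [block_dialect()].
#' @return `path`, invisibly.
#' @export
write_block_file <- function(x, path, dialect = "hapcut2") {
  assert_phasing(x)
  dialect <- block_dialect(dialect)

  sites <- as_tibble(x)
  if (nrow(sites) == 0L) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  if (dialect$coordinate_basis == "0-based") {
    sites$position <- sites$position - 1L
  }
  sites$index <- match(sites$position, sort(unique(sites$position)))
  chrom <- phasing_chromosome(x)
  if (is.na(chrom)) chrom <- "."

  ids <- unique(sites$block_id)
  if (dialect$sort_order == "by_block_id") {
    num <- suppressWarnings(as.numeric(ids))
    ids <- if (anyNA(num)) sort(ids) else ids[order(num)]
  } else {
    first_pos <- tapply(sites$position, sites$block_id, min)
    ids <- names(sort(first_pos))
  }

  out <- character()
  for (id in ids) {
    b <- sites[sites$block_id == id, , drop = FALSE]
    b <- b[order(b$position), , drop = FALSE]
    hdr <- sprintf(
      "BLOCK: offset: %s len: %d phased: %d",
      id, nrow(b), sum(!is.na(b$h1))
    )
    body <- sprintf(
      "%d\t%s\t%s\t%s\t%d%s",
      b$index,
      ifelse(is.na(b$h1), "-", as.character(b$h1)),
      ifelse(is.na(b$h2), "-", as.character(b$h2)),
      chrom,
      b$position,
      ifelse(is.na(b$annotation), "", paste0("\t", b$annotation))
    )
    out <- c(out, hdr, body, "********")
  }
  readr::write_lines(out, path)
  invisible(path)
}
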