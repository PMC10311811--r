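# Canonical in-memory representation of one tool's phased output:
# a tibble with one row per heterozygous site, carrying the tool name,
# chromosome, coordinate basis and normalization state as attributes.

PHASING_ATTRS <- c("tool_name", "chromosome", "coordinate_basis", "normalized")

new_phasing <- function(x, tool_name, chromosome, coordinate_basis, normalized) {
  new_tibble(
    x,
    nrow = nrow(x),
    tool_name = tool_name,
    chromosome = chromosome,
    coordinate_basis = coordinate_basis,
    normalized = normalized,
    class = "phasing"
  )
}

# Rebuild a phasing object from a plain tibble, copying attributes from a
# template (dplyr verbs strip custom attributes).
rebuild_phasing <- function(x, template, normalized = NULL) {
  new_phasing(
    as_tibble(x),
    tool_name = attr(template, "tool_name"),
    chromosome = attr(template, "chromosome"),
    coordinate_basis = attr(template, "coordinate_basis"),
    normalized = normalized %||% attr(template, "normalized")
  )
}

#' Construct a phasing result
#'
#' A phasing result holds one haplotype-assembly tool's output for one
#' chromosome: ordered phase blocks of biallelic heterozygous sites. Each
#' site carries the allele of the first haplotype (`h1`) and of the second
#' (`h2`), coded 0 (reference) / 1 (alternative); an unphased site (the
#' `"-"` entry of block-format files) has `NA` in both columns. Within a
#' block `h2` is always the complement of `h1` — homozygous or
#' multi-allelic genotypes are rejected at this boundary, matching the
#' convention of analysing only heterozygous SNVs.
#'
#' @param sites Data frame with columns `block_id`, `position` (1-based bp
#'   unless `coordinate_basis = "0-based"`), `h1`, `h2` (0/1/`NA`), and
#'   optionally `annotation` (opaque trailing text preserved for
#'   round-tripping). `h2` may be omitted and is then derived as `1 - h1`.
#' @param tool_name Name of the tool that produced the result.
#' @param chromosome Chromosome label; taken from a `chromosome` column if
#'   present (which must then be constant — results never mix chromosomes).
#' @param coordinate_basis `"1-based"` (default) or `"0-based"` (SDhaP-style).
#' @param normalized Whether the result is already in canonical form; set
#'   by [normalize_phasing()], rarely by hand.
#' @return A `phasing` tibble with one row per site.
#' @seealso [normalize_phasing()], [phasing_summary()], [compare_phasings()]
#' @export
#' @examples
#' phasing(
#'   tibble::tibble(
#'     block_id = c("b1", "b1", "b2", "b2"),
#'     position = c(101L, 105L, 210L, 230L),
#'     h1 = c(0L, 1L, 0L, 0L)
#'   ),
#'   tool_name = "toy", chromosome = "chr10"
#' )
phasing <- function(sites,
                    tool_name = "unknown",
                    chromosome = NULL,
                    coordinate_basis = c("1-based", "0-based"),
                    normalized = FALSE) {
  coordinate_basis <- match.arg(coordinate_basis)
  stopifnot_scalar_chr(tool_name, "tool_name")
  sites <- as_tibble(sites)

  if (!all(c("block_id", "position", "h1") %in% names(sites))) {
    hc_abort("`sites` needs columns block_id, position, h1", "usage_error")
  }
  if (!"h2" %in% names(sites)) {
    sites$h2 <- 1L - as.integer(sites$h1)
  }
  if (!"annotation" %in% names(sites)) {
    sites$annotation <- NA_character_
  }

  if ("chromosome" %in% names(sites)) {
    chroms <- unique(sites$chromosome)
    chroms <- chroms[!is.na(chroms)]
    if (length(chroms) > 1L) {
      hc_abort(
        paste0(
          "a phasing result covers one chromosome; found: ",
          paste(chroms, collapse = ", ")
        ),
        "chromosome_error"
      )
    }
    if (is.null(chromosome) && length(chroms) == 1L) chromosome <- chroms
    sites$chromosome <- NULL
  }
  if (!is.null(chromosome)) stopifnot_scalar_chr(chromosome, "chromosome")
  chromosome <- chromosome %||% NA_character_

  sites <- tibble(
    block_id = as.character(sites$block_id),
    position = as.integer(sites$position),
    h1 = as.integer(sites$h1),
    h2 = as.integer(sites$h2),
    annotation = as.character(sites$annotation)
  )

  validate_phasing_sites(sites, coordinate_basis)
  new_phasing(sites, tool_name, chromosome, coordinate_basis, normalized)
}

validate_phasing_sites <- function(sites, coordinate_basis) {
  if (nrow(sites) == 0L) return(invisible(sites))

  bad_allele <- !(sites$h1 %in% c(0L, 1L) | is.na(sites$h1)) |
    !(sites$h2 %in% c(0L, 1L) | is.na(sites$h2))
  if (any(bad_allele)) {
    hc_abort(
      paste0(
        "allele codes must be 0, 1 or NA (unphased); offending position(s): ",
        paste(head(sites$position[bad_allele], 3L), collapse = ", ")
      ),
      "allele_error"
    )
  }
  half <- xor(is.na(sites$h1), is.na(sites$h2))
  if (any(half)) {
    hc_abort(
      paste0(
        "a site is unphased on both haplotypes or neither; position(s): ",
        paste(head(sites$position[half], 3L), collapse = ", ")
      ),
      "allele_error"
    )
  }
  phased <- !is.na(sites$h1)
  hom <- phased & sites$h1 == sites$h2
  if (any(hom)) {
    hc_abort(
      paste0(
        "homozygous genotype at a phased site (h1 == h2) violates the ",
        "biallelic heterozygous model; position(s): ",
        paste(head(sites$position[hom], 3L), collapse = ", ")
      ),
      "biallelic_error"
    )
  }
  min_pos <- if (coordinate_basis == "1-based") 1L else 0L
  if (any(sites$position < min_pos, na.rm = TRUE)) {
    hc_abort(
      paste0("positions below ", min_pos, " are invalid for ", coordinate_basis,
             " coordinates"),
      "coordinate_error"
    )
  }
  dup <- duplicated(sites[c("block_id", "position")])
  if (any(dup)) {
    hc_abort(
      paste0(
        "duplicate position within a block: ",
        paste(head(sites$position[dup], 3L), collapse = ", ")
      ),
      "structure_error"
    )
  }
  invisible(sites)
}

#' @export
print.phasing <- function(x, ...) {
  n_blk <- length(unique(x$block_id))
  cat(sprintf(
    "<phasing: %s | %s | %d sites in %d blocks | %s%s>\n",
    attr(x, "tool_name"),
    attr(x, "chromosome") %||% NA_character_,
    nrow(x), n_blk,
    attr(x, "coordinate_basis"),
    if (isTRUE(attr(x, "normalized"))) " | normalized" else ""
  ))
  NextMethod()
}

#' Attribute accessors for phasing results
#'
#' @param x A `phasing` object.
#' @return A scalar string (`phasing_tool()`, `phasing_chromosome()`,
#'   `coordinate_basis()`) or logical (`is_normalized()`).
#' @export
phasing_tool <- function(x) attr(x, "tool_name")

#' @rdname phasing_tool
#' @export
phasing_chromosome <- function(x) attr(x, "chromosome")

#' @rdname phasing_tool
#' @export
coordinate_basis <- function(x) attr(x, "coordinate_basis")

#' @rdname phasing_tool
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

phased_rows <- function(x) !is.na(x$h1)

assert_phasing <- function(x, what = "x") {
  if (!inherits(x, "phasing")) {
    hc_abort(paste0("`", what, "` must be a phasing object"), "usage_error")
  }
  invisible(x)
}

assert_normalized <- function(x, what = "x") {
  assert_phasing(x, what)
  if (!is_normalized(x)) {
    hc_abort(
      paste0("`", what, "` must be normalized first; see normalize_phasing()"),
      "usage_error"
    )
  }
  invisible(x)
}

#' Normalize a phasing result to canonical form
#'
#' Brings a parsed result into the canonical form every comparison assumes:
#' unphased (`"-"`) sites removed (by default), blocks left with fewer than
#' two sites dropped (a single-SNV block asserts no phase and carries no
#' information — after this step the minimum block size is always 2), sites
#' sorted by position within blocks, blocks sorted by their first position,
#' and coordinates on the 1-based basis. Normalization is idempotent, and
#' because the canonical order is imposed here, every downstream comparison
#' is invariant to how the input file happened to be sorted.
#'
#' @param x A `phasing` object.
#' @param drop_unphased Drop `"-"` sites (default). Set `FALSE` only to keep
#'   them for raw-file round-tripping; summaries and comparisons require the
#'   default.
#' @return A normalized `phasing` object; the input is unchanged.
#' @export
normalize_phasing <- function(x, drop_unphased = TRUE) {
  assert_phasing(x)

  dup <- duplicated(x$position)
  if (any(dup)) {
    hc_abort(
      paste0(
        "position appears in more than one block: ",
        paste(head(sort(unique(x$position[dup])), 3L), collapse = ", ")
      ),
      "structure_error"
    )
  }

  out <- as_tibble(x)
  if (drop_unphased) out <- out[!is.na(out$h1), , drop = FALSE]

  if (nrow(out) > 0L) {
    keep <- names(which(table(out$block_id) >= 2L))
    out <- out[out$block_id %in% keep, , drop = FALSE]
  }
  if (nrow(out) > 0L) {
    first_pos <- tapply(out$position, out$block_id, min)
    out <- out[order(first_pos[out$block_id], out$position), , drop = FALSE]
  }

  res <- rebuild_phasing(out, x, normalized = TRUE)
  if (attr(x, "coordinate_basis") == "0-based") {
    res <- shift_coordinates(res, 1L)
  }
  attr(res, "normalized") <- TRUE
  res
}

#' Shift all positions of a phasing result
#'
#' SDhaP reports 0-based SNV positions while every other supported tool is
#' 1-based; its output must be shifted by +1 before any cross-tool
#' comparison. The coordinate basis flag is updated when the shift converts
#' between the two bases.
#'
#' @param x A `phasing` object.
#' @param offset Integer added to every position (normally `+1`).
#' @return A `phasing` object with shifted positions.
#' @export
#' @examples
#' p <- phasing(
#'   tibble::tibble(block_id = "b", position = c(0L, 4L), h1 = c(0L, 1L)),
#'   coordinate_basis = "0-based"
#' )
#' shift_coordinates(p, 1L)$position
shift_coordinates <- function(x, offset) {
  assert_phasing(x)
  offset <- as.integer(offset)
  if (length(offset) != 1L || is.na(offset)) {
    hc_abort("`offset` must be a single integer", "usage_error")
  }
  basis <- attr(x, "coordinate_basis")
  new_basis <- basis
  if (basis == "0-based" && offset == 1L) new_basis <- "1-based"
  if (basis == "1-based" && offset == -1L) new_basis <- "0-based"

  out <- as_tibble(x)
  out$position <- out$position + offset
  min_pos <- if (new_basis == "1-based") 1L else 0L
  if (any(out$position < min_pos)) {
    hc_abort(
      paste0("shift by ", offset, " produces positions below ", min_pos),
      "coordinate_error"
    )
  }
  res <- rebuild_phasing(out, x)
  attr(res, "coordinate_basis") <- new_basis
  res
}

# Phased-site count per block, in canonical block order.
block_sizes <- function(x) {
  p <- x[phased_rows(x), , drop = FALSE]
  if (nrow(p) == 0L) {
    return(tibble(block_id = character(), n_sites = integer()))
  }
  first_pos <- tapply(p$position, p$block_id, min)
  sz <- table(p$block_id)
  ids <- names(sort(first_pos))
  tibble(block_id = ids, n_sites = as.integer(sz[ids]))
}

#' Summarize block and SNV counts of a phasing result
#'
#' The per-result summary used to profile each tool's output: total number
#' of phased SNVs, total number of blocks, and the five-number-plus-mean
#' summary of phased SNVs per block. Quartiles use linear interpolation
#' between order statistics (`stats::quantile()` type 7); the mean is
#' `total_snvs / total_blocks` and is rendered to two decimals half-up in
#' formatted output. After normalization the minimum is always at least 2.
#'
#' @param x A normalized `phasing` object.
#' @return One-row tibble with columns `tool_name`, `chromosome`,
#'   `total_snvs`, `total_blocks`, `min`, `q1`, `median`, `mean`, `q3`,
#'   `max`.
#' @export
phasing_summary <- function(x) {
  assert_normalized(x)
  if (nrow(x) == 0L) {
    hc_abort("cannot summarize an empty phasing result", "empty_input_error")
  }
  if (any(!phased_rows(x))) {
    hc_abort(
      "summary requires unphased sites to be dropped (normalize with drop_unphased = TRUE)",
      "usage_error"
    )
  }
  sz <- block_sizes(x)$n_sites
  q <- unname(quantile(sz, c(0.25, 0.5, 0.75), type = 7))
  tibble(
    tool_name = phasing_tool(x),
    chromosome = phasing_chromosome(x),
    total_snvs = sum(sz),
    total_blocks = length(sz),
    min = min(sz),
    q1 = q[1],
    median = q[2],
    mean = sum(sz) / length(sz),
    q3 = q[3],
    max = max(sz)
  )
}

#' @export
tidy.phasing <- function(x, ...) {
  out <- as_tibble(x)
  out$phased <- !is.na(out$h1)
  out
}

#' @export
glance.phasing <- function(x, ...) phasing_summary(x)
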