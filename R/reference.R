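# Gold-standard position overlap, position-restriction filtering, and
# fragment-level depth filtering.

#' Overlap of inferred SNV positions with a known position set
#'
#' Counts how many of a result's phased positions appear in an externally
#' derived ("gold standard") position set. By default the known set is
#' taken as given — including homozygous-reference positions, which
#' dominate high-confidence call sets — because the published overlap
#' denominators are built that way; pass a het-only set (see
#' [read_known_haplotypes()]) to restrict. Haplotype-level accuracy against
#' the known set is deliberately not computed: at the position-overlap
#' levels seen in practice it would not be meaningful.
#'
#' @param result A normalized `phasing` object.
#' @param known Known positions: integer vector, or a data frame with a
#'   `position` column (e.g. from [read_known_haplotypes()]).
#' @return One-row tibble: `tool_name`, `inferred_total`, `overlap_count`,
#'   `overlap_pct` (half-up, 2 decimals).
#' @export
#' @examples
#' p <- phasing(tibble::tibble(
#'   block_id = "b", position = c(10L, 20L, 30L), h1 = c(0L, 1L, 0L)
#' ), normalized = TRUE)
#' position_overlap(p, c(20L, 30L, 40L, 50L))
position_overlap <- function(result, known) {
  assert_normalized(result, "result")
  if (nrow(result) == 0L) {
    hc_abort("cannot compute overlap for an empty result", "empty_input_error")
  }
  if (is.data.frame(known)) known <- known$position
  known <- unique(as.integer(known))
  inferred <- unique(result$position[phased_rows(result)])
  overlap <- sum(inferred %in% known)
  tibble(
    tool_name = phasing_tool(result),
    inferred_total = length(inferred),
    overlap_count = overlap,
    overlap_pct = round_half_up(100 * overlap / length(inferred), 2)
  )
}

#' Restrict a phasing result to a set of positions
#'
#' Drops every site whose position is outside `keep`, then re-applies the
#' singleton rule (blocks left with fewer than two sites are removed).
#' Block labels and internal order are preserved. This is how a
#' position-filtered companion result (e.g. restricting a long-block tool
#' to the positions other tools inferred) is built; note that filtering
#' fragments long blocks and can therefore increase downstream switch
#' counts.
#'
#' @param result A normalized `phasing` object.
#' @param keep Positions to keep: integer vector or data frame with a
#'   `position` column.
#' @return A normalized `phasing` object.
#' @export
filter_to_positions <- function(result, keep) {
  assert_normalized(result, "result")
  if (is.data.frame(keep)) keep <- keep$position
  keep <- unique(as.integer(keep))
  out <- as_tibble(result)
  out <- out[out$position %in% keep, , drop = FALSE]
  if (nrow(out) > 0L) {
    big <- names(which(table(out$block_id) >= 2L))
    out <- out[out$block_id %in% big, , drop = FALSE]
  }
  rebuild_phasing(out, result, normalized = TRUE)
}

#' Positions shared by two phasing results
#'
#' The intersection of the phased position sets, typically used as the
#' `keep` set for [filter_to_positions()].
#'
#' @param a,b Normalized `phasing` objects.
#' @return Sorted integer vector of shared positions.
#' @export
intersect_positions <- function(a, b) {
  assert_normalized(a, "a")
  assert_normalized(b, "b")
  sort(intersect(a$position[phased_rows(a)], b$position[phased_rows(b)]))
}

#' Read / write position sets
#'
#' `read_positions()` accepts either a single-column list of 1-based
#' positions or a 3-column BED-like file (`chrom`, `start`, `end`; 0-based
#' half-open, converted to 1-based points). `write_positions()` writes the
#' single-column form.
#'
#' @param path File path.
#' @param positions Integer vector of 1-based positions.
#' @return `read_positions()`: sorted integer vector.
#' @export
read_positions <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) return(integer())
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- unique(lengths(fields))
  if (identical(nf, 1L)) {
    pos <- as.integer(vapply(fields, `[[`, character(1), 1L))
  } else if (identical(nf, 3L)) {
    start <- as.integer(vapply(fields, `[[`, character(1), 2L))
    end <- as.integer(vapply(fields, `[[`, character(1), 3L))
    pos <- unlist(Map(function(s, e) seq.int(s + 1L, e), start, end))
  } else {
    hc_abort("position files must have 1 column or 3 BED-like columns",
             "parse_error")
  }
  if (anyNA(pos)) hc_abort("non-numeric entry in position file", "parse_error")
  sort(unique(pos))
}

#' @rdname read_positions
#' @export
write_positions <- function(positions, path) {
  readr::write_lines(as.integer(sort(unique(positions))), path)
  invisible(path)
}

#' Per-position read depth from a fragment set
#'
#' Depth of a position is the number of fragments whose allele calls cover
#' it.
#'
#' @param fragments A `fragment_set` whose index-to-position map is set.
#' @return Tibble with columns `variant_index`, `position`, `depth`.
#' @export
site_depths <- function(fragments) {
  if (!inherits(fragments, "fragment_set")) {
    hc_abort("`fragments` must be a fragment_set", "usage_error")
  }
  map <- attr(fragments, "index_to_position")
  if (is.null(map)) {
    hc_abort("fragment set has no index-to-position map", "mapping_error")
  }
  calls <- as_tibble(fragments)
  if (nrow(calls) == 0L) {
    return(tibble(variant_index = integer(), position = integer(),
                  depth = integer()))
  }
  unmapped <- setdiff(unique(calls$variant_index), map$variant_index)
  if (length(unmapped) > 0L) {
    hc_abort(
      paste0("variant index without a mapped position: ",
             paste(head(unmapped, 3L), collapse = ", ")),
      "mapping_error"
    )
  }
  calls |>
    group_by(.data$variant_index) |>
    summarise(depth = n(), .groups = "drop") |>
    left_join(map, by = "variant_index") |>
    select("variant_index", "position", "depth") |>
    arrange(.data$variant_index)
}

#' Depth-filter a fragment set
#'
#' Emulates coverage (DP) filtering at the fragment level: positions whose
#' depth is below `min_depth` are masked out of every fragment, and
#' fragments left covering fewer than two variants are removed as
#' non-informative (a read linking one site asserts no phase). Filtering
#' is monotone in `min_depth`: raising the threshold can only shrink the
#' site and fragment sets, and `min_depth = 1` removes nothing but
#' single-variant fragments.
#'
#' @param fragments A `fragment_set`.
#' @param min_depth Minimum depth a position must have (DP level, >= 1).
#' @return A filtered `fragment_set` (same `n_variants` and position map).
#' @export
filter_by_depth <- function(fragments, min_depth) {
  if (!inherits(fragments, "fragment_set")) {
    hc_abort("`fragments` must be a fragment_set", "usage_error")
  }
  min_depth <- as.integer(min_depth)
  if (is.na(min_depth) || min_depth < 1L) {
    hc_abort("`min_depth` must be an integer >= 1", "usage_error")
  }
  calls <- as_tibble(fragments)
  if (nrow(calls) > 0L) {
    depth <- table(calls$variant_index)
    masked <- as.integer(names(depth)[depth < min_depth])
    calls <- calls[!calls$variant_index %in% masked, , drop = FALSE]
    keep <- calls |>
      group_by(.data$fragment_id) |>
      summarise(nv = n(), .groups = "drop") |>
      filter(.data$nv >= 2L)
    calls <- calls[calls$fragment_id %in% keep$fragment_id, , drop = FALSE]
  }
  new_fragment_set(calls, attr(fragments, "n_variants"),
                   attr(fragments, "index_to_position"))
}
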