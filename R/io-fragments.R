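# extractHAIRS-style fragment files: haplotype-informative reads encoded as
#   <n_segments> <fragment_id> <start_1> <alleles_1> ... <start_k> <alleles_k> <qualities>
# where start indices are 1-based variant indices into the input VCF and
# allele strings are over {0,1}. Qualities are read for validation but not
# otherwise used: depth filtering counts coverage only.

new_fragment_set <- function(calls, n_variants, index_to_position) {
  new_tibble(
    calls,
    nrow = nrow(calls),
    n_variants = as.integer(n_variants),
    index_to_position = index_to_position,
    class = "fragment_set"
  )
}

#' Construct a fragment set
#'
#' A fragment set is a long tibble of per-read allele calls: one row per
#' (fragment, variant) pair with the observed allele and its quality
#' character. The variant-index-to-position map (needed to express depths
#' in chromosomal coordinates) travels with the object.
#'
#' @param calls Data frame with columns `fragment_id`, `segment` (segment
#'   number within the fragment), `variant_index` (1-based), `allele`
#'   (0/1), `quality` (single character).
#' @param n_variants Total number of indexed variants; defaults to the
#'   largest index seen.
#' @param index_to_position Optional tibble with columns `variant_index`
#'   and `position` mapping indices to chromosomal coordinates.
#' @return A `fragment_set` tibble.
#' @export
fragment_set <- function(calls, n_variants = NULL, index_to_position = NULL) {
  calls <- as_tibble(calls)
  need <- c("fragment_id", "segment", "variant_index", "allele", "quality")
  if (!all(need %in% names(calls))) {
    hc_abort(paste0("`calls` needs columns ", paste(need, collapse = ", ")),
             "usage_error")
  }
  calls <- tibble(
    fragment_id = as.character(calls$fragment_id),
    segment = as.integer(calls$segment),
    variant_index = as.integer(calls$variant_index),
    allele = as.integer(calls$allele),
    quality = as.character(calls$quality)
  )
  if (any(!calls$allele %in% c(0L, 1L))) {
    hc_abort("fragment alleles must be 0 or 1", "parse_error")
  }
  # within a fragment, indices must be strictly increasing (segments are
  # non-overlapping and ordered)
  bad <- calls |>
    group_by(.data$fragment_id) |>
    summarise(ok = all(diff(.data$variant_index) > 0L) || n() == 1L) |>
    filter(!.data$ok)
  if (nrow(bad) > 0L) {
    hc_abort(
      paste0("fragment(s) with non-increasing variant indices: ",
             paste(head(bad$fragment_id, 3L), collapse = ", ")),
      "parse_error"
    )
  }
  n_variants <- as.integer(n_variants %||% max(calls$variant_index, 0L))
  if (nrow(calls) > 0L && max(calls$variant_index) > n_variants) {
    hc_abort("a segment index exceeds n_variants", "parse_error")
  }
  if (!is.null(index_to_position)) {
    index_to_position <- as_tibble(index_to_position)[c("variant_index", "position")]
    index_to_position$variant_index <- as.integer(index_to_position$variant_index)
    index_to_position$position <- as.integer(index_to_position$position)
  }
  new_fragment_set(calls, n_variants, index_to_position)
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf(
    "<fragment_set: %d allele calls in %d fragments over %d variants>\n",
    nrow(x), length(unique(x$fragment_id)), attr(x, "n_variants")
  ))
  NextMethod()
}

#' Read an extractHAIRS-style fragment file
#'
#' @param path Path to a plain or gzip-compressed fragment file.
#' @param index_to_position Optional index-to-position map (tibble with
#'   columns `variant_index`, `position`), required later by
#'   [site_depths()].
#' @param n_variants Optional total variant count.
#' @return A `fragment_set`.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines("2 frag1 3 01 9 1 ABC", f)
#' read_fragments(f)
read_fragments <- function(path, index_to_position = NULL, n_variants = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(fragment_set(
      tibble(fragment_id = character(), segment = integer(),
             variant_index = integer(), allele = integer(),
             quality = character()),
      n_variants = n_variants %||% 0L,
      index_to_position = index_to_position
    ))
  }
  rows <- lapply(lines, function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    k <- suppressWarnings(as.integer(tok[1]))
    if (is.na(k) || length(tok) != 2L + 2L * k + 1L) {
      hc_abort(paste0("malformed fragment line: ", substr(ln, 1, 60)),
               "parse_error")
    }
    id <- tok[2]
    starts <- as.integer(tok[seq(3L, by = 2L, length.out = k)])
    alleles <- tok[seq(4L, by = 2L, length.out = k)]
    qual <- tok[length(tok)]
    if (any(grepl("[^01]", alleles))) {
      hc_abort(paste0("non-binary allele string in fragment ", id),
               "parse_error")
    }
    n_calls <- sum(nchar(alleles))
    if (n_calls != nchar(qual)) {
      hc_abort(
        paste0("fragment ", id, ": ", n_calls, " allele call(s) but ",
               nchar(qual), " quality character(s)"),
        "parse_error"
      )
    }
    idx <- unlist(lapply(seq_len(k), function(i) {
      starts[i] + seq_len(nchar(alleles[i])) - 1L
    }))
    seg <- rep(seq_len(k), times = nchar(alleles))
    tibble(
      fragment_id = id,
      segment = seg,
      variant_index = idx,
      allele = as.integer(strsplit(paste(alleles, collapse = ""), "")[[1]]),
      quality = strsplit(qual, "")[[1]]
    )
  })
  fragment_set(bind_rows(rows),
    n_variants = n_variants, index_to_position = index_to_position
  )
}

#' Write a fragment set in extractHAIRS layout
#'
#' Allele calls are re-grouped into maximal runs of consecutive variant
#' indices (the canonical segmentation extractHAIRS itself emits).
#'
#' @param x A `fragment_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(x, path) {
  if (!inherits(x, "fragment_set")) {
    hc_abort("`x` must be a fragment_set", "usage_error")
  }
  ids <- unique(x$fragment_id)
  out <- vapply(ids, function(id) {
    f <- x[x$fragment_id == id, , drop = FALSE]
    f <- f[order(f$variant_index), , drop = FALSE]
    run <- cumsum(c(1L, diff(f$variant_index) != 1L))
    segs <- vapply(split(seq_len(nrow(f)), run), function(i) {
      paste(f$variant_index[i][1], paste(f$allele[i], collapse = ""))
    }, character(1))
    paste(length(segs), id, paste(segs, collapse = " "),
          paste(f$quality, collapse = ""))
  }, character(1))
  readr::write_lines(out, path)
  invisible(path)
}

#' Per-fragment coverage and informativeness
#'
#' A fragment covering a single variant cannot link any pair of sites and
#' is therefore not haplotype-informative, although it still contributes to
#' depth.
#'
#' @param x A `fragment_set`.
#' @return Tibble with columns `fragment_id`, `n_covered`, `informative`.
#' @export
fragment_coverage <- function(x) {
  if (!inherits(x, "fragment_set")) {
    hc_abort("`x` must be a fragment_set", "usage_error")
  }
  as_tibble(x) |>
    group_by(.data$fragment_id) |>
    summarise(n_covered = n(), .groups = "drop") |>
    mutate(informative = .data$n_covered >= 2L)
}
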