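#' Place a query fragment on a reference sequence
#'
#' Scans every ungapped placement of the query (and of its reverse
#' complement) along the reference and returns the placement with the most
#' matching sites. Identity is `matches / query_length`; positions where
#' either sequence carries a gap, `N` or an ambiguity code never count as
#' matches. Ties are broken in favour of the forward strand, then the
#' leftmost placement. If the best identity falls below `min_identity`
#' an *unmapped* result is returned rather than an error, so callers can
#' branch on `mapped`.
#'
#' @param query query fragment (string), no longer than the reference.
#' @param reference reference sequence (string).
#' @param min_identity minimum acceptable identity in \[0, 1\].
#' @param reference_id label stored in the mapping.
#' @return object of class `fragment_mapping`: list with `mapped` (logical),
#'   and when mapped `reference_id`, `ref_start`, `ref_end` (1-based
#'   inclusive), `strand` (`"forward"`/`"reverse"`), `identity`,
#'   `fragment_length`.
#' @examples
#' rf <- generate_reference_and_fragment(600, 451, 554, seed = 7)
#' map_fragment(rf$fragment, rf$reference)
#' @export
map_fragment <- function(query, reference, min_identity = 0.8,
                         reference_id = "reference") {
  q <- strsplit(.norm_string(query), "", fixed = TRUE)[[1L]]
  r <- strsplit(.norm_string(reference), "", fixed = TRUE)[[1L]]
  lq <- length(q); lr <- length(r)
  if (lq == 0L || lr == 0L) stop("empty sequence")
  if (lq > lr) stop("query longer than reference")

  scan <- function(qc) {
    q_ok <- .is_state(qc)
    best <- -1L; best_off <- NA_integer_
    for (off in 0:(lr - lq)) {
      win <- r[(off + 1L):(off + lq)]
      m <- sum(qc == win & q_ok & .is_state(win))
      if (m > best) { best <- m; best_off <- off }
    }
    list(matches = best, offset = best_off)
  }

  fwd <- scan(q)
  rev <- scan(strsplit(.revcomp(paste(q, collapse = "")), "",
                       fixed = TRUE)[[1L]])
  if (fwd$matches >= rev$matches) {
    strand <- "forward"; hit <- fwd
  } else {
    strand <- "reverse"; hit <- rev
  }
  identity <- hit$matches / lq
  if (identity < min_identity) {
    return(structure(list(mapped = FALSE, reference_id = reference_id,
                          fragment_length = lq, best_identity = identity),
                     class = "fragment_mapping"))
  }
  structure(list(mapped = TRUE,
                 reference_id = reference_id,
                 ref_start = hit$offset + 1L,
                 ref_end = hit$offset + lq,
                 strand = strand,
                 identity = identity,
                 fragment_length = lq),
            class = "fragment_mapping")
}

#' Construct a fragment mapping from known coordinates
#'
#' Useful when the reference placement is already known (e.g. published
#' coordinates) and only the coordinate conversion is needed.
#'
#' @param ref_start,ref_end 1-based inclusive reference coordinates.
#' @param strand `"forward"` or `"reverse"`.
#' @param identity match fraction in \[0, 1\].
#' @param reference_id reference label.
#' @return a `fragment_mapping`.
#' @export
fragment_mapping <- function(ref_start, ref_end, strand = "forward",
                             identity = 1, reference_id = "reference") {
  ref_start <- as.integer(ref_start); ref_end <- as.integer(ref_end)
  if (ref_start < 1L || ref_end < ref_start) stop("require 1 <= ref_start <= ref_end")
  strand <- match.arg(strand, c("forward", "reverse"))
  if (identity < 0 || identity > 1) stop("identity must lie in [0, 1]")
  structure(list(mapped = TRUE, reference_id = reference_id,
                 ref_start = ref_start, ref_end = ref_end, strand = strand,
                 identity = identity,
                 fragment_length = ref_end - ref_start + 1L),
            class = "fragment_mapping")
}

#' @export
print.fragment_mapping <- function(x, ...) {
  if (!isTRUE(x$mapped)) {
    cat("Fragment mapping: UNMAPPED (best identity ",
        format(x$best_identity, digits = 3), ")\n", sep = "")
    return(invisible(x))
  }
  cat("Fragment mapping: ", x$reference_id, ":", x$ref_start, "-",
      x$ref_end, " (", x$strand, "), length ", x$fragment_length,
      ", identity ", format(x$identity, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Convert a reference coordinate to a fragment coordinate
#'
#' On the forward strand `fragment_pos = ref_pos - ref_start + 1`; the
#' reverse strand mirrors the window. Coordinates are 1-based inclusive.
#'
#' @param mapping a mapped `fragment_mapping`.
#' @param ref_pos reference position(s) inside the mapped window.
#' @return integer fragment position(s).
#' @examples
#' m <- fragment_mapping(451, 554)
#' ref_to_fragment(m, c(474, 550))   # 24, 100
#' @export
ref_to_fragment <- function(mapping, ref_pos) {
  .check_mapped(mapping)
  ref_pos <- as.integer(ref_pos)
  if (any(ref_pos < mapping$ref_start | ref_pos > mapping$ref_end))
    stop("reference position outside the mapped window [",
         mapping$ref_start, ", ", mapping$ref_end, "]")
  if (mapping$strand == "forward") ref_pos - mapping$ref_start + 1L
  else mapping$ref_end - ref_pos + 1L
}

#' Convert a fragment coordinate to a reference coordinate
#'
#' Exact inverse of [ref_to_fragment()].
#'
#' @param mapping a mapped `fragment_mapping`.
#' @param fragment_pos position(s) in `[1, fragment_length]`.
#' @return integer reference position(s).
#' @export
fragment_to_ref <- function(mapping, fragment_pos) {
  .check_mapped(mapping)
  fragment_pos <- as.integer(fragment_pos)
  if (any(fragment_pos < 1L | fragment_pos > mapping$fragment_length))
    stop("fragment position outside [1, ", mapping$fragment_length, "]")
  if (mapping$strand == "forward") mapping$ref_start + fragment_pos - 1L
  else mapping$ref_end - fragment_pos + 1L
}

.check_mapped <- function(mapping) {
  if (!inherits(mapping, "fragment_mapping") || !isTRUE(mapping$mapped))
    stop("need a successfully mapped 'fragment_mapping'")
}

#' Write a fragment mapping as a one-row TSV
#' @param mapping a `fragment_mapping`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mapping_tsv <- function(mapping, path) {
  .check_mapped(mapping)
  df <- data.frame(reference_id = mapping$reference_id,
                   start = mapping$ref_start, end = mapping$ref_end,
                   strand = mapping$strand, identity = mapping$identity)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
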